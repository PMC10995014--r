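test_that("population MESOR is the mean of individual MESORs", {
  set.seed(31)
  fits <- cohort_fits(12, 80, 10, 1.8)
  pop <- population_cosinor(fits)
  expect_equal(pop$mesor, mean(vapply(fits, `[[`, numeric(1), "mesor")))
  # amplitude/acrophase come from the averaged coefficients
  bbar <- mean(vapply(fits, `[[`, numeric(1), "beta"))
  gbar <- mean(vapply(fits, `[[`, numeric(1), "gamma"))
  expect_equal(pop$amplitude, sqrt(bbar^2 + gbar^2))
  expect_equal(pop$acrophase, atan2(gbar, bbar) %% (2 * pi))
})

test_that("identical subject fits collapse to the common parameters", {
  set.seed(4)
  f <- fit_from_params(82, 9, 2.0, noise_sd = 0.5)
  pop <- population_cosinor(list(f, f, f, f))
  expect_equal(pop$mesor, f$mesor)
  expect_equal(pop$amplitude, f$amplitude)
  expect_equal(pop$acrophase, f$acrophase)
  expect_equal(unname(diff(pop$ci["mesor", ])), 0)
})

test_that("rhythm detection uses df (2, k-2)", {
  set.seed(8)
  for (k in c(29, 30)) {
    pop <- population_cosinor(cohort_fits(k, 85, 12, 1.8))
    expect_equal(pop$df, c(2, k - 2))
    expect_lt(pop$p.value, 0.001)  # strong rhythm present
  }
  expect_error(population_cosinor(cohort_fits(2, 80, 10, 1)), "at least 3")
})

test_that("population CIs bracket the estimates and degrade gracefully", {
  set.seed(12)
  pop <- population_cosinor(cohort_fits(20, 80, 10, 1.8))
  expect_lt(pop$ci["mesor", 1], pop$mesor)
  expect_gt(pop$ci["mesor", 2], pop$mesor)
  expect_lt(pop$ci["amplitude", 1], pop$amplitude)
  # no detectable rhythm: amplitude CI spans 0 and the acrophase CI is NA
  null_pop <- population_cosinor(cohort_fits(10, 80, 0, 0, amp_sd = 6,
                                             acro_sd = 2, noise_sd = 4))
  if (null_pop$ci["amplitude", 1] <= 0) {
    expect_true(all(is.na(null_pop$ci["acrophase", ])))
  }
})

test_that("two-group comparisons report df2 = k1 + k2 - 2", {
  set.seed(14)
  p1 <- population_cosinor(cohort_fits(29, 86, 12.4, 1.81), "NSSI")
  p2 <- population_cosinor(cohort_fits(30, 79, 12.3, 1.56), "HC")
  cmp <- compare_rhythms(p1, p2)
  expect_equal(cmp$mesor_test$df, c(1, 57))
  expect_equal(cmp$acrophase_test$df, c(1, 57))
  if (cmp$amplitude_test$method == "t_test") {
    expect_equal(cmp$amplitude_test$df, 57)
  } else {
    expect_equal(cmp$amplitude_test$df, c(1, 57))
  }
})

test_that("comparing a population with itself is null across the board", {
  set.seed(19)
  pop <- population_cosinor(cohort_fits(15, 80, 10, 2.0), "G")
  cmp <- compare_rhythms(pop, pop)
  expect_equal(cmp$mesor_test$F, 0, tolerance = 1e-12)
  expect_equal(cmp$acrophase_test$F, 0, tolerance = 1e-12)
  expect_equal(cmp$amplitude_test$method, "bingham")
  expect_equal(cmp$amplitude_test$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$mesor_g$g, 0, tolerance = 1e-12)
  expect_equal(cmp$acrophase_shift$hours, 0)
})

test_that("the amplitude method switches to a t test when acrophases differ", {
  set.seed(23)
  p1 <- population_cosinor(cohort_fits(25, 80, 10, 1.0, acro_sd = 0.1))
  p2 <- population_cosinor(cohort_fits(25, 80, 10, 3.0, acro_sd = 0.1))
  cmp <- compare_rhythms(p1, p2)
  expect_lt(cmp$acrophase_test$p.value, 0.05)
  expect_equal(cmp$amplitude_test$method, "t_test")
  # pooled t on individual amplitudes, cross-checked with t.test
  tt <- t.test(p1$amplitudes, p2$amplitudes, var.equal = TRUE)
  expect_equal(cmp$amplitude_test$statistic, unname(tt$statistic))
  expect_equal(cmp$amplitude_test$p.value, tt$p.value)
})

test_that("mismatched outcomes are refused", {
  set.seed(3)
  p1 <- population_cosinor(cohort_fits(5, 80, 10, 1, outcome = "HR"))
  p2 <- population_cosinor(cohort_fits(5, 40, 10, 5, outcome = "RMSSD"))
  expect_error(compare_rhythms(p1, p2), "different outcomes")
})

test_that("hedges_g matches hand-computed small-sample values", {
  g <- hedges_g(c(1, 2, 3), c(2, 3, 4))
  expect_equal(g$d, -1)
  expect_equal(g$J, 0.8)
  expect_equal(g$g, -0.8)
  expect_equal(hedges_g(c(1, 2, 3), c(0, 2, 4))$g, 0)
  expect_true(is.na(hedges_g(c(2, 2), c(2, 2))$g))
})

test_that("acrophase conversions follow circular arithmetic", {
  expect_equal(acrophase_diff_hours(1.2, 1.2), 0)
  expect_equal(acrophase_diff_hours(pi, 0), 12)
  expect_equal(acrophase_diff_hours(5.02, 4.73), 0.29 * 24 / (2 * pi))
  # wrapping picks the minimal signed arc
  expect_equal(acrophase_diff_hours(0.1, 6.2),
               (0.1 - 6.2 + 2 * pi) * 24 / (2 * pi))
  expect_equal(rad_to_clock(0), 0)
  expect_equal(rad_to_clock(pi / 2), 6)
  expect_equal(rad_to_clock(1.81), 1.81 * 24 / (2 * pi))
  expect_equal(rad_to_clock(pi / 2, reference = 22), 4)
  # sign-convention converter is an involution
  expect_equal(acrophase_convention(acrophase_convention(1.81)), 1.81)
  expect_equal(acrophase_convention(1.81), 1.81 - 2 * pi)
})
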