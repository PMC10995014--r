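test_that("spearman correlations handle monotone, tied and constant data", {
  d <- data.frame(a = 1:10, b = (1:10)^3, c = 10:1)
  sp <- spearman_matrix(d)
  expect_equal(sp$rho["a", "b"], 1)
  expect_equal(sp$rho["a", "c"], -1)
  # mid-rank tie handling, hand-computed: ranks of x are (1, 2.5, 2.5, 4),
  # rank cross-products 4.5 over sqrt(4.5 * 5)
  d2 <- data.frame(x = c(1, 2, 2, 3), y = c(1, 2, 3, 4))
  expect_equal(spearman_matrix(d2)$rho["x", "y"],
               4.5 / sqrt(4.5 * 5), tolerance = 1e-10)
  # constant columns give NA, invariance under monotone transforms
  d3 <- data.frame(x = rnorm(10), k = rep(1, 10))
  expect_true(is.na(spearman_matrix(d3)$rho["x", "k"]))
  set.seed(2)
  d4 <- data.frame(u = rnorm(30), v = rnorm(30))
  expect_equal(spearman_matrix(d4)$rho["u", "v"],
               spearman_matrix(data.frame(u = exp(d4$u), v = d4$v))$rho["u", "v"])
})

test_that("an outcome regressed on itself has standardized B = 1", {
  set.seed(6)
  d <- data.frame(y = rnorm(40))
  d$y2 <- d$y
  r <- fit_univariate_models(d, "y", "y2")
  expect_equal(r$coefficients$estimate[r$coefficients$term == "y2"], 1,
               tolerance = 1e-10)
})

test_that("collinear designs fail with the offending column named", {
  set.seed(7)
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  d$x2 <- 2 * d$x
  expect_error(
    fit_univariate_models(d, "y", "x", covariates = "x2", adjust = TRUE),
    "collinear")
})

test_that("null predictors estimate near-zero standardized coefficients", {
  set.seed(8)
  n <- 10000
  d <- data.frame(y = rnorm(n), x = rnorm(n))
  r <- fit_univariate_models(d, "y", "x")
  b <- r$coefficients$estimate[r$coefficients$term == "x"]
  expect_lt(abs(b), 3 / sqrt(n))
})

test_that("confounders uncorrelated with the group leave its coefficient stable", {
  set.seed(9)
  n <- 4000
  grp <- rep(c("A", "B"), each = n / 2)
  d <- data.frame(group = grp,
                  age = rnorm(n, 15, 1.3), bmi = rnorm(n, 21, 3),
                  step_count = rnorm(n, 11000, 5000),
                  valid_segments = rnorm(n, 470, 120))
  d$y <- 80 + 6 * (grp == "B") + rnorm(n, 0, 8)
  r0 <- fit_univariate_models(d, "y", "group")
  r1 <- fit_univariate_models(d, "y", "group", adjust = TRUE)
  b0 <- r0$coefficients$estimate[r0$coefficients$term == "group"]
  b1 <- r1$coefficients$estimate[r1$coefficients$term == "group"]
  expect_lt(abs(b0 - b1), 0.05)
  expect_gt(b0, 0)  # B level coded 1
})

test_that("standardized coefficients are scale invariant", {
  set.seed(10)
  d <- data.frame(y = rnorm(50), x = rnorm(50))
  b1 <- fit_univariate_models(d, "y", "x")$coefficients$estimate[2]
  d$x <- d$x * 1000
  b2 <- fit_univariate_models(d, "y", "x")$coefficients$estimate[2]
  expect_equal(b1, b2, tolerance = 1e-10)
})

test_that("multivariate fits equal stacked univariate fits with shared regressors", {
  set.seed(11)
  n <- 59
  d <- data.frame(group = rep(c("A", "B"), length.out = n),
                  mesor = rnorm(n, 80, 8), amplitude = rnorm(n, 12, 4),
                  acrophase = rnorm(n, 1.8, 0.5))
  mv <- fit_multivariate_model(d, c("mesor", "amplitude", "acrophase"), "group")
  expect_equal(mv$n, 59)
  for (oc in c("mesor", "amplitude", "acrophase")) {
    uni <- fit_univariate_models(d, oc, "group")
    got <- mv$coefficients[mv$coefficients$outcome == oc, ]
    expect_equal(got$estimate, uni$coefficients$estimate, tolerance = 1e-10)
    expect_equal(got$p_z, uni$coefficients$p_z, tolerance = 1e-10)
  }
})

test_that("subjects with incomplete outcome triplets are dropped with a message", {
  set.seed(12)
  d <- data.frame(group = rep(c("A", "B"), 10),
                  mesor = rnorm(20), amplitude = rnorm(20),
                  acrophase = rnorm(20))
  d$amplitude[3] <- NA
  expect_message(
    mv <- fit_multivariate_model(d, c("mesor", "amplitude", "acrophase"),
                                 "group"),
    "dropping 1")
  expect_equal(mv$n, 19)
})

test_that("both z and t p-values are reported, z slightly smaller", {
  set.seed(13)
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  r <- fit_univariate_models(d, "y", "x")
  row <- r$coefficients[r$coefficients$term == "x", ]
  expect_true(row$p_z <= row$p_t)
  expect_true(all(c(row$p_z, row$p_t) >= 0 & c(row$p_z, row$p_t) <= 1))
})

test_that("BH adjustment adds a p_adj column without touching the intercept", {
  set.seed(14)
  d <- data.frame(y = rnorm(30), x = rnorm(30), z = rnorm(30))
  r <- fit_univariate_models(d, "y", "x", covariates = "z", adjust = TRUE)
  r2 <- adjust_pvalues(r)
  expect_true("p_adj" %in% names(r2$coefficients))
  expect_true(is.na(r2$coefficients$p_adj[r2$coefficients$term == "(Intercept)"]))
})
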