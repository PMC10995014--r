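test_that("noiseless cosines are recovered exactly", {
  t <- c(0, 6, 12, 18)
  y <- 80 + 10 * cos(2 * pi * t / 24 - pi / 2)
  f <- cosinor_fit(t, y)
  expect_equal(f$mesor, 80, tolerance = 1e-10)
  expect_equal(f$amplitude, 10, tolerance = 1e-10)
  expect_equal(f$acrophase, pi / 2, tolerance = 1e-10)

  # arbitrary phase/amplitude/sampling patterns
  set.seed(7)
  for (i in 1:20) {
    M <- runif(1, 40, 100); A <- runif(1, 0.5, 20)
    phi <- runif(1, 0, 2 * pi)
    tt <- sort(runif(12, 0, 48))
    yy <- M + A * cos(2 * pi * tt / 24 - phi)
    ff <- cosinor_fit(tt, yy)
    expect_equal(ff$mesor, M, tolerance = 1e-8)
    expect_equal(ff$amplitude, A, tolerance = 1e-8)
    expect_equal(ff$acrophase, phi, tolerance = 1e-8)
  }
})

test_that("constant data give zero amplitude and a null rhythm test", {
  f <- cosinor_fit(c(0, 5, 11, 16, 21), rep(70, 5))
  expect_equal(f$amplitude, 0, tolerance = 1e-10)
  zt <- zero_amplitude_test(f)
  expect_equal(unname(zt$statistic), 0, tolerance = 1e-10)
})

test_that("fits agree with the brute-force normal-equations oracle", {
  set.seed(123)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    tt <- sort(runif(n, 0, 48))
    yy <- runif(1, 50, 90) +
      runif(1, 0, 15) * cos(2 * pi * tt / 24 - runif(1, 0, 2 * pi)) +
      rnorm(n, 0, 3)
    f <- cosinor_fit(tt, yy)
    o <- oracle_cosinor(tt, yy)
    expect_equal(f$mesor, unname(o$mesor), tolerance = 1e-8)
    expect_equal(f$beta, o$beta, tolerance = 1e-8)
    expect_equal(f$gamma, o$gamma, tolerance = 1e-8)
  }
})

test_that("degenerate designs raise a fit-failure condition", {
  expect_error(cosinor_fit(c(0, 24, 48, 72), c(1, 2, 3, 4)),
               class = "cosinor_fit_error")
  expect_error(cosinor_fit(c(0, 1, 2), c(1, 2, 3)),
               class = "cosinor_fit_error")
  expect_error(cosinor_fit(c(0, 1, 2, 3), c(1, 2, 3, 4)),
               class = "cosinor_fit_error")  # quarter-period span guard
})

test_that("the zero-amplitude test has the documented F form and df", {
  set.seed(9)
  tt <- seq(0, 45, length.out = 10)
  yy <- 70 + 5 * cos(2 * pi * tt / 24 - 1) + rnorm(10)
  f <- cosinor_fit(tt, yy)
  zt <- zero_amplitude_test(f)
  expect_equal(unname(zt$parameter), c(2, 7))
  expect_equal(unname(zt$statistic),
               ((f$tss - f$rss) / 2) / (f$rss / 7))
  # perfect fit: infinite F, p = 0
  y0 <- 70 + 5 * cos(2 * pi * tt / 24 - 1)
  zt0 <- zero_amplitude_test(cosinor_fit(tt, y0))
  expect_equal(zt0$p.value, 0)
})

test_that("acrophase arithmetic is rotation-equivariant", {
  set.seed(21)
  tt <- sort(runif(60, 0, 48))
  yy <- 75 + 8 * cos(2 * pi * tt / 24 - 2.2) + rnorm(60)
  f0 <- cosinor_fit(tt, yy)
  for (delta in c(3, 7.5, -5)) {
    f1 <- cosinor_fit(tt + delta, yy)
    expect_equal(f1$mesor, f0$mesor, tolerance = 1e-8)
    expect_equal(f1$amplitude, f0$amplitude, tolerance = 1e-8)
    shift <- (f1$acrophase - f0$acrophase) %% (2 * pi)
    expect_equal(shift, (2 * pi * delta / 24) %% (2 * pi), tolerance = 1e-8)
    expect_equal(zero_amplitude_test(f1)$statistic,
                 zero_amplitude_test(f0)$statistic, tolerance = 1e-8)
  }
})

test_that("methods behave like a standard model object", {
  set.seed(5)
  tt <- sort(runif(50, 0, 48))
  yy <- 75 + 8 * cos(2 * pi * tt / 24 - 2.2) + rnorm(50)
  f <- cosinor_fit(tt, yy)
  expect_named(coef(f), c("mesor", "amplitude", "acrophase", "beta", "gamma"))
  expect_equal(fitted(f) + residuals(f), yy)
  expect_equal(predict(f, 0), f$mesor + f$amplitude * cos(-f$acrophase))
  s1 <- simulate(f, nsim = 2, seed = 3)
  s2 <- simulate(f, nsim = 2, seed = 3)
  expect_identical(s1, s2)
  sm <- summary(f)
  expect_s3_class(sm, "summary.cosinor_fit")
  expect_true(all(sm$coef_table$se > 0))
  # formula interface is equivalent
  d <- data.frame(y = yy, t = tt)
  ff <- cosinor_fit(y ~ t, data = d)
  expect_equal(coef(ff), coef(f))
  expect_output(print(f), "MESOR")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
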