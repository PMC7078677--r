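test_that("area statistics handle constant and white-noise series", {
  const <- list(time = seq(0, 10, by = 0.125), area = rep(0.7, 81))
  s <- area_statistics(const, n_boot = 50)
  expect_equal(s$mean_area, 0.7)
  expect_equal(s$sd_area, 0)
  expect_equal(s$boot_sd_mean, 0)
  expect_equal(s$acf$acf, 1)

  set.seed(51)
  n <- 1e4
  wn <- list(time = (0:(n - 1)) * 0.125, area = rnorm(n))
  sw <- area_statistics(wn, n_boot = 50, lag_max = 20)
  expect_equal(sw$acf$acf[1], 1)
  expect_true(all(abs(sw$acf$acf[-1]) < 4 / sqrt(n)))
  expect_true(all(abs(sw$acf$acf) <= 1))
  # bootstrap SD of the mean ~ sd/sqrt(n) for i.i.d. data
  expect_equal(sw$boot_sd_mean, sd(wn$area) / sqrt(n), tolerance = 0.35)
})

test_that("area statistics pick up the focus lifetime log", {
  tr <- list(time = c(0, 0.125, 0.25), area = c(1, 1.1, 0.9),
             lifetimes = data.frame(id = 1:2, birth = c(0, 1),
                                    death = c(2, 4), lifetime = c(2, 3)))
  expect_equal(area_statistics(tr)$mean_lifetime, 2.5)
  expect_error(area_statistics(list(area = 1)), "at least 2")
})

test_that("Welch test agrees with the textbook formula", {
  manual_welch <- function(a, b) {
    va <- var(a) / length(a)
    vb <- var(b) / length(b)
    t <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    list(t = t, p = 2 * pt(-abs(t), df))
  }
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 6)
  w <- welch_test(a, b)
  m <- manual_welch(a, b)
  expect_equal(w$statistic, m$t, tolerance = 1e-10)
  expect_equal(w$p_value, m$p, tolerance = 1e-10)

  set.seed(52)
  x <- rnorm(12, 1, 2)
  y <- rnorm(7, 0.2, 0.5)
  w2 <- welch_test(x, y)
  m2 <- manual_welch(x, y)
  expect_equal(w2$statistic, m2$t, tolerance = 1e-10)
  expect_equal(w2$p_value, m2$p, tolerance = 1e-10)

  # symmetry and degenerate cases
  w3 <- welch_test(y, x)
  expect_equal(w3$statistic, -w2$statistic, tolerance = 1e-12)
  expect_equal(w3$p_value, w2$p_value, tolerance = 1e-12)
  wid <- welch_test(a, a)
  expect_equal(wid$statistic, 0)
  expect_equal(wid$p_value, 1)
  expect_error(welch_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("the area recursion has the advertised closed forms", {
  par0 <- list(m = 0, b = 0, Phi = 0, A0 = 0.8, A_s = 0.5)
  nf <- c(2L, 0L, 3L, 1L, 0L)
  expect_equal(predict_area(par0, nf)$predicted, rep(0.8, 5))

  par1 <- list(m = 0.01, b = 0, Phi = 0.2, A0 = 0.9, A_s = 0.5)
  dec <- predict_area(par1, rep(0L, 10))$predicted
  expect_equal(dec, 0.5 + (0.9 - 0.5) * 0.8^(1:10), tolerance = 1e-12)

  expect_error(predict_area(par1, integer(0)), "empty")
  ref <- dec + 0.01
  expect_equal(predict_area(par1, rep(0L, 10), reference = ref)$rmse, 0.01,
               tolerance = 1e-12)
})

test_that("the recursion matches an independent loop implementation", {
  set.seed(53)
  nf <- rpois(200, 1.5)
  par <- list(m = 3e-3, b = -4e-4, Phi = 2e-3, A0 = 0.75, A_s = 0.5)
  oracle <- recursive_area_series(par$m, par$b, par$Phi, par$A0, par$A_s, nf)
  expect_equal(predict_area(par, nf)$predicted, oracle, tolerance = 1e-12)
})

test_that("estimator fitting recovers known parameters", {
  set.seed(54)
  nf <- rpois(2000, 1.2)
  truth <- list(m = 3e-3, b = -5e-4, Phi = 2.5e-3, A0 = 0.8, A_s = 0.5)
  clean <- recursive_area_series(truth$m, truth$b, truth$Phi, truth$A0,
                                 truth$A_s, nf)
  fit <- fit_area_estimator(clean, nf, A_s = truth$A_s)
  expect_lt(fit$rmse, 1e-10)
  expect_equal(fit$m, truth$m, tolerance = 1e-6)
  expect_equal(fit$Phi, truth$Phi, tolerance = 1e-6)

  noisy <- clean + rnorm(length(clean), 0, 1e-4)
  fitn <- fit_area_estimator(noisy, nf, A_s = truth$A_s)
  expect_equal(fitn$m, truth$m, tolerance = 0.05)
  expect_equal(fitn$b, truth$b, tolerance = 0.05)
  expect_equal(fitn$Phi, truth$Phi, tolerance = 0.05)
  expect_equal(fitn$A0, truth$A0, tolerance = 0.05)
})

test_that("predictions stay bounded for any decay rate in (0,1)", {
  set.seed(55)
  for (i in 1:20) {
    par <- list(m = runif(1, 0, 0.01), b = runif(1, -0.001, 0.001),
                Phi = runif(1, 0.01, 0.99), A0 = runif(1, 0.3, 1),
                A_s = runif(1, 0.3, 0.7))
    nf <- rpois(500, 2)
    pred <- predict_area(par, nf)$predicted
    bound <- max(abs(par$A0), par$A_s +
                   (par$m * max(nf) + abs(par$b)) / par$Phi) + 1
    expect_true(all(is.finite(pred)))
    expect_true(all(abs(pred) <= bound))
  }
})

test_that("the linear area-change fit recovers a planted slope", {
  set.seed(56)
  nf <- rpois(3000, 1.5)
  darea <- 0.002 * nf - 0.0004 + rnorm(3000, 0, 0.001)
  area <- cumsum(c(0.7, darea))
  fit <- darea_foci_fit(area, c(0L, nf))
  expect_equal(fit$slope, 0.002, tolerance = 0.05)
  expect_equal(fit$intercept, -0.0004, tolerance = 0.2)
  expect_gt(fit$correlation, 0)
  expect_lt(fit$p_value, 1e-6)
})
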