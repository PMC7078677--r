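#' Summary statistics of an area trace
#'
#' Temporal mean and standard deviation of the spine area, the normalized
#' autocorrelation function of the demeaned area series (biased
#' normalization, as returned by [stats::acf()]), a bootstrap standard
#' deviation of the temporal mean (`n_boot` i.i.d. resamples of time points
#' with replacement; note that temporal autocorrelation makes this an
#' optimistic uncertainty), and the mean focus lifetime from the lifetime
#' log.
#'
#' @param trace A `spine_trace` object (or any list with `area`, optionally
#'   `lifetimes` and `time`).
#' @param n_boot Number of bootstrap resamples (default 50).
#' @param lag_max Maximum ACF lag in steps; defaults to
#'   `min(n/2, steps in 10 min)`.
#' @return A list with `mean_area`, `sd_area`, `acf` (data frame
#'   `lag_steps`, `lag_seconds`, `acf`), `boot_sd_mean`, `mean_lifetime`.
#' @export
area_statistics <- function(trace, n_boot = 50, lag_max = NULL) {
  x <- trace$area
  n <- length(x)
  if (n < 2L) stop("trace must contain at least 2 records", call. = FALSE)
  dt <- if (!is.null(trace$time) && length(trace$time) >= 2L)
    diff(trace$time[1:2]) else NA_real_
  if (is.null(lag_max)) {
    lag_max <- min(floor(n / 2), if (is.na(dt)) floor(n / 2)
                   else floor(600 / dt))
  }
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    acf_df <- data.frame(lag_steps = 0L, lag_seconds = 0, acf = 1)
    boot_sd <- 0
  } else {
    a <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)
    acf_df <- data.frame(lag_steps = as.integer(a$lag),
                         lag_seconds = as.numeric(a$lag) *
                           (if (is.na(dt)) 1 else dt),
                         acf = as.numeric(a$acf))
    boot_means <- vapply(seq_len(n_boot), function(i)
      mean(x[sample.int(n, n, replace = TRUE)]), numeric(1))
    boot_sd <- stats::sd(boot_means)
  }
  mean_lt <- if (!is.null(trace$lifetimes) && nrow(trace$lifetimes) > 0L)
    mean(trace$lifetimes$lifetime) else NA_real_
  list(mean_area = m, sd_area = s, acf = acf_df, boot_sd_mean = boot_sd,
       mean_lifetime = mean_lt)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom, used to
#' compare mean spine areas across replicate ensembles.
#'
#' @param sample_a,sample_b Numeric vectors (each of length >= 2, with
#'   positive variance in at least one).
#' @return A list with `statistic`, `p_value`, `df`.
#' @export
welch_test <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (isTRUE(all.equal(mean(sample_a), mean(sample_b)))) {
      # identical constant samples: no evidence of a difference
      return(list(statistic = 0, p_value = 1, df = NA_real_))
    }
    stop("Welch test undefined: both samples have zero variance",
         call. = FALSE)
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Forward evaluation of the recursive foci-count area estimator
#'
#' Evaluates the recursion
#' \deqn{\bar A(t_j) = \bar A(t_{j-1}) - \Phi(\bar A(t_{j-1}) - A_s)
#'   + m\, n_f(t_j) + b}
#' over a focus-count series, starting from `A0`.  `foci_series[j]` is
#' `n_f(t_j)` and drives the prediction at step `j`.
#'
#' @param params A list with `m`, `b`, `Phi`, `A0`, `A_s` (an
#'   `estimator_params` object from [fit_area_estimator()] works directly).
#' @param foci_series Integer vector of focus counts, one per step.
#' @param A0 Optional override of the initial value (e.g. to continue a
#'   fitted recursion past its training window).
#' @param reference Optional observed area series of the same length; when
#'   supplied the RMSE against it is returned.
#' @return A list with `predicted` (numeric vector, same length as
#'   `foci_series`) and `rmse` (`NA` when no reference is given).
#' @export
predict_area <- function(params, foci_series, A0 = NULL, reference = NULL) {
  if (length(foci_series) == 0L)
    stop("empty focus-count series", call. = FALSE)
  a0 <- if (is.null(A0)) params$A0 else A0
  drive <- params$Phi * params$A_s + params$m * foci_series + params$b
  pred <- as.numeric(stats::filter(drive, 1 - params$Phi,
                                   method = "recursive",
                                   init = a0))
  rmse <- NA_real_
  if (!is.null(reference)) {
    stopifnot(length(reference) == length(pred))
    rmse <- sqrt(mean((pred - reference)^2))
  }
  list(predicted = pred, rmse = rmse)
}

#' Fit the recursive foci-count area estimator
#'
#' Nonlinear least-squares fit of the parameters `(m, b, Phi, A0)` of the
#' recursion in [predict_area()] to an observed area series, driven by the
#' observed focus-count series.  The Levenberg-Marquardt routine of
#' \pkg{minpack.lm} minimises the sum of squared differences between the
#' recursively generated series and the observed areas over the training
#' window.  `Phi` is constrained to `[0, 1]`.  The fit starts from
#' `(m, b, Phi, A0) = (1e-3, 0, 1e-3, first observed area)`.
#'
#' @param area_series Observed area series (um^2), one value per step.
#' @param foci_series Focus counts aligned with `area_series`.
#' @param A_s Resting area (um^2).
#' @param train_window Integer indices into the series used for fitting;
#'   defaults to the whole series.
#' @return An object of class `estimator_params`: a list with the fitted
#'   `m`, `b`, `Phi`, `A0`, the supplied `A_s`, the training `rmse`, and the
#'   `fit` object from [minpack.lm::nls.lm()].
#' @export
fit_area_estimator <- function(area_series, foci_series, A_s,
                               train_window = seq_along(area_series)) {
  stopifnot(length(area_series) == length(foci_series),
            all(train_window >= 1L), all(train_window <= length(area_series)))
  a <- area_series[train_window]
  nf <- foci_series[train_window]
  resid_fun <- function(par) {
    p <- list(m = par[["m"]], b = par[["b"]], Phi = par[["Phi"]],
              A0 = par[["A0"]], A_s = A_s)
    predict_area(p, nf)$predicted - a
  }
  start <- c(m = 1e-3, b = 0, Phi = 1e-3, A0 = a[1])
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    lower = c(m = -Inf, b = -Inf, Phi = 0, A0 = -Inf),
    upper = c(m = Inf, b = Inf, Phi = 1, A0 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (fit$info < 1 || fit$info > 4) {
    stop("estimator fit did not converge: ", fit$message, call. = FALSE)
  }
  est <- as.list(fit$par)
  est$A_s <- A_s
  est$rmse <- sqrt(mean(fit$fvec^2))
  est$fit <- fit
  structure(est, class = "estimator_params")
}

#' @export
print.estimator_params <- function(x, ...) {
  cat(sprintf(
    "<estimator_params> m = %.6g, b = %.6g, Phi = %.6g, A0 = %.4f, A_s = %.4f (train RMSE %.4g)\n",
    x$m, x$b, x$Phi, x$A0, x$A_s, x$rmse))
  invisible(x)
}

#' Linear relation between area change and focus count
#'
#' Ordinary least-squares fit of the per-step first difference of the area
#' series on the concurrent number of active foci,
#' `diff(area)[j] ~ n_f[j+1]`.  Its slope and intercept are the direct,
#' non-recursive counterparts of the estimator coefficients `m` and `b`.
#'
#' @param area_series Observed area series.
#' @param foci_series Focus counts aligned with `area_series`.
#' @return A list with `slope`, `intercept`, the Pearson `correlation`
#'   between `n_f` and the area change, its `p_value`, and the `lm` fit.
#' @export
darea_foci_fit <- function(area_series, foci_series) {
  stopifnot(length(area_series) == length(foci_series),
            length(area_series) >= 3L)
  darea <- diff(area_series)
  nf <- foci_series[-1L]
  fit <- stats::lm(darea ~ nf)
  ct <- stats::cor.test(nf, darea)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = unname(ct$estimate), p_value = ct$p.value, lm = fit)
}
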