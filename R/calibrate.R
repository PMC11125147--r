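# Bayesian calibration: closed-form Gaussian-process posterior update of the
# baseline given one new day of measurements, and gap imputation from the
# posterior.

#' Calibrate a baseline against a new day of measurements
#'
#' Treats the baseline as the Gaussian-process prior over the day's
#' coefficient vector (mean `coef_mean`, covariance `coef_cov`) and conditions
#' on the new day's observations under the additive-noise model, giving the
#' standard conjugate update
#' \deqn{C^* = \bar C + \Sigma_C \Phi \,[\Phi' \Sigma_C \Phi + \sigma^2 I]^{-1}
#'       (Y^* - \Phi' \bar C),}
#' \deqn{\Sigma^* = \Sigma_C - \Sigma_C \Phi\,
#'       [\Phi' \Sigma_C \Phi + \sigma^2 I]^{-1} \Phi' \Sigma_C.}
#' The `N x N` system is solved by Cholesky factorization (never explicit
#' inversion); if factorization fails it is retried once with a jitter of
#' `1e-10` times the mean diagonal, and an informative error suggesting a
#' noise floor is raised if that also fails.  The posterior covariance is
#' symmetrized and eigenvalue-clipped after the update.  With zero
#' observations the posterior equals the prior exactly.
#'
#' @param baseline An [estimate_baseline()] (or [read_baseline()]) result.
#' @param new_day A [day_record()] with the newly collected measurements
#'   (may be empty).
#' @return An object of class `"hr_posterior"` with elements `coef_post`,
#'   `cov_post`, `baseline`, `new_day`.
#' @export
calibrate_day <- function(baseline, new_day) {
  stopifnot(inherits(baseline, "hr_baseline"), inherits(new_day, "day_record"))
  basis <- baseline$basis
  n <- length(new_day$values)
  if (n == 0L) {
    return(structure(
      list(coef_post = baseline$coef_mean, cov_post = baseline$coef_cov,
           baseline = baseline, new_day = new_day),
      class = "hr_posterior"))
  }
  check_in_domain(basis, new_day$timestamps)
  phi <- eval_basis(basis, new_day$timestamps)          # P x N
  sig <- baseline$coef_cov
  sphi <- sig %*% phi                                   # P x N
  if (max(abs(sphi)) == 0) {
    # infinitely confident prior: no data can move it
    return(structure(
      list(coef_post = baseline$coef_mean, cov_post = sig,
           baseline = baseline, new_day = new_day),
      class = "hr_posterior"))
  }
  a <- crossprod(phi, sphi)                             # Phi' Sigma Phi, N x N
  diag(a) <- diag(a) + baseline$noise_var
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-10 * mean(diag(a))
    ch <- tryCatch(chol(a + diag(jitter, n)), error = function(e) NULL)
    if (is.null(ch))
      stop("calibration system is numerically singular (zero noise variance ",
           "with a rank-deficient prior covariance?); set a noise floor via ",
           "the baseline's noise_var", call. = FALSE)
  }
  resid <- new_day$values - drop(crossprod(phi, baseline$coef_mean))
  solve_chol <- function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
  coef_post <- baseline$coef_mean + drop(sphi %*% solve_chol(resid))
  cov_post <- sig - sphi %*% solve_chol(t(sphi))
  structure(
    list(coef_post = coef_post, cov_post = psd_repair(cov_post),
         baseline = baseline, new_day = new_day),
    class = "hr_posterior"
  )
}

#' @export
print.hr_posterior <- function(x, ...) {
  cat(sprintf("hr_posterior: subject %s, calibrated on day %d (%d obs), P = %d\n",
              x$baseline$subject, x$new_day$day, length(x$new_day$values),
              x$baseline$basis$n_basis))
  invisible(x)
}

#' Calibrated (posterior) functional mean on a grid
#'
#' @param post A [calibrate_day()] result.
#' @param grid Numeric vector of times (hours) inside the basis domain.
#' @return Numeric vector of calibrated mean heart rates (bpm).
#' @export
posterior_mean <- function(post, grid) {
  stopifnot(inherits(post, "hr_posterior"))
  drop(crossprod(eval_basis(post$baseline$basis, grid), post$coef_post))
}

#' Calibrated curve with uncertainty band
#'
#' Same contract as [baseline_band()] but with the posterior coefficient mean
#' and covariance; the posterior band is pointwise never wider than the
#' baseline band (conditioning cannot increase variance).
#'
#' @inheritParams baseline_band
#' @param post A [calibrate_day()] result.
#' @return A `"curve_estimate"` data frame.
#' @export
posterior_band <- function(post, grid, k_sigma = 3, include_noise = FALSE) {
  stopifnot(inherits(post, "hr_posterior"))
  if (!is.numeric(k_sigma) || length(k_sigma) != 1L || k_sigma < 0)
    stop("invalid configuration: 'k_sigma' must be a single nonnegative number",
         call. = FALSE)
  grid <- as.numeric(grid)
  m <- posterior_mean(post, grid)
  s <- pointwise_sd(post$baseline$basis, post$cov_post, grid,
                    if (include_noise) post$baseline$noise_var else 0)
  new_curve_estimate(grid, m, s, k_sigma)
}

#' Impute heart rate over a gap with uncertainty
#'
#' Evaluates the calibrated posterior curve and band over a grid spanning a
#' data gap, and flags grid points that lie farther than `max_gap_hours` from
#' any observation of the calibrating day — there the curve is driven by the
#' prior, and the flag advertises extrapolation.  With an empty calibrating
#' day the result reproduces the baseline curve and band and every point is
#' flagged.
#'
#' @param post A [calibrate_day()] result.
#' @param gap_grid Numeric vector of times (hours) inside the basis domain.
#' @param k_sigma Band half-width in standard deviations (default 3).
#' @param include_noise Add the noise variance to the pointwise variance.
#' @param max_gap_hours Distance (hours) to the nearest observation beyond
#'   which a grid point is flagged as extrapolated (default 1).
#' @return A `"curve_estimate"` data frame with an extra logical column
#'   `extrapolated`.
#' @export
impute_gaps <- function(post, gap_grid, k_sigma = 3, include_noise = FALSE,
                        max_gap_hours = 1) {
  stopifnot(inherits(post, "hr_posterior"))
  out <- posterior_band(post, gap_grid, k_sigma = k_sigma,
                        include_noise = include_noise)
  obs <- post$new_day$timestamps
  out$extrapolated <- if (length(obs)) {
    vapply(out$time_hours, function(t) min(abs(obs - t)) > max_gap_hours,
           logical(1))
  } else {
    rep(TRUE, nrow(out))
  }
  out
}
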