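# Pooling per-day fits into the heart-rate baseline prior: coefficient mean,
# debiased coefficient covariance, noise variance, and the induced Gaussian
# process mean/covariance functions with their 3-sigma band.

#' Estimate a subject's heart-rate baseline from multiple days
#'
#' Fits each day's measurements onto the basis, then pools the per-day
#' coefficient estimates into the baseline prior of the basis-expansion
#' Gaussian process:
#' \itemize{
#'   \item `coef_mean` — the mean of the per-day coefficient estimates,
#'     defining the functional mean curve;
#'   \item `sample_cov` — the outer-product sample covariance of the per-day
#'     coefficients (divisor `M - 1`);
#'   \item `coef_cov_raw` — the debiased coefficient covariance: the sample
#'     covariance minus the average noise-induced coefficient variance
#'     `(noise_var / M) * sum_i gram_inverse_i`.  Unbiased for the true
#'     between-day coefficient covariance, but can be indefinite in finite
#'     samples;
#'   \item `coef_cov` — the PSD repair of `coef_cov_raw` (eigenvalue
#'     clipping), used everywhere a valid variance is required;
#'   \item `noise_var` — the pooled residual-based noise variance.
#' }
#'
#' Days are excluded (and listed with reasons in `excluded_days`) when they
#' have fewer than `min_obs` observations or when their unridged Gram matrix
#' is numerically singular.  `M` counts retained days only.
#'
#' @param days List of [day_record()] objects for one subject.
#' @param basis An [hr_basis()] object.
#' @param min_obs Minimum observations per day (default `n_basis + 2`: enough
#'   rows for a full-rank fit with residual degrees of freedom to spare).
#' @param ridge Ridge penalty forwarded to [fit_day()] (default 0).
#' @param dof_min Degrees-of-freedom guard forwarded to
#'   [estimate_noise_variance()].
#' @param vif_max Per-day identifiability cap: a day is excluded when any
#'   diagonal entry of its inverse Gram matrix — the factor by which the
#'   noise variance is inflated in that coefficient's estimate — exceeds
#'   this value (default 10, i.e. every coefficient must be estimable to
#'   within about 3 noise standard deviations).  Long missing blocks can
#'   leave a basis function with almost no data under it; such a day passes
#'   the rank test yet contributes a wildly unstable coefficient that would
#'   contaminate the pooled mean and covariance.  Set to `Inf` to disable.
#' @return An object of class `"hr_baseline"`.
#' @export
estimate_baseline <- function(days, basis, min_obs = NULL, ridge = 0,
                              dof_min = 0.5, vif_max = 10) {
  stopifnot(inherits(basis, "hr_basis"))
  if (inherits(days, "day_record")) days <- list(days)
  stopifnot(length(days) >= 1L, all(vapply(days, inherits, TRUE, "day_record")))
  if (is.null(min_obs)) min_obs <- basis$n_basis + 2L
  excluded <- data.frame(day = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  fits <- list()
  for (d in days) {
    if (length(d$values) < min_obs) {
      excluded <- rbind(excluded, data.frame(
        day = d$day, reason = sprintf("fewer than %d observations", min_obs)))
      next
    }
    f <- fit_day(basis, d, ridge = ridge)
    if (!f$rank_ok && ridge == 0) {
      excluded <- rbind(excluded, data.frame(
        day = d$day, reason = "numerically singular Gram matrix"))
      next
    }
    vif <- max(diag(f$gram_inverse))
    if (!is.finite(vif) || vif > vif_max) {
      excluded <- rbind(excluded, data.frame(
        day = d$day,
        reason = sprintf("ill-identified coefficients (variance inflation %.3g)",
                         vif)))
      next
    }
    fits[[length(fits) + 1L]] <- f
  }
  m <- length(fits)
  if (m < 2L)
    stop("insufficient data: need at least 2 usable days to estimate a ",
         "baseline, got ", m, call. = FALSE)
  noise_var <- as.numeric(estimate_noise_variance(fits, dof_min = dof_min))
  coef_mat <- matrix(vapply(fits, `[[`, numeric(basis$n_basis), "coefficients"),
                     nrow = m, ncol = basis$n_basis, byrow = TRUE)
  coef_mean <- colMeans(coef_mat)
  sample_cov <- stats::cov(coef_mat)
  gram_inv_sum <- Reduce(`+`, lapply(fits, `[[`, "gram_inverse"))
  coef_cov_raw <- sample_cov - (noise_var / m) * gram_inv_sum
  structure(
    list(coef_mean = coef_mean,
         coef_cov = psd_repair(coef_cov_raw),
         coef_cov_raw = coef_cov_raw,
         sample_cov = sample_cov,
         noise_var = noise_var,
         n_days = m,
         basis = basis,
         subject = fits[[1L]]$subject,
         fitted_days = vapply(fits, `[[`, integer(1), "day"),
         excluded_days = excluded),
    class = "hr_baseline"
  )
}

#' @export
print.hr_baseline <- function(x, ...) {
  cat(sprintf("hr_baseline: subject %s, %d days pooled (%d excluded), P = %d\n",
              x$subject, x$n_days, nrow(x$excluded_days), x$basis$n_basis))
  cat(sprintf("  noise sd %.2f bpm; mean curve %.1f-%.1f bpm over the day\n",
              sqrt(x$noise_var),
              min(baseline_mean(x, seq(x$basis$t_start, x$basis$t_end,
                                       length.out = 97))),
              max(baseline_mean(x, seq(x$basis$t_start, x$basis$t_end,
                                       length.out = 97)))))
  invisible(x)
}

#' Construct a baseline directly from known parameters
#'
#' Builds an `"hr_baseline"` from an explicit coefficient mean, coefficient
#' covariance and noise variance, bypassing estimation — useful for priors
#' taken from the literature, for simulation studies against known ground
#' truth, and for testing.  The covariance is PSD-repaired on entry.
#'
#' @param basis An [hr_basis()] object.
#' @param coef_mean Numeric vector of length `n_basis`.
#' @param coef_cov Symmetric `P x P` covariance of the coefficients.
#' @param noise_var Nonnegative measurement-noise variance (bpm^2).
#' @param n_days Nominal number of days backing the prior (bookkeeping only).
#' @param subject Subject identifier.
#' @return An `"hr_baseline"` object.
#' @export
new_hr_baseline <- function(basis, coef_mean, coef_cov, noise_var,
                            n_days = 2L, subject = "S1") {
  stopifnot(inherits(basis, "hr_basis"),
            length(coef_mean) == basis$n_basis,
            is.numeric(noise_var), length(noise_var) == 1L, noise_var >= 0)
  coef_cov <- as.matrix(coef_cov)
  stopifnot(nrow(coef_cov) == basis$n_basis, ncol(coef_cov) == basis$n_basis)
  structure(
    list(coef_mean = as.numeric(coef_mean),
         coef_cov = psd_repair(coef_cov),
         coef_cov_raw = coef_cov,
         sample_cov = coef_cov,
         noise_var = as.numeric(noise_var),
         n_days = as.integer(n_days),
         basis = basis,
         subject = as.character(subject),
         fitted_days = seq_len(n_days),
         excluded_days = data.frame(day = integer(0), reason = character(0))),
    class = "hr_baseline"
  )
}

#' Nearest positive-semidefinite repair by eigenvalue clipping
#'
#' Symmetrizes the input, eigendecomposes, clips negative eigenvalues to zero
#' and reconstructs.  Idempotent on PSD inputs.  Used on the debiased
#' coefficient covariance (which can be indefinite in finite samples) and on
#' the posterior covariance after the closed-form update (float asymmetry).
#'
#' @param m A square numeric matrix (symmetrized internally).
#' @return A symmetric PSD matrix of the same dimension.
#' @export
psd_repair <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) != ncol(m))
    stop("'m' must be a square numeric matrix", call. = FALSE)
  if (any(!is.finite(m)))
    stop("matrix contains non-finite entries", call. = FALSE)
  s <- (m + t(m)) / 2
  e <- eigen(s, symmetric = TRUE)
  out <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  (out + t(out)) / 2
}

#' Baseline functional mean on a grid
#'
#' Evaluates the Gaussian-process mean function — the basis expansion of the
#' pooled coefficient mean — on a grid of times.
#'
#' @param baseline An [estimate_baseline()] result.
#' @param grid Numeric vector of times (hours) inside the basis domain.
#' @return Numeric vector of mean heart rates (bpm), one per grid point.
#' @export
baseline_mean <- function(baseline, grid) {
  stopifnot(inherits(baseline, "hr_baseline"))
  drop(crossprod(eval_basis(baseline$basis, grid), baseline$coef_mean))
}

#' Baseline covariance function
#'
#' Evaluates the Gaussian-process covariance function
#' `k(t, tau) = Phi(t)' Sigma_C Phi(tau)` (with the PSD-repaired coefficient
#' covariance) elementwise over two equal-length time vectors, recycling a
#' scalar argument.
#'
#' @param baseline An [estimate_baseline()] result.
#' @param t,tau Times in hours inside the basis domain.
#' @return Numeric vector of covariances (bpm^2); symmetric in `(t, tau)` and
#'   nonnegative on the diagonal `t == tau`.
#' @export
baseline_cov <- function(baseline, t, tau) {
  stopifnot(inherits(baseline, "hr_baseline"))
  cov_quadform(baseline$basis, baseline$coef_cov, t, tau)
}

cov_quadform <- function(basis, sigma, t, tau) {
  n <- max(length(t), length(tau))
  t <- rep_len(as.numeric(t), n)
  tau <- rep_len(as.numeric(tau), n)
  pt <- eval_basis(basis, t)
  ptau <- eval_basis(basis, tau)
  # averaging the two evaluation orders makes k(t, tau) == k(tau, t) exact
  # in floating point, not just up to rounding
  (colSums(pt * (sigma %*% ptau)) + colSums(ptau * (sigma %*% pt))) / 2
}

# Pointwise latent sd sqrt(k(t,t) [+ noise]) on a grid.
pointwise_sd <- function(basis, sigma, grid, noise_var = 0) {
  phi <- eval_basis(basis, grid)
  v <- colSums(phi * (sigma %*% phi))
  sqrt(pmax(v, 0) + noise_var)
}

new_curve_estimate <- function(grid, mean, sd, k_sigma) {
  structure(
    data.frame(time_hours = grid, mean_bpm = mean, sd_bpm = sd,
               lower = mean - k_sigma * sd, upper = mean + k_sigma * sd),
    k_sigma = k_sigma,
    class = c("curve_estimate", "data.frame")
  )
}

#' Baseline curve with uncertainty band
#'
#' Evaluates the baseline functional mean and its pointwise standard deviation
#' on a grid and forms the `mean +/- k_sigma * sd` band.  By default the band
#' describes the latent curve (the plausible range of the underlying
#' heart-rate pattern); set `include_noise = TRUE` to add the measurement-noise
#' variance and describe the range of raw observations instead.
#'
#' @param baseline An [estimate_baseline()] result.
#' @param grid Numeric vector of times (hours) inside the basis domain.
#' @param k_sigma Band half-width in standard deviations (default 3).
#' @param include_noise Add the noise variance to the pointwise variance
#'   (default `FALSE`).
#' @return A `"curve_estimate"` data frame with columns `time_hours`,
#'   `mean_bpm`, `sd_bpm`, `lower`, `upper`.
#' @export
baseline_band <- function(baseline, grid, k_sigma = 3, include_noise = FALSE) {
  stopifnot(inherits(baseline, "hr_baseline"))
  if (!is.numeric(k_sigma) || length(k_sigma) != 1L || k_sigma < 0)
    stop("invalid configuration: 'k_sigma' must be a single nonnegative number",
         call. = FALSE)
  grid <- as.numeric(grid)
  m <- baseline_mean(baseline, grid)
  s <- pointwise_sd(baseline$basis, baseline$coef_cov, grid,
                    if (include_noise) baseline$noise_var else 0)
  new_curve_estimate(grid, m, s, k_sigma)
}

#' Serialize a baseline to JSON
#'
#' Writes the full baseline (basis specification, coefficient mean and
#' covariances, noise variance, bookkeeping) as a JSON document that
#' [read_baseline()] restores exactly (floating-point values round-trip at
#' full precision).
#'
#' @param baseline An [estimate_baseline()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_baseline <- function(baseline, path) {
  stopifnot(inherits(baseline, "hr_baseline"))
  b <- baseline$basis
  doc <- list(
    format = "begp-baseline",
    basis = list(n_basis = b$n_basis, order = b$order, knots = b$knots,
                 t_start = b$t_start, t_end = b$t_end),
    subject = baseline$subject,
    coef_mean = baseline$coef_mean,
    coef_cov = as.vector(t(baseline$coef_cov)),
    coef_cov_raw = as.vector(t(baseline$coef_cov_raw)),
    sample_cov = as.vector(t(baseline$sample_cov)),
    noise_var = baseline$noise_var,
    n_days = baseline$n_days,
    fitted_days = baseline$fitted_days,
    excluded_days = baseline$excluded_days
  )
  # I(17) significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Restore a baseline written by [write_baseline()]
#'
#' @param path Path to a baseline JSON file.
#' @return An `"hr_baseline"` object.
#' @export
read_baseline <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "begp-baseline")
    stop("'", path, "' is not a begp baseline file", call. = FALSE)
  basis <- hr_basis(doc$basis$n_basis, doc$basis$order,
                    doc$basis$t_start, doc$basis$t_end)
  p <- basis$n_basis
  as_mat <- function(v) matrix(v, nrow = p, ncol = p, byrow = TRUE)
  excl <- as.data.frame(doc$excluded_days)
  if (!nrow(excl)) excl <- data.frame(day = integer(0), reason = character(0))
  structure(
    list(coef_mean = as.numeric(doc$coef_mean),
         coef_cov = as_mat(doc$coef_cov),
         coef_cov_raw = as_mat(doc$coef_cov_raw),
         sample_cov = as_mat(doc$sample_cov),
         noise_var = doc$noise_var,
         n_days = doc$n_days,
         basis = basis,
         subject = doc$subject,
         fitted_days = as.integer(doc$fitted_days),
         excluded_days = excl),
    class = "hr_baseline"
  )
}
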