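# Independent oracles and fixture builders shared across the suite.
# Each oracle deliberately takes a different numerical route than the
# implementation it checks.

# Random well-conditioned PSD matrix (A A' + ridge I).
random_psd <- function(p, ridge = 0.1) {
  a <- matrix(rnorm(p * p), p, p)
  tcrossprod(a) + diag(ridge, p)
}

# Random day with well-spread timestamps inside [0, 24].
random_day <- function(n, day = 1L, noise_sd = 0, coef = NULL,
                       basis = hr_basis(5, 4)) {
  t <- sort(runif(n, 0, 24))
  if (is.null(coef)) coef <- rnorm(basis$n_basis, 70, 5)
  y <- drop(crossprod(eval_basis(basis, t), coef)) + rnorm(n, 0, noise_sd)
  day_record(t, pmax(y, 1), day = day)
}

# Normal-equations oracle: generic least squares via QR on the transposed
# design (never the Gram-matrix route used by fit_day).
ls_oracle <- function(phi, y) {
  qr.solve(t(phi), y)
}

# Information-form posterior oracle (Woodbury dual of the N x N update),
# requiring an invertible prior covariance.
posterior_oracle <- function(coef_mean, coef_cov, phi, y, noise_var) {
  prec <- solve(coef_cov) + tcrossprod(phi) / noise_var
  cov_post <- solve(prec)
  coef_post <- drop(cov_post %*% (solve(coef_cov, coef_mean) +
                                    phi %*% y / noise_var))
  list(coef_post = coef_post, cov_post = cov_post)
}

# Eigendecomposition-based PSD projection, written independently of
# psd_repair (uses a loop-free spectral reconstruction with crossprod).
psd_oracle <- function(m) {
  s <- (m + t(m)) / 2
  e <- eigen(s, symmetric = TRUE)
  v <- pmax(e$values, 0)
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(v))
    out <- out + v[k] * tcrossprod(e$vectors[, k])
  out
}

# A small baseline built directly from supplied parameters, for tests that
# need exact control of the prior.
manual_baseline <- function(basis, coef_mean, coef_cov, noise_var,
                            n_days = 5L) {
  new_hr_baseline(basis, coef_mean, coef_cov, noise_var, n_days = n_days)
}

# Multi-day dataset drawn straight from the observation model (coefficients
# from N(coef_true, coef_cov_true), additive N(0, noise_sd^2) noise) on a
# fixed regular grid -- the minimal generative setup for estimator checks.
model_days <- function(m, n, basis, coef_true, coef_cov_true, noise_sd) {
  t <- seq(0.05, 23.95, length.out = n)
  phi <- eval_basis(basis, t)
  root <- chol(coef_cov_true)
  lapply(seq_len(m), function(i) {
    ci <- coef_true + drop(crossprod(root, rnorm(length(coef_true))))
    day_record(t, drop(crossprod(phi, ci)) + rnorm(n, 0, noise_sd), day = i)
  })
}
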