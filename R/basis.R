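# B-spline basis system and per-day least-squares coefficient fitting.

#' B-spline basis system on a daily time domain
#'
#' Constructs a clamped B-spline basis on `[t_start, t_end]` with uniformly
#' spaced interior knots and full-multiplicity boundary knots, so that exactly
#' `n_basis` basis functions are defined and they form a partition of unity on
#' the domain.  The basis carries the time domain with it; all downstream
#' evaluation is restricted to that domain.
#'
#' The default of 13 cubic basis functions over a 24 h day gives one inflection
#' roughly every 2.4 h, enough to resolve the night/day swing of a diurnal
#' heart-rate pattern without chasing measurement noise.
#'
#' @param n_basis Number of basis functions `P` (default 13).
#' @param order Spline order (polynomial degree + 1; 4 = cubic, the default).
#' @param t_start,t_end Domain endpoints in hours since local midnight
#'   (defaults 0 and 24, one diurnal period).
#' @return An object of class `"hr_basis"` with elements `n_basis`, `order`,
#'   `knots` (the full knot vector), `t_start`, `t_end`.
#' @examples
#' b <- hr_basis(13, 4)
#' phi <- eval_basis(b, c(0, 6, 12, 18, 24))
#' colSums(phi)  # partition of unity: all 1
#' @export
hr_basis <- function(n_basis = 13L, order = 4L, t_start = 0, t_end = 24) {
  n_basis <- as.integer(n_basis)
  order <- as.integer(order)
  if (length(n_basis) != 1L || length(order) != 1L || is.na(n_basis) || is.na(order))
    stop("'n_basis' and 'order' must be single integers", call. = FALSE)
  if (order < 1L)
    stop("invalid configuration: 'order' must be >= 1", call. = FALSE)
  if (n_basis < order)
    stop("invalid configuration: 'n_basis' (", n_basis,
         ") must be >= 'order' (", order, ")", call. = FALSE)
  t_start <- as.numeric(t_start)
  t_end <- as.numeric(t_end)
  if (!is.finite(t_start) || !is.finite(t_end) || t_end <= t_start)
    stop("invalid domain: need t_end > t_start", call. = FALSE)
  n_interior <- n_basis - order
  interior <- if (n_interior > 0L) {
    seq(t_start, t_end, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  } else {
    numeric(0)
  }
  structure(
    list(n_basis = n_basis, order = order,
         knots = c(rep(t_start, order), interior, rep(t_end, order)),
         t_start = t_start, t_end = t_end),
    class = "hr_basis"
  )
}

#' @export
print.hr_basis <- function(x, ...) {
  cat(sprintf("B-spline basis: %d functions, order %d (degree %d), domain [%g, %g] h\n",
              x$n_basis, x$order, x$order - 1L, x$t_start, x$t_end))
  invisible(x)
}

check_in_domain <- function(basis, t, what = "timestamp") {
  bad <- which(!is.finite(t) | t < basis$t_start | t > basis$t_end)
  if (length(bad))
    stop(sprintf("%s %g outside basis domain [%g, %g]",
                 what, t[bad[1L]], basis$t_start, basis$t_end), call. = FALSE)
  invisible(TRUE)
}

#' Evaluate the basis kernel matrix at a set of timestamps
#'
#' Returns the `P x N` matrix with entry `(p, j)` equal to the p-th basis
#' function evaluated at the j-th timestamp.  Columns at identical timestamps
#' are identical; every timestamp must lie inside the basis domain.
#'
#' @param basis An [hr_basis()] object.
#' @param timestamps Numeric vector of times in hours.
#' @return A `P x N` numeric matrix.
#' @export
eval_basis <- function(basis, timestamps) {
  stopifnot(inherits(basis, "hr_basis"))
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) == 0L)
    return(matrix(numeric(0), nrow = basis$n_basis, ncol = 0L))
  check_in_domain(basis, timestamps)
  t(splines::splineDesign(basis$knots, timestamps, ord = basis$order,
                          outer.ok = FALSE))
}

#' One day of irregular heart-rate measurements
#'
#' Canonical container for a single day's sensor trace: timestamps are sorted
#' ascending (stable for ties; exact duplicates are retained, least squares
#' handles them), values must be finite and positive.
#'
#' @param timestamps Hours since local midnight, each in `[0, 24]` for the
#'   default domain (domain enforcement happens at fit time against the basis).
#' @param values Heart-rate measurements in bpm, same length as `timestamps`.
#' @param day Integer day index.
#' @param subject Subject identifier.
#' @return An object of class `"day_record"`.
#' @export
day_record <- function(timestamps, values, day = 1L, subject = "S1") {
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values))
    stop("timestamps and values must have equal length", call. = FALSE)
  if (anyNA(timestamps) || any(!is.finite(timestamps)))
    stop("timestamps must be finite", call. = FALSE)
  if (length(values) && (any(!is.finite(values)) || any(values <= 0)))
    stop("heart-rate values must be finite and positive", call. = FALSE)
  o <- order(timestamps)
  structure(
    list(day = as.integer(day), subject = as.character(subject),
         timestamps = timestamps[o], values = values[o]),
    class = "day_record"
  )
}

#' @export
print.day_record <- function(x, ...) {
  cat(sprintf("day_record: subject %s, day %d, %d observations",
              x$subject, x$day, length(x$values)))
  if (length(x$values))
    cat(sprintf(" over [%.2f, %.2f] h, HR %.0f-%.0f bpm",
                min(x$timestamps), max(x$timestamps),
                min(x$values), max(x$values)))
  cat("\n")
  invisible(x)
}

# Moore-Penrose pseudo-inverse of a symmetric matrix via eigendecomposition.
sym_pinv <- function(m, tol = 1e-12) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- e$values > max(abs(e$values)) * tol
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Least-squares basis-coefficient fit for one day
#'
#' Projects one day's measurements onto the basis: the coefficients solve the
#' normal equations built from the basis kernel matrix, optionally ridge
#' stabilized.  When the Gram matrix is numerically singular (relative
#' condition number above `cond_tol`) and `ridge = 0`, the minimum-norm
#' least-squares solution is returned and the fit is flagged via
#' `rank_ok = FALSE` rather than raising an error.
#'
#' The returned fit carries the diagnostics needed for pooled estimation:
#' residuals, the trace of the hat matrix (equal to `P` for a full-rank,
#' unridged fit), the residual degrees of freedom `dof = N - hat_trace`, and
#' the inverse Gram matrix used for the covariance debiasing step.
#'
#' @param basis An [hr_basis()] object.
#' @param day A [day_record()] with at least one observation in the domain.
#' @param ridge Nonnegative ridge penalty added to the Gram diagonal
#'   (default 0, the plain normal equations).
#' @param cond_tol Relative condition-number threshold above which the Gram
#'   matrix is treated as singular (default 1e10).
#' @return An object of class `"day_fit"` with elements `coefficients`,
#'   `fitted`, `residuals`, `hat_trace`, `dof`, `gram_inverse`, `n_obs`,
#'   `rank_ok`, `day`, `subject`, `ridge`.
#' @export
fit_day <- function(basis, day, ridge = 0, cond_tol = 1e10) {
  stopifnot(inherits(basis, "hr_basis"), inherits(day, "day_record"))
  if (!is.numeric(ridge) || length(ridge) != 1L || ridge < 0)
    stop("'ridge' must be a single nonnegative number", call. = FALSE)
  n <- length(day$values)
  if (n < 1L)
    stop("cannot fit an empty day (no observations)", call. = FALSE)
  phi <- eval_basis(basis, day$timestamps)           # P x N
  p <- basis$n_basis
  gram <- tcrossprod(phi)                            # Phi Phi^T, P x P
  ev <- eigen((gram + t(gram)) / 2, symmetric = TRUE, only.values = TRUE)$values
  rank_ok <- ev[p] > 0 && ev[1] / ev[p] < cond_tol
  if (ridge > 0) {
    gram_inv <- chol2inv(chol(gram + diag(ridge, p)))
  } else if (rank_ok) {
    gram_inv <- chol2inv(chol(gram))
  } else {
    gram_inv <- sym_pinv(gram)
  }
  coef <- drop(gram_inv %*% (phi %*% day$values))
  fitted <- drop(crossprod(phi, coef))
  resid <- day$values - fitted
  hat_trace <- sum(phi * (gram_inv %*% phi))         # trace of Phi^T G^-1 Phi
  structure(
    list(coefficients = coef, fitted = fitted, residuals = resid,
         hat_trace = hat_trace, dof = n - hat_trace,
         gram_inverse = gram_inv, n_obs = n, rank_ok = rank_ok,
         day = day$day, subject = day$subject, ridge = ridge),
    class = "day_fit"
  )
}

#' @export
print.day_fit <- function(x, ...) {
  cat(sprintf("day_fit: day %d, %d obs, %d coefficients, dof %.2f%s\n",
              x$day, x$n_obs, length(x$coefficients), x$dof,
              if (x$rank_ok) "" else " [rank deficient]"))
  invisible(x)
}

#' Pooled unbiased estimate of the measurement-noise variance
#'
#' Averages, over the retained day fits, the ratio of the residual sum of
#' squares to the residual degrees of freedom (the trace of `I - H` for that
#' day).  Under the additive i.i.d. Gaussian noise model this ratio is
#' unbiased for the noise variance day by day, so the average is too.  Days
#' whose residual degrees of freedom fall at or below `dof_min` are excluded
#' (the ratio is unstable there) and counted in the `"n_excluded"` attribute.
#'
#' @param fits List of [fit_day()] results.
#' @param dof_min Minimum residual degrees of freedom for a day to enter the
#'   average (default 0.5).
#' @return Nonnegative scalar estimate of the noise variance (bpm^2), with
#'   attributes `n_used` and `n_excluded`.
#' @export
estimate_noise_variance <- function(fits, dof_min = 0.5) {
  if (inherits(fits, "day_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "day_fit")))
  dofs <- vapply(fits, `[[`, numeric(1), "dof")
  keep <- dofs > dof_min
  if (!any(keep))
    stop("cannot estimate noise variance: no day has residual degrees of ",
         "freedom above ", dof_min, call. = FALSE)
  ratios <- vapply(fits[keep], function(f) sum(f$residuals^2) / f$dof, numeric(1))
  structure(mean(ratios), n_used = sum(keep), n_excluded = sum(!keep))
}
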