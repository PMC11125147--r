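# Seeded synthetic-data generator emulating multi-day wearable heart-rate
# collection: smooth diurnal truth curves, day-to-day coefficient variation,
# additive Gaussian sensor noise, sporadic motion-artifact shocks,
# contiguous-block missingness, and a paired dense low-noise reference sensor.

sub_seed <- function(seed, k) {
  (abs(as.integer(seed)) + as.integer(k) * 1009L) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draw n samples from N(mean, sigma); sigma may be singular (eigen sqrt).
rmvn <- function(n, mean, sigma) {
  p <- length(mean)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  t(mean + root %*% matrix(stats::rnorm(n * p), p, n))
}

#' Configuration for the synthetic wearable-heart-rate generator
#'
#' Defaults emulate the data-collection conditions the method targets: about
#' two weeks of monitoring (15 days), 1-minute sampling over 24 h (1440
#' samples/day), additive sensor noise of 3 bpm, sporadic motion-artifact
#' shocks (5% of samples, 25 bpm scale — placeholders, since artifact
#' magnitude and rate are rarely characterized for consumer devices), and a
#' 25% missing-data rate realized as contiguous blocks averaging 1 h
#' (device charging / removal), matching observed per-subject missing rates
#' of roughly 0.12-0.42.  The paired reference ("ECG-like") sensor is dense,
#' nearly noise free (1 bpm) and artifact free, with lighter independent
#' missingness.
#'
#' @param n_days Days of collection (default 15).
#' @param samples_per_day Regular-grid samples per day (default 1440,
#'   i.e. 1-minute resolution).
#' @param noise_sd Measurement-noise standard deviation in bpm (default 3).
#' @param coef_true Optional true coefficient mean vector (length must match
#'   the basis); generated by [make_diurnal_truth()] when `NULL`.
#' @param coef_cov_true Optional true coefficient covariance (PSD); generated
#'   when `NULL`.
#' @param artifact_rate Fraction of samples hit by a motion-artifact shock
#'   (default 0.05).
#' @param artifact_sd Shock scale in bpm (default 25).
#' @param artifact_positive If `TRUE`, shocks are one-sided positive
#'   (PPG artifacts typically inflate heart rate); default `FALSE`
#'   (symmetric).
#' @param missing_rate Target fraction of samples deleted from the noisy
#'   sensor (default 0.25); must be below 0.98.
#' @param missing_block_hours Mean length of a contiguous deleted block in
#'   hours (default 1).
#' @param ecg_noise_sd Reference-sensor noise sd in bpm (default 1).
#' @param ecg_missing_rate Reference-sensor missing fraction (default 0.05).
#' @param seed Integer seed; separate RNG streams are derived from it for
#'   coefficients, noise, artifacts and missingness, so toggling one
#'   mechanism does not perturb the others.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_days = 15L, samples_per_day = 1440L, noise_sd = 3,
                       coef_true = NULL, coef_cov_true = NULL,
                       artifact_rate = 0.05, artifact_sd = 25,
                       artifact_positive = FALSE,
                       missing_rate = 0.25, missing_block_hours = 1,
                       ecg_noise_sd = 1, ecg_missing_rate = 0.05,
                       seed = 1L) {
  cfg <- list(n_days = as.integer(n_days),
              samples_per_day = as.integer(samples_per_day),
              noise_sd = noise_sd, coef_true = coef_true,
              coef_cov_true = coef_cov_true,
              artifact_rate = artifact_rate, artifact_sd = artifact_sd,
              artifact_positive = isTRUE(artifact_positive),
              missing_rate = missing_rate,
              missing_block_hours = missing_block_hours,
              ecg_noise_sd = ecg_noise_sd,
              ecg_missing_rate = ecg_missing_rate,
              seed = as.integer(seed))
  if (cfg$n_days < 1L) stop("'n_days' must be >= 1", call. = FALSE)
  if (cfg$samples_per_day < 2L)
    stop("'samples_per_day' must be >= 2", call. = FALSE)
  for (f in c("artifact_rate", "missing_rate", "ecg_missing_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be in [0, 1]", call. = FALSE)
  for (f in c("noise_sd", "artifact_sd", "ecg_noise_sd", "missing_block_hours"))
    if (cfg[[f]] < 0) stop("'", f, "' must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Generate a plausible diurnal ground-truth pattern
#'
#' Draws (deterministically for a fixed seed) a smooth diurnal mean curve —
#' low nocturnal heart rate with a daytime elevation of at least 12 bpm,
#' bounded within `[45, 110]` bpm — projects it onto the basis to obtain the
#' true coefficient mean, and pairs it with an AR(1)-correlated coefficient
#' covariance scaled so that the day-to-day curve standard deviation lies
#' between roughly 1 and 8 bpm.
#'
#' @param basis An [hr_basis()] object.
#' @param seed Integer seed.
#' @return A list with `coef_true` (length `P`) and `coef_cov_true`
#'   (`P x P` PSD).
#' @export
make_diurnal_truth <- function(basis, seed = 1L) {
  stopifnot(inherits(basis, "hr_basis"))
  with_seed(sub_seed(seed, 0L), {
    level <- min(max(62 + stats::rnorm(1, 0, 5), 52), 72)
    amp <- min(max(17 + stats::rnorm(1, 0, 3), 12), 24)
    peak <- min(max(14 + stats::rnorm(1, 0, 1.5), 11), 17)
    width <- min(max(5.5 + stats::rnorm(1, 0, 0.75), 4), 7)
    sd_c <- min(max(4 + stats::rnorm(1, 0, 0.5), 2.5), 6)
  })
  span <- basis$t_end - basis$t_start
  grid <- basis$t_start + span * (0:1439) / 1440
  mid <- basis$t_start + span * (peak - 0) / 24  # peak stated in hours-of-day
  curve <- level + amp * exp(-((grid - mid) / width)^2)
  proj <- fit_day(basis, day_record(grid, curve, day = 0L))
  rho <- 0.4
  p <- basis$n_basis
  corr <- rho^abs(outer(seq_len(p), seq_len(p), `-`))
  list(coef_true = proj$coefficients, coef_cov_true = sd_c^2 * corr)
}

# Contiguous-block deletion mask: exponential block lengths (mean
# `mean_len` samples), blocks added until the target count is reached; the
# final block is trimmed so the realized missing count equals the target.
block_mask <- function(n, rate, mean_len) {
  target <- min(floor(rate * n), n - 1L)
  removed <- rep(FALSE, n)
  guard <- 0L
  while (sum(removed) < target && guard < 100000L) {
    guard <- guard + 1L
    len <- max(1L, ceiling(stats::rexp(1, 1 / max(mean_len, 1e-9))))
    start <- sample.int(n, 1L)
    idx <- start:min(n, start + len - 1L)
    new <- idx[!removed[idx]]
    room <- target - sum(removed)
    if (length(new) > room) new <- new[seq_len(room)]
    removed[new] <- TRUE
  }
  removed
}

# Maximal runs of removed samples, as a data frame (start index, length).
mask_blocks <- function(removed) {
  r <- rle(removed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

#' Simulate one subject's paired-sensor heart-rate dataset
#'
#' For each day draws a coefficient vector around the true diurnal pattern,
#' evaluates the dense truth curve on the regular grid, then produces
#' \itemize{
#'   \item a noisy, gappy "PPG-like" record: truth + Gaussian noise +
#'     Bernoulli motion-artifact shocks, with contiguous blocks deleted until
#'     the target missing fraction is met (emitted values are floored at
#'     1 bpm, as a sensor never reports nonpositive heart rate);
#'   \item a dense, low-noise, artifact-free "ECG-like" reference record with
#'     independent lighter missingness.
#' }
#' All randomness comes from streams derived from `config$seed`, one per
#' mechanism, so the output is fully reproducible and toggling one mechanism
#' leaves the others unchanged.
#'
#' @param config A [sim_config()].
#' @param basis An [hr_basis()] object.
#' @param subject Subject identifier used in the emitted records.
#' @return An object of class `"hr_sim"`: `days` (noisy [day_record()]s),
#'   `ground_truth_days` (reference [day_record()]s), `truth` (function
#'   `(day, t)` evaluating the day's true curve), `coef_days` (`P x n_days`
#'   true coefficients), `grid`, dense matrices `truth_mat`/`noisy_mat`,
#'   per-day logical masks `artifact` / `removed` / `removed_ecg`, block logs,
#'   realized missing rates, `config`, `basis`, `subject`.
#' @export
simulate_hr_dataset <- function(config, basis, subject = "S1") {
  stopifnot(inherits(config, "sim_config"), inherits(basis, "hr_basis"))
  if (config$missing_rate >= 0.98)
    stop("refusing to simulate with missing_rate >= 0.98: nothing left to fit",
         call. = FALSE)
  truth_pars <- if (is.null(config$coef_true) || is.null(config$coef_cov_true)) {
    make_diurnal_truth(basis, config$seed)
  } else {
    list(coef_true = config$coef_true, coef_cov_true = config$coef_cov_true)
  }
  p <- basis$n_basis
  if (length(truth_pars$coef_true) != p)
    stop("'coef_true' length must match the basis (", p, ")", call. = FALSE)
  n <- config$samples_per_day
  m <- config$n_days
  span <- basis$t_end - basis$t_start
  grid <- basis$t_start + span * (0:(n - 1L)) / n
  phi <- eval_basis(basis, grid)                               # P x n

  coefs <- with_seed(sub_seed(config$seed, 1L),
                     t(rmvn(m, truth_pars$coef_true, truth_pars$coef_cov_true)))
  truth_mat <- crossprod(phi, coefs)                           # n x m
  noise <- with_seed(sub_seed(config$seed, 2L),
                     matrix(stats::rnorm(n * m, 0, config$noise_sd), n, m))
  art <- with_seed(sub_seed(config$seed, 3L), {
    hit <- matrix(stats::runif(n * m) < config$artifact_rate, n, m)
    shock <- matrix(stats::rnorm(n * m, 0, config$artifact_sd), n, m)
    if (config$artifact_positive) shock <- abs(shock)
    list(hit = hit, shock = shock)
  })
  noisy_mat <- truth_mat + noise + ifelse(art$hit, art$shock, 0)
  noisy_mat <- pmax(noisy_mat, 1)

  mean_len <- config$missing_block_hours * n / span            # hours -> samples
  removed <- with_seed(sub_seed(config$seed, 4L), {
    lapply(seq_len(m), function(i)
      if (config$missing_rate > 0) block_mask(n, config$missing_rate, mean_len)
      else rep(FALSE, n))
  })
  ecg <- with_seed(sub_seed(config$seed, 5L), {
    vals <- truth_mat + matrix(stats::rnorm(n * m, 0, config$ecg_noise_sd), n, m)
    rem <- lapply(seq_len(m), function(i)
      if (config$ecg_missing_rate > 0)
        block_mask(n, config$ecg_missing_rate, mean_len)
      else rep(FALSE, n))
    list(vals = pmax(vals, 1), removed = rem)
  })

  days <- lapply(seq_len(m), function(i) {
    keep <- !removed[[i]]
    day_record(grid[keep], noisy_mat[keep, i], day = i, subject = subject)
  })
  truth_days <- lapply(seq_len(m), function(i) {
    keep <- !ecg$removed[[i]]
    day_record(grid[keep], ecg$vals[keep, i], day = i, subject = subject)
  })
  structure(
    list(days = days, ground_truth_days = truth_days,
         truth = function(day, t)
           drop(crossprod(eval_basis(basis, t), coefs[, day])),
         coef_days = coefs,
         coef_true = truth_pars$coef_true,
         coef_cov_true = truth_pars$coef_cov_true,
         grid = grid, truth_mat = truth_mat, noisy_mat = noisy_mat,
         artifact = lapply(seq_len(m), function(i) art$hit[, i]),
         removed = removed, removed_ecg = ecg$removed,
         block_log = lapply(removed, mask_blocks),
         realized_missing = vapply(removed, mean, numeric(1)),
         config = config, basis = basis, subject = subject),
    class = "hr_sim"
  )
}

#' @export
print.hr_sim <- function(x, ...) {
  cat(sprintf(
    "hr_sim: subject %s, %d days x %d samples, noise sd %g bpm, realized missing %.3f\n",
    x$subject, x$config$n_days, x$config$samples_per_day, x$config$noise_sd,
    mean(x$realized_missing)))
  invisible(x)
}

sim_frame <- function(records) {
  do.call(rbind, lapply(records, function(d)
    data.frame(subject_id = d$subject, day = d$day,
               time_hours = d$timestamps, hr_bpm = d$values)))
}

#' Write a simulated dataset to long-format CSV files
#'
#' Emits `ppg.csv` (the noisy, gappy sensor), `ecg.csv` (the dense reference
#' sensor), `truth.csv` (the complete noise-free truth on the regular grid)
#' — all with header `subject_id,day,time_hours,hr_bpm` — and a
#' `manifest.json` recording the configuration, seed, package version and
#' realized per-day missing rates.  Floats are written at full round-trip
#' precision, so the files re-read losslessly.
#'
#' @param sim An [simulate_hr_dataset()] result, or a list of them
#'   (multiple subjects are concatenated into the same files).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hr_dataset <- function(sim, dir) {
  sims <- if (inherits(sim, "hr_sim")) list(sim) else sim
  stopifnot(all(vapply(sims, inherits, TRUE, "hr_sim")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  bind <- function(get) do.call(rbind, lapply(sims, get))
  ppg <- bind(function(s) sim_frame(s$days))
  ecg <- bind(function(s) sim_frame(s$ground_truth_days))
  truth <- bind(function(s) do.call(rbind, lapply(
    seq_len(s$config$n_days), function(i)
      data.frame(subject_id = s$subject, day = i, time_hours = s$grid,
                 hr_bpm = s$truth_mat[, i]))))
  write_csv17(ppg, file.path(dir, "ppg.csv"))
  write_csv17(ecg, file.path(dir, "ecg.csv"))
  write_csv17(truth, file.path(dir, "truth.csv"))
  manifest <- list(
    format = "begp-sim-manifest",
    package_version = as.character(utils::packageVersion("begp")),
    subjects = lapply(sims, function(s) list(
      subject = s$subject,
      seed = s$config$seed,
      config = s$config[setdiff(names(s$config),
                                c("coef_true", "coef_cov_true"))],
      realized_missing = s$realized_missing,
      realized_missing_ecg = vapply(s$removed_ecg, mean, numeric(1)),
      artifact_count = sum(vapply(s$artifact, sum, numeric(1)))))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17))
  invisible(dir)
}
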