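# Pooled baseline estimation, PSD repair, and the Gaussian-process
# mean/covariance/band surface.

test_that("identical noiseless days collapse to a degenerate baseline", {
  set.seed(3)
  b <- hr_basis(5, 4)
  coef <- c(60, 75, 90, 70, 65)
  t <- seq(0.2, 23.8, length.out = 30)
  y <- drop(crossprod(eval_basis(b, t), coef))
  days <- lapply(1:4, function(i) day_record(t, y, day = i))
  bl <- estimate_baseline(days, b)
  expect_equal(bl$coef_mean, coef, tolerance = 1e-8)
  expect_lt(max(abs(bl$sample_cov)), 1e-12)
  expect_lt(max(abs(bl$coef_cov)), 1e-12)
  expect_equal(bl$noise_var, 0, tolerance = 1e-12)
  expect_equal(bl$n_days, 4L)
})

test_that("constant-basis two-day baseline reproduces hand arithmetic", {
  b <- hr_basis(1, 1)
  days <- list(day_record(c(2, 10, 20), c(60, 60, 60), day = 1),
               day_record(c(2, 10, 20), c(80, 80, 80), day = 2))
  bl <- estimate_baseline(days, b, min_obs = 1)
  expect_equal(bl$coef_mean, 70)
  expect_equal(as.numeric(bl$sample_cov), 200)  # var of {60, 80}
  expect_equal(bl$noise_var, 0)
})

test_that("too few usable days raises an insufficient-data error", {
  b <- hr_basis(5, 4)
  days <- list(random_day(30, day = 1, basis = b))
  expect_error(estimate_baseline(days, b), "at least 2 usable days")
})

test_that("short and rank-deficient days are excluded with reasons", {
  set.seed(5)
  b <- hr_basis(5, 4)
  days <- list(random_day(30, day = 1, basis = b),
               random_day(30, day = 2, basis = b),
               day_record(c(1, 2, 3), c(60, 61, 62), day = 3),      # too short
               day_record(rep(6, 10), rnorm(10, 70, 1), day = 4))   # clustered
  bl <- estimate_baseline(days, b)
  expect_equal(bl$n_days, 2L)
  expect_setequal(bl$excluded_days$day, c(3L, 4L))
  expect_match(bl$excluded_days$reason[bl$excluded_days$day == 3],
               "fewer than")
  expect_match(bl$excluded_days$reason[bl$excluded_days$day == 4],
               "singular")
})

test_that("debiased coefficient covariance is unbiased elementwise", {
  set.seed(19)
  b <- hr_basis(3, 3)
  coef_true <- c(65, 85, 60)
  sigma_true <- random_psd(3, ridge = 1) * 2
  reps <- 300
  raw <- array(NA_real_, c(reps, 3, 3))
  for (r in seq_len(reps)) {
    days <- model_days(20, 60, b, coef_true, sigma_true, noise_sd = 5)
    raw[r, , ] <- estimate_baseline(days, b)$coef_cov_raw
  }
  mc_mean <- apply(raw, c(2, 3), mean)
  mc_se <- apply(raw, c(2, 3), sd) / sqrt(reps)
  expect_true(all(abs(mc_mean - sigma_true) < 3 * mc_se + 1e-10))
})

test_that("PSD repair clips eigenvalues, is idempotent, and matches its oracle", {
  expect_equal(psd_repair(diag(2)), diag(2))
  expect_equal(psd_repair(diag(c(1, -0.5))), diag(c(1, 0)))
  set.seed(29)
  a <- matrix(rnorm(25), 5, 5); a <- a + t(a); a <- a - diag(3, 5)
  r <- psd_repair(a)
  expect_lt(max(abs(r - psd_oracle(a))), 1e-10)
  expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
  expect_equal(psd_repair(r), r, tolerance = 1e-12)
  expect_error(psd_repair(matrix(c(1, NA, NA, 1), 2)), "non-finite")
  # clipping never increases the top eigenvalue
  top <- function(m) max(eigen((m + t(m)) / 2, symmetric = TRUE,
                               only.values = TRUE)$values)
  expect_lte(top(r), top(a) + 1e-10)
})

test_that("baseline mean evaluates the basis expansion of the coefficient mean", {
  set.seed(37)
  b <- hr_basis(6, 4)
  bl <- manual_baseline(b, rnorm(6, 70, 5), random_psd(6), 9)
  grid <- runif(20, 0, 24)
  direct <- vapply(grid, function(t) {
    phi <- eval_basis(b, t)
    s <- 0
    for (p in 1:6) s <- s + bl$coef_mean[p] * phi[p, 1]
    s
  }, numeric(1))
  expect_equal(baseline_mean(bl, grid), direct, tolerance = 1e-12)
  # constant basis: mean is the coefficient everywhere
  blc <- manual_baseline(hr_basis(1, 1), 70, matrix(9), 1)
  expect_equal(baseline_mean(blc, c(0, 6, 24)), rep(70, 3))
  expect_error(baseline_mean(bl, 25), "outside")
})

test_that("covariance function matches the double-loop oracle and is symmetric", {
  set.seed(43)
  b <- hr_basis(5, 4)
  sig <- random_psd(5)
  bl <- manual_baseline(b, rnorm(5, 70, 5), sig, 9)
  t1 <- runif(20, 0, 24); t2 <- runif(20, 0, 24)
  direct <- mapply(function(t, tau) {
    pt <- eval_basis(b, t); ptau <- eval_basis(b, tau)
    s <- 0
    for (p in 1:5) for (q in 1:5)
      s <- s + pt[p, 1] * bl$coef_cov[p, q] * ptau[q, 1]
    s
  }, t1, t2)
  expect_equal(baseline_cov(bl, t1, t2), direct, tolerance = 1e-12)
  expect_identical(baseline_cov(bl, t1, t2), baseline_cov(bl, t2, t1))
  expect_true(all(baseline_cov(bl, t1, t1) >= 0))
  # zero covariance propagates
  bl0 <- manual_baseline(b, rnorm(5, 70, 5), matrix(0, 5, 5), 9)
  expect_equal(baseline_cov(bl0, t1, t2), rep(0, 20))
  # scalar case
  blc <- manual_baseline(hr_basis(1, 1), 70, matrix(9), 1)
  expect_equal(baseline_cov(blc, c(1, 12), c(5, 20)), c(9, 9))
})

test_that("uncertainty band obeys its closed form and edge cases", {
  b <- hr_basis(1, 1)
  bl <- manual_baseline(b, 70, matrix(4), 5)
  band <- baseline_band(bl, c(0, 6, 12, 24))
  expect_equal(band$lower, rep(64, 4))
  expect_equal(band$upper, rep(76, 4))
  expect_true(all(band$lower <= band$mean_bpm & band$mean_bpm <= band$upper))
  # k_sigma = 0 collapses the band onto the mean
  b0 <- baseline_band(bl, c(3, 9), k_sigma = 0)
  expect_equal(b0$lower, b0$mean_bpm)
  expect_equal(b0$upper, b0$mean_bpm)
  # zero coefficient covariance collapses the latent band
  bl0 <- manual_baseline(b, 70, matrix(0), 5)
  expect_equal(baseline_band(bl0, c(3, 9))$sd_bpm, c(0, 0))
  # include_noise adds the measurement variance
  expect_equal(baseline_band(bl0, 3, include_noise = TRUE)$sd_bpm, sqrt(5))
  expect_error(baseline_band(bl, 1:3, k_sigma = -1), "invalid configuration")
})

test_that("pointwise variance is continuous on a fine grid", {
  set.seed(47)
  b <- hr_basis(13, 4)
  bl <- manual_baseline(b, rnorm(13, 70, 5), random_psd(13), 9)
  grid <- seq(0, 24, length.out = 24 * 60 + 1)
  v <- baseline_cov(bl, grid, grid)
  expect_lt(max(abs(diff(v))), 1)  # bpm^2 per minute; no jumps
})

test_that("baseline estimates converge as the number of days grows", {
  set.seed(59)
  b <- hr_basis(3, 3)
  coef_true <- c(65, 85, 60)
  sigma_true <- diag(c(4, 6, 3))
  err_mean <- err_cov <- numeric(0)
  for (m in c(10, 50, 200)) {
    e1 <- e2 <- numeric(30)
    for (r in 1:30) {
      bl <- estimate_baseline(model_days(m, 40, b, coef_true, sigma_true, 4), b)
      e1[r] <- max(abs(bl$coef_mean - coef_true))
      e2[r] <- max(abs(bl$coef_cov - sigma_true))
    }
    err_mean <- c(err_mean, mean(e1)); err_cov <- c(err_cov, mean(e2))
  }
  expect_true(all(diff(err_mean) < 0))
  expect_true(all(diff(err_cov) < 0))
})

test_that("baseline serialization round-trips exactly", {
  set.seed(61)
  b <- hr_basis(6, 4)
  days <- lapply(1:5, function(i) random_day(40, day = i, noise_sd = 3, basis = b))
  bl <- estimate_baseline(days, b)
  path <- withr::local_tempfile(fileext = ".json")
  write_baseline(bl, path)
  bl2 <- read_baseline(path)
  expect_identical(bl2$coef_mean, bl$coef_mean)
  expect_identical(bl2$coef_cov, bl$coef_cov)
  expect_identical(bl2$coef_cov_raw, bl$coef_cov_raw)
  expect_identical(bl2$noise_var, bl$noise_var)
  expect_identical(bl2$n_days, bl$n_days)
  expect_identical(bl2$basis$knots, bl$basis$knots)
  expect_error(read_baseline(withr::local_tempfile(lines = "{}",
                                                   fileext = ".json")),
               "not a begp baseline")
})
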