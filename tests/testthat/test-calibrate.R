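# Closed-form posterior updating, posterior curves/bands, and gap imputation.

test_that("zero observations leave the posterior equal to the prior", {
  set.seed(2)
  b <- hr_basis(5, 4)
  bl <- manual_baseline(b, rnorm(5, 70, 5), random_psd(5), 9)
  post <- calibrate_day(bl, day_record(numeric(0), numeric(0)))
  expect_identical(post$coef_post, bl$coef_mean)
  expect_identical(post$cov_post, bl$coef_cov)
  grid <- seq(0, 24, by = 0.5)
  expect_equal(posterior_mean(post, grid), baseline_mean(bl, grid))
  expect_equal(posterior_band(post, grid), baseline_band(bl, grid))
})

test_that("a zero-variance prior is never moved by data", {
  b <- hr_basis(4, 4)
  bl <- manual_baseline(b, c(60, 70, 80, 65), matrix(0, 4, 4), 9)
  d <- day_record(c(3, 9, 15, 21), c(120, 130, 140, 150))
  post <- calibrate_day(bl, d)
  expect_equal(post$coef_post, bl$coef_mean, tolerance = 1e-12)
  expect_lt(max(abs(post$cov_post)), 1e-12)
  expect_equal(posterior_band(post, c(6, 18))$sd_bpm, c(0, 0))
})

test_that("update matches the information-form oracle on a fixed instance", {
  set.seed(13)
  b <- hr_basis(5, 4)
  sig <- random_psd(5)
  bl <- manual_baseline(b, rnorm(5, 70, 5), sig, 4)
  d <- random_day(30, noise_sd = 2, basis = b)
  post <- calibrate_day(bl, d)
  phi <- eval_basis(b, d$timestamps)
  oracle <- posterior_oracle(bl$coef_mean, bl$coef_cov, phi, d$values,
                             bl$noise_var)
  expect_lt(max(abs(post$coef_post - oracle$coef_post)), 1e-8)
  expect_lt(max(abs(post$cov_post - oracle$cov_post)), 1e-8)
})

test_that("posterior covariance is symmetric PSD and never exceeds the prior", {
  set.seed(17)
  b <- hr_basis(6, 4)
  grid <- seq(0, 24, length.out = 145)
  for (rep in 1:5) {
    bl <- manual_baseline(b, rnorm(6, 70, 5), random_psd(6), runif(1, 1, 16))
    post <- calibrate_day(bl, random_day(sample(5:50, 1), noise_sd = 3,
                                         basis = b))
    expect_identical(post$cov_post, t(post$cov_post))
    expect_gte(min(eigen(post$cov_post, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-12)
    prior_sd <- baseline_band(bl, grid)$sd_bpm
    post_sd <- posterior_band(post, grid)$sd_bpm
    expect_true(all(post_sd <= prior_sd + 1e-8))
  }
})

test_that("calibration shrinks toward the data in the near-noiseless limit", {
  set.seed(19)
  b <- hr_basis(5, 4)
  coef_day <- c(55, 85, 95, 75, 60)
  t <- seq(0.2, 23.8, length.out = 40)
  y <- drop(crossprod(eval_basis(b, t), coef_day))
  bl <- manual_baseline(b, rep(70, 5), diag(25, 5), 1e-12)
  post <- calibrate_day(bl, day_record(t, y))
  expect_equal(posterior_mean(post, t), y, tolerance = 1e-4)
})

test_that("a single high observation pulls the mean part way toward it", {
  set.seed(23)
  b <- hr_basis(5, 4)
  bl <- manual_baseline(b, rep(70, 5), random_psd(5), 9)
  t_obs <- 12.3
  prior_at <- baseline_mean(bl, t_obs)
  post <- calibrate_day(bl, day_record(t_obs, prior_at + 30))
  post_at <- posterior_mean(post, t_obs)
  expect_gt(post_at, prior_at)
  expect_lt(post_at, prior_at + 30)
})

test_that("data at the prior mean leave the mean fixed while variance shrinks", {
  set.seed(29)
  b <- hr_basis(5, 4)
  bl <- manual_baseline(b, rnorm(5, 70, 5), random_psd(5), 4)
  t <- seq(1, 23, length.out = 25)
  post <- calibrate_day(bl, day_record(t, baseline_mean(bl, t)))
  expect_equal(post$coef_post, bl$coef_mean, tolerance = 1e-10)
  expect_lt(sum(diag(post$cov_post)), sum(diag(bl$coef_cov)))
})

test_that("posterior update is invariant to observation order", {
  set.seed(31)
  b <- hr_basis(5, 4)
  bl <- manual_baseline(b, rnorm(5, 70, 5), random_psd(5), 4)
  t <- runif(20, 0, 24); y <- rnorm(20, 75, 8)
  p1 <- calibrate_day(bl, day_record(t, y))
  perm <- sample(20)
  p2 <- calibrate_day(bl, day_record(t[perm], y[perm]))
  expect_equal(p1$coef_post, p2$coef_post, tolerance = 1e-12)
  expect_equal(p1$cov_post, p2$cov_post, tolerance = 1e-12)
})

test_that("nested data sets contract the posterior monotonically", {
  set.seed(37)
  b <- hr_basis(5, 4)
  bl <- manual_baseline(b, rnorm(5, 70, 5), random_psd(5), 4)
  t <- sort(runif(40, 0, 24)); y <- rnorm(40, 75, 6)
  sub <- sort(sample(40, 15))
  p_small <- calibrate_day(bl, day_record(t[sub], y[sub]))
  p_large <- calibrate_day(bl, day_record(t, y))
  grid <- seq(0, 24, length.out = 97)
  expect_true(all(posterior_band(p_large, grid)$sd_bpm <=
                    posterior_band(p_small, grid)$sd_bpm + 1e-8))
})

test_that("posterior-mean accuracy improves with more observations", {
  set.seed(41)
  b <- hr_basis(5, 4)
  sig <- random_psd(5)
  coef_day <- c(58, 88, 98, 72, 62)
  grid <- seq(0, 24, length.out = 97)
  truth <- drop(crossprod(eval_basis(b, grid), coef_day))
  bl <- manual_baseline(b, rep(70, 5), sig, 9)
  mse <- numeric(0)
  for (n in c(5, 20, 100)) {
    e <- numeric(100)
    for (r in 1:100) {
      t <- sort(runif(n, 0, 24))
      y <- drop(crossprod(eval_basis(b, t), coef_day)) + rnorm(n, 0, 3)
      post <- calibrate_day(bl, day_record(t, pmax(y, 1)))
      e[r] <- mean((posterior_mean(post, grid) - truth)^2)
    }
    mse <- c(mse, mean(e))
  }
  expect_true(all(diff(mse) < 0))
})

test_that("imputation is consistent at observed times and flags far gaps", {
  set.seed(43)
  b <- hr_basis(6, 4)
  bl <- manual_baseline(b, rnorm(6, 70, 5), random_psd(6), 4)
  t_obs <- c(seq(0.5, 9.5, by = 0.5), seq(14.5, 23.5, by = 0.5))  # gap 10-14
  y <- rnorm(length(t_obs), 72, 5)
  post <- calibrate_day(bl, day_record(t_obs, y))
  imp <- impute_gaps(post, t_obs)
  expect_equal(imp$mean_bpm, posterior_mean(post, t_obs))
  expect_false(any(imp$extrapolated))
  gap_grid <- seq(10, 14, by = 0.25)
  gap <- impute_gaps(post, gap_grid)
  obs_sd <- posterior_band(post, t_obs)$sd_bpm
  expect_true(all(gap$sd_bpm >= min(obs_sd)))
  expect_true(gap$extrapolated[gap_grid == 12])   # deep in the gap
  expect_false(gap$extrapolated[1])               # 0.5 h from data
  # no observations at all: prior curve, all flagged
  p0 <- calibrate_day(bl, day_record(numeric(0), numeric(0)))
  full <- impute_gaps(p0, seq(0, 24, by = 1))
  expect_equal(full$mean_bpm, baseline_mean(bl, seq(0, 24, by = 1)))
  expect_true(all(full$extrapolated))
})

test_that("degenerate zero-variance zero-noise calibration falls back to the prior", {
  b <- hr_basis(4, 4)
  bl <- manual_baseline(b, rep(70, 4), matrix(0, 4, 4), 0)
  d <- day_record(c(20, 22), c(70, 75))
  post <- calibrate_day(bl, d)
  expect_identical(post$coef_post, bl$coef_mean)
  expect_identical(post$cov_post, bl$coef_cov)
})
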