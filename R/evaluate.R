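# Benchmark of heart-rate estimators against a ground-truth sensor:
#   A raw noisy-sensor values        B population mean of all subjects
#   C subject-specific mean          D subject's baseline functional mean
#   E calibrated functional mean (the proposed estimator)
# scored by MSE and error standard deviation under a leave-one-day-out
# protocol.

method_result <- function(method_id, estimates, truth_values) {
  estimates <- as.numeric(estimates)
  truth_values <- as.numeric(truth_values)
  stopifnot(length(estimates) == length(truth_values))
  errors <- estimates - truth_values
  n <- length(errors)
  structure(
    list(method_id = method_id, estimates = estimates, errors = errors,
         mse = mean(errors^2),
         error_sd = if (n >= 2L) stats::sd(errors) else NA_real_,
         n_test = n),
    class = "method_result"
  )
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("Method %s: MSE %.2f (Error SD %.2f) over %d test points\n",
              x$method_id, x$mse, x$error_sd, x$n_test))
  invisible(x)
}

# Index of the nearest observed timestamp for each test timestamp; NA when
# farther than max_gap_hours.
nearest_index <- function(test_t, obs_t, max_gap_hours = Inf) {
  vapply(test_t, function(t) {
    i <- which.min(abs(obs_t - t))
    if (abs(obs_t[i] - t) <= max_gap_hours) i else NA_integer_
  }, integer(1))
}

#' Method A: raw noisy-sensor values
#'
#' Scores the raw noisy sensor itself: for each test timestamp, the estimate
#' is the sensor value at the nearest available timestamp of the same day.
#'
#' @param noisy_day A nonempty [day_record()] from the noisy sensor.
#' @param test A [day_record()] holding the ground-truth test points.
#' @param max_gap_hours Maximum timestamp mismatch allowed (default `Inf`;
#'   the leave-one-day-out driver restricts the test set up front instead).
#' @return A `"method_result"`.
#' @export
method_a_raw <- function(noisy_day, test, max_gap_hours = Inf) {
  stopifnot(inherits(noisy_day, "day_record"), inherits(test, "day_record"))
  if (!length(noisy_day$values))
    stop("method A requires a nonempty noisy day", call. = FALSE)
  idx <- nearest_index(test$timestamps, noisy_day$timestamps, max_gap_hours)
  keep <- !is.na(idx)
  method_result("A", noisy_day$values[idx[keep]], test$values[keep])
}

history_values <- function(history) {
  if (inherits(history, "day_record")) history <- list(history)
  if (is.list(history))
    history <- unlist(lapply(history, `[[`, "values"), use.names = FALSE)
  as.numeric(history)
}

#' Method B: population mean of all subjects
#'
#' A single scalar — the grand mean of all historical values pooled across
#' subjects, each observation weighted equally — used as the estimate at
#' every test timestamp.
#'
#' @param all_subjects_history Historical values: a numeric vector, a
#'   [day_record()], or a list of them (pooled).
#' @param test A [day_record()] holding the ground-truth test points.
#' @return A `"method_result"`.
#' @export
method_b_population_mean <- function(all_subjects_history, test) {
  vals <- history_values(all_subjects_history)
  if (!length(vals)) stop("empty history", call. = FALSE)
  method_result("B", rep(mean(vals), length(test$values)), test$values)
}

#' Method C: subject-specific mean
#'
#' As [method_b_population_mean()], but pooling only the subject's own
#' historical values.
#'
#' @param subject_history Historical values for one subject (vector,
#'   [day_record()], or list of them).
#' @param test A [day_record()] holding the ground-truth test points.
#' @return A `"method_result"`.
#' @export
method_c_subject_mean <- function(subject_history, test) {
  vals <- history_values(subject_history)
  if (!length(vals)) stop("empty history", call. = FALSE)
  method_result("C", rep(mean(vals), length(test$values)), test$values)
}

#' Method D: the subject's baseline functional mean
#'
#' @param baseline An [estimate_baseline()] result (fit without the test day).
#' @param test A [day_record()] holding the ground-truth test points.
#' @return A `"method_result"`.
#' @export
method_d_functional_mean <- function(baseline, test) {
  method_result("D", baseline_mean(baseline, test$timestamps), test$values)
}

#' Method E: the calibrated functional mean (proposed)
#'
#' @param posterior A [calibrate_day()] result; by protocol the calibration
#'   consumed the test day's noisy-sensor measurements, never the
#'   ground-truth sensor.
#' @param test A [day_record()] holding the ground-truth test points.
#' @return A `"method_result"`.
#' @export
method_e_calibrated <- function(posterior, test) {
  method_result("E", posterior_mean(posterior, test$timestamps), test$values)
}

#' Leave-one-day-out benchmark for one subject
#'
#' For each day with both a noisy record and a ground-truth record: the
#' baseline is estimated from the remaining noisy days, calibrated with the
#' test day's noisy measurements, and all five methods are scored against the
#' ground-truth sensor on that day.  Test points are the ground-truth
#' observations whose timestamp lies within `max_gap_hours` of some noisy
#' observation of the same day; unmatched points are dropped from every
#' method identically, so all methods are scored on the same test set.
#' Errors are pooled across test days into one result per method.
#'
#' @param noisy_days List of noisy [day_record()]s (the subject's history).
#' @param truth_days List of ground-truth [day_record()]s (days without one
#'   are never test days).
#' @param basis An [hr_basis()] object.
#' @param population_values Optional numeric vector of historical values from
#'   the *other* subjects of the cohort; method B pools these with the
#'   subject's own history (each observation weighted equally).  When `NULL`
#'   (single-subject case) B degenerates to C.
#' @param max_gap_hours Maximum noisy/ground-truth timestamp mismatch
#'   (default 5 minutes).
#' @param min_obs,ridge Forwarded to [estimate_baseline()].
#' @return Named list of pooled `"method_result"`s (`A` ... `E`) with
#'   attributes `n_test_days` and `skipped` (days skipped, with reasons).
#' @export
leave_one_day_out <- function(noisy_days, truth_days, basis,
                              population_values = NULL,
                              max_gap_hours = 5 / 60,
                              min_obs = NULL, ridge = 0) {
  stopifnot(all(vapply(noisy_days, inherits, TRUE, "day_record")),
            all(vapply(truth_days, inherits, TRUE, "day_record")))
  if (length(noisy_days) < 3L)
    stop("leave-one-day-out needs at least 3 days of noisy data", call. = FALSE)
  noisy_idx <- vapply(noisy_days, `[[`, integer(1), "day")
  errs <- list(A = numeric(0), B = numeric(0), C = numeric(0),
               D = numeric(0), E = numeric(0))
  skipped <- character(0)
  n_test_days <- 0L
  for (td in truth_days) {
    pos <- match(td$day, noisy_idx)
    if (is.na(pos)) {
      skipped <- c(skipped, sprintf("day %d: no noisy record", td$day))
      next
    }
    noisy_test <- noisy_days[[pos]]
    idx <- nearest_index(td$timestamps, noisy_test$timestamps, max_gap_hours)
    keep <- !is.na(idx)
    if (sum(keep) < 2L) {
      skipped <- c(skipped, sprintf("day %d: fewer than 2 matched test points",
                                    td$day))
      next
    }
    test <- day_record(td$timestamps[keep], td$values[keep],
                       day = td$day, subject = td$subject)
    history <- noisy_days[-pos]
    baseline <- estimate_baseline(history, basis, min_obs = min_obs,
                                  ridge = ridge)
    post <- calibrate_day(baseline, noisy_test)
    hist_vals <- history_values(history)
    pop_vals <- c(population_values, hist_vals)
    res <- list(
      A = method_a_raw(noisy_test, test),
      B = method_b_population_mean(pop_vals, test),
      C = method_c_subject_mean(hist_vals, test),
      D = method_d_functional_mean(baseline, test),
      E = method_e_calibrated(post, test)
    )
    for (m in names(errs)) errs[[m]] <- c(errs[[m]], res[[m]]$errors)
    n_test_days <- n_test_days + 1L
  }
  if (n_test_days == 0L)
    stop("no usable test day for this subject", call. = FALSE)
  out <- lapply(names(errs), function(m)
    method_result(m, errs[[m]], rep(0, length(errs[[m]]))))
  names(out) <- names(errs)
  structure(out, n_test_days = n_test_days, skipped = skipped)
}

#' Cohort-level benchmark table
#'
#' Runs the leave-one-day-out benchmark for every subject in a cohort and
#' assembles the per-subject and pooled ("Overall") MSE / Error SD table.
#' Method B's population mean pools all subjects' noisy historical values
#' (for each subject's evaluation, the other subjects' full records plus the
#' subject's own non-test days, observation-weighted).  Subjects lacking a
#' ground-truth record or with fewer than 3 noisy days are skipped with a
#' logged reason, mirroring studies where the reference sensor failed for
#' some participants.
#'
#' @param cohort Named list: for each subject, a list with elements `noisy`
#'   and `truth`, each a list of [day_record()]s (the shape returned by
#'   [read_hr_csv()] for the paired files).
#' @param basis An [hr_basis()] object.
#' @param ... Forwarded to [leave_one_day_out()].
#' @return An object of class `"benchmark_table"`: `per_subject` (list of
#'   per-subject method results), `overall` (pooled), `skipped_subjects`.
#' @export
run_benchmark <- function(cohort, basis, ...) {
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  subjects <- names(cohort)
  all_vals <- lapply(cohort, function(s) history_values(s$noisy))
  per_subject <- list()
  skipped <- character(0)
  for (s in subjects) {
    noisy <- cohort[[s]]$noisy
    truth <- cohort[[s]]$truth
    if (is.null(truth) || !length(truth)) {
      skipped <- c(skipped, sprintf("%s: no ground-truth record", s))
      next
    }
    if (length(noisy) < 3L) {
      skipped <- c(skipped, sprintf("%s: fewer than 3 noisy days", s))
      next
    }
    pop <- unlist(all_vals[setdiff(subjects, s)], use.names = FALSE)
    res <- tryCatch(
      leave_one_day_out(noisy, truth, basis, population_values = pop, ...),
      error = function(e) {
        skipped <<- c(skipped, sprintf("%s: %s", s, conditionMessage(e)))
        NULL
      })
    if (!is.null(res)) per_subject[[s]] <- res
  }
  if (!length(per_subject))
    stop("no subject could be evaluated", call. = FALSE)
  methods <- c("A", "B", "C", "D", "E")
  overall <- lapply(methods, function(m) {
    e <- unlist(lapply(per_subject, function(r) r[[m]]$errors),
                use.names = FALSE)
    method_result(m, e, rep(0, length(e)))
  })
  names(overall) <- methods
  structure(list(per_subject = per_subject, overall = overall,
                 skipped_subjects = skipped),
            class = "benchmark_table")
}

#' Long-format data frame of a benchmark table
#'
#' @param x A [run_benchmark()] result.
#' @param ... Unused.
#' @return Data frame with columns `subject` (including `"Overall"`),
#'   `method`, `mse`, `error_sd`, `n_test`.
#' @export
as.data.frame.benchmark_table <- function(x, ...) {
  rows <- list()
  for (s in names(x$per_subject))
    for (m in names(x$per_subject[[s]]))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, method = m,
        mse = x$per_subject[[s]][[m]]$mse,
        error_sd = x$per_subject[[s]][[m]]$error_sd,
        n_test = x$per_subject[[s]][[m]]$n_test)
  for (m in names(x$overall))
    rows[[length(rows) + 1L]] <- data.frame(
      subject = "Overall", method = m,
      mse = x$overall[[m]]$mse, error_sd = x$overall[[m]]$error_sd,
      n_test = x$overall[[m]]$n_test)
  do.call(rbind, rows)
}

#' @export
print.benchmark_table <- function(x, ...) {
  df <- as.data.frame(x)
  cell <- function(s, m) {
    r <- df[df$subject == s & df$method == m, ]
    sprintf("%.2f (%.2f)", r$mse, r$error_sd)
  }
  subs <- c(names(x$per_subject), "Overall")
  wide <- do.call(rbind, lapply(subs, function(s)
    data.frame(subject = s,
               A = cell(s, "A"), B = cell(s, "B"), C = cell(s, "C"),
               D = cell(s, "D"), E = cell(s, "E"))))
  cat("Benchmark: MSE (Error SD) vs ground-truth sensor\n")
  print(wide, row.names = FALSE)
  if (length(x$skipped_subjects))
    cat("Skipped:", paste(x$skipped_subjects, collapse = "; "), "\n")
  invisible(x)
}
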