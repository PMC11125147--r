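# Long-format CSV ingestion and run configuration.

hr_csv_columns <- c("subject_id", "day", "time_hours", "hr_bpm")

# CSV writer with exact float round trip: doubles are rendered with 17
# significant digits (the shortest width guaranteed to survive decimal
# serialization), so read.csv restores bit-identical values.
write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a long-format heart-rate CSV
#'
#' Reads a CSV with header `subject_id,day,time_hours,hr_bpm` (`time_hours`
#' is decimal hours since local midnight; missing data are simply absent
#' rows), groups rows by subject and day, sorts timestamps, and drops rows
#' whose heart rate is non-finite or outside the physiological plausibility
#' range `[hr_min, hr_max]` bpm, reporting the dropped count to stderr.
#'
#' @param path CSV file path.
#' @param hr_min,hr_max Plausibility bounds in bpm (defaults 20 and 260);
#'   set to `-Inf`/`Inf` to disable the filter.
#' @return Named list (one element per subject) of lists of [day_record()]s,
#'   with attribute `n_dropped`.
#' @export
read_hr_csv <- function(path, hr_min = 20, hr_max = 260) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e)
      stop("empty or unreadable input '", path, "': ", conditionMessage(e),
           call. = FALSE))
  missing <- setdiff(hr_csv_columns, names(df))
  if (length(missing))
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(df))
    stop("empty input: '", path, "' has a header but no rows", call. = FALSE)
  ok <- is.finite(df$hr_bpm) & df$hr_bpm >= hr_min & df$hr_bpm <= hr_max
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("read_hr_csv: dropped %d row(s) with heart rate outside [%g, %g] bpm",
                    n_dropped, hr_min, hr_max))
  df <- df[ok, , drop = FALSE]
  if (!nrow(df))
    stop("empty input: no rows of '", path, "' survive the plausibility filter",
         call. = FALSE)
  out <- lapply(split(df, df$subject_id), function(sub) {
    days <- lapply(split(sub, sub$day), function(d)
      day_record(d$time_hours, d$hr_bpm, day = d$day[1L],
                 subject = d$subject_id[1L]))
    days[order(vapply(days, `[[`, integer(1), "day"))]
  })
  structure(out, n_dropped = n_dropped)
}

default_run_config <- function() {
  list(
    model = list(n_basis = 13L, spline_order = 4L, ridge = 0,
                 min_obs_per_day = NULL, t_period = 24),
    simulate = as.list(unclass(sim_config()))[
      setdiff(names(unclass(sim_config())), c("coef_true", "coef_cov_true"))],
    evaluate = list(max_gap_hours = 5 / 60),
    seed = 1L
  )
}

#' Read and validate a run configuration (YAML or JSON)
#'
#' Configuration files hold up to four blocks — `model` (`n_basis`,
#' `spline_order`, `ridge`, `min_obs_per_day`, `t_period`), `simulate`
#' (the [sim_config()] fields), `evaluate` (`max_gap_hours`) — plus a
#' top-level `seed`.  Omitted keys take the package defaults; unknown keys
#' are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for the
#'   defaults.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(user)) return(cfg)
  bad_top <- setdiff(names(user), names(cfg))
  if (length(bad_top))
    stop("unknown config key(s): ", paste(bad_top, collapse = ", "),
         call. = FALSE)
  for (block in intersect(names(user), c("model", "simulate", "evaluate"))) {
    bad <- setdiff(names(user[[block]]), names(cfg[[block]]))
    if (length(bad))
      stop("unknown config key(s) in '", block, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg[[block]][names(user[[block]])] <- user[[block]]
  }
  if (!is.null(user$seed)) cfg$seed <- as.integer(user$seed)
  cfg
}

config_basis <- function(cfg) {
  hr_basis(cfg$model$n_basis, cfg$model$spline_order,
           t_start = 0, t_end = cfg$model$t_period)
}

config_sim <- function(cfg, seed = NULL) {
  args <- cfg$simulate
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_config, args)
}

# Small provenance manifest written next to CLI outputs.
write_run_manifest <- function(path, command, cfg, seed, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(format = "begp-run-manifest", command = command,
         package_version = as.character(utils::packageVersion("begp")),
         seed = seed, config = cfg, input_md5 = hashes),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
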