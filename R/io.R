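#' Read a raw accelerometer CSV
#'
#' Expects the documented dialect: header `t_s,ax_g,ay_g,az_g`, one row per
#' sample, times in seconds from session start, acceleration in g. Malformed
#' files are rejected, naming the first offending line; nothing is silently
#' repaired.
#'
#' @param path CSV file path.
#' @return Tibble `t_s`, `ax_g`, `ay_g`, `az_g` with strictly increasing
#'   timestamps.
#' @export
read_accel_csv <- function(path) {
  df <- .read_checked(path, c(t_s = "d", ax_g = "d", ay_g = "d", az_g = "d"))
  if (nrow(df)) {
    bad <- which(diff(df$t_s) <= 0)
    if (length(bad))
      abort(sprintf("%s: timestamps not strictly increasing at line %d.",
                    path, bad[1] + 2L))  # +1 header, +1 second row of pair
  }
  .validate_accel(df)
}

#' Write a raw accelerometer CSV
#' @param accel Tibble `t_s`, `ax_g`, `ay_g`, `az_g`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(accel, path) {
  readr::write_csv(.validate_accel(accel), path)
  invisible(path)
}

#' Read / write a connectivity CSV
#'
#' One row per connected interval, header `start_s,end_s`; intervals must be
#' disjoint, sorted and half-open.
#'
#' @param path File path.
#' @return Tibble `start_s`, `end_s`.
#' @export
read_connectivity_csv <- function(path) {
  .validate_intervals(.read_checked(path, c(start_s = "d", end_s = "d")))
}

#' @rdname read_connectivity_csv
#' @param intervals Tibble `start_s`, `end_s`.
#' @export
write_connectivity_csv <- function(intervals, path) {
  readr::write_csv(.validate_intervals(intervals), path)
  invisible(path)
}

#' Read a 15-second epoch CSV from a criterion posture monitor
#'
#' Expects header `epoch_start_s,sitting_s,standing_s,stepping_s`: epochs
#' sorted at exact 15-second spacing, per-behavior seconds non-negative and
#' summing to at most the epoch length. Derived totals are the per-behavior
#' epoch sums in minutes.
#'
#' @param path CSV file path.
#' @param epoch_s Epoch length in seconds, default 15.
#' @param col_map Optional named character vector mapping the documented
#'   column names to the names used in the file, e.g.
#'   `c(epoch_start_s = "time", sitting_s = "sit")`, for externally produced
#'   exports.
#' @return List with `epochs` (tibble) and `totals` (one-row tibble of
#'   minutes with composites).
#' @export
read_epoch_csv <- function(path, epoch_s = 15, col_map = NULL) {
  need <- c("epoch_start_s", "sitting_s", "standing_s", "stepping_s")
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  .stop_on_problems(df, path)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df))
        abort(sprintf("%s: mapped column '%s' not found.", path, col_map[[std]]))
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  if (!all(need %in% names(df)))
    abort(sprintf("%s: missing columns %s.", path,
                  paste(setdiff(need, names(df)), collapse = ", ")))
  df <- as_tibble(df)[need]
  if (nrow(df) == 0L) {
    warn(sprintf("%s: no epochs; totals are zero.", path))
    return(list(epochs = df,
                totals = derive_composites(tibble(sitting_min = 0,
                                                  standing_min = 0,
                                                  stepping_min = 0))))
  }
  secs <- as.matrix(df[c("sitting_s", "standing_s", "stepping_s")])
  if (any(secs < 0) || any(rowSums(secs) > epoch_s + 1e-9)) {
    i <- which(rowSums(secs) > epoch_s + 1e-9 | apply(secs < 0, 1, any))[1]
    abort(sprintf("%s: epoch %d has invalid behavior seconds.", path, i))
  }
  if (nrow(df) > 1L) {
    gaps <- diff(df$epoch_start_s)
    bad <- which(abs(gaps - epoch_s) > 1e-9)
    if (length(bad))
      abort(sprintf("%s: epochs not at %g-second spacing at epoch %d.",
                    path, epoch_s, bad[1] + 1L))
  }
  totals <- derive_composites(tibble(
    sitting_min = sum(df$sitting_s) / 60,
    standing_min = sum(df$standing_s) / 60,
    stepping_min = sum(df$stepping_s) / 60))
  list(epochs = df, totals = totals)
}

#' Tally a behavior timeline into fixed epochs
#'
#' Converts an interval timeline (e.g. a ground-truth bout schedule or a
#' classified timeline) into per-epoch behavior seconds in the epoch CSV
#' layout, emulating a criterion device's export.
#'
#' @param timeline Tibble `start_s`, `end_s`, `label`.
#' @param epoch_s Epoch length, default 15 s.
#' @return Tibble `epoch_start_s`, `sitting_s`, `standing_s`, `stepping_s`.
#' @export
timeline_to_epochs <- function(timeline, epoch_s = 15) {
  stopifnot(all(c("start_s", "end_s", "label") %in% names(timeline)))
  if (!nrow(timeline))
    return(tibble(epoch_start_s = numeric(), sitting_s = numeric(),
                  standing_s = numeric(), stepping_s = numeric()))
  t0 <- floor(min(timeline$start_s) / epoch_s) * epoch_s
  t1 <- max(timeline$end_s)
  starts <- seq(t0, t1 - 1e-9, by = epoch_s)
  out <- purrr::map_dfr(starts, function(s) {
    e <- s + epoch_s
    ov <- pmax(0, pmin(timeline$end_s, e) - pmax(timeline$start_s, s))
    tibble(epoch_start_s = s,
           sitting_s = sum(ov[timeline$label == "sitting"]),
           standing_s = sum(ov[timeline$label == "standing"]),
           stepping_s = sum(ov[timeline$label == "stepping"]))
  })
  out
}

#' Read / write paired per-subject measurements
#'
#' CSV layout `subject_id,behavior,test_min,criterion_min`, behaviors among
#' sitting, standing, stepping (composites are derived at analysis time).
#'
#' @param path File path.
#' @return Tibble in the paired layout.
#' @export
read_paired_csv <- function(path) {
  df <- .read_checked(path, c(subject_id = "c", behavior = "c",
                              test_min = "d", criterion_min = "d"))
  if (!all(df$behavior %in% .base_behaviors)) {
    bad <- which(!df$behavior %in% .base_behaviors)[1]
    abort(sprintf("%s: unknown behavior '%s' at line %d.",
                  path, df$behavior[bad], bad + 1L))
  }
  .validate_paired(df)
}

#' @rdname read_paired_csv
#' @param paired Tibble `subject_id`, `behavior`, `test_min`, `criterion_min`.
#' @export
write_paired_csv <- function(paired, path) {
  readr::write_csv(.validate_paired(paired), path)
  invisible(path)
}

#' Write a classified timeline CSV
#' @param timeline Tibble `start_s`, `end_s`, `label`.
#' @param path Output path.
#' @export
write_timeline_csv <- function(timeline, path) {
  stopifnot(all(c("start_s", "end_s", "label") %in% names(timeline)))
  readr::write_csv(as_tibble(timeline)[c("start_s", "end_s", "label")], path)
  invisible(path)
}

#' Read / write behavior totals as JSON
#'
#' Keys `sitting_min`, `standing_min`, `stepping_min`, `stationary_min`,
#' `upright_min`, `recording_min`, plus any provenance fields supplied.
#'
#' @param totals One-row data frame of totals.
#' @param path File path.
#' @param extra Named list of provenance fields (e.g. seed, config hash) to
#'   embed alongside the totals.
#' @export
write_totals_json <- function(totals, path, extra = list()) {
  keys <- c("sitting_min", "standing_min", "stepping_min",
            "stationary_min", "upright_min", "recording_min")
  totals <- derive_composites(totals)
  out <- c(as.list(totals[1, keys]), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_totals_json
#' @export
read_totals_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- c("sitting_min", "standing_min", "stepping_min")
  if (!all(keys %in% names(raw)))
    abort(sprintf("%s: missing totals keys.", path))
  derive_composites(tibble(sitting_min = raw$sitting_min,
                           standing_min = raw$standing_min,
                           stepping_min = raw$stepping_min))
}

#' Write / read an agreement report
#'
#' JSON keeps the full per-behavior table (without point clouds); the CSV is
#' a flat long table with one row per behavior and statistic.
#'
#' @param report An `agreement_report`.
#' @param path File path.
#' @param extra Named list of provenance fields embedded in the JSON.
#' @export
write_agreement_json <- function(report, path, extra = list()) {
  stopifnot(inherits(report, "agreement_report"))
  out <- c(list(n_subjects = report$n_subjects, fraction = report$fraction,
                regions = as.list(report$regions),
                table = tidy(report)), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_agreement_json
#' @return `read_agreement_json()` returns the per-behavior tibble with
#'   attributes `n_subjects` and `fraction`.
#' @export
read_agreement_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as_tibble(raw$table)
  attr(tab, "n_subjects") <- raw$n_subjects
  attr(tab, "fraction") <- raw$fraction
  tab
}

#' @rdname write_agreement_json
#' @export
write_agreement_csv <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  long <- tidy(report) |>
    dplyr::mutate(dplyr::across(!"behavior", as.character)) |>
    tidyr::pivot_longer(!"behavior", names_to = "statistic",
                        values_to = "value")
  readr::write_csv(long, path)
  invisible(path)
}

# read a CSV with an exact column contract; reject rather than repair
.read_checked <- function(path, spec) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  types <- paste(unname(spec), collapse = "")
  df <- suppressWarnings(
    readr::read_csv(path, col_types = types, show_col_types = FALSE))
  if (!all(names(spec) %in% names(df)))
    abort(sprintf("%s: missing columns %s.", path,
                  paste(setdiff(names(spec), names(df)), collapse = ", ")))
  .stop_on_problems(df, path)
  num <- names(spec)[unname(spec) == "d"]
  for (col in num) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      abort(sprintf("%s: non-numeric value in '%s' at line %d.",
                    path, col, bad[1] + 1L))
  }
  as_tibble(df)[names(spec)]
}

.stop_on_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr))
    abort(sprintf("%s: malformed value at line %d (%s).",
                  path, pr$row[1], pr$expected[1]))
  invisible(df)
}
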