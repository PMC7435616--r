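#' Classifier configuration
#'
#' Bundles the tunable parameters of the posture/stepping decision-rule state
#' machine.
#'
#' @param z_threshold Normalized z-axis cutoff separating sitting from
#'   standing. A reading strictly above the threshold feeds the sitting
#'   counter; a reading at or below it feeds the standing counter. Default
#'   0.8, dimensionless.
#' @param counter_limit Number of consecutive same-posture readings required
#'   to commit a posture and stop the step counter. Default 75 readings.
#' @param step_mode Step-detector sensitivity preset: `"normal"`,
#'   `"sensitive"` or `"robust"`. See [detect_steps()].
#' @param adjustment_threshold_min Discrepancy (minutes) between summed
#'   behavior counters and elapsed recording time at which the weighted
#'   reconciliation is applied. Default 15 minutes.
#' @param sampling_rate_hz Nominal accelerometer sampling rate. Default 6.25.
#' @param step_trigger_g Dynamic-acceleration magnitude (g) above which a
#'   reading counts as detected movement, entering the stepping state.
#'   Default 0.2 g.
#' @param z_smooth_s Width (seconds) of the causal moving-average low-pass
#'   applied to the z component and to the total magnitude before forming the
#'   normalized z ratio. Default 1 s; set to 0 to classify raw readings.
#'
#' @return A list of class `"classifier_config"`.
#' @export
classifier_config <- function(z_threshold = 0.8,
                              counter_limit = 75L,
                              step_mode = c("normal", "sensitive", "robust"),
                              adjustment_threshold_min = 15,
                              sampling_rate_hz = 6.25,
                              step_trigger_g = 0.2,
                              z_smooth_s = 1) {
  step_mode <- match.arg(step_mode)
  if (!is.numeric(z_threshold) || z_threshold <= 0 || z_threshold >= 1)
    abort("`z_threshold` must lie strictly between 0 and 1.")
  counter_limit <- as.integer(counter_limit)
  if (is.na(counter_limit) || counter_limit < 1L)
    abort("`counter_limit` must be a positive integer.")
  if (adjustment_threshold_min <= 0)
    abort("`adjustment_threshold_min` must be positive.")
  if (sampling_rate_hz <= 0) abort("`sampling_rate_hz` must be positive.")
  if (step_trigger_g <= 0) abort("`step_trigger_g` must be positive.")
  if (z_smooth_s < 0) abort("`z_smooth_s` must be non-negative.")
  structure(
    list(z_threshold = z_threshold, counter_limit = counter_limit,
         step_mode = step_mode,
         adjustment_threshold_min = adjustment_threshold_min,
         sampling_rate_hz = sampling_rate_hz,
         step_trigger_g = step_trigger_g, z_smooth_s = z_smooth_s),
    class = "classifier_config")
}

#' Recording window
#'
#' The configured recording period (working hours), in seconds from session
#' start. Only readings inside the window are ever classified.
#'
#' @param start_s,end_s Window limits in seconds; the window is half-open
#'   `[start_s, end_s)`.
#' @param max_duration_s Optional upper bound on the window duration; the
#'   wear protocol this package targets uses 3--8 working hours, but no bound
#'   is enforced unless one is supplied.
#' @return A list of class `"recording_window"`.
#' @export
recording_window <- function(start_s, end_s, max_duration_s = NULL) {
  if (!is.numeric(start_s) || !is.numeric(end_s) || end_s <= start_s)
    abort("`end_s` must be greater than `start_s`.")
  if (!is.null(max_duration_s) && (end_s - start_s) > max_duration_s)
    abort("recording window exceeds `max_duration_s`.")
  structure(list(start_s = start_s, end_s = end_s), class = "recording_window")
}

#' Normalized z-axis value
#'
#' The gravity-projection index of the thigh axis: 0 for a perfectly vertical
#' thigh (standing), 1 for a perfectly horizontal thigh (sitting). Computed as
#' |az| divided by the total acceleration magnitude and clamped to \[0, 1\];
#' under pure gravity this equals |sin(inclination)| of the thigh from
#' vertical.
#'
#' @param ax,ay,az Acceleration components in g; vectorized.
#' @return Numeric vector of values in \[0, 1\].
#' @export
#' @examples
#' normalized_z(0, 0, 1)        # horizontal thigh -> 1
#' normalized_z(1, 0, 0)        # vertical thigh -> 0
#' normalized_z(cos(pi / 4), 0, sin(pi / 4))  # 45 degrees -> sqrt(0.5)
normalized_z <- function(ax, ay, az) {
  mag <- sqrt(ax^2 + ay^2 + az^2)
  if (any(!is.finite(mag)) || any(mag == 0))
    abort("invalid sample: zero or non-finite acceleration vector.")
  pmin(1, pmax(0, abs(az) / mag))
}

#' Posture from the normalized z value
#'
#' Sitting when the value is strictly above the threshold; standing when it is
#' equal to or below it.
#'
#' @param z Normalized z values in \[0, 1\]; vectorized.
#' @param threshold Cutoff, default 0.8.
#' @return Character vector, `"sitting"` or `"standing"`.
#' @export
posture_from_z <- function(z, threshold = 0.8) {
  if (any(z < 0 | z > 1, na.rm = TRUE))
    abort("`z` must lie in [0, 1].")
  ifelse(z > threshold, "sitting", "standing")
}

# causal moving average over k samples; the first k-1 values use the
# expanding mean so no reading is dropped
.causal_ma <- function(x, k) {
  if (k <= 1L) return(x)
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  head_n <- seq_len(min(k, n))
  out[head_n] <- cs[head_n] / head_n
  if (n > k) {
    idx <- (k + 1L):n
    out[idx] <- (cs[idx] - cs[idx - k]) / k
  }
  out
}

#' Classify a sensor stream into sitting, standing and stepping time
#'
#' Runs the counter-based decision-rule state machine over a raw triaxial
#' thigh-accelerometer stream. Readings are classified only inside the
#' recording window and inside connected (Bluetooth-linked) intervals. When a
#' reading's dynamic acceleration exceeds the step trigger, stepping time
#' accrues and both posture counters reset; each quiet reading increments
#' exactly one posture counter (sitting if the smoothed normalized z exceeds
#' the threshold, standing otherwise) and zeroes the other; when a counter
#' reaches `counter_limit` readings the elapsed span is committed to that
#' posture and the step counter stops.
#'
#' @param accel Data frame with columns `t_s`, `ax_g`, `ay_g`, `az_g`:
#'   strictly increasing timestamps (seconds) and acceleration in g.
#' @param window A [recording_window()]. Defaults to the full span of the
#'   stream.
#' @param connected Optional data frame with columns `start_s`, `end_s`
#'   giving the disjoint, sorted intervals during which device and software
#'   were connected. `NULL` means connected throughout.
#' @param config A [classifier_config()].
#' @param adjust Apply the weighted time-reconciliation against elapsed
#'   window time when the discrepancy reaches the configured threshold?
#'   Default `TRUE`.
#'
#' @return A list of class `"activity_classification"`:
#'   \describe{
#'     \item{timeline}{tibble `start_s`, `end_s`, `label` of contiguous,
#'       non-overlapping intervals covering the window; gaps and out-of-window
#'       spans are labelled `"unmonitored"`.}
#'     \item{totals}{one-row tibble of minutes: `sitting_min`, `standing_min`,
#'       `stepping_min`, `stationary_min`, `upright_min`, `recording_min`
#'       (after reconciliation when `adjust = TRUE`).}
#'     \item{raw_totals}{the same totals before reconciliation.}
#'     \item{steps}{tibble of detected step events (`t_s`, `height_g`) from
#'       [detect_steps()] in the configured mode.}
#'     \item{elapsed_min, monitored_min}{window duration and connected-within-
#'       window duration, minutes.}
#'     \item{adjusted}{logical, whether reconciliation was triggered.}
#'   }
#' @export
classify_stream <- function(accel,
                            window = NULL,
                            connected = NULL,
                            config = classifier_config(),
                            adjust = TRUE) {
  stopifnot(inherits(config, "classifier_config"))
  accel <- .validate_accel(accel)
  if (is.null(window)) {
    window <- recording_window(min(accel$t_s),
                               max(accel$t_s) + 1 / config$sampling_rate_hz)
  }
  stopifnot(inherits(window, "recording_window"))
  dt <- 1 / config$sampling_rate_hz

  inside <- accel$t_s >= window$start_s & accel$t_s < window$end_s
  acc <- accel[inside, , drop = FALSE]
  elapsed_min <- (window$end_s - window$start_s) / 60

  if (nrow(acc) == 0L) {
    timeline <- tibble(start_s = window$start_s, end_s = window$end_s,
                       label = "unmonitored")
    totals <- derive_composites(
      tibble(sitting_min = 0, standing_min = 0, stepping_min = 0))
    return(structure(
      list(timeline = timeline, totals = totals, raw_totals = totals,
           steps = tibble(t_s = numeric(), height_g = numeric()),
           elapsed_min = elapsed_min, monitored_min = 0, adjusted = FALSE),
      class = "activity_classification"))
  }

  monitored <- .in_intervals(acc$t_s, connected)

  k <- max(1L, as.integer(round(config$z_smooth_s * config$sampling_rate_hz)))
  mag <- sqrt(acc$ax_g^2 + acc$ay_g^2 + acc$az_g^2)
  z_lp <- .causal_ma(abs(acc$az_g), k)
  mag_lp <- .causal_ma(mag, k)
  if (any(mag_lp == 0)) abort("invalid sample: zero acceleration vector.")
  z_norm <- pmin(1, pmax(0, z_lp / mag_lp))

  g_lp <- .causal_ma(mag, max(1L, 2L * k))
  dyn <- pmax(0, mag - g_lp)
  step_trig <- dyn > config$step_trigger_g

  # tolerance guards the boundary against round-off in the moving average:
  # a constant stream exactly at the threshold must classify as standing
  thr <- config$z_threshold * (1 + 256 * .Machine$double.eps)
  posture_code <- ifelse(z_norm > thr, 1L, 2L)
  label_code <- run_state_machine(posture_code, step_trig, monitored,
                                  config$counter_limit)
  labels <- c("unmonitored", "sitting", "standing", "stepping")[label_code + 1L]

  timeline <- .labels_to_timeline(acc$t_s, labels, dt, window)
  mins <- vapply(.base_behaviors, function(b) sum(labels == b) * dt / 60,
                 numeric(1))
  raw_totals <- derive_composites(
    tibble(sitting_min = mins[["sitting"]], standing_min = mins[["standing"]],
           stepping_min = mins[["stepping"]]))
  monitored_min <- sum(monitored) * dt / 60

  totals <- raw_totals
  adjusted <- FALSE
  if (adjust &&
      abs(elapsed_min - raw_totals$recording_min) >=
        config$adjustment_threshold_min &&
      raw_totals$recording_min > 0) {
    totals <- weighted_adjustment(raw_totals, elapsed_min,
                                  threshold = config$adjustment_threshold_min)
    adjusted <- TRUE
  }

  steps <- detect_steps(acc[monitored, , drop = FALSE],
                        mode = config$step_mode,
                        rate_hz = config$sampling_rate_hz)

  structure(
    list(timeline = timeline, totals = totals, raw_totals = raw_totals,
         steps = steps, elapsed_min = elapsed_min,
         monitored_min = monitored_min, adjusted = adjusted),
    class = "activity_classification")
}

#' @export
print.activity_classification <- function(x, ...) {
  cat("Activity classification\n")
  cat(sprintf("  elapsed %.1f min, monitored %.1f min%s\n",
              x$elapsed_min, x$monitored_min,
              if (x$adjusted) ", weighted adjustment applied" else ""))
  print(x$totals)
  invisible(x)
}

.validate_accel <- function(accel) {
  need <- c("t_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(accel)))
    abort(paste0("`accel` must have columns ", paste(need, collapse = ", "), "."))
  accel <- as_tibble(accel)[need]
  if (nrow(accel) == 0L) return(accel)
  if (any(!is.finite(as.matrix(accel))))
    abort("`accel` contains non-finite values.")
  bad <- which(diff(accel$t_s) <= 0)
  if (length(bad))
    abort(sprintf("timestamps not strictly increasing at row %d.", bad[1] + 1L))
  if (any(abs(accel[c("ax_g", "ay_g", "az_g")]) > 16))
    abort("acceleration outside the sensor's +/-16 g range.")
  accel
}

.validate_intervals <- function(iv) {
  need <- c("start_s", "end_s")
  if (!all(need %in% names(iv)))
    abort("interval table must have columns start_s, end_s.")
  iv <- as_tibble(iv)[need]
  if (nrow(iv) == 0L) return(iv)
  if (any(iv$end_s <= iv$start_s)) abort("intervals must satisfy end_s > start_s.")
  if (is.unsorted(iv$start_s, strictly = TRUE) ||
      any(iv$start_s[-1] < iv$end_s[-nrow(iv)]))
    abort("intervals must be disjoint and sorted.")
  iv
}

# membership of time points in a set of half-open [start, end) intervals
.in_intervals <- function(t, intervals) {
  if (is.null(intervals)) return(rep(TRUE, length(t)))
  intervals <- .validate_intervals(intervals)
  res <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals)))
    res <- res | (t >= intervals$start_s[i] & t < intervals$end_s[i])
  res
}

# run-length encode per-reading labels into a contiguous timeline over the
# window; each reading covers [t, t + dt)
.labels_to_timeline <- function(t, labels, dt, window) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  tl <- tibble(start_s = t[starts], end_s = t[ends] + dt, label = r$values)
  # clamp reading spans to the window and fill sampling gaps as unmonitored
  tl$end_s <- pmin(tl$end_s, c(tl$start_s[-1], window$end_s))
  pieces <- list()
  if (tl$start_s[1] > window$start_s)
    pieces[[length(pieces) + 1L]] <-
      tibble(start_s = window$start_s, end_s = tl$start_s[1],
             label = "unmonitored")
  pieces[[length(pieces) + 1L]] <- tl
  last_end <- tl$end_s[nrow(tl)]
  if (last_end < window$end_s)
    pieces[[length(pieces) + 1L]] <-
      tibble(start_s = last_end, end_s = window$end_s, label = "unmonitored")
  out <- dplyr::bind_rows(pieces)
  # merge adjacent intervals sharing a label
  keep <- c(TRUE, out$label[-1] != out$label[-nrow(out)] |
                  out$start_s[-1] != out$end_s[-nrow(out)])
  grp <- cumsum(keep)
  out |>
    dplyr::mutate(.grp = grp) |>
    dplyr::summarise(start_s = min(.data$start_s), end_s = max(.data$end_s),
                     label = .data$label[1], .by = ".grp") |>
    dplyr::select(!".grp")
}

#' Weighted time-reconciliation adjustment
#'
#' When the behavior counters disagree with the elapsed recording time by at
#' least the threshold (typically because of temporal Bluetooth
#' disconnections), each behavior is rescaled by `elapsed_min /
#' recording_min` and rounded to whole minutes by the largest-remainder rule,
#' so the rounded components sum exactly to the (rounded) elapsed time. For
#' example, counters of 75 min stepping, 10 min standing and 15 min sitting
#' against 115 elapsed minutes reconcile to 86, 12 and 17 minutes.
#'
#' @param totals One-row data frame with `sitting_min`, `standing_min`,
#'   `stepping_min` (composites, if present, are recomputed).
#' @param elapsed_min Elapsed recording time in minutes.
#' @param threshold Discrepancy (minutes) at which the adjustment triggers;
#'   default 15. Below the threshold the totals are returned unchanged.
#' @return One-row tibble of adjusted totals with composites.
#' @export
#' @examples
#' weighted_adjustment(
#'   tibble::tibble(sitting_min = 15, standing_min = 10, stepping_min = 75),
#'   elapsed_min = 115)
weighted_adjustment <- function(totals, elapsed_min, threshold = 15) {
  stopifnot(elapsed_min > 0)
  base <- c(sitting_min = totals$sitting_min[1],
            standing_min = totals$standing_min[1],
            stepping_min = totals$stepping_min[1])
  if (any(base < 0)) abort("totals must be non-negative.")
  recording <- sum(base)
  if (abs(elapsed_min - recording) < threshold)
    return(derive_composites(tibble(!!!as.list(base))))
  if (recording == 0)
    abort("unadjustable session: zero recorded time but elapsed time exceeds the threshold.")
  target <- round(elapsed_min)
  scaled <- base * elapsed_min / recording
  rounded <- .largest_remainder(scaled, target)
  derive_composites(tibble(!!!as.list(rounded)))
}

# integerise `x` to sum to `target` by largest remainder; ties broken by
# larger scaled value, then by position
.largest_remainder <- function(x, target) {
  fl <- floor(x)
  rem <- target - sum(fl)
  frac <- x - fl
  ord <- order(-frac, -x, seq_along(x))
  bump <- integer(length(x))
  if (rem > 0) bump[ord[seq_len(rem)]] <- 1L
  if (rem < 0) bump[order(frac, x, seq_along(x))[seq_len(-rem)]] <- -1L
  fl + bump
}

#' Composite behavior totals
#'
#' Stationary time is sitting plus standing; upright time is standing plus
#' stepping; total recording time is the sum of all three.
#'
#' @param totals Data frame with `sitting_min`, `standing_min`, `stepping_min`.
#' @return The input as a tibble with `stationary_min`, `upright_min` and
#'   `recording_min` added (recomputed if already present).
#' @export
derive_composites <- function(totals) {
  totals |>
    as_tibble() |>
    dplyr::mutate(
      stationary_min = .data$sitting_min + .data$standing_min,
      upright_min = .data$standing_min + .data$stepping_min,
      recording_min = .data$sitting_min + .data$standing_min +
        .data$stepping_min)
}
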