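#' Ground-truth activity script
#'
#' An ordered schedule of sitting / standing / stepping bouts used to
#' synthesize accelerometer signals and to score how well the classifier
#' recovers the scripted totals.
#'
#' @param behavior Character vector of bout behaviors, each one of
#'   `"sitting"`, `"standing"`, `"stepping"`.
#' @param duration_s Positive bout durations in seconds, same length.
#' @param cadence_steps_per_min Stepping cadence used for stepping bouts,
#'   default 100 steps per minute (ordinary walking).
#' @return Tibble `behavior`, `duration_s` with attribute
#'   `cadence_steps_per_min`, class `"activity_script"`.
#' @export
activity_script <- function(behavior, duration_s, cadence_steps_per_min = 100) {
  if (length(behavior) != length(duration_s) || !length(behavior))
    abort("`behavior` and `duration_s` must be non-empty and equal length.")
  if (!all(behavior %in% .base_behaviors))
    abort("behaviors must be sitting, standing or stepping.")
  if (any(duration_s <= 0)) abort("bout durations must be positive.")
  if (cadence_steps_per_min <= 0) abort("cadence must be positive.")
  structure(tibble(behavior = behavior, duration_s = as.numeric(duration_s)),
            cadence_steps_per_min = cadence_steps_per_min,
            class = c("activity_script", class(tibble())))
}

#' Signal noise model
#'
#' Parameters of the measurement-noise and dropout processes applied to a
#' synthetic accelerometer stream.
#'
#' @param orientation_jitter_sd SD of the noise added to the gravity
#'   projection (normalized-z scale, dimensionless). Default 0.02.
#' @param dynamic_noise_g SD (g) of white noise added to each axis.
#'   Default 0.03.
#' @param transition_s Duration (s) of the linear posture-transition ramp at
#'   each bout boundary. Default 1.
#' @param disconnect_rate_per_hr Poisson rate of Bluetooth disconnection
#'   events per hour. Default 0 (no dropouts).
#' @param disconnect_mean_s Mean duration (s) of an exponential disconnection
#'   gap. Default 60.
#' @return A list of class `"noise_model"`.
#' @export
noise_model <- function(orientation_jitter_sd = 0.02,
                        dynamic_noise_g = 0.03,
                        transition_s = 1,
                        disconnect_rate_per_hr = 0,
                        disconnect_mean_s = 60) {
  vals <- c(orientation_jitter_sd, dynamic_noise_g, transition_s,
            disconnect_rate_per_hr, disconnect_mean_s)
  if (any(vals < 0)) abort("noise-model parameters must be non-negative.")
  structure(list(orientation_jitter_sd = orientation_jitter_sd,
                 dynamic_noise_g = dynamic_noise_g,
                 transition_s = transition_s,
                 disconnect_rate_per_hr = disconnect_rate_per_hr,
                 disconnect_mean_s = disconnect_mean_s),
            class = "noise_model")
}

# thigh inclination from vertical, per behavior: sitting = horizontal thigh,
# standing = vertical, stepping = near-vertical with gait dynamics
.behavior_phi <- c(sitting = pi / 2, standing = 0, stepping = 20 * pi / 180)

#' Generate a synthetic thigh-accelerometer stream
#'
#' Synthesizes a triaxial stream following a ground-truth [activity_script()]:
#' sitting bouts place gravity on the z (thigh-normal) axis, standing bouts on
#' the x (thigh-longitudinal) axis, and stepping bouts add a short
#' acceleration burst per stride at the scripted cadence. Posture changes ramp
#' linearly over `transition_s`, orientation jitter and white dynamic noise
#' are added, and Bluetooth disconnection gaps are carved out by a Poisson
#' process with exponential gap lengths.
#'
#' @param script An [activity_script()].
#' @param noise A [noise_model()].
#' @param rate_hz Sampling rate, default 6.25 Hz.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param stride_amp_g Peak stride acceleration in g, default 0.8.
#' @return List of class `"accel_signal"`:
#'   \describe{
#'     \item{accel}{tibble `t_s`, `ax_g`, `ay_g`, `az_g`.}
#'     \item{connected}{tibble `start_s`, `end_s` of connected intervals.}
#'     \item{truth}{one-row tibble of scripted per-behavior minutes with
#'       composites (before dropout).}
#'     \item{truth_monitored}{the same totals restricted to connected time.}
#'     \item{timeline}{ground-truth bout timeline `start_s`, `end_s`, `label`.}
#'   }
#' @export
generate_signal <- function(script,
                            noise = noise_model(),
                            rate_hz = 6.25,
                            seed = NULL,
                            stride_amp_g = 0.8) {
  stopifnot(inherits(script, "activity_script"), inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  cadence <- attr(script, "cadence_steps_per_min")

  total_s <- sum(script$duration_s)
  n <- floor(total_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  bout_end <- cumsum(script$duration_s)
  bout_start <- c(0, utils::head(bout_end, -1L))
  idx <- findInterval(t, bout_start)
  behavior <- script$behavior[idx]

  # target inclination with a linear ramp over transition_s into each bout
  phi_target <- .behavior_phi[behavior]
  phi <- phi_target
  if (noise$transition_s > 0) {
    into <- t - bout_start[idx]
    ramp <- pmin(1, into / noise$transition_s)
    phi_prev <- .behavior_phi[script$behavior[pmax(1L, idx - 1L)]]
    first_bout <- idx == 1L
    phi <- ifelse(first_bout, phi_target,
                  phi_prev + ramp * (phi_target - phi_prev))
  }

  # orientation jitter on the gravity-projection scale
  zfrac <- pmin(1, pmax(0, sin(phi) +
                            rnorm(n, 0, noise$orientation_jitter_sd)))
  phi_eff <- asin(zfrac)
  ax <- cos(phi_eff)
  ay <- numeric(n)
  az <- sin(phi_eff)

  # one burst per stride at the scripted cadence, along the thigh axis
  stepping <- behavior == "stepping"
  if (any(stepping)) {
    period <- 60 / cadence
    tau <- (t - bout_start[idx]) %% period
    burst_len <- min(0.35, period / 2)
    burst <- ifelse(stepping & tau < burst_len,
                    stride_amp_g * sin(pi * tau / burst_len), 0)
    ax <- ax + burst
  }

  ax <- ax + rnorm(n, 0, noise$dynamic_noise_g)
  ay <- ay + rnorm(n, 0, noise$dynamic_noise_g)
  az <- az + rnorm(n, 0, noise$dynamic_noise_g)

  connected <- .draw_connected(total_s, noise)
  accel <- tibble(t_s = t, ax_g = ax, ay_g = ay, az_g = az)

  timeline <- tibble(start_s = bout_start, end_s = bout_end,
                     label = script$behavior)
  truth <- .script_totals(timeline)
  truth_monitored <- .script_totals(.intersect_timeline(timeline, connected))

  structure(list(accel = accel, connected = connected, truth = truth,
                 truth_monitored = truth_monitored, timeline = timeline),
            class = "accel_signal")
}

.draw_connected <- function(total_s, noise) {
  if (noise$disconnect_rate_per_hr <= 0 || noise$disconnect_mean_s <= 0)
    return(tibble(start_s = 0, end_s = total_s))
  n_ev <- rpois(1, noise$disconnect_rate_per_hr * total_s / 3600)
  if (n_ev == 0) return(tibble(start_s = 0, end_s = total_s))
  starts <- sort(stats::runif(n_ev, 0, total_s))
  lens <- rexp(n_ev, 1 / noise$disconnect_mean_s)
  gaps <- tibble(start_s = starts, end_s = pmin(starts + lens, total_s))
  # merge overlapping gaps
  merged <- list(gaps[1, ])
  for (i in seq_len(nrow(gaps))[-1]) {
    last <- merged[[length(merged)]]
    if (gaps$start_s[i] <= last$end_s) {
      merged[[length(merged)]]$end_s <- max(last$end_s, gaps$end_s[i])
    } else merged[[length(merged) + 1L]] <- gaps[i, ]
  }
  gaps <- dplyr::bind_rows(merged)
  conn_start <- c(0, gaps$end_s)
  conn_end <- c(gaps$start_s, total_s)
  keep <- conn_end > conn_start
  tibble(start_s = conn_start[keep], end_s = conn_end[keep])
}

.script_totals <- function(timeline) {
  mins <- vapply(.base_behaviors, function(b)
    sum(timeline$end_s[timeline$label == b] -
        timeline$start_s[timeline$label == b]) / 60, numeric(1))
  derive_composites(tibble(sitting_min = mins[["sitting"]],
                           standing_min = mins[["standing"]],
                           stepping_min = mins[["stepping"]]))
}

.intersect_timeline <- function(timeline, intervals) {
  out <- list()
  for (i in seq_len(nrow(intervals))) {
    s <- pmax(timeline$start_s, intervals$start_s[i])
    e <- pmin(timeline$end_s, intervals$end_s[i])
    keep <- e > s
    if (any(keep))
      out[[length(out) + 1L]] <- tibble(start_s = s[keep], end_s = e[keep],
                                        label = timeline$label[keep])
  }
  if (!length(out))
    return(tibble(start_s = numeric(), end_s = numeric(), label = character()))
  dplyr::bind_rows(out)
}

#' Between-device error model for paired measurements
#'
#' Describes the disagreement between the test monitor and the criterion
#' device at the session-total level: an additive bias and a per-subject
#' disagreement SD per behavior. Defaults are on the scale of a 3--8 h
#' office-work session.
#'
#' @param bias_min Named additive bias (test minus criterion) in minutes for
#'   `sitting`, `standing`, `stepping`.
#' @param noise_sd_min Named per-subject SD of the disagreement in minutes.
#' @param distribution `"normal"` (default) or `"lognormal"` for the
#'   criterion draw, so both normal and skewed regimes can be emulated.
#' @return A list of class `"error_model"`.
#' @export
error_model <- function(bias_min = c(sitting = -1.66, standing = -4.85,
                                     stepping = 1.15),
                        noise_sd_min = c(sitting = 14.65, standing = 13.50,
                                         stepping = 8.30),
                        distribution = c("normal", "lognormal")) {
  distribution <- match.arg(distribution)
  if (any(noise_sd_min < 0)) abort("`noise_sd_min` must be non-negative.")
  stopifnot(all(.base_behaviors %in% names(bias_min)),
            all(.base_behaviors %in% names(noise_sd_min)))
  structure(list(bias_min = bias_min, noise_sd_min = noise_sd_min,
                 distribution = distribution),
            class = "error_model")
}

#' Generate paired test/criterion session totals
#'
#' Draws per-subject criterion minutes for sitting, standing and stepping
#' around population means, then produces the test-device value as criterion
#' plus the behavior's bias plus Gaussian disagreement noise. Negative draws
#' are truncated at zero. Defaults emulate an office-working population
#' wearing both monitors for one workday session.
#'
#' @param n_subjects Number of subjects (≥ 2).
#' @param behavior_means Named mean criterion minutes per behavior.
#' @param behavior_sds Named between-subject SDs of the criterion minutes.
#' @param error An [error_model()].
#' @param seed Optional integer seed.
#' @return Tibble `subject_id`, `behavior`, `test_min`, `criterion_min` with
#'   `n_subjects * 3` rows.
#' @export
generate_paired_measurements <- function(n_subjects,
                                         behavior_means = c(sitting = 180.5,
                                                            standing = 75.4,
                                                            stepping = 24.0),
                                         behavior_sds = c(sitting = 92.1,
                                                          standing = 36.1,
                                                          stepping = 10.5),
                                         error = error_model(),
                                         seed = NULL) {
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  stopifnot(inherits(error, "error_model"),
            all(.base_behaviors %in% names(behavior_means)),
            all(.base_behaviors %in% names(behavior_sds)))
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(.base_behaviors, function(b) {
    m <- behavior_means[[b]]; s <- behavior_sds[[b]]
    crit <- if (error$distribution == "lognormal") {
      sdlog <- sqrt(log(1 + (s / m)^2))
      rlnorm(n_subjects, log(m) - sdlog^2 / 2, sdlog)
    } else {
      rnorm(n_subjects, m, s)
    }
    crit <- pmax(0, crit)
    test <- pmax(0, crit + error$bias_min[[b]] +
                   rnorm(n_subjects, 0, error$noise_sd_min[[b]]))
    tibble(subject_id = sprintf("S%03d", seq_len(n_subjects)),
           behavior = b, test_min = test, criterion_min = crit)
  })
}
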