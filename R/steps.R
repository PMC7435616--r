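#' Step event detection
#'
#' Detects candidate step events from the dynamic component of the
#' acceleration magnitude. The gravity contribution is removed with a causal
#' moving average, local maxima of the residual are pruned to a refractory
#' spacing (highest peak wins), and a sensitivity preset then decides which
#' surviving peaks count as steps:
#'
#' * `sensitive` — lowest peak threshold; catches weak steps at the cost of
#'   false positives.
#' * `normal` — balanced threshold for general use.
#' * `robust` — highest threshold; rejects spurious transients such as a
#'   seated leg stretch, at the cost of missed weak steps.
#'
#' Because the candidate peaks and their refractory pruning are computed once,
#' independently of the preset, the detected event sets are nested:
#' robust events are a subset of normal events, which are a subset of
#' sensitive events.
#'
#' @param accel Data frame with columns `t_s`, `ax_g`, `ay_g`, `az_g`; the
#'   samples of one connected interval.
#' @param mode Sensitivity preset, `"normal"` (default), `"sensitive"` or
#'   `"robust"`.
#' @param rate_hz Sampling rate in Hz, default 6.25.
#' @param refractory_s Minimum spacing between step events in seconds
#'   (default 0.3, i.e. a cadence ceiling of 200 steps/min).
#' @param thresholds Named numeric vector of peak thresholds in g for the
#'   three presets; must be increasing from sensitive to robust.
#' @return Tibble with one row per event: `t_s`, `height_g`.
#' @export
detect_steps <- function(accel,
                         mode = c("normal", "sensitive", "robust"),
                         rate_hz = 6.25,
                         refractory_s = 0.3,
                         thresholds = c(sensitive = 0.08, normal = 0.15,
                                        robust = 0.30)) {
  mode <- match.arg(mode)
  stopifnot(all(c("sensitive", "normal", "robust") %in% names(thresholds)),
            thresholds[["sensitive"]] <= thresholds[["normal"]],
            thresholds[["normal"]] <= thresholds[["robust"]])
  empty <- tibble(t_s = numeric(), height_g = numeric())
  if (is.null(accel) || nrow(accel) < 3L) return(empty)

  mag <- sqrt(accel$ax_g^2 + accel$ay_g^2 + accel$az_g^2)
  k <- max(1L, as.integer(round(2 * rate_hz)))
  # positive part only: a step is an acceleration burst above the local
  # gravity baseline; the rebound below baseline is not a second event
  dyn <- pmax(0, mag - .causal_ma(mag, k))

  n <- length(dyn)
  is_max <- c(FALSE, dyn[2:(n - 1)] > dyn[1:(n - 2)] &
                     dyn[2:(n - 1)] >= dyn[3:n], FALSE)
  # candidate floor below the most permissive preset: never affects any mode
  cand <- which(is_max & dyn >= 0.5 * thresholds[["sensitive"]])
  if (!length(cand)) return(empty)

  # refractory pruning, highest peak first, independent of the preset
  ord <- cand[order(-dyn[cand], accel$t_s[cand])]
  kept_t <- numeric(0)
  kept <- integer(0)
  for (i in ord) {
    ti <- accel$t_s[i]
    if (!length(kept_t) || all(abs(kept_t - ti) >= refractory_s)) {
      kept <- c(kept, i)
      kept_t <- c(kept_t, ti)
    }
  }
  kept <- sort(kept)
  events <- tibble(t_s = accel$t_s[kept], height_g = dyn[kept])
  events[events$height_g >= thresholds[[mode]], ]
}
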