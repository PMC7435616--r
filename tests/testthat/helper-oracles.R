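# Independent reference implementations used as oracles. These deliberately
# re-derive results from first principles (explicit formulas, enumeration,
# literal walks of the decision rules) rather than calling package internals.

# Literal per-reading walk of the decision-rule flow: posture counters compete
# with the step trigger; a counter reaching `limit` commits its posture over
# the readings it counted; readings before any commit (and after a trigger)
# belong to stepping; state is forgotten across unmonitored readings.
naive_decision_walk <- function(posture, trig, monitored, limit) {
  n <- length(posture)
  lab <- integer(n)
  current <- 3L
  sit <- 0L
  stand <- 0L
  sit_idx <- integer(0)
  stand_idx <- integer(0)
  for (i in seq_len(n)) {
    if (!monitored[i]) {
      lab[i] <- 0L
      current <- 3L; sit <- 0L; stand <- 0L
      sit_idx <- integer(0); stand_idx <- integer(0)
      next
    }
    if (trig[i]) {
      lab[i] <- 3L
      current <- 3L; sit <- 0L; stand <- 0L
      sit_idx <- integer(0); stand_idx <- integer(0)
      next
    }
    if (posture[i] == 1L) {
      sit <- sit + 1L; sit_idx <- c(sit_idx, i)
      stand <- 0L; stand_idx <- integer(0)
    } else {
      stand <- stand + 1L; stand_idx <- c(stand_idx, i)
      sit <- 0L; sit_idx <- integer(0)
    }
    lab[i] <- current
    if (sit == limit) {
      lab[sit_idx] <- 1L
      current <- 1L; sit <- 0L; stand <- 0L
      sit_idx <- integer(0); stand_idx <- integer(0)
    } else if (stand == limit) {
      lab[stand_idx] <- 2L
      current <- 2L; sit <- 0L; stand <- 0L
      sit_idx <- integer(0); stand_idx <- integer(0)
    }
  }
  lab
}

# constant-orientation stream with a given normalized z value
const_stream <- function(z, duration_s, rate_hz = 6.25) {
  n <- floor(duration_s * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  tibble::tibble(t_s = t, ax_g = sqrt(1 - z^2), ay_g = 0, az_g = z)
}

# textbook paired t statistic and two-sided p-value
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = tt, p = 2 * pt(-abs(tt), df = n - 1))
}

# exact signed-rank two-sided p by full enumeration of sign patterns
# (requires distinct non-zero |d|)
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  list(V = v_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Lin's CCC from explicit 1/n moments
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Pearson r from the definitional sums
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_bland_altman <- function(x, y) {
  d <- x - y
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  list(bias = m, lower = m - 1.96 * s, upper = m + 1.96 * s)
}

oracle_tost_ci <- function(x, y, conf = 0.90) {
  d <- x - y
  n <- length(d)
  m <- mean(d)
  se <- sd(d) / sqrt(n)
  q <- qt(1 - (1 - conf) / 2, n - 1)
  c(m - q * se, m + q * se)
}

# fixed 10-pair toy table used by the oracle suite
toy_pairs <- function() {
  tibble::tibble(
    test      = c(231.5, 188.0, 305.2, 142.7, 266.9,
                  199.3, 254.1, 175.8, 289.4, 221.6),
    criterion = c(240.0, 181.5, 297.8, 150.2, 275.3,
                  205.0, 248.6, 184.1, 280.7, 230.2))
}
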