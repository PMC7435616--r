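test_that("normalized z hits both posture endpoints and the 45-degree projection", {
  expect_equal(normalized_z(0, 0, 1), 1)
  expect_equal(normalized_z(1, 0, 0), 0)
  # hand-computed trigonometric oracle: gravity projection at 45 deg is cos(45)
  expect_equal(normalized_z(cos(pi / 4), 0, sin(pi / 4)), cos(pi / 4))
  expect_equal(normalized_z(0, 0, -1), 1)    # sign of the axis is irrelevant
  expect_error(normalized_z(0, 0, 0), "invalid sample")
})

test_that("the 0.8 posture rule assigns the boundary to standing", {
  expect_identical(posture_from_z(0.9), "sitting")
  expect_identical(posture_from_z(0.8), "standing")
  expect_identical(posture_from_z(0.0), "standing")
  expect_identical(posture_from_z(0.8 + 1e-9), "sitting")
  expect_error(posture_from_z(1.2), "0, 1")
})

test_that("constant streams just above and at the threshold classify wholly", {
  for (z in c(0.81, 0.8 + 1e-6)) {
    res <- classify_stream(const_stream(z, 300))
    expect_equal(res$totals$sitting_min, res$elapsed_min, tolerance = 1e-12)
    expect_equal(res$totals$standing_min, 0)
    expect_equal(res$totals$stepping_min, 0)
  }
  res <- classify_stream(const_stream(0.80, 300))
  expect_equal(res$totals$standing_min, res$elapsed_min, tolerance = 1e-12)
  expect_equal(res$totals$sitting_min, 0)
})

test_that("weighted adjustment reproduces the reconciliation example", {
  totals <- tibble::tibble(sitting_min = 15, standing_min = 10,
                           stepping_min = 75)
  adj <- weighted_adjustment(totals, elapsed_min = 115)
  expect_identical(c(adj$stepping_min, adj$standing_min, adj$sitting_min),
                   c(86, 12, 17))
  expect_equal(adj$recording_min, 115)
})

test_that("weighted adjustment leaves sub-threshold discrepancies alone", {
  totals <- tibble::tibble(sitting_min = 10, standing_min = 30,
                           stepping_min = 60)
  adj <- weighted_adjustment(totals, elapsed_min = 100)
  expect_equal(adj$sitting_min, 10)
  expect_equal(adj$standing_min, 30)
  expect_equal(adj$stepping_min, 60)
  expect_error(
    weighted_adjustment(tibble::tibble(sitting_min = 0, standing_min = 0,
                                       stepping_min = 0), 120),
    "unadjustable")
})

test_that("largest-remainder reconciliation conserves the total exactly", {
  set.seed(41)
  for (i in 1:50) {
    base <- round(stats::runif(3, 0, 200), 2)
    if (sum(base) == 0) next
    elapsed <- round(sum(base) + sample(c(-1, 1), 1) * stats::runif(1, 16, 60))
    if (elapsed <= 0) next
    totals <- tibble::tibble(sitting_min = base[1], standing_min = base[2],
                             stepping_min = base[3])
    adj <- weighted_adjustment(totals, elapsed)
    comp <- c(adj$sitting_min, adj$standing_min, adj$stepping_min)
    scaled <- base * elapsed / sum(base)
    expect_identical(sum(comp), as.numeric(round(elapsed)))
    expect_true(all(comp == floor(comp)))            # integer minutes
    expect_true(all(abs(comp - scaled) < 1))         # within 1 of unrounded
  }
})

test_that("composite totals are the defining sums", {
  tot <- derive_composites(tibble::tibble(sitting_min = 191.0,
                                          standing_min = 70.3,
                                          stepping_min = 22.0))
  expect_equal(tot$stationary_min, 261.3)
  expect_equal(tot$upright_min, 92.3)
  expect_equal(tot$recording_min, 283.3)
  zero <- derive_composites(tibble::tibble(sitting_min = 0, standing_min = 0,
                                           stepping_min = 0))
  expect_true(all(zero == 0))
})

test_that("pure single-posture streams are recovered in full", {
  sit <- generate_signal(activity_script("sitting", 600),
                         noise_model(orientation_jitter_sd = 0,
                                     dynamic_noise_g = 0, transition_s = 0))
  res <- classify_stream(sit$accel)
  expect_equal(res$totals$sitting_min, 10, tolerance = 1e-6)
  expect_equal(res$totals$stepping_min, 0)
})

test_that("classification is gated to the window and connected intervals", {
  acc <- const_stream(0.95, 1200)
  connected <- tibble::tibble(start_s = 0, end_s = 600)
  win <- recording_window(0, 1200)
  res <- classify_stream(acc, window = win, connected = connected,
                         adjust = FALSE)
  expect_equal(res$monitored_min, 10, tolerance = 1e-6)
  expect_equal(res$totals$recording_min, res$monitored_min, tolerance = 1e-6)
  # no labeled interval intersects the disconnection gap
  lab <- dplyr::filter(res$timeline, label != "unmonitored")
  expect_true(all(lab$end_s <= 600 + 1e-9))
  # timeline is contiguous and non-overlapping over the window
  tl <- res$timeline
  expect_equal(tl$start_s[1], 0)
  expect_equal(tl$end_s[nrow(tl)], 1200)
  expect_true(all(abs(tl$start_s[-1] - tl$end_s[-nrow(tl)]) < 1e-9))
})

test_that("degenerate inputs are rejected or yield empty classifications", {
  res <- classify_stream(const_stream(0.9, 0.1)[0, ],
                         window = recording_window(0, 60))
  expect_equal(res$totals$recording_min, 0)
  expect_identical(res$timeline$label, "unmonitored")
  bad <- const_stream(0.9, 10)
  bad$t_s[5] <- bad$t_s[4]
  expect_error(classify_stream(bad), "strictly increasing")
  big <- const_stream(0.9, 10)
  big$ax_g[3] <- 20
  expect_error(classify_stream(big), "16 g")
})

test_that("the state machine agrees with a naive walk of the decision rules", {
  set.seed(99)
  for (case in 1:30) {
    n <- sample(50:500, 1)
    posture <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
    trig <- stats::runif(n) < 0.05
    monitored <- stats::runif(n) < 0.95
    limit <- sample(c(3L, 5L, 10L, 75L), 1)
    got <- wearagree:::run_state_machine(posture, trig, monitored, limit)
    want <- naive_decision_walk(posture, trig, monitored, limit)
    expect_identical(got, want)
  }
})

test_that("classified time conserves monitored duration", {
  sig <- generate_signal(
    activity_script(c("sitting", "stepping", "standing", "sitting"),
                    c(400, 120, 300, 380)),
    noise_model(disconnect_rate_per_hr = 15, disconnect_mean_s = 45),
    seed = 5)
  res <- classify_stream(sig$accel, connected = sig$connected, adjust = FALSE)
  expect_equal(res$totals$recording_min, res$monitored_min, tolerance = 1e-9)
})
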