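test_that("statistics on a fixed toy table match textbook computation", {
  tp <- toy_pairs()
  x <- tp$test; y <- tp$criterion

  ot <- oracle_paired_t(x, y)
  dt <- diff_test(x, y, method = "t")
  expect_equal(dt$statistic, ot$statistic, tolerance = 1e-10)
  expect_equal(dt$p_value, ot$p, tolerance = 1e-10)

  cc <- lin_ccc(x, y)
  expect_equal(cc$ccc, oracle_ccc(x, y), tolerance = 1e-12)

  cr <- correlation_ci(x, y, method = "pearson")
  expect_equal(cr$estimate, oracle_pearson(x, y), tolerance = 1e-10)

  ba <- bland_altman(x, y)
  ob <- oracle_bland_altman(x, y)
  expect_equal(ba$mean_bias, ob$bias, tolerance = 1e-10)
  expect_equal(ba$loa_lower, ob$lower, tolerance = 1e-10)
  expect_equal(ba$loa_upper, ob$upper, tolerance = 1e-10)

  to <- tost_equivalence(x, y, equivalence_region_for(absolute = 30))
  oc <- oracle_tost_ci(x, y)
  expect_equal(c(to$ci90_low, to$ci90_high), oc, tolerance = 1e-10)
})

test_that("the signed-rank branch matches exact enumeration", {
  tp <- toy_pairs()[1:8, ]
  got <- diff_test(tp$test, tp$criterion, method = "wilcoxon")
  want <- oracle_wilcoxon_exact(tp$test, tp$criterion)
  expect_equal(got$statistic, want$V)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
})

test_that("the normality gate picks the right difference test", {
  set.seed(14)
  x <- rnorm(20, 100, 10)
  y <- x + rnorm(20, 0, 5)
  expect_identical(diff_test(x, y)$test_name, "paired t")
  skew <- x + c(rep(0.1, 17), 40, 55, 70)
  expect_lt(shapiro.test(skew - x)$p.value, 0.05)
  expect_identical(diff_test(skew, x)$test_name, "Wilcoxon signed-rank")
  expect_warning(res <- diff_test(x, x + 2), "degenerate")
  expect_true(is.na(res$p_value))
})

test_that("correlation handles identities, sign flips and large samples", {
  x <- toy_pairs()$test
  expect_equal(correlation_ci(x, x, method = "pearson")$estimate, 1)
  expect_equal(correlation_ci(x, -x + 500, method = "pearson")$estimate, -1)
  expect_error(correlation_ci(x, rep(5, length(x))), "zero variance")
  set.seed(2)
  n <- 10000
  u <- rnorm(n)
  v <- 0.9 * u + sqrt(1 - 0.81) * rnorm(n)
  expect_lt(abs(correlation_ci(u, v, method = "pearson")$estimate - 0.9), 0.01)
})

test_that("CCC is penalised by location shift and bounded by |r|", {
  x <- toy_pairs()$test
  expect_equal(lin_ccc(x, x)$ccc, 1)
  shifted <- x + 25
  cc <- lin_ccc(x, shifted)$ccc
  r <- oracle_pearson(x, shifted)
  expect_lt(cc, r)
  set.seed(6)
  for (case in 1:20) {
    a <- rnorm(15, 50, 10)
    b <- 0.8 * a + rnorm(15, 10, 8)
    expect_lte(abs(lin_ccc(a, b)$ccc), abs(oracle_pearson(a, b)) + 1e-12)
  }
})

test_that("McBride bands map the published CCC values", {
  expect_identical(mcbride_category(0.98), "substantial")
  expect_identical(mcbride_category(0.93), "moderate")
  expect_identical(mcbride_category(0.74), "poor")
  expect_identical(mcbride_category(c(0.995, 0.95, 0.90, 0.899)),
                   c("almost perfect", "substantial", "moderate", "poor"))
  expect_error(mcbride_category(1.2), "-1, 1")
})

test_that("Bland-Altman limits are the closed form and symmetric about the bias", {
  x <- c(10, 12, 15, 19); y <- c(13, 13, 14, 16)  # differences -3, -1, 1, 3
  ba <- bland_altman(x, y)
  expect_equal(ba$mean_bias, 0)
  s <- sqrt(20 / 3)
  expect_equal(ba$loa_lower, -1.96 * s, tolerance = 1e-12)
  expect_equal(ba$loa_upper, 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$loa_upper - ba$mean_bias, ba$mean_bias - ba$loa_lower,
               tolerance = 1e-12)
  ident <- bland_altman(x, x)
  expect_equal(c(ident$mean_bias, ident$loa_lower, ident$loa_upper), c(0, 0, 0))
})

test_that("equivalence regions derive from the criterion mean with half-up rounding", {
  expect_equal(equivalence_region_for(c(75.4))$half_width_min, 11)
  expect_equal(equivalence_region_for(c(24.0))$half_width_min, 4)
  expect_equal(
    equivalence_region_for(c(75.4), rounding = "none")$half_width_min,
    11.31, tolerance = 1e-12)
  expect_equal(equivalence_region_for(absolute = 30)$half_width_min, 30)
  expect_error(equivalence_region_for(c(50), fraction = 0), "fraction")
  expect_error(equivalence_region_for(c(-5)), "not positive")
})

test_that("TOST verdicts follow interval containment and are monotone in the region", {
  x <- toy_pairs()$test; y <- toy_pairs()$criterion
  res4 <- tost_equivalence(x, y, equivalence_region_for(absolute = 4))
  res40 <- tost_equivalence(x, y, equivalence_region_for(absolute = 40))
  expect_equal(res4$equivalent,
               res4$ci90_low >= -4 && res4$ci90_high <= 4)
  expect_true(res40$equivalent)
  # monotone: equivalent at h implies equivalent at any larger h
  hs <- seq(1, 50, by = 1)
  verdicts <- vapply(hs, function(h)
    tost_equivalence(x, y, equivalence_region_for(absolute = h))$equivalent,
    logical(1))
  expect_true(all(diff(as.integer(verdicts)) >= 0))
  # zero-variance differences collapse the interval to the point estimate
  resz <- tost_equivalence(x, x, equivalence_region_for(absolute = 1))
  expect_equal(c(resz$ci90_low, resz$ci90_high), c(0, 0))
  expect_true(resz$equivalent)
})

test_that("equivalence escalation equals an exhaustive grid scan", {
  set.seed(17)
  y <- rnorm(25, 100, 15)
  x <- y + 0.12 * 100 + rnorm(25, 0, 0.01)
  esc <- escalate_equivalence(x, y, rounding = "none")
  grid <- seq(0.10, 0.50, by = 0.05)
  scan <- grid[vapply(grid, function(f)
    tost_equivalence(x, y,
                     equivalence_region_for(y, fraction = f,
                                            rounding = "none"))$equivalent,
    logical(1))]
  expect_equal(esc$min_fraction, scan[1])
  # zero-difference pairs are equivalent at the first fraction tried
  z <- escalate_equivalence(y, y)
  expect_equal(z$min_fraction, 0.10)
  # bias beyond the largest fraction: no equivalence on the grid
  far <- escalate_equivalence(y + 80, y, max_fraction = 0.50)
  expect_true(is.na(far$min_fraction))
})

test_that("the full protocol recovers injected per-behavior biases", {
  err <- error_model(bias_min = c(sitting = -2, standing = -5, stepping = 1),
                     noise_sd_min = c(sitting = 8, standing = 8, stepping = 4))
  pm <- generate_paired_measurements(500, error = err, seed = 44)
  rep <- full_agreement_analysis(pm)
  tab <- tidy(rep)
  for (b in c("sitting", "standing", "stepping")) {
    got <- tab$mean_bias[tab$behavior == b]
    want <- err$bias_min[[b]]
    se <- err$noise_sd_min[[b]] / sqrt(500)
    expect_lt(abs(got - want), 3 * se)
  }
})

test_that("perfect agreement yields unit CCC and equivalence everywhere", {
  pm <- generate_paired_measurements(
    20, error = error_model(bias_min = c(sitting = 0, standing = 0,
                                         stepping = 0),
                            noise_sd_min = c(sitting = 0, standing = 0,
                                             stepping = 0)),
    seed = 10)
  # the degenerate-difference warning per behavior is the documented behavior
  tab <- suppressWarnings(tidy(full_agreement_analysis(pm)))
  expect_true(all(tab$ccc == 1))
  expect_true(all(tab$equivalent))
  expect_true(all(tab$mean_bias == 0))
})

test_that("report methods expose tidy, glance and a Bland-Altman autoplot", {
  pm <- generate_paired_measurements(20, seed = 12)
  rep <- full_agreement_analysis(pm)
  tab <- tidy(rep)
  expect_false("points" %in% names(tab))
  gl <- glance(rep)
  expect_equal(gl$n_subjects, 20)
  expect_equal(gl$n_behaviors, nrow(tab))
  p <- ggplot2::ggplot_build(autoplot(rep))
  expect_gt(nrow(p$data[[1]]), 0)
})
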