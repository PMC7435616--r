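#' Paired difference test with a normality gate
#'
#' Tests whether the test device differs from the criterion on average. The
#' paired differences are screened with a Shapiro-Wilk test; a paired t-test
#' is used when normality is not rejected, a Wilcoxon signed-rank test
#' otherwise. With fewer than 3 pairs (Shapiro-Wilk undefined) the t-test is
#' used. Identical differences throughout are reported as a degenerate case
#' rather than fabricating a p-value.
#'
#' @param test,criterion Paired numeric vectors of per-subject minutes.
#' @param alpha Normality-screen level, default 0.05.
#' @param method `"auto"` (default) applies the gate; `"t"` or `"wilcoxon"`
#'   force a test.
#' @return One-row tibble: `test_name`, `statistic`, `p_value`, `shapiro_p`,
#'   `mean_diff`.
#' @export
diff_test <- function(test, criterion, alpha = 0.05,
                      method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  .check_pairs(test, criterion, min_n = 2L)
  d <- test - criterion
  if (sd(d) == 0) {
    warn("all paired differences are identical; difference test is degenerate.")
    return(tibble(test_name = "degenerate (zero-variance differences)",
                  statistic = NA_real_, p_value = NA_real_,
                  shapiro_p = NA_real_, mean_diff = mean(d)))
  }
  shapiro_p <- if (length(d) >= 3L) shapiro.test(d)$p.value else NA_real_
  use_t <- switch(method,
                  auto = is.na(shapiro_p) || shapiro_p >= alpha,
                  t = TRUE, wilcoxon = FALSE)
  if (use_t) {
    fit <- t.test(test, criterion, paired = TRUE)
    tibble(test_name = "paired t", statistic = unname(fit$statistic),
           p_value = fit$p.value, shapiro_p = shapiro_p, mean_diff = mean(d))
  } else {
    fit <- suppressWarnings(wilcox.test(test, criterion, paired = TRUE))
    tibble(test_name = "Wilcoxon signed-rank",
           statistic = unname(fit$statistic), p_value = fit$p.value,
           shapiro_p = shapiro_p, mean_diff = mean(d))
  }
}

#' Correlation between test and criterion with a normality gate
#'
#' Pearson's r (with its Fisher-z confidence interval) when both margins pass
#' a Shapiro-Wilk screen, Spearman's rank correlation otherwise. The Spearman
#' interval applies the Fisher transformation to the rank correlation.
#'
#' @inheritParams diff_test
#' @param conf_level Confidence level, default 0.95.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return One-row tibble: `cor_method`, `estimate`, `conf_low`, `conf_high`.
#' @export
correlation_ci <- function(test, criterion, alpha = 0.05, conf_level = 0.95,
                           method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  .check_pairs(test, criterion, min_n = 3L)
  if (sd(test) == 0 || sd(criterion) == 0)
    abort("correlation undefined: a margin has zero variance.")
  n <- length(test)
  if (method == "auto") {
    norm_ok <- shapiro.test(test)$p.value >= alpha &&
      shapiro.test(criterion)$p.value >= alpha
    method <- if (norm_ok) "pearson" else "spearman"
  }
  if (method == "pearson") {
    fit <- cor.test(test, criterion, conf.level = conf_level)
    tibble(cor_method = "pearson", estimate = unname(fit$estimate),
           conf_low = fit$conf.int[1], conf_high = fit$conf.int[2])
  } else {
    rho <- cor(test, criterion, method = "spearman")
    if (n > 3 && abs(rho) < 1) {
      z <- atanh(rho)
      se <- 1 / sqrt(n - 3)
      q <- qnorm(1 - (1 - conf_level) / 2)
      ci <- tanh(z + c(-1, 1) * q * se)
    } else ci <- c(rho, rho)
    tibble(cor_method = "spearman", estimate = rho,
           conf_low = ci[1], conf_high = ci[2])
  }
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two measures of the same quantity, penalising both
#' imprecision (scatter about the best-fit line) and inaccuracy (location and
#' scale shifts from the identity line):
#' \deqn{\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with biased (1/n) sample moments. The confidence interval applies the
#' Fisher z-transformation with Lin's asymptotic variance.
#'
#' @inheritParams diff_test
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `ccc`, `conf_low`, `conf_high`, `category`
#'   (McBride interpretation of the point estimate).
#' @export
lin_ccc <- function(test, criterion, conf_level = 0.95) {
  .check_pairs(test, criterion, min_n = 3L)
  x <- test; y <- criterion
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0)
    abort("CCC undefined: both margins have zero variance.")
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)

  if (sx2 > 0 && sy2 > 0 && abs(ccc) < 1) {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mx - my) / (sx2 * sy2)^0.25
    z <- atanh(ccc)
    se2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
            2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
            ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
    q <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(z + c(-1, 1) * q * sqrt(se2))
  } else ci <- c(ccc, ccc)

  tibble(ccc = ccc, conf_low = ci[1], conf_high = ci[2],
         category = mcbride_category(ccc))
}

#' McBride interpretation bands for the CCC
#'
#' Maps a concordance correlation coefficient to a qualitative agreement
#' category: poor below 0.90, moderate in \[0.90, 0.95), substantial in
#' \[0.95, 0.99), almost perfect at 0.99 and above.
#'
#' @param ccc Numeric vector of CCC values in \[-1, 1\].
#' @return Character vector of categories.
#' @export
#' @examples
#' mcbride_category(c(0.98, 0.93, 0.74))
mcbride_category <- function(ccc) {
  if (any(ccc < -1 | ccc > 1, na.rm = TRUE)) abort("`ccc` must lie in [-1, 1].")
  dplyr::case_when(
    ccc >= 0.99 ~ "almost perfect",
    ccc >= 0.95 ~ "substantial",
    ccc >= 0.90 ~ "moderate",
    .default = "poor")
}

#' Bland-Altman mean bias and limits of agreement
#'
#' Mean of the paired differences (test minus criterion) with 95% limits of
#' agreement at mean ± 1.96 SD of the differences. The per-subject
#' (mean, difference) points used for the Bland-Altman plot are returned as a
#' nested list-column.
#'
#' @inheritParams diff_test
#' @return One-row tibble: `mean_bias`, `loa_lower`, `loa_upper`, `sd_diff`,
#'   `n`, and list-column `points` of tibbles (`mean`, `diff`).
#' @export
bland_altman <- function(test, criterion) {
  .check_pairs(test, criterion, min_n = 2L)
  d <- test - criterion
  bias <- mean(d)
  s <- sd(d)
  tibble(mean_bias = bias,
         loa_lower = bias - 1.96 * s,
         loa_upper = bias + 1.96 * s,
         sd_diff = s, n = length(d),
         points = list(tibble(mean = (test + criterion) / 2, diff = d)))
}

#' Equivalence region for a behavior
#'
#' Half-width of the symmetric equivalence region, derived as a fraction
#' (default 15%) of the criterion-device central tendency, rounded half-up to
#' whole minutes by default. An absolute half-width can be supplied instead
#' to apply a pre-specified region verbatim.
#'
#' @param criterion Numeric vector of criterion minutes (ignored when
#'   `absolute` is given).
#' @param fraction Fraction of the criterion central tendency, default 0.15.
#' @param center Function giving the central tendency, default [mean].
#' @param rounding `"halfup"` (default, whole minutes) or `"none"`.
#' @param absolute Optional absolute half-width in minutes, overriding the
#'   fractional derivation.
#' @return One-row tibble: `half_width_min`, `derivation`, `fraction`.
#' @export
#' @examples
#' equivalence_region_for(c(70, 80.8))          # 15% of 75.4 -> 11 min
#' equivalence_region_for(absolute = 30)
equivalence_region_for <- function(criterion = NULL, fraction = 0.15,
                                   center = mean,
                                   rounding = c("halfup", "none"),
                                   absolute = NULL) {
  rounding <- match.arg(rounding)
  if (!is.null(absolute)) {
    if (absolute <= 0) abort("`absolute` half-width must be positive.")
    return(tibble(half_width_min = absolute, derivation = "absolute",
                  fraction = NA_real_))
  }
  if (is.null(criterion) || !length(criterion))
    abort("`criterion` values are required unless `absolute` is given.")
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must lie in (0, 1).")
  ct <- center(criterion)
  if (!is.finite(ct) || ct <= 0)
    abort("invalid region: criterion central tendency is not positive.")
  hw <- fraction * ct
  if (rounding == "halfup") hw <- floor(hw + 0.5)
  if (hw <= 0) abort("invalid region: half-width rounds to zero.")
  tibble(half_width_min = hw, derivation = "fraction_of_criterion",
         fraction = fraction)
}

#' Interval-containment equivalence verdict
#'
#' Equivalence holds when the confidence interval for the mean difference
#' lies entirely within the symmetric region \[-half_width, +half_width\].
#'
#' @param ci_low,ci_high Interval bounds for the mean difference, minutes.
#' @param half_width Region half-width, minutes.
#' @return Logical; vectorized.
#' @export
equivalence_verdict <- function(ci_low, ci_high, half_width) {
  stopifnot(all(ci_low <= ci_high), all(half_width > 0))
  ci_low >= -half_width & ci_high <= half_width
}

#' TOST paired equivalence test
#'
#' Two one-sided paired t-tests, operationalised as the 90% confidence
#' interval for the mean paired difference: the devices are declared
#' equivalent when that interval lies entirely within the equivalence region.
#' With zero-variance differences the interval collapses to the point
#' estimate and the verdict is still defined.
#'
#' @inheritParams diff_test
#' @param region One-row data frame with `half_width_min`, e.g. from
#'   [equivalence_region_for()].
#' @param conf_level Confidence level of the interval, default 0.90
#'   (equivalent to two one-sided tests at 5%).
#' @return One-row tibble: `ci90_low`, `ci90_high`, `half_width_min`,
#'   `equivalent`.
#' @export
tost_equivalence <- function(test, criterion, region, conf_level = 0.90) {
  .check_pairs(test, criterion, min_n = 2L)
  hw <- region$half_width_min[1]
  if (!is.finite(hw) || hw <= 0) abort("invalid equivalence region.")
  d <- test - criterion
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    ci <- c(m, m)
  } else {
    q <- qt(1 - (1 - conf_level) / 2, df = n - 1)
    ci <- m + c(-1, 1) * q * s / sqrt(n)
  }
  tibble(ci90_low = ci[1], ci90_high = ci[2], half_width_min = hw,
         equivalent = equivalence_verdict(ci[1], ci[2], hw))
}

#' Smallest equivalence fraction supporting equivalence
#'
#' Re-runs the TOST procedure over an escalating grid of equivalence
#' fractions (default 10%, then 5% increments) and reports the first fraction
#' at which the devices are equivalent, or `NA` if none on the grid is.
#'
#' @inheritParams diff_test
#' @param start_fraction First fraction tried, default 0.10.
#' @param step Grid increment, default 0.05.
#' @param max_fraction Largest fraction tried, default 0.50.
#' @param center,rounding Passed to [equivalence_region_for()].
#' @return One-row tibble: `min_fraction` (NA if never equivalent),
#'   `half_width_min` at that fraction (NA likewise).
#' @export
escalate_equivalence <- function(test, criterion, start_fraction = 0.10,
                                 step = 0.05, max_fraction = 0.50,
                                 center = mean,
                                 rounding = c("halfup", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(start_fraction > 0, step > 0, max_fraction <= 1,
            start_fraction <= max_fraction)
  fractions <- seq(start_fraction, max_fraction, by = step)
  for (f in fractions) {
    region <- equivalence_region_for(criterion, fraction = f, center = center,
                                     rounding = rounding)
    res <- tost_equivalence(test, criterion, region)
    if (res$equivalent)
      return(tibble(min_fraction = f,
                    half_width_min = region$half_width_min))
  }
  tibble(min_fraction = NA_real_, half_width_min = NA_real_)
}

.check_pairs <- function(test, criterion, min_n = 2L) {
  if (length(test) != length(criterion))
    abort("`test` and `criterion` must have equal length.")
  if (length(test) < min_n)
    abort(sprintf("at least %d complete pairs are required.", min_n))
  if (any(!is.finite(test)) || any(!is.finite(criterion)))
    abort("paired minutes must be finite.")
}

#' Full device-agreement analysis
#'
#' Runs the complete validation protocol per behavior: paired difference test
#' (t or Wilcoxon after a normality screen), correlation (Pearson or
#' Spearman), Lin's CCC with McBride interpretation, Bland-Altman mean bias
#' and limits of agreement, the TOST equivalence verdict against a 15%-of-
#' criterion region (or supplied absolute regions), and the smallest
#' equivalence fraction on a 5% grid. Composite behaviors (stationary =
#' sitting + standing, upright = standing + stepping, recording = all three)
#' are formed per subject from the base behaviors before analysis.
#'
#' @param paired Data frame `subject_id`, `behavior`, `test_min`,
#'   `criterion_min` with behaviors among sitting, standing, stepping.
#' @param fraction Equivalence fraction of the criterion mean, default 0.15.
#' @param regions Optional named numeric vector of absolute region
#'   half-widths (minutes) per behavior, overriding the fractional rule,
#'   e.g. `c(sitting = 30, standing = 11, stepping = 4)`.
#' @param alpha Normality-screen level for the t/Wilcoxon and
#'   Pearson/Spearman gates, default 0.05.
#' @param conf_level Confidence level for correlation and CCC intervals,
#'   default 0.95.
#' @return An object of class `"agreement_report"`; see [tidy.agreement_report()],
#'   [glance.agreement_report()] and [autoplot.agreement_report()]. Its
#'   `$table` is a tibble with one row per analysed behavior.
#' @export
full_agreement_analysis <- function(paired, fraction = 0.15, regions = NULL,
                                    alpha = 0.05, conf_level = 0.95) {
  paired <- .validate_paired(paired)
  full <- add_composite_behaviors(paired)

  rows <- purrr::map(.all_behaviors, function(b) {
    sub <- dplyr::filter(full, .data$behavior == b)
    if (nrow(sub) < 2L) {
      warn(sprintf("behavior '%s' has fewer than 2 complete pairs; skipped.", b))
      return(NULL)
    }
    x <- sub$test_min; y <- sub$criterion_min
    region <- if (!is.null(regions) && b %in% names(regions)) {
      equivalence_region_for(absolute = regions[[b]])
    } else {
      equivalence_region_for(y, fraction = fraction)
    }
    dt <- diff_test(x, y, alpha = alpha)
    cr <- tryCatch(correlation_ci(x, y, alpha = alpha,
                                  conf_level = conf_level),
                   error = function(e) tibble(cor_method = NA_character_,
                                              estimate = NA_real_,
                                              conf_low = NA_real_,
                                              conf_high = NA_real_))
    cc <- tryCatch(lin_ccc(x, y, conf_level = conf_level),
                   error = function(e) tibble(ccc = NA_real_,
                                              conf_low = NA_real_,
                                              conf_high = NA_real_,
                                              category = NA_character_))
    ba <- bland_altman(x, y)
    to <- tost_equivalence(x, y, region)
    es <- escalate_equivalence(x, y)
    tibble(behavior = b, n = length(x),
           test_name = dt$test_name, p_value = dt$p_value,
           cor_method = cr$cor_method, r = cr$estimate,
           r_conf_low = cr$conf_low, r_conf_high = cr$conf_high,
           ccc = cc$ccc, ccc_conf_low = cc$conf_low,
           ccc_conf_high = cc$conf_high, ccc_category = cc$category,
           mean_bias = ba$mean_bias, loa_lower = ba$loa_lower,
           loa_upper = ba$loa_upper,
           region_half_width = to$half_width_min,
           region_derivation = region$derivation,
           ci90_low = to$ci90_low, ci90_high = to$ci90_high,
           equivalent = to$equivalent,
           min_equivalence_fraction = es$min_fraction,
           points = ba$points)
  })
  structure(list(table = dplyr::bind_rows(rows),
                 fraction = fraction, regions = regions,
                 n_subjects = dplyr::n_distinct(paired$subject_id)),
            class = "agreement_report")
}

#' Add composite behaviors to paired measurements
#'
#' Forms stationary (sitting + standing), upright (standing + stepping) and
#' recording (all three) per subject and device, keeping only subjects with
#' every needed component.
#'
#' @inheritParams full_agreement_analysis
#' @return Tibble in the same layout with composite rows appended.
#' @export
add_composite_behaviors <- function(paired) {
  paired <- .validate_paired(paired)
  wide <- paired |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "behavior",
                       values_from = c("test_min", "criterion_min"))
  comps <- list(stationary = c("sitting", "standing"),
                upright = c("standing", "stepping"),
                recording = .base_behaviors)
  extra <- purrr::imap(comps, function(parts, name) {
    tcols <- paste0("test_min_", parts)
    ccols <- paste0("criterion_min_", parts)
    if (!all(c(tcols, ccols) %in% names(wide))) return(NULL)
    ok <- stats::complete.cases(wide[c(tcols, ccols)])
    tibble(subject_id = wide$subject_id[ok], behavior = name,
           test_min = rowSums(wide[ok, tcols, drop = FALSE]),
           criterion_min = rowSums(wide[ok, ccols, drop = FALSE]))
  })
  dplyr::bind_rows(c(list(paired), unname(purrr::compact(extra))))
}

.validate_paired <- function(paired) {
  need <- c("subject_id", "behavior", "test_min", "criterion_min")
  if (!all(need %in% names(paired)))
    abort(paste0("`paired` must have columns ",
                 paste(need, collapse = ", "), "."))
  paired <- as_tibble(paired)[need]
  if (!all(paired$behavior %in% .all_behaviors))
    abort("behaviors must be among sitting, standing, stepping (composites are derived).")
  if (any(paired$test_min < 0 | paired$criterion_min < 0, na.rm = TRUE))
    abort("minutes must be non-negative.")
  paired
}
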