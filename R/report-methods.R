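#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an agreement report
#'
#' One row per analysed behavior with every statistic as a column; the
#' nested Bland-Altman point clouds are dropped.
#'
#' @param x An `agreement_report` from [full_agreement_analysis()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.agreement_report <- function(x, ...) {
  dplyr::select(x$table, !"points")
}

#' One-row summary of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return One-row tibble: `n_subjects`, `n_behaviors`, `n_equivalent`,
#'   `fraction`.
#' @export
glance.agreement_report <- function(x, ...) {
  tibble(n_subjects = x$n_subjects,
         n_behaviors = nrow(x$table),
         n_equivalent = sum(x$table$equivalent, na.rm = TRUE),
         fraction = x$fraction)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Device-agreement report: %d subjects, %d behaviors\n",
              x$n_subjects, nrow(x$table)))
  print(tidy(x))
  invisible(x)
}

#' Bland-Altman plot of an agreement report
#'
#' Per-subject differences against pair means, faceted by behavior, with the
#' mean bias (solid) and 95% limits of agreement (dashed).
#'
#' @param object An `agreement_report`.
#' @param behaviors Behaviors to plot; default all analysed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, behaviors = NULL, ...) {
  tab <- object$table
  if (!is.null(behaviors)) tab <- dplyr::filter(tab, .data$behavior %in% behaviors)
  pts <- tab |>
    dplyr::select("behavior", "points") |>
    tidyr::unnest("points")
  lines <- tab |>
    dplyr::select("behavior", "mean_bias", "loa_lower", "loa_upper") |>
    tidyr::pivot_longer(!"behavior", names_to = "line", values_to = "y")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$y,
                                     linetype = .data$line == "mean_bias"),
                        show.legend = FALSE) +
    ggplot2::facet_wrap(~behavior, scales = "free") +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid",
                                              `FALSE` = "dashed")) +
    ggplot2::labs(x = "Mean of devices (min)",
                  y = "Test - criterion (min)")
}

#' Timeline plot of a classified stream
#'
#' @param object An `activity_classification` from [classify_stream()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activity_classification <- function(object, ...) {
  tl <- object$timeline
  ggplot2::ggplot(tl) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_s / 60,
                                    xmax = .data$end_s / 60,
                                    ymin = 0, ymax = 1,
                                    fill = .data$label)) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "Session time (min)", y = NULL, fill = "Behavior")
}
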