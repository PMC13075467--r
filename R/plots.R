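#' Plot a TSS coverage metaprofile
#'
#' @param object A [metaprofile()] result.
#' @param ... Unused.
#' @return A ggplot object: normalized coverage against offset from the TSS
#'   (transcription orientation).
#' @export
autoplot.cf_metaprofile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$mean_cov)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "Offset from TSS (bp, transcription-oriented)",
                  y = "Normalized coverage") +
    ggplot2::theme_minimal()
}

#' Volcano plot of case-control rank fold changes
#'
#' @param comparison A [compare_groups()] result (optionally after
#'   [volcano_dedup()]).
#' @param q_threshold Significance threshold drawn as a horizontal line.
#' @return A ggplot object of `log2FC` against `-log10(q)`.
#' @export
plot_volcano <- function(comparison, q_threshold = 0.05) {
  check_columns(comparison, c("feature", "log2FC", "q"), "comparison")
  df <- dplyr::mutate(comparison,
                      status = dplyr::case_when(
                        .data$q < q_threshold & .data$log2FC > 0 ~ "up",
                        .data$q < q_threshold & .data$log2FC < 0 ~ "down",
                        TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2FC, y = -log10(.data$q),
                                   color = .data$status)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold),
                        linetype = "dashed", color = "grey50") +
    ggplot2::scale_color_manual(values = c(up = "#d7301f", down = "#2b8cbe",
                                           ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change of median rank", y = "-log10(q)") +
    ggplot2::theme_minimal()
}

#' ROC curve of a LOOCV classifier
#'
#' @param object A [loocv_predict()] result.
#' @param ... Unused.
#' @return A ggplot object of the out-of-fold ROC curve with the AUC and CI
#'   in the subtitle.
#' @export
autoplot.cf_classifier <- function(object, ...) {
  df <- object$oof %>%
    dplyr::arrange(dplyr::desc(.data$prob)) %>%
    dplyr::mutate(tpr = cumsum(.data$y == 1) / sum(.data$y == 1),
                  fpr = cumsum(.data$y == 0) / sum(.data$y == 0))
  df <- dplyr::bind_rows(tibble(tpr = 0, fpr = 0), df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(color = "#d7301f") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("LOOCV AUC = %.3f (95%% CI %.3f-%.3f)",
                                     object$auc, object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves
#'
#' @param object A [km_logrank()] result.
#' @param ... Unused.
#' @return A ggplot step-curve per group with the log-rank p in the
#'   subtitle.
#' @export
autoplot.cf_km <- function(object, ...) {
  start <- object$curves %>%
    dplyr::distinct(.data$group) %>%
    dplyr::mutate(time = 0, survival = 1)
  df <- dplyr::bind_rows(start, object$curves)
  sub <- if (!is.na(object$p)) {
    paste0("log-rank p = ", format.pval(object$p, digits = 3))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Recurrence-free survival",
                  subtitle = sub) +
    ggplot2::theme_minimal()
}

#' Rank distributions per cell-type group
#'
#' @param ranks Long rank tibble from [deconvolve_samples()].
#' @param by Grouping column (default `"category"`).
#' @return A ggplot boxplot of ranks per group, ordered by median rank.
#' @export
plot_rank_distribution <- function(ranks, by = "category") {
  check_columns(ranks, c("rank", by), "ranks")
  df <- dplyr::mutate(ranks,
                      label = stats::reorder(.data[[by]], .data$rank, median))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$rank)) +
    ggplot2::geom_boxplot(fill = "#a6bddb") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Cell type rank (higher = more cfDNA)") +
    ggplot2::theme_minimal()
}
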