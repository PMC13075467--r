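#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test
#'
#' Exact p-value when the smaller group has at most 8 observations and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @return A tibble `(statistic, p, exact)` where `statistic` is the
#'   Mann-Whitney U of the first group.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  res <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided"))
  p <- res$p.value
  # Fully tied samples have zero rank variance; the approximation returns
  # NaN there, but the distributions are identical, so p is 1.
  if (is.nan(p)) p <- 1
  tibble(statistic = unname(res$statistic), p = p, exact = exact)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Case-control comparison of rank features
#'
#' For every feature, compares case against control values with a two-sided
#' Wilcoxon rank-sum test, computes the fold change of median values
#' (`log2(median_case / median_control)`) and adjusts the p-values by BH
#' across all features tested in this call (one FDR family per contrast).
#'
#' @param data Long tibble with columns `feature`, `group` and `value`
#'   (typically per-sample cell-type ranks or group median ranks).
#' @param case,control Group labels of the two arms.
#' @return A tibble `(feature, n_case, n_control, median_case,
#'   median_control, log2FC, p, q)`.
#' @export
compare_groups <- function(data, case, control) {
  check_columns(data, c("feature", "group", "value"), "comparison data")
  feats <- unique(data$feature)
  rows <- purrr::map(feats, function(f) {
    va <- data$value[data$feature == f & data$group == case]
    vb <- data$value[data$feature == f & data$group == control]
    va <- va[!is.na(va)]
    vb <- vb[!is.na(vb)]
    if (!length(va) || !length(vb)) {
      cf_log("feature '%s' absent in one arm; skipped", f, level = "WARN")
      return(NULL)
    }
    test <- wilcoxon_rank_sum(va, vb)
    tibble(feature = f, n_case = length(va), n_control = length(vb),
           median_case = median(va), median_control = median(vb),
           log2FC = log2(median(va) / median(vb)), p = test$p)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) stop("no feature present in both arms", call. = FALSE)
  out$q <- bh_fdr(out$p)
  out
}

#' Deduplicate multi-tissue cell types for a volcano view
#'
#' A cell type observed in several tissues contributes several comparison
#' rows; for display only the instance with the largest absolute log2 fold
#' change is kept, with ties broken by smaller q and then tissue name.
#'
#' @param rows Comparison tibble carrying `cell_type`, `tissue`, `log2FC`
#'   and `q` columns.
#' @return One row per cell type.
#' @export
volcano_dedup <- function(rows) {
  check_columns(rows, c("cell_type", "tissue", "log2FC", "q"), "volcano rows")
  rows %>%
    dplyr::arrange(dplyr::desc(abs(.data$log2FC)), .data$q, .data$tissue) %>%
    dplyr::distinct(.data$cell_type, .keep_all = TRUE)
}

#' Longitudinal comparison of each timepoint against baseline
#'
#' Unpaired two-sided Wilcoxon rank-sum tests comparing the baseline value
#' distribution of each feature with every later timepoint. (A paired
#' signed-rank variant is available via `paired = TRUE` for sensitivity
#' analyses; the unpaired test is the default contract.)
#'
#' @param data Long tibble with columns `feature`, `timepoint`, `value`, and
#'   `patient_id` when `paired = TRUE`.
#' @param baseline Baseline timepoint label.
#' @param paired Use a paired Wilcoxon signed-rank test on patients present
#'   at both timepoints.
#' @return A tibble `(feature, timepoint, n_baseline, n, p)`.
#' @export
longitudinal_compare <- function(data, baseline, paired = FALSE) {
  check_columns(data, c("feature", "timepoint", "value"), "longitudinal data")
  if (!any(data$timepoint == baseline)) {
    stop("baseline timepoint '", baseline, "' not present", call. = FALSE)
  }
  others <- setdiff(unique(data$timepoint), baseline)
  if (!length(others)) {
    cf_log("only the baseline timepoint is present; empty result", level = "WARN")
    return(tibble(feature = character(), timepoint = character(),
                  n_baseline = integer(), n = integer(), p = numeric()))
  }
  grid <- tidyr::expand_grid(feature = unique(data$feature), timepoint = others)
  purrr::pmap_dfr(grid, function(feature, timepoint) {
    base <- data[data$feature == feature & data$timepoint == baseline, ]
    tp <- data[data$feature == feature & data$timepoint == timepoint, ]
    if (!nrow(tp)) return(NULL)
    if (paired) {
      check_columns(data, "patient_id", "longitudinal data")
      common <- intersect(base$patient_id, tp$patient_id)
      if (!length(common)) return(NULL)
      d <- tp$value[match(common, tp$patient_id)] -
        base$value[match(common, base$patient_id)]
      p <- suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
      tibble(feature = feature, timepoint = timepoint,
             n_baseline = length(common), n = length(common), p = p)
    } else {
      test <- wilcoxon_rank_sum(base$value, tp$value)
      tibble(feature = feature, timepoint = timepoint,
             n_baseline = nrow(base), n = nrow(tp), p = test$p)
    }
  })
}

#' Per-patient rank change between two timepoints
#'
#' Computes `value(t1) - value(t0)` per patient and feature; patients
#' missing either timepoint are excluded (count logged).
#'
#' @param data Long tibble with columns `patient_id`, `feature`,
#'   `timepoint`, `value` and optionally `category` (carried through).
#' @param t0,t1 Timepoint labels.
#' @return A long tibble `(patient_id, feature, delta, ...)`.
#' @export
rank_change <- function(data, t0, t1) {
  check_columns(data, c("patient_id", "feature", "timepoint", "value"),
                "rank-change data")
  extra <- intersect("category", names(data))
  wide <- data %>%
    dplyr::filter(.data$timepoint %in% c(t0, t1)) %>%
    dplyr::select(dplyr::all_of(c("patient_id", "feature", "timepoint",
                                  "value", extra))) %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value")
  if (!all(c(t0, t1) %in% names(wide))) {
    stop("no patient has both timepoints", call. = FALSE)
  }
  incomplete <- is.na(wide[[t0]]) | is.na(wide[[t1]])
  n_excl <- dplyr::n_distinct(wide$patient_id[incomplete])
  if (n_excl) cf_log("%d patient(s) missing a timepoint excluded from rank change",
                     n_excl)
  out <- wide[!incomplete, ]
  if (!nrow(out)) stop("no patient has both timepoints", call. = FALSE)
  out$delta <- out[[t1]] - out[[t0]]
  dplyr::select(out, dplyr::all_of(c("patient_id", "feature", extra, "delta")))
}

#' Select the most dynamic features by rank-change IQR
#'
#' Ranks features by the interquartile range (Q3 - Q1, linear-interpolation
#' quantiles) of their per-patient rank change and keeps the top `k`,
#' restricted to immune categories when a `category` column is present.
#' Ties are broken by feature id ascending.
#'
#' @param delta Long tibble `(patient_id, feature, delta)`, optionally with
#'   `category`.
#' @param k Number of features to select.
#' @param categories Categories eligible for selection (ignored when
#'   `delta` has no `category` column).
#' @return A list of class `cf_feature_selection`: tibble `iqr`
#'   (feature, iqr) and character vector `selected`.
#' @export
iqr_select <- function(delta, k = 10,
                       categories = c("monocytes", "lymphocytes", "granulocytes")) {
  check_columns(delta, c("feature", "delta"), "delta matrix")
  eligible <- delta
  if ("category" %in% names(delta) && !is.null(categories)) {
    eligible <- delta[delta$category %in% categories, ]
  }
  if (!nrow(eligible)) stop("no eligible features", call. = FALSE)
  iqr_tbl <- eligible %>%
    dplyr::group_by(feature = .data$feature) %>%
    dplyr::summarise(iqr = unname(diff(quantile(.data$delta, c(0.25, 0.75),
                                                type = 7))),
                     .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$iqr), .data$feature)
  if (nrow(iqr_tbl) < k) {
    cf_log("only %d eligible features; reducing k from %d", nrow(iqr_tbl), k,
           level = "WARN")
    k <- nrow(iqr_tbl)
  }
  structure(list(iqr = iqr_tbl, selected = iqr_tbl$feature[seq_len(k)], k = k),
            class = "cf_feature_selection")
}

#' @export
print.cf_feature_selection <- function(x, ...) {
  cat("<cf_feature_selection> top ", x$k, " features by rank-change IQR:\n",
      sep = "")
  print(utils::head(x$iqr, x$k))
  invisible(x)
}

#' Spearman correlation between aggregated ranks and a covariate
#'
#' Tests the association between a per-sample rank aggregate (e.g. the
#' median rank of effector T-cell subsets) and an external numeric
#' covariate (e.g. a WGS-derived T-cell fraction) with Spearman's rho and a
#' t-approximation p-value.
#'
#' @param data Tibble with columns `value` and `covariate` (one row per
#'   sample); missing pairs are dropped.
#' @return A tibble `(rho, p, n)`.
#' @export
covariate_correlation <- function(data) {
  check_columns(data, c("value", "covariate"), "covariate data")
  ok <- is.finite(data$value) & is.finite(data$covariate)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rho <- spearman_rho(data$value[ok], data$covariate[ok])
  if (is.na(rho) || abs(rho) == 1) {
    p <- if (is.na(rho)) NA_real_ else 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p = p, n = n)
}
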