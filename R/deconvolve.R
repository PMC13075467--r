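#' Tie-aware Spearman correlation
#'
#' Pearson correlation of average-ranked vectors after pairwise removal of
#' missing entries. Returns `NA` (with a warning) when fewer than 3 complete
#' pairs remain or when either ranked vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Spearman's rho in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    cf_log("fewer than 3 complete pairs; Spearman rho is NA", level = "WARN")
    return(NA_real_)
  }
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (sd(rx) == 0 || sd(ry) == 0) {
    cf_log("zero variance in ranked vector; Spearman rho is NA", level = "WARN")
    return(NA_real_)
  }
  cor(rx, ry)
}

#' Correlate cell-type expression profiles with TSS coverage
#'
#' For each reference cell type, computes Spearman's rho between its
#' expression profile and the sample's gene-level TSS coverage over the
#' shared genes, with pairwise-complete handling of missing coverage.
#' Because expressed TSSs are coverage-depleted, a stronger negative rho
#' indicates a greater inferred cfDNA contribution from that cell type.
#'
#' @param gene_coverage Tibble `(gene_id, mean_cov)` for one sample.
#' @param reference A [new_reference()] object.
#' @param shared_genes Gene ids to use; defaults to
#'   [intersect_genes()] of the two inputs.
#' @return A tibble `(cell_type, rho, n_genes)`.
#' @export
correlate_celltypes <- function(gene_coverage, reference, shared_genes = NULL) {
  stopifnot(inherits(reference, "cf_reference"))
  check_columns(gene_coverage, c("gene_id", "mean_cov"), "gene coverage")
  if (is.null(shared_genes)) {
    shared_genes <- intersect_genes(reference, gene_coverage$gene_id)
  }
  cov <- gene_coverage$mean_cov[match(shared_genes, gene_coverage$gene_id)]
  expr <- reference$expr[, shared_genes, drop = FALSE]
  rho <- vapply(seq_len(nrow(expr)), function(k) {
    suppressWarnings(spearman_rho(expr[k, ], cov))
  }, numeric(1))
  n_complete <- sum(is.finite(cov))
  if (anyNA(rho)) {
    cf_log("%d cell type(s) with missing rho (constant or < 3 complete pairs)",
           sum(is.na(rho)), level = "WARN")
  }
  tibble(cell_type = rownames(expr), rho = rho, n_genes = n_complete)
}

#' Rank cell types by strength of negative correlation
#'
#' The cell type with the most negative rho receives the highest rank `N`
#' (greatest inferred contribution); tied rho values receive average ranks.
#' Missing rho values are excluded, reducing `N` for that sample.
#'
#' @param rho_table Output of [correlate_celltypes()], optionally with
#'   extra columns (carried through).
#' @return The input with a `rank` column added and missing-rho rows
#'   dropped.
#' @export
rank_celltypes <- function(rho_table) {
  check_columns(rho_table, c("cell_type", "rho"), "rho table")
  keep <- !is.na(rho_table$rho)
  if (!any(keep)) stop("all rho values missing; cannot rank", call. = FALSE)
  if (any(!keep)) {
    cf_log("excluding %d cell type(s) with missing rho from ranking; N reduced to %d",
           sum(!keep), sum(keep), level = "WARN")
  }
  if (sum(keep) < 2) stop("need at least 2 non-missing rho values", call. = FALSE)
  out <- rho_table[keep, ]
  out$rank <- rank(-out$rho)
  out
}

#' Deconvolve one sample: correlation, ranking, annotation
#'
#' Convenience composition of [correlate_celltypes()] and
#' [rank_celltypes()], joining the reference's category / compartment /
#' tissue annotations onto the result.
#'
#' @inheritParams correlate_celltypes
#' @return A tibble `(cell_type, rho, n_genes, rank, ...annotations)`.
#' @export
deconvolve_sample <- function(gene_coverage, reference, shared_genes = NULL) {
  correlate_celltypes(gene_coverage, reference, shared_genes) %>%
    rank_celltypes() %>%
    dplyr::left_join(reference$annotation, by = "cell_type")
}

#' Deconvolve a cohort of samples
#'
#' Applies [deconvolve_sample()] to each sample of a long coverage table.
#'
#' @param coverage Long tibble `(sample_id, gene_id, mean_cov)` (a
#'   `coverage` column is also accepted).
#' @param reference A [new_reference()] object.
#' @return A long tibble of per-sample cell-type ranks.
#' @export
deconvolve_samples <- function(coverage, reference) {
  if (!("mean_cov" %in% names(coverage)) && "coverage" %in% names(coverage)) {
    coverage <- dplyr::rename(coverage, mean_cov = "coverage")
  }
  check_columns(coverage, c("sample_id", "gene_id", "mean_cov"), "coverage")
  shared <- intersect_genes(reference, unique(coverage$gene_id))
  coverage %>%
    dplyr::group_by(sample_id = .data$sample_id) %>%
    dplyr::group_modify(~ deconvolve_sample(.x, reference, shared)) %>%
    dplyr::ungroup()
}

#' Median rank per broader cell-type group
#'
#' Groups cell types into broader labels (categories, compartments or
#' tissues) by taking the median of member ranks within each sample.
#'
#' @param ranks Long rank tibble from [deconvolve_samples()] (or a
#'   single-sample tibble from [deconvolve_sample()]).
#' @param by Name of the column in `ranks` holding the grouping label, or a
#'   mapping tibble `(cell_type, label)`.
#' @return A tibble `(sample_id, label, median_rank, n_members)`; groups in
#'   a supplied mapping with no ranked members get `NA`.
#' @export
group_rank <- function(ranks, by = "category") {
  check_columns(ranks, c("cell_type", "rank"), "ranks")
  has_sample <- "sample_id" %in% names(ranks)
  if (!has_sample) ranks$sample_id <- "sample"
  if (is.data.frame(by)) {
    check_columns(by, c("cell_type", "label"), "grouping")
    ranks <- dplyr::inner_join(ranks, by, by = "cell_type")
    labels <- unique(by$label)
  } else {
    check_columns(ranks, by, "ranks")
    ranks$label <- ranks[[by]]
    labels <- unique(ranks$label)
  }
  out <- ranks %>%
    dplyr::group_by(sample_id = .data$sample_id, label = .data$label) %>%
    dplyr::summarise(median_rank = median(.data$rank),
                     n_members = dplyr::n(), .groups = "drop") %>%
    tidyr::complete(.data$sample_id, label = labels,
                    fill = list(n_members = 0L))
  if (!has_sample) out$sample_id <- NULL
  out
}

#' Per-sample median rank over a named cell-type set
#'
#' Aggregates the ranks of an explicit set of cell types (e.g. effector
#' T-cell subsets from blood and lymph node) to one value per sample, for
#' comparison against an external covariate.
#'
#' @param ranks Long rank tibble with `sample_id`, `cell_type`, `rank`.
#' @param cell_types Character vector of cell-type ids.
#' @return A tibble `(sample_id, value)` of median ranks.
#' @export
celltype_set_rank <- function(ranks, cell_types) {
  check_columns(ranks, c("sample_id", "cell_type", "rank"), "ranks")
  missing <- setdiff(cell_types, unique(ranks$cell_type))
  if (length(missing)) {
    cf_log("%d requested cell type(s) absent from ranks", length(missing),
           level = "WARN")
  }
  ranks %>%
    dplyr::filter(.data$cell_type %in% cell_types) %>%
    dplyr::group_by(sample_id = .data$sample_id) %>%
    dplyr::summarise(value = median(.data$rank), .groups = "drop")
}
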