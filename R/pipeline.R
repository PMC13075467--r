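#' Gene-level GC-corrected coverage for one or many samples
#'
#' Runs the per-sample coverage stage end to end: estimate the GC bias
#' model from the sample's own fragments, compute per-transcript windowed
#' coverage and aggregate transcripts to genes.
#'
#' @param fragments A fragment tibble (one sample) or a list of fragment
#'   tibbles / a multi-sample tibble with a `sample_id` column.
#' @param annotation TSS annotation tibble.
#' @param config A [coverage_config()].
#' @param gc_correct Apply the binned GC correction (default `TRUE`).
#' @return A tibble `(sample_id, gene_id, mean_cov)`.
#' @export
coverage_from_fragments <- function(fragments, annotation,
                                    config = coverage_config(),
                                    gc_correct = TRUE) {
  if (is.data.frame(fragments)) {
    check_columns(fragments, "sample_id", "fragments")
    fragments <- split(fragments, fragments$sample_id)
  }
  purrr::imap_dfr(fragments, function(fr, sid) {
    if (!is.null(fr$sample_id) && length(unique(fr$sample_id)) == 1) {
      sid <- fr$sample_id[1]
    }
    window_gc <- if ("gc" %in% names(annotation)) annotation$gc
    model <- if (gc_correct) estimate_gc_bias(fr, config, window_gc = window_gc) else NULL
    compute_tss_coverage(fr, annotation, model, config) %>%
      aggregate_transcripts() %>%
      dplyr::mutate(sample_id = sid, .before = 1) %>%
      dplyr::select(dplyr::all_of(c("sample_id", "gene_id", "mean_cov")))
  })
}

#' Mixture-weighted bulk expression profile of a simulated reference
#'
#' The synthetic analogue of a whole-blood bulk RNA profile: mean TPM per
#' gene is taken as the base-mixture-weighted average of the cell-type
#' profiles, so marker genes of abundant types are highly expressed and
#' background genes have TPM 0.
#'
#' @param reference A [simulate_reference()] result.
#' @param weights Mixture weights; defaults to the hematopoietic base
#'   mixture used by [simulate_cohort()].
#' @return A tibble `(gene_id, tpm)`.
#' @export
bulk_profile <- function(reference, weights = NULL) {
  stopifnot(inherits(reference, "cf_reference"))
  if (is.null(weights)) weights <- base_mixture_weights(reference)
  w <- check_weights(weights, reference)
  tibble(gene_id = colnames(reference$expr),
         tpm = drop(w %*% reference$expr))
}

#' Hematopoietic base mixture weights of a reference
#'
#' The default healthy-plasma mixture: category weights (monocytes 0.30,
#' lymphocytes 0.25, granulocytes 0.20, remaining categories sharing the
#' rest) split evenly among the member cell types of each category.
#'
#' @param reference An annotated [new_reference()] object.
#' @return Named numeric vector of weights on the simplex.
#' @export
base_mixture_weights <- function(reference) {
  stopifnot(inherits(reference, "cf_reference"))
  ann <- reference$annotation
  check_columns(ann, "category", "reference annotation")
  cat_w <- cf_base_category_weights()
  weights <- setNames(numeric(nrow(reference$expr)), rownames(reference$expr))
  for (cat in unique(ann$category)) {
    members <- ann$cell_type[ann$category == cat]
    weights[members] <- cat_w[[cat]] / length(members)
  }
  weights / sum(weights)
}
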