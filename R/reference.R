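#' Cell-type expression reference
#'
#' Container for a cell-type-by-gene matrix of mean expression together with
#' per-cell-type annotations (category, compartment, tissue). A biological
#' cell type sampled in several tissues appears once per tissue as a distinct
#' reference row, mirroring the convention of multi-tissue single-cell
#' atlases; volcano deduplication relies on this.
#'
#' @param expr Numeric matrix, cell types in rows, genes in columns,
#'   non-negative mean expression.
#' @param annotation Tibble with columns `cell_type` and optionally
#'   `category`, `compartment`, `tissue`; one row per reference row.
#' @param gene_gc Optional named numeric vector of per-gene GC fractions of
#'   the TSS window (used by the coverage simulator).
#' @return An object of class `cf_reference`.
#' @export
new_reference <- function(expr, annotation = NULL, gene_gc = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (any(expr < 0)) stop("expression must be non-negative", call. = FALSE)
  if (anyDuplicated(rownames(expr))) {
    stop("cell-type ids must be unique", call. = FALSE)
  }
  if (is.null(annotation)) {
    annotation <- tibble(cell_type = rownames(expr))
  }
  stopifnot(identical(sort(annotation$cell_type), sort(rownames(expr))))
  structure(list(expr = expr,
                 annotation = as_tibble(annotation),
                 gene_gc = gene_gc),
            class = "cf_reference")
}

#' @export
print.cf_reference <- function(x, ...) {
  cat("<cf_reference> ", nrow(x$expr), " cell types x ", ncol(x$expr),
      " genes\n", sep = "")
  if ("category" %in% names(x$annotation)) {
    tab <- table(x$annotation$category)
    cat("categories: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.cf_reference <- function(x, ...) {
  as_tibble(x$expr, rownames = "cell_type") %>%
    tidyr::pivot_longer(-"cell_type", names_to = "gene_id",
                        values_to = "expression") %>%
    dplyr::left_join(x$annotation, by = "cell_type")
}

#' Average single cells into cell-type expression profiles
#'
#' Collapses a cell-by-gene matrix to a cell-type-by-gene reference by
#' taking the arithmetic mean of all cells carrying the same label.
#'
#' @param cell_matrix Numeric matrix, cells in rows, genes in columns.
#' @param labels Character vector of cell-type labels, one per row of
#'   `cell_matrix`; `NA` labels are an error.
#' @return A [new_reference()] object without category annotations.
#' @export
build_celltype_profiles <- function(cell_matrix, labels) {
  stopifnot(is.matrix(cell_matrix), !is.null(colnames(cell_matrix)))
  if (length(labels) != nrow(cell_matrix)) {
    stop("one label per cell is required", call. = FALSE)
  }
  if (anyNA(labels)) stop("unlabeled cell at row ", which(is.na(labels))[1],
                          call. = FALSE)
  sums <- rowsum(cell_matrix, group = labels)
  counts <- as.vector(table(labels)[rownames(sums)])
  expr <- sums / counts
  cf_log("averaged %d cells into %d cell-type profiles",
         nrow(cell_matrix), nrow(expr))
  new_reference(expr)
}

#' Intersect reference genes with coverage genes
#'
#' The deconvolution operates on the genes shared between the expression
#' reference and the TSS coverage profile (the analogue of the protein-coding
#' genes common to the gene annotation and the single-cell atlas).
#'
#' @param reference A [new_reference()] object.
#' @param coverage_genes Character vector of gene ids with coverage values.
#' @return Sorted character vector of shared gene ids.
#' @export
intersect_genes <- function(reference, coverage_genes) {
  stopifnot(inherits(reference, "cf_reference"), length(coverage_genes) > 0)
  shared <- sort(intersect(colnames(reference$expr), coverage_genes))
  if (!length(shared)) {
    stop("no genes shared between reference and coverage", call. = FALSE)
  }
  cf_log("%d genes shared between reference and coverage", length(shared))
  shared
}

#' Attach category / compartment / tissue annotations to a reference
#'
#' @param reference A [new_reference()] object.
#' @param mapping Tibble with columns `cell_type`, `category` and optionally
#'   `compartment` and `tissue`.
#' @param allow_default If `TRUE`, cell types absent from `mapping` fall back
#'   to category `"other_tissue"` with a warning; otherwise they are an error.
#' @return The reference with its annotation table replaced.
#' @export
assign_categories <- function(reference, mapping, allow_default = FALSE) {
  stopifnot(inherits(reference, "cf_reference"))
  check_columns(mapping, c("cell_type", "category"), "category mapping")
  ann <- tibble(cell_type = rownames(reference$expr)) %>%
    dplyr::left_join(as_tibble(mapping), by = "cell_type")
  unmapped <- ann$cell_type[is.na(ann$category)]
  if (length(unmapped)) {
    if (!allow_default) {
      stop("unmapped cell type(s): ", paste(unmapped, collapse = ", "),
           call. = FALSE)
    }
    cf_log("assigning default category 'other_tissue' to %d unmapped cell type(s)",
           length(unmapped), level = "WARN")
    ann$category[is.na(ann$category)] <- "other_tissue"
  }
  reference$annotation <- ann
  reference
}
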