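#' Read cfDNA fragments from a BED file
#'
#' Fragments are genomic intervals in BED coordinates (0-based, half-open).
#' An optional fourth column carries the per-fragment GC fraction used by
#' [estimate_gc_bias()]. Malformed records abort with the offending line
#' number rather than being silently dropped.
#'
#' @param path Path to a BED3/BED4 file (tab-separated, no header).
#' @param sample_id Sample identifier attached to every fragment; defaults to
#'   the file name without its extension.
#' @return A tibble with columns `chrom`, `start`, `end`, `gc` (`NA` when the
#'   file has no GC column) and `sample_id`.
#' @export
read_fragments <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("fragment file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty fragment file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("fewer than 3 tab-separated columns at line ", which(nf < 3L)[1],
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start != floor(start) |
                 end != floor(end))
  if (length(bad)) stop("malformed coordinates at line ", bad[1], call. = FALSE)
  bad <- which(end <= start)
  if (length(bad)) stop("end <= start at line ", bad[1], call. = FALSE)
  gc <- rep(NA_real_, length(lines))
  if (any(nf >= 4L)) {
    has4 <- nf >= 4L
    gc[has4] <- suppressWarnings(
      as.numeric(vapply(fields[has4], `[[`, character(1), 4L)))
    bad <- which(has4 & (is.na(gc) | gc < 0 | gc > 1))
    if (length(bad)) stop("GC fraction outside [0,1] at line ", bad[1], call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  cf_log("read %d fragments from %s", length(lines), path)
  tibble(chrom = chrom, start = start, end = end, gc = gc,
         sample_id = sample_id)
}

#' Write cfDNA fragments to a BED file
#'
#' Inverse of [read_fragments()]: writes BED3 when no fragment carries a GC
#' value and BED4 otherwise, so that read -> write round-trips a well-formed
#' file byte-identically.
#'
#' @param fragments Fragment tibble as returned by [read_fragments()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(fragments, path) {
  check_columns(fragments, c("chrom", "start", "end"), "fragments")
  has_gc <- "gc" %in% names(fragments) && any(!is.na(fragments$gc))
  lines <- paste(fragments$chrom,
                 format(fragments$start, scientific = FALSE, trim = TRUE),
                 format(fragments$end, scientific = FALSE, trim = TRUE),
                 sep = "\t")
  if (has_gc) {
    lines <- paste(lines, vapply(fragments$gc, function(g) {
      if (is.na(g)) "NA" else format(g, scientific = FALSE, trim = TRUE)
    }, character(1)), sep = "\t")
  }
  writeLines(lines, path)
  cf_log("wrote %d fragments to %s", length(lines), path)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects a tab-separated file with header columns `gene_id`,
#' `transcript_id`, `chrom`, `tss` (0-based position of the transcription
#' start site) and `strand` (`+` or `-`). Additional columns are preserved.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per transcript.
#' @export
read_tss_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  if (!nrow(ann)) stop("no TSS records in ", path, call. = FALSE)
  check_columns(ann, c("gene_id", "transcript_id", "chrom", "tss", "strand"),
                "TSS annotation")
  validate_tss_annotation(ann)
  cf_log("read %d TSS records (%d genes) from %s",
         nrow(ann), dplyr::n_distinct(ann$gene_id), path)
  ann
}

# Shared invariant checks for TSS annotation tables (read or simulated).
validate_tss_annotation <- function(ann) {
  if (!nrow(ann)) stop("no TSS records", call. = FALSE)
  if (anyDuplicated(ann[c("gene_id", "transcript_id")])) {
    stop("duplicate (gene_id, transcript_id) pair in TSS annotation", call. = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (any(is.na(ann$tss)) || any(ann$tss < 0)) {
    stop("tss positions must be non-negative", call. = FALSE)
  }
  invisible(ann)
}

#' Read a gene-by-entity expression matrix
#'
#' First column holds gene identifiers; all remaining columns must be
#' non-negative numbers (e.g. mean TPM per bulk sample, or one column per
#' cell). Duplicated gene ids and negative values are rejected.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with gene ids as row names.
#' @export
read_expression_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"))
  if (!nrow(raw) || ncol(raw) < 2) {
    stop("expression matrix needs a gene column and at least one value column",
         call. = FALSE)
  }
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene id: ", genes[duplicated(genes)][1], call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(genes, names(raw)[-1]))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at gene '%s', column '%s'",
                 genes[idx[1]], colnames(vals)[idx[2]]), call. = FALSE)
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative expression at gene '%s', column '%s'",
                 genes[idx[1]], colnames(vals)[idx[2]]), call. = FALSE)
  }
  cf_log("read %d x %d expression matrix from %s", nrow(vals), ncol(vals), path)
  vals
}

#' Read a cohort sample sheet
#'
#' Expects a tab-separated file with header columns `sample_id`,
#' `patient_id` and `group`; optional columns `timepoint`, `relapse`,
#' `surv_time_months` and `surv_event`, plus any number of numeric covariate
#' columns (e.g. an externally estimated T-cell fraction). Empty strings and
#' `"NA"` are read as missing.
#'
#' @param path Path to the TSV file.
#' @return A cohort tibble.
#' @export
read_sample_sheet <- function(path) {
  cohort <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                            na = c("", "NA"))
  if (!nrow(cohort)) stop("empty sample sheet: ", path, call. = FALSE)
  check_columns(cohort, c("sample_id", "patient_id", "group"), "sample sheet")
  if (anyDuplicated(cohort$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (all(c("surv_time_months", "surv_event") %in% names(cohort))) {
    orphan <- !is.na(cohort$surv_time_months) & is.na(cohort$surv_event)
    if (any(orphan)) {
      stop("surv_event missing for sample(s) with surv_time_months: ",
           paste(cohort$sample_id[orphan], collapse = ", "), call. = FALSE)
    }
  }
  cf_log("read %d samples (%d groups) from %s", nrow(cohort),
         dplyr::n_distinct(cohort$group), path)
  cohort
}

#' Descriptive cohort summary (n (%); median (Q1, Q3))
#'
#' Summarises a cohort table the way clinical baseline tables are printed:
#' per-level counts and integer percentages for categorical variables,
#' median and quartiles for numeric ones. Percentages use non-missing
#' denominators and half-up rounding; a value recorded as `NA` is excluded
#' from the denominator while an explicit level such as `"Unknown"` counts.
#'
#' @param cohort A cohort tibble.
#' @param variables Character vector of columns to summarise; defaults to all
#'   columns except `sample_id` and `patient_id`.
#' @return A tibble with columns `variable`, `level`, `n`, `n_nonmissing`,
#'   `pct` (integer percent, `NA` for numeric variables), `median`, `q1`,
#'   `q3` (`NA` for categorical variables).
#' @examples
#' cohort <- tibble::tibble(
#'   sample_id = paste0("s", 1:124), patient_id = paste0("p", 1:124),
#'   group = "cancer_CRC",
#'   sex = rep(c("Female", "Male"), c(54, 70)))
#' summarize_cohort(cohort, "sex")  # Female 44%, Male 56%
#' @export
summarize_cohort <- function(cohort, variables = NULL) {
  stopifnot(nrow(cohort) >= 1)
  if (is.null(variables)) {
    variables <- setdiff(names(cohort), c("sample_id", "patient_id"))
  }
  check_columns(cohort, variables, "cohort")
  purrr::map_dfr(variables, function(v) {
    x <- cohort[[v]]
    n_non <- sum(!is.na(x))
    if (n_non == 0) {
      return(tibble(variable = v, level = NA_character_, n = 0L,
                    n_nonmissing = 0L, pct = NA_real_,
                    median = NA_real_, q1 = NA_real_, q3 = NA_real_))
    }
    if (is.numeric(x)) {
      qs <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      tibble(variable = v, level = NA_character_, n = n_non,
             n_nonmissing = n_non, pct = NA_real_,
             median = qs[2], q1 = qs[1], q3 = qs[3])
    } else {
      counts <- table(x[!is.na(x)])
      tibble(variable = v, level = names(counts),
             n = as.integer(counts), n_nonmissing = n_non,
             pct = round_half_up(100 * as.integer(counts) / n_non),
             median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    }
  })
}
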