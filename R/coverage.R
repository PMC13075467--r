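#' Coverage computation configuration
#'
#' @param window_bp Half-width of the TSS window in bp (the window spans
#'   `2 * window_bp + 1` positions centred on the TSS).
#' @param gc_bins Number of equal-width GC bins on `[0, 1]` for bias
#'   estimation.
#' @param min_fragments Minimum fragments required per sample.
#' @return A list of class `cf_coverage_config`.
#' @export
coverage_config <- function(window_bp = 1000, gc_bins = 50, min_fragments = 1) {
  stopifnot(window_bp > 0, gc_bins >= 2, min_fragments >= 0)
  structure(list(window_bp = as.integer(window_bp),
                 gc_bins = as.integer(gc_bins),
                 min_fragments = as.integer(min_fragments)),
            class = "cf_coverage_config")
}

#' Estimate a binned GC bias model from fragments
#'
#' Fragments are binned by GC fraction into equal-width bins; each occupied
#' bin receives a weight proportional to `global mean bin rate / bin rate`,
#' so over-represented GC strata are down-weighted. When `window_gc` (the
#' GC fractions of the annotated TSS windows) is supplied, a bin's rate is
#' fragments per window in that stratum -- the observed-over-expected
#' contract of genome-wide GC correction -- which stops uneven window
#' counts per stratum from leaking into the weights; without it the raw
#' fragment count is the rate. Empty bins get weight 1 and weights are
#' rescaled so their fragment-weighted mean is exactly 1.
#'
#' @param fragments Fragment tibble with a `gc` column (may be all `NA`).
#' @param config A [coverage_config()].
#' @param window_gc Optional numeric vector of per-window GC fractions
#'   describing the GC opportunity of the annotated regions.
#' @return An object of class `cf_gc_model`: a tibble of bins with counts
#'   and weights plus the bin breaks.
#' @export
estimate_gc_bias <- function(fragments, config = coverage_config(),
                             window_gc = NULL) {
  stopifnot(inherits(config, "cf_coverage_config"))
  if (nrow(fragments) < config$min_fragments) {
    stop("sample has fewer than min_fragments fragments", call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = config$gc_bins + 1L)
  gc <- fragments$gc
  if (!("gc" %in% names(fragments)) || all(is.na(gc))) {
    cf_log("fragments carry no GC values; using identity GC model", level = "WARN")
    model <- tibble(bin = seq_len(config$gc_bins),
                    gc_lo = breaks[-length(breaks)], gc_hi = breaks[-1],
                    count = 0L, weight = 1)
    return(structure(list(bins = model, breaks = breaks), class = "cf_gc_model"))
  }
  gc <- gc[!is.na(gc)]
  gc_bin <- function(v) {
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
         config$gc_bins)
  }
  counts <- tabulate(gc_bin(gc), nbins = config$gc_bins)
  opportunity <- if (is.null(window_gc)) {
    rep(1, config$gc_bins)
  } else {
    tabulate(gc_bin(window_gc[!is.na(window_gc)]), nbins = config$gc_bins)
  }
  occupied <- counts > 0 & opportunity > 0
  rate <- ifelse(occupied, counts / opportunity, NA_real_)
  global_rate <- mean(rate[occupied])
  weight <- ifelse(occupied, global_rate / rate, 1)
  # Rescale occupied bins so the fragment-weighted mean weight is exactly 1
  # (bins outside the opportunity distribution keep weight 1).
  weight[occupied] <- weight[occupied] *
    (sum(counts) - sum(counts[!occupied])) / sum(counts[occupied] * weight[occupied])
  model <- tibble(bin = seq_len(config$gc_bins),
                  gc_lo = breaks[-length(breaks)], gc_hi = breaks[-1],
                  count = counts, weight = weight)
  cf_log("GC model: %d/%d occupied bins over %d fragments",
         sum(occupied), config$gc_bins, length(gc))
  structure(list(bins = model, breaks = breaks), class = "cf_gc_model")
}

#' @export
print.cf_gc_model <- function(x, ...) {
  occ <- x$bins[x$bins$count > 0, ]
  cat("<cf_gc_model> ", nrow(x$bins), " bins, ", nrow(occ), " occupied; ",
      "weight range ", if (nrow(occ)) paste(signif(range(occ$weight), 3),
                                            collapse = " - ") else "1 - 1",
      "\n", sep = "")
  invisible(x)
}

#' Per-fragment GC weights under a bias model
#'
#' @param model A [estimate_gc_bias()] model (or `NULL` for identity).
#' @param gc Numeric vector of fragment GC fractions (`NA` -> weight 1).
#' @return Numeric vector of weights.
#' @export
gc_weights <- function(model, gc) {
  if (is.null(model)) return(rep(1, length(gc)))
  stopifnot(inherits(model, "cf_gc_model"))
  w <- rep(1, length(gc))
  ok <- !is.na(gc)
  bin <- pmin(pmax(findInterval(gc[ok], model$breaks, rightmost.closed = TRUE), 1L),
              nrow(model$bins))
  w[ok] <- model$bins$weight[bin]
  w
}

# Internal: overlaps between fragments and TSS windows.
# Returns a tibble (tx = row index into windows, frag = row index into
# fragments, ov_start, ov_end) in 1-based inclusive window coordinates.
window_overlaps <- function(fragments, annotation, window_bp) {
  res <- vector("list", 0)
  win_start <- pmax(annotation$tss - window_bp, 0) + 1   # 1-based inclusive
  win_end <- annotation$tss + window_bp + 1
  clipped <- annotation$tss - window_bp < 0
  if (any(clipped)) {
    cf_log("%d TSS window(s) clipped at chromosome start", sum(clipped),
           level = "WARN")
  }
  for (chr in unique(annotation$chrom)) {
    ti <- which(annotation$chrom == chr)
    fi <- which(fragments$chrom == chr)
    if (!length(fi)) next
    ir_w <- IRanges::IRanges(start = win_start[ti], end = win_end[ti])
    ir_f <- IRanges::IRanges(start = fragments$start[fi] + 1,
                             end = fragments$end[fi])
    hits <- IRanges::findOverlaps(ir_f, ir_w)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    res[[length(res) + 1]] <- tibble(
      tx = ti[si], frag = fi[qi],
      ov_start = pmax(IRanges::start(ir_f)[qi], IRanges::start(ir_w)[si]),
      ov_end = pmin(IRanges::end(ir_f)[qi], IRanges::end(ir_w)[si]))
  }
  if (!length(res)) {
    tibble(tx = integer(), frag = integer(),
           ov_start = integer(), ov_end = integer())
  } else {
    dplyr::bind_rows(res)
  }
}

#' Per-transcript mean GC-corrected coverage in the TSS window
#'
#' A fragment contributes its GC weight at every base it overlaps within the
#' `+/- window_bp` window of each transcript's TSS (a pileup, not a midpoint
#' count). The summed weighted depth is divided by the full window length
#' (`2 * window_bp + 1`, also for windows clipped at position 0) and then by
#' the sample-wide mean over all annotated windows, so the per-sample
#' average is exactly 1.
#'
#' @param fragments Fragment tibble for one sample.
#' @param annotation TSS annotation tibble.
#' @param gc_model A [estimate_gc_bias()] model or `NULL` for no correction.
#' @param config A [coverage_config()].
#' @return A tibble `(transcript_id, gene_id, strand, mean_cov)` where
#'   `mean_cov` is sample-normalized (mean 1 across transcripts).
#' @export
compute_tss_coverage <- function(fragments, annotation,
                                 gc_model = NULL,
                                 config = coverage_config()) {
  stopifnot(inherits(config, "cf_coverage_config"))
  validate_tss_annotation(annotation)
  w <- config$window_bp
  ov <- window_overlaps(fragments, annotation, w)
  wts <- gc_weights(gc_model, fragments$gc)
  depth_sum <- rep(0, nrow(annotation))
  if (nrow(ov)) {
    contrib <- wts[ov$frag] * (ov$ov_end - ov$ov_start + 1)
    agg <- rowsum(contrib, group = ov$tx)
    depth_sum[as.integer(rownames(agg))] <- agg[, 1]
  }
  mean_depth <- depth_sum / (2 * w + 1)
  overall <- mean(mean_depth)
  if (overall <= 0) {
    stop("no fragments overlap any annotated TSS window", call. = FALSE)
  }
  cf_log("coverage over %d windows from %d fragments (sample mean depth %.4g)",
         nrow(annotation), nrow(fragments), overall)
  tibble(transcript_id = annotation$transcript_id,
         gene_id = annotation$gene_id,
         strand = annotation$strand,
         mean_cov = mean_depth / overall)
}

#' Aggregate per-transcript coverage to genes
#'
#' Multiple transcripts of the same gene are aggregated by the arithmetic
#' mean; transcripts with missing values are excluded from the mean and
#' counted in the log.
#'
#' @param tx_coverage Output of [compute_tss_coverage()].
#' @return A tibble `(gene_id, mean_cov, n_transcripts)`.
#' @export
aggregate_transcripts <- function(tx_coverage) {
  check_columns(tx_coverage, c("gene_id", "mean_cov"), "transcript coverage")
  n_missing <- sum(is.na(tx_coverage$mean_cov))
  if (n_missing) cf_log("%d transcript(s) with missing coverage excluded from gene means",
                        n_missing)
  tx_coverage %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(mean_cov = mean(.data$mean_cov, na.rm = TRUE),
                     n_transcripts = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(mean_cov = ifelse(is.nan(.data$mean_cov), NA_real_,
                                    .data$mean_cov))
}

#' Positional coverage metaprofile across a gene set
#'
#' Computes the position-wise mean of sample-normalized coverage over all
#' transcripts of the genes in `gene_set`, indexed by offset from the TSS.
#' Offsets are oriented along transcription: for minus-strand transcripts
#' the genomic offsets are flipped so that positive offsets are always
#' downstream of the TSS.
#'
#' @param fragments Fragment tibble for one sample.
#' @param annotation TSS annotation tibble.
#' @param gene_set Character vector of gene ids (subset of the annotation).
#' @param gc_model A [estimate_gc_bias()] model or `NULL`.
#' @param config A [coverage_config()].
#' @return A tibble `(offset, mean_cov)` of class `cf_metaprofile`.
#' @export
metaprofile <- function(fragments, annotation, gene_set,
                        gc_model = NULL, config = coverage_config()) {
  stopifnot(inherits(config, "cf_coverage_config"))
  validate_tss_annotation(annotation)
  if (!length(gene_set)) stop("empty gene set", call. = FALSE)
  missing <- setdiff(gene_set, annotation$gene_id)
  if (length(missing)) {
    stop("gene(s) not in annotation: ", paste(utils::head(missing, 3), collapse = ", "),
         call. = FALSE)
  }
  w <- config$window_bp
  L <- 2L * w + 1L
  ann <- annotation[annotation$gene_id %in% gene_set, ]
  ov <- window_overlaps(fragments, ann, w)
  wts <- gc_weights(gc_model, fragments$gc)
  depth <- matrix(0, nrow(ann), L + 1L)
  if (nrow(ov)) {
    # Delta-encoded pileup per window: +weight at overlap start, -weight
    # one past the end, then cumulative sum along offsets. Offsets are
    # anchored at tss - window_bp even for windows clipped at position 0.
    win_lo <- ann$tss - w + 1
    a <- ov$ov_start - win_lo[ov$tx] + 1L
    b <- ov$ov_end - win_lo[ov$tx] + 2L
    wf <- wts[ov$frag]
    add <- rowsum(c(wf, -wf), group = c((a - 1L) * nrow(ann) + ov$tx,
                                        (b - 1L) * nrow(ann) + ov$tx))
    idx <- as.integer(rownames(add))
    depth[idx] <- add[, 1]
    depth <- t(apply(depth, 1, cumsum))
  }
  depth <- depth[, seq_len(L), drop = FALSE]
  # Transcription orientation: flip minus-strand rows.
  minus <- ann$strand == "-"
  depth[minus, ] <- depth[minus, rev(seq_len(L)), drop = FALSE]
  # Normalize by the sample-wide mean window depth (the same divisor used
  # for mean_cov), then average across transcripts.
  sample_mean <- mean_window_depth(fragments, annotation, gc_model, config)
  prof <- colMeans(depth) / sample_mean
  structure(tibble(offset = seq(-w, w), mean_cov = prof),
            class = c("cf_metaprofile", "tbl_df", "tbl", "data.frame"))
}

# Internal: sample-wide mean weighted window depth over all annotated
# windows (the normalization constant shared by mean_cov and metaprofile).
mean_window_depth <- function(fragments, annotation, gc_model, config) {
  w <- config$window_bp
  ov <- window_overlaps(fragments, annotation, w)
  wts <- gc_weights(gc_model, fragments$gc)
  total <- if (nrow(ov)) sum(wts[ov$frag] * (ov$ov_end - ov$ov_start + 1)) else 0
  total / (2 * w + 1) / nrow(annotation)
}

#' Compare per-gene coverage against bulk expression classes
#'
#' Classifies genes by a bulk expression profile -- unexpressed (mean TPM of
#' 0), expressed (top `top_n` by TPM, ties broken by TPM descending then
#' gene id ascending) and other -- and tests whether the expressed class has
#' depressed TSS coverage relative to the unexpressed class (two-sided
#' Wilcoxon rank-sum, BH-adjusted).
#'
#' @param gene_coverage Tibble `(gene_id, mean_cov)` from
#'   [aggregate_transcripts()].
#' @param bulk Tibble `(gene_id, tpm)` of mean TPM per gene.
#' @param top_n Number of top-expressed genes (reduced with a warning when
#'   fewer genes have TPM > 0).
#' @return A list of class `cf_class_report`: per-gene classes, per-class
#'   summary (n, median coverage), the expressed - unexpressed median
#'   difference, `p`, `q` and the `separated` flag (`q < 0.05`).
#' @export
expression_class_report <- function(gene_coverage, bulk, top_n = 2000) {
  check_columns(gene_coverage, c("gene_id", "mean_cov"), "gene coverage")
  check_columns(bulk, c("gene_id", "tpm"), "bulk profile")
  if (any(bulk$tpm < 0)) stop("TPM must be non-negative", call. = FALSE)
  df <- dplyr::inner_join(gene_coverage, bulk, by = "gene_id")
  n_nonzero <- sum(df$tpm > 0)
  if (n_nonzero < top_n) {
    cf_log("only %d genes with TPM > 0; reducing top_n from %d",
           n_nonzero, top_n, level = "WARN")
    top_n <- n_nonzero
  }
  expressed <- df %>%
    dplyr::filter(.data$tpm > 0) %>%
    dplyr::arrange(dplyr::desc(.data$tpm), .data$gene_id) %>%
    dplyr::slice_head(n = top_n) %>%
    dplyr::pull("gene_id")
  df$class <- ifelse(df$tpm == 0, "unexpressed",
                     ifelse(df$gene_id %in% expressed, "expressed", "other"))
  summary <- df %>%
    dplyr::group_by(class = .data$class) %>%
    dplyr::summarise(n = dplyr::n(),
                     median_cov = median(.data$mean_cov, na.rm = TRUE),
                     .groups = "drop")
  cov_e <- df$mean_cov[df$class == "expressed"]
  cov_u <- df$mean_cov[df$class == "unexpressed"]
  if (length(cov_e) && length(cov_u)) {
    test <- wilcoxon_rank_sum(cov_e[!is.na(cov_e)], cov_u[!is.na(cov_u)])
    p <- test$p
  } else {
    p <- NA_real_
  }
  q <- if (is.na(p)) NA_real_ else bh_fdr(p)
  diff <- median(cov_e, na.rm = TRUE) - median(cov_u, na.rm = TRUE)
  structure(list(genes = as_tibble(df), summary = summary,
                 median_difference = diff, p = p, q = q,
                 separated = isTRUE(q < 0.05)),
            class = "cf_class_report")
}

#' @export
print.cf_class_report <- function(x, ...) {
  cat("<cf_class_report> expressed - unexpressed median coverage difference: ",
      signif(x$median_difference, 4), "\n", sep = "")
  cat("Wilcoxon p = ", format.pval(x$p), ", q = ", format.pval(x$q),
      "; separated: ", x$separated, "\n", sep = "")
  print(x$summary)
  invisible(x)
}
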