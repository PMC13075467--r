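#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' statistical structure the coverage-based deconvolution assumes: cell-type
#' expression profiles with disjoint marker blocks, mixture-weighted bulk
#' expression, TSS coverage depletion monotone in expression, multiplicative
#' GC bias and lognormal noise.
#'
#' The closed-form coverage model is
#' `cov_g = B * g(GC_g) * (1 - d * s_g) * eps_g`, where
#' `x_g = sum_k w_k e[k, g]` is mixture-weighted expression,
#' `s_g = log1p(x_g) / max_h log1p(x_h)` the bounded depletion score,
#' `g(GC) = 1 + gc_bias_amplitude * (GC_g - mean(GC))` the multiplicative GC
#' effect and `eps_g` lognormal(0, noise_sd^2).
#'
#' @param n_celltypes Number of reference cell types `K` (>= 2).
#' @param n_genes Number of genes `G` (>= `K * n_markers`).
#' @param n_markers Marker genes per cell type (disjoint blocks).
#' @param expr_scale Scale of marker expression (lognormal location).
#' @param depletion Depletion depth `d` in `[0, 1]`; 0 disables depletion.
#' @param noise_sd Lognormal noise sd `sigma` (>= 0).
#' @param gc_bias_amplitude GC bias amplitude in `[0, 1)`.
#' @param baseline_coverage Baseline coverage `B` (> 0).
#' @param window_bp Half-width of the TSS window in bp.
#' @param frag_len_mean,frag_len_sd Fragment length distribution (normal,
#'   truncated at 50 bp).
#' @param n_fragments Fragments drawn per simulated sample.
#' @param seed Base RNG seed; per-sample streams are derived from it.
#' @return A list of class `cf_sim_config`.
#' @export
sim_config <- function(n_celltypes = 8, n_genes = 1000, n_markers = 40,
                       expr_scale = 10, depletion = 0.8, noise_sd = 0.1,
                       gc_bias_amplitude = 0, baseline_coverage = 1,
                       window_bp = 1000, frag_len_mean = 167,
                       frag_len_sd = 20, n_fragments = 1e5, seed = 1L) {
  stopifnot(n_celltypes >= 2,
            n_genes >= n_celltypes * n_markers,
            n_markers >= 1,
            expr_scale > 0,
            is_fraction(depletion),
            noise_sd >= 0,
            gc_bias_amplitude >= 0, gc_bias_amplitude < 1,
            baseline_coverage > 0,
            window_bp > 0,
            frag_len_mean > 0, frag_len_sd >= 0,
            n_fragments >= 0)
  structure(list(n_celltypes = as.integer(n_celltypes),
                 n_genes = as.integer(n_genes),
                 n_markers = as.integer(n_markers),
                 expr_scale = expr_scale, depletion = depletion,
                 noise_sd = noise_sd, gc_bias_amplitude = gc_bias_amplitude,
                 baseline_coverage = baseline_coverage,
                 window_bp = as.integer(window_bp),
                 frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
                 n_fragments = as.integer(n_fragments),
                 seed = as.integer(seed)),
            class = "cf_sim_config")
}

# Fixed label cycles for simulated cell-type annotation.
cf_categories <- c("monocytes", "lymphocytes", "granulocytes",
                   "progenitor_erythroid", "endothelial", "other_tissue",
                   "stromal", "hepatic")
cf_compartments <- c(monocytes = "immune", lymphocytes = "immune",
                     granulocytes = "immune", progenitor_erythroid = "immune",
                     endothelial = "endothelial", other_tissue = "epithelial",
                     stromal = "stromal", hepatic = "epithelial")
cf_tissues <- c("blood", "spleen", "lymph_node", "thymus", "bone_marrow",
                "liver", "lung", "colon")

# Hematopoietic-dominant base mixture over categories: monocytes, lymphocytes
# and granulocytes dominate plasma cfDNA; remaining categories share the rest.
cf_base_category_weights <- function() {
  base <- c(monocytes = 0.30, lymphocytes = 0.25, granulocytes = 0.20)
  rest <- setdiff(cf_categories, names(base))
  c(base, setNames(rep((1 - sum(base)) / length(rest), length(rest)), rest))
}

#' Simulate an annotated cell-type expression reference
#'
#' Each cell type receives a disjoint block of `n_markers` marker genes with
#' lognormal expression centred on `expr_scale`; background expression is
#' zero, so the mixture bulk profile has a genuine unexpressed (TPM = 0)
#' class. Categories and tissues are assigned by cycling through fixed label
#' lists; per-gene GC fractions of the TSS windows are drawn uniformly on
#' `[0.3, 0.6]`.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return A [new_reference()] object with `gene_gc` set.
#' @export
simulate_reference <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cf_sim_config"))
  K <- config$n_celltypes
  G <- config$n_genes
  m <- config$n_markers
  genes <- sprintf("gene_%04d", seq_len(G))
  types <- sprintf("ct%02d_%s", seq_len(K),
                   cf_tissues[(seq_len(K) - 1L) %% length(cf_tissues) + 1L])
  withr::with_seed(derive_seed(seed, "reference"), {
    expr <- matrix(0, K, G, dimnames = list(types, genes))
    for (k in seq_len(K)) {
      block <- ((k - 1L) * m + 1L):(k * m)
      expr[k, block] <- rlnorm(m, meanlog = log(config$expr_scale), sdlog = 0.5)
    }
    gene_gc <- setNames(runif(G, 0.3, 0.6), genes)
  })
  category <- cf_categories[(seq_len(K) - 1L) %% length(cf_categories) + 1L]
  annotation <- tibble(cell_type = types,
                       category = category,
                       compartment = unname(cf_compartments[category]),
                       tissue = cf_tissues[(seq_len(K) - 1L) %% length(cf_tissues) + 1L])
  new_reference(expr, annotation, gene_gc)
}

#' Simulate a synthetic TSS annotation matching a reference
#'
#' Places one transcript per reference gene on a synthetic chromosome with
#' TSSs spaced at least twice the window width apart (so TSS windows never
#' overlap), alternating strands.
#'
#' @param config A [sim_config()].
#' @param reference A [simulate_reference()] result (for gene ids).
#' @return A TSS annotation tibble.
#' @export
simulate_tss_annotation <- function(config, reference) {
  stopifnot(inherits(config, "cf_sim_config"), inherits(reference, "cf_reference"))
  genes <- colnames(reference$expr)
  G <- length(genes)
  spacing <- 4L * config$window_bp +
    2L * as.integer(ceiling(config$frag_len_mean + 4 * config$frag_len_sd))
  ann <- tibble(gene_id = genes,
                transcript_id = paste0(genes, "_t1"),
                chrom = "chrS",
                tss = 2L * config$window_bp + spacing * (seq_len(G) - 1L),
                strand = rep_len(c("+", "-"), G),
                gc = unname(reference$gene_gc[genes]))
  validate_tss_annotation(ann)
}

# Internal: depletion scores s_g in [0,1] for a weighted mixture.
depletion_scores <- function(reference, weights) {
  w <- check_weights(weights, reference)
  x <- drop(w %*% reference$expr)
  lx <- log1p(x)
  mx <- max(lx)
  if (mx > 0) lx / mx else lx * 0
}

# Internal: validate mixture weights on the K-simplex; returns a row vector
# ordered like the reference rows.
check_weights <- function(weights, reference) {
  K <- nrow(reference$expr)
  if (!is.null(names(weights))) {
    stopifnot(setequal(names(weights), rownames(reference$expr)))
    weights <- weights[rownames(reference$expr)]
  }
  if (length(weights) != K) stop("need one weight per cell type", call. = FALSE)
  if (any(weights < 0)) stop("mixture weights must be non-negative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("mixture weights must sum to 1 (within 1e-9)", call. = FALSE)
  }
  matrix(weights, nrow = 1)
}

# Internal: multiplicative GC effect per gene.
gc_effect <- function(reference, config) {
  if (config$gc_bias_amplitude == 0 || is.null(reference$gene_gc)) {
    return(rep(1, ncol(reference$expr)))
  }
  gcv <- reference$gene_gc[colnames(reference$expr)]
  1 + config$gc_bias_amplitude * (gcv - mean(gcv))
}

#' Simulate closed-form per-gene TSS coverage for one sample
#'
#' Applies the coverage model documented in [sim_config()] directly, without
#' drawing fragments: expression is mixed with the sample's weights, turned
#' into a bounded depletion score, scaled by baseline coverage, GC effect and
#' lognormal noise.
#'
#' @param reference A [simulate_reference()] result.
#' @param weights Mixture weights on the K-simplex (named or in reference
#'   row order).
#' @param config A [sim_config()].
#' @param seed Seed for the noise stream.
#' @return A tibble with columns `gene_id` and `coverage`.
#' @export
simulate_sample_coverage <- function(reference, weights, config,
                                     seed = config$seed) {
  stopifnot(inherits(reference, "cf_reference"), inherits(config, "cf_sim_config"))
  s <- depletion_scores(reference, weights)
  gfac <- gc_effect(reference, config)
  G <- ncol(reference$expr)
  eps <- if (config$noise_sd > 0) {
    withr::with_seed(derive_seed(seed, "coverage"),
                     rlnorm(G, 0, config$noise_sd))
  } else {
    rep(1, G)
  }
  tibble(gene_id = colnames(reference$expr),
         coverage = unname(config$baseline_coverage * gfac *
                             (1 - config$depletion * s) * eps))
}

#' Simulate cfDNA fragments around TSS windows
#'
#' Draws fragment midpoints uniformly across each TSS window (plus a margin
#' of one fragment length so pileup is unbiased at the window edges) and
#' accepts a midpoint at offset `u` from the TSS with probability
#' `1 - d * s_g * exp(-u^2 / (2 * 300^2))`: expressed genes lose fragments
#' near the TSS, emulating the nucleosome-depleted region. Genes receive
#' candidate fragments proportionally to their GC effect and lognormal noise
#' factor, and each fragment's GC fraction is its gene's window GC plus small
#' jitter, so binned GC correction is exercisable.
#'
#' @param reference A [simulate_reference()] result.
#' @param weights Mixture weights on the K-simplex.
#' @param annotation TSS annotation from [simulate_tss_annotation()].
#' @param config A [sim_config()].
#' @param seed Seed for this sample's stream.
#' @param sample_id Sample id recorded on the fragments.
#' @return A fragment tibble (`chrom`, `start`, `end`, `gc`, `sample_id`).
#' @export
simulate_fragments <- function(reference, weights, annotation, config,
                               seed = config$seed, sample_id = "sim") {
  stopifnot(inherits(reference, "cf_reference"), inherits(config, "cf_sim_config"))
  if (config$n_fragments <= 0) stop("zero fragments requested", call. = FALSE)
  s <- depletion_scores(reference, weights)
  gfac <- gc_effect(reference, config)
  genes <- colnames(reference$expr)
  ann <- annotation[match(genes, annotation$gene_id), ]
  if (anyNA(ann$gene_id)) stop("annotation must cover all reference genes", call. = FALSE)
  w <- config$window_bp
  margin <- as.integer(ceiling((config$frag_len_mean + 4 * config$frag_len_sd) / 2))
  withr::with_seed(derive_seed(seed, paste0("fragments:", sample_id)), {
    rate <- gfac * if (config$noise_sd > 0) rlnorm(length(genes), 0, config$noise_sd) else 1
    n_g <- as.vector(stats::rmultinom(1, config$n_fragments, rate / sum(rate)))
    gene_idx <- rep.int(seq_along(genes), n_g)
    u <- runif(length(gene_idx), -w - margin, w + margin)
    accept <- runif(length(gene_idx)) >=
      config$depletion * s[gene_idx] * exp(-u^2 / (2 * 300^2))
    gene_idx <- gene_idx[accept]
    u <- u[accept]
    len <- rnorm(length(u), config$frag_len_mean, config$frag_len_sd)
    while (any(len < 50)) {
      redo <- len < 50
      len[redo] <- rnorm(sum(redo), config$frag_len_mean, config$frag_len_sd)
    }
    len <- as.integer(round(len))
    mid <- ann$tss[gene_idx] + as.integer(round(u))
    start <- pmax(0L, mid - len %/% 2L)
    gc <- pmin(1, pmax(0, reference$gene_gc[gene_idx] +
                         rnorm(length(gene_idx), 0, 0.01)))
  })
  frag <- tibble(chrom = ann$chrom[gene_idx],
                 start = start,
                 end = start + len,
                 gc = unname(gc),
                 sample_id = sample_id)
  frag <- dplyr::arrange(frag, .data$chrom, .data$start, .data$end, .data$gc)
  cf_log("simulated %d fragments (%d candidates) for %s",
         nrow(frag), config$n_fragments, sample_id)
  frag
}

#' Expected normalized window coverage of the fragment simulator
#'
#' Numerically integrates the Gaussian acceptance kernel of
#' [simulate_fragments()], smeared by the fragment length, over the TSS
#' window. The per-gene expectation is proportional to
#' `1 - d * s_g * kappa`, where `kappa` is the window-averaged smeared
#' kernel; the result is normalized to mean 1 to match the output of the
#' coverage pipeline.
#'
#' @param reference A [simulate_reference()] result.
#' @param weights Mixture weights on the K-simplex.
#' @param config A [sim_config()].
#' @return A tibble with columns `gene_id` and `expected_cov` (mean 1).
#' @export
expected_fragment_coverage <- function(reference, weights, config) {
  s <- depletion_scores(reference, weights)
  w <- config$window_bp
  L <- config$frag_len_mean
  # Smear the acceptance kernel with a box of one mean fragment length, then
  # average over window positions: depth at p integrates accepted midpoints
  # in [p - L/2, p + L/2].
  u <- seq(-w - L, w + L)
  kern <- exp(-u^2 / (2 * 300^2))
  half <- floor(L / 2)
  csum <- cumsum(kern)
  pos <- seq(-w, w)
  i_lo <- match(pmax(pos - half, -w - L), u)
  i_hi <- match(pmin(pos + half, w + L), u)
  smeared <- (csum[i_hi] - c(0, csum)[i_lo]) / (i_hi - i_lo + 1)
  kappa <- mean(smeared)
  gfac <- gc_effect(reference, config)
  expected <- gfac * (1 - config$depletion * s * kappa)
  tibble(gene_id = colnames(reference$expr),
         expected_cov = expected / mean(expected))
}

#' Cohort simulation design
#'
#' @param n_healthy,n_cancer Samples per arm (pretreatment).
#' @param delta Case-control mixture shift: added to the lymphocyte-category
#'   weights and subtracted from the monocyte-category weights (split evenly
#'   among category members), then renormalized.
#' @param concentration Dirichlet concentration multiplier; per-sample
#'   weights are drawn from `Dirichlet(concentration * base)`.
#' @param cancer_group Group label for the cancer arm.
#' @param timepoints Optional character vector of ordered timepoint labels
#'   for cancer patients; the first is baseline.
#' @param trajectory Optional tibble `(timepoint, category, offset)`; the
#'   offset is added to that category's weights at that timepoint.
#' @param relapse_frac Fraction of cancer patients labelled relapse.
#' @param relapse_effect Extra weight offset applied to lymphocyte-category
#'   weights at non-baseline timepoints of relapse patients.
#' @return A list of class `cf_cohort_design`.
#' @export
cohort_design <- function(n_healthy = 30, n_cancer = 30, delta = 0,
                          concentration = 100, cancer_group = "cancer_CRC",
                          timepoints = NULL, trajectory = NULL,
                          relapse_frac = 0, relapse_effect = 0) {
  stopifnot(n_healthy >= 0, n_cancer >= 0, concentration > 0,
            is_fraction(relapse_frac))
  structure(list(n_healthy = as.integer(n_healthy),
                 n_cancer = as.integer(n_cancer), delta = delta,
                 concentration = concentration, cancer_group = cancer_group,
                 timepoints = timepoints, trajectory = trajectory,
                 relapse_frac = relapse_frac, relapse_effect = relapse_effect),
            class = "cf_cohort_design")
}

# Internal: spread category-level offsets onto per-type base weights.
shift_weights <- function(base, annotation, offsets) {
  out <- base
  for (cat in names(offsets)) {
    members <- annotation$cell_type[annotation$category == cat]
    if (!length(members)) next
    out[members] <- out[members] + offsets[[cat]] / length(members)
  }
  if (any(out < 0)) {
    stop("weight shift produces negative weights", call. = FALSE)
  }
  out / sum(out)
}

#' Simulate a full case-control (optionally longitudinal) cohort
#'
#' Healthy samples draw mixture weights from a Dirichlet around the
#' hematopoietic base mixture; cancer samples shift weight `delta` from the
#' monocyte to the lymphocyte category before drawing, emulating the
#' adaptive-up / innate-down pattern of cancer cohorts. Longitudinal designs
#' add per-timepoint category offsets, and relapse patients an extra
#' lymphocyte offset after baseline. The exact weights used are recorded as
#' ground truth.
#'
#' @param config A [sim_config()].
#' @param design A [cohort_design()].
#' @param output `"coverage"` for closed-form per-gene coverage (fast) or
#'   `"fragments"` for BED-style fragment sets.
#' @param seed Base seed; per-sample streams are derived from it.
#' @return A list of class `cf_cohort_sim` with elements `reference`,
#'   `annotation` (TSS table, fragments output only), `cohort` (sample
#'   sheet tibble), `truth` (long tibble of the weights used) and
#'   `coverage` (long tibble) or `fragments` (named list of tibbles).
#' @export
simulate_cohort <- function(config, design, output = c("coverage", "fragments"),
                            seed = config$seed) {
  stopifnot(inherits(config, "cf_sim_config"), inherits(design, "cf_cohort_design"))
  output <- match.arg(output)
  reference <- simulate_reference(config, seed = seed)
  ann_tss <- if (output == "fragments") simulate_tss_annotation(config, reference)
  ann <- reference$annotation
  base <- base_mixture_weights(reference)

  tps <- design$timepoints %||% "baseline"
  baseline_tp <- tps[1]
  rows <- list()
  idx <- 0L
  add_sample <- function(group, patient, tp, relapse) {
    idx <<- idx + 1L
    tibble(sample_id = sprintf("s%03d_%s", idx, tp), patient_id = patient,
           group = group, timepoint = tp, relapse = relapse)
  }
  for (i in seq_len(design$n_healthy)) {
    rows[[length(rows) + 1L]] <- add_sample("healthy", sprintf("H%03d", i),
                                            baseline_tp, NA_integer_)
  }
  n_relapse <- round(design$relapse_frac * design$n_cancer)
  for (i in seq_len(design$n_cancer)) {
    rel <- as.integer(i <= n_relapse)
    for (tp in tps) {
      rows[[length(rows) + 1L]] <- add_sample(design$cancer_group,
                                              sprintf("P%03d", i), tp, rel)
    }
  }
  cohort <- dplyr::bind_rows(rows)

  # Per-sample expected weights, then a Dirichlet draw around them.
  sample_weights <- function(row) {
    offsets <- list()
    if (row$group != "healthy" && design$delta != 0) {
      offsets$lymphocytes <- (offsets$lymphocytes %||% 0) + design$delta
      offsets$monocytes <- (offsets$monocytes %||% 0) - design$delta
    }
    if (!is.null(design$trajectory)) {
      tr <- design$trajectory[design$trajectory$timepoint == row$timepoint, ]
      for (j in seq_len(nrow(tr))) {
        offsets[[tr$category[j]]] <- (offsets[[tr$category[j]]] %||% 0) + tr$offset[j]
      }
    }
    if (!is.na(row$relapse) && row$relapse == 1 &&
        row$timepoint != baseline_tp && design$relapse_effect != 0) {
      offsets$lymphocytes <- (offsets$lymphocytes %||% 0) + design$relapse_effect
    }
    mean_w <- shift_weights(base, ann, offsets)
    withr::with_seed(derive_seed(seed, paste0("weights:", row$sample_id)), {
      g <- rgamma(length(mean_w), shape = design$concentration * mean_w)
      if (sum(g) == 0) g <- mean_w
      setNames(g / sum(g), names(mean_w))
    })
  }

  truth <- list()
  cov_rows <- list()
  fragments <- list()
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    wts <- sample_weights(row)
    truth[[i]] <- tibble(sample_id = row$sample_id, cell_type = names(wts),
                         weight = unname(wts))
    if (output == "coverage") {
      cov <- simulate_sample_coverage(reference, wts, config,
                                      seed = derive_seed(seed, row$sample_id))
      cov_rows[[i]] <- dplyr::mutate(cov, sample_id = row$sample_id,
                                     .before = 1)
    } else {
      fragments[[row$sample_id]] <-
        simulate_fragments(reference, wts, ann_tss, config,
                           seed = seed, sample_id = row$sample_id)
    }
  }

  # Simple survival outcome: relapse patients fail early, others are
  # censored late; times in months from baseline.
  cancer_pat <- unique(cohort$patient_id[cohort$group != "healthy"])
  surv <- withr::with_seed(derive_seed(seed, "survival"), {
    rel <- cohort$relapse[match(cancer_pat, cohort$patient_id)]
    tibble(patient_id = cancer_pat,
           surv_time_months = ifelse(rel == 1, runif(length(cancer_pat), 3, 30),
                                     runif(length(cancer_pat), 24, 48)),
           surv_event = as.integer(rel == 1))
  })
  cohort <- dplyr::left_join(cohort, surv, by = "patient_id")

  structure(list(reference = reference, annotation = ann_tss, cohort = cohort,
                 truth = dplyr::bind_rows(truth),
                 coverage = if (output == "coverage") dplyr::bind_rows(cov_rows),
                 fragments = if (output == "fragments") fragments),
            class = "cf_cohort_sim")
}

#' @export
print.cf_cohort_sim <- function(x, ...) {
  cat("<cf_cohort_sim> ", nrow(x$cohort), " samples, ",
      nrow(x$reference$expr), " cell types, ",
      ncol(x$reference$expr), " genes\n", sep = "")
  print(table(x$cohort$group, x$cohort$timepoint))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
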