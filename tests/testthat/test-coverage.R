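test_that("GC bias weights are inverse bin rates with unit weighted mean", {
  # Two occupied bins with counts 100 and 300 -> weights 2 and 2/3.
  fr <- tibble::tibble(chrom = "chr1", start = 0, end = 100,
                       gc = c(rep(0.25, 100), rep(0.75, 300)),
                       sample_id = "s")
  model <- estimate_gc_bias(fr, coverage_config(gc_bins = 2))
  expect_equal(model$bins$weight, c(2, 2 / 3))
  expect_equal(sum(model$bins$count * model$bins$weight) / sum(model$bins$count), 1)

  # All fragments in one bin -> weight 1 everywhere.
  fr1 <- dplyr::mutate(fr, gc = 0.5)
  m1 <- estimate_gc_bias(fr1, coverage_config())
  expect_true(all(m1$bins$weight == 1))

  # No GC column -> identity model with a warning.
  frna <- dplyr::mutate(fr, gc = NA_real_)
  expect_warning(mna <- estimate_gc_bias(frna, coverage_config()), "no GC")
  expect_true(all(mna$bins$weight == 1))
  expect_equal(gc_weights(mna, c(0.2, NA)), c(1, 1))
})

test_that("opportunity-normalised GC weights keep the unit-mean invariant", {
  withr::with_seed(4, {
    window_gc <- runif(300, 0.3, 0.6)
    gene <- sample(300, 5000, replace = TRUE)
    fr <- tibble::tibble(chrom = "c", start = 0, end = 1,
                         gc = pmin(1, pmax(0, window_gc[gene] + rnorm(5000, 0, 0.01))),
                         sample_id = "s")
  })
  model <- estimate_gc_bias(fr, coverage_config(), window_gc = window_gc)
  wmean <- sum(model$bins$count * model$bins$weight) / sum(model$bins$count)
  expect_equal(wmean, 1, tolerance = 1e-9)
  expect_true(all(model$bins$weight > 0))
})

test_that("windowed mean coverage matches uniform-depth expectations", {
  cfgw <- coverage_config(window_bp = 5)
  ann <- tiny_annotation(c("gA", "gB"), window_bp = 5)
  # Depth exactly 2 everywhere: two identical fragments spanning each window.
  span <- function(tss) tibble::tibble(chrom = "chrT", start = tss - 10,
                                       end = tss + 10, gc = NA_real_,
                                       sample_id = "s")
  fr <- dplyr::bind_rows(span(ann$tss[1]), span(ann$tss[1]),
                         span(ann$tss[2]), span(ann$tss[2]))
  cov <- compute_tss_coverage(fr, ann, NULL, cfgw)
  expect_equal(cov$mean_cov, c(1, 1))

  # Depth 4 vs 0 -> normalized 2.0 and 0.0.
  fr4 <- dplyr::bind_rows(span(ann$tss[1]), span(ann$tss[1]),
                          span(ann$tss[1]), span(ann$tss[1]))
  cov4 <- compute_tss_coverage(fr4, ann, NULL, cfgw)
  expect_equal(cov4$mean_cov, c(2, 0))
})

test_that("windowed coverage equals a brute-force per-base pileup", {
  cfgw <- coverage_config(window_bp = 8)
  ann <- tiny_annotation(sprintf("g%d", 1:6), window_bp = 8, spacing = 60)
  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- sample(20:100, 1)
      start <- sample(0:max(ann$tss + 20), n, replace = TRUE)
      fr <- tibble::tibble(chrom = "chrT", start = start,
                           end = start + sample(5:40, n, replace = TRUE),
                           gc = runif(n), sample_id = "s")
      model <- estimate_gc_bias(fr, cfgw)
      wts <- gc_weights(model, fr$gc)
      cov <- compute_tss_coverage(fr, ann, model, cfgw)
      oracle <- vapply(ann$tss, function(tss) {
        oracle_window_mean(fr, tss, 8, wts)
      }, numeric(1))
      expect_equal(cov$mean_cov, oracle / mean(oracle), tolerance = 1e-12)
      expect_equal(mean(cov$mean_cov), 1, tolerance = 1e-9)  # normalization
    }
  })
})

test_that("transcripts aggregate to gene means", {
  tx <- tibble::tibble(transcript_id = c("t1", "t2", "t3", "t4"),
                       gene_id = c("gA", "gA", "gB", "gC"),
                       strand = "+",
                       mean_cov = c(0.8, 1.2, 0.7, NA))
  agg <- aggregate_transcripts(tx)
  expect_equal(agg$mean_cov[agg$gene_id == "gA"], 1)
  expect_equal(agg$mean_cov[agg$gene_id == "gB"], 0.7)
  expect_true(is.na(agg$mean_cov[agg$gene_id == "gC"]))

  # Mean over non-missing transcripts only.
  tx2 <- tibble::tibble(transcript_id = c("t1", "t2"), gene_id = "g",
                        strand = "+", mean_cov = c(2, NA))
  expect_equal(aggregate_transcripts(tx2)$mean_cov, 2)
})

test_that("metaprofile respects strand orientation and gene subsets", {
  cfgw <- coverage_config(window_bp = 10)
  ann <- tibble::tibble(gene_id = c("plus", "minus"),
                        transcript_id = c("p_t", "m_t"),
                        chrom = "chrT", tss = c(100, 300),
                        strand = c("+", "-"))
  # One fragment 3 bp downstream (genomic right) of each TSS.
  fr <- tibble::tibble(chrom = "chrT", start = c(103, 303), end = c(106, 306),
                       gc = NA_real_, sample_id = "s")
  prof_plus <- metaprofile(fr, ann, "plus", NULL, cfgw)
  prof_minus <- metaprofile(fr, ann, "minus", NULL, cfgw)
  expect_equal(prof_plus$mean_cov[prof_plus$offset %in% 3:5] > 0,
               rep(TRUE, 3))
  # For the minus-strand gene the same genomic offsets appear upstream.
  expect_equal(prof_minus$mean_cov[prof_minus$offset %in% -5:-3] > 0,
               rep(TRUE, 3))
  expect_true(all(prof_minus$mean_cov[prof_minus$offset %in% 3:5] == 0))

  # A single-gene set equals that gene's positional profile.
  both <- metaprofile(fr, ann, c("plus", "minus"), NULL, cfgw)
  expect_equal(both$mean_cov,
               (prof_plus$mean_cov + prof_minus$mean_cov) / 2)
  expect_error(metaprofile(fr, ann, character(0), NULL, cfgw), "empty gene set")
  expect_error(metaprofile(fr, ann, "nope", NULL, cfgw), "not in annotation")
})

test_that("expression classes separate under depletion and not without", {
  cfg <- sim_config(n_celltypes = 3, n_genes = 120, n_markers = 20,
                    noise_sd = 0.1, depletion = 0.8, seed = 23)
  ref <- simulate_reference(cfg)
  w <- setNames(c(0.5, 0.3, 0.2), rownames(ref$expr))
  cov <- simulate_sample_coverage(ref, w, cfg)
  bulk <- bulk_profile(ref, w)
  expect_warning(
    rep_d <- expression_class_report(
      dplyr::rename(cov, mean_cov = coverage), bulk, top_n = 2000),
    "reducing top_n")
  expect_true(rep_d$separated)
  expect_lt(rep_d$median_difference, 0)

  cfg0 <- sim_config(n_celltypes = 3, n_genes = 120, n_markers = 20,
                     noise_sd = 0.1, depletion = 0, seed = 23)
  cov0 <- simulate_sample_coverage(simulate_reference(cfg0), w, cfg0)
  rep_0 <- suppressWarnings(expression_class_report(
    dplyr::rename(cov0, mean_cov = coverage), bulk, top_n = 40))
  expect_false(rep_0$separated)
})

test_that("top-n ties at the boundary resolve by TPM then gene id", {
  cov <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        mean_cov = c(1, 1, 1, 1))
  bulk <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                         tpm = c(5, 3, 3, 0))
  rep1 <- suppressWarnings(expression_class_report(cov, bulk, top_n = 2))
  classes <- setNames(rep1$genes$class, rep1$genes$gene_id)
  expect_equal(unname(classes[c("a", "b", "c", "d")]),
               c("expressed", "expressed", "other", "unexpressed"))
})
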