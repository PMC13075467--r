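cfg_small <- sim_config(n_celltypes = 3, n_genes = 30, n_markers = 5,
                        noise_sd = 0, depletion = 0.5, n_fragments = 5000,
                        seed = 42)

test_that("simulated reference has disjoint marker blocks and is deterministic", {
  ref <- simulate_reference(cfg_small)
  expect_equal(dim(ref$expr), c(3, 30))
  nonzero <- apply(ref$expr > 0, 2, sum)
  expect_true(all(nonzero <= 1))              # marker blocks do not overlap
  expect_equal(sum(ref$expr > 0), 3 * 5)
  expect_true(all(!is.na(ref$annotation$category)))

  ref2 <- simulate_reference(cfg_small)
  expect_identical(ref$expr, ref2$expr)
  expect_identical(ref$gene_gc, ref2$gene_gc)

  # Distinct types are less correlated than a type with itself.
  cc <- cor(t(ref$expr))
  expect_true(all(cc[upper.tri(cc)] < 1))
  expect_true(all(diag(cc) == 1))
})

test_that("sim_config validates its bounds", {
  expect_error(sim_config(n_celltypes = 1), "n_celltypes")
  expect_error(sim_config(n_genes = 10, n_celltypes = 4, n_markers = 5))
  expect_error(sim_config(depletion = 1.2))
  expect_error(sim_config(gc_bias_amplitude = 1))
})

test_that("closed-form coverage follows the depletion model exactly when noise is off", {
  ref <- simulate_reference(cfg_small)
  w <- setNames(c(1, 0, 0), rownames(ref$expr))
  cov <- simulate_sample_coverage(ref, w, cfg_small)
  s <- cfrank:::depletion_scores(ref, w)
  expect_equal(cov$coverage, unname(1 * (1 - 0.5 * s)), tolerance = 1e-12)

  # d = 0: flat baseline coverage.
  cfg0 <- sim_config(n_celltypes = 3, n_genes = 30, n_markers = 5,
                     noise_sd = 0, depletion = 0, baseline_coverage = 2.5,
                     seed = 42)
  cov0 <- simulate_sample_coverage(simulate_reference(cfg0),
                                   c(0.2, 0.3, 0.5), cfg0)
  expect_true(all(cov0$coverage == 2.5))

  # Spearman between the source profile and coverage is exactly -1.
  expect_equal(spearman_rho(ref$expr[1, ], cov$coverage), -1)

  expect_error(simulate_sample_coverage(ref, c(0.5, 0.2, 0.2), cfg_small),
               "sum to 1")
})

test_that("fragment simulation is reproducible and respects its contracts", {
  ref <- simulate_reference(cfg_small)
  ann <- simulate_tss_annotation(cfg_small, ref)
  w <- setNames(c(1, 0, 0), rownames(ref$expr))
  fr1 <- simulate_fragments(ref, w, ann, cfg_small, sample_id = "a")
  fr2 <- simulate_fragments(ref, w, ann, cfg_small, sample_id = "a")
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_fragments(fr1, p1)
  write_fragments(fr2, p2)
  expect_identical(readLines(p1), readLines(p2))  # same seed, same bytes
  expect_true(all(fr1$end - fr1$start >= 50))
  expect_true(all(fr1$gc >= 0 & fr1$gc <= 1))

  cfg_none <- cfg_small
  cfg_none$n_fragments <- 0L
  expect_error(simulate_fragments(ref, w, ann, cfg_none), "zero fragments")
})

test_that("without depletion the empirical metaprofile is flat", {
  cfg0 <- sim_config(n_celltypes = 2, n_genes = 10, n_markers = 2,
                     noise_sd = 0, depletion = 0, n_fragments = 6e4, seed = 5)
  ref <- simulate_reference(cfg0)
  ann <- simulate_tss_annotation(cfg0, ref)
  fr <- simulate_fragments(ref, c(0.5, 0.5), ann, cfg0)
  prof <- metaprofile(fr, ann, ann$gene_id, config = coverage_config())
  centre <- mean(prof$mean_cov[abs(prof$offset) <= 100])
  flank <- mean(prof$mean_cov[abs(prof$offset) >= 900])
  expect_equal(centre / flank, 1, tolerance = 0.05)
})

test_that("deep depletion produces the expected centre/flank coverage ratio", {
  # One dominant gene with s = 1 under a one-hot mixture, d = 0.9: the
  # acceptance probability at the TSS is 0.1 (slightly smeared by fragment
  # length), at the window edge ~1.
  cfg <- sim_config(n_celltypes = 2, n_genes = 4, n_markers = 2,
                    noise_sd = 0, depletion = 0.9, n_fragments = 1e5, seed = 9)
  ref <- simulate_reference(cfg)
  ann <- simulate_tss_annotation(cfg, ref)
  w <- setNames(c(1, 0), rownames(ref$expr))
  s <- cfrank:::depletion_scores(ref, w)
  top_gene <- names(ref$gene_gc)[which.max(s)]
  fr <- simulate_fragments(ref, w, ann, cfg)
  prof <- metaprofile(fr, ann, top_gene, config = coverage_config())
  centre <- mean(prof$mean_cov[abs(prof$offset) <= 40])
  flank <- mean(prof$mean_cov[abs(prof$offset) >= 950])
  expect_equal(centre / flank, 0.115, tolerance = 0.25)
})

test_that("fragment-level and closed-form coverage agree at high depth", {
  cfg <- sim_config(n_celltypes = 2, n_genes = 10, n_markers = 3,
                    noise_sd = 0, depletion = 0.8, n_fragments = 1e5, seed = 21)
  ref <- simulate_reference(cfg)
  ann <- simulate_tss_annotation(cfg, ref)
  w <- setNames(c(0.7, 0.3), rownames(ref$expr))
  fr <- simulate_fragments(ref, w, ann, cfg)
  cov <- coverage_from_fragments(fr, ann, gc_correct = FALSE)
  expected <- expected_fragment_coverage(ref, w, cfg)
  joined <- dplyr::inner_join(cov, expected, by = "gene_id")
  expect_true(all(abs(joined$mean_cov / joined$expected_cov - 1) < 0.05))
})

test_that("cohort simulation records truth on the simplex and is reproducible", {
  cfg <- sim_config(n_celltypes = 8, n_genes = 160, n_markers = 20,
                    noise_sd = 0.1, seed = 31)
  des <- cohort_design(n_healthy = 5, n_cancer = 5, delta = 0.1)
  sim1 <- simulate_cohort(cfg, des)
  sim2 <- simulate_cohort(cfg, des)
  expect_identical(sim1$truth, sim2$truth)
  expect_identical(sim1$coverage, sim2$coverage)
  sums <- sim1$truth %>%
    dplyr::group_by(sample_id) %>%
    dplyr::summarise(s = sum(weight))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_equal(nrow(sim1$cohort), 10)

  # Shifts that would push a category weight negative are an error.
  expect_error(simulate_cohort(cfg, cohort_design(n_healthy = 2, n_cancer = 2,
                                                  delta = 0.5)),
               "negative")
})

test_that("a concentrated shifted cohort separates lymphocyte weights completely", {
  cfg <- sim_config(n_celltypes = 8, n_genes = 160, n_markers = 20, seed = 13)
  des <- cohort_design(n_healthy = 10, n_cancer = 10, delta = 0.2,
                       concentration = 500)
  sim <- simulate_cohort(cfg, des)
  lymph_type <- sim$reference$annotation$cell_type[
    sim$reference$annotation$category == "lymphocytes"]
  truth <- sim$truth %>%
    dplyr::filter(cell_type %in% lymph_type) %>%
    dplyr::group_by(sample_id) %>%
    dplyr::summarise(w = sum(weight)) %>%
    dplyr::left_join(sim$cohort, by = "sample_id")
  expect_gt(min(truth$w[truth$group != "healthy"]),
            max(truth$w[truth$group == "healthy"]))
})
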