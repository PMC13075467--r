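test_that("wilcoxon rank-sum reproduces exact enumerations", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1), c(2))$p, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact wilcoxon p equals full enumeration on random small instances", {
  withr::with_seed(43, {
    checked <- 0
    while (checked < 100) {
      na <- sample(1:5, 1)
      nb <- sample(1:5, 1)
      vals <- sample(1:50, na + nb)           # distinct -> no ties
      a <- vals[seq_len(na)]
      b <- vals[-seq_len(na)]
      expect_equal(wilcoxon_rank_sum(a, b)$p, oracle_wilcoxon_p(a, b),
                   tolerance = 1e-12)
      checked <- checked + 1
    }
  })
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::with_seed(47, {
    for (rep in 1:100) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      q <- bh_fdr(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      # Monotone in the sorted-p order.
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  })
})

test_that("group comparison computes medians, fold changes and one FDR family", {
  data <- tibble::tibble(
    feature = rep(c("f1", "f2"), each = 8),
    group = rep(rep(c("case", "ctrl"), each = 4), 2),
    value = c(150, 200, 250, 210, 90, 100, 110, 105,
              10, 12, 9, 11, 10, 12, 9, 11))
  res <- compare_groups(data, "case", "ctrl")
  expect_equal(res$log2FC[res$feature == "f1"],
               log2(205 / 102.5))
  expect_equal(res$log2FC[res$feature == "f2"], 0)
  expect_equal(res$p[res$feature == "f2"], 1)
  expect_true(all(res$q >= res$p))
  expect_equal(res$q, bh_fdr(res$p))

  # Median ratio 200 vs 100 -> log2FC exactly 1.
  d2 <- tibble::tibble(feature = "f", group = rep(c("case", "ctrl"), each = 3),
                       value = c(100, 200, 300, 50, 100, 150))
  expect_equal(compare_groups(d2, "case", "ctrl")$log2FC, 1)

  # A feature absent in one arm is skipped with a warning.
  d3 <- dplyr::bind_rows(data,
                         tibble::tibble(feature = "f3", group = "case",
                                        value = 1:3))
  expect_warning(res3 <- compare_groups(d3, "case", "ctrl"), "f3")
  expect_equal(sort(res3$feature), c("f1", "f2"))
})

test_that("volcano deduplication keeps the largest |log2FC| per cell type", {
  rows <- tibble::tibble(
    cell_type = c("tcell", "tcell", "mono", "nk", "nk"),
    tissue = c("blood", "spleen", "blood", "blood", "thymus"),
    log2FC = c(0.5, -0.8, -0.3, 0.4, 0.4),
    q = c(0.01, 0.02, 0.5, 0.2, 0.01))
  out <- volcano_dedup(rows)
  expect_equal(nrow(out), 3)
  expect_equal(out$log2FC[out$cell_type == "tcell"], -0.8)
  expect_equal(out$tissue[out$cell_type == "nk"], "thymus")  # q tie-break
  expect_equal(out$log2FC[out$cell_type == "mono"], -0.3)    # single tissue
})

test_that("longitudinal comparisons test each timepoint against baseline", {
  withr::with_seed(53, {
    base <- rnorm(20, 150, 10)
    data <- tibble::tibble(
      feature = "classic_monocytes",
      timepoint = rep(c("pre_op", "post_op", "followup"), each = 20),
      value = c(base, rnorm(20, 120, 10), base + rnorm(20, 0, 1)))
  })
  res <- longitudinal_compare(data, baseline = "pre_op")
  expect_equal(nrow(res), 2)
  expect_lt(res$p[res$timepoint == "post_op"], 0.01)
  expect_gt(res$p[res$timepoint == "followup"], 0.05)

  same <- tibble::tibble(feature = "f", timepoint = rep(c("t0", "t1"), each = 3),
                         value = rep(c(1, 2, 3), 2))
  expect_equal(longitudinal_compare(same, "t0")$p, 1)

  only_base <- same[same$timepoint == "t0", ]
  expect_warning(empty <- longitudinal_compare(only_base, "t0"), "only the baseline")
  expect_equal(nrow(empty), 0)
  expect_error(longitudinal_compare(same, "nope"), "not present")
})

test_that("rank change pairs timepoints within patients", {
  data <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p2", "p3"),
    feature = "f",
    timepoint = c("t0", "t1", "t0", "t1", "t0"),
    value = c(120, 150, 100, 100, 80))
  delta <- rank_change(data, "t0", "t1")
  expect_equal(delta$delta[delta$patient_id == "p1"], 30)
  expect_equal(delta$delta[delta$patient_id == "p2"], 0)
  expect_false("p3" %in% delta$patient_id)   # missing t1 -> excluded
  expect_error(rank_change(data[data$patient_id == "p3", ], "t0", "t1"),
               "both timepoints")
})

test_that("IQR feature selection uses type-7 quantiles and category filters", {
  delta <- tibble::tibble(
    patient_id = rep(paste0("p", 1:4), 3),
    feature = rep(c("fa", "fb", "fc"), each = 4),
    category = rep(c("monocytes", "lymphocytes", "stromal"), each = 4),
    delta = c(1, 2, 3, 4, 5, 5, 5, 5, 0, 40, -40, 10))
  sel <- iqr_select(delta, k = 2)
  # fa: Q1 = 1.75, Q3 = 3.25 -> IQR 1.5; fb constant -> 0; fc filtered out.
  expect_equal(sel$iqr$iqr[sel$iqr$feature == "fa"], 1.5)
  expect_equal(sel$selected, c("fa", "fb"))

  sel_all <- iqr_select(delta, k = 2, categories = NULL)
  expect_equal(sel_all$selected[1], "fc")

  expect_warning(sel_red <- iqr_select(delta, k = 10), "reducing k")
  expect_equal(length(sel_red$selected), 2)

  # A constant feature is never selected over any varying one.
  expect_equal(iqr_select(delta, k = 1)$selected, "fa")
})

test_that("covariate correlation gives exact rho and calibrated null p", {
  d <- tibble::tibble(value = c(10, 20, 30, 40), covariate = c(10, 20, 30, 40))
  expect_equal(covariate_correlation(d)$rho, 1)
  d2 <- tibble::tibble(value = 1:5, covariate = 5:1)
  expect_equal(covariate_correlation(d2)$rho, -1)
  expect_error(covariate_correlation(d[1:2, ]), "at least 3")

  withr::with_seed(59, {
    ps <- replicate(200, {
      covariate_correlation(tibble::tibble(value = rnorm(20),
                                           covariate = rnorm(20)))$p
    })
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
  expect_gt(mean(ps), 0.35)   # roughly uniform under the null
})
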