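#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_case > score_control) + 0.5 * P(tie)` over all case-control
#' pairs, computed via average ranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as_binary(labels)
  stopifnot(length(scores) == length(labels))
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  if (m == 0 || n == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

#' DeLong confidence interval for the AUC
#'
#' Wald interval from the DeLong placement-value variance estimate, clipped
#' to `[0, 1]`. Degenerate cases (zero variance, AUC exactly 0 or 1) are
#' clipped with a warning.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1 = case); at least 2 per class.
#' @param level Confidence level.
#' @return A tibble `(auc, ci_low, ci_high, se)`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  labels <- as_binary(labels)
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  if (length(cases) < 2 || length(controls) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  psi <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  a <- mean(psi)
  v10 <- rowMeans(psi)   # placement of each case among controls
  v01 <- colMeans(psi)   # placement of each control among cases
  s2 <- stats::var(v10) / length(cases) + stats::var(v01) / length(controls)
  se <- sqrt(s2)
  if (se == 0 || a %in% c(0, 1)) {
    cf_log("degenerate AUC variance; interval clipped", level = "WARN")
  }
  zq <- qnorm(1 - (1 - level) / 2)
  tibble(auc = a,
         ci_low = max(0, a - zq * se),
         ci_high = min(1, a + zq * se),
         se = se)
}

#' LASSO-logistic classification with leave-one-out cross-validation
#'
#' For every penalty in the grid, each sample is held out in turn; the
#' training fold is standardised on its own statistics (no leakage), a
#' LASSO-logistic model is fitted along the penalty path with warm starts,
#' and the held-out probability recorded. The penalty maximising the
#' out-of-fold AUC is chosen (ties resolved towards the larger, sparser
#' penalty); the reported AUC is that penalty's LOOCV AUC and the final
#' coefficients come from a full-data refit at the chosen penalty.
#'
#' @param X Numeric matrix, samples by features.
#' @param y Binary labels; at least 3 per class and 6 total.
#' @param lambda_grid Increasing penalty grid (default
#'   [lasso_lambda_grid()]).
#' @param standardize Standardise within each training fold.
#' @return An object of class `cf_classifier` with out-of-fold
#'   probabilities, the chosen penalty, AUC with DeLong CI, the per-lambda
#'   AUC profile and the full-data fit.
#' @export
loocv_predict <- function(X, y, lambda_grid = lasso_lambda_grid(),
                          standardize = TRUE) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  y <- as_binary(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 6 || min(table(y)) < 3) {
    stop("need at least 6 samples with >= 3 per class", call. = FALSE)
  }
  stopifnot(all(diff(lambda_grid) > 0))
  lam_desc <- rev(lambda_grid)
  oof <- matrix(NA_real_, n, length(lambda_grid))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    if (standardize) {
      std <- standardize_columns(Xtr)
    } else {
      std <- list(Xs = Xtr, center = rep(0, ncol(X)), scale = rep(1, ncol(X)),
                  keep = rep(TRUE, ncol(X)))
    }
    path <- cd_logistic_path(std$Xs, ytr, lam_desc)
    xi <- (X[i, std$keep] - std$center[std$keep]) / std$scale[std$keep]
    eta <- path$b0s + drop(xi %*% path$betas)
    oof[i, ] <- rev(plogis(eta))   # back to ascending grid order
  }
  auc_by_lambda <- apply(oof, 2, auc, labels = y)
  best <- max(auc_by_lambda)
  chosen_idx <- max(which(auc_by_lambda == best))   # ties -> larger lambda
  lambda <- lambda_grid[chosen_idx]
  fit <- fit_lasso_logistic(X, y, lambda, standardize = standardize)
  ci <- auc_ci(oof[, chosen_idx], y)
  cf_log("LOOCV: chose lambda = %.4g with AUC = %.3f", lambda, best)
  structure(list(oof = tibble(sample = rownames(X) %||% as.character(seq_len(n)),
                              y = y, prob = oof[, chosen_idx]),
                 lambda = lambda, auc = best,
                 ci_low = ci$ci_low, ci_high = ci$ci_high,
                 auc_by_lambda = tibble(lambda = lambda_grid,
                                        auc = auc_by_lambda),
                 fit = fit, n = n),
            class = "cf_classifier")
}

#' @export
print.cf_classifier <- function(x, ...) {
  cat("<cf_classifier> LOOCV AUC = ", round(x$auc, 3),
      " (95% CI ", round(x$ci_low, 3), "-", round(x$ci_high, 3),
      "), lambda = ", signif(x$lambda, 4), "\n", sep = "")
  nz <- sum(x$fit$coefficients != 0)
  cat(nz, " nonzero coefficient(s) of ", length(x$fit$coefficients),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cf_classifier <- function(x, ...) {
  tidy(x$fit) %>% dplyr::filter(.data$estimate != 0 | .data$term == "(Intercept)")
}

#' @export
glance.cf_classifier <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         lambda = x$lambda, n = x$n,
         n_features = length(x$fit$coefficients),
         n_nonzero = sum(x$fit$coefficients != 0))
}

#' Detection call at a fixed specificity
#'
#' Sets the score threshold to the smallest control score `t` such that the
#' fraction of controls at or above `t` does not exceed `1 - spec`; a sample
#' is called detected when its score is at least `t`.
#'
#' @param case_scores,control_scores Numeric score vectors.
#' @param spec Target specificity in `(0, 1]`.
#' @return A list of class `cf_detection`: `threshold`, achieved
#'   `specificity`, per-case `detected` flags and the detection `rate`.
#' @export
detection_call <- function(case_scores, control_scores, spec = 0.95) {
  if (!length(control_scores)) stop("no control scores", call. = FALSE)
  stopifnot(is_fraction(spec))
  if (length(control_scores) < 20) {
    cf_log("fewer than 20 controls; specificity threshold is unstable",
           level = "WARN")
  }
  cand <- sort(unique(control_scores))
  frac_ge <- vapply(cand, function(t) mean(control_scores >= t), numeric(1))
  ok <- frac_ge <= 1 - spec
  threshold <- if (any(ok)) {
    cand[which(ok)[1]]
  } else {
    mx <- max(control_scores)
    mx + pmax(abs(mx) * 1e-12, 1e-12)   # just above the maximum control
  }
  detected <- case_scores >= threshold
  structure(list(threshold = threshold,
                 specificity = mean(control_scores < threshold),
                 detected = detected,
                 rate = mean(detected)),
            class = "cf_detection")
}

#' @export
print.cf_detection <- function(x, ...) {
  cat("<cf_detection> threshold = ", signif(x$threshold, 4),
      ", specificity = ", round(x$specificity, 3),
      ", detection rate = ", round(x$rate, 3), "\n", sep = "")
  invisible(x)
}

#' Relapse classification from longitudinal rank changes
#'
#' Composes the relapse-prediction pipeline: per-patient rank change
#' between a baseline and an on-treatment timepoint, selection of the `k`
#' immune cell types with the highest rank-change IQR, and LASSO-logistic
#' LOOCV classification of relapse labels on those features.
#'
#' @param ranks Long rank tibble `(sample_id, cell_type, category, rank)`.
#' @param cohort Cohort tibble `(sample_id, patient_id, timepoint,
#'   relapse)`.
#' @param t0,t1 Baseline and on-treatment timepoint labels.
#' @param k Number of features to select.
#' @param lambda_grid Penalty grid for [loocv_predict()].
#' @return A `cf_classifier` with the selection attached as
#'   `$feature_selection`.
#' @export
relapse_pipeline <- function(ranks, cohort, t0, t1, k = 10,
                             lambda_grid = lasso_lambda_grid()) {
  check_columns(ranks, c("sample_id", "cell_type", "rank"), "ranks")
  check_columns(cohort, c("sample_id", "patient_id", "timepoint", "relapse"),
                "cohort")
  data <- ranks %>%
    dplyr::inner_join(cohort, by = "sample_id") %>%
    dplyr::filter(!is.na(.data$relapse)) %>%
    dplyr::rename(feature = "cell_type", value = "rank")
  delta <- rank_change(data, t0, t1)
  sel <- iqr_select(delta, k = k)
  wide <- delta %>%
    dplyr::filter(.data$feature %in% sel$selected) %>%
    dplyr::select(dplyr::all_of(c("patient_id", "feature", "delta"))) %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "delta")
  Xmat <- as.matrix(wide[, sel$selected, drop = FALSE])
  rownames(Xmat) <- wide$patient_id
  ylab <- cohort$relapse[match(wide$patient_id, cohort$patient_id)]
  res <- loocv_predict(Xmat, ylab, lambda_grid = lambda_grid)
  res$feature_selection <- sel
  res
}
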