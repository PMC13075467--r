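#' The default LASSO tuning grid
#'
#' 100 log-spaced penalty values from 1e-4 to 1e1 (inclusive), strictly
#' increasing.
#'
#' @return Numeric vector of length 100.
#' @export
lasso_lambda_grid <- function() {
  10^seq(-4, 1, length.out = 100)
}

soft_threshold <- function(z, g) {
  sign(z) * pmax(abs(z) - g, 0)
}

# Internal: coerce labels to 0/1.
as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1)", call. = FALSE)
  as.numeric(y)
}

# Internal: column standardization with population (1/n) variance, the
# scaling under which the lambda >= lambda_max identity is exact.
standardize_columns <- function(X) {
  center <- colMeans(X)
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))
  zero <- scale <= .Machine$double.eps
  if (any(zero)) {
    cf_log("%d constant feature column(s) dropped from the fit", sum(zero),
           level = "WARN")
  }
  Xs <- sweep(X[, !zero, drop = FALSE], 2, center[!zero])
  Xs <- sweep(Xs, 2, scale[!zero], "/")
  list(Xs = Xs, center = center, scale = scale, keep = !zero)
}

# Internal: penalized IRLS with cyclic coordinate descent on standardized
# predictors. Objective: mean negative log-likelihood + lambda * sum(|beta|)
# with an unpenalized intercept. Convergence: max coefficient change < tol.
cd_logistic <- function(Xs, y, lambda, beta = NULL, b0 = NULL,
                        tol = 1e-7, maxit = 100L) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  ybar <- mean(y)
  if (is.null(beta)) beta <- numeric(p)
  if (is.null(b0)) b0 <- qlogis(min(max(ybar, 1e-5), 1 - 1e-5))
  for (iter in seq_len(maxit)) {
    beta_old <- beta
    b0_old <- b0
    eta <- drop(b0 + Xs %*% beta)
    prob <- pmin(pmax(plogis(eta), 1e-5), 1 - 1e-5)
    wq <- prob * (1 - prob)
    z <- eta + (y - prob) / wq
    # Weighted penalized least squares on the working response.
    r <- z - eta
    for (sweep_i in seq_len(1000L)) {
      delta_max <- 0
      for (j in seq_len(p)) {
        xj <- Xs[, j]
        num <- sum(wq * xj * r) / n + sum(wq * xj^2) / n * beta[j]
        den <- sum(wq * xj^2) / n
        bj_new <- soft_threshold(num, lambda) / den
        if (bj_new != beta[j]) {
          r <- r - xj * (bj_new - beta[j])
          delta_max <- max(delta_max, abs(bj_new - beta[j]))
          beta[j] <- bj_new
        }
      }
      b0_new <- b0 + sum(wq * r) / sum(wq)
      r <- r - (b0_new - b0)
      delta_max <- max(delta_max, abs(b0_new - b0))
      b0 <- b0_new
      if (delta_max < tol) break
    }
    if (max(abs(beta - beta_old), abs(b0 - b0_old)) < tol) break
  }
  list(beta = beta, b0 = b0, iter = iter)
}

#' Fit a LASSO-regularised logistic regression at one penalty
#'
#' Minimises the mean negative log-likelihood plus `lambda * sum(|beta|)`
#' (intercept unpenalised) by penalised IRLS with cyclic coordinate
#' descent; predictors are standardised to mean 0 / variance 1 internally
#' and coefficients returned on the original scale. At
#' `lambda >= max_j |x_j' (y - ybar)| / n` (standardised columns) the
#' solution is exactly the null model with intercept `logit(ybar)`.
#'
#' @param X Numeric matrix, samples by features (column names required).
#' @param y Binary labels (0/1, logical, or a two-level factor whose second
#'   level is the positive class).
#' @param lambda Positive penalty.
#' @param standardize Standardise columns before fitting (default `TRUE`).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @return An object of class `cf_lasso` with elements `coefficients`
#'   (original scale), `intercept`, `beta_std`, `lambda` and the
#'   standardisation parameters.
#' @export
fit_lasso_logistic <- function(X, y, lambda, standardize = TRUE, tol = 1e-7) {
  stopifnot(is.matrix(X), !is.null(colnames(X)), lambda > 0)
  y <- as_binary(y)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2) stop("labels are constant", call. = FALSE)
  if (any(!is.finite(X))) stop("features must be finite", call. = FALSE)
  if (standardize) {
    std <- standardize_columns(X)
  } else {
    std <- list(Xs = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)),
                keep = rep(TRUE, ncol(X)))
  }
  fit <- cd_logistic(std$Xs, y, lambda, tol = tol)
  beta <- setNames(numeric(ncol(X)), colnames(X))
  beta[std$keep] <- fit$beta / std$scale[std$keep]
  intercept <- fit$b0 - sum(fit$beta * std$center[std$keep] / std$scale[std$keep])
  structure(list(coefficients = beta, intercept = intercept,
                 beta_std = fit$beta, b0_std = fit$b0,
                 lambda = lambda, standardize = standardize,
                 center = std$center, scale = std$scale, keep = std$keep,
                 Xs = std$Xs, y = y),
            class = "cf_lasso")
}

#' @export
predict.cf_lasso <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(newdata))
  newdata <- newdata[, names(object$coefficients), drop = FALSE]
  eta <- drop(object$intercept + newdata %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

#' @export
print.cf_lasso <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("<cf_lasso> lambda = ", signif(x$lambda, 4), ", ", nz, "/",
      length(x$coefficients), " nonzero coefficients\n", sep = "")
  invisible(x)
}

#' @export
tidy.cf_lasso <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' Check Karush-Kuhn-Tucker conditions of a LASSO solution
#'
#' At the optimum, the gradient of the mean negative log-likelihood on the
#' standardised scale must satisfy `|g_j| <= lambda` for zero coefficients
#' and `g_j = -lambda * sign(beta_j)` for nonzero ones.
#'
#' @param fit A [fit_lasso_logistic()] object.
#' @param tol Slack allowed on the conditions.
#' @return A tibble `(term, beta, gradient, ok)`.
#' @export
lasso_kkt <- function(fit, tol = 1e-6) {
  stopifnot(inherits(fit, "cf_lasso"))
  eta <- drop(fit$b0_std + fit$Xs %*% fit$beta_std)
  prob <- plogis(eta)
  g <- -drop(crossprod(fit$Xs, fit$y - prob)) / nrow(fit$Xs)
  ok <- ifelse(fit$beta_std == 0,
               abs(g) <= fit$lambda + tol,
               abs(g + fit$lambda * sign(fit$beta_std)) <= tol)
  tibble(term = colnames(fit$Xs) %||% paste0("x", seq_along(g)),
         beta = fit$beta_std, gradient = g, ok = ok)
}

# Internal: standardized-scale path fit with warm starts, lambdas given in
# decreasing order. Returns coefficient matrix (p x nlambda) and intercepts.
cd_logistic_path <- function(Xs, y, lambdas, tol = 1e-7) {
  p <- ncol(Xs)
  betas <- matrix(0, p, length(lambdas))
  b0s <- numeric(length(lambdas))
  beta <- numeric(p)
  b0 <- NULL
  for (i in seq_along(lambdas)) {
    fit <- cd_logistic(Xs, y, lambdas[i], beta = beta, b0 = b0, tol = tol)
    beta <- fit$beta
    b0 <- fit$b0
    betas[, i] <- beta
    b0s[i] <- b0
  }
  list(betas = betas, b0s = b0s)
}
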