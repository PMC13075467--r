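#' Median-probability risk stratification
#'
#' Splits samples into `"high"` and `"low"` groups at the median predicted
#' probability; scores exactly at the median go to `"low"`, so the split is
#' deterministic.
#'
#' @param probabilities Numeric vector of predicted probabilities.
#' @return Character vector of `"high"` / `"low"` labels.
#' @export
stratify_median <- function(probabilities) {
  stopifnot(is.numeric(probabilities), length(probabilities) >= 2)
  ifelse(probabilities > median(probabilities), "high", "low")
}

#' Kaplan-Meier curves and log-rank test for recurrence-free survival
#'
#' Administratively censors follow-up at `censor_months` (events after the
#' horizon become censorings at the horizon), estimates the product-limit
#' survival curve per group and, with two or more groups and at least one
#' event, a log-rank chi-square test.
#'
#' @param time Follow-up times in months (non-negative).
#' @param event Event indicator (1 = relapse/event, 0 = censored).
#' @param group Group labels (e.g. from [stratify_median()]).
#' @param censor_months Administrative censoring horizon (default 36, i.e.
#'   3 years).
#' @return A list of class `cf_km`: `curves` tibble `(group, time,
#'   n_risk, n_event, survival)`, `chisq`, `df`, `p`, and per-group sizes.
#' @export
km_logrank <- function(time, event, group = NULL, censor_months = 36) {
  stopifnot(is.numeric(time), all(time >= 0, na.rm = TRUE))
  event <- as_binary(event)
  if (is.null(group)) group <- rep("all", length(time))
  stopifnot(length(event) == length(time), length(group) == length(time))
  ok <- !is.na(time) & !is.na(event) & !is.na(group)
  if (sum(ok) < length(time)) {
    cf_log("%d sample(s) with missing survival data dropped", sum(!ok))
  }
  time <- time[ok]; event <- event[ok]; group <- as.character(group[ok])
  over <- time > censor_months
  event[over] <- 0
  time[over] <- censor_months
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- if (is.null(fit$strata)) {
    rep(unique(group), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, survival = fit$surv)
  n_groups <- dplyr::n_distinct(group)
  if (n_groups < 2) {
    chisq <- NA_real_; df <- NA_integer_; p <- NA_real_
  } else if (sum(event) == 0) {
    cf_log("no events observed; log-rank p undefined", level = "WARN")
    chisq <- NA_real_; df <- n_groups - 1L; p <- NA_real_
  } else {
    lr <- survival::survdiff(survival::Surv(time, event) ~ group)
    chisq <- lr$chisq
    df <- n_groups - 1L
    p <- pchisq(chisq, df = df, lower.tail = FALSE)
  }
  structure(list(curves = curves, chisq = chisq, df = df, p = p,
                 n = table(group), censor_months = censor_months),
            class = "cf_km")
}

#' @export
print.cf_km <- function(x, ...) {
  cat("<cf_km> groups: ",
      paste(names(x$n), as.integer(x$n), sep = "=", collapse = ", "),
      "; follow-up censored at ", x$censor_months, " months\n", sep = "")
  if (!is.na(x$p)) {
    cat("log-rank chi-square = ", round(x$chisq, 3), " (", x$df,
        " df), p = ", format.pval(x$p), "\n", sep = "")
  } else {
    cat("log-rank test not available\n")
  }
  invisible(x)
}

#' @export
tidy.cf_km <- function(x, ...) {
  x$curves
}

#' @export
glance.cf_km <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, p = x$p,
         n = sum(x$n), n_groups = length(x$n))
}
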