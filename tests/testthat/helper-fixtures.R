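# Shared fixtures built in code at test time.

# Write a BED file from lines and return its path.
write_bed <- function(lines, path = withr::local_tempfile(fileext = ".bed",
                                                          .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# A tiny deterministic reference: K cell types, each with `m` marker genes
# carrying distinct expression values, zero elsewhere.
tiny_reference <- function(K = 3, G = 12, m = 3) {
  genes <- sprintf("g%02d", seq_len(G))
  types <- paste0("t", seq_len(K))
  expr <- matrix(0, K, G, dimnames = list(types, genes))
  for (k in seq_len(K)) {
    expr[k, ((k - 1) * m + 1):(k * m)] <- seq_len(m) + k / 10
  }
  new_reference(expr)
}

# Minimal TSS annotation: one transcript per gene, plus strand, spaced far
# apart on one synthetic chromosome.
tiny_annotation <- function(genes, window_bp = 10, spacing = 100) {
  tibble::tibble(gene_id = genes,
                 transcript_id = paste0(genes, "_t1"),
                 chrom = "chrT",
                 tss = 5 * window_bp + spacing * (seq_along(genes) - 1),
                 strand = "+")
}

# Brute-force per-base pileup oracle: weighted depth of every window
# position, averaged over the full window, for one transcript.
oracle_window_mean <- function(fragments, tss, window_bp, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(fragments))
  positions <- (tss - window_bp):(tss + window_bp)  # 0-based positions
  depth <- vapply(positions, function(p) {
    covering <- fragments$start <= p & fragments$end > p
    sum(weights[covering])
  }, numeric(1))
  mean(depth)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * (n - na) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force BH step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force AUC by pairwise counting.
oracle_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (ca in cases) for (co in controls) {
    total <- total + (ca > co) + 0.5 * (ca == co)
  }
  total / (length(cases) * length(controls))
}

# Hand product-limit estimator at the event times of one group.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    d <- sum(time == times[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  tibble::tibble(time = times, survival = surv)
}
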