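# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive enumeration / textbook formulas, never the
# code paths they validate.

# Benjamini-Hochberg step-up, enumerated directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# Welch t, df and two-sided p from the textbook formulas, scalar arithmetic.
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pairwise-concordance AUC by explicit double loop (ties weight 0.5).
auc_oracle <- function(ld, li) {
  tot <- 0
  for (a in li) for (b in ld)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ld) * length(li))
}

# Weighted KS running sum enumerated step by step.
es_oracle <- function(ranked, set, exponent = 1) {
  hit <- ranked$gene %in% set
  nr <- sum(abs(ranked$metric[hit])^exponent)
  nmiss <- sum(!hit)
  run <- 0; best <- 0; best_i <- 0
  for (i in seq_len(nrow(ranked))) {
    run <- run + if (hit[i]) abs(ranked$metric[i])^exponent / nr else
      -1 / nmiss
    if (abs(run) > abs(best)) { best <- run; best_i <- i }
  }
  list(es = best, peak_index = best_i)
}

# Exhaustive cutpoint search for the sensitivity+specificity maximum, using
# the same candidate grid definition (midpoints plus infinite sentinels).
threshold_sum_oracle <- function(ld, li) {
  s <- sort(unique(c(ld, li)))
  cand <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  max(vapply(cand, function(t) mean(ld < t) + mean(li >= t), numeric(1)))
}

# Pearson r straight from the covariance formula.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# Tiny deterministic log-space expression matrix for unit tests.
tiny_norm <- function(values, genes, samples, space = "log_cpm") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  expr_matrix(m, space)
}
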