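# Shared statistical internals.

# Vectorised Welch two-sample t over the rows of a matrix.
# grp: logical vector over columns, TRUE = group 1 (LI), FALSE = group 2 (LD).
# Returns mean_diff (group1 - group2), t, Welch-Satterthwaite df, two-sided p.
# Rows with zero variance in both groups: se = 0; if the means are equal t is
# set to 0 and p to 1 (flagged); an exact mean difference with zero variance
# yields t = +/-Inf, p = 0.
welch_rows <- function(X, grp) {
  n1 <- sum(grp); n2 <- sum(!grp)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples (got ", n1, " and ", n2, ")",
         call. = FALSE)
  X1 <- X[, grp, drop = FALSE]; X2 <- X[, !grp, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  diff <- m1 - m2
  t <- diff / sqrt(se2)
  zero <- se2 == 0
  flagged <- zero & diff == 0
  t[flagged] <- 0
  df[zero] <- NA_real_
  p <- ifelse(zero, ifelse(diff == 0, 1, 0), 2 * pt(-abs(t), df))
  data.frame(mean_diff = diff, t_stat = t, df = df, p = p,
             zero_variance = zero, row.names = rownames(X))
}

#' @importFrom stats pt
NULL

# Per-row z-scores with the sample (n-1) standard deviation.
zscore_rows <- function(X) {
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  list(z = (X - mu) / sdv, sd = sdv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
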