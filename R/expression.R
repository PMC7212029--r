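# Expression analysis: log-CPM normalisation, z-score outlier calling,
# Welch differential expression with Benjamini-Hochberg control, and
# signature scoring.

#' Normalise counts to log2 counts-per-million
#'
#' `log2(1 + 1e6 * count / library_size)` per cell, with the library size
#' being the column sum. Exact zeros map to exact zeros, and the transform
#' is monotone in the source counts per sample.
#'
#' @param mat an [expr_matrix()] with `space = "counts"`.
#' @param prior_count pseudo-count added before the log (default 1).
#' @return an [expr_matrix()] with `space = "log_cpm"` and per-sample
#'   library sizes retained in `lib_sizes`.
#' @export
log_cpm <- function(mat, prior_count = 1) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$space != "counts")
    stop("log_cpm expects a counts matrix (got space=", mat$space, ")",
         call. = FALSE)
  lib <- colSums(mat$values)
  zero <- names(lib)[lib == 0]
  if (length(zero))
    stop("zero library size for sample ", zero[1], call. = FALSE)
  v <- log2(prior_count + sweep(mat$values, 2, lib / 1e6, "/"))
  expr_matrix(v, "log_cpm", lib_sizes = lib)
}

#' Call expression outliers by cohort-relative z-score
#'
#' z-scores are computed per gene across all samples of the matrix with the
#' sample (n-1) standard deviation; `is_outlier` is inclusive at the
#' threshold (z >= threshold).
#'
#' @param norm an [expr_matrix()] in a log space.
#' @param genes genes to score.
#' @param threshold z-score cut-off (default 2).
#' @return data.frame with columns gene, sample_id, z, is_outlier.
#' @export
zscore_outliers <- function(norm, genes, threshold = 2) {
  stopifnot(inherits(norm, "expr_matrix"))
  if (ncol(norm$values) < 3L)
    stop("zscore_outliers needs >= 3 samples", call. = FALSE)
  miss <- setdiff(genes, rownames(norm$values))
  if (length(miss))
    stop("gene absent from matrix: ", miss[1], call. = FALSE)
  X <- norm$values[genes, , drop = FALSE]
  zs <- zscore_rows(X)
  if (any(zs$sd == 0))
    stop("zero variance for gene ", genes[which(zs$sd == 0)[1]],
         call. = FALSE)
  data.frame(gene = rep(genes, ncol(X)),
             sample_id = rep(colnames(X), each = length(genes)),
             z = as.vector(zs$z),
             is_outlier = as.vector(zs$z >= threshold))
}

label_groups <- function(values, labels) {
  labels <- labels[!is.na(labels)]
  bad <- setdiff(unique(labels), c("LD", "LI"))
  if (length(bad))
    stop("labels must be LD or LI (got '", bad[1], "'); exclude EX samples",
         call. = FALSE)
  shared <- intersect(colnames(values), names(labels))
  list(values = values[, shared, drop = FALSE],
       is_li = labels[shared] == "LI")
}

#' Differential expression between LD and LI samples
#'
#' Per-gene Welch two-sample t-test on log-CPM with Welch-Satterthwaite
#' degrees of freedom, two-sided p-values, and Benjamini-Hochberg q-values
#' over all tested genes. `mean_diff` is mean(LI) - mean(LD), so positive
#' values are LI-upregulated. Genes with zero variance in both groups and
#' equal means are flagged and reported with t = 0, p = 1.
#'
#' @param norm an [expr_matrix()] in a log space.
#' @param labels named character vector `sample_id -> "LD"/"LI"`.
#' @return data.frame with columns gene, mean_diff, t_stat, df, p, q,
#'   zero_variance.
#' @export
differential_expression <- function(norm, labels) {
  stopifnot(inherits(norm, "expr_matrix"))
  g <- label_groups(norm$values, labels)
  w <- welch_rows(g$values, g$is_li)
  data.frame(gene = rownames(g$values), mean_diff = w$mean_diff,
             t_stat = w$t_stat, df = w$df, p = w$p,
             q = p.adjust(w$p, method = "BH"),
             zero_variance = w$zero_variance, row.names = NULL)
}

#' Score samples against a gene signature
#'
#' The score is the mean, over signature genes present in the matrix, of the
#' gene-wise z-score of log-CPM; scores therefore have mean zero over the
#' cohort. Genes absent from the matrix are reported in the `dropped`
#' attribute.
#'
#' @param norm an [expr_matrix()] in a log space.
#' @param genes character vector of signature genes.
#' @param name signature name recorded on the output.
#' @return data.frame with columns sample_id, signature, score; attribute
#'   `dropped` lists absent genes.
#' @export
signature_score <- function(norm, genes, name = "signature") {
  stopifnot(inherits(norm, "expr_matrix"))
  present <- intersect(genes, rownames(norm$values))
  dropped <- setdiff(genes, present)
  if (!length(present))
    stop("no signature gene present in the matrix", call. = FALSE)
  X <- norm$values[present, , drop = FALSE]
  zs <- zscore_rows(X)
  if (any(zs$sd == 0))
    stop("zero variance for signature gene ",
         present[which(zs$sd == 0)[1]], call. = FALSE)
  out <- data.frame(sample_id = colnames(X), signature = name,
                    score = colMeans(zs$z), row.names = NULL)
  attr(out, "dropped") <- dropped
  out
}
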