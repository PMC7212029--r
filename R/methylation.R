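# Gene-level methylation summaries, differential methylation, CIMP-stratified
# comparisons, and methylation-expression correlation.

#' Mean beta value per gene and sample
#'
#' Unweighted mean over the probes mapped to each requested gene.
#'
#' @param meth a [meth_matrix()].
#' @param genes genes to summarise; default every gene in the probe map.
#' @return data.frame with columns gene, sample_id, mean_beta.
#' @export
mean_beta_per_gene <- function(meth, genes = unique(meth$probe_map$gene)) {
  stopifnot(inherits(meth, "meth_matrix"))
  out <- lapply(genes, function(g) {
    pr <- meth$probe_map$probe[meth$probe_map$gene == g]
    if (!length(pr))
      stop("no probes mapped to gene ", g, call. = FALSE)
    data.frame(gene = g, sample_id = colnames(meth$beta),
               mean_beta = colMeans(meth$beta[pr, , drop = FALSE]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Differentially methylated probes between LD and LI samples
#'
#' Per-probe Welch t-test on beta values with BH q-values over all tested
#' probes. `mean_diff` is mean(LD) - mean(LI): direction `hyper` means
#' hypermethylated in LD tumours, matching the expected LD hypermethylation
#' of Wnt negative regulators.
#'
#' @param meth a [meth_matrix()].
#' @param labels named character vector `sample_id -> "LD"/"LI"`.
#' @return data.frame with columns probe, gene, mean_diff, t_stat, df, p, q,
#'   direction, zero_variance.
#' @export
dmp_test <- function(meth, labels) {
  stopifnot(inherits(meth, "meth_matrix"))
  g <- label_groups(meth$beta, labels)
  w <- welch_rows(g$values, !g$is_li)   # group 1 = LD
  gene <- meth$probe_map$gene[match(rownames(g$values),
                                    meth$probe_map$probe)]
  data.frame(probe = rownames(g$values), gene = gene,
             mean_diff = w$mean_diff, t_stat = w$t_stat, df = w$df,
             p = w$p, q = p.adjust(w$p, method = "BH"),
             direction = ifelse(w$mean_diff > 0, "hyper", "hypo"),
             zero_variance = w$zero_variance, row.names = NULL)
}

#' CIMP-stratified methylation comparison
#'
#' For each gene and tumour class (LD, LI) separately, compares mean beta
#' between CIMP-positive and CIMP-negative samples with a two-sided Welch
#' test. Strata with fewer than 2 samples on either side are reported with
#' `testable = FALSE` rather than dropped. A gene whose methylation tracks
#' expression (not CIMP) should show no effect here; CIMP-driven bimodal
#' genes should.
#'
#' @param summary data.frame from [mean_beta_per_gene()].
#' @param labels named character vector `sample_id -> "LD"/"LI"`.
#' @param cimp_flags named logical vector `sample_id -> CIMP positive?`.
#' @return data.frame with columns gene, class, n_cimp_pos, n_cimp_neg,
#'   mean_cimp_pos, mean_cimp_neg, p, testable.
#' @export
cimp_stratified_comparison <- function(summary, labels, cimp_flags) {
  out <- list()
  for (g in unique(summary$gene)) {
    for (cl in c("LD", "LI")) {
      d <- summary[summary$gene == g, , drop = FALSE]
      d <- d[!is.na(labels[d$sample_id]) & labels[d$sample_id] == cl, ,
             drop = FALSE]
      cp <- cimp_flags[d$sample_id]
      xpos <- d$mean_beta[!is.na(cp) & cp]
      xneg <- d$mean_beta[!is.na(cp) & !cp]
      row <- data.frame(gene = g, class = cl,
                        n_cimp_pos = length(xpos), n_cimp_neg = length(xneg),
                        mean_cimp_pos = if (length(xpos)) mean(xpos)
                                        else NA_real_,
                        mean_cimp_neg = if (length(xneg)) mean(xneg)
                                        else NA_real_,
                        p = NA_real_, testable = FALSE)
      if (length(xpos) >= 2L && length(xneg) >= 2L &&
          (sd(xpos) > 0 || sd(xneg) > 0)) {
        row$p <- stats::t.test(xpos, xneg)$p.value
        row$testable <- TRUE
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Correlation between gene methylation and expression
#'
#' Pearson correlation between per-sample mean beta and log-CPM of the same
#' gene over the samples shared by both inputs, with the two-sided p-value
#' from the t transform of r on n - 2 degrees of freedom.
#'
#' @param summary data.frame from [mean_beta_per_gene()].
#' @param norm an [expr_matrix()] in a log space.
#' @return data.frame with columns gene, r, p, n.
#' @export
meth_expr_correlation <- function(summary, norm) {
  stopifnot(inherits(norm, "expr_matrix"))
  out <- lapply(intersect(unique(summary$gene), rownames(norm$values)),
                function(g) {
    d <- summary[summary$gene == g, , drop = FALSE]
    shared <- intersect(d$sample_id, colnames(norm$values))
    if (length(shared) < 3L)
      stop("fewer than 3 shared samples for gene ", g, call. = FALSE)
    b <- d$mean_beta[match(shared, d$sample_id)]
    e <- norm$values[g, shared]
    if (sd(b) == 0 || sd(e) == 0)
      stop("undefined correlation for gene ", g,
           ": zero variance", call. = FALSE)
    ct <- stats::cor.test(b, e, method = "pearson")
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
               n = length(shared))
  })
  do.call(rbind, out)
}
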