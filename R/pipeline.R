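# End-to-end pipeline: simulate -> ground truth -> expression -> GSEA ->
# methylation -> biomarker, with a machine-readable JSON report.

#' Placeholder Wnt target gene-set collection
#'
#' The four curated Wnt target subsets used in enrichment analysis (global
#' responsive, stem cell, proliferative, negative regulator) are
#' study-specific; this collection ships desk-scale placeholders over the
#' simulated gene panel so the enrichment stage runs end to end. The
#' negative-regulator set is the real five-gene NR panel; the CAF signature
#' matches the simulated stromal genes. Users supply their own curated GMT
#' for real data.
#'
#' @param config a [simulation_config()] (defines the panel).
#' @return a [gene_set_collection()].
#' @export
default_gene_sets <- function(config = simulation_config()) {
  nr <- names(config$class_effects)
  bg <- sprintf("BG%03d", seq_len(config$n_background))
  sets <- list(
    wnt_negative_regulators = nr,
    wnt_global_responsive = c(nr, bg[1:10]),
    wnt_stem_cell = bg[11:18],
    wnt_proliferative = bg[19:26],
    caf_signature = config$caf_genes)
  for (nm in names(sets))
    attr(sets[[nm]], "description") <- paste("placeholder set:", nm)
  gene_set_collection(sets)
}

labels_vector <- function(labels_df, keep = c("LD", "LI")) {
  l <- setNames(labels_df$label, labels_df$sample_id)
  l[l %in% keep]
}

#' Run the full stratification pipeline on a synthetic cohort
#'
#' Simulates a cohort, writes it to `out_dir`, re-establishes molecular
#' ground truth from the simulated data (fusion detection, mutation
#' interpretation, RSPO-high calling, class assignment), then runs
#' differential expression, gene-set enrichment, methylation analysis and
#' AXIN2 biomarker derivation on the derived (not planted) labels, and
#' writes `report.json`. Identical config + seed gives a byte-identical
#' report.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @param n_perm GSEA permutations (default 500).
#' @param n_boot bootstrap replicates for the AUC CI (default 1000).
#' @param gene_sets a [gene_set_collection()]; default
#'   [default_gene_sets()].
#' @return the report, invisibly (also written as JSON).
#' @export
run_full <- function(config = simulation_config(), out_dir,
                     n_perm = 500L, n_boot = 1000L,
                     gene_sets = default_gene_sets(config)) {
  sim <- simulate_cohort(config)
  write_cohort(sim, out_dir, config)
  bundle <- sim$bundle

  cls <- classify_cohort(bundle, min_overlap = config$min_overlap)
  labels <- labels_vector(cls$labels)
  write.table(cls$labels, file.path(out_dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")

  norm <- log_cpm(bundle$expression)
  write_expression_tsv(norm, file.path(out_dir, "normalized.tsv"))
  de <- differential_expression(norm, labels)
  write.table(de, file.path(out_dir, "de_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")
  caf <- signature_score(norm, config$caf_genes, name = "caf_signature")

  gsea <- gsea_test(norm, labels, gene_sets, n_perm = n_perm,
                    seed = config$seed + 11L)
  gsea_flat <- gsea[setdiff(names(gsea), "leading_edge")]
  write.table(gsea_flat, file.path(out_dir, "gsea.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")

  meth <- bundle$methylation
  beta_sum <- mean_beta_per_gene(meth)
  dmp <- dmp_test(meth, labels)
  cimp <- setNames(bundle$annotation$cimp_status == "positive",
                   bundle$annotation$sample_id)
  cimp_tab <- cimp_stratified_comparison(beta_sum, labels, cimp)
  corr <- meth_expr_correlation(beta_sum, norm)

  bm <- derive_biomarker(norm, labels, gene = "AXIN2", n_boot = n_boot,
                         seed = config$seed + 12L)
  truth_all <- labels_vector(cls$labels, keep = c("LD", "LI", "EX"))
  applied <- apply_classifier(bm$rule, norm, truth = truth_all)
  write.table(applied$predictions, file.path(out_dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")

  nr_genes <- names(config$class_effects)
  de_nr <- de[de$gene %in% nr_genes, ]
  report <- list(
    n_samples = config$n_samples,
    class_counts = as.list(table(cls$labels$label)),
    ld_subtypes = as.list(table(
      cls$labels$ld_subtype[cls$labels$label == "LD"])),
    fusion_calls = nrow(cls$fusion_calls),
    rspo_high = length(cls$rspo_high),
    exclusivity_flag_counts = as.list(cls$exclusivity$flag_counts),
    de_negative_regulators = lapply(seq_len(nrow(de_nr)), function(i)
      list(gene = de_nr$gene[i], mean_diff = de_nr$mean_diff[i],
           q = de_nr$q[i])),
    gsea = lapply(seq_len(nrow(gsea)), function(i)
      list(set = gsea$set[i], es = gsea$es[i], nes = gsea$nes[i],
           p_nominal = gsea$p_nominal[i],
           leading_edge = gsea$leading_edge[[i]])),
    n_dmp_q05 = sum(dmp$q < 0.05),
    n_dmp_hyper_q05 = sum(dmp$q < 0.05 & dmp$direction == "hyper"),
    meth_expr_correlation = lapply(seq_len(nrow(corr)), function(i)
      list(gene = corr$gene[i], r = corr$r[i], p = corr$p[i])),
    cimp_comparison = lapply(seq_len(nrow(cimp_tab)), function(i)
      as.list(cimp_tab[i, ])),
    caf_score_mean_rspo_high = {
      hi <- cls$labels$sample_id[cls$labels$ld_subtype == "RSPO_HIGH"]
      if (length(hi)) mean(caf$score[caf$sample_id %in% hi]) else NA
    },
    biomarker = list(
      gene = bm$gene, auc = bm$summary$auc, ci_low = bm$summary$ci_low,
      ci_high = bm$summary$ci_high, threshold = bm$rule$threshold,
      sensitivity = bm$rule$sensitivity,
      specificity = bm$rule$specificity,
      applied_sensitivity = applied$report$sensitivity,
      applied_specificity = applied$report$specificity,
      ex_score_summary = as.list(applied$report$score_summary$EX)),
    seed = config$seed)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
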