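# Single-gene expression biomarker: ROC curve, AUC with bootstrap CI,
# threshold maximising sensitivity + specificity, and classifier application.
#
# The positive class is LD (the clinically actionable, ligand-inhibitor
# sensitive group) and the decision score is low expression: a sample is
# called LD when its expression falls below the threshold. With LI samples
# expressing more AXIN2, the reported AUC equals the conventional
# orientation P(x_LI > x_LD).

check_roc_labels <- function(scores, labels) {
  shared <- intersect(names(scores), names(labels))
  labels <- labels[shared]
  bad <- setdiff(unique(labels), c("LD", "LI"))
  if (length(bad))
    stop("contract error: labels must be LD or LI (got '", bad[1],
         "'); EX samples must be removed before ROC analysis",
         call. = FALSE)
  list(scores = as.numeric(scores[shared]), labels = unname(labels))
}

auc_concordance <- function(ld_scores, li_scores) {
  n_ld <- length(ld_scores); n_li <- length(li_scores)
  r <- rank(c(li_scores, ld_scores), ties.method = "average")
  (sum(r[seq_len(n_li)]) - n_li * (n_li + 1) / 2) / (n_li * n_ld)
}

#' ROC curve for a low-expression LD classifier
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted scores plus infinite sentinels; at threshold tau a sample is
#' called LD when its score is strictly below tau. Sensitivity is the
#' fraction of LD samples called LD, specificity the fraction of LI samples
#' called LI. The AUC is the pairwise concordance P(x_LI > x_LD) with ties
#' weighted 0.5; the trapezoidal area under the curve equals it.
#'
#' @param scores named numeric vector of expression values.
#' @param labels named character vector `sample_id -> "LD"/"LI"` (EX not
#'   allowed).
#' @return object of class `wnt_roc`: list with `points` (threshold,
#'   sensitivity, specificity; threshold descending), `auc`, `n_ld`, `n_li`.
#' @export
roc_curve <- function(scores, labels) {
  d <- check_roc_labels(scores, labels)
  ld <- d$scores[d$labels == "LD"]
  li <- d$scores[d$labels == "LI"]
  if (!length(ld) || !length(li))
    stop("both classes must be non-empty", call. = FALSE)
  s <- sort(unique(d$scores))
  cand <- c(Inf, rev(if (length(s) > 1) (s[-1] + s[-length(s)]) / 2), -Inf)
  pts <- data.frame(
    threshold = cand,
    sensitivity = vapply(cand, function(t) mean(ld < t), numeric(1)),
    specificity = vapply(cand, function(t) mean(li >= t), numeric(1)))
  structure(list(points = pts, auc = auc_concordance(ld, li),
                 n_ld = length(ld), n_li = length(li)),
            class = "wnt_roc")
}

#' @export
print.wnt_roc <- function(x, ...) {
  cat(sprintf("ROC (positive class LD, call LD when expression < threshold)\n"))
  cat(sprintf("  n_LD = %d, n_LI = %d, AUC = %.4f\n", x$n_ld, x$n_li, x$auc))
  invisible(x)
}

#' @method plot wnt_roc
#' @export
plot.wnt_roc <- function(x, ...) {
  graphics::plot(1 - x$points$specificity, x$points$sensitivity,
                 type = "s", xlab = "1 - specificity",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# trapezoidal area under the (FPR, sensitivity) curve; equals the
# concordance AUC and is cross-checked against it in the test suite
trapezoid_auc <- function(curve) {
  fpr <- 1 - curve$points$specificity
  sens <- curve$points$sensitivity
  o <- order(fpr, sens)   # monotone staircase: ties in FPR sorted by sens
  fpr <- fpr[o]; sens <- sens[o]
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Resamples within each class, recomputes the concordance AUC, and reports
#' the percentile interval. A fixed seed gives an identical interval.
#'
#' @param scores,labels as in [roc_curve()].
#' @param n_boot bootstrap replicates (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return object of class `roc_summary`: auc, ci_low, ci_high, ci_method,
#'   n_ld, n_li, n_boot, level, seed.
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 2000L, level = 0.95,
                         seed = 1L) {
  d <- check_roc_labels(scores, labels)
  ld <- d$scores[d$labels == "LD"]
  li <- d$scores[d$labels == "LI"]
  if (length(ld) < 2L || length(li) < 2L)
    stop("bootstrap needs >= 2 samples per class", call. = FALSE)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b)
    auc_concordance(sample(ld, replace = TRUE),
                    sample(li, replace = TRUE)), numeric(1))
  a <- (1 - level) / 2
  ci <- unname(quantile(reps, c(a, 1 - a)))
  structure(list(auc = auc_concordance(ld, li), ci_low = ci[1],
                 ci_high = ci[2],
                 ci_method = "stratified percentile bootstrap",
                 n_ld = length(ld), n_li = length(li),
                 n_boot = n_boot, level = level, seed = seed),
            class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f to %.3f; %s, %d replicates)\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$ci_method, x$n_boot))
  invisible(x)
}

#' Select the expression threshold maximising sensitivity + specificity
#'
#' Scans the candidate thresholds of the ROC curve for the cutpoint with
#' the largest sensitivity + specificity (Youden-style). Ties are broken by
#' higher specificity, then by lower threshold.
#'
#' @param curve a `wnt_roc` from [roc_curve()].
#' @param gene gene symbol recorded on the rule (default "AXIN2").
#' @return object of class `threshold_rule`: gene, threshold, sensitivity,
#'   specificity. The rule is: call LD when expression < threshold.
#' @export
select_threshold <- function(curve, gene = "AXIN2") {
  p <- curve$points
  j <- p$sensitivity + p$specificity
  best <- order(-j, -p$specificity, p$threshold)[1]
  structure(list(gene = gene, threshold = p$threshold[best],
                 sensitivity = p$sensitivity[best],
                 specificity = p$specificity[best]),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf(
    "call LD when %s expression < %.3f (sens %.1f%%, spec %.1f%%)\n",
    x$gene, x$threshold, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Apply a threshold rule to an expression matrix
#'
#' Samples with expression strictly below the threshold are called LD;
#' expression at or above it (including exactly at the boundary) is called
#' LI. When ground-truth labels are supplied, a performance report is
#' computed on the LD/LI samples only; EX samples are never scored into the
#' confusion matrix but their expression is summarised separately.
#'
#' @param rule a [select_threshold()] rule.
#' @param norm an [expr_matrix()] in a log space (same expression space as
#'   the one the rule was derived in; a warning is issued otherwise).
#' @param truth optional named character vector `sample_id ->
#'   "LD"/"LI"/"EX"`.
#' @param trained_space expression space the rule was derived in (default
#'   `"log_cpm"`).
#' @return list with `predictions` (data.frame sample_id, score, predicted)
#'   and, when truth is given, `report` (confusion counts, sensitivity,
#'   specificity, per-class score summaries including EX).
#' @export
apply_classifier <- function(rule, norm, truth = NULL,
                             trained_space = "log_cpm") {
  stopifnot(inherits(rule, "threshold_rule"))
  if (!rule$gene %in% rownames(norm$values))
    stop("gene ", rule$gene, " absent from matrix", call. = FALSE)
  if (norm$space != trained_space)
    warning("applying a threshold derived in space '", trained_space,
            "' to a matrix in space '", norm$space, "'")
  score <- norm$values[rule$gene, ]
  pred <- ifelse(score < rule$threshold, "LD", "LI")
  predictions <- data.frame(sample_id = colnames(norm$values),
                            score = unname(score),
                            predicted = unname(pred), row.names = NULL)
  if (is.null(truth)) return(list(predictions = predictions))
  truth <- truth[intersect(names(truth), predictions$sample_id)]
  t_lab <- truth[predictions$sample_id]
  summarise <- function(x) if (!length(x))
    c(n = 0, mean = NA, sd = NA, min = NA, max = NA) else
    c(n = length(x), mean = mean(x), sd = sd(x), min = min(x), max = max(x))
  scored <- !is.na(t_lab) & t_lab %in% c("LD", "LI")
  tp <- sum(scored & t_lab == "LD" & pred == "LD")
  fn <- sum(scored & t_lab == "LD" & pred == "LI")
  tn <- sum(scored & t_lab == "LI" & pred == "LI")
  fp <- sum(scored & t_lab == "LI" & pred == "LD")
  report <- list(
    confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    score_summary = list(
      LD = summarise(score[scored & t_lab == "LD"]),
      LI = summarise(score[scored & t_lab == "LI"]),
      EX = summarise(score[!is.na(t_lab) & t_lab == "EX"])))
  list(predictions = predictions, report = report)
}

#' Derive the single-gene biomarker end to end
#'
#' Convenience wrapper: extracts the gene's expression, fits the ROC curve,
#' bootstraps the AUC confidence interval and selects the threshold.
#'
#' @param norm an [expr_matrix()] in a log space.
#' @param labels named character vector `sample_id -> "LD"/"LI"` (EX samples
#'   are dropped with their ids recorded).
#' @param gene biomarker gene (default "AXIN2").
#' @param n_boot,level,seed passed to [bootstrap_ci()].
#' @return object of class `wnt_biomarker`: gene, roc, summary, rule,
#'   excluded (EX sample ids).
#' @export
derive_biomarker <- function(norm, labels, gene = "AXIN2", n_boot = 2000L,
                             level = 0.95, seed = 1L) {
  if (!gene %in% rownames(norm$values))
    stop("gene ", gene, " absent from matrix", call. = FALSE)
  ex <- names(labels)[labels == "EX"]
  labels <- labels[labels %in% c("LD", "LI")]
  scores <- norm$values[gene, ]
  curve <- roc_curve(scores, labels)
  structure(list(gene = gene, roc = curve,
                 summary = bootstrap_ci(scores, labels, n_boot = n_boot,
                                        level = level, seed = seed),
                 rule = select_threshold(curve, gene = gene),
                 excluded = ex),
            class = "wnt_biomarker")
}

#' @export
print.wnt_biomarker <- function(x, ...) {
  cat(sprintf("%s biomarker (LD vs LI, n = %d vs %d)\n", x$gene,
              x$roc$n_ld, x$roc$n_li))
  print(x$summary)
  print(x$rule)
  if (length(x$excluded))
    cat(sprintf("  %d EX samples reported separately\n",
                length(x$excluded)))
  invisible(x)
}
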