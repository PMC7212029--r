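# ROC, AUC, bootstrap CI, threshold selection, classifier application.

named_scores <- function(ld, li) {
  s <- c(ld, li)
  names(s) <- paste0("S", seq_along(s))
  labels <- setNames(rep(c("LD", "LI"), c(length(ld), length(li))),
                     names(s))
  list(scores = s, labels = labels)
}

test_that("AUC covers perfect separation, full ties, and the 3/4 case", {
  d <- named_scores(c(1, 2), c(3, 4))
  r <- roc_curve(d$scores, d$labels)
  expect_equal(r$auc, 1.0)

  t <- named_scores(c(5, 5), c(5, 5))
  expect_equal(roc_curve(t$scores, t$labels)$auc, 0.5)

  m <- named_scores(c(1, 2), c(3, 1.5))
  expect_equal(roc_curve(m$scores, m$labels)$auc, 0.75)

  ex <- d$labels; ex[1] <- "EX"
  expect_error(roc_curve(d$scores, ex), "contract error")
  one <- setNames(rep("LD", 4), names(d$scores))
  expect_error(roc_curve(d$scores, one), "non-empty")
})

test_that("curve is monotone with both endpoints present", {
  set.seed(6)
  d <- named_scores(rnorm(15, 4), rnorm(25, 6))
  r <- roc_curve(d$scores, d$labels)
  p <- r$points    # thresholds descending
  expect_equal(p$sensitivity[1], 1); expect_equal(p$specificity[1], 0)
  expect_equal(p$sensitivity[nrow(p)], 0)
  expect_equal(p$specificity[nrow(p)], 1)
  expect_true(all(diff(p$sensitivity) <= 0))
  expect_true(all(diff(p$specificity) >= 0))
})

test_that("AUC equals brute-force concordance and the trapezoidal area", {
  set.seed(17)
  for (i in 1:150) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    ld <- round(rnorm(n1, 5), sample(0:2, 1))   # rounding induces ties
    li <- round(rnorm(n2, 6), sample(0:2, 1))
    d <- named_scores(ld, li)
    r <- roc_curve(d$scores, d$labels)
    expect_equal(r$auc, auc_oracle(ld, li), tolerance = 1e-14)
    expect_equal(wntstrat:::trapezoid_auc(r), r$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(29)
  d <- named_scores(rnorm(20, 4), rnorm(30, 6))
  base <- roc_curve(d$scores, d$labels)$auc
  for (f in list(function(x) 3 * x - 7, exp, function(x) x^3))
    expect_equal(roc_curve(f(d$scores), d$labels)$auc, base,
                 tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  d <- named_scores(rnorm(20, 4), rnorm(30, 6))
  ours <- roc_curve(d$scores, d$labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = d$labels, predictor = d$scores, levels = c("LD", "LI"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("threshold selection is optimal with documented tie-breaks", {
  d <- named_scores(c(1, 2), c(3, 4))
  rule <- select_threshold(roc_curve(d$scores, d$labels))
  expect_equal(rule$threshold, 2.5)
  expect_equal(rule$sensitivity, 1)
  expect_equal(rule$specificity, 1)

  # equal sums at 1.5 and 3.5: higher specificity wins
  tie <- named_scores(c(1, 3), c(2, 4))
  rule2 <- select_threshold(roc_curve(tie$scores, tie$labels))
  expect_equal(rule2$threshold, 1.5)
  expect_equal(rule2$specificity, 1)

  set.seed(43)
  for (i in 1:150) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    ld <- round(rnorm(n1, 5), 1); li <- round(rnorm(n2, 6), 1)
    dd <- named_scores(ld, li)
    r <- select_threshold(roc_curve(dd$scores, dd$labels))
    expect_equal(r$sensitivity + r$specificity,
                 threshold_sum_oracle(ld, li), tolerance = 1e-12)
  }
})

test_that("bootstrap CI is deterministic, contains the AUC, narrows with n", {
  d <- named_scores(rnorm(25, 4), rnorm(25, 6.5))
  a <- bootstrap_ci(d$scores, d$labels, n_boot = 400, seed = 5)
  b <- bootstrap_ci(d$scores, d$labels, n_boot = 400, seed = 5)
  expect_identical(c(a$ci_low, a$ci_high), c(b$ci_low, b$ci_high))
  expect_lte(a$ci_low, a$auc); expect_gte(a$ci_high, a$auc)

  sep <- named_scores(rnorm(50, 0), rnorm(50, 20))
  ci <- bootstrap_ci(sep$scores, sep$labels, n_boot = 400, seed = 9)
  expect_gte(ci$ci_low, 0.9)

  set.seed(57)
  widths <- vapply(1:10, function(i) {
    small <- named_scores(rnorm(25, 4), rnorm(25, 5.5))
    big <- named_scores(rnorm(200, 4), rnorm(200, 5.5))
    ws <- bootstrap_ci(small$scores, small$labels, n_boot = 300, seed = i)
    wb <- bootstrap_ci(big$scores, big$labels, n_boot = 300, seed = i)
    c(ws$ci_high - ws$ci_low, wb$ci_high - wb$ci_low)
  }, numeric(2))
  expect_lt(mean(widths[2, ]), mean(widths[1, ]))
})

test_that("classifier application uses the boundary-to-LI convention", {
  X <- matrix(c(5, 6, 7), 1, 3,
              dimnames = list("AXIN2", paste0("S", 1:3)))
  norm <- expr_matrix(X, "log_cpm")
  rule <- structure(list(gene = "AXIN2", threshold = 6,
                         sensitivity = NA, specificity = NA),
                    class = "threshold_rule")
  res <- apply_classifier(rule, norm)
  expect_equal(res$predictions$predicted, c("LD", "LI", "LI"))
  expect_null(res$report)

  truth <- c(S1 = "LD", S2 = "EX", S3 = "LI")
  res2 <- apply_classifier(rule, norm, truth)
  expect_equal(unname(res2$report$confusion), c(1, 0, 1, 0))
  expect_equal(res2$report$score_summary$EX[["n"]], 1)
  expect_equal(res2$report$sensitivity, 1)

  bad <- structure(list(gene = "NKD1", threshold = 6), class = "threshold_rule")
  expect_error(apply_classifier(bad, norm), "absent")
})

# Closed-form Gaussian tail oracle for classifier performance on a synthetic
# cohort. Log-CPM of a gene is its log2 signal plus a compositional offset
# log2(1e6 / sum_g 2^x_g); the expected offset is computed per scenario
# (LI / LD without RSPO shift / LD with RSPO shift +- CAF shift).
analytic_performance <- function(cfg, tau) {
  lognorm_mean <- function(mu, sigma) 2^mu * exp((sigma * log(2))^2 / 2)
  base_sum <- function(ld) {
    s <- 0
    for (g in names(cfg$class_effects)) {
      e <- cfg$class_effects[[g]]
      s <- s + lognorm_mean(if (ld) e[["mu_ld"]] else e[["mu_li"]],
                            e[["sigma"]])
    }
    s + 2 * lognorm_mean(cfg$rspo_mu, cfg$rspo_sigma) +
      length(cfg$caf_genes) * lognorm_mean(cfg$caf_mu, cfg$caf_sigma) +
      cfg$n_background * lognorm_mean(cfg$background_mu,
                                      cfg$background_sigma)
  }
  rspo_extra <- lognorm_mean(cfg$rspo_mu + cfg$rspo_shift, cfg$rspo_sigma) -
    lognorm_mean(cfg$rspo_mu, cfg$rspo_sigma)
  caf_extra <- length(cfg$caf_genes) *
    (lognorm_mean(cfg$caf_mu + cfg$caf_shift, cfg$caf_sigma) -
       lognorm_mean(cfg$caf_mu, cfg$caf_sigma))
  ax <- cfg$class_effects$AXIN2
  off <- function(total) log2(1e6 / total)
  p <- cfg$ld_subtype_proportions
  sens_by <- c(
    rspo_fusion = pnorm((tau - off(base_sum(TRUE) + rspo_extra) -
                           ax[["mu_ld"]]) / ax[["sigma"]]),
    rspo_high = pnorm((tau - off(base_sum(TRUE) + rspo_extra + caf_extra) -
                         ax[["mu_ld"]]) / ax[["sigma"]]),
    rnf43 = pnorm((tau - off(base_sum(TRUE)) - ax[["mu_ld"]]) /
                    ax[["sigma"]]))
  list(sensitivity = sum(p[names(sens_by)] * sens_by),
       specificity = 1 - pnorm((tau - off(base_sum(FALSE)) -
                                  ax[["mu_li"]]) / ax[["sigma"]]))
}

test_that("applied classifier performance matches the Gaussian tail oracle", {
  cfg_train <- simulation_config(seed = 101)
  train <- simulate_cohort(cfg_train)
  labels <- setNames(train$truth$true_class, train$truth$sample_id)
  norm <- log_cpm(train$bundle$expression)
  bm <- derive_biomarker(norm, labels, n_boot = 200, seed = 1)

  cfg_eval <- simulation_config(n_samples = 2000, seed = 102)
  eval_ <- simulate_cohort(cfg_eval)
  res <- apply_classifier(bm$rule, log_cpm(eval_$bundle$expression),
                          truth = setNames(eval_$truth$true_class,
                                           eval_$truth$sample_id))
  want <- analytic_performance(cfg_train, bm$rule$threshold)
  expect_lt(abs(res$report$sensitivity - want$sensitivity), 0.05)
  expect_lt(abs(res$report$specificity - want$specificity), 0.05)
})
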