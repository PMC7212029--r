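# Normalisation, outlier calling, differential expression, signatures.

test_that("log-CPM follows the formula and is scale invariant per sample", {
  cm <- matrix(c(0, 10, 990, 0, 20, 1980), 3, 2,
               dimnames = list(c("A", "B", "C"), c("S1", "S2")))
  norm <- log_cpm(expr_matrix(cm, "counts"))
  expect_equal(norm$space, "log_cpm")
  expect_equal(norm$values["A", "S1"], 0)                   # log2(1 + 0)
  expect_equal(norm$values["B", "S1"], log2(1 + 1e6 * 10 / 1000))
  expect_equal(round(norm$values["B", "S1"], 4), 13.2879)
  # S2 doubles every count of S1: CPM, hence log-CPM, unchanged
  expect_equal(norm$values[, "S1"], norm$values[, "S2"])
  expect_equal(unname(norm$lib_sizes), c(1000, 2000))

  zero <- expr_matrix(matrix(c(1, 0, 2, 0), 2, 2,
                             dimnames = list(c("A", "B"), c("S1", "S2"))),
                      "counts")
  zero$values[, 2] <- 0
  expect_error(log_cpm(zero), "zero library size for sample S2")
})

test_that("z-score outliers use the sample sd and an inclusive threshold", {
  norm <- tiny_norm(c(1, 2, 3, 4, 100), "G1", paste0("S", 1:5))
  out <- zscore_outliers(norm, "G1")
  z100 <- out$z[out$sample_id == "S5"]
  expect_equal(z100, (100 - 22) / sqrt(7610 / 4), tolerance = 1e-12)
  expect_equal(round(z100, 3), 1.788)
  expect_false(out$is_outlier[out$sample_id == "S5"])

  # z exactly at the threshold is an outlier
  x <- c(-1, -1, 1, 1)
  norm2 <- tiny_norm(x, "G1", paste0("S", 1:4))
  out2 <- zscore_outliers(norm2, "G1", threshold = max(scale(x)))
  expect_true(any(out2$is_outlier))

  flat <- tiny_norm(rep(5, 4), "G1", paste0("S", 1:4))
  expect_error(zscore_outliers(flat, "G1"), "zero variance for gene G1")
})

test_that("differential expression handles nulls and flags degeneracy", {
  norm <- tiny_norm(c(1, 2, 3, 1, 2, 3,
                      5, 5, 5, 5, 5, 5), c("G1", "G2"), paste0("S", 1:6))
  labels <- setNames(rep(c("LD", "LI"), each = 3), paste0("S", 1:6))
  de <- differential_expression(norm, labels)
  expect_equal(de$t_stat[de$gene == "G1"], 0)
  expect_equal(de$p[de$gene == "G1"], 1)
  expect_true(de$zero_variance[de$gene == "G2"])
  expect_equal(de$p[de$gene == "G2"], 1)

  expect_error(differential_expression(
    norm, setNames(c("LD", rep("LI", 5)), paste0("S", 1:6))),
    ">= 2 samples")
  expect_error(differential_expression(
    norm, setNames(c("EX", rep("LI", 5)), paste0("S", 1:6))), "EX")
})

test_that("BH q-values equal the step-up oracle; worked 4-gene case", {
  norm <- tiny_norm(rnorm(40), paste0("G", 1:4), paste0("S", 1:10))
  # the documented hand example: p = .01,.02,.03,.04 -> q all .04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))

  set.seed(5)
  for (i in 1:100) {
    p <- runif(sample(2:50, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-14)
  }
})

test_that("Welch statistics match the textbook oracle and t.test", {
  set.seed(8)
  for (i in 1:60) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 3)); y <- rnorm(n2, 2)
    X <- rbind(G1 = c(x, y))
    colnames(X) <- paste0("S", seq_len(n1 + n2))
    labels <- setNames(rep(c("LI", "LD"), c(n1, n2)), colnames(X))
    de <- differential_expression(expr_matrix(X, "log_cpm"), labels)
    o <- welch_oracle(x, y)
    tt <- t.test(x, y)
    expect_equal(de$t_stat, o$t, tolerance = 1e-10)
    expect_equal(de$df, o$df, tolerance = 1e-10)
    expect_equal(de$p, o$p, tolerance = 1e-10)
    expect_equal(de$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(de$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("planted AXIN2 effect is detected at extreme significance", {
  hits <- vapply(1:10, function(seed) {
    cfg <- simulation_config(n_samples = 100, ld_fraction = 0.5,
                             seed = seed)
    sim <- simulate_cohort(cfg)
    labels <- setNames(sim$truth$true_class, sim$truth$sample_id)
    de <- differential_expression(log_cpm(sim$bundle$expression), labels)
    de$q[de$gene == "AXIN2"] < 1e-6 && de$mean_diff[de$gene == "AXIN2"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("signature scores are mean z-scores with dropped-gene reporting", {
  set.seed(12)
  X <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("A", "B", "C"), paste0("S", 1:10)))
  norm <- expr_matrix(X, "log_cpm")
  one <- signature_score(norm, "A")
  z <- (X["A", ] - mean(X["A", ])) / sd(X["A", ])
  expect_equal(one$score, unname(z))

  multi <- signature_score(norm, c("A", "B", "MISSING"), name = "caf")
  expect_equal(attr(multi, "dropped"), "MISSING")
  expect_equal(mean(multi$score), 0, tolerance = 1e-9)

  expect_error(signature_score(norm, "ZZZ"), "no signature gene")
  flat <- expr_matrix(matrix(5, 1, 4, dimnames = list("A", paste0("S", 1:4))),
                      "log_cpm")
  expect_error(signature_score(flat, "A"), "zero variance")
})

test_that("RSPO-high samples are flagged with high recall, low false positives", {
  res <- vapply(1:8, function(seed) {
    sim <- simulate_cohort(simulation_config(seed = seed))
    norm <- log_cpm(sim$bundle$expression)
    out <- zscore_outliers(norm, c("RSPO2", "RSPO3"))
    flagged <- unique(out$sample_id[out$is_outlier])
    planted <- sim$truth$sample_id[sim$truth$true_subtype == "RSPO_HIGH"]
    rspo_any <- sim$truth$sample_id[sim$truth$true_subtype %in%
                                      c("RSPO_HIGH", "RSPO_FUSION")]
    c(recall = mean(planted %in% flagged),
      fpr = mean(setdiff(sim$truth$sample_id, rspo_any) %in% flagged))
  }, numeric(2))
  expect_gte(mean(res["recall", ]), 0.9)
  expect_lte(mean(res["fpr", ]), 0.02)
})
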