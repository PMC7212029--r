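# Fusion detection, driver interpretation, class assignment and the
# mutual-exclusivity summary.

lib1 <- function() synthetic_junction_library()

test_that("fusion detection requires an exact breakpoint-spanning window", {
  lib <- lib1()
  jct <- lib[["PTPRK-RSPO3"]]
  expect_equal(nrow(detect_fusions(Biostrings::DNAStringSet(), lib, "S1")),
               0L)

  full <- Biostrings::DNAStringSet(setNames(jct$sequence, "r1"))
  calls <- detect_fusions(full, lib, "S1")
  expect_equal(calls$fusion_id, "PTPRK-RSPO3")
  expect_equal(calls$supporting_reads, 1L)

  upstream <- Biostrings::DNAStringSet(
    setNames(substr(jct$sequence, 1, jct$breakpoint_offset), "r1"))
  expect_equal(nrow(detect_fusions(upstream, lib, "S1")), 0L)

  expect_error(detect_fusions(full, lib, "S1", min_overlap = 500),
               "min_overlap.*PTPRK-RSPO3")
})

test_that("detection is invariant to read order and reverse complement", {
  lib <- lib1()
  jct <- lib[["EIF3E-RSPO2"]]
  params <- list(read_length = 50L, n_junction_reads = 6L,
                 n_background_reads = 10L, rc_fraction = 0)
  reads <- simulate_junction_reads("S1", jct, params, seed = 9)
  base <- detect_fusions(reads, lib, "S1")
  expect_equal(base$supporting_reads, 6L)

  shuffled <- reads[rev(seq_along(reads))]
  expect_equal(detect_fusions(shuffled, lib, "S1")$supporting_reads, 6L)

  flipped <- Biostrings::reverseComplement(reads)
  expect_equal(detect_fusions(flipped, lib, "S1")$supporting_reads, 6L)
})

test_that("raising min_supporting_reads never adds a call", {
  lib <- lib1()
  jct <- lib[["PTPRK-RSPO3"]]
  reads <- simulate_junction_reads(
    "S1", jct, list(read_length = 50L, n_junction_reads = 3L,
                    n_background_reads = 20L, rc_fraction = 0.5), seed = 4)
  for (k in 1:5) {
    calls_k <- detect_fusions(reads, lib, "S1", min_supporting_reads = k)
    calls_k1 <- detect_fusions(reads, lib, "S1", min_supporting_reads = k + 1)
    expect_true(all(calls_k1$fusion_id %in% calls_k$fusion_id))
  }
  expect_equal(nrow(detect_fusions(reads, lib, "S1",
                                   min_supporting_reads = 4)), 0L)
})

test_that("mutations map to driver flags per the functional rules", {
  expect_true(is.na(classify_mutation(
    data.frame(sample_id = "S", gene = "APC", variant_class = "silent",
               protein_position = 12L))))
  expect_equal(classify_mutation(
    data.frame(sample_id = "S", gene = "CTNNB1",
               variant_class = "missense", protein_position = 45L)),
    "ctnnb1_act")
  expect_true(is.na(classify_mutation(
    data.frame(sample_id = "S", gene = "CTNNB1",
               variant_class = "missense", protein_position = 200L))))
  expect_equal(classify_mutation(
    data.frame(sample_id = "S", gene = "RNF43",
               variant_class = "frameshift", protein_position = NA)),
    "rnf43_lof")
  expect_equal(classify_mutation(
    data.frame(sample_id = "S", gene = "APC",
               variant_class = "splice_site", protein_position = NA)),
    "apc_lof")
})

test_that("RSPO-high requires an outlier without any fusion call", {
  out <- data.frame(gene = c("RSPO3", "RSPO3", "RSPO2"),
                    sample_id = c("A", "B", "C"),
                    z = c(2.4, 2.4, 1.9),
                    is_outlier = c(TRUE, TRUE, FALSE))
  fus <- data.frame(sample_id = "B", fusion_id = "PTPRK-RSPO3",
                    gene = "RSPO3", supporting_reads = 5L)
  expect_equal(call_rspo_high(out, fus), "A")
})

test_that("class assignment partitions samples with documented reasons", {
  prof <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                     apc_lof     = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                     ctnnb1_act  = FALSE,
                     rnf43_lof   = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                     rspo_fusion = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                     rspo_high   = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  lab <- assign_class(prof)
  expect_equal(lab$label, c("LI", "EX", "LD", "EX", "LD"))
  expect_equal(lab$reason[2], "concurrent")
  expect_equal(lab$reason[4], "no driver")
  expect_equal(lab$ld_subtype, c("none", "none", "AMBIGUOUS", "none",
                                 "RSPO_HIGH"))
  # every sample gets exactly one label; subtype is set iff label is LD
  expect_equal(nrow(lab), nrow(prof))
  expect_true(all((lab$ld_subtype != "none") == (lab$label == "LD")))
})

test_that("random driver profiles always yield a complete partition", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    prof <- data.frame(sample_id = paste0("S", seq_len(n)),
                       apc_lof = runif(n) < 0.4,
                       ctnnb1_act = runif(n) < 0.1,
                       rnf43_lof = runif(n) < 0.2,
                       rspo_fusion = runif(n) < 0.2,
                       rspo_high = runif(n) < 0.2)
    lab <- assign_class(prof)
    expect_true(all(lab$label %in% c("LD", "LI", "EX")))
    expect_equal(sum(table(lab$label)), n)
    expect_true(all((lab$ld_subtype != "none") == (lab$label == "LD")))
  }
})

test_that("exclusivity summary counts flags and pairwise co-occurrence", {
  prof <- data.frame(sample_id = c("a", "b", "c"),
                     apc_lof = c(TRUE, TRUE, FALSE),
                     ctnnb1_act = FALSE,
                     rnf43_lof = c(FALSE, FALSE, TRUE),
                     rspo_fusion = FALSE, rspo_high = FALSE)
  s <- exclusivity_summary(prof)
  expect_equal(unname(s$flag_counts), c(0, 3, 0))
  expect_equal(s$co_occurrence["apc_lof", "rnf43_lof"], 0)
  expect_equal(s$co_occurrence["apc_lof", "apc_lof"], 2)

  both <- prof[1, ]; both$rnf43_lof <- TRUE
  s2 <- exclusivity_summary(both)
  expect_equal(unname(s2$flag_counts[">=2"]), 1)
  expect_equal(s2$co_occurrence["apc_lof", "rnf43_lof"], 1)
  expect_true(isSymmetric(s2$co_occurrence))

  s0 <- exclusivity_summary(prof[0, ])
  expect_equal(unname(s0$flag_counts), c(0, 0, 0))
  expect_true(all(s0$co_occurrence == 0))
})

test_that("classification recovers planted ground truth without co-occurrence", {
  cfg <- simulation_config(n_samples = 250, co_occurrence_rate = 0,
                           seed = 31)
  sim <- simulate_cohort(cfg)
  cls <- classify_cohort(sim$bundle)
  m <- merge(cls$labels, sim$truth, by = "sample_id")
  expect_equal(mean(m$label == m$true_class), 1)
  expect_equal(mean(m$ld_subtype[m$label == "LD"] ==
                      m$true_subtype[m$label == "LD"]), 1)
})
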