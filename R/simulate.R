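# Synthetic multi-omic cohort generator with planted ground truth.
#
# Each cohort layer (class labels, mutations, expression, methylation, reads)
# draws from its own RNG stream seeded as seed + fixed offset, so adding or
# regenerating one layer never perturbs another layer's draws.

# Synthetic junction sequences for the two recurrent RSPO fusions (PTPRK-RSPO3
# and EIF3E-RSPO2 style). The sequences are random 160-mers, breakpoint at 80:
# they are synthetic stand-ins, not genomic sequence.
JUNCTION_RSPO3 <- "TGCCTATACGACGCGCGTCTCTGTGTCTCATGTATGGGTCTAGGTAGGTACACCCTGCTAAGTAACCCTAGAAGATTTTTCCGTAATTTTCAAAGTTCACGCGGGATCTCAATGTCGATTTCTCTCCGGCTGGGTCAACTATGTGTAGGGGTTATCCTTG"
JUNCTION_RSPO2 <- "GAGGGCATTATATAACGCAGCCAACGCGATTCAACATGACAATCACTGAAGGATTGGGTATCGGCCAGACATCGACGAGCAGCCAAAGCGTACGGACGTACGAATAATGCAGTTGAGCTTGTGGTCGCAGGTTGGACATATCGAGGGTGTCCCTTTGTCT"
DECOY_SEQ <- "GGGGCAAACAGTCGAGGGGGCTGTGATGGGTCAGTAATAATTCAACCGGACCTAGTCGTCCTAACTGAAGCCCTTGACCACTGTCCCACTCTTTCAGTCCGTATTCCGGCATGTGACCCTTTGTCTGCGCTAGAGGTGCTAAGAGATCGGGATTTGTTGTTTAGCGGGATGTCAGTAACCGGCCTTGCTGCGTATAAGAGCTCTACGTAGCGGTGAAGATAGGATCCAACCGGTCCAATCGACCCTCCGATAACTAAACGCCGAGTGCATCATAACATACCCACCTATCCTTGCTGTGGCGTCGGGCACCGCCTCTCCTTCAGGTGATATCAAGGCATGCTTGTGGCCCCGCATTCGCATCTACCGGTCCCCCTAGGAATGTGACCGTTACGTTTGCATT"

#' Built-in synthetic RSPO fusion junction library
#'
#' Two junction records (one per RSPO gene) with known breakpoint offsets,
#' suitable for [detect_fusions()] and for planting junction-spanning reads.
#' Sequences are synthetic stand-ins generated once, not genomic sequence.
#'
#' @return A `junction_library`: named list of records with fields
#'   `fusion_id`, `gene`, `sequence`, `breakpoint_offset` (0-based).
#' @export
synthetic_junction_library <- function() {
  junction_library(list(
    list(fusion_id = "PTPRK-RSPO3", gene = "RSPO3",
         sequence = JUNCTION_RSPO3, breakpoint_offset = 80L),
    list(fusion_id = "EIF3E-RSPO2", gene = "RSPO2",
         sequence = JUNCTION_RSPO2, breakpoint_offset = 80L)))
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by [simulate_cohort()]: cohort size
#' and LD prevalence, the LD subtype mix, class-dependent Gaussian
#' log2-expression of the five Wnt negative regulators, library-size and
#' count sampling, methylation coupling models, and fusion read generation.
#'
#' Defaults describe a discovery-style colorectal cohort: n = 600 tumours
#' with an 11.3\% LD fraction split 45/20/35 between RSPO-fusion, RSPO-high
#' and RNF43 subtypes; AXIN2 log2 means 4.2 (LD) vs 6.3 (LI) with sd 0.8,
#' giving a theoretical AUC of about 0.968; AXIN2/NKD1 methylation linearly
#' coupled to expression on the logit scale with noise calibrated so the
#' generating-model beta-expression correlation is about -0.7; NOTUM/APCDD1
#' methylation bimodal and CIMP-driven.
#'
#' @param n_samples cohort size.
#' @param ld_fraction probability a sample is ligand-dependent.
#' @param ld_subtype_proportions named probabilities (`rspo_fusion`,
#'   `rspo_high`, `rnf43`) summing to 1.
#' @param co_occurrence_rate probability a sample additionally carries a
#'   driver of the opposite class.
#' @param ctnnb1_prob probability an LI sample carries a CTNNB1 hotspot
#'   missense rather than an APC truncation.
#' @param class_effects named list `gene -> c(mu_ld, mu_li, sigma)` in log2
#'   units.
#' @param rspo_mu,rspo_sigma baseline log2 expression of RSPO2/RSPO3.
#' @param rspo_shift log2 shift added to one RSPO gene in RSPO-fusion and
#'   RSPO-high samples; large enough that the z >= 2 outlier rule fires in
#'   expectation.
#' @param caf_genes,caf_mu,caf_sigma,caf_shift cancer-associated fibroblast
#'   signature genes, their baseline, and the extra shift in RSPO-high
#'   (stroma-rich) samples.
#' @param n_background,background_mu,background_sigma background genes.
#' @param library_size_log_mean,library_size_log_sd natural-log parameters of
#'   the log-normal per-sample library size.
#' @param meth_models named list of per-gene methylation models; each either
#'   `list(type = "linear_coupled", intercept, slope, noise)` (logit-scale
#'   beta coupled to log2 expression) or
#'   `list(type = "cimp_bimodal", beta_low, beta_high, noise)`.
#' @param probes_per_gene probes simulated per modelled gene.
#' @param cimp_prevalence probability a sample is CIMP positive.
#' @param fusion_read_params list with `read_length`, `n_junction_reads`,
#'   `n_background_reads`, `rc_fraction` (fraction of reads emitted as
#'   reverse complements).
#' @param min_overlap minimum bases required on each side of the breakpoint
#'   for a read to span the junction.
#' @param overdispersion count overdispersion multiplier (1 = pure Poisson).
#' @param seed integer master seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_samples = 600L,
    ld_fraction = 0.113,
    ld_subtype_proportions = c(rspo_fusion = 0.45, rspo_high = 0.20,
                               rnf43 = 0.35),
    co_occurrence_rate = 0.02,
    ctnnb1_prob = 0.15,
    class_effects = list(
      AXIN2  = c(mu_ld = 4.2, mu_li = 6.3, sigma = 0.8),
      NKD1   = c(mu_ld = 3.6, mu_li = 5.5, sigma = 0.9),
      APCDD1 = c(mu_ld = 5.1, mu_li = 6.6, sigma = 0.9),
      NOTUM  = c(mu_ld = 4.0, mu_li = 6.0, sigma = 1.0),
      DKK4   = c(mu_ld = 2.2, mu_li = 3.9, sigma = 1.1)),
    rspo_mu = 2.0, rspo_sigma = 0.5, rspo_shift = 7,
    caf_genes = paste0("CAF", 1:8), caf_mu = 5, caf_sigma = 0.8,
    caf_shift = 2,
    n_background = 85L, background_mu = 5, background_sigma = 0.8,
    library_size_log_mean = log(3e5), library_size_log_sd = 0.25,
    meth_models = list(
      AXIN2  = list(type = "linear_coupled", intercept = 0.9,
                    slope = 0.35, noise = 0.65),
      NKD1   = list(type = "linear_coupled", intercept = 0.75,
                    slope = 0.35, noise = 0.67),
      NOTUM  = list(type = "cimp_bimodal", beta_low = 0.2,
                    beta_high = 0.7, noise = 0.05),
      APCDD1 = list(type = "cimp_bimodal", beta_low = 0.2,
                    beta_high = 0.7, noise = 0.05)),
    probes_per_gene = 3L,
    cimp_prevalence = 0.2,
    fusion_read_params = list(read_length = 50L, n_junction_reads = 20L,
                              n_background_reads = 100L, rc_fraction = 0.5),
    min_overlap = 10L,
    overdispersion = 1,
    seed = 1L) {
  cfg <- structure(
    list(n_samples = as.integer(n_samples), ld_fraction = ld_fraction,
         ld_subtype_proportions = ld_subtype_proportions,
         co_occurrence_rate = co_occurrence_rate, ctnnb1_prob = ctnnb1_prob,
         class_effects = class_effects, rspo_mu = rspo_mu,
         rspo_sigma = rspo_sigma, rspo_shift = rspo_shift,
         caf_genes = caf_genes, caf_mu = caf_mu, caf_sigma = caf_sigma,
         caf_shift = caf_shift, n_background = as.integer(n_background),
         background_mu = background_mu, background_sigma = background_sigma,
         library_size_log_mean = library_size_log_mean,
         library_size_log_sd = library_size_log_sd,
         meth_models = meth_models,
         probes_per_gene = as.integer(probes_per_gene),
         cimp_prevalence = cimp_prevalence,
         fusion_read_params = fusion_read_params,
         min_overlap = as.integer(min_overlap),
         overdispersion = overdispersion, seed = as.integer(seed)),
    class = "simulation_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1))
      stop("invalid config field '", nm, "': must be a probability in [0,1]",
           call. = FALSE)
  }
  if (cfg$n_samples < 0L)
    stop("invalid config field 'n_samples': must be >= 0", call. = FALSE)
  chk_prob(cfg$ld_fraction, "ld_fraction")
  chk_prob(cfg$co_occurrence_rate, "co_occurrence_rate")
  chk_prob(cfg$ctnnb1_prob, "ctnnb1_prob")
  chk_prob(cfg$cimp_prevalence, "cimp_prevalence")
  p <- cfg$ld_subtype_proportions
  if (!all(c("rspo_fusion", "rspo_high", "rnf43") %in% names(p)))
    stop("invalid config field 'ld_subtype_proportions': names must be ",
         "rspo_fusion, rspo_high, rnf43", call. = FALSE)
  chk_prob(p, "ld_subtype_proportions")
  if (abs(sum(p) - 1) > 1e-9)
    stop("invalid config field 'ld_subtype_proportions': must sum to 1",
         call. = FALSE)
  for (g in names(cfg$class_effects)) {
    e <- cfg$class_effects[[g]]
    if (length(e) != 3L || e[["sigma"]] <= 0)
      stop("invalid config field 'class_effects': ", g,
           " needs (mu_ld, mu_li, sigma) with sigma > 0", call. = FALSE)
  }
  if (cfg$probes_per_gene < 1L)
    stop("invalid config field 'probes_per_gene': must be >= 1",
         call. = FALSE)
  fp <- cfg$fusion_read_params
  if (fp$read_length < 2L * cfg$min_overlap)
    stop("invalid config field 'fusion_read_params': read_length must be ",
         ">= 2 * min_overlap", call. = FALSE)
  for (m in names(cfg$meth_models)) {
    mm <- cfg$meth_models[[m]]
    if (!mm$type %in% c("linear_coupled", "cimp_bimodal"))
      stop("invalid config field 'meth_models': unknown type for ", m,
           call. = FALSE)
  }
  invisible(cfg)
}

panel_genes <- function(cfg) {
  c(names(cfg$class_effects), "RSPO2", "RSPO3", cfg$caf_genes,
    sprintf("BG%03d", seq_len(cfg$n_background)))
}

#' Closed-form AUC implied by the generator for one gene
#'
#' For class-conditional Gaussian log2 expression the probability that a
#' random LI sample exceeds a random LD sample is
#' `pnorm((mu_li - mu_ld) / sqrt(sigma_ld^2 + sigma_li^2))`; the generator
#' uses a common sigma per gene. This is the parameter-recovery oracle for
#' the downstream ROC analysis.
#'
#' @param config a [simulation_config()].
#' @param gene gene symbol present in `class_effects`.
#' @return theoretical AUC in \[0,1\].
#' @export
theoretical_auc <- function(config, gene) {
  e <- config$class_effects[[gene]]
  if (is.null(e)) stop("unknown gene '", gene, "' in class_effects",
                       call. = FALSE)
  pnorm((e[["mu_li"]] - e[["mu_ld"]]) / sqrt(2 * e[["sigma"]]^2))
}

#' Simulate junction-spanning and background reads for one sample
#'
#' Junction reads each contain, as an exact substring, at least `min_overlap`
#' bases on both sides of the breakpoint; background reads are drawn from a
#' junction-free decoy sequence. A configurable fraction of reads is emitted
#' reverse-complemented. Qualities are constant.
#'
#' @param sample_id sample identifier used in read names.
#' @param junction a junction record (see [synthetic_junction_library()]).
#' @param params list with `read_length`, `n_junction_reads`,
#'   `n_background_reads`, `rc_fraction`.
#' @param seed integer seed.
#' @param min_overlap minimum bases on each side of the breakpoint.
#' @return A [Biostrings::DNAStringSet] of reads.
#' @export
simulate_junction_reads <- function(sample_id, junction, params, seed,
                                    min_overlap = 10L) {
  L <- params$read_length
  jlen <- nchar(junction$sequence)
  if (jlen < L)
    stop("config error for ", junction$fusion_id,
         ": junction shorter than read_length", call. = FALSE)
  off <- junction$breakpoint_offset
  # 0-based start s must satisfy s <= off - min_overlap and
  # s + L >= off + min_overlap, and 0 <= s <= jlen - L
  lo <- max(0L, off + min_overlap - L)
  hi <- min(jlen - L, off - min_overlap)
  if (hi < lo)
    stop("config error for ", junction$fusion_id,
         ": no read placement spans the breakpoint with min_overlap = ",
         min_overlap, call. = FALSE)
  set.seed(seed)
  nj <- params$n_junction_reads
  nb <- params$n_background_reads
  jr <- character(0)
  if (nj > 0) {
    starts <- sample(lo:hi, nj, replace = TRUE)
    jr <- substring(junction$sequence, starts + 1L, starts + L)
  }
  br <- character(0)
  if (nb > 0) {
    dstarts <- sample(seq_len(nchar(DECOY_SEQ) - L + 1L), nb, replace = TRUE)
    br <- substring(DECOY_SEQ, dstarts, dstarts + L - 1L)
  }
  reads <- Biostrings::DNAStringSet(c(jr, br))
  if (length(reads)) {
    names(reads) <- c(if (nj > 0) sprintf("%s_J%03d", sample_id, seq_len(nj)),
                      if (nb > 0) sprintf("%s_B%03d", sample_id, seq_len(nb)))
    rc <- runif(length(reads)) < (params$rc_fraction %||% 0)
    if (any(rc))
      reads[rc] <- Biostrings::reverseComplement(reads[rc])
  }
  reads
}

#' Simulate a multi-omic cohort with planted ground truth
#'
#' Draws per-sample LD/LI classes and LD subtypes, plants the corresponding
#' driver mutations (APC/CTNNB1 for LI, RNF43 for LD-RNF43) plus silent
#' passengers and rare opposite-class co-occurring drivers, generates
#' class-conditional Gaussian log2 expression converted to Poisson counts
#' around a compositional mean, couples AXIN2/NKD1 methylation to expression
#' on the logit scale, drives NOTUM/APCDD1 methylation by CIMP status, and
#' emits junction-spanning reads for RSPO-fusion samples.
#'
#' Identical `config` (including its `seed`) gives bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with `bundle` (a [cohort_bundle()]; reads held in memory as
#'   `DNAStringSet`s) and `truth` (data.frame of planted per-sample class,
#'   subtype, driver flags and CIMP status).
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  cfg <- config
  n <- cfg$n_samples
  genes <- panel_genes(cfg)
  lib <- synthetic_junction_library()

  if (n == 0L) {
    ann <- data.frame(sample_id = character(), cohort = character(),
                      cimp_status = character(), cms = character())
    mut <- data.frame(sample_id = character(), gene = character(),
                      variant_class = character(),
                      protein_position = integer())
    ev <- matrix(0L, nrow = length(genes), ncol = 0,
                 dimnames = list(genes, NULL))
    truth <- data.frame(sample_id = character(), true_class = character(),
                        true_subtype = character(),
                        planted_drivers = character(), cimp = logical())
    return(list(bundle = cohort_bundle(ann, mut,
                                       expr_matrix(ev, "counts")),
                truth = truth))
  }

  ids <- sprintf("S%04d", seq_len(n))

  ## --- layer 1: classes, subtypes, CIMP -------------------------------
  set.seed(cfg$seed + 1L)
  is_ld <- runif(n) < cfg$ld_fraction
  subtype <- rep("none", n)
  p <- cfg$ld_subtype_proportions
  subtype[is_ld] <- sample(c("RSPO_FUSION", "RSPO_HIGH", "RNF43"),
                           sum(is_ld), replace = TRUE,
                           prob = p[c("rspo_fusion", "rspo_high", "rnf43")])
  cimp <- runif(n) < cfg$cimp_prevalence
  # which RSPO gene carries the shift / fusion for each RSPO-driven sample
  rspo_gene <- rep(NA_character_, n)
  rspo_driven <- subtype %in% c("RSPO_FUSION", "RSPO_HIGH")
  rspo_gene[rspo_driven] <- sample(c("RSPO2", "RSPO3"), sum(rspo_driven),
                                   replace = TRUE)

  ## --- layer 2: mutations ---------------------------------------------
  set.seed(cfg$seed + 2L)
  hotspots <- default_ctnnb1_hotspots()
  mut <- list()
  drivers <- vector("list", n)
  add <- function(sample, gene, vc, pos)
    data.frame(sample_id = sample, gene = gene, variant_class = vc,
               protein_position = pos)
  for (i in seq_len(n)) {
    d <- character(0)
    if (!is_ld[i]) {
      if (runif(1) < cfg$ctnnb1_prob) {
        mut[[length(mut) + 1L]] <- add(ids[i], "CTNNB1", "missense",
                                       sample(hotspots, 1))
        d <- c(d, "ctnnb1_act")
      } else {
        mut[[length(mut) + 1L]] <- add(ids[i], "APC",
                                       sample(c("nonsense", "frameshift"), 1),
                                       sample(100:2800, 1))
        d <- c(d, "apc_lof")
      }
    } else if (subtype[i] == "RNF43") {
      mut[[length(mut) + 1L]] <- add(ids[i], "RNF43", "frameshift",
                                     sample(1:700, 1))
      d <- c(d, "rnf43_lof")
    } else {
      d <- c(d, if (subtype[i] == "RSPO_FUSION") "rspo_fusion"
             else "rspo_high")
    }
    if (runif(1) < cfg$co_occurrence_rate) {
      if (is_ld[i]) {
        mut[[length(mut) + 1L]] <- add(ids[i], "APC", "nonsense",
                                       sample(100:2800, 1))
        d <- c(d, "apc_lof")
      } else {
        mut[[length(mut) + 1L]] <- add(ids[i], "RNF43", "frameshift",
                                       sample(1:700, 1))
        d <- c(d, "rnf43_lof")
      }
    }
    npass <- rpois(1, 0.8)
    if (npass > 0)
      mut[[length(mut) + 1L]] <- add(rep(ids[i], npass),
                                     sample(genes, npass, replace = TRUE),
                                     "silent",
                                     sample(50:900, npass, replace = TRUE))
    drivers[[i]] <- d
  }
  mut <- if (length(mut)) do.call(rbind, mut) else
    data.frame(sample_id = character(), gene = character(),
               variant_class = character(), protein_position = integer())

  ## --- layer 3: expression --------------------------------------------
  set.seed(cfg$seed + 3L)
  mu <- matrix(0, nrow = length(genes), ncol = n,
               dimnames = list(genes, ids))
  sg <- setNames(rep(cfg$background_sigma, length(genes)), genes)
  for (g in names(cfg$class_effects)) {
    e <- cfg$class_effects[[g]]
    mu[g, ] <- ifelse(is_ld, e[["mu_ld"]], e[["mu_li"]])
    sg[g] <- e[["sigma"]]
  }
  for (g in c("RSPO2", "RSPO3")) {
    mu[g, ] <- cfg$rspo_mu + cfg$rspo_shift * (!is.na(rspo_gene) &
                                                 rspo_gene == g)
    sg[g] <- cfg$rspo_sigma
  }
  for (g in cfg$caf_genes) {
    mu[g, ] <- cfg$caf_mu + cfg$caf_shift * (subtype == "RSPO_HIGH")
    sg[g] <- cfg$caf_sigma
  }
  bg <- sprintf("BG%03d", seq_len(cfg$n_background))
  mu[bg, ] <- cfg$background_mu
  x <- mu + rnorm(length(mu)) * sg[rep(seq_along(genes), n)]
  libsize <- exp(rnorm(n, cfg$library_size_log_mean,
                       cfg$library_size_log_sd))
  prop <- sweep(2^x, 2, colSums(2^x), "/")
  lam <- sweep(prop, 2, libsize, "*")
  if (cfg$overdispersion > 1)
    lam <- lam * matrix(stats::rgamma(length(lam),
                                      shape = 1 / (cfg$overdispersion - 1),
                                      scale = cfg$overdispersion - 1),
                        nrow = nrow(lam))
  counts <- matrix(rpois(length(lam), lam), nrow = nrow(lam),
                   dimnames = dimnames(lam))

  ## --- layer 4: methylation -------------------------------------------
  set.seed(cfg$seed + 4L)
  k <- cfg$probes_per_gene
  mm <- cfg$meth_models
  probes <- unlist(lapply(names(mm), function(g) sprintf("%s_p%d", g,
                                                         seq_len(k))))
  beta <- matrix(NA_real_, nrow = length(probes), ncol = n,
                 dimnames = list(probes, ids))
  for (g in names(mm)) {
    m <- mm[[g]]
    for (j in seq_len(k)) {
      pr <- sprintf("%s_p%d", g, j)
      if (m$type == "linear_coupled") {
        lg <- m$intercept - m$slope * x[g, ] + rnorm(n, 0, m$noise)
        beta[pr, ] <- plogis(lg)
      } else {
        b <- ifelse(cimp, m$beta_high, m$beta_low) + rnorm(n, 0, m$noise)
        beta[pr, ] <- pmin(1, pmax(0, b))
      }
    }
  }
  probe_map <- data.frame(probe = probes,
                          gene = rep(names(mm), each = k))

  ## --- layer 5: fusion reads ------------------------------------------
  fusion_id <- rep(NA_character_, n)
  reads <- list()
  fus <- which(subtype == "RSPO_FUSION")
  for (i in fus) {
    jrec <- lib[[which(vapply(lib, `[[`, character(1), "gene") ==
                         rspo_gene[i])[1]]]
    fusion_id[i] <- jrec$fusion_id
    reads[[ids[i]]] <- simulate_junction_reads(
      ids[i], jrec, cfg$fusion_read_params,
      seed = cfg$seed + 5000L + i, min_overlap = cfg$min_overlap)
  }

  ## --- assemble ---------------------------------------------------------
  cms <- rep("unknown", n)
  cms[subtype == "RSPO_HIGH"] <- "CMS4"
  ann <- data.frame(sample_id = ids, cohort = "synthetic",
                    cimp_status = ifelse(cimp, "positive", "negative"),
                    cms = cms)
  truth <- data.frame(
    sample_id = ids,
    true_class = ifelse(is_ld, "LD", "LI"),
    true_subtype = subtype,
    planted_drivers = vapply(drivers, paste, character(1), collapse = ","),
    cimp = cimp,
    fusion_id = fusion_id)
  bundle <- cohort_bundle(
    annotation = ann, mutations = mut,
    expression = expr_matrix(counts, "counts"),
    methylation = meth_matrix(beta, probe_map),
    reads_by_sample = if (length(reads)) reads else NULL)
  list(bundle = bundle, truth = truth)
}

#' Write a simulated cohort to a directory
#'
#' Emits `annotation.tsv`, `mutations.tsv`, `expression.tsv` (counts),
#' `beta.tsv` + `probe_map.tsv`, `reads/<sample>.fastq`, `truth.tsv` and the
#' resolved configuration as `config.lock.yaml`. Output is byte-identical
#' for identical input.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param config the [simulation_config()] used (written as lock file).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- sim$bundle
  write.table(b$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, eol = "\n")
  write_mutations_tsv(b$mutations, file.path(dir, "mutations.tsv"))
  write_expression_tsv(b$expression, file.path(dir, "expression.tsv"))
  if (!is.null(b$methylation))
    write_methylation_tsv(b$methylation, file.path(dir, "beta.tsv"),
                          file.path(dir, "probe_map.tsv"))
  tr <- sim$truth
  tr$cimp <- as.character(tr$cimp)
  tr$fusion_id[is.na(tr$fusion_id)] <- ""
  write.table(tr, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  if (!is.null(b$reads_by_sample)) {
    rd <- file.path(dir, "reads")
    dir.create(rd, showWarnings = FALSE)
    for (s in names(b$reads_by_sample)) {
      r <- b$reads_by_sample[[s]]
      Biostrings::writeXStringSet(
        r, file.path(rd, paste0(s, ".fastq")), format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(r))))
    }
  }
  if (!is.null(config))
    yaml::write_yaml(c(list(schema_version = 1L), unclass(config)),
                     file.path(dir, "config.lock.yaml"))
  invisible(dir)
}
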