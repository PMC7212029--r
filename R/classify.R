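# Molecular ground truthing: fusion detection from reads, driver mutation
# interpretation, RSPO-high calling, LD/LI/EX class assignment, and the
# mutual-exclusivity summary.

DRIVER_FLAGS <- c("apc_lof", "ctnnb1_act", "rnf43_lof", "rspo_fusion",
                  "rspo_high")

#' Construct / read an RSPO fusion junction library
#'
#' A junction record holds the breakpoint-spanning sequence of one known
#' fusion: `sequence[0..offset)` is the upstream partner, `sequence[offset..)`
#' the RSPO portion (offset is 0-based). On disk the library is FASTA with a
#' `breakpoint=<offset>` tag and a `gene=<symbol>` tag in each description.
#'
#' @param records list of lists with fields `fusion_id`, `gene`, `sequence`,
#'   `breakpoint_offset`.
#' @return named list of records, class `junction_library`.
#' @export
junction_library <- function(records) {
  for (r in records) {
    if (!grepl("^[ACGT]+$", r$sequence))
      stop("junction ", r$fusion_id, ": sequence must be over {A,C,G,T}",
           call. = FALSE)
    if (r$breakpoint_offset <= 0L ||
        r$breakpoint_offset >= nchar(r$sequence))
      stop("junction ", r$fusion_id, ": breakpoint_offset must lie strictly ",
           "inside the sequence", call. = FALSE)
    if (!r$gene %in% c("RSPO2", "RSPO3"))
      stop("junction ", r$fusion_id, ": gene must be RSPO2 or RSPO3",
           call. = FALSE)
  }
  structure(setNames(records,
                     vapply(records, `[[`, character(1), "fusion_id")),
            class = "junction_library")
}

#' @rdname junction_library
#' @param path FASTA file whose descriptions carry `gene=` and `breakpoint=`
#'   tags.
#' @export
read_junction_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  recs <- lapply(seq_along(seqs), function(i) {
    desc <- names(seqs)[i]
    id <- sub("\\s.*$", "", desc)
    gene <- sub(".*gene=(\\S+).*", "\\1", desc)
    off <- suppressWarnings(as.integer(sub(".*breakpoint=(\\d+).*", "\\1",
                                           desc)))
    if (is.na(off))
      stop("junction ", id, ": missing breakpoint=<offset> tag",
           call. = FALSE)
    list(fusion_id = id, gene = gene,
         sequence = as.character(seqs[[i]]), breakpoint_offset = off)
  })
  junction_library(recs)
}

#' @rdname junction_library
#' @param library a `junction_library`.
#' @export
write_junction_fasta <- function(library, path) {
  seqs <- Biostrings::DNAStringSet(vapply(library, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- vapply(library, function(r)
    sprintf("%s gene=%s breakpoint=%d", r$fusion_id, r$gene,
            r$breakpoint_offset), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Detect RSPO fusions from RNA-seq reads of one sample
#'
#' A read supports a fusion if the read, or its reverse complement, contains
#' as an exact substring the junction window of `min_overlap` bases on each
#' side of the breakpoint. Calls are emitted where the supporting read count
#' reaches `min_supporting_reads`; each read counts at most once per fusion.
#'
#' @param reads a [Biostrings::DNAStringSet], or a FASTQ file path.
#' @param library a [junction_library()].
#' @param sample_id identifier recorded on the calls.
#' @param min_overlap bases required each side of the breakpoint (default 10).
#' @param min_supporting_reads minimum read support per call (default 1).
#' @return data.frame with columns sample_id, fusion_id, gene,
#'   supporting_reads (one row per emitted call).
#' @export
detect_fusions <- function(reads, library, sample_id = "sample",
                           min_overlap = 10L, min_supporting_reads = 1L) {
  if (is.character(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  empty <- data.frame(sample_id = character(), fusion_id = character(),
                      gene = character(), supporting_reads = integer())
  windows <- lapply(library, function(r) {
    off <- r$breakpoint_offset
    if (off < min_overlap || nchar(r$sequence) - off < min_overlap)
      stop("config error: min_overlap = ", min_overlap,
           " too large for junction ", r$fusion_id, call. = FALSE)
    substr(r$sequence, off - min_overlap + 1L, off + min_overlap)
  })
  if (length(reads) == 0L) return(empty)
  fwd <- as.character(reads)
  rev <- as.character(Biostrings::reverseComplement(reads))
  calls <- lapply(names(windows), function(fid) {
    w <- windows[[fid]]
    support <- grepl(w, fwd, fixed = TRUE) | grepl(w, rev, fixed = TRUE)
    n <- sum(support)
    if (n >= min_supporting_reads)
      data.frame(sample_id = sample_id, fusion_id = fid,
                 gene = library[[fid]]$gene, supporting_reads = n)
  })
  out <- do.call(rbind, calls)
  if (is.null(out)) empty else out
}

#' Default CTNNB1 exon-3 phosphodegron hotspot positions
#'
#' Serine/threonine codons of the beta-catenin degradation motif whose
#' missense mutation blocks phosphorylation-dependent degradation.
#'
#' @return integer vector of protein positions.
#' @export
default_ctnnb1_hotspots <- function() c(32L, 33L, 34L, 35L, 37L, 41L, 45L)

#' Interpret mutation records as Wnt driver events
#'
#' Truncating APC or RNF43 variants (nonsense, frameshift, splice site) are
#' loss-of-function drivers; CTNNB1 missense variants at a hotspot position
#' are activating. Everything else (silent, missense outside hotspots,
#' other genes) is no driver.
#'
#' @param mutations data.frame as from [read_mutations_tsv()].
#' @param hotspots named list `gene -> integer positions`; default CTNNB1
#'   exon-3 set.
#' @return the input with an added `driver_flag` column
#'   (`apc_lof`/`ctnnb1_act`/`rnf43_lof` or NA).
#' @export
classify_mutations <- function(mutations,
                               hotspots = list(
                                 CTNNB1 = default_ctnnb1_hotspots())) {
  lof <- c("nonsense", "frameshift", "splice_site")
  flag <- rep(NA_character_, nrow(mutations))
  flag[mutations$gene == "APC" & mutations$variant_class %in% lof] <-
    "apc_lof"
  flag[mutations$gene == "RNF43" & mutations$variant_class %in% lof] <-
    "rnf43_lof"
  hs <- hotspots[["CTNNB1"]] %||% integer()
  flag[mutations$gene == "CTNNB1" &
         mutations$variant_class == "missense" &
         !is.na(mutations$protein_position) &
         mutations$protein_position %in% hs] <- "ctnnb1_act"
  mutations$driver_flag <- flag
  mutations
}

#' @rdname classify_mutations
#' @param record a single-row mutation record (data.frame or list).
#' @return `classify_mutation`: the driver flag string, or NA if none.
#' @export
classify_mutation <- function(record,
                              hotspots = list(
                                CTNNB1 = default_ctnnb1_hotspots())) {
  classify_mutations(as.data.frame(record), hotspots)$driver_flag[1]
}

#' Flag RSPO-high samples
#'
#' A sample is RSPO-high if it carries an outlier-expression call
#' (z >= threshold, computed on log-CPM) for RSPO2 or RSPO3 and has no
#' fusion call for any RSPO gene: outlier expression is then attributed to a
#' stromal R-Spondin source rather than a fusion transcript.
#'
#' @param outliers data.frame from [zscore_outliers()] (RSPO2/RSPO3 rows are
#'   used).
#' @param fusions data.frame of fusion calls ([detect_fusions()] output,
#'   possibly row-bound over samples).
#' @return character vector of flagged sample ids.
#' @export
call_rspo_high <- function(outliers, fusions) {
  o <- outliers[outliers$gene %in% c("RSPO2", "RSPO3") & outliers$is_outlier,
                , drop = FALSE]
  setdiff(unique(o$sample_id), unique(fusions$sample_id))
}

#' Assemble per-sample Wnt driver profiles
#'
#' @param sample_ids all cohort sample ids.
#' @param mutations output of [classify_mutations()].
#' @param fusion_calls row-bound [detect_fusions()] output (may be empty).
#' @param rspo_high_samples character vector from [call_rspo_high()].
#' @return data.frame with one row per sample: the five driver flags as
#'   logicals plus an `evidence` list-column of supporting record
#'   descriptions (every TRUE flag has at least one entry).
#' @export
build_driver_profiles <- function(sample_ids, mutations,
                                  fusion_calls = NULL,
                                  rspo_high_samples = character()) {
  prof <- data.frame(sample_id = sample_ids)
  for (f in DRIVER_FLAGS) prof[[f]] <- FALSE
  ev <- setNames(vector("list", length(sample_ids)), sample_ids)
  mk <- function(flag, src) sprintf("%s: %s", flag, src)
  if (nrow(mutations)) {
    hit <- mutations[!is.na(mutations$driver_flag), , drop = FALSE]
    for (i in seq_len(nrow(hit))) {
      s <- hit$sample_id[i]; f <- hit$driver_flag[i]
      prof[[f]][prof$sample_id == s] <- TRUE
      ev[[s]] <- c(ev[[s]], mk(f, sprintf("%s %s p.%s", hit$gene[i],
                                          hit$variant_class[i],
                                          hit$protein_position[i])))
    }
  }
  if (!is.null(fusion_calls) && nrow(fusion_calls)) {
    for (i in seq_len(nrow(fusion_calls))) {
      s <- fusion_calls$sample_id[i]
      prof$rspo_fusion[prof$sample_id == s] <- TRUE
      ev[[s]] <- c(ev[[s]], mk("rspo_fusion",
                               sprintf("%s (%d reads)",
                                       fusion_calls$fusion_id[i],
                                       fusion_calls$supporting_reads[i])))
    }
  }
  for (s in intersect(rspo_high_samples, sample_ids)) {
    prof$rspo_high[prof$sample_id == s] <- TRUE
    ev[[s]] <- c(ev[[s]], mk("rspo_high", "RSPO2/3 outlier, no fusion"))
  }
  prof$evidence <- I(unname(ev[prof$sample_id]))
  prof
}

#' Assign LD / LI / EX class labels from driver profiles
#'
#' LI evidence is APC loss or CTNNB1 activation; LD evidence is RNF43 loss,
#' an RSPO fusion or RSPO-high status. Samples with both kinds of evidence
#' (reason `"concurrent"`) or neither (reason `"no driver"`) are excluded
#' (EX). LD samples get a subtype: RSPO_FUSION, then RNF43, then RSPO_HIGH
#' by flag priority, or AMBIGUOUS when more than one LD flag is set.
#'
#' @param profiles data.frame from [build_driver_profiles()].
#' @return data.frame with columns sample_id, label (LD/LI/EX), ld_subtype,
#'   reason.
#' @export
assign_class <- function(profiles) {
  li_ev <- profiles$apc_lof | profiles$ctnnb1_act
  n_ld_flags <- profiles$rnf43_lof + profiles$rspo_fusion +
    profiles$rspo_high
  ld_ev <- n_ld_flags > 0L
  label <- ifelse(li_ev & ld_ev, "EX",
                  ifelse(!li_ev & !ld_ev, "EX",
                         ifelse(li_ev, "LI", "LD")))
  subtype <- rep("none", nrow(profiles))
  is_ld <- label == "LD"
  subtype[is_ld & n_ld_flags > 1L] <- "AMBIGUOUS"
  single <- is_ld & n_ld_flags == 1L
  subtype[single & profiles$rspo_fusion] <- "RSPO_FUSION"
  subtype[single & profiles$rnf43_lof] <- "RNF43"
  subtype[single & profiles$rspo_high] <- "RSPO_HIGH"
  reason <- ifelse(li_ev & ld_ev, "concurrent",
                   ifelse(!li_ev & !ld_ev, "no driver",
                          ifelse(li_ev, "LI driver only",
                                 "LD driver only")))
  data.frame(sample_id = profiles$sample_id, label = label,
             ld_subtype = subtype, reason = reason)
}

#' Summarise mutual exclusivity of Wnt drivers
#'
#' @param profiles data.frame from [build_driver_profiles()].
#' @return list with `flag_counts` (samples carrying 0 / 1 / >=2 driver
#'   flags) and `co_occurrence` (symmetric 5x5 matrix of pairwise flag
#'   co-occurrence counts; diagonal = per-flag totals).
#' @export
exclusivity_summary <- function(profiles) {
  M <- as.matrix(as.data.frame(profiles[DRIVER_FLAGS])) * 1L
  if (nrow(profiles) == 0L)
    M <- matrix(0L, nrow = 0, ncol = length(DRIVER_FLAGS),
                dimnames = list(NULL, DRIVER_FLAGS))
  per_sample <- rowSums(M)
  co <- t(M) %*% M
  list(flag_counts = c(`0` = sum(per_sample == 0),
                       `1` = sum(per_sample == 1),
                       `>=2` = sum(per_sample >= 2)),
       co_occurrence = co)
}

#' Run the full ground-truthing stage on a cohort bundle
#'
#' Detects fusions from any per-sample reads, interprets mutations,
#' computes RSPO2/3 expression outliers on log-CPM, flags RSPO-high
#' samples, and assigns LD/LI/EX labels.
#'
#' @param bundle a [cohort_bundle()].
#' @param junctions a [junction_library()]; default the built-in synthetic
#'   one.
#' @param z_threshold outlier z-score cut-off (default 2).
#' @param min_overlap,min_supporting_reads fusion calling parameters.
#' @param hotspots hotspot table for [classify_mutations()].
#' @return list with `labels`, `profiles`, `fusion_calls`, `rspo_high`,
#'   `exclusivity`.
#' @export
classify_cohort <- function(bundle, junctions = synthetic_junction_library(),
                            z_threshold = 2, min_overlap = 10L,
                            min_supporting_reads = 1L,
                            hotspots = list(
                              CTNNB1 = default_ctnnb1_hotspots())) {
  samples <- bundle$annotation$sample_id
  fusion_calls <- do.call(rbind, c(
    list(data.frame(sample_id = character(), fusion_id = character(),
                    gene = character(), supporting_reads = integer())),
    lapply(names(bundle$reads_by_sample), function(s)
      detect_fusions(bundle$reads_by_sample[[s]], junctions, sample_id = s,
                     min_overlap = min_overlap,
                     min_supporting_reads = min_supporting_reads))))
  norm <- if (bundle$expression$space == "counts")
    log_cpm(bundle$expression) else bundle$expression
  outliers <- zscore_outliers(norm, c("RSPO2", "RSPO3"),
                              threshold = z_threshold)
  rspo_high <- call_rspo_high(outliers, fusion_calls)
  muts <- classify_mutations(bundle$mutations, hotspots)
  profiles <- build_driver_profiles(samples, muts, fusion_calls, rspo_high)
  list(labels = assign_class(profiles), profiles = profiles,
       fusion_calls = fusion_calls, rspo_high = rspo_high,
       exclusivity = exclusivity_summary(profiles))
}
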