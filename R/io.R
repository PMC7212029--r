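# Readers/writers for the on-disk formats (TSV matrices and tables, GMT gene
# sets) plus the CohortBundle container and its validator. All files are
# tab-separated UTF-8 with Unix newlines; '#'-prefixed lines are comments,
# except the mandatory '#space=' declaration in expression matrices.

VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice_site",
                     "inframe", "silent", "other")

# common MAF spellings -> closed vocabulary (matched case-insensitively)
VARIANT_ALIASES <- c(
  missense           = "missense",
  missense_mutation  = "missense",
  nonsense           = "nonsense",
  nonsense_mutation  = "nonsense",
  frameshift         = "frameshift",
  frame_shift_ins    = "frameshift",
  frame_shift_del    = "frameshift",
  splice_site        = "splice_site",
  inframe            = "inframe",
  in_frame_ins       = "inframe",
  in_frame_del       = "inframe",
  silent             = "silent",
  synonymous         = "silent",
  other              = "other"
)

CIMP_LEVELS <- c("positive", "negative", "unknown")
CMS_LEVELS  <- c("CMS1", "CMS2", "CMS3", "CMS4", "unknown")
EXPR_SPACES <- c("counts", "log_cpm", "log_arbitrary")

#' Construct an expression matrix
#'
#' A thin container for a gene-by-sample numeric matrix together with the
#' declared expression space. `counts` matrices must hold nonnegative
#' integers; `log_cpm` / `log_arbitrary` hold finite reals.
#'
#' @param values numeric matrix with gene symbols as rownames and sample ids
#'   as colnames.
#' @param space one of `"counts"`, `"log_cpm"`, `"log_arbitrary"`.
#' @param lib_sizes optional named per-sample library sizes (retained through
#'   normalisation).
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, space, lib_sizes = NULL) {
  space <- match.arg(space, EXPR_SPACES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("values must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ",
         rownames(values)[duplicated(rownames(values))][1], call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1], call. = FALSE)
  if (space == "counts" &&
      (any(values < 0) || any(values != round(values))))
    stop("counts matrix must contain nonnegative integers", call. = FALSE)
  structure(list(values = values, space = space, lib_sizes = lib_sizes),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (space=%s)\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

read_tsv_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  comment <- grepl("^#", lines)
  body <- lines[!comment]
  if (length(body) < 1L)
    stop("format error in ", path, ": no header row", call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("format error in ", path, ": duplicate sample id '",
         samples[duplicated(samples)][1], "'", call. = FALSE)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  n <- length(rows)
  ids <- character(n)
  vals <- matrix(NA_real_, nrow = n, ncol = length(samples))
  for (i in seq_len(n)) {
    f <- rows[[i]]
    if (length(f) != length(header))
      stop("format error in ", path, ": row ", i, " has ", length(f),
           " fields, expected ", length(header), call. = FALSE)
    ids[i] <- trimws(f[1])
    x <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(x))
    if (length(bad))
      stop("format error in ", path, ": non-numeric value '", f[-1][bad[1]],
           "' at row '", ids[i], "', column '", samples[bad[1]], "'",
           call. = FALSE)
    vals[i, ] <- x
  }
  if (anyDuplicated(ids))
    stop("format error in ", path, ": duplicate gene id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  dimnames(vals) <- list(ids, samples)
  list(values = vals, comments = lines[comment])
}

#' Read a gene-by-sample expression TSV
#'
#' The first column holds gene symbols, remaining columns one sample each.
#' A comment line `#space=counts|log_cpm|log_arbitrary` declaring the
#' expression space is required.
#'
#' @param path path to a TSV file.
#' @return An [expr_matrix()].
#' @export
read_expression_tsv <- function(path) {
  m <- read_tsv_matrix(path)
  sp <- sub("^#space=", "", grep("^#space=", m$comments, value = TRUE))
  if (length(sp) != 1L || !sp %in% EXPR_SPACES)
    stop("format error in ", path,
         ": missing or invalid '#space=' declaration", call. = FALSE)
  expr_matrix(m$values, space = sp)
}

#' Write an expression matrix as TSV
#'
#' Counts are written exactly; normalised values at 15 significant digits,
#' so a write/read round trip reproduces them to at least 12 digits.
#'
#' @param mat an [expr_matrix()].
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "expr_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  v <- mat$values
  fmt <- if (mat$space == "counts") function(x) sprintf("%d", as.integer(x))
         else function(x) sprintf("%.15g", x)
  writeLines(c(sprintf("#space=%s", mat$space),
               paste(c("gene", colnames(v)), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i)
                 paste(c(rownames(v)[i], fmt(v[i, ])), collapse = "\t"),
                 character(1))),
             con, sep = "\n")
  invisible(path)
}

#' Read a mutation table (minimal MAF-like dialect)
#'
#' Requires columns `sample_id`, `gene`, `variant_class`, `protein_position`
#' (position may be empty). Variant classes are normalised case-insensitively
#' through an alias table covering common MAF spellings
#' (`Nonsense_Mutation`, `Frame_Shift_Del`, ...). Fusions are not accepted
#' here; they arrive via RNA-seq reads.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns sample_id, gene, variant_class,
#'   protein_position (integer, NA when absent).
#' @export
read_mutations_tsv <- function(path) {
  d <- read.delim(path, sep = "\t", comment.char = "#",
                  colClasses = "character", check.names = FALSE)
  req <- c("sample_id", "gene", "variant_class", "protein_position")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(d) == 0L)
    return(data.frame(sample_id = character(), gene = character(),
                      variant_class = character(),
                      protein_position = integer()))
  vc <- VARIANT_ALIASES[tolower(trimws(d$variant_class))]
  if (anyNA(vc))
    stop("format error in ", path, ": unknown variant_class '",
         d$variant_class[which(is.na(vc))[1]], "'", call. = FALSE)
  pos <- trimws(d$protein_position)
  pos[pos == ""] <- NA_character_
  ipos <- suppressWarnings(as.integer(pos))
  if (any(!is.na(pos) & (is.na(ipos) | ipos < 1L)))
    stop("format error in ", path, ": protein_position must be a positive ",
         "integer or empty", call. = FALSE)
  data.frame(sample_id = trimws(d$sample_id), gene = trimws(d$gene),
             variant_class = unname(vc), protein_position = ipos)
}

#' @rdname read_mutations_tsv
#' @param mutations data.frame as returned by `read_mutations_tsv`.
#' @export
write_mutations_tsv <- function(mutations, path) {
  out <- mutations
  out$protein_position <- ifelse(is.na(out$protein_position), "",
                                 as.character(out$protein_position))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a line are deduplicated; duplicate set names are an error.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors, with a `description` attribute
#'   per set; class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("format error in ", path, ": line ", short[1],
         " has fewer than 3 fields", call. = FALSE)
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_))
    stop("format error in ", path, ": duplicate set name '",
         names_[duplicated(names_)][1], "'", call. = FALSE)
  sets <- lapply(fields, function(f) {
    g <- unique(trimws(f[-(1:2)]))
    attr(g, "description") <- f[2]
    g
  })
  names(sets) <- names_
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @param sets named list of character gene vectors (optionally carrying a
#'   `description` attribute each).
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene set names must be unique and non-missing", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("empty gene set: ", names(sets)[lengths(sets) == 0L][1],
         call. = FALSE)
  structure(sets, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    if (is.null(d)) d <- nm
    paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
  }, character(1)), con, sep = "\n")
  invisible(path)
}

#' Read a sample annotation table
#'
#' Columns: `sample_id`, `cohort`, `cimp_status` (positive/negative/unknown),
#' `cms` (CMS1-4/unknown).
#'
#' @param path path to a TSV file.
#' @return data.frame of per-sample annotation.
#' @export
read_annotation_tsv <- function(path) {
  d <- read.delim(path, sep = "\t", comment.char = "#",
                  colClasses = "character", check.names = FALSE)
  req <- c("sample_id", "cohort", "cimp_status", "cms")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- d[req]
  if (anyDuplicated(d$sample_id))
    stop("format error in ", path, ": duplicate sample_id '",
         d$sample_id[duplicated(d$sample_id)][1], "'", call. = FALSE)
  bad <- setdiff(unique(d$cimp_status), CIMP_LEVELS)
  if (length(bad))
    stop("format error in ", path, ": invalid cimp_status '", bad[1], "'",
         call. = FALSE)
  bad <- setdiff(unique(d$cms), CMS_LEVELS)
  if (length(bad))
    stop("format error in ", path, ": invalid cms '", bad[1], "'",
         call. = FALSE)
  d
}

#' Read a methylation beta matrix with its probe-to-gene map
#'
#' @param beta_path probe-by-sample TSV of beta values in \[0,1\].
#' @param probe_map_path two-column TSV (`probe`, `gene`).
#' @return list with `beta` (matrix), `probe_map` (data.frame); class
#'   `meth_matrix`.
#' @export
read_methylation_tsv <- function(beta_path, probe_map_path) {
  m <- read_tsv_matrix(beta_path)
  pm <- read.delim(probe_map_path, sep = "\t", comment.char = "#",
                   colClasses = "character", check.names = FALSE)
  meth_matrix(m$values, pm)
}

#' @rdname read_methylation_tsv
#' @param beta numeric probe-by-sample matrix in \[0,1\].
#' @param probe_map data.frame with columns `probe`, `gene`.
#' @export
meth_matrix <- function(beta, probe_map) {
  if (!all(c("probe", "gene") %in% names(probe_map)))
    stop("probe_map needs columns probe, gene", call. = FALSE)
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe id", call. = FALSE)
  if (any(beta < 0 | beta > 1))
    stop("beta values must lie in [0,1]", call. = FALSE)
  unk <- setdiff(probe_map$probe, rownames(beta))
  if (length(unk))
    stop("probe_map refers to unknown probe '", unk[1], "'", call. = FALSE)
  structure(list(beta = beta,
                 probe_map = probe_map[c("probe", "gene")]),
            class = "meth_matrix")
}

#' @rdname read_methylation_tsv
#' @param meth a `meth_matrix`.
#' @param beta_path,probe_map_path output paths.
#' @export
write_methylation_tsv <- function(meth, beta_path, probe_map_path) {
  con <- file(beta_path, "wb")
  v <- meth$beta
  writeLines(c(paste(c("probe", colnames(v)), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i)
                 paste(c(rownames(v)[i], sprintf("%.15g", v[i, ])),
                       collapse = "\t"), character(1))),
             con, sep = "\n")
  close(con)
  write.table(meth$probe_map, probe_map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n")
  invisible(beta_path)
}

#' Bundle the omic layers of one cohort
#'
#' @param annotation data.frame from [read_annotation_tsv()].
#' @param mutations data.frame from [read_mutations_tsv()].
#' @param expression an [expr_matrix()].
#' @param methylation optional `meth_matrix`.
#' @param reads_by_sample optional named list mapping sample ids to FASTQ
#'   paths or in-memory `DNAStringSet` read sets.
#' @return list of the layers, class `cohort_bundle`.
#' @export
cohort_bundle <- function(annotation, mutations, expression,
                          methylation = NULL, reads_by_sample = NULL) {
  structure(list(annotation = annotation, mutations = mutations,
                 expression = expression, methylation = methylation,
                 reads_by_sample = reads_by_sample),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "cohort_bundle: %d samples, %d mutation records, %d genes",
    " (expression), %s methylation, %d read sets\n"),
    nrow(x$annotation), nrow(x$mutations), nrow(x$expression$values),
    if (is.null(x$methylation)) "no" else
      sprintf("%d probes", nrow(x$methylation$beta)),
    length(x$reads_by_sample)))
  invisible(x)
}

#' Validate a cohort bundle
#'
#' Checks every container invariant (unique ids, enum values, beta range,
#' probe map integrity, counts integrality) plus cross-layer consistency:
#' every sample referenced by any layer must appear in the annotation, and
#' expression and methylation must share at least one sample. Violations are
#' returned as data, not raised.
#'
#' @param bundle a [cohort_bundle()].
#' @return character vector of violation messages; empty means valid.
#' @export
validate_bundle <- function(bundle) {
  v <- character()
  ann <- bundle$annotation
  if (anyDuplicated(ann$sample_id))
    v <- c(v, sprintf("duplicate sample_id in annotation: %s",
                      ann$sample_id[duplicated(ann$sample_id)][1]))
  bad <- setdiff(unique(ann$cimp_status), CIMP_LEVELS)
  if (length(bad)) v <- c(v, sprintf("invalid cimp_status: %s", bad[1]))
  bad <- setdiff(unique(ann$cms), CMS_LEVELS)
  if (length(bad)) v <- c(v, sprintf("invalid cms: %s", bad[1]))

  known <- ann$sample_id
  orphan <- function(ids, layer)
    sprintf("sample %s referenced by %s absent from annotation",
            setdiff(unique(ids), known), layer)
  v <- c(v, orphan(bundle$mutations$sample_id, "mutations"))
  v <- c(v, orphan(colnames(bundle$expression$values), "expression"))
  bad <- setdiff(unique(bundle$mutations$variant_class), VARIANT_CLASSES)
  if (length(bad)) v <- c(v, sprintf("invalid variant_class: %s", bad[1]))
  pp <- bundle$mutations$protein_position
  if (any(!is.na(pp) & pp < 1L))
    v <- c(v, "protein_position < 1 in mutations")

  ev <- bundle$expression$values
  if (bundle$expression$space == "counts" &&
      (any(ev < 0) || any(ev != round(ev))))
    v <- c(v, "expression declared counts but holds non-count values")

  if (!is.null(bundle$methylation)) {
    b <- bundle$methylation$beta
    v <- c(v, orphan(colnames(b), "methylation"))
    out <- which(b < 0 | b > 1, arr.ind = TRUE)
    if (nrow(out))
      v <- c(v, sprintf("beta outside [0,1] at probe %s, sample %s",
                        rownames(b)[out[1, 1]], colnames(b)[out[1, 2]]))
    unk <- setdiff(bundle$methylation$probe_map$probe, rownames(b))
    if (length(unk))
      v <- c(v, sprintf("probe_map refers to unknown probe %s", unk[1]))
    if (!length(intersect(colnames(b), colnames(ev))))
      v <- c(v, "expression and methylation share no sample")
  }
  if (!is.null(bundle$reads_by_sample))
    v <- c(v, orphan(names(bundle$reads_by_sample), "reads"))
  v
}
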