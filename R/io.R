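#' Read a BED file of peaks
#'
#' Parses BED 3-6+ (0-based half-open). Columns 1-6 are interpreted as
#' chrom, start, end, name, score, strand; any further columns (narrowPeak /
#' broadPeak extensions) are preserved opaquely in `extra` and restored
#' verbatim by [write_bed()]. `track`, `browser` and `#` comment lines are
#' skipped. Records are returned in file order; sorting is an explicit
#' downstream operation.
#'
#' @param path path to a BED file.
#' @param normalize_chrom_names `"none"` (default, names taken literally),
#'   `"strip"` (remove a leading `"chr"`) or `"add"` (prepend `"chr"` where
#'   missing). Mixing annotation sources with inconsistent naming is the most
#'   common silent failure in peak analysis, hence the explicit flag.
#' @return an [intervals()] data frame in file order.
#' @export
read_bed <- function(path, normalize_chrom_names = c("none", "strip", "add")) {
  normalize_chrom_names <- match.arg(normalize_chrom_names)
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(is_data)
  lines <- lines[is_data]
  if (length(lines) == 0L) return(empty_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED parse error at line %d of %s: fewer than 3 fields",
                 lineno[which(nf < 3L)[1]], path))
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get(1L)
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d of %s: bad coordinates '%s'",
                 lineno[bad[1]], path, lines[bad[1]]))
  chrom <- switch(normalize_chrom_names,
                  none = chrom,
                  strip = sub("^chr", "", chrom),
                  add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)))
  extra <- vapply(fields, function(f) {
    if (length(f) > 6L) paste(f[-(1:6)], collapse = "\t") else NA_character_
  }, "")
  strand <- get(6L)
  strand[!is.na(strand) & strand == "."] <- NA_character_  # "." round-trips as "."
  intervals(chrom = chrom, start = start, end = end,
            name = get(4L), score = get(5L), strand = strand, extra = extra)
}

#' Write intervals as BED
#'
#' Emits as many of the BED columns as are populated; a round trip through
#' [read_bed()] then `write_bed()` reproduces a well-formed input file
#' byte-identically (scores and extra columns are carried as text).
#'
#' @param x an [intervals()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  cols <- list(x$chrom, x$start, x$end, x$name, x$score, x$strand, x$extra)
  # trailing all-NA columns are omitted; interior NAs become "."
  keep <- 7L
  while (keep > 3L && all(is.na(cols[[keep]]))) keep <- keep - 1L
  lines <- do.call(paste, c(lapply(cols[seq_len(keep)], function(v) {
    v <- as.character(v); v[is.na(v)] <- "."; v
  }), sep = "\t"))
  if (nrow(x) == 0L) lines <- character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a TSV with header columns `gene_id, chrom, strand, tss, biotype`;
#' `tss` is the 0-based position of the first transcribed base. Duplicate
#' gene identifiers and strands outside `{+,-}` are errors.
#'
#' @param path path to the TSV.
#' @inheritParams read_bed
#' @return a `data.frame` with the five columns, one row per gene.
#' @export
read_gene_table <- function(path, normalize_chrom_names = c("none", "strip", "add")) {
  normalize_chrom_names <- match.arg(normalize_chrom_names)
  if (!file.exists(path)) stop("gene table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("gene_id", "chrom", "strand", "tss", "biotype")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  df$tss <- suppressWarnings(as.integer(df$tss))
  validate_gene_table(df)
  df$chrom <- switch(normalize_chrom_names,
                     none = df$chrom,
                     strip = sub("^chr", "", df$chrom),
                     add = ifelse(grepl("^chr", df$chrom), df$chrom, paste0("chr", df$chrom)))
  df
}

validate_gene_table <- function(df) {
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) stop("duplicate gene_id in gene table: ", dup[1])
  if (any(!df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-' (got '",
         df$strand[which(!df$strand %in% c("+", "-"))[1]], "')")
  if (anyNA(df$tss) || any(df$tss < 0L)) stop("tss must be a non-negative integer")
  invisible(df)
}

#' Read a gene-by-cell-type expression table
#'
#' TSV with first column `gene_id` and one numeric non-negative column per
#' cell type. Genes present in the table but absent from an annotation (and
#' vice versa) are reported, never silently dropped: see `unmatched`.
#'
#' @param path path to the TSV.
#' @param genes optional gene table (from [read_gene_table()]) to match
#'   against.
#' @return list with `matrix` (genes x cell types, rownames = gene_id) and
#'   `unmatched` (list of `in_expression_only`, `in_annotation_only`;
#'   both empty if `genes` is `NULL`).
#' @export
read_expression_table <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("expression table must start with a gene_id column")
  if (ncol(df) < 2L) stop("expression table has no cell-type columns")
  ids <- as.character(df$gene_id)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("expression values must be numeric")
  if (anyNA(m)) stop("expression values must not be missing")
  if (any(m < 0)) stop("expression values must be non-negative")
  rownames(m) <- ids
  unmatched <- list(in_expression_only = character(), in_annotation_only = character())
  if (!is.null(genes)) {
    unmatched$in_expression_only <- setdiff(ids, genes$gene_id)
    unmatched$in_annotation_only <- setdiff(genes$gene_id, ids)
  }
  list(matrix = m, unmatched = unmatched)
}

#' Write a run summary as JSON
#'
#' @param summary a named list of counts, thresholds and tables.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
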