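CANONICAL_MARKS <- c("H3K4me3", "H3K27ac", "H3K4me1", "H3K27me3")

#' Promoter window of a gene
#'
#' The promoter is the region from `upstream_bp` bases upstream of the TSS
#' through `downstream_bp` bases downstream of it (the TSS base counts as
#' the first downstream base), strand-aware, clamped at position 0. With the
#' defaults (1000 up, 10 down) the window is 1010 bp wide.
#'
#' @param tss integer vector of 0-based TSS positions.
#' @param strand character vector in `{+,-}`.
#' @param upstream_bp,downstream_bp window extent in bases.
#' @return data.frame with `start`, `end` (0-based half-open).
#' @export
promoter_window <- function(tss, strand, upstream_bp = 1000L, downstream_bp = 10L) {
  stopifnot(all(strand %in% c("+", "-")), upstream_bp >= 0L, downstream_bp >= 1L)
  plus <- strand == "+"
  start <- ifelse(plus, tss - upstream_bp, tss - downstream_bp + 1L)
  end <- ifelse(plus, tss + downstream_bp, tss + upstream_bp + 1L)
  start <- pmax(0L, as.integer(start))
  data.frame(start = start, end = as.integer(end))
}

#' Classify a regulatory element from its histone marks
#'
#' Rule table (evaluated in order; the "active marks" are H3K4me3 and
#' H3K27ac at promoters, H3K27ac alone at enhancers):
#'
#' * promoter: **active** iff both H3K4me3 and H3K27ac present; else
#'   **repressed** iff H3K27me3 present and no active mark; else **poised**
#'   iff H3K4me1 present, H3K27me3 absent and no active mark; else
#'   unclassified.
#' * enhancer: **active** iff H3K27ac; else **repressed** iff H3K27me3;
#'   else **poised** iff H3K4me1; else unclassified.
#'
#' Bivalent promoters (H3K4me3 + H3K27me3, no H3K27ac, no H3K4me1) fall
#' through to unclassified: the active rule needs both active marks and the
#' repressed rule forbids any; set `bivalent_as = "poised"` to override.
#'
#' @param marks character vector, a subset of
#'   `c("H3K4me3","H3K27ac","H3K4me1","H3K27me3")`.
#' @param locus_kind `"promoter"` or `"enhancer"`.
#' @param bivalent_as state assigned to bivalent promoters.
#' @return one of `"active"`, `"repressed"`, `"poised"`, `"unclassified"`.
#' @export
classify_element <- function(marks, locus_kind = c("promoter", "enhancer"),
                             bivalent_as = c("unclassified", "poised")) {
  locus_kind <- match.arg(locus_kind)
  bivalent_as <- match.arg(bivalent_as)
  unknown <- setdiff(marks, CANONICAL_MARKS)
  if (length(unknown)) stop("unknown histone mark: ", unknown[1])
  has <- CANONICAL_MARKS %in% marks
  names(has) <- CANONICAL_MARKS
  if (locus_kind == "promoter") {
    active_marks <- has["H3K4me3"] || has["H3K27ac"]
    if (has["H3K4me3"] && has["H3K27ac"]) return("active")
    if (has["H3K27me3"] && !active_marks) return("repressed")
    if (has["H3K4me1"] && !has["H3K27me3"] && !active_marks) return("poised")
    if (bivalent_as == "poised" &&
        has["H3K4me3"] && has["H3K27me3"] && !has["H3K27ac"] && !has["H3K4me1"])
      return("poised")
    return("unclassified")
  }
  if (has["H3K27ac"]) return("active")
  if (has["H3K27me3"]) return("repressed")
  if (has["H3K4me1"]) return("poised")
  "unclassified"
}

#' Annotate the regulatory landscape from histone-mark peaks
#'
#' Produces one promoter element per gene (its strand-aware promoter window,
#' annotated with every mark whose peaks overlap the window by at least 1 bp)
#' plus enhancer elements: the maximal merged runs of mark coverage outside
#' all promoter windows, each annotated with the marks covering at least 1 bp
#' of the run. Every base of every mark peak is thereby accounted for either
#' inside a promoter window or in the enhancer footprint.
#'
#' @param mark_peaks named list of [intervals()] sets; names must be drawn
#'   from the four canonical marks.
#' @param genes gene table (see [read_gene_table()]).
#' @param upstream_bp,downstream_bp promoter window extent.
#' @param bivalent_as passed to [classify_element()].
#' @return data.frame of elements with columns `chrom, start, end,
#'   locus_kind, state, marks` (comma-separated), `gene_id` (NA for
#'   enhancers).
#' @export
annotate_landscape <- function(mark_peaks, genes,
                               upstream_bp = 1000L, downstream_bp = 10L,
                               bivalent_as = "unclassified") {
  unknown <- setdiff(names(mark_peaks), CANONICAL_MARKS)
  if (length(unknown)) stop("unknown histone mark: ", unknown[1])
  win <- promoter_window(genes$tss, genes$strand, upstream_bp, downstream_bp)
  prom <- intervals(chrom = genes$chrom, start = win$start, end = win$end,
                    name = genes$gene_id, strand = genes$strand)
  mark_of_prom <- lapply(names(mark_peaks), function(mk) {
    hit <- overlap_bp_per_anchor(prom, mark_peaks[[mk]]) >= 1L
    ifelse(hit, mk, NA_character_)
  })
  prom_marks <- apply(do.call(cbind, c(mark_of_prom, list(rep(NA_character_, nrow(prom))))),
                      1L, function(r) paste(r[!is.na(r)], collapse = ","))
  prom_state <- vapply(prom_marks, function(m) {
    classify_element(strsplit(m, ",", fixed = TRUE)[[1L]], "promoter", bivalent_as)
  }, "", USE.NAMES = FALSE)
  prom_df <- data.frame(chrom = prom$chrom, start = prom$start, end = prom$end,
                        locus_kind = "promoter", state = prom_state,
                        marks = prom_marks, gene_id = genes$gene_id,
                        stringsAsFactors = FALSE)

  all_marks <- if (length(mark_peaks) == 0L) empty_intervals() else
    normalize_intervals(do.call(rbind, lapply(mark_peaks, function(p) {
      p <- as_intervals(p)
      data.frame(chrom = p$chrom, start = p$start, end = p$end,
                 stringsAsFactors = FALSE)
    })))
  enh <- interval_subtract(all_marks, prom)
  if (nrow(enh) > 0L) {
    mark_of_enh <- lapply(names(mark_peaks), function(mk) {
      hit <- overlap_bp_per_anchor(enh, mark_peaks[[mk]]) >= 1L
      ifelse(hit, mk, NA_character_)
    })
    enh_marks <- apply(do.call(cbind, c(mark_of_enh, list(rep(NA_character_, nrow(enh))))),
                       1L, function(r) paste(r[!is.na(r)], collapse = ","))
    enh_state <- vapply(enh_marks, function(m) {
      classify_element(strsplit(m, ",", fixed = TRUE)[[1L]], "enhancer", bivalent_as)
    }, "", USE.NAMES = FALSE)
    enh_df <- data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                         locus_kind = "enhancer", state = enh_state,
                         marks = enh_marks, gene_id = NA_character_,
                         stringsAsFactors = FALSE)
  } else {
    enh_df <- prom_df[0, , drop = FALSE]
  }
  out <- rbind(prom_df, enh_df)
  rownames(out) <- NULL
  out
}

#' Replicate-consensus peak set
#'
#' Keeps the replicate-1 peaks (whole, original coordinates) that either
#' overlap any replicate-2 peak or overlap any regulatory element; the two
#' rescue routes are unioned and deduplicated, so the result is always a
#' subset of replicate 1.
#'
#' @param rep1,rep2 [intervals()] peak sets for the two replicates.
#' @param regulatory [intervals()] of regulatory elements (may be empty).
#' @param min_overlap_bp minimum shared bases for either route.
#' @return subset of `rep1` in original order.
#' @export
consensus_peaks <- function(rep1, rep2, regulatory = empty_intervals(),
                            min_overlap_bp = 1L) {
  rep1 <- as_intervals(rep1)
  in_both <- overlap_bp_per_anchor(rep1, rep2) >= min_overlap_bp
  in_reg <- if (nrow(as_intervals(regulatory)) > 0L)
    overlap_bp_per_anchor(rep1, regulatory) >= min_overlap_bp
  else rep(FALSE, nrow(rep1))
  out <- rep1[in_both | in_reg, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export regulatory elements as BED9
#'
#' Name column is `state:locus_kind`; itemRgb encodes the state (active
#' green, repressed red, poised orange, unclassified grey).
#'
#' @param elements data.frame from [annotate_landscape()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(elements, path) {
  rgb <- c(active = "0,160,0", repressed = "200,0,0",
           poised = "230,140,0", unclassified = "150,150,150")
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t.\t%d\t%d\t%s",
                   elements$chrom, elements$start, elements$end,
                   paste0(elements$state, ":", elements$locus_kind),
                   elements$start, elements$end, rgb[elements$state])
  writeLines(lines, path)
  invisible(path)
}
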