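#' Construct a set of genomic intervals
#'
#' Intervals are the atom of every set operation in the screen. Coordinates
#' are 0-based half-open throughout the package: an interval covers bases
#' `start, start+1, ..., end-1`. BED maps onto this convention directly.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer vectors; `0 <= start < end` elementwise.
#' @param name optional character vector of interval names (`NA` allowed).
#' @param score optional score column, kept as character so that BED
#'   round-trips are byte-identical; never used in computation.
#' @param strand optional character vector in `"+"`, `"-"` or `NA`.
#' @param extra optional character vector holding any BED columns beyond 6,
#'   preserved opaquely.
#' @return a `data.frame` of class `"intervals"` with columns
#'   `chrom, start, end, name, score, strand, extra`.
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer(),
                      name = NA_character_, score = NA_character_,
                      strand = NA_character_, extra = NA_character_) {
  n <- length(chrom)
  x <- data.frame(
    chrom  = as.character(chrom),
    start  = as.integer(start),
    end    = as.integer(end),
    name   = rep_len(as.character(name), n),
    score  = rep_len(as.character(score), n),
    strand = rep_len(as.character(strand), n),
    extra  = rep_len(as.character(extra), n),
    stringsAsFactors = FALSE
  )
  class(x) <- c("intervals", "data.frame")
  validate_intervals(x)
  x
}

#' Validate interval invariants
#'
#' Checks `0 <= start < end` and non-empty chromosome names; stops with an
#' informative message on the first violation.
#'
#' @param x an `intervals` data frame.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end))
    stop("interval coordinates must be integers, not NA")
  bad <- which(x$start < 0L | x$start >= x$end)
  if (length(bad))
    stop(sprintf("invalid interval at row %d: start=%d end=%d (need 0 <= start < end)",
                 bad[1], x$start[bad[1]], x$end[bad[1]]))
  if (any(!nzchar(x$chrom) | is.na(x$chrom)))
    stop("chromosome names must be non-empty")
  bad_strand <- !is.na(x$strand) & !x$strand %in% c("+", "-")
  if (any(bad_strand))
    stop(sprintf("strand must be '+', '-' or NA (got '%s')", x$strand[which(bad_strand)[1]]))
  invisible(x)
}

empty_intervals <- function() intervals()

as_intervals <- function(x) {
  if (inherits(x, "intervals")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  intervals(chrom = x$chrom, start = x$start, end = x$end,
            name = if ("name" %in% names(x)) x$name else NA_character_,
            score = if ("score" %in% names(x)) x$score else NA_character_,
            strand = if ("strand" %in% names(x)) x$strand else NA_character_,
            extra = if ("extra" %in% names(x)) x$extra else NA_character_)
}

#' Sort and merge an interval set
#'
#' Sorts by (chrom, start, end) and merges overlapping *or touching*
#' intervals (abutting intervals `[a,b)` and `[b,c)` merge into `[a,c)`:
#' region semantics are footprint-based). Names, scores and strands are
#' dropped on merged output. Total covered length is preserved or reduced,
#' never increased.
#'
#' @param x an `intervals` data frame.
#' @return a normalized `intervals` data frame: sorted, pairwise
#'   non-overlapping and non-touching within each chromosome.
#' @export
normalize_intervals <- function(x) {
  x <- as_intervals(x)
  if (nrow(x) == 0L) return(empty_intervals())
  o <- order(x$chrom, x$start, x$end)
  chrom <- x$chrom[o]; start <- x$start[o]; end <- x$end[o]
  # run id increments where a new chrom starts or the running max end < start
  n <- length(start)
  run <- integer(n); run[1] <- 1L
  cur_end <- end[1]
  for (i in seq_len(n)[-1]) {
    if (chrom[i] != chrom[i - 1L] || start[i] > cur_end) {
      run[i] <- run[i - 1L] + 1L
      cur_end <- end[i]
    } else {
      run[i] <- run[i - 1L]
      cur_end <- max(cur_end, end[i])
    }
  }
  first <- which(!duplicated(run))
  last <- c(first[-1L] - 1L, n)
  intervals(chrom = chrom[first],
            start = start[first],
            end = vapply(seq_along(first),
                         function(g) max(end[first[g]:last[g]]), integer(1)))
}

#' Do two single intervals overlap?
#'
#' True iff same chromosome and the intervals share at least one base under
#' half-open semantics: `a$start < b$end && b$start < a$end`. Abutting
#' intervals do not overlap.
#'
#' @param a,b single-row `intervals` (or data frames with chrom/start/end).
#' @return logical scalar.
#' @export
intervals_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Total number of bases covered by an interval set
#' @param x an `intervals` data frame.
#' @return integer number of covered bases (overlaps counted once).
#' @export
covered_length <- function(x) {
  x <- normalize_intervals(x)
  if (nrow(x) == 0L) return(0L)
  sum(x$end - x$start)
}

#' Common footprint of several interval sets
#'
#' Returns the maximal runs of bases covered by at least one interval from
#' *every* input set, per chromosome (the Venn-diagram core of a multi-factor
#' co-binding analysis). The result is normalized.
#'
#' @param sets non-empty list of `intervals` data frames.
#' @return normalized `intervals` of the common footprint.
#' @export
multi_intersect <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("multi_intersect requires a non-empty list of interval sets")
  sets <- lapply(sets, normalize_intervals)
  k <- length(sets)
  if (k == 1L) return(sets[[1L]])
  if (any(vapply(sets, nrow, 0L) == 0L)) return(empty_intervals())
  # sweep: +1 at each start, -1 at each end; emit runs where depth == k.
  # each set is normalized so depth == number of sets covering a base.
  ev_chrom <- unlist(lapply(sets, function(s) rep(s$chrom, 2L)))
  ev_pos <- unlist(lapply(sets, function(s) c(s$start, s$end)))
  ev_d <- unlist(lapply(sets, function(s) rep(c(1L, -1L), each = nrow(s))))
  o <- order(ev_chrom, ev_pos, -ev_d)  # starts before ends at equal pos
  ev_chrom <- ev_chrom[o]; ev_pos <- ev_pos[o]; ev_d <- ev_d[o]
  out_chrom <- character(); out_start <- integer(); out_end <- integer()
  depth <- 0L; open_at <- NA_integer_; cur <- ""
  for (i in seq_along(ev_pos)) {
    if (ev_chrom[i] != cur) { depth <- 0L; cur <- ev_chrom[i] }
    prev <- depth
    depth <- depth + ev_d[i]
    if (prev < k && depth == k) {
      open_at <- ev_pos[i]
    } else if (prev == k && depth < k) {
      if (ev_pos[i] > open_at) {
        out_chrom <- c(out_chrom, cur)
        out_start <- c(out_start, open_at)
        out_end <- c(out_end, ev_pos[i])
      }
    }
  }
  if (length(out_start) == 0L) return(empty_intervals())
  normalize_intervals(intervals(out_chrom, out_start, out_end))
}

overlap_bp_per_anchor <- function(anchor, other) {
  # for each anchor interval, total bases shared with the footprint of `other`
  other <- normalize_intervals(other)
  n <- nrow(anchor)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  if (nrow(other) == 0L) return(out)
  for (ch in unique(anchor$chrom)) {
    ai <- which(anchor$chrom == ch)
    oi <- which(other$chrom == ch)
    if (length(oi) == 0L) next
    os <- other$start[oi]; oe <- other$end[oi]
    for (j in ai) {
      w <- pmin(anchor$end[j], oe) - pmax(anchor$start[j], os)
      out[j] <- sum(w[w > 0L])
    }
  }
  out
}

#' Keep anchor intervals that overlap another set
#'
#' Returns the subset of `anchor` intervals, kept whole with their original
#' coordinates and annotation columns, that share at least `min_overlap_bp`
#' bases with the footprint of `other`.
#'
#' @param anchor,other `intervals` data frames.
#' @param min_overlap_bp minimum shared bases (default 1, the bedtools
#'   convention).
#' @return the overlapping subset of `anchor`, in original order.
#' @export
filter_overlapping <- function(anchor, other, min_overlap_bp = 1L) {
  anchor <- as_intervals(anchor)
  keep <- overlap_bp_per_anchor(anchor, other) >= min_overlap_bp
  out <- anchor[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subtract one footprint from another
#'
#' Bases covered by `a` but not by `b`, as a normalized interval set.
#'
#' @param a,b `intervals` data frames.
#' @return normalized `intervals` of the difference footprint.
#' @export
interval_subtract <- function(a, b) {
  a <- normalize_intervals(a)
  b <- normalize_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  out_chrom <- character(); out_start <- integer(); out_end <- integer()
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    bi <- which(b$chrom == a$chrom[i] & b$start < e & b$end > s)
    cuts <- b[bi, , drop = FALSE]
    cuts <- cuts[order(cuts$start), , drop = FALSE]
    pos <- s
    for (j in seq_len(nrow(cuts))) {
      if (cuts$start[j] > pos) {
        out_chrom <- c(out_chrom, a$chrom[i])
        out_start <- c(out_start, pos); out_end <- c(out_end, cuts$start[j])
      }
      pos <- max(pos, cuts$end[j])
    }
    if (pos < e) {
      out_chrom <- c(out_chrom, a$chrom[i])
      out_start <- c(out_start, pos); out_end <- c(out_end, e)
    }
  }
  if (length(out_start) == 0L) return(empty_intervals())
  intervals(out_chrom, out_start, out_end)
}

#' Distance from a point to an interval
#'
#' 0 if the point lies within `[start, end)`; otherwise the distance in
#' bases to the nearest covered base. Chromosome agreement is the caller's
#' responsibility. Vectorized over intervals.
#'
#' @param point integer genomic position (0-based).
#' @param start,end integer vectors defining half-open intervals.
#' @return integer vector of distances.
#' @export
point_interval_distance <- function(point, start, end) {
  inside <- point >= start & point < end
  d <- pmin(abs(point - start), abs(point - (end - 1L)))
  d[inside] <- 0L
  as.integer(d)
}
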