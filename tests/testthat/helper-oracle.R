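# Per-base boolean-array oracle for the interval algebra: every set
# operation is re-derived by literally painting bases of one small
# chromosome and reading runs back off the array.

oracle_cover <- function(x, len, chrom = "chr1") {
  v <- logical(len)
  x <- as.data.frame(x)
  for (i in seq_len(nrow(x))) {
    if (x$chrom[i] != chrom) next
    lo <- x$start[i] + 1L
    hi <- min(len, x$end[i])
    if (lo <= hi) v[lo:hi] <- TRUE
  }
  v
}

runs_from_cover <- function(v, chrom = "chr1") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(intervals())
  intervals(chrom, starts[keep], ends[keep])
}

oracle_normalize <- function(x, len) runs_from_cover(oracle_cover(x, len))

oracle_multi_intersect <- function(sets, len) {
  runs_from_cover(Reduce(`&`, lapply(sets, oracle_cover, len = len)))
}

oracle_filter_overlapping <- function(anchor, other, len) {
  co <- oracle_cover(other, len)
  keep <- vapply(seq_len(nrow(anchor)), function(i) {
    any(co[(anchor$start[i] + 1L):anchor$end[i]])
  }, logical(1))
  out <- anchor[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_subtract <- function(a, b, len) {
  runs_from_cover(oracle_cover(a, len) & !oracle_cover(b, len))
}

random_interval_set <- function(n_max = 50L, len = 10000L) {
  n <- sample.int(n_max, 1L)
  s <- sample.int(len - 1L, n, replace = TRUE) - 1L
  w <- sample.int(300L, n, replace = TRUE)
  intervals("chr1", s, pmin(len, s + w))
}

coords <- function(x) {
  data.frame(chrom = as.character(x$chrom), start = as.integer(x$start),
             end = as.integer(x$end), stringsAsFactors = FALSE)
}

expect_same_intervals <- function(got, want) {
  expect_equal(coords(got), coords(want))
}
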