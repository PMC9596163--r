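#' Counts per million
#'
#' Library-size normalization: each column is divided by its sum and scaled
#' to one million, so every sample column sums to exactly 1e6 (up to
#' floating-point tolerance).
#'
#' @param counts numeric matrix of non-negative counts (genes x samples), or
#'   a vector for a single sample.
#' @return matrix (or vector) of CPM values.
#' @export
cpm <- function(counts) {
  if (is.null(dim(counts))) {
    ls <- sum(counts)
    if (ls <= 0) stop("library size must be positive")
    return(counts / ls * 1e6)
  }
  ls <- colSums(counts)
  if (any(ls <= 0)) stop("library size must be positive in every sample")
  sweep(counts, 2L, ls, "/") * 1e6
}

#' Classify genes into four expression bands
#'
#' The reference-sample values are cut at the first quartile, the mean and
#' the third quartile (quantiles by linear interpolation, R type 7):
#' **not** expressed below q1, **low** from q1 up to (excluding) the mean,
#' **medium** from the mean through q3 inclusive, **high** above q3. For
#' strongly skewed data the mean can exceed q3, in which case values between
#' q3 and the mean are still "low" (the band boundaries are evaluated in
#' that order); classes remain exhaustive and mutually exclusive.
#'
#' @param values named numeric vector of expression in the reference cell
#'   type; at least 4 values.
#' @return list with `thresholds` (`q1`, `mean`, `q3`) and `classes`, a
#'   character vector parallel to `values` (named if `values` is).
#' @export
classify_expression <- function(values) {
  if (length(values) < 4L) stop("need at least 4 values to classify expression")
  if (anyNA(values)) stop("expression values must not be missing")
  q1 <- unname(stats::quantile(values, 0.25, type = 7))
  q3 <- unname(stats::quantile(values, 0.75, type = 7))
  mu <- mean(values)
  cls <- ifelse(values < q1, "not",
                ifelse(values < mu, "low",
                       ifelse(values <= q3, "medium", "high")))
  names(cls) <- names(values)
  list(thresholds = list(q1 = q1, mean = mu, q3 = q3), classes = cls)
}

#' Cell-type specificity scores and ranks
#'
#' For each candidate gene the score compares its expression in the target
#' cell type with the strongest other cell type, on a pseudocounted log
#' scale: `log2((v_target + 1) / (max_other + 1))` (metric
#' `"log_ratio_max"`). Alternatives: `"log_ratio_mean"` replaces the max by
#' the mean of the other cell types; `"zscore"` is the target value's
#' z-score across cell types. Candidates are ordered by descending score,
#' ties broken lexicographically by gene id; rank 1 is the most specific.
#'
#' @param mat numeric matrix, genes x cell types, rownames = gene ids.
#' @param target name of the target cell-type column.
#' @param candidates character vector of gene ids (must all be in `mat`).
#' @param metric specificity metric (see above).
#' @return data.frame `gene_id, score, rank`, ordered by rank.
#' @export
specificity_rank <- function(mat, target, candidates = rownames(mat),
                             metric = c("log_ratio_max", "log_ratio_mean", "zscore")) {
  metric <- match.arg(metric)
  if (!target %in% colnames(mat)) stop("target cell type not in matrix: ", target)
  missing <- setdiff(candidates, rownames(mat))
  if (length(missing))
    stop("candidate gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  sub <- mat[candidates, , drop = FALSE]
  v_t <- sub[, target]
  others <- sub[, setdiff(colnames(sub), target), drop = FALSE]
  score <- switch(metric,
    log_ratio_max = log2((v_t + 1) / (apply(others, 1L, max) + 1)),
    log_ratio_mean = log2((v_t + 1) / (rowMeans(others) + 1)),
    zscore = {
      mu <- rowMeans(sub); sdv <- apply(sub, 1L, stats::sd)
      ifelse(sdv > 0, (v_t - mu) / sdv, 0)
    })
  o <- order(-score, candidates)
  data.frame(gene_id = candidates[o], score = unname(score[o]),
             rank = seq_along(o), stringsAsFactors = FALSE)
}
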