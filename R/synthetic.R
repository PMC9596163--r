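#' Configuration of the synthetic peak landscape
#'
#' The generator plants a small, fully-known regulatory landscape: genes on
#' alternating strands along a handful of chromosomes; a set of target genes
#' whose promoters carry one peak per factor plus active-promoter marks
#' (H3K4me3 + H3K27ac) and whose expression is specifically high in the
#' first (target) cell type; non-target genes with randomly assigned
#' promoter states; background factor and mark peaks confined to a gene
#' desert at least `gene_window_bp` from any promoter midpoint; and a pair
#' of jittered replicate tracks for the first factor.
#'
#' Defaults describe the study conditions the screen is tested under: 200
#' genes over 2 chromosomes of 8 Mb (promoters spaced 30 kb), 20 planted
#' targets, 3 factors, 300 +/- 100 bp peaks, 50 background peaks per factor,
#' and 5 cell types with negative-binomial expression (mean 500 in the
#' target cell type for planted targets, 50 elsewhere).
#'
#' @param n_chroms,chrom_length_bp genome shape.
#' @param n_genes,n_targets gene counts (`n_targets <= n_genes`).
#' @param gene_spacing_bp distance between consecutive promoters.
#' @param n_factors number of co-binding factors (>= 2 for a screen).
#' @param peak_width_mean_bp,peak_width_jitter_bp peak width distribution
#'   (uniform on mean +/- jitter).
#' @param background_peaks_per_factor,background_mark_peaks_per_mark counts
#'   of desert peaks.
#' @param replicate_jitter_bp positional jitter of replicate-2 peaks.
#' @param replicate_dropout_prob probability a replicate-2 peak is dropped.
#' @param mark_noise_prob probability a planted mark is missing or a
#'   spurious mark appears at a promoter.
#' @param cell_types cell-type labels, target type first.
#' @param target_expr_mean,target_expr_size negative-binomial parameters for
#'   planted targets in the target cell type.
#' @param background_expr_mean,background_expr_size negative-binomial
#'   parameters everywhere else.
#' @param gene_window_bp used to place background peaks out of reach.
#' @param seed integer seed; the whole landscape is a deterministic function
#'   of the configuration.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_chroms = 2L, chrom_length_bp = 8e6,
                             n_genes = 200L, n_targets = 20L,
                             gene_spacing_bp = 30000L,
                             n_factors = 3L,
                             peak_width_mean_bp = 300L, peak_width_jitter_bp = 100L,
                             background_peaks_per_factor = 50L,
                             background_mark_peaks_per_mark = 10L,
                             replicate_jitter_bp = 50L,
                             replicate_dropout_prob = 0,
                             mark_noise_prob = 0,
                             cell_types = c("iOL", "OPC", "mOL", "astrocyte", "neuron"),
                             target_expr_mean = 500, target_expr_size = 10,
                             background_expr_mean = 50, background_expr_size = 5,
                             gene_window_bp = 100000L,
                             seed = 1L) {
  stopifnot(n_targets <= n_genes, n_factors >= 2L,
            replicate_dropout_prob >= 0, replicate_dropout_prob <= 1,
            mark_noise_prob >= 0, mark_noise_prob <= 1,
            length(cell_types) >= 2L)
  genes_per_chrom <- ceiling(n_genes / n_chroms)
  need <- 1e5 + genes_per_chrom * gene_spacing_bp + gene_window_bp + 2e5
  if (need > chrom_length_bp)
    stop("chromosome too short to place ", genes_per_chrom,
         " genes plus a background desert; need >= ", need, " bp")
  structure(as.list(environment()), class = "synthetic_config")
}

nb_draw <- function(n, mean, size) stats::rnbinom(n, mu = mean, size = size)

#' Generate a synthetic landscape with a truth manifest
#'
#' Deterministic given `config$seed`: a single Mersenne-Twister stream
#' drives every stochastic choice in a fixed order (target choice, peak
#' widths and offsets, replicate jitter and dropout, mark noise, expression
#' draws), so two runs with the same configuration produce identical files.
#' Target expression classes are enforced by rejection sampling (at most
#' 100 rounds) so the truth manifest is guaranteed to hold.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional directory; when given, per-factor BED files
#'   (plus `rep1`/`rep2` for the first factor), the 4 mark BEDs, the gene
#'   table, the expression table and `truth.json` are written there.
#' @return list with `peaks_by_factor`, `replicates`, `mark_peaks`,
#'   `genes`, `expression` (matrix), `truth` (planted targets, states and
#'   expression classes) and `files` (paths, when `out_dir` given).
#' @export
generate_landscape <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  cf <- config
  chroms <- paste0("chr", seq_len(cf$n_chroms))
  genes_per_chrom <- ceiling(cf$n_genes / cf$n_chroms)

  # --- genes: evenly spaced promoters, alternating strand ------------------
  idx <- seq_len(cf$n_genes)
  chrom <- chroms[((idx - 1L) %/% genes_per_chrom) + 1L]
  pos_in_chrom <- ((idx - 1L) %% genes_per_chrom)
  tss <- as.integer(1e5 + pos_in_chrom * cf$gene_spacing_bp +
                      sample.int(2000L, cf$n_genes, replace = TRUE))
  strand <- rep(c("+", "-"), length.out = cf$n_genes)
  biotype <- rep("protein_coding", cf$n_genes)
  # a few non-coding genes to exercise the biotype filter (never targets)
  n_nc <- max(0L, min(10L, cf$n_genes - cf$n_targets - 5L))
  genes <- data.frame(gene_id = sprintf("gene%03d", idx), chrom = chrom,
                      strand = strand, tss = tss, biotype = biotype,
                      stringsAsFactors = FALSE)
  targets <- sort(sample(genes$gene_id, cf$n_targets))
  if (n_nc > 0L) {
    nc_pool <- setdiff(genes$gene_id, targets)
    nc <- sample(nc_pool, n_nc)
    genes$biotype[genes$gene_id %in% nc] <- "lncRNA"
  }
  win <- promoter_window(genes$tss, genes$strand)
  prom_mid <- (win$start + win$end) %/% 2L
  is_target <- genes$gene_id %in% targets

  # --- promoter states: targets active; others drawn ----------------------
  state_pool <- c("active", "poised", "repressed", "none")
  other_state <- sample(state_pool, cf$n_genes, replace = TRUE,
                        prob = c(0.3, 0.2, 0.2, 0.3))
  planted_state <- ifelse(is_target, "active", other_state)

  draw_width <- function(n)
    as.integer(cf$peak_width_mean_bp +
                 sample.int(2L * cf$peak_width_jitter_bp + 1L, n, replace = TRUE) -
                 cf$peak_width_jitter_bp - 1L)

  peak_at <- function(center, chrom, n_offset_bp = 100L) {
    w <- draw_width(length(center))
    off <- sample.int(2L * n_offset_bp + 1L, length(center), replace = TRUE) -
      n_offset_bp - 1L
    s <- pmax(0L, as.integer(center + off - w %/% 2L))
    intervals(chrom = chrom, start = s, end = s + w)
  }

  state_marks <- list(active = c("H3K4me3", "H3K27ac"), poised = "H3K4me1",
                      repressed = "H3K27me3", none = character())

  # --- mark peaks at promoters, with optional noise ------------------------
  mark_rows <- lapply(CANONICAL_MARKS, function(mk) {
    planted <- vapply(planted_state, function(s) mk %in% state_marks[[s]], TRUE)
    keep <- planted & (stats::runif(cf$n_genes) >= cf$mark_noise_prob)
    spurious <- !planted & (stats::runif(cf$n_genes) < cf$mark_noise_prob)
    gi <- which(keep | spurious)
    if (!length(gi)) return(empty_intervals())
    peak_at(prom_mid[gi], genes$chrom[gi])
  })
  names(mark_rows) <- CANONICAL_MARKS

  # --- background desert: shared across factors and marks ------------------
  desert_lo <- 1e5 + genes_per_chrom * cf$gene_spacing_bp + cf$gene_window_bp + 5e4
  desert_hi <- cf$chrom_length_bp - 5e4
  desert_peaks <- function(n) {
    ch <- sample(chroms, n, replace = TRUE)
    center <- as.integer(desert_lo + floor(stats::runif(n) * (desert_hi - desert_lo)))
    peak_at(center, ch, n_offset_bp = 1L)
  }
  mark_peaks <- lapply(CANONICAL_MARKS, function(mk) {
    bg <- desert_peaks(cf$background_mark_peaks_per_mark)
    normalize_order(rbind(mark_rows[[mk]], bg))
  })
  names(mark_peaks) <- CANONICAL_MARKS

  # --- factor peaks: one per target promoter + desert background ----------
  factor_labels <- paste0("factor", seq_len(cf$n_factors))
  ti <- which(is_target)
  peaks_by_factor <- lapply(factor_labels, function(fl) {
    at_targets <- peak_at(prom_mid[ti], genes$chrom[ti])
    bg <- desert_peaks(cf$background_peaks_per_factor)
    normalize_order(rbind(at_targets, bg))
  })
  names(peaks_by_factor) <- factor_labels

  # --- replicates for the first factor -------------------------------------
  rep1 <- peaks_by_factor[[1L]]
  jit <- sample.int(2L * cf$replicate_jitter_bp + 1L, nrow(rep1), replace = TRUE) -
    cf$replicate_jitter_bp - 1L
  keep2 <- stats::runif(nrow(rep1)) >= cf$replicate_dropout_prob
  rep2 <- intervals(chrom = rep1$chrom[keep2],
                    start = pmax(0L, rep1$start[keep2] + jit[keep2]),
                    end = pmax(1L, rep1$end[keep2] + jit[keep2]))
  replicates <- list(list(rep1 = rep1, rep2 = rep2))
  names(replicates) <- factor_labels[1L]

  # --- expression: targets specifically high in the first cell type --------
  n_ct <- length(cf$cell_types)
  expr <- matrix(nb_draw(cf$n_genes * n_ct, cf$background_expr_mean,
                         cf$background_expr_size),
                 nrow = cf$n_genes, ncol = n_ct,
                 dimnames = list(genes$gene_id, cf$cell_types))
  expr[is_target, 1L] <- nb_draw(sum(is_target), cf$target_expr_mean,
                                 cf$target_expr_size)
  for (round in seq_len(100L)) {
    cls <- classify_expression(expr[, 1L])$classes
    bad <- is_target & !cls[genes$gene_id] %in% c("medium", "high")
    if (!any(bad)) break
    if (round == 100L)
      stop("could not enforce medium/high target expression in 100 rounds")
    expr[bad, 1L] <- nb_draw(sum(bad), cf$target_expr_mean, cf$target_expr_size)
  }
  expr_classes <- classify_expression(expr[, 1L])$classes

  truth <- list(planted_targets = targets,
                planted_states = stats::setNames(planted_state, genes$gene_id),
                planted_expression_class = expr_classes)

  out <- list(peaks_by_factor = peaks_by_factor, replicates = replicates,
              mark_peaks = mark_peaks, genes = genes, expression = expr,
              truth = truth, config = cf)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (fl in factor_labels) {
      files[[fl]] <- file.path(out_dir, paste0(fl, ".bed"))
      write_bed(peaks_by_factor[[fl]], files[[fl]])
    }
    files$rep1 <- file.path(out_dir, paste0(factor_labels[1L], "_rep1.bed"))
    files$rep2 <- file.path(out_dir, paste0(factor_labels[1L], "_rep2.bed"))
    write_bed(rep1, files$rep1); write_bed(rep2, files$rep2)
    for (mk in CANONICAL_MARKS) {
      files[[mk]] <- file.path(out_dir, paste0(mk, ".bed"))
      write_bed(mark_peaks[[mk]], files[[mk]])
    }
    files$genes <- file.path(out_dir, "genes.tsv")
    utils::write.table(genes, files$genes, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files$expression <- file.path(out_dir, "expression.tsv")
    utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                  check.names = FALSE),
                       files$expression, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files$truth <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, files$truth, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE)
    out$files <- files
  }
  out
}

# sort peaks by position without merging (a peak track, not a footprint)
normalize_order <- function(x) {
  x <- as_intervals(x)
  o <- order(x$chrom, x$start, x$end)
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision/recall of a candidate set against planted truth
#'
#' Standard set-based scores. An empty candidate set has precision 1.0 by
#' convention (no false positives were asserted) and recall 0.
#'
#' @param candidates character vector of candidate gene ids.
#' @param truth a truth manifest (list with `planted_targets`).
#' @return list with `precision`, `recall`, `f1`.
#' @export
score_recovery <- function(candidates, truth) {
  planted <- truth$planted_targets
  tp <- length(intersect(candidates, planted))
  precision <- if (length(candidates) == 0L) 1.0 else tp / length(candidates)
  recall <- if (length(planted) == 0L) 1.0 else tp / length(planted)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}
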