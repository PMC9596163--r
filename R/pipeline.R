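#' Run the screen from a configuration file
#'
#' Reads a YAML configuration naming the input files and any screen
#' parameters, runs the full pipeline (replicate consensus, landscape
#' annotation, common regions, expression-gated gene assignment,
#' specificity ranking) and writes `candidates.tsv`, `associations.tsv`,
#' `common_regions.bed`, `elements.bed` and `summary.json` to `out_dir`.
#'
#' Configuration keys: `factors` (map label -> BED path, or for one factor
#' a map with `rep1`/`rep2` paths), `marks` (map mark -> BED path), `genes`
#' (TSV path), `expression` (TSV path), plus any argument of
#' [screen_config()] (e.g. `gene_window_bp`, `common_mode`,
#' `required_state`, `gating_celltype`, `normalize_chrom_names`).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return the `screen_result`, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  cf <- if (is.character(config)) yaml::read_yaml(config) else config
  for (key in c("factors", "marks", "genes", "expression"))
    if (is.null(cf[[key]])) stop("config is missing required key: ", key)
  ncn <- if (is.null(cf$normalize_chrom_names)) "none" else cf$normalize_chrom_names

  peaks_by_factor <- list(); replicates <- list()
  for (lab in names(cf$factors)) {
    spec <- cf$factors[[lab]]
    if (is.list(spec) && !is.null(spec$rep1)) {
      replicates[[lab]] <- list(rep1 = read_bed(spec$rep1, ncn),
                                rep2 = read_bed(spec$rep2, ncn))
      peaks_by_factor[[lab]] <- replicates[[lab]]$rep1
    } else {
      peaks_by_factor[[lab]] <- read_bed(spec, ncn)
    }
  }
  mark_peaks <- lapply(cf$marks, read_bed, normalize_chrom_names = ncn)
  genes <- read_gene_table(cf$genes, ncn)
  expr <- read_expression_table(cf$expression, genes)
  if (length(expr$unmatched$in_expression_only))
    message(length(expr$unmatched$in_expression_only),
            " gene(s) in expression table have no annotation")

  sc_args <- cf[intersect(names(cf), names(formals(screen_config)))]
  sc_args$factors <- names(cf$factors)
  sconf <- do.call(screen_config, sc_args)

  res <- run_screen(peaks_by_factor, mark_peaks, genes, expr$matrix, sconf,
                    replicates = if (length(replicates)) replicates else NULL)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$associations, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(res$common_regions, file.path(out_dir, "common_regions.bed"))
  write_elements_bed(res$elements, file.path(out_dir, "elements.bed"))
  summary <- c(res$summary,
               list(top_candidates = utils::head(res$candidates, 20L),
                    version = as.character(utils::packageVersion("regscreen"))))
  write_summary_json(summary, file.path(out_dir, "summary.json"))
  invisible(res)
}

#' Simulate, screen and score in one call
#'
#' Convenience wrapper: generates a synthetic landscape, runs the screen on
#' it with defaults matching the generator's geometry, and scores the
#' recovered candidates against the planted truth.
#'
#' @param sim_config a [synthetic_config()].
#' @param screen_overrides named list of [screen_config()] arguments to
#'   override the defaults.
#' @param use_replicates whether to run the first factor through replicate
#'   consensus (default `TRUE`).
#' @return list with `scores` (precision/recall/f1), `result` (the
#'   `screen_result`) and `landscape`.
#' @export
recover_targets <- function(sim_config = synthetic_config(),
                            screen_overrides = list(),
                            use_replicates = TRUE) {
  land <- generate_landscape(sim_config)
  args <- c(list(factors = names(land$peaks_by_factor),
                 gene_window_bp = sim_config$gene_window_bp),
            screen_overrides)
  args <- args[!duplicated(names(args), fromLast = TRUE)]
  sconf <- do.call(screen_config, args)
  res <- run_screen(land$peaks_by_factor, land$mark_peaks, land$genes,
                    land$expression, sconf,
                    replicates = if (use_replicates) land$replicates else NULL)
  list(scores = score_recovery(res$candidates$gene_id, land$truth),
       result = res, landscape = land)
}
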