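#' Screen configuration
#'
#' Bundles every tunable of the co-binding screen with the defaults that
#' mirror the published filter chain: a 1010-bp promoter window (1000 bp
#' upstream to 10 bp downstream of the TSS), a 100-kb gene-association
#' window around the promoter midpoint, at least 1 bp of overlap everywhere,
#' common regions as the multi-factor footprint, only regions at active
#' promoters, only protein-coding genes, and an expression gate coupling
#' element state to expression class (active needs medium/high, poised low,
#' repressed not expressed).
#'
#' @param factors character vector of factor labels (>= 2 for a screen).
#' @param promoter_upstream_bp,promoter_downstream_bp promoter window extent.
#' @param gene_window_bp maximum distance from the promoter midpoint for a
#'   region-to-gene association.
#' @param min_overlap_bp minimum shared bases for any overlap test.
#' @param common_mode `"footprint"` (common bases of all factors) or
#'   `"anchor:<label>"` (whole peaks of the anchor factor overlapping every
#'   other set).
#' @param required_state `"active_promoter"` (default) or `"any"`.
#' @param biotype_filter gene biotype kept (`"protein_coding"`; `NA` keeps all).
#' @param expression_gate named list mapping element state to the expression
#'   classes allowed for an association to pass; states absent from the map
#'   (including `"unclassified"`) never pass.
#' @param gating_celltype column of the expression table used for gating;
#'   `NULL` means the first column.
#' @param specificity_metric passed to [specificity_rank()].
#' @param bivalent_as passed to [classify_element()].
#' @return a list of class `"screen_config"`.
#' @export
screen_config <- function(factors,
                          promoter_upstream_bp = 1000L,
                          promoter_downstream_bp = 10L,
                          gene_window_bp = 100000L,
                          min_overlap_bp = 1L,
                          common_mode = "footprint",
                          required_state = c("active_promoter", "any"),
                          biotype_filter = "protein_coding",
                          expression_gate = list(active = c("medium", "high"),
                                                 poised = "low",
                                                 repressed = "not"),
                          gating_celltype = NULL,
                          specificity_metric = "log_ratio_max",
                          bivalent_as = "unclassified") {
  required_state <- match.arg(required_state)
  stopifnot(length(factors) >= 1L, promoter_upstream_bp >= 0L,
            promoter_downstream_bp >= 1L, gene_window_bp >= 0L,
            min_overlap_bp >= 1L)
  if (!(common_mode == "footprint" || grepl("^anchor:", common_mode)))
    stop("common_mode must be 'footprint' or 'anchor:<label>'")
  structure(list(factors = factors,
                 promoter_upstream_bp = as.integer(promoter_upstream_bp),
                 promoter_downstream_bp = as.integer(promoter_downstream_bp),
                 gene_window_bp = as.integer(gene_window_bp),
                 min_overlap_bp = as.integer(min_overlap_bp),
                 common_mode = common_mode,
                 required_state = required_state,
                 biotype_filter = biotype_filter,
                 expression_gate = expression_gate,
                 gating_celltype = gating_celltype,
                 specificity_metric = specificity_metric,
                 bivalent_as = bivalent_as),
            class = "screen_config")
}

#' Regions commonly bound by every factor
#'
#' Footprint mode returns the maximal runs of bases covered by every
#' factor's peak set ([multi_intersect()]); anchor mode returns the anchor
#' factor's peaks, kept whole, that overlap every other factor's set.
#'
#' @param peaks_by_factor named list of [intervals()] peak sets.
#' @param config a [screen_config()].
#' @return [intervals()] of common regions.
#' @export
common_regions <- function(peaks_by_factor, config) {
  missing <- setdiff(config$factors, names(peaks_by_factor))
  if (length(missing))
    stop("factor(s) named in config but missing from peak sets: ",
         paste(missing, collapse = ", "))
  sets <- peaks_by_factor[config$factors]
  if (config$common_mode == "footprint") {
    regions <- multi_intersect(sets)
    return(regions[regions$end - regions$start >= config$min_overlap_bp, ,
                   drop = FALSE])
  }
  anchor_label <- sub("^anchor:", "", config$common_mode)
  if (!anchor_label %in% names(sets))
    stop("anchor factor not among configured factors: ", anchor_label)
  anchor <- as_intervals(sets[[anchor_label]])
  for (lab in setdiff(names(sets), anchor_label))
    anchor <- filter_overlapping(anchor, sets[[lab]], config$min_overlap_bp)
  anchor
}

#' Assign common regions to genes
#'
#' A region associates with a gene if it overlaps the gene's promoter window
#' (`in_promoter`, distance 0) or lies within `gene_window_bp` of the
#' promoter-window midpoint (`within_window`; distance measured from the
#' midpoint to the nearest base of the region). The element state backing
#' the association is the gene's promoter element for `in_promoter` links,
#' else the enhancer element overlapping the region (unclassified if none).
#' The expression gate passes when the gene's expression class is among the
#' classes allowed for that state; genes missing from `expr_classes` get
#' `gate_passed = FALSE` with a warning. A region within reach of several
#' genes associates with all of them.
#'
#' @param regions [intervals()] of common regions.
#' @param elements data.frame from [annotate_landscape()].
#' @param genes gene table.
#' @param expr_classes named character vector gene -> expression class.
#' @param config a [screen_config()].
#' @return data.frame of associations: `gene_id, chrom, region_start,
#'   region_end, link_kind, distance_bp, element_state, expression_class,
#'   gate_passed`.
#' @export
assign_regions_to_genes <- function(regions, elements, genes, expr_classes, config) {
  regions <- as_intervals(regions)
  out <- list()
  prom <- elements[elements$locus_kind == "promoter", , drop = FALSE]
  prom <- prom[match(genes$gene_id, prom$gene_id), , drop = FALSE]
  if (anyNA(prom$gene_id))
    stop("elements must include one promoter element per gene")
  enh <- elements[elements$locus_kind == "enhancer", , drop = FALSE]
  mid <- (prom$start + prom$end) %/% 2L
  missing_expr <- character()
  for (i in seq_len(nrow(regions))) {
    rs <- regions$start[i]; re <- regions$end[i]; rc <- regions$chrom[i]
    same <- which(prom$chrom == rc)
    if (!length(same)) next
    in_prom <- rs < prom$end[same] & prom$start[same] < re
    dist <- point_interval_distance(mid[same], rs, re)
    hit <- in_prom | dist <= config$gene_window_bp
    if (!any(hit)) next
    # enhancer state backing within_window links: the enhancer overlapping
    # the region most, unclassified when the region touches no enhancer
    ei <- which(enh$chrom == rc & enh$start < re & enh$end > rs)
    enh_state <- if (length(ei)) {
      ov <- pmin(re, enh$end[ei]) - pmax(rs, enh$start[ei])
      enh$state[ei[which.max(ov)]]
    } else "unclassified"
    for (j in which(hit)) {
      g <- same[j]
      state <- if (in_prom[j]) prom$state[g] else enh_state
      cls <- expr_classes[genes$gene_id[g]]
      if (is.na(cls)) {
        missing_expr <- c(missing_expr, genes$gene_id[g])
        cls <- NA_character_
      }
      gate <- !is.na(cls) && state %in% names(config$expression_gate) &&
        cls %in% config$expression_gate[[state]]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes$gene_id[g], chrom = rc,
        region_start = rs, region_end = re,
        link_kind = if (in_prom[j]) "in_promoter" else "within_window",
        distance_bp = if (in_prom[j]) 0L else dist[j],
        element_state = state, expression_class = cls,
        gate_passed = gate, stringsAsFactors = FALSE)
    }
  }
  if (length(missing_expr))
    warning("gene(s) missing from expression classes (gate failed): ",
            paste(unique(missing_expr), collapse = ", "))
  if (!length(out))
    return(data.frame(gene_id = character(), chrom = character(),
                      region_start = integer(), region_end = integer(),
                      link_kind = character(), distance_bp = integer(),
                      element_state = character(), expression_class = character(),
                      gate_passed = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Run the full co-binding target screen
#'
#' Pipeline: replicate consensus for factors with replicates (a replicate-1
#' peak survives if found in replicate 2 or in a marked regulatory element)
#' -> regulatory-landscape annotation -> common regions across all factors
#' -> keep regions whose element state satisfies `required_state` -> assign
#' regions to genes and apply the expression gate -> keep gate-passed
#' associations to genes of the configured biotype -> deduplicate genes ->
#' attach specificity scores and ranks.
#'
#' @param peaks_by_factor named list of [intervals()] peak sets, one per
#'   factor label in `config$factors`.
#' @param mark_peaks named list of histone-mark [intervals()] sets.
#' @param genes gene table.
#' @param expression numeric matrix genes x cell types (rownames = ids).
#' @param config a [screen_config()].
#' @param replicates optional named list: for a factor label, a list with
#'   `rep1` and `rep2` peak sets; that factor's peaks are replaced by their
#'   consensus before intersection.
#' @return list of class `"screen_result"` with `candidates` (gene_id,
#'   n_supporting_regions, link_kinds, score, rank), `associations`,
#'   `common_regions`, `kept_regions`, `elements`, `expr_classes`,
#'   `thresholds` and `summary` (the Venn-funnel counts).
#' @export
run_screen <- function(peaks_by_factor, mark_peaks, genes, expression, config,
                       replicates = NULL) {
  elements <- annotate_landscape(mark_peaks, genes,
                                 config$promoter_upstream_bp,
                                 config$promoter_downstream_bp,
                                 config$bivalent_as)
  marked <- elements[elements$locus_kind == "enhancer" | nzchar(elements$marks), ,
                     drop = FALSE]
  marked_iv <- if (nrow(marked)) intervals(marked$chrom, marked$start, marked$end)
               else empty_intervals()
  for (lab in names(replicates)) {
    peaks_by_factor[[lab]] <- consensus_peaks(replicates[[lab]]$rep1,
                                              replicates[[lab]]$rep2,
                                              marked_iv, config$min_overlap_bp)
  }
  regions <- common_regions(peaks_by_factor, config)

  active_prom <- elements[elements$locus_kind == "promoter" &
                            elements$state == "active", , drop = FALSE]
  active_prom_iv <- if (nrow(active_prom))
    intervals(active_prom$chrom, active_prom$start, active_prom$end)
  else empty_intervals()
  at_active_prom <- filter_overlapping(regions, active_prom_iv, config$min_overlap_bp)
  kept <- if (config$required_state == "active_promoter") at_active_prom else regions

  gating_col <- if (is.null(config$gating_celltype)) colnames(expression)[1]
                else config$gating_celltype
  if (!gating_col %in% colnames(expression))
    stop("gating cell type not in expression matrix: ", gating_col)
  known <- intersect(genes$gene_id, rownames(expression))
  cls_fit <- classify_expression(expression[known, gating_col])
  expr_classes <- cls_fit$classes

  assoc <- assign_regions_to_genes(kept, elements, genes, expr_classes, config)
  passed <- assoc[assoc$gate_passed, , drop = FALSE]
  if (!is.na(config$biotype_filter)) {
    bio <- genes$biotype[match(passed$gene_id, genes$gene_id)]
    passed <- passed[bio == config$biotype_filter, , drop = FALSE]
  }

  cand_ids <- sort(unique(passed$gene_id))
  if (length(cand_ids)) {
    rankable <- intersect(cand_ids, rownames(expression))
    target_ct <- gating_col
    spec <- specificity_rank(expression, target_ct, rankable,
                             config$specificity_metric)
    n_sup <- vapply(spec$gene_id, function(g) sum(passed$gene_id == g), 0L)
    lk <- vapply(spec$gene_id, function(g)
      paste(sort(unique(passed$link_kind[passed$gene_id == g])), collapse = ","), "")
    candidates <- data.frame(gene_id = spec$gene_id,
                             n_supporting_regions = unname(n_sup),
                             link_kinds = unname(lk),
                             score = spec$score, rank = spec$rank,
                             stringsAsFactors = FALSE)
  } else {
    candidates <- data.frame(gene_id = character(),
                             n_supporting_regions = integer(),
                             link_kinds = character(), score = numeric(),
                             rank = integer(), stringsAsFactors = FALSE)
  }

  n_common <- nrow(regions)
  n_active <- nrow(at_active_prom)
  summary <- list(
    n_sites_per_factor = lapply(peaks_by_factor[config$factors], function(p) nrow(as_intervals(p))),
    n_common_regions = n_common,
    n_active_promoter_regions = n_active,
    pct_active_promoter = if (n_common > 0) 100 * n_active / n_common else NA_real_,
    n_associations = nrow(assoc),
    n_gate_passed_associations = nrow(passed),
    n_candidate_genes = nrow(candidates),
    gating_celltype = gating_col,
    thresholds = cls_fit$thresholds
  )
  structure(list(candidates = candidates, associations = assoc,
                 common_regions = regions, kept_regions = kept,
                 elements = elements, expr_classes = expr_classes,
                 thresholds = cls_fit$thresholds, summary = summary,
                 config = config),
            class = "screen_result")
}
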