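# a tiny hand-built landscape: one target gene with co-bound active
# promoter, one distal gene reachable through the 100-kb window, one
# expressed gene with no binding, one non-coding gene
tiny_landscape <- function() {
  genes <- data.frame(
    gene_id = c("target", "distal", "silent", "nc"),
    chrom = "chr1",
    strand = c("+", "+", "+", "+"),
    tss = c(5000L, 90000L, 300000L, 800000L),
    biotype = c("protein_coding", "protein_coding", "protein_coding", "lncRNA"),
    stringsAsFactors = FALSE)
  # promoter of "target" is [4000, 5010); factors co-bind inside it
  peaks <- list(f1 = intervals("chr1", c(4400, 598000), c(4700, 599500)),
                f2 = intervals("chr1", c(4300, 598000), c(4600, 599500)),
                f3 = intervals("chr1", c(4450, 598000), c(4800, 599500)))
  marks <- list(H3K4me3 = intervals("chr1", c(4200, 598500), c(4900, 599300)),
                H3K27ac = intervals("chr1", c(4200, 598500), c(4900, 599300)))
  expr <- matrix(c(500, 400, 450, 470,
                   10, 10, 10, 10), ncol = 2,
                 dimnames = list(genes$gene_id, c("iOL", "OPC")))
  list(genes = genes, peaks = peaks, marks = marks, expr = expr)
}

test_that("common regions: footprint mode reproduces the multi-set example", {
  cfg <- screen_config(factors = c("A", "B", "C"))
  sets <- list(A = intervals("chr1", c(0, 20), c(10, 30)),
               B = intervals("chr1", 5, 25),
               C = intervals("chr1", 8, 40))
  expect_same_intervals(common_regions(sets, cfg),
                        intervals("chr1", c(8, 20), c(10, 25)))
  two <- list(A = sets$A, B = sets$A)
  expect_same_intervals(common_regions(two, screen_config(c("A", "B"))),
                        normalize_intervals(sets$A))
  expect_error(common_regions(sets[1:2], cfg), "missing")
})

test_that("common regions: anchor mode keeps whole anchor peaks", {
  cfg <- screen_config(factors = c("A", "B", "C"), common_mode = "anchor:A")
  sets <- list(A = intervals("chr1", 0, 100),
               B = intervals("chr1", 50, 60),
               C = intervals("chr1", 90, 95))
  expect_same_intervals(common_regions(sets, cfg), intervals("chr1", 0, 100))
  cfg_bad <- screen_config(factors = c("A", "B"), common_mode = "anchor:Z")
  expect_error(common_regions(sets[1:2], cfg_bad), "anchor")
})

test_that("region-to-gene assignment distinguishes promoter and window links", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 5000L, biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  elements <- data.frame(chrom = "chr1", start = 4000L, end = 5010L,
                         locus_kind = "promoter", state = "active",
                         marks = "H3K4me3,H3K27ac", gene_id = "g1",
                         stringsAsFactors = FALSE)
  cfg <- screen_config("f1")
  cls <- c(g1 = "high")
  # inside the promoter window: distance 0, gate passes
  a1 <- assign_regions_to_genes(intervals("chr1", 4500, 4600),
                                elements, genes, cls, cfg)
  expect_equal(a1$link_kind, "in_promoter")
  expect_equal(a1$distance_bp, 0L)
  expect_true(a1$gate_passed)
  # promoter midpoint is (4000+5010)/2 = 4505; region at 104000 is 99495 away
  a2 <- assign_regions_to_genes(intervals("chr1", 104000, 104200),
                                elements, genes, cls, cfg)
  expect_equal(a2$link_kind, "within_window")
  expect_equal(a2$distance_bp, 99495L)
  expect_equal(a2$element_state, "unclassified")  # no enhancer under the region
  expect_false(a2$gate_passed)
  # 101000 bp away: no association at all
  a3 <- assign_regions_to_genes(intervals("chr1", 105505, 105700),
                                elements, genes, cls, cfg)
  expect_equal(nrow(a3), 0L)
})

test_that("genes missing from expression classes fail the gate with a warning", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 5000L, biotype = "protein_coding",
                      stringsAsFactors = FALSE)
  elements <- data.frame(chrom = "chr1", start = 4000L, end = 5010L,
                         locus_kind = "promoter", state = "active",
                         marks = "", gene_id = "g1", stringsAsFactors = FALSE)
  expect_warning(
    a <- assign_regions_to_genes(intervals("chr1", 4500, 4600), elements,
                                 genes, c(other = "high"), screen_config("f1")),
    "missing")
  expect_false(a$gate_passed)
})

test_that("the screen recovers the co-bound, expressed, coding target", {
  L <- tiny_landscape()
  cfg <- screen_config(factors = names(L$peaks))
  res <- run_screen(L$peaks, L$marks, L$genes, L$expr, cfg)
  # the desert co-bound region at 598-599 kb has active-ENHANCER marks only,
  # so with the default active-promoter filter a single candidate survives
  expect_equal(res$candidates$gene_id, "target")
  expect_equal(res$summary$n_common_regions, 2L)
  expect_equal(res$summary$n_active_promoter_regions, 1L)
  expect_equal(res$summary$pct_active_promoter, 50)
  # relaxing the state filter brings in the nc gene's promoter-window link?
  # no: the desert region is 100 kb+ from every promoter midpoint except nc
  res_any <- run_screen(L$peaks, L$marks, L$genes, L$expr,
                        screen_config(names(L$peaks), required_state = "any"))
  expect_true(all(res$candidates$gene_id %in% res_any$candidates$gene_id))
})

test_that("emptying one factor's peaks empties the screen but not the summary", {
  L <- tiny_landscape()
  L$peaks$f2 <- intervals()
  res <- run_screen(L$peaks, L$marks, L$genes, L$expr,
                    screen_config(names(L$peaks)))
  expect_equal(res$summary$n_common_regions, 0L)
  expect_equal(res$summary$n_candidate_genes, 0L)
  expect_equal(nrow(res$candidates), 0L)
})

test_that("summary counts are mutually consistent", {
  L <- tiny_landscape()
  res <- run_screen(L$peaks, L$marks, L$genes, L$expr,
                    screen_config(names(L$peaks)))
  s <- res$summary
  expect_lte(s$n_active_promoter_regions, s$n_common_regions)
  expect_equal(s$pct_active_promoter,
               100 * s$n_active_promoter_regions / s$n_common_regions)
  expect_equal(s$n_candidate_genes, nrow(res$candidates))
  expect_true(all(res$candidates$n_supporting_regions >= 1L))
  expect_equal(sort(res$candidates$rank), seq_len(nrow(res$candidates)))
})

test_that("biotype filter removes non-coding genes from the candidate set", {
  L <- tiny_landscape()
  # make the nc gene's promoter (window [799000, 800010)) active and co-bound
  L$peaks <- lapply(L$peaks, function(p)
    normalize_intervals(rbind(p, intervals("chr1", 799300, 799600))))
  L$marks <- lapply(L$marks, function(p)
    rbind(p, intervals("chr1", 799100, 799700)))
  with_bio <- run_screen(L$peaks, L$marks, L$genes, L$expr,
                         screen_config(names(L$peaks)))
  expect_false("nc" %in% with_bio$candidates$gene_id)
  no_bio <- run_screen(L$peaks, L$marks, L$genes, L$expr,
                       screen_config(names(L$peaks), biotype_filter = NA))
  expect_true("nc" %in% no_bio$candidates$gene_id)
})
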