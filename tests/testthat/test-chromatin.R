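# independent restatement of the classification rules: first matching row
# of an explicit rule list wins (required marks all present, forbidden all
# absent); used as the oracle for the 32-case truth table.
rule_table <- list(
  promoter = list(
    list(state = "active", required = c("H3K4me3", "H3K27ac"), forbidden = character()),
    list(state = "repressed", required = "H3K27me3", forbidden = c("H3K4me3", "H3K27ac")),
    list(state = "poised", required = "H3K4me1",
         forbidden = c("H3K4me3", "H3K27ac", "H3K27me3"))),
  enhancer = list(
    list(state = "active", required = "H3K27ac", forbidden = character()),
    list(state = "repressed", required = "H3K27me3", forbidden = "H3K27ac"),
    list(state = "poised", required = "H3K4me1", forbidden = c("H3K27ac", "H3K27me3"))))

oracle_classify <- function(marks, kind) {
  for (rule in rule_table[[kind]]) {
    if (all(rule$required %in% marks) && !any(rule$forbidden %in% marks))
      return(rule$state)
  }
  "unclassified"
}

all_marks <- c("H3K4me3", "H3K27ac", "H3K4me1", "H3K27me3")
mark_subsets <- lapply(0:15, function(b) all_marks[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0])

test_that("promoter windows are strand-aware, 1010 bp, clamped at zero", {
  w <- promoter_window(c(5000L, 5000L, 500L), c("+", "-", "+"))
  expect_equal(w$start, c(4000L, 4991L, 0L))
  expect_equal(w$end, c(5010L, 6001L, 510L))
  expect_equal(w$end[1] - w$start[1], 1010L)
  expect_equal(w$end[2] - w$start[2], 1010L)
})

test_that("element classification matches the rule table on all 32 cases", {
  for (kind in c("promoter", "enhancer")) {
    for (marks in mark_subsets) {
      expect_equal(classify_element(marks, kind), oracle_classify(marks, kind),
                   info = paste(kind, paste(marks, collapse = "+")))
    }
  }
  expect_error(classify_element("H3K9me3", "promoter"), "unknown")
})

test_that("bivalent promoters are unclassified by default, poised on request", {
  bivalent <- c("H3K4me3", "H3K27me3")
  expect_equal(classify_element(bivalent, "promoter"), "unclassified")
  expect_equal(classify_element(bivalent, "promoter", bivalent_as = "poised"),
               "poised")
  # the override targets only the bivalent combination
  expect_equal(classify_element(c("H3K4me3", "H3K27me3", "H3K4me1"),
                                "promoter", bivalent_as = "poised"),
               "unclassified")
})

demo_genes <- function() {
  data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 5000L,
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

test_that("landscape annotation separates promoter marks from distal enhancers", {
  marks <- list(H3K4me3 = intervals("chr1", 4500, 4800),
                H3K27ac = intervals("chr1", 55000, 55400))
  el <- annotate_landscape(marks, demo_genes())
  prom <- el[el$locus_kind == "promoter", ]
  enh <- el[el$locus_kind == "enhancer", ]
  expect_equal(nrow(prom), 1L)
  expect_equal(prom$marks, "H3K4me3")
  expect_equal(prom$state, "unclassified")
  expect_equal(nrow(enh), 1L)
  expect_equal(enh$state, "active")
  expect_equal(c(enh$start, enh$end), c(55000L, 55400L))
})

test_that("a landscape with no marks yields unclassified promoters only", {
  el <- annotate_landscape(list(), demo_genes())
  expect_equal(nrow(el), 1L)
  expect_equal(el$state, "unclassified")
  expect_equal(el$locus_kind, "promoter")
})

test_that("a mark peak straddling a promoter edge is split base-exactly", {
  # promoter window of g1 is [4000, 5010); peak [4900, 5300) straddles it
  marks <- list(H3K27ac = intervals("chr1", 4900, 5300))
  el <- annotate_landscape(marks, demo_genes())
  prom <- el[el$locus_kind == "promoter", ]
  enh <- el[el$locus_kind == "enhancer", ]
  expect_equal(prom$marks, "H3K27ac")
  expect_equal(c(enh$start, enh$end), c(5010L, 5300L))
  # per-base accounting: promoter-assigned + enhancer footprint = mark footprint
  len <- 10000L
  prom_cover <- oracle_cover(intervals("chr1", 4000, 5010), len) &
    oracle_cover(marks$H3K27ac, len)
  enh_cover <- oracle_cover(intervals(enh$chrom, enh$start, enh$end), len)
  expect_equal(prom_cover | enh_cover, oracle_cover(marks$H3K27ac, len))
})

test_that("every mark base lands in a promoter window or the enhancer footprint", {
  set.seed(11)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(3000L, 7000L),
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  win <- promoter_window(genes$tss, genes$strand)
  for (rep in 1:20) {
    marks <- list(H3K4me3 = random_interval_set(10L, 10000L),
                  H3K27ac = random_interval_set(10L, 10000L),
                  H3K4me1 = random_interval_set(10L, 10000L),
                  H3K27me3 = random_interval_set(10L, 10000L))
    el <- annotate_landscape(marks, genes)
    enh <- el[el$locus_kind == "enhancer", ]
    len <- 10000L
    all_cover <- Reduce(`|`, lapply(marks, oracle_cover, len = len))
    prom_cover <- oracle_cover(intervals("chr1", win$start, win$end), len)
    enh_cover <- if (nrow(enh)) oracle_cover(intervals(enh$chrom, enh$start, enh$end), len)
                 else logical(len)
    expect_equal(enh_cover, all_cover & !prom_cover)
  }
})

test_that("consensus keeps rep1 peaks found in rep2 or in regulatory elements", {
  rep1 <- intervals("chr1", c(0, 200, 400), c(100, 300, 500))
  rep2 <- intervals("chr1", 250, 320)
  reg <- intervals("chr1", 0, 50)
  expect_same_intervals(consensus_peaks(rep1, rep2, reg),
                        intervals("chr1", c(0, 200), c(100, 300)))
  # degenerate: no regulatory rescue
  expect_same_intervals(consensus_peaks(rep1, rep2),
                        intervals("chr1", 200, 300))
  # rep2 = rep1 keeps everything, nothing new
  expect_same_intervals(consensus_peaks(rep1, rep1, reg), rep1)
})

test_that("consensus is a subset of replicate 1 on random instances", {
  set.seed(21)
  for (rep in 1:50) {
    r1 <- random_interval_set(30L, 8000L)
    r2 <- random_interval_set(30L, 8000L)
    reg <- random_interval_set(10L, 8000L)
    cons <- consensus_peaks(r1, r2, reg)
    expect_lte(nrow(cons), nrow(r1))
    expect_true(all(paste(cons$chrom, cons$start, cons$end) %in%
                      paste(r1$chrom, r1$start, r1$end)))
    # oracle: exactly the rep1 peaks overlapping rep2 or reg
    want <- unique(rbind(coords(oracle_filter_overlapping(r1, r2, 8000L)),
                         coords(oracle_filter_overlapping(r1, reg, 8000L))))
    got <- unique(coords(cons))
    expect_setequal(paste(got$start, got$end), paste(want$start, want$end))
  }
})
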