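#!/usr/bin/env Rscript

# Step 1: generate the default synthetic regulatory landscape.
#
# 200 genes over 2 chromosomes, 20 planted targets whose promoters are
# co-bound by all 3 factors, carry H3K4me3 + H3K27ac, and are specifically
# highly expressed in the first cell type (iOL). Writes the per-factor and
# per-mark BED files, the gene and expression tables and the truth manifest
# under results/sim/, so step 2 can consume them purely from disk.

library(regscreen)

out_dir <- "results/sim"
cfg <- synthetic_config(seed = 1L)
land <- generate_landscape(cfg, out_dir)

cat("wrote", length(land$files), "files to", out_dir, "\n")
cat("genes:", nrow(land$genes),
    " planted targets:", length(land$truth$planted_targets), "\n")
cat("targets:", paste(land$truth$planted_targets, collapse = " "), "\n")
cls <- table(land$truth$planted_expression_class[land$truth$planted_targets])
cat("target expression classes (iOL):",
    paste(names(cls), cls, sep = "=", collapse = " "), "\n")
for (fl in names(land$peaks_by_factor))
  cat(sprintf("%s: %d peaks\n", fl, nrow(land$peaks_by_factor[[fl]])))
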