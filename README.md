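# regscreen

Rule-based screening for candidate target genes that are **co-bound by
several chromatin regulators at active regulatory elements**, with
candidates ranked by how specific their expression is to one cell type.

The package is written for regulatory genomicists who have peak calls in
hand — per-factor ChIP-seq peak sets (e.g. a transcription factor plus
chromatin remodelers) and the four canonical histone-mark tracks — and want
a transparent, fully testable implementation of the classic funnel:

1. **Replicate consensus.** For a factor with two replicates, keep the
   replicate-1 peaks found in replicate 2 *or* falling in a marked
   regulatory element.
2. **Common regions.** Intersect the factor peak sets; the default unit is
   the common footprint, the maximal runs of bases bound by every factor
   (an anchor-peak mode is available).
3. **Chromatin state.** Promoters are the windows from 1000 bp upstream to
   10 bp downstream of each TSS. A promoter is *active* with
   H3K4me3 ∧ H3K27ac, *repressed* with H3K27me3 and no active mark,
   *poised* with H3K4me1 and no active or repressed mark. Regions of mark
   coverage outside promoters are enhancers (*active* with H3K27ac, else
   *repressed* with H3K27me3, else *poised* with H3K4me1).
4. **Gene assignment with expression gating.** A common region at an active
   promoter is assigned to a gene if it lies in the gene's promoter window
   or within 100 kb of the promoter midpoint. Genes are classed from the
   reference cell type's expression as *not* (< Q1), *low* (Q1 ≤ v < mean),
   *medium* (mean ≤ v ≤ Q3) or *high* (> Q3); an association passes the
   gate when the element state and the class agree (active → medium/high,
   poised → low, repressed → not).
5. **Specificity ranking.** Surviving protein-coding genes are ranked by
   `score(g) = log2((v_target(g) + 1) / (max_other(g) + 1))` — the
   pseudocounted log-ratio of the target-cell-type expression over the
   strongest other cell type. Rank 1 is the most specific.

All genomic set operations run on an in-house 0-based half-open interval
algebra that is tested exhaustively against a per-base boolean-array oracle
(and cross-checked against IRanges), so every step of the funnel is
verifiable. A synthetic-data module generates a complete toy landscape —
genes, factor peaks, jittered replicates, histone marks, an expression
matrix — with a machine-readable truth manifest of planted targets, making
the whole screen checkable end to end without any external data.

## Worked example

The `analysis/` scripts are a thin narrative workflow over the package:

```sh
Rscript analysis/01_simulate.R    # toy landscape + truth -> results/sim/
Rscript analysis/02_screen.R     # the screen itself     -> results/screen/
Rscript analysis/03_robustness.R # noise sweeps          -> results/robustness.tsv
```

`02_screen.R` prints the funnel and the top candidates:

```
common regions: 20
at active promoters: 20 (100%)
candidate genes: 20
top 5 by iOL specificity:
 gene_id n_supporting_regions  link_kinds    score rank
 gene075                    1 in_promoter 3.662965    1
 gene163                    1 in_promoter 3.415957    2
 gene040                    1 in_promoter 3.328054    3
 gene194                    1 in_promoter 3.310568    4
 gene138                    1 in_promoter 3.271027    5
recovery vs truth: precision 1.000 recall 1.000
```

The 20 common regions are exactly the 20 planted target promoters; every
candidate is a planted target (precision = recall = 1 on the noise-free
landscape); the score column is the log2 ratio of iOL expression over the
strongest of OPC/mOL/astrocyte/neuron. From R the same run is:

```r
library(regscreen)
rec <- recover_targets(synthetic_config(seed = 1))
rec$scores                    # $precision 1, $recall 1, $f1 1
head(rec$result$candidates)   # ranked candidate table
```

On real data, point `run_pipeline()` at a YAML config naming your BED peak
files, gene table (TSV: `gene_id, chrom, strand, tss, biotype`) and
gene × cell-type expression TSV; it writes `candidates.tsv`,
`associations.tsv`, `common_regions.bed`, `elements.bed` and `summary.json`.

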