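---
title: "Methods: a rule-based screen for co-bound target genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a rule-based screen for co-bound target genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regscreen)
```

# The problem and the model

Chromatin regulators rarely act alone: a transcription factor and the
chromatin remodelers it cooperates with tend to co-occupy the regulatory
elements of the genes they jointly control. Given peak calls for several
such factors, the four canonical histone marks (H3K4me3, H3K27ac, H3K4me1,
H3K27me3) and a gene × cell-type expression table, the screen implemented
here asks: *which genes have an active promoter co-bound by every factor,
are expressed consistently with that chromatin state, and are specifically
expressed in the cell type of interest?* The motivating application is
oligodendrocyte biology — finding genes that key oligodendrogenesis
regulators jointly activate in immature oligodendrocytes — but nothing in
the code is specific to that system.

The screen is deliberately rule-based rather than statistical. Each rule is
an explicit, unit-testable predicate, and the package's claim is not that
these rules are optimal but that they are implemented exactly as stated.

# Coordinates and the interval algebra

All coordinates are 0-based half-open, the native BED convention; an
interval covers bases `start … end-1`. Any 1-based input would be converted
at its reader; none of the supported formats requires it. A single
convention applied everywhere is the only reliable defence against
off-by-one drift in window arithmetic.

The set operations (normalize, multi-set footprint intersection,
anchor-overlap filtering, subtraction) are implemented in-house as sorted
sweeps rather than delegated to an interval library, because the screen's
correctness reduces entirely to their correctness and we want them testable
against a brute-force oracle. The oracle paints every covered base of a
small chromosome into a logical array and reads runs back off it; the test
suite checks exact agreement on 1000+ random instances (chromosomes up to
10 kb, up to 50 intervals per set, up to 4 sets) and additionally
cross-checks normalize and pairwise intersection against IRanges.
Design points:

* **Touching intervals merge** during normalization (`[0,10)` + `[10,20)` →
  `[0,20)`): regions are treated as footprints, and two abutting peaks
  describe one contiguous stretch of bound chromatin.
* **Overlap means ≥ 1 shared base** (`min_overlap_bp = 1`, configurable),
  matching the bedtools default; abutting intervals do not overlap.
* **Footprint vs anchor counting.** The "common regions" of a multi-factor
  screen are ambiguous as a counting unit: one can count maximal runs of
  bases bound by every factor (footprint) or anchor peaks of one factor
  that every other factor touches. Footprint is the default
  (`common_mode = "footprint"`) because it is symmetric in the factors;
  `common_mode = "anchor:<label>"` provides the other reading.

# Promoters, enhancers and chromatin states

The promoter window runs from 1000 bp upstream of the TSS to 10 bp
downstream of it, strand-aware and clamped at position 0 — 1010 bp in
total, with the TSS the first base of the downstream side. Both extents are
parameters (`promoter_upstream_bp`, `promoter_downstream_bp`); the defaults
are the conventional narrow promoter used in peak-annotation practice.

A promoter element exists for every gene, annotated with every mark whose
peaks overlap the window by ≥ 1 bp. Enhancers are the maximal merged runs
of mark coverage *outside* all promoter windows, each annotated with the
marks covering ≥ 1 bp of the run; a mark peak straddling a promoter edge
contributes its inside bases to the promoter and its outside bases to the
enhancer footprint, so every marked base is accounted for exactly once
(a per-base test asserts this). The rule table is then:

| locus | active | repressed | poised |
|---|---|---|---|
| promoter | H3K4me3 ∧ H3K27ac | H3K27me3, no active mark | H3K4me1, no H3K27me3, no active mark |
| enhancer | H3K27ac | H3K27me3 (¬active) | H3K4me1 (¬active, ¬repressed) |

"Active marks" are H3K4me3/H3K27ac at promoters and H3K27ac alone at
enhancers. Anything else is `unclassified`. Two genuinely open choices:

* **Bivalent promoters** (H3K4me3 + H3K27me3, no H3K27ac, no H3K4me1)
  satisfy no rule: the active rule needs both active marks and the
  repressed rule forbids any. We leave them `unclassified` by default
  rather than silently folding them into a state the rules do not name;
  `bivalent_as = "poised"` opts into the common alternative reading.
* **Chromatin state is chromatin evidence only.** The coupling of state to
  expression ("active" elements should belong to expressed genes) is
  applied downstream as the expression *gate*, not folded into the state
  call, so the two evidence types remain separately inspectable.

# Replicate consensus

For a factor with two replicates of unequal quality, the consensus keeps
the replicate-1 peaks (whole, original coordinates) that overlap any
replicate-2 peak, plus the replicate-1 peaks falling in a marked regulatory
element; the union is deduplicated, so the consensus is always a subset of
replicate 1. The regulatory-element rescue route expresses that a peak in
good-quality chromatin context is credible even when the weaker replicate
missed it. Consensus is applied *before* the multi-factor intersection —
the factor's peak list should be finalized before asking what other factors
share it. Order matters only when the element annotation is noisy; the
pipeline holds element annotation fixed across both uses.

# Gene assignment and the expression gate

A common region associates with a gene in two ways: `in_promoter` (≥ 1 bp
overlap with the promoter window, distance 0) or `within_window` (nearest
base of the region within `gene_window_bp` — default 100 kb — of the
promoter-window midpoint). The midpoint is the midpoint of the 1010-bp
*window*, not of any peak; distance is measured to the region's nearest
base because peaks are extended objects and the nearest-base reading is the
permissive convention. A region within reach of several genes associates
with all of them — deduplication happens at the gene level, not by a
nearest-gene tie-break.

The element state backing an association is the gene's promoter element for
`in_promoter` links; for `within_window` links it is the enhancer element
overlapping the region (the most-overlapping one if several), or
`unclassified` if the region touches no enhancer. The gate then passes when
the gene's expression class is allowed for that state (defaults:
active → medium/high, poised → low, repressed → not; `unclassified` is
absent from the map and never passes). Expression classes are computed in
one named reference cell type (`gating_celltype`, defaulting to the first
expression column): the screen must state which population its "expressed"
judgement refers to.

Expression classes cut the reference column at Q1, mean and Q3:
*not* < Q1 ≤ *low* < mean ≤ *medium* ≤ Q3 < *high*, with "below"/"above"
read strictly. Quantiles use linear interpolation (R's type 7 default — the
default of the analysis environment this procedure is native to). For
right-skewed expression data the mean can exceed Q3, in which case values
between Q3 and the mean are "low" and the medium band shrinks; for
heavy-left data the low band can be empty. The bands remain exhaustive and
mutually exclusive in all cases (property-tested on 1000 random vectors).
The classes are computed on whatever units the input table carries (CPM via
`cpm()`, or already-normalized values); the choice of units is the user's
and is echoed in the run summary.

# Specificity ranking

No standard definition exists for "the most cell-type-specific gene in a
heatmap", so the package names its metric explicitly:

`score(g) = log2( (v_target(g) + 1) / (max over other cell types v(g) + 1) )`

The max (rather than mean) denominator makes the score a worst-case
contrast — a gene highly expressed in the target type *and* one other type
scores near 0 — and the pseudocount keeps it finite and shrinks ratios at
low expression. Ties break lexicographically by gene id so ranks are
deterministic. `log_ratio_mean` and `zscore` are available alternatives;
rankings agree on clear-cut cases and differ where specificity is genuinely
ambiguous, which is why the metric is a named parameter rather than a
hidden constant.

# The synthetic landscape

`generate_landscape()` plants a fully-known toy genome: by default 200
genes on alternating strands (exercising the minus-strand promoter
arithmetic), promoters spaced 30 kb along 2 chromosomes of 8 Mb; 20 target
genes whose promoters carry one peak per factor (3 factors) plus
H3K4me3 + H3K27ac; non-target promoters drawn across active/poised/
repressed/unmarked states; background factor and mark peaks confined to a
desert ≥ 100 kb from every promoter midpoint; replicate 2 of factor 1 as
jittered (± 50 bp), optionally dropped copies of replicate 1; and
negative-binomial expression (mean 500, size 10 for targets in the first
cell type; mean 50, size 5 elsewhere across 5 cell types). Peak widths are
300 ± 100 bp, typical of point-source factor calls. Target expression
classes are enforced by rejection sampling (≤ 100 rounds) so the truth
manifest is true by construction, and the whole landscape is a
deterministic function of the seed through a single Mersenne-Twister stream
with a documented draw order — two runs with the same configuration are
byte-identical.

What it emulates: co-binding at promoters, state-consistent marks,
replicate irreproducibility, specific expression, and the two noise knobs
the screen is sensitive to (replicate dropout; missing/spurious marks).
What it does **not** emulate: genome-scale peak counts, realistic peak
shapes and widths, enhancer-driven targets (planted targets are
promoter-bound), correlated noise between marks, chromosome-name
inconsistencies, and mapping artefacts. Perfect recovery on the noise-free
landscape therefore shows the plumbing is exact — every planted signal
survives every rule — not that the rules would isolate true targets in real
data, where the interesting failure modes are biological, not algorithmic.
Under the standard noisy setting (10% dropout, 5% mark noise) recall is
expected near `(1 − 0.05)² ≈ 0.90`: a target is lost when either required
active mark drops, while the consensus rule's element-rescue route makes
dropout nearly free.

# Numerical choices and degenerate inputs

* Windows are clamped at chromosome start; promoter windows may overlap
  each other and a region then associates with every overlapped gene.
* An empty factor peak set yields zero common regions and a valid empty
  candidate table with a fully populated summary.
* Genes absent from the expression table gate to `FALSE` with a warning,
  never silently.
* `pct_active_promoter` is `NA` (not 0) when there are no common regions.
* Interval scores are carried as text so BED round-trips are
  byte-identical; scores take no part in computation.
* Chromosome names are taken literally; `normalize_chrom_names` must be
  set explicitly to strip or add `chr` prefixes.

# Problem sizes in the test suite

The oracle-equivalence suite uses 1000+ random instances on ≤ 10 kb
chromosomes with ≤ 50 intervals per set; recovery tests run the full
screen on the default 200-gene landscape across 20 noise-free and 10 noisy
seeds; classification properties use 1000 random vectors. These sizes give
sub-minute suites while exercising every code path at densities (peak
width ≈ 3% of chromosome length) far above genomic reality, which makes
collision-driven edge cases *more* frequent in tests than in use.

# Known limitations

Enhancer-mediated regulation is only partly represented: a distal region
inherits an enhancer state but candidate discovery is promoter-centric by
default. There is no statistical enrichment testing of the overlaps (no
permutation p-values), no signal-level analysis (peaks only), no
FPKM/length normalization, and the screen trusts its inputs'
chromosome-name conventions modulo the explicit normalization flag.
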