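---
title: "Modelling transcript abundance from TSS-anchored histone-modification signal"
author: "xylosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcript abundance from TSS-anchored histone-modification signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylosig)
```

## The problem

Trimethylation of histone H3 lysine 4 (H3K4me3) and lysine 27 (H3K27me3)
mark transcriptionally active and Polycomb-repressed chromatin,
respectively. In tissues such as developing secondary xylem, where the
two antagonistic marks coexist on overlapping gene sets, three questions
recur: how much of steady-state transcript abundance is reflected in the
local ChIP-seq signal of each mark; whether the *genomic span* of a mark
(its peak length, a proxy for the number of consecutively modified
nucleosomes) carries biological information beyond mere presence; and
whether marked genes differ in tissue specificity. `xylosig` packages the
full analysis chain for these questions — signal quantification, state
classification, predictive modelling, span clustering and specificity
statistics — together with a synthetic-data generator that plants known
structure so that every stage can be validated end to end.

## Signal quantification

All coordinates are handled as `GRanges`/`IRanges` (1-based, closed), the
Bioconductor convention; BED-family inputs are converted at the boundary
by `rtracklayer`. Coverage lives in a `CoverageTrack` (run-length encoded
per-base coverage, one library per object).

The elementary quantity is **nett coverage**: the average per-base
coverage of the treatment library minus that of its input control over a
region. It is deliberately *not* floored at zero — the regression below
treats signal as a continuous covariate, and local depletion is
information.

Per gene, the window of ±2 kb around the TSS is divided into forty 100-bp
bins, numbered 1 (most upstream, −2000..−1900) to 40 (most downstream),
in the direction of transcription; bin 21 is the first bin downstream of
the TSS and bin 25 sits 400–500 bp downstream, the canonical position of
the H3K4me3 maximum. For minus-strand genes the physical window is
reflected so that a bin index always means the same oriented distance
from the TSS. Bins that reach past a chromosome end contribute zero
coverage over the missing bases while keeping the full 100-bp
denominator, so edge genes are not silently inflated.

Two aggregate signals complete the per-gene feature set: the **total
signal** (nett coverage averaged over the whole transcribed region —
being a per-base average it is free of gene-length bias by construction)
and the **peak length** (genomic span of the longest significant peak
overlapping the gene, 0 if none). TSS metaprofiles normalize each track
to counts per million before averaging so that treatment and input are
comparable; "relative coverage" is not otherwise defined by the upstream
tools, and CPM is the minimal choice that makes libraries of different
depth commensurable.

## Occupancy and bivalency

A gene is *occupied* by a mark when its transcribed region overlaps a
significant peak by at least one basepair — a deliberately permissive
rule that matches how target lists are built in practice. Combining two
marks yields four mutually exclusive states (`K4only`, `K27only`,
`bivalent`, `unmarked`); the bivalent count is reported as a percentage
of the repressive-mark set, the convention used when asking what
fraction of Polycomb targets may be poised. With 5,776
repressive-mark genes of which 2,708 are also activating-marked, the
package reports 46.9%:

```{r bivalency}
ids <- sprintf("g%05d", 1:25000)
k4set <- ids[1:19605]
k27set <- c(ids[1:2708], ids[20001:23068])
k4 <- data.frame(gene_id = ids, occupied = ids %in% k4set,
                 peak_length = ifelse(ids %in% k4set, 50L, 0L))
k27 <- data.frame(gene_id = ids, occupied = ids %in% k27set,
                  peak_length = ifelse(ids %in% k27set, 50L, 0L))
round(classifyStates(k4, k27)$bivalent_pct_of_k27, 1)
```

When a gene is overlapped by several peaks, its `peak_length` feature is
that of the *longest* overlapping peak: deterministic, and aligned with
the span signal the clustering analyses. Category
enrichment/depletion (tandem duplicates, TE families) is measured
against the expectation that the category inherits the genome-wide
marked fraction, with a two-tailed hypergeometric p-value constructed by
doubling the smaller tail (capped at 1). Tail-doubling is one of several
defensible two-tailed constructions; it is stated here because results
near the tails differ slightly between constructions. The Fisher 2×2
path instead uses minimum-likelihood summation, matching `fisher.test`
and `binom.test`.

## The expression model

FPKM is mapped through the Yeo-Johnson transform, the power-family
transform defined for all reals (so FPKM = 0 needs no pseudocount and
zero-FPKM genes are retained by default). The exponent λ maximizes the
normal-theory profile log-likelihood over [−3, 3]; the optimizer is
`stats::optimize` (golden-section with parabolic refinement, tolerance
1e−6), checked in the tests against a dense grid and against
`car::powerTransform`.

Each mark's predictive feature is chosen by a **bin scan**: the Pearson
correlation of each of the 40 bin signals with transformed expression,
selecting the bin maximizing |r| and reporting the signed r. Magnitude
is the criterion because a repressive mark's most informative bin is its
most *negative* one; ties resolve to the lowest bin index. Whether the
scan correlates against transformed or raw FPKM is a flag
(`scanTransformed`, default transformed).

The model itself is ordinary least squares with intercept on a
reproducible 60/40 train/test split. Test-set accuracy is the squared
Pearson correlation between predicted and observed — robust to
calibration shifts, and therefore the reported `R2_test`. Per-predictor
contributions are **partial eta-squared** with Type-II sums of squares:
for predictor *j*, `SS_j` is the increase in residual sum of squares
when *j* is dropped from the full model, and
η² = SS_j / (SS_j + SS_residual) — the fraction of otherwise-unexplained
variance that the predictor uniquely accounts for. The implementation
refits from the model matrix directly; `car::Anova(type = 2)` serves as
an independent oracle in the test suite.

## Peak-length classes and term-pattern clusters

Genes occupied by a mark are ranked by peak length and cut into four
contiguous, near-equal classes (class 1 shortest; earlier classes absorb
the remainder; ties break lexicographically by gene id, making the
assignment deterministic). Within each class, flat term
over-representation is tested one-sided against a hypergeometric null
and BH-adjusted within the class; a term is "present" in a class at
adjusted p < α (default 0.05). The default background is the occupied
gene set — the question being *where along the span axis* a term
concentrates, not whether it is enriched among occupied genes at all —
with `background = "genome"`-style overrides available.

Each term's 4-bit presence pattern falls into one of 2⁴ − 1 = 15
possible nonzero clusters. The **weighted peak-length score** of a
pattern multiplies presence in classes 1–4 by 0.1–0.4 and divides by the
number of present classes, so it lies in [0.1, 0.4]; a pattern and its
class-reversal sum to 0.5. Clusters are enumerated by descending score
(ties by descending bit value), so cluster 1 is always the
longest-peaks-only pattern `(0,0,0,1)` with score 0.4. Cluster
inflation/deflation is an exact two-sided binomial test of each
cluster's term count against the uniform rate 1/15. A diagnostic
correlation of peak length against gene length is reported alongside, to
rule out gene-length bias behind the class enrichments.

## Tissue specificity

Specificity uses the Shannon entropy of a gene's relative expression
across T tissues, in bits: 0 when expression is confined to one tissue,
log₂ T when uniform. The entropy is computed on the raw FPKM simplex
(p_t = FPKM_t / ΣFPKM), with no per-gene max-normalization beforehand —
the simplest index with those bounds, stated explicitly because several
variants circulate. It is scale-invariant per gene and
tissue-permutation-invariant, both property-tested. Categories are
compared by two-sample Kolmogorov–Smirnov tests with direction reported
as the sign of the median difference. For the discrete view, each gene
is assigned to the tissue of its maximum FPKM (ties deterministically to
the lowest tissue index, with the tie fraction reported), and the
category × tissue counts go through a global Pearson chi-squared test
with post-hoc adjusted standardized residuals,
(O − E)/√(E(1 − rowsum/N)(1 − colsum/N)), which are approximately
N(0, 1) under independence and localize the deviating cells.

## The synthetic study generator

`simulateStudy()` produces every input the pipeline consumes — GFF3-able
gene models with internal UTR/exon/intron structure, bedGraph-able
treatment/input tracks for both marks, narrowPeak-able peak calls, a
multi-tissue FPKM table, a flat term map and category labels — plus the
planted truth needed to score recovery.

The central design decision is the planted dependence structure. Per
gene, a latent standardized transformed expression *y* ~ N(0,1) is
drawn, and each mark's planted bin signal is s = ρ·y + √(1−ρ²)·ε with
independent noise, so ρ is exactly the planted signal–expression
correlation. Given a target two-predictor population R² (default 0.50)
and an activating:repressive effect-variance ratio q = ρ_act²/ρ_rep²
(default 10), the activating correlation solves
(2 − R²)a² − (q + 1)a + qR² = 0 with a = ρ_act², which makes the
population R² of the regression of y on both signals equal the target
*exactly* (the two signals acquire correlation ρ_act·ρ_rep ≈ −0.15).
The defaults give ρ_act ≈ 0.698, ρ_rep ≈ −0.221, population partial
η² ≈ 0.474 / 0.026. For calibration-style checks the config can instead
pin ρ_act directly (`calibrateRAct = 0.65`), keeping the 10:1 ratio.

Focal-tissue FPKM is expm1(μ + σ·y) with log-scale draws below zero
becoming FPKM 0 (about 2% of genes at the default μ = 2, σ = 1), so
log1p(FPKM) is linear in y and the Yeo-Johnson fit lands near λ ≈ 0; the
recovered λ is data-dependent and is not asserted against any external
value. Tissue structure multiplies a Dirichlet proportion vector:
broad genes use a symmetric concentration of 10 (mean entropy within
~0.1 bit of log₂ 7), a 30% tissue-specific fraction uses concentration
20 on one dominant tissue and 0.2 elsewhere (mean entropy well under
1 bit). Because each gene's row is rescaled so that its focal column
equals the planted focal FPKM, and entropy is scale-invariant, the
entropy structure and the regression link coexist without interference.

Coverage tracks are piecewise-constant at the 100-bp bin resolution
inside the ±2 kb window and coarser outside; all consumers are
resolution-agnostic (tested by comparing merged and re-segmented
tracks). The treatment track adds, on top of the shared baseline, a
Gaussian envelope (sd 250 bp) centred on the planted bin whose height in
that bin is exactly 5 + s in coverage units; neighbouring bins receive
independent per-bin noise (sd 0.6) so the planted bin strictly maximizes
|r| in expectation and the bin scan is genuinely discriminative rather
than trivially tied. Genes are spaced ≥ 4.5 kb apart so neighbouring TSS
windows never overlap and planted signals cannot bleed between genes.

Peaks are centred on the TSS of a configured fraction of genes
(defaults 0.54 activating / 0.16 repressive, the approximate marked
fractions in woody-tissue data) with log-normal lengths independent of
gene length; "xylogenesis-like" planted terms are drawn exclusively from
the longest-peak quartile, so the clustering procedure should recover
the `(0,0,0,1)` pattern at score 0.4. Category labels plant a
configurable enrichment fold among marked genes while preserving the
overall category fraction.

What the generator does *not* emulate: read-level noise and mapping
artefacts, replicate structure and peak-calling uncertainty, correlated
signals between neighbouring genes, DAG structure among terms, and any
dependence of expression noise on expression level. Passing tests
therefore demonstrate that the implementation recovers planted
population structure under idealized sampling, not that real tissues
satisfy the model.

## Numerical choices and degenerate inputs

* Correlations of constant vectors are undefined; the package returns
  `NA` with a warning (`densityCorrelation`, `profileCorrelation`,
  `lengthVsGeneLength`) rather than a silent value.
* Empirical permutation p-values use the +1 correction,
  (1 + #{null at least as extreme}) / (1 + n_perm), doubled and capped
  at 1 — never exactly 0. The null re-places each peak uniformly within
  its own chromosome, preserving its length.
* The collinearity warning in the regression triggers at condition
  number 1e4 and carries variance inflation factors; a rank-deficient
  fit is an error, not a warning.
* bedGraph inputs with overlapping intervals are rejected; fractional
  coverage accumulates cumulative-sum float dust, which the track
  constructor clamps only within −1e−6 of zero.
* All simulation randomness flows from a single config seed through
  derived streams; callers' RNG state is saved and restored around every
  seeded internal.

## Problem sizes

The default study conditions — 5,000 genes, 2 chromosomes, 7 tissues —
are the scale at which all planted-recovery checks run; the regression
recovery is additionally replicated over five generator seeds, and the
clustering null over 100 label permutations. These sizes were chosen so
that sampling noise on a correlation is ~0.014 (n = 5,000), an order of
magnitude below every margin being asserted.

## Known limitations

One gene is one transcribed region; isoforms are assumed collapsed
upstream (e.g. to the longest transcript) and no attempt is made to
infer a collapse rule. Term enrichment is flat — no ontology DAG
propagation or semantic collapsing. The regression is a single 60/40
split by design (matching the analysis it operationalizes), not a
cross-validation scheme, and makes no causal claim: signal predicts
abundance in the statistical sense only.
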