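# xylosig

Integrative analysis of antagonistic histone marks (H3K4me3-like
activating, H3K27me3-like repressive) and transcript abundance around
transcription start sites, for epigenomics analysts working with
ChIP-seq coverage, peak calls and multi-tissue RNA-seq in systems such
as developing secondary xylem.

The package implements, as tested reusable functions:

* **Signal quantification** — nett (treatment − input) per-base
  coverage; forty 100-bp bins anchored at the TSS (±2 kb, strand
  oriented; bin 21 starts at the TSS, bin 25 sits 400–500 bp
  downstream); length-normalized total signal; CPM-normalized TSS
  metaprofiles, optionally stratified by expression class.
* **Occupancy and bivalency** — a gene is occupied when any significant
  peak overlaps its transcribed region by ≥ 1 bp; four mutually
  exclusive chromatin states with the bivalent share of the
  repressive-mark set; category enrichment/depletion versus the
  marked-fraction expectation (two-tailed hypergeometric); summit
  annotation against a priority-resolved genome partition; genome
  coverage fractions; peak-density correlations; nonspecific-peak
  subtraction; a chromosome-bounded length-preserving permutation null
  for TE-family overlap.
* **Expression model** — Yeo-Johnson transform of FPKM with λ optimized
  by profile likelihood; a per-mark bin scan selecting the bin with
  maximal |Pearson r| against transformed expression (signed r
  reported); 60/40 train/test multiple linear regression with
  `R²_test = cor(pred, obs)²`; partial η² (Type-II SS) variance
  partitioning per predictor.
* **Peak-length clusters** — four equal-size peak-length classes;
  per-class one-sided hypergeometric term enrichment (BH within class);
  the 15 nonzero presence patterns as clusters, ranked by the weighted
  peak-length score `s = Σ pattern_c · 0.1c / Σ pattern_c ∈ [0.1, 0.4]`;
  exact two-sided binomial inflation test per cluster against p₀ = 1/15.
* **Tissue specificity** — Shannon entropy `H = −Σ p_t log₂ p_t` of the
  FPKM simplex (0 = one tissue, log₂ T = uniform); KS comparisons
  between chromatin-state categories; mean relative-expression profiles;
  max-tissue discretization with a global chi-squared test and post-hoc
  adjusted standardized residuals.
* **Synthetic study generator** — genomes, coverage tracks, peaks, term
  maps, labels and a 7-tissue expression matrix with *planted* structure
  (signal–expression correlations, population R², term–peak-length
  coupling, entropy structure, enrichment folds), deterministic given a
  seed, so every pipeline stage is testable without external data.

Data containers are Bioconductor idiom: genes and peaks are `GRanges`,
coverage is an S4 `CoverageTrack` over `RleList`, the fitted model is an
S4 `RegressionReport` with accessors.

## Worked example

Simulate a study with known planted structure, quantify signals, and
model transformed FPKM from the two marks:

```r
library(xylosig)

st <- simulateStudy(simConfig(seed = 3))
ft <- quantifyGenes(
  st$genes,
  list(k4  = c(st$tracks$activating,  list(peaks = st$peaks$activating)),
       k27 = c(st$tracks$repressive, list(peaks = st$peaks$repressive))),
  fpkm = setNames(st$expression[, "DSX"], rownames(st$expression)))
report <- runModelPipeline(ft, c(k4 = "bin", k27 = "bin"), seed = 11)
report
#> RegressionReport (3000 train / 2000 test genes)
#>   lambda  : -0.05883
#>   R2 train: 0.5042   R2 test: 0.5116
#>   partial eta-squared:
#>     k4_bin25                 0.4794
#>     k27_bin21                0.0261
#>   bin scan k4           bin 25, r = 0.703
#>   bin scan k27          bin 21, r = -0.226
```

Reading the output: the bin scan recovered the planted predictive bins
(25 for the activating mark, 21 for the repressive one); the activating
signal correlates strongly and positively with transformed abundance
(r = 0.70), the repressive signal weakly and negatively (r = −0.23); the
two-predictor model explains ~51% of held-out variance, of which the
activating mark uniquely accounts for the overwhelming share
(η² 0.479 vs 0.026) — all in line with the generator's planted
population values (ρ = 0.698/−0.221, R² = 0.50).

The peak-length clustering on the same study recovers the planted
"xylogenesis-like" terms in the top-scoring cluster:

```r
cl <- runClusterAnalysis(st$truth$peakLengthsActivating, st$termMap)
subset(cl$summary, term_count > 0)
#>    cluster_id pattern score term_count fold direction      p_value
#> 1           1    0001   0.4         10   15         1 1.733153e-12
```

A thin command-line wrapper over these functions ships at
`inst/scripts/xylosig.R` (subcommands `simulate`, `quantify`,
`metaprofile`, `model`, `clusters`, `specificity`).

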