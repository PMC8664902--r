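---
title: "Window-based differential methylation analysis for MeDIP-Seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based differential methylation analysis for MeDIP-Seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

# The analysis problem

MeDIP-Seq measures DNA methylation indirectly: sonicated genomic fragments
(150-300 bp) are immunoprecipitated with a 5-methylcytosine antibody and
sequenced, so the data are *enrichment counts*, not per-base methylation
fractions. An epigenome-wide association study (EWAS) on such data asks, for
two groups of samples (e.g. controls vs. rheumatoid-arthritis patients),
where along the genome the methylation enrichment differs. The analysis unit
is a fixed 1 kb genomic window; regions of one or more adjacent
differentially methylated windows are reported as differential DNA
methylation regions (DMRs), the candidate epimutation biomarkers.

`medipdmr` implements that workflow end to end:

1. tile the genome into 1 kb windows (`tile_genome`),
2. count fragments per window by midpoint (`count_fragments`),
3. filter low-count windows (`filter_windows`),
4. test each window with a negative-binomial exact conditional test under
   TMM normalization (`diff_test`),
5. merge adjacent significant windows into DMRs (`call_dmrs`),
6. annotate DMRs with CpG density and nearby genes (`summarize_dmr`,
   `associate_genes`),
7. compare DMR sets across cohorts or cell types (`venn_overlap`,
   `extended_overlap`, `find_clusters`),
8. summarize samples by PCA over DMR windows (`compute_pca`).

A synthetic-data module (`generate_genome`, `simulate_cohort`,
`simulate_window_counts`, `emit_fragments`) generates complete datasets with
known injected DMRs, so every stage is testable without sequencing data.

# The statistical model

## Count model

The count of sample $j$ in window $w$ is modelled as negative binomial with
mean $\mu_{wj}$ and dispersion $\phi$, using the mean-variance relation

$$\operatorname{Var}(y_{wj}) = \mu_{wj} + \phi\,\mu_{wj}^2 .$$

$\phi = 0$ recovers the Poisson; $\phi \approx 0.1$ is typical biological
replicate variability for enrichment counts. $\mu_{wj}$ factorizes into a
window proportion and the sample's effective library size.

## TMM normalization

Between-sample composition bias is removed with trimmed-mean-of-M-values
scaling (`tmm_factors`): each sample is compared to an automatically chosen
reference; per window, the log-ratio of relative abundances (M) and average
log abundance (A) are formed over windows observed in both samples; the most
extreme 30% of M and 5% of A are trimmed on each side; the factor is the
precision-weighted mean of the surviving M-values, and factors are rescaled
to geometric mean 1. Effective library size = raw library size x factor.

## Dispersion estimation

Dispersion is estimated by conditional maximum likelihood after a
quantile-to-quantile adjustment of the counts to a common library size (the
geometric mean of the effective sizes). The adjustment maps each count
through matched normal and gamma approximations of its NB distribution and
averages the two (`estimate_dispersion`). The common $\phi$ maximizes the
conditional log-likelihood of the adjusted counts given each window's group
total, summed over windows; two rounds of adjust-then-maximize are used,
starting from $\phi = 0.01$. Optional per-window (tagwise) estimates
maximize a weighted likelihood that adds `prior_df` (default 10) residual
degrees of freedom of the genome-wide average likelihood, shrinking windows
toward the common value; with 13 samples per arm the tagwise estimates sit
close to the common one by design.

## Exact conditional test

For a two-group design the per-window test conditions on the total of the
adjusted group sums: with per-group NB size $n_g/\phi$, the reference-group
sum follows a negative hypergeometric distribution given the total
(binomial when $\phi = 0$). The two-sided p-value doubles the smaller tail,
including the observed outcome's full probability mass in its tail, capped
at 1 — a deterministic and slightly conservative convention. The log2 fold
change (case vs. control; positive = methylation gain in cases) is computed
from the adjusted group means with a moderation prior count of 0.125; the
prior never enters the p-value. FDR is controlled with Benjamini-Hochberg
q-values (`adjust_fdr`).

## DMR calling

Windows with $p <$ `p_threshold` (strict inequality; default $10^{-4}$)
are merged into maximal runs of genomically contiguous *tested* windows:
adjacency means consecutive genome-wide window indices, so a window removed
by the count filter breaks a run. DMR boundaries are the union of the
constituent significant windows only. Each DMR records its number of
significant windows, minimum p and q, signed maximum log fold change, CpG
count (brute scan of the reference sequence) and CpG density per 100 bp.

A note on the threshold ladder (`threshold_ladder`): the DMR count is
non-increasing as the cutoff tightens whenever significant windows are
sparse (the practical regime at stringent cutoffs), but it is not a theorem
in general — tightening can split a multi-window run into several DMRs.
The significant-window total, by contrast, is always monotone; the tests
distinguish the two regimes.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_size` | 1000 | bp | the field-standard MeDIP analysis resolution |
| `min_avg_count` | 5 | fragments/window | keeps NB testing powered at n = 13/arm |
| `p_threshold` | 1e-4 | — | strict DMR-calling cutoff |
| `relaxed_threshold` | 0.05 | — | extended-overlap relaxed window cutoff |
| `gene_distance` | 10000 | bp | covers proximal and distal promoters |
| `prior_df` | 10 | df | tagwise dispersion shrinkage weight |
| cluster `span` / `min_dmrs` | 2e6 / 3 | bp / count | package defaults; no external criterion exists for DMR clusters |

# The synthetic generator: what it emulates and what it does not

The generator's defaults emulate the study conditions at desk scale: two
1 Mb chromosomes (2,000 windows), cohorts of 13 control + 13 case samples,
log-normal library sizes around 2.5e5 fragments per sample (a 1/100
miniature of ~25 million reads per sample), NB dispersion 0.1, sonicated
fragment lengths uniform on 150-300 bp, and injected DMRs of 1-3 windows
with signed log2 fold changes of magnitude 2. The designed CpG landscape
spans the low-density "CpG desert" range (1-3 CpG/100 bp) in which MeDIP
DMRs predominantly reside, with occasional denser blocks; the window
baseline follows $\mu \propto 1 + 0.5\,d$ with $d$ the realized CpG density
per 100 bp, reflecting that MeDIP enriches methylated CpG-containing
fragments (the exact shape is immaterial to the tests). Ages are drawn
uniformly on 30-75 years and have no effect on counts — age is descriptive
in the emulated design.

The generator deliberately omits: read-level sequence simulation and
alignment error, PCR duplicates, mappability and GC bias, sex chromosomes
and copy-number effects, and any covariate structure (age, site, race)
influencing counts. Passing tests therefore demonstrate the pipeline's
statistical and structural correctness under the stated NB model — not
robustness to those real-data artifacts.

Two construction choices make tests sharp. CpG planting is exact:
`round(L d / 100)` CG dinucleotides are placed at random non-overlapping
positions in a CG-free background, so realized density equals the design up
to rounding and a 0-density region contains no CG at all. Fragment
placement draws the midpoint uniformly inside the source window and trims
both ends symmetrically at chromosome bounds (preserving the midpoint), so
`emit_fragments` followed by `count_fragments` is the identity on count
matrices.

# Numerical and design choices

- **Coordinates** are 0-based half-open (BED) everywhere internally;
  "overlap" means >= 1 bp intersection of half-open intervals.
- **Midpoint assignment** (not overlap-weighted) makes counting invertible
  and unambiguous; trailing partial windows are kept, and their true length
  is used in density arithmetic.
- **Library sizes** are column sums at construction; the count filter keeps
  the full-depth values, since they describe sequencing depth rather than
  the tested subset.
- **Exact test variant**: classic exact conditional testing with
  common + tagwise dispersion was chosen over GLM/quasi-likelihood because
  the design is a plain two-group comparison; covariate adjustment is out
  of scope.
- **Sign conventions**: fold changes are case vs. control with the first
  factor level as reference; PCA fixes each component's sign by making its
  largest-magnitude loading positive, so outputs are byte-stable.
- **Gene association** uses the interval gap to the gene *body* (not the
  TSS), inclusive at 10 kb; this is the only reading consistent with most
  DMRs overlapping their gene while the distance window is said to capture
  promoters. Strand never enters the distance. Abutting intervals get
  distance 0.
- **Cohort statistics** report mean and SEM (sd/sqrt(n)) per group with a
  pooled-variance Student t-test between arms (Welch behind a flag);
  published cohort tables of this design print values matching SEM even
  where legends say SD, so SEM is the implemented statistic.
- **Degenerate inputs**: empty DMR sets produce empty (not missing)
  tables; a filter that removes every window, a zero-length chromosome, a
  zero-library sample, and a truth region outside the genome all fail fast
  with named errors.
- **Ties**: maxLFC takes the first window on ties of |log fc|; DMR names
  are `DMR_<chrom>_<k>` in genomic order, deterministically.

# Problem sizes used by the tests

The suite runs the full statistical chain at 2,000 windows x 26 samples
(the desk-scale study conditions) for calibration, dispersion-recovery and
DMR-recovery checks; far-tail calibration pools 100 replicate null
simulations of 1,000 windows (1e5 p-values); oracle-equivalence checks use
randomized instances of <= 100 windows against brute-force O(n^2)
references. The end-to-end pipeline test runs a 2 x 0.2 Mb genome with 26
samples through files on disk, twice, and compares checksums.

# Known limitations

- The exact test's doubled-tail convention is mildly conservative at loose
  thresholds (visible only when pooling ~1e5 null p-values); it is never
  anti-conservative in our simulations.
- Tagwise shrinkage uses a single genome-wide anchor rather than an
  abundance-dependent trend.
- Combined multi-site cohorts are treated as a plain two-group design; any
  site/population confound is the user's responsibility to consider.
- The quantile adjustment uses normal/gamma approximations to the NB; for
  extremely low counts (filtered out by default) the adjustment is
  approximate.
- Overlap analytics report structure only; no permutation significance of
  overlaps is computed.

# A minimal run

```{r example, eval = FALSE}
sim <- simulate_dataset("inputs", seed = 1)
cfg <- default_config("demo",
                      sample_sheet = sim$sample_sheet,
                      fragments_dir = sim$fragments_dir,
                      genome = sim$genome,
                      truth = sim$truth)
run <- run_comparison(cfg, "outputs")
run$dmr_set
extended_overlap(list(demo = run$dmr_set), list(demo = run$results))
```
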