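---
title: "Methods: absolute microbiome profiling, load estimation, and bile-acid quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute microbiome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coproquant)
```

# The measurement problem

16S rRNA gene amplicon sequencing is compositional: read counts inform
only about *fractions* of a community. Two biologically opposite events —
a taxon collapsing versus the rest of the community expanding — produce
identical relative profiles. The remedy implemented here is to anchor
each sample's relative profile to an independently measured *total* 16S
copy load, producing absolute abundances (copies per gram of lumenal
contents, or per 100 ng of mucosal DNA). The package is organized around
a mouse self-reinoculation (coprophagy) study design — four treatment
groups, six gastrointestinal sites, lumenal contents plus mid-small-
intestine mucosa and gallbladder bile — but every stage is a generic
operation on plain tables.

# Load estimators

**qPCR.** Each run carries a 10-fold standard dilution series; the curve
Cq = a + b·log₁₀(copies) is fit by OLS and reported with R² and
efficiency 10^(−1/b) − 1 (a valid run has b < 0). Sample copies are the
inverse prediction 10^((C̄q − a)/b) from the mean of triplicate Cq values
(wells that fail to amplify are dropped; if fewer than two remain, the
sample is flagged below the detection limit). The 95% CI propagates
*both* variance components — the triplicate SEM and the calibration-line
uncertainty at the observed Cq (delta method on the inverse prediction,
Welch–Satterthwaite degrees of freedom). Ignoring the curve component is
tempting but measurably anticonservative: in simulation it drops coverage
of the nominal 95% interval to ~90%, while the combined interval covers
at ~95%.

**ddPCR.** With K of N droplets positive and droplet volume v, mean
occupancy is λ = −ln((N−K)/N) and concentration λ/v × dilution. The CI
is the exact (Clopper–Pearson) binomial interval on the positive fraction
pushed through the same transform. Saturated runs (K = N) are flagged
`above_range`; runs under 3 positive droplets are flagged `below_llod`
(the conventional instrument calling floor), with K = 0 reported as 0
plus an upper bound. The droplet volume defaults to 0.85 nL, the usual
vendor value; it is a parameter, not a constant.

**MPN.** For a serial-dilution culture assay with nᵢ wells receiving
volume vᵢ of original sample and pᵢ positive wells, the log-likelihood
is ℓ(λ) = Σᵢ [pᵢ ln(1 − e^{−λvᵢ}) − (nᵢ − pᵢ)λvᵢ], maximized by a 1-D
search over log₁₀λ (interval [−9, 15], tolerance 1e−10; unimodal in λ).
The 95% CI uses the log-normal approximation on ln λ with the observed
Fisher information I = Σ nᵢ(λvᵢ)² e^{−λvᵢ}/(1 − e^{−λvᵢ}). All-negative
plates are reported as 0 with the upper bound solving P(all negative) =
0.05; all-positive plates as `above_range` with the analogous lower
bound. No small-sample bias correction is applied; the default design
(8 ten-fold dilutions × 8 wells, 10 µL inoculum — so the first dilution
delivers 10⁻³ mL of original sample per well) fixes SE(ln MPN) near 0.4,
which means a *correct* MPN estimate typically deviates ~30% from truth.
That imprecision is a property of the assay, not of the estimator: the
implementation agrees with a dense grid-search likelihood oracle to
better than 0.1% and its intervals cover at ~95%. Claims that require
~10% point accuracy are attainable with the molecular assays only.

# Absolute profiling

Counts become fractions per sample (all-zero samples are flagged and
excluded), then each row is multiplied by its sample's load. A per-cell
lower limit of detection equals the load equivalent of a single read at
that sample's depth; cells under it — and all cells of samples whose
load itself is below the assay LLOD — carry a flag rather than being
altered. Zeros stay zero; the only pseudocount in the package lives
inside the CLR transform.

Two contaminant filters run in sequence and their flags are unioned:

1. **Prevalence rule** — any taxon with zero counts in every
   cecum-contents sample but reads elsewhere is flagged. Cecum contents
   profile the full lower-gut community, so a genuine gut organism should
   appear there at least once.
2. **Frequency score** — reagent contaminants enter at a fixed ambient
   mass per reaction, so their read *fraction* scales inversely with
   sample DNA concentration. For each remaining taxon with ≥ 5 nonzero
   samples, the residual sum of squares of log(frequency) under a
   contaminant model (slope fixed at −1 against log concentration) is
   compared with a constant-frequency biological model:
   score = SSRc/(SSRc + SSRb) ∈ [0, 1], flagged below 0.5. The score is
   symmetric by construction, which is why 0.5 is the natural default.

Removal re-normalizes relative tables but never rescales absolute
tables: deleting a contaminant removes artifactual mass, and the
remaining absolute values are already in physical units. (A consequence
worth knowing: with contaminants present, the estimated biological
fractions are depressed by the share of reads the contaminants consumed,
so exact ground-truth recovery is only defined for contaminant-free
input; the exact-identity test runs with an empty contaminant panel, and
the contaminated case is checked by rank correlation instead.)
Chloroplast and mitochondrial (Rickettsiales-labelled) amplicons of
dietary origin are kept by default and dropped on request.

Taxonomic collapse follows the QIIME2 "collapse" convention: lineages
are padded to the target depth with an empty-rank placeholder, so an ASV
unassigned below, say, order still aggregates under its deepest assigned
prefix. Row sums are conserved at every level, and collapsing at genus
then order equals collapsing at order directly.

# Functional gene content

Absolute abundances are in 16S copies; dividing each ASV by its
predicted per-genome 16S copy number yields genome equivalents, and the
matrix product with a per-ASV gene-copy table gives absolute
KEGG-ortholog abundances: gene[s,k] = Σₐ genomes[s,a]·copies[a,k]. The
hidden-state prediction that produces the gene-copy table is consumed as
data, never re-derived; the package adds only the absolute-scaling
arithmetic, which is linear — group contrasts in total load carry
straight through to gene content. Predicted gene copies are not enzyme
activity; the bile-acid module provides the metabolic read-out that can
corroborate (or contradict) an inference.

# Bile-acid quantification

Peak areas from a targeted LC-MS run are processed in four steps:

1. **Drift correction.** A pooled QC sample injected first and after
   every 8 injections tracks sensitivity drift; per species, a
   piecewise-linear factor through QC-area ratios is interpolated over
   injection index and divided out (injections outside the QC bracket use
   the nearest QC's factor). A piecewise-linear model is the weakest
   assumption consistent with periodic QC anchoring; a global polynomial
   would extrapolate.
2. **Calibration.** A 7-point series (0.05–30 µM), collected three times
   within the run, is pooled into one weighted least-squares line per
   species. The default weighting is 1/x: detector noise is close to
   proportional (constant CV), and an unweighted fit lets the 30 µM
   standards dominate, biasing the intercept by amounts that materialize
   as spurious ~0.1 µM signals at the bottom of the range — precisely
   where below-LLOQ censoring decisions are made.
3. **Inversion and units.** The response is the analyte/IS area ratio
   when a matched deuterated internal standard (fixed 5 µM) exists,
   otherwise the corrected area. Extract concentrations below the lowest
   calibration level (0.05 µM) are set to 0 and flagged `below_lloq`;
   above 30 µM they are reported but flagged. Per-sample amounts apply
   the recorded dilution chain — ×100 for contents (extraction in 9
   volumes, 10% decant, reconstitution at ×100 of the original sample;
   with 1 g ≈ 1 mL the chain is mass-free), ×10 000 for bile (pre-diluted
   ×10 in ethanol and ×10 in water) — giving nmol/g contents and nmol/mL
   bile. Units are explicit metadata on every output. The co-eluting
   UDCA/HDCA pair is reported once, as a sum, under `"UDCA+HDCA"`.
4. **Pool summaries.** With every panel species classified on two axes
   (tauro/glyco/unconjugated; primary/secondary), each sample reports its
   total pool, fraction unconjugated, and fraction secondary (conjugated
   plus unconjugated secondary species over total). Fractions are
   invariant under uniform scaling, so they are robust to any residual
   per-sample recovery factor.

# Statistics

* **CLR PCA** (relative data): a pseudocount equal to the global minimum
  nonzero value is added to zero cells only, then ln(x) − mean(ln x) per
  row. CLR rows sum to zero and the transform is invariant to per-sample
  count scaling.
* **log₁₀-standardized PCA** (absolute data): per feature,
  (log₁₀x − mean)/SD with the sample (n−1) SD — the convention is
  recorded because "mean 0, SD 1" alone does not pin it down. Zeros are
  floored (default: smallest positive cell / 10) before the log;
  zero-variance features are dropped with a warning. PCA itself is exact
  (SVD of the centered matrix) with a deterministic sign convention: the
  largest-magnitude loading of each component is positive.
* **Group comparisons**: tie-corrected Kruskal–Wallis omnibus, pairwise
  two-sided Wilcoxon–Mann–Whitney — exact whenever both groups have ≤ 8
  observations (the study's n = 6), normal approximation with continuity
  correction otherwise — and Benjamini–Hochberg adjustment across the
  pairwise family within each feature. Under a 1000-replicate null
  simulation, ≤ 5% of features show any adjusted rejection at q < 0.05.
* **Load correlations** are Pearson on log₁₀ loads: total loads are
  log-normally distributed across samples and analyzed on the log scale
  throughout.

# The synthetic study

`simulation_config()` fixes the study conditions: 6 mice per group, four
groups, six sites, depth 10⁴ reads, triplicate qPCR (Cq SD 0.15 cycles,
efficiency 0.95), ~20 000 droplets of 0.85 nL with an instrument-style
auto-dilution targeting λ ≈ 0.05–0.5, the 8 × 8 MPN design above, and an
LC-MS run with 8% area CV, −0.002/injection drift, QC every 8
injections, and the 7-point calibration run three times.

Ground truth is layered: per-group-per-site log₁₀ total loads (upper-gut
coprophagic means ~10⁸–10⁹ copies/g versus ~10⁵–10⁶·⁵ under blocked
self-reinoculation, shared ~10¹¹ in the large intestine, SD 0.4); a
small panel of order-level taxa in three behavior classes — *fecal* taxa
with true abundance exactly **zero** in the TC-F upper gut (so
detection-limit flagging has an unambiguous target), stable
*true-small-intestine* taxa dominated by *Lactobacillales*, and
*cecum-shifted* taxa reduced ×0.1 in the TC-F cecum only; reagent
contaminants with fixed ambient copies per reaction and no biological
abundance anywhere; and per-group-per-site bile-acid pools whose
unconjugated fraction rises down the coprophagic small intestine
(0.15 → 0.35 → 0.55) while staying ≤ 0.02 under blocked
self-reinoculation. Pool fractions are exact by construction: per-sample
totals split over the conjugation × origin grid as products of the two
fractions, then over species by fixed within-cell weights. Where the
study design fixes a value (group sizes, assay designs, calibration
ranges) the default *is* that value; where it does not (per-taxon effect
sizes, noise magnitudes), defaults were chosen once at field-plausible
levels to reproduce the qualitative patterns, and are not tuned.

Counts are multinomial at the configured depth over biological mass plus
ambient contaminant mass — which makes the inverse-frequency contaminant
signature emerge mechanistically rather than being painted on.
Dirichlet-multinomial overdispersion is available (`overdispersion`) but
off by default, as no count-noise model beyond multinomial is implied by
the design. One sequential RNG stream seeded from the config makes the
whole study bit-reproducible.

With `noise = FALSE` every stochastic draw is replaced by its
expectation (possibly non-integer counts and well tallies). Each
estimator then inverts its generator exactly — the basis of the
pipeline-identity tests. Two caveats are deliberate: the exact-identity
profiling test uses an empty contaminant panel (see above), and
bile-acid *pool fractions* are not exactly recovered even without noise,
because species below the 0.05 µM LLOQ are censored to zero; per-species
amounts inside the validated range are exact.

What the generator does *not* emulate: sequencing reads and denoising,
chimeras, taxonomic misclassification, droplet fluorescence thresholds,
chromatographic peak integration, inter-run batch effects, and
compositional interactions between taxa. Passing tests therefore
demonstrate correctness of the *quantification arithmetic and its
statistics* under the stated noise model, not robustness to upstream
bioinformatic error.

# Problem sizes and numerical choices

Verification runs use the sizes stated with each check: 1000 plates for
the MPN/oracle comparison, 500 simulated assays per decade over
10²–10⁹ copies for recovery, 200 replicate studies for contaminant-filter
power, 1000 replicates for null FDR calibration, and 100 replicate
studies for the four direction tests — all chosen as the smallest sizes
at which the binomial uncertainty of the reported rates is comfortably
below the margins being tested. Tolerances: estimator-vs-oracle 0.1%
relative; exact identities at square-root machine precision; the MPN
likelihood search at 1e−10 on log₁₀λ. Ties in ranks fall back to the
normal approximation (exact MWU enumeration is undefined under ties);
degenerate inputs (all-identical values, zero-variance features,
all-zero rows, saturated assays) return flagged results or named errors
rather than NaNs.

# Known limitations

* MPN point estimates carry the ~30% design-level imprecision discussed
  above; treat them as order-of-magnitude measurements with honest CIs.
* The frequency score needs ≥ 5 nonzero samples and positive DNA
  concentrations; very rare contaminants fall through to the prevalence
  rule.
* Absolute tables are not rescaled after contaminant removal; if the
  contaminant fraction of reads is large, biological absolute values are
  biased low by that fraction (a switchable design choice).
* Gene-content scaling inherits every limitation of marker-gene
  functional inference; it predicts gene copies, not expression or
  activity.
* Bile-acid amounts assume proportional (9-volume) extraction, so sample
  mass cancels from the dilution chain; fixed-volume protocols need a
  per-sample chain in the metadata.
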