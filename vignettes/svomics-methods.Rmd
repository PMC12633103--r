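---
title: "Methods: structural-variant multi-omics QTL mapping, fine-mapping and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural-variant multi-omics QTL mapping, fine-mapping and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svomics)
```

This vignette documents the statistical models behind `svomics`, the
parameters that matter, the design of the synthetic-data generator, and
the numerical choices made where the design space was genuinely open.
Nothing here states an empirical result that the package's tests and
`scripts/acceptance.R` do not themselves compute.

## Data model and coordinate conventions

Variants live in a `variant_callset`: a record table plus a samples ×
variants dosage matrix over {0, 1, 2, NA}. Coordinates are 1-based
inclusive throughout (VCF `POS`), with closed intervals `[start, end]`.
Insertions span `start .. start + length`, so `end − start` recovers the
length for every SV type; this convention was chosen because it makes
interval arithmetic uniform across types, and it is validated against
four independently known breakpoint/length pairs in the test suite. BED
export converts to 0-based half-open at the boundary. Multi-allelic VCF
records are split into biallelic records at read time (one record per
alternate allele, genotype = dosage of that allele); SVs are required to
be ≥50 bp, the standard definitional floor for a structural variant.

Molecular phenotypes live in an `omics_matrix` whose state tag moves
only along `raw_counts → log_norm → {rank_norm | zscore}`. The two
terminal states serve different consumers: rank-normalized matrices feed
QTL mapping (robust to outliers, exact null calibration), z-score
matrices feed outlier calling (outliers must be preserved, not
flattened). Keeping the two normalization tracks independent — each with
its own PC configuration — reflects that they answer different
questions and should not share tuning.

## Allele frequencies, filtering and imputation

AF is computed over non-missing genotypes, `Σg / (2·n_called)`; MAF is
`min(AF, 1 − AF)`. The default filter drops variants missing in more
than 50% of samples and below MAF 0.02, both boundaries inclusive (a
variant at exactly MAF 0.02 is kept). Missing genotypes are imputed by
iterative low-rank completion: missing cells start at column means, and
the matrix is alternately centered, approximated by its rank-k truncated
SVD (k = 10 by default, tolerance 1e-4, ≤200 sweeps) and refilled at the
missing cells. Observed dosages are never altered and imputed values are
clipped to [0, 2]. The defaults were chosen once: k = 10 captures the
dominant population-structure axes at cohort scale, and the tests verify
exact recovery of masked entries on genuinely low-rank matrices plus a
better-than-column-mean RMSE guarantee on correlated genotypes.

`genotype_r2` uses pairwise-complete observations (listwise deletion
would discard most of a sparse cohort); the LD proxy of an SV is the
max-r² SNV within a window, ties broken by distance then id so the
result is deterministic.

## Discovery saturation

For each of `n_orders` random orderings of the cohort the number of
distinct variants carried by at least one sampled genome is accumulated
per MAF stratum and averaged. The saturation point is the smallest n
after which the mean marginal gain stays below 0.5 new variants per
genome over a 20-genome lookahead. Both constants are exposed: the
lookahead smooths Monte-Carlo noise in the tail, and 0.5/genome is a
pragmatic "essentially flat" rule — saturation-point definitions are not
standardized, so these numbers should be treated as a reporting
convention, not estimands. Extrapolation uses the binomial detection
model: a variant at AF f is seen in n diploid genomes with probability
1 − (1−f)^(2n); integrating over the empirical AF density gives the
expected undiscovered fraction, and the projection is the smallest n
pushing that below 1%.

## Normalization and molecular outliers

Expression counts are log-CPM normalized (edgeR, prior count 1).
Feature filtering keeps a gene if it passes either the
minimum-expression rule (≥ min_count in ≥ min_frac of samples) or a
CV² trend test (standardized residual of log CV² above a loess trend on
log mean), so lowly-but-variably expressed genes survive. The
rank-inverse-normal transform uses offset (r − 0.5)/n with average ranks
for ties; the alternative Blom offset differs negligibly above n ≈ 100,
and the choice is recorded here once rather than made configurable.

Outlier z-scores: per-feature center/scale, SVD of the z matrix, OLS
residualization of each feature against the top n_pcs left singular
vectors plus numeric covariates (age, sex), then re-center/re-scale.
PC removal absorbs batch and cell-composition structure; the tests plant
a global factor and verify its post-residual correlation with every
feature drops below 0.05 while a planted z = −20 outlier orthogonal to
the factor survives. Global-outlier samples are those whose count of
|z| > 3 features exceeds the upper Tukey fence (Q3 + 1.5·IQR) of the
cohort's count distribution; with fewer than 8 samples the fence is
meaningless and removal is skipped with a warning. The Tukey rule is
applied uniformly across omes, with both the per-feature threshold and
the fence multiplier configurable. Note that on a cohort whose count
distribution is degenerate at zero the fence is zero and any sample with
a single call is "excessive" — recall of the caller itself is therefore
always measured on the pre-removal call list.

## Methylation segmentation and outliers

CpGs are grouped by greedy left-to-right extension: a CpG joins the open
segment iff its correlation with the segment's running mean profile is
≥ r_min (0.5) and its gap to the previous CpG is ≤ 1 kb. This replaces a
model-based changepoint segmentation with a transparent two-parameter
rule; the synthetic boundary-recovery test (Rand index ≥ 0.9 at CpG
noise SD 0.05) is the calibration evidence for the defaults. The
variability filter transforms segment betas with
t = logit(1 − |0.5 − β|), which maps hyper- and hypomethylation
symmetrically and sends constitutively all-or-nothing segments toward
zero; β is clamped to [1e-3, 1 − 1e-3] and the transform argument to
≤ 1 − 1e-3 because t diverges at β = 0.5 exactly. Segments whose log CV²
sits more than 3 SD above a loess mean–variance trend are "variable".
Outlier calls require both |z| ≥ 2.5 and |Δβ| ≥ 0.25 against the cohort
median — the median was chosen as the Δ reference for robustness, since
an outlier inflates its own segment's mean. The delta gate is what makes
calls biologically meaningful: a segment with SD 0.002 can show z = 100
for a Δ of 0.2 that no one would call an outlier.

## Rare-SV enrichment and prioritization

The analysis unit is the (feature, sample) pair, pooled across samples.
A pair is exposed when the sample carries (dosage ≥ 1) a rare SV — AF
below threshold, or allele count exactly 1 for singletons — within
100 kb of the feature anchor; the outcome is outlier status at the
stratum's direction and z threshold. The odds ratio is the cross-product
(a·d)/(b·c) with Haldane's +0.5 applied only when a cell is zero, the CI
is Woolf's, and the p-value is the exact hypergeometric test, two-sided.
Pooling across samples (rather than averaging per-sample ORs) matches
how the 2×2 contrasts are usually reported; both conventions coincide
under the generator's exchangeable samples.

The prioritization cascade takes externally computed posterior scores in
[0, 1] (the hierarchical outlier-integration model that produces them is
deliberately out of scope — scores are an input) and applies cumulative
gates: rare SV near gene → gene outlier |z| > 2 → risk-gene membership →
score strictly > 0.6 → score and risk gene jointly.

## cis SV-QTL mapping

A feature–variant pair is tested when the SV's full interval intersects
the ±1 Mb window around the feature anchor. This interval rule is the
reason for a bespoke mapper: breakpoint-only matching drops long SVs
whose body crosses the window. The reported distance is the gap between
the SV interval and the anchor (0 if overlapping).

The model is OLS: rank-normalized phenotype ~ dosage + age + sex +
one-hot diagnosis (healthy-control reference) + n_pcs phenotype PCs.
`map_qtls` residualizes phenotypes and genotypes against the shared
covariate design once and reduces each pair to a simple regression —
the Frisch–Waugh decomposition — with the full model's residual degrees
of freedom, so coefficient, SE and p equal the per-pair `fit_qtl` OLS to
1e-10 (asserted in the tests). Multiple testing defaults to Bonferroni
across all tested pairs in the ome, with BH available; the family is all
pairs rather than per-feature because cis-window sizes vary wildly
between features and per-feature scoping is offered as a flag instead.
The PC count is chosen by maximizing discovery yield over a grid, ties
to the smallest count; the factor-masking test confirms yield is
maximized at or above the true number of planted hidden factors.

## Fine-mapping (sum of single effects)

`susie_fit` implements iterative Bayesian stepwise selection: the model
is y = Σ_l X b_l + e with each b_l having exactly one nonzero
coordinate. Each sweep removes effect l from the fitted values, runs a
Bayesian single-effect regression on the residual — per-variant Bayes
factors under a N(0, V_l) effect prior, inclusion weights α_l ∝ BF —
and updates posterior moments. V_l is estimated per effect by maximizing
the single-effect marginal likelihood on the log scale (grid-free 1-D
optimization); when no V beats V = 0 the effect switches off, which is
what gives clean null behavior (pure-noise responses yield no credible
sets in ≥90% of seeds, asserted). The residual variance update ERSS/n is
the exact coordinate-ascent maximizer, and the ELBO is computed with the
per-effect KL obtained through the single-effect marginal-likelihood
identity; monotonicity to 1e-6 is asserted on every fit in the suite.
Defaults L = 10, coverage 0.95, purity floor 0.25, tolerance 1e-3 follow
the reference implementation of this model class. Credible sets are the
smallest α-prefix reaching the coverage; sets with minimum absolute
inter-member correlation below 0.25 are purged; duplicated sets are
reported once. The lead variant is the member with the highest PIP, and
sets are classed SV-led / contains-SV / SNV-only.

Phenotypes for fine-mapping should be the covariate-residualized, scaled
values from the QTL model; X should be the combined SV+SNV dosage
matrix, imputed and standardized (the function standardizes internally
by default and drops zero-variance columns with the mapping preserved).

## Colocalization

Loci are defined by merging 100 kb windows around variants with
p < 1e-5 (GWAS) or p < 1e-4 (QTL) and keeping merged windows containing
both signal types. Per-variant Wakefield log-ABFs are computed from
p-values with effect-variance approximation V = 1/(2N·MAF·(1−MAF))
(further divided by s(1−s) for case-control traits) and prior SDs
0.15/0.2 (quantitative / case-control) — the established defaults of
the p-value-only ABF method, exposed as arguments along with the
configuration priors p1 = p2 = 1e-4, p12 = 1e-5. Hypothesis sums are
evaluated in log space; the H3 sum over distinct pairs uses the identity
ΣΣ_{i≠j} = (Σ_i)(Σ_j) − Σ_i(both), with a guard for the degenerate case.
The implementation is checked against a plain-loop brute-force
enumerator to 1e-9 in log space on ≤20-variant loci. Variants are
matched across datasets by (chrom, pos) with id fallback; allele
harmonization is unnecessary because p-value-derived ABFs are sign-free.
Colocalizations are retained at PP.H4 strictly > 0.5 and annotated with
fine-mapping flags (SV in credible set / SV is lead); risk genes are
features whose maximum PP.H4 across contexts exceeds the same cut.

## The synthetic-data generator

The generator emulates the statistical structure of a population-scale
long-read aging cohort and is the ground-truth source for every
downstream test. Its defaults are fixed study conditions, not tuning
knobs:

* 551 samples; ages U(55, 90); sex Bernoulli(0.5); diagnosis
  categorical over CN/MCI/AD/PD (0.45/0.2/0.25/0.1).
* MAF spectrum Beta(0.22, 1) scaled to (0.001, 0.5], which places about
  40% of variants below 1% MAF — the rare-shifted shape typical of SV
  call sets at this cohort size.
* SV lengths: lognormal modes at ~300 bp, ~2.5 kb and ~6 kb
  (Alu/SVA/LINE-1 weights 0.35/0.08/0.05) over a broad background;
  types INS/DEL/DUP/INV at 0.48/0.42/0.05/0.05.
* Genotypes Binomial(2, MAF) (Hardy–Weinberg, no inbreeding); 2%
  missingness injected uniformly at random to exercise imputation.
* LD by copy-then-perturb: the tagged SNV is a copy of the SV column
  with a fraction 1 − √r² of samples resampled, giving expected r² equal
  to the target (exact at 1, independent at 0, ±0.1 at n ≥ 500,
  self-checked on every run). Haplotype simulation would model decay
  with distance but is unnecessary for tagging and fine-mapping tests.
  Targets exceeding the allele-frequency LD bound
  (p(1−q))/(q(1−p)) are rejected.
* Phenotypes: planted betas act on the standardized dosage; hidden
  factors have N(0, factor_sd²) loadings; expression maps the Gaussian
  latent to counts via a per-gene log base mean and a Poisson draw
  (a count model had to be chosen; log-normal–Poisson is the simplest
  that yields realistic overdispersion).
* Methylation: segments share a per-sample latent level (segment mean
  U(0.08, 0.92), per-sample SD 0.05) plus CpG noise; planted outliers
  shift one sample's latent by Δ and values are clipped to [0, 1] with
  the clip count reported. Because clipping eats shifts planted near
  the boundaries, recall fixtures plant toward the interior.
* Outlier enrichment: with baseline rate p0 = 2Φ(−z) a target odds
  ratio OR fixes the exposed rate p1 = OR·p0/(1 − p0 + OR·p0), and each
  exposed pair receives a large shift with probability
  (p1 − p0)/(1 − p0) — so the expected 2×2 table has exactly the
  configured OR.
* GWAS summaries: z ~ MVN(Rλ, R) with λ the non-centrality at causal
  variants; this is the standard joint model for summary statistics
  under LD and provides shared- vs distinct-causal colocalization
  fixtures.

What the generator does not emulate: haplotype structure and
recombination maps, ancestry stratification, genotyping error that
correlates with SV length or repeat content, batch structure in the
omics beyond linear hidden factors, and count overdispersion beyond
log-normal–Poisson. Passing tests therefore demonstrate correctness of
the estimators under the stated generative assumptions, not robustness
to every artifact of real cohorts.

## Problem sizes and numerical choices

The test suite and acceptance script run at deliberately modest sizes —
e.g. 200 null replicates of 5,000 cis tests at n = 500 for mapper
calibration, 300–500 single-effect fine-mapping replicates at n = 400,
p = 50, 100 colocalization loci of 30 variants, 50–100 enrichment
replicates at n = 2,000 × 200 features — chosen so the whole validation
completes in minutes on one core while keeping Monte-Carlo error well
inside the asserted tolerances (binomial 3·SE bands are computed from
the actual replicate counts, never hard-coded).

Numerical conventions worth knowing: genotype correlation uses
pairwise-complete entries; `map_qtls` treats residualized genotype
columns with sum of squares below 1e-12 as constant and skips them;
rank-normalization of a constant feature returns zeros with a flag;
ELBO convergence is |Δ| < 1e-3 by default with monotonicity asserted at
1e-6; colocalization clips p = 0 inputs to the smallest positive double
with a warning; window boundaries are inclusive everywhere
(a gap of exactly d counts at threshold d; an SV whose interval touches
the cis-window edge is tested, one base past it is not).

## Known limitations

* The mapper fits one variant at a time; conditional and interaction
  QTLs are out of scope (fine-mapping handles allelic heterogeneity up
  to L effects).
* Fine-mapping requires individual-level genotypes; no summary-stat
  mode.
* The cross-technology merge is a greedy nearest-start pairing with
  positional tolerance and reciprocal size ratio, not a graph-based
  multi-sample merge; it is adequate for concordance accounting, not
  for building a consensus call set.
* Breakends, phased genotypes and copy numbers beyond {0, 1, 2} are not
  modeled.
* The saturation point and the extrapolated cohort size depend on
  reporting conventions (threshold, lookahead, undiscovered fraction)
  and should be quoted with them.
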