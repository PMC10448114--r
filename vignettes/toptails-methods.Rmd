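---
title: "Methods: poly(A) tail profiling, RNA kinetics and translational engagement of TOP mRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) tail profiling, RNA kinetics and translational engagement of TOP mRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toptails)
```

# The scientific question

Transcripts carrying a 5'-terminal oligopyrimidine (TOP) motif — a
cap-proximal tract of roughly 4–15 pyrimidines — encode most of the
translational machinery (ribosomal proteins, elongation factors). During
neuronal differentiation these mRNAs are transcriptionally silenced, yet
they remain unusually stable and become *more* translationally active,
and this switch is mirrored in their poly(A) tail-length profile: tails
redistribute from the long (~120 nt) class into the ~60 nt class (two
PABP footprints) and, late in differentiation, into the decay-prone
<30 nt class.

`toptails` implements the complete analysis that supports this picture,
from raw per-read tail-length tables to the final enrichment statistics,
together with a seeded simulator that generates every input with known
ground truth. All quantitative claims made by the package about itself
are the ones its test suite and `scripts/acceptance.R` compute.

# Tail profiling

**Input.** Per-read tail-length estimates in the nanopolish-`polya` TSV
dialect. Only reads with a `PASS` QC tag are analysed; unknown tags are
mapped to `OTHER` and treated as non-PASS, so tool-version drift cannot
silently admit reads.

**Filters.** Transcripts on an exclusion list (mitochondrial genome,
pseudogenes) are dropped, and a transcript is profiled only if its PASS
reads pooled over *all* samples and conditions reach
`min_reads_per_contig` (default 30). The pooled reading of the filter is
a deliberate choice: imposing per-sample minima would preferentially
discard transcripts that are downregulated in one condition, biasing the
very contrasts of interest. The filter is applied after PASS selection,
since non-PASS reads carry no usable length estimate.

**Bins.** Tail lengths fall into `[0, 30)`, `[30, 90]` and `(90, Inf)`
nt. The boundary values 30 and 90 are assigned to the middle ("~60 nt")
band, matching the inclusive phrasing "30- to 90-nt"; the edges are
configurable through `default_pipeline_config()`.

**Differential tail shift.** The test units are per-replicate bin
fractions (proportions, not percentages — the t statistic is scale
invariant, and deltas are reported on the proportion scale). Each
transcript is tested with a two-tailed two-sample Student's t test with
pooled variance (Welch available via `var_equal = FALSE`), and calls are
made at a raw p ≤ 0.05 with *no* multiple-testing correction: this stage
is a screening step whose calls feed a downstream enrichment test, and
the null calibration of the raw threshold is itself verified by
simulation. Degenerate zero-variance cases are resolved by rule (p = 1
if the means agree, 0 otherwise, flagged `degenerate`); transcripts with
fewer than two replicates in a condition are skipped with a recorded
reason rather than tested.

# Turnover kinetics from metabolic labeling

**Model.** 4sU labeling converts labeled uridines to read as cytidines;
the labeled fraction of a transcript's molecules follows first-order
turnover. For a chase after saturating labeling (catabolic design)
`f(t) = A e^{-kt}`; for pulse labeling at steady state (anabolic design)
`f(t) = 1 - e^{-kt}`. In both designs the rate is the transcript's
turnover rate `k`; the "synthesis half-life" reported for the anabolic
course is the time to half-saturation of the label. The exact functional
forms are the package's own modelling convention — the minimal forms
consistent with saturation-anchored normalization — and the simulator
generates data by the same convention, which makes the fitter testable
against ground truth.

**Normalization.** Observed conversion rates are normalized to the
saturation conversion of the same transcript, estimated as the
replicate-mean conversion of the catabolic course at t = 0 (the chase
starts from a transcriptome saturated by ~13 h of labeling). Mean-based
(not per-replicate) normalization is used; values above 1 are kept so
the fit sees the full noise. Transcripts whose saturation does not
exceed the background conversion are flagged `unnormalizable` and never
fitted.

**Fitting.** Nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`), in minutes internally, with `k > 0` enforced, initial
guess `k0 = ln2/180 min` and, for decay, free amplitude `A0 = f(0)`.
Replicates are pooled into one joint fit (per-replicate fitting would
discard the cross-replicate constraint at only 4 time points). When the
binomial sampling scale of the conversions is known (coverage and
saturation), the fit is iteratively reweighted by the implied binomial
variance of each point — two reweights, weights from fitted values so
that observed noise does not leak into its own weight. The r² reported
is always the unweighted `1 - SSres/SStot`; flat data (`SStot = 0`) get
r² = 0 by definition, which routes them into the `low_r2` bin.

**Filters.** A fit is `ok` only if r² > 0.6 and the half-life lies
strictly inside (0, 5000) minutes; otherwise `low_r2` or `outlier`.
`filter_fits()` re-applies the rule under new thresholds and is monotone
(lowering the r² threshold never demotes an accepted fit).

**Known limitation.** With time points at 0/3/6/9 h and conversion rates
on the few-percent scale, the anabolic (synthesis) half-life is weakly
identified for fast transcripts: the curve saturates before the first
collection point and the informative high-conversion observations carry
the largest binomial noise. Decay fits do not share this weakness (their
informative points sit at low conversion, where binomial noise is small,
and the free amplitude absorbs normalization error). The package's
recovery tests therefore hold decay fits to a tighter accuracy than
synthesis fits; both bounds are computed, not asserted from theory.

# Differential accumulation and translational engagement

These are deliberately simplified, fully specified statistics. They do
**not** reproduce DESeq2's empirical-Bayes dispersion shrinkage or
Xtail's posterior machinery; they expose the same ranked effects and
thresholds with transparent formulas, and the package's tests calibrate
them against the generator's known truth.

**Size factors.** Median-of-ratios: pseudo-reference = per-gene
geometric mean over samples (genes containing any zero are excluded from
the reference); each sample's factor is the median ratio to the
reference. The test suite cross-checks the implementation against
DESeq2's `estimateSizeFactorsForMatrix` on random matrices.

**NB Wald test.** Per-gene dispersions by method of moments on
normalized counts under `Var(y) = mu E[1/s] + alpha mu^2`, floored at
1e-8 and, by default, at a loess mean–dispersion trend ("trended
floor"): a raw moment estimate below the trend is far more likely an
under-dispersed fluke than a genuinely precise gene, and using it
directly would overstate significance. The effect is
`log2((mu_B + 0.5)/(mu_A + 0.5))`; its delta-method standard error uses
the same variance model; two-sided p from the standard normal;
Benjamini–Hochberg adjustment (`bh_adjust()`, a validated wrapper over
`p.adjust`), calls at q ≤ 0.05.

**Delta log2 TE.** Each assay is size-factor normalized within itself
(RFP and RNA library depths are unrelated); per-replicate
`TE = log2((rfp + 0.5)/(rna + 0.5))`; the statistic is the difference of
condition means. Significance comes from permuting condition labels
jointly across assays — the RNA/RFP pairing of each biological sample is
never broken, which preserves within-sample coupling under the null —
exhaustively when at most 500 distinct relabelings exist (20 for a 3v3
design), otherwise by seeded Monte-Carlo. Engagement is called at
`|delta| > 0.5`. Note that a *global* TE shift affecting most genes is
absorbed by within-assay normalization and is not identifiable; effects
are interpretable relative to the bulk of the transcriptome.

# Enrichment and the test-selection procedure

**TOP classifier.** A 5'UTR is TOP when position +1 is a pyrimidine and
the maximal pyrimidine run starting there has length ≥ 4. The canonical
C-start is *not* required by default (the motif definition names only
the pyrimidine tract); `strict = TRUE` enforces it. Runs longer than 15
still classify as TOP and the length is reported uncapped.

**Hypergeometric enrichment.** Upper-tail probability
`P(X >= k) = sum C(M,i) C(N-M, s-i) / C(N,s)`, computed in log space
(`lchoose`) for stability; `k` = TOP genes among the tested transcripts,
`s` = tested set size, `M` = TOP genes among the captured universe,
`N` = universe size. The universe is the set of transcripts that
survived profiling — enrichment is computed against what the experiment
could actually have called. The upper tail (overrepresentation) is the
implemented convention.

**Group comparisons.** `compare_groups()` encodes the screening
procedure: Shapiro–Wilk normality per group and a Levene test (mean
centring) for variance homogeneity, both at a configurable 0.05. Two
normal homoscedastic groups → Student's t (paired variant when paired);
two normal heteroscedastic groups → Welch's t (an explicit extension —
the procedure as stated leaves this cell undefined and silently running
a pooled t there would be wrong); two non-normal groups → Wilcoxon;
more than two groups → ANOVA + Dunnett against the reference,
Games–Howell (Welch degrees of freedom with the studentized-range
distribution; validated against an independent implementation), or
Kruskal–Wallis with Bonferroni-corrected pairwise Wilcoxon tests. Every
result carries its decision trace.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the analysis is validated under.

* **Scale.** 1000 transcripts, 10% TOP, two conditions (D0/D6), 3
  biological replicates, tail-read depth 100 per transcript and
  replicate, 200 informative positions per conversion observation, time
  points 0/3/6/9 h. These sizes keep full-study generation and analysis
  in seconds while leaving every test statistic well-populated.
* **Tails.** Three-component Gaussian mixture, means 15/60/120 nt, SDs
  7/10/15 nt, baseline weights 0.10/0.55/0.35 (most molecules ~60 nt, a
  substantial ~120 nt class); measurement noise SD 5 nt; truncation at 0
  by resampling, so bin leakage is controlled by the stated SDs alone.
  Differentiation moves TOP weight 0.20 from the 120 nt to the 60 nt
  component (all post-baseline conditions) and 0.10 from 60 nt to the
  short class (final condition), the two-phase signature; downregulated
  non-TOP transcripts receive a smaller 0.05 mid-to-short transfer,
  since <30 nt accumulation accompanies decay generally.
* **Kinetics.** Decay half-lives log-uniform 60–2400 min; TOP
  transcripts from the upper range 600–2400 min. Saturation conversion
  uniform 0.02–0.10 (the few-percent T-to-C rates typical of saturating
  4sU labeling); background conversion 0.001.
* **Counts.** Baseline expression log-uniform 20–2000 (TOP from the
  abundant 200–2000 end, as expected of ribosomal-protein mRNAs); TOP
  log2 fold change −1 during differentiation; 20% of non-TOP genes
  differential at ±1.5; log-normal library-size factors (SD 0.1). RNA
  counts are NB with biological dispersion 0.05. RFP counts are coupled
  to the *realised* RNA of the same sample with a small conditional
  excess dispersion (0.01): the biological variation is shared between
  the assays of one sample rather than drawn twice, so each assay's
  marginal dispersion stays ≈ 0.05 while the within-sample coupling that
  the paired permutation test relies on is present in the data. TOP
  transcripts gain ΔTE = +0.8 log2 units.
* **UTRs.** TOP 5'UTRs start with C followed by a pyrimidine run of
  total length 4–15 (uniform) terminated by a purine; non-TOP UTRs start
  with a purine. The classifier recovers the labels with zero error by
  construction — that test checks the plumbing, not the biology.

**What the simulator does not emulate.** Raw nanopore signal and
basecalling artefacts; length-dependent capture bias; SNP-induced
false conversions and mapping error in the labeling data; batch
effects; multi-condition kinetic changes (rates are constant per
transcript); UTR sequence composition beyond the motif itself. Passing
tests therefore demonstrate that the statistics recover the structure
they assume, not that they are robust to artefacts they never see.

# Numerical choices

* Exponential fits: `nlsLM` with `maxiter = 200`, `ftol = ptol =
  1e-15` (so noiseless curves invert to ~1e-9 relative error); lower
  bound `k >= 1e-9` per minute (half-life below ~7e8 min —
  unconstrained in practice, but a strictly positive bound keeps the
  optimizer's internal scaling well-conditioned).
* Binomial IRLS weights floor the fitted conversion probability at
  `0.5/coverage` to avoid infinite weights at zero conversions.
* The hypergeometric tail is summed in log space; terms with impossible
  draws contribute exactly zero through `lchoose = -Inf`.
* Permutation p-values compare `|delta|` with a 1e-12 tie tolerance so
  that the observed labeling (always among the exhaustive relabelings)
  counts as at least as extreme as itself.
* The tail-shift test is vectorized arithmetic over transcripts; the
  suite checks it against `stats::t.test` case by case.

# Problem sizes used by the tests

Module tests run at 10–500 transcripts. The acceptance-style checks use
the stated study scales: 100 transcripts for exact bin-fraction
equivalence; every hypergeometric configuration with N ≤ 60; 500
transcripts for kinetic parameter recovery at coverage 200; 2000
transcripts / 2000 genes for the null calibrations of the tail-shift and
Wald tests; the full 1000-transcript study for the end-to-end signature;
and 4000 Monte-Carlo permutations against the exhaustive 20-relabeling
enumeration. The whole suite completes in about a minute on one CPU.

# Known limitations

* Synthesis (anabolic) half-lives are intrinsically noisy at this
  design, as discussed above; interpret them through the r² filter and
  expect coarser accuracy than for decay.
* The tail-shift stage reproduces the raw p ≤ 0.05 screening threshold
  by design; its output is not an FDR-controlled discovery list.
* The NB Wald substitute is slightly conservative at very low counts
  (pseudocount shrinkage) and does not share information across genes
  beyond the dispersion trend floor.
* The fitted median decay half-life underestimates the true median for
  long-lived transcripts: little decay occurs within the 9 h window, so
  accepted fits are the ones that happened to show decay. The TOP vs
  non-TOP *ordering* is preserved, which is what the integrated analysis
  interprets.
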