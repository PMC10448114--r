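# toptails

Integrated analysis of poly(A) tail-length processing, RNA turnover and
translational engagement of 5'-terminal oligopyrimidine (TOP) mRNAs
during cellular differentiation.

## The problem

TOP mRNAs — transcripts beginning with a cap-proximal tract of ~4–15
pyrimidines — encode the translational machinery. During neuronal
differentiation they are transcriptionally silenced yet remain highly
stable and become more translationally active, and the switch is written
into their poly(A) tails: molecules redistribute from the ~120 nt tail
class into the ~60 nt class (two PABP footprints) and, late in
differentiation, into the decay-prone <30 nt class. Demonstrating this
requires joining four assays: nanopore direct-RNA tail-length
measurements, metabolic-labeling (4sU / T→C conversion) time courses,
RNA-seq and ribosome-footprint (RFP) count matrices, and 5'UTR
sequences.

`toptails` implements that joined analysis for R users, plus a seeded
synthetic-data generator that emulates all four input kinds with known
ground truth, so every stage is testable end to end.

## What it computes

* **Tail profiles** — per transcript × sample bin fractions over
  `[0,30)`, `[30,90]`, `(90,∞)` nt from PASS-filtered nanopolish-polya
  tables, with mitochondrial/pseudogene exclusion and a ≥30-read pooled
  contig filter; per-transcript differential tail-shift calls by a
  two-tailed pooled-variance Student's t test at p ≤ 0.05
  (`build_tail_profiles()`, `test_bin_fraction_change()`).
* **Turnover kinetics** — labeled fractions normalized to the
  saturation conversion (catabolic t = 0 anchor), exponential fits
  `A·e^{−kt}` (decay) and `1 − e^{−kt}` (synthesis) by
  Levenberg–Marquardt with binomial variance reweighting; half-life
  `t½ = ln2/k` in minutes; acceptance filters r² > 0.6 and
  0 < t½ < 5000 min (`normalize_conversions()`, `fit_kinetics()`,
  `filter_fits()`).
* **Differential accumulation** — median-of-ratios size factors,
  method-of-moments NB dispersions with a trended floor, Wald test on
  log2 fold changes, Benjamini–Hochberg q ≤ 0.05 (`nb_wald_test()`).
* **Translational engagement** — Δlog2TE between conditions from
  paired RNA/RFP libraries with a label-permutation p-value (exhaustive
  for 3v3), engagement at |Δlog2TE| > 0.5 (`delta_log2_te()`).
* **TOP classification and enrichment** — the 5' pyrimidine-run rule
  (`classify_top_motif()`) and an exact upper-tail hypergeometric test
  `P(X ≥ k)` with (k, s, M, N) computed in log space
  (`hypergeometric_enrichment()`).
* **Assumption-guided comparisons** — Shapiro–Wilk/Levene screening
  routing to Student/Welch/Wilcoxon/ANOVA+Dunnett/Games–Howell/
  Kruskal–Wallis+Bonferroni, plus a two-sided KS test
  (`compare_groups()`, `ks_two_sided()`).

## Worked example

```r
library(toptails)

study <- simulate_study(seed = 1)   # 1000 transcripts, 10% TOP, D0 vs D6
res   <- analyze_study(study)
print(res)
```

```
Integrated TOP-transcript analysis
  transcripts profiled:            933
  ~60 nt gainers (p <= 0.05):      67 (TOP enrichment p = 1.78e-43)
  <30 nt gainers (p <= 0.05):      93 (TOP enrichment p = 8.12e-59)
  median decay half-life (h):      TOP 10.2 vs non-TOP 2.4
  differentially accumulated:      239 (q <= 0.05)
  TOP translationally engaged:     95% (median dTE 0.72)
```

Reading the output: of 1000 simulated transcripts, 933 pass the
exclusion and ≥30-read filters. 67 transcripts significantly gain ~60 nt
tails between D0 and D6, and the TOP set is overwhelmingly
overrepresented among them (hypergeometric p ≈ 2e-43); likewise for
<30 nt gainers. Fitted decay half-lives rank TOP transcripts (median
~10 h among accepted fits) well above the rest of the transcriptome
(~2.4 h). The Wald test calls 239 differentially accumulated genes at
q ≤ 0.05, and 95% of TOP genes are called translationally engaged
(|Δlog2TE| > 0.5) against an injected ΔTE of +0.8 — the qualitative
signature the analysis is designed to expose: downregulated, stable,
~60 nt-tailed, translationally activated TOP mRNAs.

Individual stages are available directly, e.g.

```r
reads <- read_polya_table("polya.tsv", require_pass = TRUE)
prof  <- build_tail_profiles(reads, min_reads = 30)
shift <- test_bin_fraction_change(prof, "D0", "D6", bin = "about60")

hypergeometric_enrichment(k = 40, s = 67, M = 100, N = 933)
```

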