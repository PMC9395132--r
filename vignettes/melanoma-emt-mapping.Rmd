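---
title: "Mapping melanoma de-differentiation onto the EMT axis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping melanoma de-differentiation onto the EMT axis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melaxis)
```

## The scientific question

Melanoma phenotypic heterogeneity is usually organised along a
proliferative–invasive (P–I) de-differentiation axis: melanocytic cells
proliferate, undifferentiated cells invade, and transitory and neural-crest
stem-cell-like (NCSC) states sit in between. Because invasion is the
hallmark of mesenchymal biology, it is tempting to equate this axis with
the epithelial–mesenchymal transition (EMT). `melaxis` implements the
quantitative machinery for testing that equation per dataset: if
de-differentiation were a full EMT, both a *gain* of mesenchymal programs
and a *loss* of epithelial programs should track the P–I axis; if plasticity
is "one-dimensional", only the mesenchymal gain should. The package scores
each sample on both decompositions (plus metabolic surrogates) and supplies
the downstream statistics — correlation surveys, gradients, discrete
phenotype calls, conditional enrichment — that discriminate the two
hypotheses.

## Scoring engines

All engines consume a log2-scale genes × samples matrix
(`tpm_log2()` applies TPM scaling and `log2(x + 1)`; `collapse_probes()`
averages multi-probe genes). Scores are always computed within one dataset,
never across concatenated cohorts, because cross-dataset batch structure
would swamp within-cohort biology; the meta-analysis stage then combines
per-dataset *correlations*, which are comparable across platforms.

**ssGSEA.** Genes are ranked per sample (average ranks at ties; the top
gene has rank $N$) and the ranked list is walked from top to bottom. At
each position the running in-set fraction, weighted by $\mathrm{rank}^\alpha$
and normalised over the set, minus the uniform out-of-set fraction, is
accumulated; the score is the sum of this running difference over all $N$
positions. Two choices are deliberately explicit because the enrichment
literature varies on them:

* $\alpha = 0.25$, the originating method's published default. The
  downstream survey is Spearman-based, so the exact exponent affects score
  scale far more than inference.
* no cross-sample range normalisation by default (`normalize = FALSE`).
  Normalisation divides by `max − min` of the scores in the dataset at
  hand, which makes scores incomparable between runs on subsets; rank-based
  correlations are invariant to it anyway. The option is exposed for
  completeness.

Walk order at exactly tied expression values is made deterministic by
breaking ties on the gene identifier; weights still use average ranks, so
the score is permutation-invariant.

**Signed KS.** Within a sample, the ECDFs of epithelial-gene and
mesenchymal-gene expression are compared:
$D^+ = \sup(F_E - F_M)$, $D^- = \sup(F_M - F_E)$, score $= D^+ - D^-$.
This "difference of one-sided statistics" form was chosen over a
significance-gated signed KS because it is antisymmetric
(`score(E, M) = -score(M, E)` exactly), bounded in $[-1, 1]$, and zero when
the two distributions coincide. Positive = mesenchymal genes sit higher.
The epithelial/mesenchymal lists come in tumor and cell-line flavours;
`score_panel(context =)` selects one pair for the KS, E and M scores.

**76GS.** A weighted sum of signature-gene expression where each weight is
the gene's cross-sample Pearson correlation with CDH1 (weight 1 for CDH1
itself), mean-centered across samples; higher = more epithelial. When the
anchor is missing the engine falls back to unit weights with a warning
rather than failing — on reduced public matrices CDH1 is occasionally
filtered out, and a degraded score with a logged provenance beats a dead
pipeline. Requires ≥ 3 samples (weights are correlations) and zero-variance
genes get weight 0.

**singscore.** The mean ascending rank $\bar R$ of the set genes, rescaled
by its attainable extremes $\bar R_{\min} = (|S|+1)/2$ and
$\bar R_{\max} = N - (|S|-1)/2$ and centred, giving a score in
$[-0.5, 0.5]$. Used for the HIF-1 signature (59 target genes).

**FAO.** Mean across the 14 fatty-acid-oxidation enzyme genes of their
per-gene cross-sample z-scores; zero-variance genes are dropped with a
warning.

Gene-set/matrix intersection is the silent failure mode of any signature
survey, so every engine records matched-gene counts in the score table's
metadata and `score_panel()` refuses to run when a required set is absent.

## Inference stages

**Correlation survey.** `spearman_pair()` computes $\rho$ as the Pearson
correlation of average ranks. P-values come from the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation on $n - 2$ df, two-sided
(the survey flags both directions); for $n \le 7$ the exact permutation
null is enumerated instead — beyond that the enumeration cost
($n!$ correlations) buys nothing, as the $t$ approximation's error is
already far below the 0.05 decision threshold. Records are flagged
significant when $|\rho| > 0.36$ and $p < 0.05$; `volcano_summary()` counts
significant records and splits them by axis identity and sign, mirroring a
volcano plot's quadrants.

**Moving-window gradients.** A window spanning 60% of the axis range slides
in 1%-of-range steps from the axis minimum until its right edge reaches the
maximum; each placement records the mean response over samples in the
closed window. The gradient is the OLS slope of window means on window
centers. Windows are intentionally wide: the estimator is meant to read the
*direction and steepness* of a trend, not its curvature. Empty windows are
dropped; a single-window profile returns `NA` slope.

**Phenotype calls.** For each of the four phenotype score columns
independently, the top `ceil(0.10 n)` samples are flagged. Ceiling (rather
than rounding) guarantees at least one call in small cohorts, and ties at
the cutoff are all included and logged. Multi-membership is retained — a
sample near two phenotype archetypes legitimately carries both flags.

**Intermediate M band and conditional tests.** "Intermediate M score
range" is not a standardised notion, so the default is the most literal
one: the middle third of the *observed score range*
($[\min + r/3,\ \min + 2r/3]$); a quantile band
(`method = "quantile"`) is exposed for sensitivity analysis, and on
strongly skewed score distributions the two can differ materially — worth
checking both. Enrichment of a phenotype among band samples is tested with
the one-proportion Z statistic
$z = (\hat p - p_0)/\sqrt{p_0(1-p_0)/n}$, upper-tailed (the question is
enrichment, not depletion). The null proportion defaults to the marginal
flag fraction (≈ 0.10 under the top-10% rule), the standard enrichment
null when no external prior exists.

**Trend verdicts.** `phenotype_trend()` orders phenotype-wise medians along
melanocytic → transitory → NCSC → undifferentiated and classifies the shape
with tolerance $\varepsilon = 10^{-9}$: monotone (strict in every step),
flat, or *peaked* when an interior phenotype's median exceeds the
endpoints, medians do not fall before the peak and do not rise after it —
so a plateau from the peak onward still counts as a peak. Anything else is
reported as `irregular` rather than forced into a class.

## The synthetic-data generator

`simulate_dataset()` is a first-class module, not a test fixture: it
encodes the coupling structure the pipeline is designed to detect, with
ground truth, so every qualitative claim the inference stages make is
checkable. Per sample a latent de-differentiation coordinate
$d \sim U(0,1)$ is drawn (a continuum, with quartile labels layered on,
rather than four discrete clusters — the discrete phenotypes are a
discretisation of the biology, not the biology). Program activities:

* proliferative, OXPHOS, FAO: $a(1 - d)$ (melanocytic-associated,
  monotone decline);
* invasive: $a\,d$;
* mesenchymal, glycolysis, HIF-1: $a\,B(d)$ where
  $B(d) = (d/m)^{cm}((1-d)/(1-m))^{c(1-m)}$ is a smooth unimodal bump with
  mode $m = 0.7$ (the NCSC position) and concentration $c = 4$ — rising
  through the melanocytic-to-NCSC stretch and falling toward the
  undifferentiated end;
* epithelial: $0.3\,a\,z$ with $z \sim N(0,1)$ independent of $d$ — the
  "one-dimensional EMT" null;
* four phenotype marker programs: Gaussian kernels
  $a\exp(-(d - c_p)^2/2\sigma^2)$, $\sigma = 0.12$, centred on the quartile
  midpoints $c_p \in \{0.125, 0.375, 0.625, 0.875\}$. These exist because
  the top-10% assignment stage needs per-phenotype marker scores; their
  kernels make the flagged samples cluster inside the correct quartile of
  $d$, which is what makes label-recovery precision assertable.

Each program gene is its program activity plus $N(0, \sigma_n^2)$ noise on
the log2 scale (all engines are rank-based or linear there); background
genes are baseline plus noise. Defaults — 200 samples, 30 genes per
program (14 for FAO, matching its score's gene count), 150 background
genes, amplitude $a = 3$ log2 units, noise sd 1, baseline 6 — were chosen
once as a plausible bulk-expression regime in which the programmed sign
structure is recoverable but not trivial (per-gene signal-to-noise of
order 1, program estimates sharpened by averaging ~30 genes). No published
effect-size scale exists for these programs; the amplitudes are arbitrary
in that specific sense and documented as such.

`simulate_batch()` emulates a multi-cohort survey: per-dataset seeds are
derived from one master seed and effect sizes receive a ±20% uniform
multiplicative jitter, so batch members differ in coupling strength the way
real cohorts do.

What the generator does *not* emulate: platform and library-size effects,
single-cell dropout, correlated noise between genes, partially overlapping
gene sets, or epithelial programs that are weakly (rather than not at all)
coupled to the axis. Passing tests therefore demonstrate that the machinery
recovers a known structure through the full scoring-and-inference path —
not that any particular real cohort has that structure.

## Numerical choices and degenerate inputs

* Ties everywhere are broken by average rank (deterministic,
  permutation-invariant); the ssGSEA walk order additionally uses the gene
  identifier as a tiebreak.
* Constant vectors are errors where the statistic is undefined (Spearman,
  band on a degenerate range, axis without spread); zero-variance genes are
  dropped-with-warning where the score can proceed without them (FAO,
  76GS weights).
* The KS sup is evaluated on the union of observed values (exact for step
  ECDFs); window membership uses closed intervals with a $10^{-12}$ guard
  against floating-point edge exclusion.
* The one-proportion Z p-value is the normal upper tail of the closed-form
  statistic. Against the exact binomial tail its error is dominated by the
  half-point-mass discreteness offset near the null; in the decision
  regime ($z \ge 2$, band sizes ≥ 200) the raw tails agree to within 0.01,
  and near the null the normal tail matches the exact mid-p tail to the
  same bound (p₀ = 0.1 being the slowest case, needing n ≈ 400 for that
  bound due to skewness).
* All simulation entry points take explicit seeds and restore the caller's
  RNG state; reruns of `run_full_pipeline()` with the same config are
  byte-identical, and its manifest records md5 checksums of every output.

## Problem sizes

The shipped analysis scripts and tests run on 200-sample, ~500-gene
simulated datasets and 20-to-40-dataset batches — sizes at which every
qualitative contrast the generator encodes (mesenchymal-vs-epithelial
coupling asymmetry, NCSC peak, OXPHOS decline, transitory enrichment in
the intermediate band) is decisively recoverable, and a full batch
analysis completes in well under a minute. Nothing in the implementation
is specific to these sizes; real cohorts with tens of thousands of genes
only change constant factors in the per-sample $O(N \log N)$ ranking.

## Known limitations

* The bundled gene-set fixtures are synthetic stand-ins with the correct
  cardinalities (76 genes anchored on CDH1; 59 HIF-1 targets; 14 FAO
  enzymes; placeholder proliferative/invasive/phenotype/E/M lists); real
  analyses should load the published lists via `read_gmt()`.
* The 76GS engine implements the CDH1-anchored correlation weighting; the
  original signature's fixed gene list and externally fitted weights are
  user-supplied inputs, not reimplemented constants.
* No multiple-testing correction is applied across a batch's correlation
  records — the survey's significance rule is a per-dataset filter, and
  its volcano summary reports fractions, not family-wise claims.
* Spearman p-values for 7 < n < 30 lean on the t-approximation, which is
  mildly anticonservative at the extreme tails.
* The conditional-probability stage treats the band and the calls as
  fixed; uncertainty in the band boundaries themselves is not propagated.
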