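---
title: "Sex- and age-resolved heterochromatin and repeat analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex- and age-resolved heterochromatin and repeat analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`hetage` analyses window-level H3K9me3 ChIP-seq enrichment, repeat-family
chromatin and expression, and survivorship in a species where males carry a
large, recently formed, repeat-rich neo-Y chromosome. The pipeline starts at
count/coverage tables (read mapping is upstream and out of scope) and covers:

1. a genome model: chromosomes with Muller labels, sex-linkage and centromere
   sides, tiled into fixed half-open windows (0-based, BED convention), with a
   repeat-density rule separating euchromatic arms from pericentromeric
   heterochromatin;
2. four window-level ChIP normalizations (no-spike; spike scale factor;
   regression to a pooled spike reference; quantile-quantile matching to it);
3. fold-change-based calling of windows gaining/losing H3K9me3 between ages,
   compartment attribution and a Fisher exact sex contrast;
4. per-repeat-family enrichment, Y-enrichment classification from male/female
   gDNA coverage, and a negative-binomial Wald test for differential
   expression with copy-number-aware normalization;
5. Kaplan-Meier survivorship with Greenwood variance and log-log confidence
   bands;
6. a synthetic-data generator that plants all of the above effects with known
   sizes, so each stage can be validated by parameter recovery.

## Windows and the pericentromere boundary

Windows tile each chromosome without overlap; the terminal window may be
short. The default analysis grid is 5 kb; display tracks use 25 kb and TSS
profiles 100 bp. The pericentromere boundary applies a 40% repeat-masked
cutoff over 100-kb sliding windows walked away from the centromere end; the
boundary is the first offset where the sliding average drops below the
cutoff. The scan steps by the analysis window size (the finest resolution
consistent with the window grid; the step is otherwise a free choice), and a
window exactly at 40% counts as pericentromeric. The dot chromosome is
treated as entirely pericentric (it has no euchromatic arm), and the neo-Y
pericentromere is a configured span at the centromere end of the scaffold —
it is defined from independent evidence (satellite-flanking H3K9me3), not
from the repeat scan, because the whole neo-Y is repeat-rich.

Karyotype bookkeeping uses one-decimal megabase values per chromosome; sums
therefore inherit +-0.1 Mb precision. The "haploid" view counts one copy of
each element and does not double-count the Y/neo-Y against its X/neo-X
homologs.

## Normalization

The default (no-spike) signal scales ChIP and Input each by library size and
then by the median of its own values over euchromatic windows of the two
major autosomal arms (Muller B and E), taking the per-window ratio. It is
invariant to sequencing depth by construction. Windows with zero Input are
reported missing, never infinite, and excluded from medians and calls.

The spike scale factor is evaluated literally, left-associatively, as

c = 1 + [ChIP_sample / (Input_spike / Input_sample)] / (Input_spike + ChIP_spike)

on raw mapped-read totals. Note the expression is invariant to scaling all
four totals jointly (the ratio and the denominator scale together), but not
to scaling the ChIP library alone — that is the quantity carrying the
spike-in information.

The regression method fits a monotone log-linear map from each sample's
spike-in signal to the pooled reference and applies it to the sample's
signal; a "logistic regression" in the sense of a binary-outcome model is
not applicable to a continuous positive ratio, so the log-scale monotone fit
is used. The quantile method matches the sample's spike-signal distribution
to the pooled reference by interpolated quantile mapping on log2 scale
(extended beyond the observed range by a unit-slope shift, which makes a
pure location shift map exactly); it is idempotent. All methods are checked
for rank concordance of their top-20% windows against a permutation chance
level.

Replicate QC flags a replicate whose median pericentromeric signal falls
below 50% of its replicate group's median (the signature of a failed
pull-down, which depresses the sample and spike jointly); exclusion itself
stays a config-level decision.

## Differential heterochromatin

Calls are pure fold-change thresholds on replicate-mean signal: loss when
young/old >= 1.5, gain when old/young >= 1.5 (inclusive), no p-values and no
multiple-testing correction. Replicates are combined by arithmetic mean.
Both condition means must be positive for a call; others are "none". The
Fisher sex contrast uses the conventional two-sided rule (sum of tables with
probability <= observed); the marginal totals are the analyzable windows per
sex, which is a configurable choice because male and female genomes differ
(females carry no Y windows).

## Repeat quantification and differential expression

Per-family enrichment is (ChIP/autosome-median) / (Input/autosome-median);
dividing by the Input cancels both copy number and depth. Y-enrichment
classifies families by depth-normalized log2(male/female) gDNA coverage at a
default cutoff of 0.585 (1.5-fold, matching the fold convention used
elsewhere; whether the original classification used a fixed ratio or a
ranked quantile is not recoverable, so the threshold is exposed as a
parameter). Depth normalization uses single-copy coverage because total
repeat coverage itself differs between sexes.

Differential expression removes rRNA rows first (their abundance differences
between total-RNA libraries are technical), computes median-of-ratios size
factors, then fits a per-feature NB GLM (log link, variance mu + alpha mu^2)
with a two-level design. The dispersion is estimated per feature by
Cox-Reid-adjusted maximum likelihood with a floor of 1e-8 and no shrinkage
across features: plain joint ML is materially biased downward at 3 vs 3
replicates, inflating the Wald type-I error well above nominal, while the
CR adjustment (a REML-like correction, still per-feature) brings it back.
For the same reason p-values use a t reference on the residual degrees of
freedom rather than the normal. The implementation is validated two ways:
type-I error on generator-null features must land in [0.025, 0.10] at
nominal 0.05, and fold changes/size factors are cross-checked against an
independent NB GLM implementation (DESeq2) on a common matrix. Significance
follows the fold + raw-p rule (|log2FC| >= 0.58, p < 0.05); BH-adjusted
p-values are reported alongside.

## Survivorship

Kaplan-Meier through the standard product-limit machinery, Greenwood
variance, log-log confidence intervals (the CI method is not dictated by the
data; log-log is chosen because it respects [0,1]). Deaths precede
censorings at tied days. The median is the first time S(t) <= 0.5; when the
curve never reaches 0.5 the median is reported as "> last observed day".
Administrative truncation — stopping the whole assay once one sex falls
below 50% survivorship — is modelled as right-censoring at the stop day.
A consequence worth noting: under the stop rule only the shorter-lived sex's
median is observable; the other sex's planted median can be recovered only
with the stop rule disabled, which is how the generator's female median is
checked.

## The synthetic-data generator

The generator emulates the study conditions end to end: a scaled
published-proportion karyotype (default 1/500 of the assembled lengths;
recovery runs that need more windows use 1/100 or 1/50 — these are
problem-size choices, stated here once), 5-kb windows, ~20% spike-in
chromatin per library, 4 ChIP and 3 RNA replicates per sex and age, and
negative-binomial counts throughout (variance mu + alpha mu^2; alpha = 0
switches to a noise-free mode in which counts equal their expectations,
used to verify the documented mean structure exactly).

Planted effects and their defaults, chosen a priori from the study's stated
conditions or, where unstated, from what is realistic for this data type:

* true enrichment 1 + 6 x repeat_fraction (pericentromeric windows reach
  ~5-7x, typical of H3K9me3);
* a 30% H3K9me3 deficit on neo-Y arm windows with repeat fraction > 0.7;
* aging loss of 40% (males) / 10% (females) on pericentromeric,
  neo-Y-pericentromeric and dot windows in old flies;
* ChIP/Input window dispersion 0.02, RNA dispersion 0.05 (typical
  biological-replicate overdispersion), gDNA dispersion 0.01 (deep coverage
  is near-Poisson);
* 303 TE families of which 81 are Y-enriched, 780 satellites of which 9 are;
  Y-enriched families carry 4-fold more male copies (log2 bias 2);
* Y-enriched TEs are expressed 2.3-fold higher at baseline in both sexes and
  a further 4-fold in males; satellites carry 8% of female repeat
  expression; these three numbers are calibrated analytically so the
  expected repeat fraction of non-rRNA transcripts is 3.7% in young females
  and works out to ~8.0% in young males;
* the neo-Y origin share of male TE transcripts is 0.585 for Y-enriched and
  0.08 for unbiased families, calibrated so ~47% of young-male TE
  transcripts are neo-Y-derived;
* 21 satellites are up-regulated 3-fold in old males;
* lifespans are Gompertz with shape 0.09/day and rates solved from planted
  medians of 78 (male) and 110 (female) days; assay sizes 1304 males / 1765
  females in vials of 20; a small exponential escape hazard; the
  administrative stop rule on by default.

What the generator does **not** emulate: read-level artifacts (mappability,
GC bias, cross-species mis-mapping of the spike-in), positional
autocorrelation of signal along chromosomes, piRNA-mediated regulation, and
between-replicate batch structure. Passing recovery tests therefore shows
the statistics are implemented correctly and are well-calibrated under the
assumed count model — not that the pipeline is robust to upstream mapping
pathologies.

## Numerical choices and degenerate inputs

Fold-change thresholds are inclusive. Median-based scalings error on a zero
median rather than producing infinities. The quantile map deduplicates tied
quantile knots before interpolation. The NB fit is bounded (log-dispersion
in [log 1e-8, 5]; group log-means in [-30, 30]) and falls back to its
moment-based start if optimization fails; all-zero features are excluded;
a group with all-zero counts hits the mean floor and yields an extreme but
finite fold change. Subsampling uses sequential hypergeometric draws, which
is an exact multivariate-hypergeometric thinning. All generator randomness
is scoped: the global RNG state is saved and restored, and every stream is
a deterministic function of the config seed plus a fixed per-layer offset.

## Known limitations

* The window-call stage is threshold-based by design and inherits the
  arbitrariness of the 1.5-fold cutoff; no significance is attached to
  individual windows.
* The Fisher contrast depends on the choice of marginal totals, which is
  documented and configurable but not uniquely determined.
* The NB Wald test is per-feature; at very low counts it is conservative
  and its fold-change estimates attenuate slightly.
* The regression normalization assumes a monotone log-linear spike
  relationship; grossly non-linear spike distortions would require the
  quantile method.
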