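---
title: "Methods: expression progression in staged maize anthers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression progression in staged maize anthers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antherprog)
```

# The biological setting

Maize anthers pass through a stereotyped pre-meiotic progression indexed by
organ length: 0.15 mm primordia of pluripotent Layer2-derived cells, 0.25 mm
anthers with a freshly specified archesporial (AR) column, 0.4 mm anthers in
a purely proliferative phase, 0.7 mm anthers after the final somatic cell
specification (middle layer and tapetum), and 1.0 mm anthers with all five
lobe cell types differentiated. Two-color microarray profiling of this
series, of the *mac1* mutant (excess AR cells, missing somatic layers), and
of laser-microdissected (LCM) cell collections yields a characteristic set
of analyses: present/absent calls against negative-control probes,
a stage-pattern taxonomy (constitutive, stage-specific, and "trough"
transcripts detectable at every stage but one), fold-change tests between
conditions, sequential marker filters, cell-type enrichment against whole
anthers, and transcript-protein concordance. This package implements that
analysis pipeline as reusable, tested functions and pairs it with a
synthetic-data generator that plants each of these signal classes with
known truth, so every step can be validated by recovery.

# Detection model

Each array-channel's negative-control foregrounds estimate a background
Gaussian; a probe measurement scores ON when it exceeds
`mean + 3.0 * SD` of those controls (sample SD, n-1 denominator,
computed per column after normalization). Under the Gaussian null the
false-ON probability is the standard-normal upper tail beyond the
multiplier, `estimate_fdr(3) = 0.00135`, i.e. the familiar 0.13%. Replicates
are combined per (stage, genotype, tissue) group as a support fraction; a
group call is ON when at least 75% of its measurements score ON, OFF when
none do, and AMBIGUOUS otherwise. Because the generator draws OFF probes and
negative controls from the same linear-scale Gaussian, the empirical
false-ON rate of null probes is analytically checkable and is verified at
10^6 draws in the test suite.

Ambiguous group calls (support strictly between 0 and 75%) count as
"not detected" in pattern classification, matching the single ON universe
the detection rule defines; `classify_patterns(ambiguous = "exclude")`
instead drops such probes, for users who prefer the stricter exclusion
reading.

# Normalization

Normalization is two-step. Within each array, M = log2(Cy5) - log2(Cy3) is
corrected by a robust loess fit on A (tricube weights, `limma::loessFit`),
and the two channel intensities are reconstructed from (A, corrected M);
per-channel intensities are needed downstream because detection calls and
the pathway analyses operate on single-channel values. Between arrays the
default is rank-mean quantile normalization of the reconstructed
intensities (`limma::normalizeQuantiles`, ties averaged); the literal
"quartile" reading -- scaling every column to a common 75th percentile --
is available behind `method = "q75"` since the phrase is ambiguous in the
field's usage.

Two numerical choices deserve comment.

* **Loess span 0.5 with 4 robustifying iterations.** With ON/OFF biology,
  probes absent in one channel of an array form a one-signed cloud of large
  |M| concentrated in the intensity band between the background cluster and
  the expressed cluster. A narrow span (0.3) lets that cloud form a local
  majority and the fit absorbs genuine presence/absence signal, inflating
  the reconstructed background channel past the detection threshold. A
  wider window anchored by the non-differential majority, plus extra
  robustness iterations, makes the fit track the dye bias rather than the
  biology. The span remains a user parameter for arrays with a different
  geometry.
* **Quantile normalization operates on the values as given** (linear
  scale): every column's sorted values are replaced by the across-column
  mean of sorted values, which preserves within-column ranks and is
  idempotent. Detection thresholds are computed afterwards on the
  normalized scale.

# Differential expression

The fold rule is 1.5-fold with a two-sided t-test at p <= 0.05; log2(1.5)
is evaluated at full precision (0.585, displayed as 0.58). When the two
conditions co-hybridized on the same arrays (every array carries one sample
of each), the test is a one-sample t on the per-array log2 ratios, which
cancels array effects; otherwise a Welch two-sample t on log2 intensities.
No multiple-testing correction is applied by default, matching the bare
p-value rule; Benjamini-Hochberg adjustment is available via
`adjust = "BH"`. The constitutive between-stage series uses a plain
two-fold cutoff on ratios of average (arithmetic mean linear) intensities,
with no p-value -- this mirrors the pathway-mapping convention, where
average intensities rather than replicate tests drive the call. Gene sets
are flagged either when any member changes or when the changed fraction
strictly exceeds a threshold (default 0.45, the "more than 45% of composite
enzymes" rule).

# Marker filters

The pluripotency filter is an ordered conjunction: significant
downregulation (log2 < -0.585, p < 0.05) across the first transition, again
across the second, then "remain low or OFF later". The last clause is
qualitative in origin and is formalized here as: at each later stage the
probe is not called ON, or its stage-mean log2 intensity lies below that
stage's lower quartile over expressed probes. Gene-level scoring of curated
lists uses an any-probe rule -- a gene is constitutive if at least one of
its probes is -- and genes without probes are reported separately rather
than entering the denominator. Mutant persistence takes the wild-type-derived
reference set (ON at both earlier stages, not ON at the focal stage) and
reports the fraction called ON in the mutant at that stage; direct-target
candidates are the same-direction intersections of the mutant-vs-wild-type
tests at the two profiled stages.

# LCM enrichment and non-lobe assignment

Each LCM collection is tested against equivalently staged whole anthers
with the 1.5-fold rule; a probe is *enriched* in a zone when called UP
there and detected in that zone's sample. Non-lobe (connective and
vasculature) assignment unions two disjoint reason classes: probes
significantly DOWN in all three collections while present in the LCM data,
and probes detected in whole anther but in none of the collections whose
whole-anther intensity lies above the median of expressed whole-anther
probes. The quantile universe for that median is "probes called ON in whole
anther"; the source analyses left this universe implicit, so it is fixed
here and documented. Trough refinement partitions a trough set
exhaustively by later-stage behaviour (off everywhere, detected but
enriched nowhere, enriched in exactly one, two, or three zones) and reports
raw counts alongside fractions, because the published percentage for this
analysis has no single self-consistent denominator.

# Transcript-protein concordance

Proteins are linked to transcripts by gene id; multiple proteins of a gene
are summed (abundances are additive on the linear scale), multiple probes
of a gene averaged on the log2 scale. Only proteins with abundances at
every compared stage are ratioed, reflecting the ratiometric quantitation
design in which stage-specific proteins cannot be quantified. Decile
indices are computed independently per axis with a stable first-occurrence
tie-break so tables are bit-reproducible; margins are n/10 within one.
Cross-study overlap of small-protein sets restricts both sets to
molecular-weight bins lying fully inside the requested range (a bin
straddling a boundary is excluded, and this is the documented convention).

# The synthetic-data generator

`generate_experiment()` emulates the hybridization design: arrays arranged
in dye-swapped loops over the ordered stage series (each array
co-hybridizes consecutive stages; alternate loops reverse the dye
assignment), four replicate measurements per stage by default, and optional
mutant-vs-wild-type arrays at two stages. Because the five-stage grid is
0.15/0.25/0.4/0.7/1.0 mm, the mutant's earlier comparison stage is mapped
onto 0.25 mm, the nearest profiled wild-type stage.

The signal model: negative controls and OFF probes draw linear Gaussian
background (default mean 100, SD 20), making the detection FDR analytic; ON
probes have a per-probe log2 level anchored at an offset above the
detection point log2(mean + 3 SD) (default +2), spread by a right-skewed
exponential component (mean 1.5 log2 units) plus a small Gaussian jitter to
emulate the orders-of-magnitude dynamic range of real fluorescence data,
wiggled per stage (SD 0.3) to create between-stage differential expression
among constitutive probes, and measured with log2 replicate noise (SD
0.25). Dye bias is a smooth bounded function of A
(`amplitude * sin(A / 1.5)`) attached to the dyes, so swapped pairs carry
opposite sample-wise sign and the loess step is genuinely exercised.
Planted classes cover constitutive ON/OFF, one stage-specific and one
trough class per stage, a pluripotency-decline trajectory (high at 0.15 mm,
stepping down across both early transitions, background afterwards, and
elevated in the mutant), mutant-persistent trough probes, and
mutant-direct-target probes shifted four-fold in the mutant at both
profiled stages. Default class fractions were chosen once to emulate the
study conditions -- roughly half the probes constitutive, a large trough
cohort at the 0.4 mm focal stage planted at low offset (+0.8) above the
detection point so that, as in the real data, most trough transcripts sit
below the median at the preceding stage, and persistent plus pluripotent
probes comprising ~84% of the focal-OFF set so the mutant persistence
fraction matches the published regime by construction.

The LCM generator mixes zone signals into the whole-anther channel with
configurable fractions (defaults 0.25/0.30/0.35 for AR, ML/TAP and EPI/EN
plus 0.10 non-lobe), plants zone-enriched probes at four-fold, non-lobe
probes elevated in the non-lobe component (hence DOWN in every collection
relative to whole), and non-lobe-specific probes absent from every
collection yet high in whole anther. The protein generator sets the
base-stage protein level equal to the RNA level and adds per-transition
increments `c * dRNA + sqrt(1 - c^2) * sd(dRNA) * z`, so the Pearson
correlation of paired consecutive-stage log2 ratios equals the requested
`rna_protein_corr` in expectation, exactly 1 on the identity line when all
noise terms are silenced.

Determinism: one master seed; each array's measurements come from a
deterministically derived substream, so identical configurations are
bit-identical regardless of how many arrays precede.

**What the simulator does not emulate:** scanner artifacts, spatial/print-tip
effects, probe cross-hybridization, a continuum of weakly expressed probes
between background and the expressed cluster, intensity-dependent variance,
or correlated replicate structure. Passing recovery tests therefore show
that the pipeline's logic is correct under its stated noise model, not that
the thresholds are optimal for any particular real array platform.

# Degenerate inputs and tie-breaks

Zero-variance groups in a t-test get p = 1 when the means agree and p = 0
otherwise, so noise-free constructions behave sensibly. Quartile placement
uses type-7 quantiles with the conventions: "below the median" is strict,
"in the lowest quartile" means at or below the Q1 boundary, "above" is
strict. Class counts from fractions use floor-plus-largest-remainder
rounding. Probes missing a call at any stage are labelled `excluded` and
never silently dropped. Empty query sets return explicit empty results
rather than errors wherever the quantity is a summary of a set.

# Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
staged experiments of 2,000-2,500 probes with 100 negative controls and
four replicates per stage, an LCM experiment of 1,500 probes, a
2,000-protein concordance table, and a 10^6-draw null simulation for the
detection FDR (with 20,000 negative controls so threshold-estimation error
is negligible next to binomial error). These sizes were chosen so every
recovery statistic has comfortable sampling margins while the whole suite
runs in well under a minute on one CPU.

# Known limitations

* The t-test is unmoderated; with two replicates per group an
  empirical-Bayes variance moderation (as in limma's `eBayes`) would be the
  natural extension and is deliberately not the default, to keep the
  fold/p rule faithful.
* The pipeline treats every measurement of a stage as a biological
  replicate; technical dye-swap duplicates of the same biological pool are
  not collapsed before testing.
* Gene-level collapse rules (any-probe constitutive; mean-of-log2 RNA;
  summed protein abundance) are conventions, stated here, not inferences.
* The "quartile method" ambiguity (quantile vs 75th-percentile scaling) is
  resolved in favour of quantile normalization as the default; both are
  implemented and the choice is logged by the pipeline.
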