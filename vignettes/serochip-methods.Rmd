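---
title: "Methods: autofluorescence-corrected IgE quantification on allergen microarrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autofluorescence-corrected IgE quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serochip)
library(dplyr)
```

## The measurement model

A two-channel allergen microarray reports, per printed spot, the median
foreground intensity in the red channel (635 nm, driven by the labelled
anti-IgE secondary antibody) and the green channel (532 nm). Spotted
material autofluoresces in both channels, so the red signal of a spot is a
sum of two sources: autofluorescence and bound secondary antibody. The green
channel is unaffected by antibody binding and is therefore a pure
autofluorescence readout. On mock arrays — incubated with buffer and
secondary antibody but no serum — red is pure autofluorescence too, and
tracks green linearly within an allergen:

$$\log_2 R = m_a \log_2 G + b_a + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma_a^2).$$

`serochip` fits this line per allergen by ordinary least squares over all
unflagged mock spots (pooled across mock arrays), then estimates the IgE
contribution of a serum-array spot as the residual from that line,

$$\text{corrected} = \log_2 R - (\hat m_a \log_2 G + \hat b_a).$$

Working on the log2 scale follows the processing order of the pipeline
(discard flags, log-transform, correct, threshold). The additive
decomposition of red into autofluorescence plus antibody signal is most
natural on the raw intensity scale, and the generator exposes a raw-scale
signal regime (`signal_scale = "raw"`) so the sensitivity of downstream
results to this choice can be explored; the log2 regime is the default and
the one the test suite exercises.

Key assumptions, stated plainly: linearity of red on green within allergen;
Gaussian residuals on the log2 scale; green unaffected by serum; mock arrays
drawn from the same autofluorescence process as sample arrays. The
synthetic-data generator reproduces exactly this structure, which is what
makes the false-positive-rate calibration testable to Monte-Carlo accuracy.

## Detection thresholds and the 1% false-positive rate

The detection threshold for allergen $a$ is an upper percentile (default
$p = 0.99$) of the corrected mock distribution; a corrected signal strictly
greater than $\tau_a$ is a positive call, and the per-cell "microarray
units" are threshold-subtracted values. Thresholding is meant to deliver a
1% false-positive rate on null spots.

Two interpolated empirical-quantile conventions are supported
(`interp_quantile()`). The conventional default in R places the $p$-th
quantile at position $(n-1)p + 1$ (type 7). At the mock-spot counts this
design produces — 36 mock arrays × 3 replicate spots ≈ 108 values per
allergen — that convention is materially biased for the *operating
characteristic*: the expected fraction of fresh null spots exceeding the
type-7 99th percentile of 108 values is ≈ 1.9%, nearly double the nominal
rate, simply because the estimated quantile sits at expected coverage
$0.99\,n/(n+1)$. The plotting-position convention $(n+1)p$ (type 6) has
expected coverage $p$ and delivers the nominal 1% held-out rate at any $n$.
`calibrate_thresholds()` therefore defaults to type 6; type 7 remains one
argument away, and both are exact-quantile interpolations. This is the one
place the package deliberately departs from R's default quantile convention,
because the threshold's purpose is rate control, not quantile point
estimation.

The realized held-out rate is itself a random variable: with 108 training
values per allergen and 80 allergens, threshold-estimation noise contributes
about ±0.13 percentage points (1 sd) around 1%, which dominates the binomial
noise of scoring ~21,000 held-out spots. The acceptance script reports the
realized rate at the supplied seed; values in roughly 0.8–1.3% are ordinary
draws of this distribution.

## Replicate aggregation

Flagged spots (`flag < 0`, the scanner convention for bad/absent spots) are
removed before any transformation. A serum–allergen cell with more than 50%
of its expected replicates missing is recorded as missing — the rule is
applied per cell, the stricter and more local of the readings the
missing-data rule admits, and the expected count comes from the layout, so
wholly-flagged cells are counted, not silently skipped. Surviving replicates
are combined with a one-step Tukey biweight mean: location = median, scale =
unscaled MAD, tuning constant $c = 5$, weights $(1-u^2)^2$ for $|u|<1$. The
biweight is the standard robust "Tukey" location estimate in microarray
practice; with triplicate spots it discards a single wild replicate entirely
(e.g. the aggregate of (1, 2, 10) is ≈ 1.52). The Tukey trimean and plain
median are available alternatives. Thresholded units may legitimately be
negative; positivity is the strict `> 0` rule, and no flooring is applied to
stored values.

## Reproducibility statistics

* **CV report** — per-cell CV = sd/mean at three levels: across arrays
  within a slide; across slide means; across day means. Cells with replicate
  mean ≤ 0.5 microarray units are excluded (near-zero means make CV
  explode), and medians are taken within allergen class. On synthetic data
  the higher levels aggregate before dispersing, so their CVs are not
  larger than the intra-slide CV; real data ordinarily adds slide- and
  day-level drift that the generator deliberately does not model (see
  *Limitations*).
* **ANOVA variance shares** — a crossed fixed-main-effects model fitted by
  sequential (type I) sums of squares in the order array position, slide,
  serum, allergen, with shares reported against the total including error.
  Array *identity* would alias slide and serum, so the 12-level position
  factor plays the "array" role; with the default design this yields the
  11/8/5/79 degree-of-freedom pattern of a 6-sera × 18-replicate study. The
  exact mixed/nested structure of a given study is not recoverable from
  shares alone, so the model is kept to the simple crossed form and the
  share computation (`variance_share()`) is exact arithmetic.
* **Replicate regression** — every within-serum pair of replicate arrays is
  regressed (OLS of one profile on the other over shared non-missing
  allergens), summarized by median R² and median slope. The default design
  yields 6 × C(18,2) = 918 pairs.
* **Concordance** — array calls (thresholded > 0) against ELISA calls
  (> 0.35 kU/L, strict) in a 2×2 with proportions of total and the fraction
  of ELISA positives captured by the array.

No multiple-testing correction is applied to matched-pairs p-values by
default (raw two-tailed p-values are reported); the paired test refuses
zero-variance differences rather than fabricating p = 1.

## Clustering and support values

Allergen profiles are clustered by average linkage (UPGMA) under
correlation distance $d = 1 - r$, computed with pairwise-complete
observations (no value imputation). The UPGMA implementation breaks
minimum-distance ties deterministically by the lexicographically smallest
pair of cluster representative labels, making the tree invariant to input
order; on tie-free inputs it agrees with `stats::hclust` to machine
precision, and the test suite checks it against a brute-force recomputation
oracle on randomized 4- and 5-item matrices, ties included.

Clade support:

* **BP** — ordinary bootstrap: resample sera (rows) with replacement,
  recluster, count the fraction of trees containing the clade
  (B = 1000 by default).
* **AU** — multiscale bootstrap: repeat the bootstrap at resample sizes
  $\mathrm{round}(r\,n)$ for $r = 0.5, 0.6, \ldots, 1.4$, probit-transform
  the support curve $z_r = \Phi^{-1}(1 - \mathrm{BP}_r)$ (with
  $\mathrm{BP}_r$ clipped to $[1/(B+1),\, B/(B+1)]$ to keep probits finite),
  fit $z_r = v\sqrt r + c/\sqrt r$ by weighted least squares with
  delta-method binomial weights $B\,\phi(z)^2 / (\mathrm{BP}(1-\mathrm{BP}))$,
  and report $\mathrm{AU} = 1 - \Phi(v - c)$. Curves at frequency 0 or 1 at
  every scale are degenerate and clip to 0 or 1 with a flag. The fit is
  exactly invertible: support curves generated from known $(v, c)$ recover
  them to numerical precision, which the tests assert.

Trees export to Newick with ultrametric branch lengths (leaf depth 0, node
depth = merge height / 2) and `AU/BP` node labels; labels containing spaces
or metacharacters are single-quoted.

## The synthetic study

The generator is the package's stand-in for scanner data and defines the
conditions under which everything is validated:

| parameter | default | meaning |
|---|---|---|
| `mu_g_range` | (6, 12) | per-label mean log2 green (autofluorescence brightness) |
| `sigma_g` | 0.5 | spot-to-spot sd of log2 green within a label |
| `m_range`, `b_range` | (0.8, 1.1), (0.5, 2) | per-label red-on-green line |
| `sigma_eps` | 0.3 | residual sd of log2 red about the line |
| `flag_rate` | 0.02 | probability a spot is QC-flagged |
| design | 6 sera × 18 arrays + 36 mocks, 3 days, 12-array slides | 144 arrays on 12 slides |
| `dilution_ref` | 0.25 | serum fraction at which profile effects are expressed |
| effects | ~20% prevalence, 1.5–5 log2 units, scaled by serum total-IgE class | specific IgE added to red only |

Per-label autofluorescence parameters are drawn once, deterministically,
when the config is created; all simulators are pure functions of
(config, seed), and per-array seeds are derived from one top-level seed.
The magnitudes and panel composition (21 pollen species × three extract
fractions, nine non-pollen extracts, five recombinant major allergens,
triplicate printing, six-replicate controls and standards) were chosen once
to be realistic for a pollen-focused serology chip of this design; no
numeric equality with any published table is claimed for synthetic output.
Serum-to-serum heterogeneity in total IgE load (low/moderate/high classes)
is included because a reproducibility panel deliberately spans a wide range
of specific-IgE levels. The dilution response is the simplest monotone map,
$h(d) = d/d_\mathrm{ref}$ applied multiplicatively to log2 effects. Standard
dilution-series spots share autofluorescence parameters per isotype with
mean intensity scaling in log2(pg/spot) — a series is one printed material —
and only the IgE series gains secondary-antibody signal, which is exactly
what the standard-curve QC (rank correlation of mean red with pg/spot,
pass bar 0.9) consumes; standards are never used for normalization.

What the generator does **not** model, hence what green tests do not show
about real data: spatial artifacts and print-tip effects, scanner
saturation, slide- and day-level intensity drift, batch effects in the
secondary antibody, non-Gaussian autofluorescence tails, and cross-reactive
structure beyond what a profile's correlation blocks plant. ELISA values are
generated by a mixture construction with configurable sensitivity and
specificity relative to the 0.35 kU/L cutoff — a convention for exercising
concordance code, not a calibrated immunoassay model.

## Numerical choices and degenerate inputs

* Intensities are floored at 1 before log2, so zero-intensity spots map to
  0 rather than $-\infty$.
* Allergens with fewer than 3 usable mock spots are uncalibratable (no fit,
  no threshold, absent from the IgE matrix, listed in the run report);
  zero green variance falls back to an intercept-only model with a warning;
  thresholds from fewer than 20 mock values are flagged low-confidence.
* Corrected signal exactly at threshold is a negative call (strict
  inequality); missing corrected values propagate through thresholding and
  aggregation.
* A biweight scale (MAD) of 0 returns the median; an aggregation cell with
  exactly 50% missing is kept (the discard rule is strictly more than 50%).
* Zero-variance columns are excluded from correlation distance with a
  warning; single-level ANOVA factors are dropped with a warning; paired
  tests with < 2 complete pairs or zero-variance differences error.
* Simulated intensities are continuous (no rounding to scanner integers):
  GPR round-trips format doubles to 17 significant digits so write/read is
  exact, and the noise-free limit of the generator sits exactly on the
  autofluorescence line.

## Problem sizes used in validation

The test suite and acceptance script run entirely on synthetic data sized
to the study design they emulate: the default 144-array study for replicate
concordance and ANOVA structure; 36 training mock arrays plus 90 held-out
mock arrays (~21,000 null spot values) for false-positive-rate calibration;
67 mock arrays (~200 spots per allergen) for parameter recovery; 30-sera
studies with planted 6-allergen correlation blocks and B = 1000 bootstrap
replicates for cluster support. These sizes make every check reproducible
on a single CPU in minutes while keeping the Monte-Carlo error small
relative to the tolerances asserted.

## Known limitations

* Between-array normalization is out of scope by design: the method corrects
  autofluorescence and thresholds per allergen but applies no quantile or
  loess normalization, and microarray units are not converted to kU/L.
* The ANOVA is a fixed-effects variance-share summary, not a variance
  component estimator; nested/mixed alternatives would need the raw design.
* AU p-values carry no standard errors, and the bootstrap resamples sera,
  so support values are conditional on the serum panel.
* With triplicate spots the biweight has limited breakdown; two wild
  replicates in one cell will move the aggregate.
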