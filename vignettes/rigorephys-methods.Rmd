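---
title: "Quality control and cross-laboratory reproducibility statistics for extracellular electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control and cross-laboratory reproducibility statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigorephys)
```

## The problem

When several laboratories run nominally identical extracellular
electrophysiology experiments — same probe, same stereotaxic target, same
behavioural task — how much of the variation in their results is biology
and how much is the lab? `rigorephys` implements the two ingredients needed
to answer that question quantitatively:

1. **Recording-inclusion quality control**: a fixed set of computed
   criteria applied to every unit and every recording, so that comparisons
   are made only on data of verifiable quality.
2. **Reproducibility statistics**: permutation tests, power analyses,
   classifier-decoding nulls, task-modulation statistics and
   low-dimensional population embeddings that test whether the remaining
   variation is systematically associated with lab identity.

Because real multi-lab datasets are large and external, the package ships a
synthetic-data module that generates populations with exactly the
statistical structure the analyses assume. Everything below can therefore
be exercised end-to-end in seconds, with known ground truth.

## Quality-control metrics

### Single units

**Sliding refractory-period confidence.** A sorted unit contaminated by
spikes from other neurons shows inter-spike intervals (ISIs) shorter than
the absolute refractory period. Rather than assuming a refractory-period
length, the metric scans a grid of 50 log-spaced candidate lengths
$t_r \in [0.5, 10]$ ms. At each $t_r$ the observed violation count
$k(t_r)$ (consecutive ISIs below $t_r$) is compared with the count expected
if the unit were contaminated at exactly the maximum acceptable level
$c = 0.1$ by an independent Poisson process:
$$\lambda(t_r) = 2\, t_r\, c\, N\, r,$$
with $N$ spikes and mean rate $r = N/D$ over duration $D$; the factor 2
counts a contaminating spike violating against either neighbour. The
confidence that contamination is below $c$ is the Poisson survival
probability $P[\mathrm{Pois}(\lambda) > k]$, and the unit passes if this
exceeds 0.9 at *any* candidate length. The same contamination model drives
the synthetic generator (`gen_spike_train()` injects contaminating spikes
as an independent Poisson process at rate $c/(1-c)\,r$), so metric and
generator are mutually consistent and the calibration claimed for the
metric is testable: clean trains pass and trains at 20% contamination fail
essentially always at $N \ge 10^4$ spikes.

**Amplitude cutoff.** Spikes missed by the detection threshold truncate
the low tail of a unit's spike-amplitude histogram. With 100 equal-width
bins, the height of the lowest bin is compared with the bins in the top
quarter (by bin index) above the histogram peak:
$\mathrm{sd\_distance} = (h_{\text{low}} - \bar h_{\text{high}})/
\mathrm{sd}(h_{\text{high}})$, and
$\mathrm{low\_bin\_fraction} = h_{\text{low}}/h_{\text{peak}}$. A unit
passes with `sd_distance < 5` and `low_bin_fraction < 0.1`. No Gaussian
assumption is made; a flat top quantile (zero SD) maps to an infinite
distance unless the low bin equals its mean. The bin count (100) is a
package default, exposed as an argument.

**Median amplitude.** The median spike amplitude must exceed 50 uV
(strict inequality; a unit at exactly 50 uV fails).

### Whole recordings

* **Yield**: at least 0.1 QC-passing units per electrode channel, per
  brain region.
* **Noise**: median AP-band RMS across channels strictly below 40 uV.
* **LFP depth derivative**: per-channel power spectral density by Welch's
  method (Hann windows of 1024 samples, 50% overlap — implemented in the
  package and verified against Parseval and white-noise oracles),
  converted as $\mathrm{dB} = 10\log_{10}(\mathrm{PSD})$, averaged over
  20–80 Hz, differentiated along channel depth (central differences,
  absolute value — the sign depends on probe orientation); the median
  absolute derivative must be strictly below 0.05 dB/um. Whether band
  power is the mean or the median over frequency bins is an open choice;
  the mean is used.

### The exclusion cascade

Sessions are excluded in a fixed order: data-acquisition failures
(hardware, histology), visually assessed criteria (drift, noisy channels,
artefacts, epileptiform activity — ingested as precomputed boolean flags,
since they are assessed by manual inspection), computed recording criteria
(yield, noise), the behaviour criterion (at least 400 completed trials),
and finally a lab-session-count rule (at least 3 sessions per lab) for
analyses that compare across labs. A session is attributed to the *first*
criterion it fails, so the per-criterion tallies are disjoint and
`survivors + sum(tally) = input`. On the published bookkeeping (121
recorded sessions with 10+8+1+10+2+1+1+1+5 failures) the cascade leaves
82 survivors.

## Reproducibility statistics

### The max-CDF-distance permutation test

For a feature measured across labs, the test statistic is, for each lab,
the largest absolute difference between the lab's empirical CDF and the
empirical CDF of all remaining labs (the two-sample KS distance of lab vs
rest), maximized over labs. The null hypothesis — mice are assigned to
labs at random — is sampled by permuting the mouse-to-lab assignment
(preserving the number of mice per lab; a mouse's neurons travel with it)
50,000 times by default. Significance is declared at $\alpha = 0.01$,
a deliberately stringent level playing the role of a correction for the
number of regions. The p-value uses the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{perm}})$, which
never returns exactly zero and differs from the plain proportion by at
most $1/n_{\text{perm}}$. Because the statistic is rank-based it is
invariant under strictly monotone transforms of the feature, and the
sampled p-value agrees with exhaustive enumeration on small problems
(verified in the tests).

### Power analysis

For each lab, all of its values are shifted up (or down) by an additive
amount and a binary search finds the smallest magnitude at which the test
becomes significant. The permutation null is frozen — the same
relabellings are reused at every candidate shift — so the search target is
deterministic, and the returned shift $\Delta$ satisfies
$p(\Delta) < \alpha$ and $p(\Delta - \mathrm{tol}\cdot\mathrm{sign}(\Delta))
\ge \alpha$. The default tolerance is 0.1% of the pooled value range, with
at most 20 bisection iterations after geometric bracket expansion. An
already-significant configuration is flagged and returns zero shifts.

### Decoding with a shuffle null

As a complement that is sensitive to multivariate structure, a random
forest (200 trees, stratified 5-fold cross-validation) predicts the lab
(or region) of each recording from five markers: yield, firing rate, LFP
band power, AP-band RMS and spike amplitude. The null distribution is the
cross-validated accuracy on label-shuffled data (500 shuffles by default);
the p-value is the fraction of shuffled accuracies at least as large as
the observed one. Tree count and fold scheme are package defaults.

### Task modulation and the Fano factor

Six window comparisons classify each unit as modulated or not on correct,
non-zero-contrast trials, using Wilcoxon signed-rank tests for paired
windows (pre/post stimulus, movement, feedback, and a longer
baseline-vs-movement comparison) and rank-sum tests for unpaired ones
(left vs right choice, left vs right stimulus side), each at
$\alpha = 0.05$ with no unit-level correction. The window bounds
(baseline $[-0.2, 0)$ s pre-stimulus; post-stimulus $[0, 0.4)$ s;
pre/post-movement $[-0.2, 0)/[0, 0.2)$ s; post-feedback $[0, 0.2)$ s) are
package defaults, overridable per call. Windows are half-open; a test with
fewer than 5 usable trials on a side — or a unit that is silent in every
window — is undetermined and excluded from population proportions, which
in turn require at least 4 units in the target region per session.

The Fano factor (variance/mean of spike counts, unbiased variance
estimator) is computed in the 40–200 ms window after movement onset on
correct, full-contrast, right-side-stimulus trials; it is 1 for Poisson
spiking, which the tests verify to within three standard errors at 1000
trials.

### PETH embedding

Each cell is summarized by two peri-event time histograms aligned to first
movement onset — fast ($\mathrm{RT} < 0.15$ s) and slow
($\mathrm{RT} > 0.15$ s) trials, 100 bins of 20 ms spanning $-0.5$ to
$1.5$ s — each normalized as $(\mathrm{PETH} - b)/(b + \varepsilon)$ with
$b$ the mean baseline rate in $[-0.5, -0.2)$ s pre-movement and
$\varepsilon = 0.5$ sp/s (both package choices; the offset protects
near-silent cells). The concatenated rows form an $N \times 2T$ matrix
whose mean-centered truncated SVD gives a $k = 2$ embedding; centering is
chosen so the first component captures variance, with an uncentered
option. Per-cell goodness of fit is
$r^2 = 1 - \|y - \hat y\|^2 / \|y - \bar y\|^2$.

Lab and region structure in the embedding is tested three ways: a
two-sample KS test of a target subset's first-PC distribution against all
remaining cells (at $\alpha = 0.01$ Bonferroni-corrected over regions); a
2D distance permutation test (distance between a group's mean embedding
and the remaining cells' mean, against a label-shuffle null); and a
cell-number-controlled variant that repeatedly subsamples the minimum
group size from each side and combines the KS p-values with Fisher's
method ($\chi^2$ with $2 n_{\text{samplings}}$ df, default 100
samplings). Fisher's method assumes independent p-values while repeated
subsamples overlap, so the combined p-value is not guaranteed uniform
under the null; the procedure is implemented as specified and its
calibration is measured empirically rather than assumed.

### Outliers and variance decomposition

Within a region (pooled across sessions), a neuron is a firing-rate
outlier when its absolute deviation from the median rate exceeds 15% of
the rate range — a scale-equivariant rule. Outlier vs non-outlier (and
modulated vs non-modulated) groups are compared feature-by-feature (x, y,
z, amplitude, peak-to-trough duration) with two-sample KS tests,
Bonferroni-corrected over the five features. An OLS regression of
session-averaged rate on those five covariates (standardized internally
for conditioning, coefficients reported back on the raw scale — an exact
transformation, verified against a normal-equations oracle) reports the
unadjusted $R^2$; in realistic synthetic regimes this sits around 5%,
i.e. spatial position and waveform explain little rate variability.

### Probe-targeting geometry

A traced probe track is reduced to a straight line by total least squares
(first principal axis through the centroid); its brain-surface entry point
is the intersection with an injectable surface, by default the plane
DV = 0 of the package's synthetic atlas frame (real surface meshes are out
of scope). Displacements from the planned trajectory are reported per axis
and as Euclidean distance in the surface plane; angles use the absolute
dot product because traced directions carry a sign ambiguity. Labs enter
the across-lab comparison only with at least 4 insertions.

## The synthetic-data generator

`gen_multilab_population()` builds the lab → mouse → session → unit
hierarchy the analyses consume. Its defaults describe the standardized
study design the statistics assume: 10 labs, 4 mice per lab, one insertion
per mouse spanning the five target regions (VISa/am, CA1, DG, LP, PO) with
20 units each; baseline rates around 6 sp/s with lognormal unit-to-unit
and mouse-level variability (Gaussian-family variability is an assumption
— the distributional family of real per-mouse variability is not known);
2 ms refractory period, zero contamination; amplitudes 150 +/- 30 uV;
500-trial sessions with an unbiased lead-in block followed by alternating
20:80/80:20 biased blocks and log-normal reaction times with mean 0.15 s
(only the empirical mean is specified; log-normal is the package's
choice). Regions receive distinct event-locked response templates (a
transient, a sustained step, a ramp, a late step, and an unmodulated
region) — an invented minimal basis sufficient to make regions separable
in the PETH embedding while labs, balanced over regions, are not.

With `lab_effects` absent, per-mouse features are exchangeable across labs
(the permutation null); with `lab_effects` set, the named lab's firing
rate, amplitude, AP-band RMS or LFP power is shifted additively (the
alternative). Identical configs produce bit-identical populations, and
generators leave the caller's RNG state untouched.

What the generator does **not** emulate: raw voltage waveforms, spike
sorting artefacts, electrode drift, non-stationary firing, correlated
noise across units, or histology imaging. Passing tests therefore
demonstrate that the statistics behave correctly under their own model
assumptions — calibrated nulls, power against injected effects — not that
real recordings satisfy those assumptions.

## Numerical choices and degenerate inputs

* Violation counts use consecutive ISIs only; the factor 2 in
  $\lambda(t_r)$ accounts for either-neighbour violations. Confidence uses
  the strict survival function $P(X > k)$.
* Sessions round-trip losslessly through the on-disk layout (one
  directory per session; units/spikes/trials/channels/PSD as CSV or
  Parquet tables with full-precision numeric formatting; metadata and
  trajectories as JSON). Generator configs are read from YAML.
* Units with fewer than 2 spikes, fewer than 50 amplitudes, or a
  zero-amplitude range fail QC with a reason, never an exception.
* The observed statistic is compared with its null by non-strict
  inequality ($\ge$), the conservative choice.
* Fano factors with zero mean count, tests with under 5 trials per side,
  and silent units are undetermined (NA), not failures.
* Times are seconds from session start; positions are um in a
  right-handed atlas frame with DV increasing with depth; 0-based depth
  along the probe.

## Problem sizes used in the tests

The test-suite and the acceptance script run the full pipeline at reduced
but statistically meaningful scale, chosen once: calibration of the
permutation test uses 200 null datasets of 10 labs x 4 mice at 2,000
permutations each; metric calibrations use 200 seeds at 10,000+ spikes or
amplitudes per unit; the embedding analyses use 5 labs x 3 mice with 20
units per session and 150 trials. The defaults of the user-facing
functions remain at study scale (50,000 permutations, 500 shuffles).

## Known limitations

* Visual QC criteria are ingested as flags, not computed from raw data.
* No raw-voltage processing: spike sorting, destriping and alignment are
  upstream of this package.
* The subsampled Fisher combination inherits the dependence caveat above.
* The brain surface is a plane in the synthetic frame; real surface
  geometry must be supplied through the injectable surface function.
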