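# rigorephys

Quality-control standards and cross-laboratory reproducibility statistics
for extracellular electrophysiology, with a synthetic multi-lab data
generator so the whole pipeline runs end-to-end without any recording on
disk.

## What it does

When several labs run nominally identical Neuropixels-style experiments,
two questions arise: *is each recording good enough to compare?* and *do
the surviving data differ systematically by lab?* `rigorephys` implements
both halves:

**Recording-inclusion QC.** Per unit: a sliding refractory-period
contamination confidence — for each candidate refractory length
`t_r ∈ [0.5, 10]` ms the observed violation count `k(t_r)` is compared
with the count expected at 10% contamination,
`λ(t_r) = 2 t_r · 0.1 · N · r`, and the unit passes if the Poisson
survival probability `P[Pois(λ) > k]` exceeds 0.9 anywhere on the grid;
an amplitude-cutoff estimate of missed spikes (lowest histogram bin vs the
top quartile of bins above the peak; pass at `< 5` SDs and a low-bin
fraction `< 0.1`); and a median spike amplitude `> 50 µV`. Per recording:
yield `≥ 0.1` passing units/channel per region, median AP-band RMS
`< 40 µV`, and a median absolute depth-derivative of 20–80 Hz LFP power
(Welch PSD, `dB = 10·log10`) `< 0.05 dB/µm`. An ordered exclusion cascade
(acquisition → visual criteria → computed criteria → ≥ 400 behavioural
trials → ≥ 3 sessions/lab) attributes each excluded session to its first
failing criterion.

**Reproducibility statistics.** The max-CDF-distance permutation test
(for each lab, the KS distance between its feature distribution and the
rest, maximized over labs; null by permuting the mouse→lab assignment,
`α = 0.01`); a binary-search power analysis returning the smallest lab
shift that would make the test fire; random-forest lab decoding against a
label-shuffle null; six Wilcoxon task-modulation window tests and a
movement-window Fano factor; PCA embedding of fast/slow double PETHs with
KS, 2D-distance-permutation and cell-number-controlled Fisher-combined
tests; firing-rate outlier detection and a 5-feature OLS variance
decomposition (unadjusted R²); and probe-targeting geometry
(total-least-squares trajectory fit, surface displacement, angle
deviation).

## Worked example

Generate a 10-lab synthetic population in which one lab's firing rates
are shifted by +5 spikes/s, run unit QC, and test the shift:

```r
library(rigorephys)

cfg <- synth_config(seed = 42, n_labs = 10, mice_per_lab = 4,
                    units_per_region = c("VISa/am" = 5, CA1 = 5, DG = 5,
                                         LP = 5, PO = 5),
                    n_trials = 200,
                    lab_effects = list(lab_04 = list(firing_rate = 5)))
pop <- gen_multilab_population(cfg)

s <- pop[[1]]
unit_qc(s$units[[1]], session_duration(s))
#> QC report: PASS
#>   rp_confidence                   1 (threshold 0.9): pass
#>   cutoff_sd_distance        -0.2521 (threshold 5): pass
#>   cutoff_low_bin           0.007463 (threshold 0.1): pass
#>   median_amplitude              142 (threshold 50): pass

tab <- feature_table(pop)   # one row per unit (here one session per mouse)
permutation_test(tab$session_mean_rate, tab$lab_id,
                 mouse = tab$session_id, n_perm = 5000, seed = 1)
#> Across-lab permutation test (max-CDF distance)
#>   statistic = 0.4644, p = 0.0014 (5000 permutations)  [significant at 0.01]
```

The QC report shows the three single-unit criteria with their measured
values: a contamination confidence of 1 (no refractory violations beyond
chance), an intact amplitude distribution, and a healthy median amplitude.
The permutation test detects the injected lab effect (p = 0.0014 < 0.01);
on the same population without `lab_effects` the identical call gives
p = 0.36 — the null is retained when labs are exchangeable.

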