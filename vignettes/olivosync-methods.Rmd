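---
title: "Methods: quantifying how complex-spike synchrony shapes cerebellar nuclear firing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying how complex-spike synchrony shapes cerebellar nuclear firing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olivosync)
```

## The scientific question

Purkinje cells (PCs) are the sole output of the cerebellar cortex and inhibit
neurons of the deep cerebellar nuclei (DCN). Their climbing-fiber-evoked
complex spikes (CSs) fire at only ~1 Hz per cell, but the gap-junction-coupled
inferior olive synchronizes CSs across PCs, preferentially within
rostrocaudally running cortical bands. Because tens of PCs converge on each
DCN neuron, the functional impact of a CS plausibly depends less on the single
cell than on how many converging PCs fire together. This package implements an
analysis pipeline for multi-electrode recordings (one DCN neuron plus an array
of PCs) that asks: how strongly does the population synchrony of CSs among the
*presynaptic* PCs modulate DCN firing, and how much does the *temporal
precision* of that synchrony matter?

Because raw recordings of this kind are not publicly available, the package
pairs every analysis stage with a seeded synthetic generator that produces
sessions with the same statistical structure plus ground truth, so each stage
is verified by parameter recovery rather than by eye.

## Pipeline stages and their models

### Connectivity: the two-slope test on CS-triggered correlograms

A PC synapsing on the recorded DCN cell leaves a short-latency inhibitory
footprint in the CS-triggered correlogram of DCN activity (1 ms bins, lags
labeled by bin centers ..., -0.5, +0.5, ...). `slope_test()` fits
least-squares lines to the bin rates in a pre-CS window (-10 to 0 ms, or -15
to -5 ms when an excitatory deflection is visible at the CS) and a post-CS
window (3 to 13 ms), and compares the slopes with a pooled-variance t
statistic on `n1 + n2 - 4` degrees of freedom. A PC is called presynaptic
only if, in addition to significance (two-sided alpha = 0.05), the post-CS
slope is the more negative one, the inhibition onset falls within 5 ms of the
CS (consistent with a monosynaptic PC-DCN conduction time), and the trough
does not already begin before the CS.

Two of these gates automate judgments that are otherwise made visually:

* *Excitation at the CS* is declared when any bin in [-5, +3) ms exceeds the
  baseline mean by more than 2 baseline SDs (threshold configurable).
* *Broad troughs centered on 0* arise when a non-presynaptic PC merely shares
  CS synchrony with true presynaptic cells; they are vetoed by testing whether
  the mean rate in the 5 ms immediately preceding the CS is already
  significantly (2 SD) below baseline. A literal backward walk along the
  smoothed histogram was rejected: any moving average hovers around its own
  baseline mean, so a noise-level walk falsely excludes a large fraction of
  true connections.

### Spatial restriction of the presynaptic group

PC-to-DCN projections are topographic, so a correctly identified presynaptic
group should be narrow along the mediolateral (ML) axis of the array but not
along the rostrocaudal (RC) axis. `spatial_permutation_test()` compares the
observed mean pairwise separation along one axis against 1000 random
same-size groups drawn from the occupied electrode positions (one cell per
location), and reports the percentile of the observed value.

Because the separation statistic is strongly discrete (multiples of the
250 um pitch averaged over a handful of pairs), counting ties fully into the
percentile biases random-group percentiles upward (measured mean ~58 instead
of 50, wrecking the uniform null calibration). The package therefore uses the
standard *mid-p* convention - ties contribute half their mass - which makes
random-group percentiles approximately uniform while leaving column-confined
groups far below the 5th percentile.

### Pairwise synchrony: the zero-lag coefficient C(0)

Whole-session synchrony of a PC pair is the correlation of their binarized
trains: with X(i), Y(i) the zero-one indicators of a CS onset in 1 ms bin i,
and V, W their mean-centered versions,

$$C(0) = \frac{\sum_i V(i)W(i)}{\sqrt{\sum_i V(i)^2 \sum_i W(i)^2}},$$

which is 1 for perfectly synchronized trains and 0 in expectation for
independent ones. The 1 ms bin width matches the correlogram resolution and
the binarization granularity standard in multielectrode CS work; the full
recording duration is used. `c0()` is checked against an independent Pearson
oracle (`cor()` on the binary vectors) to 1e-12.

### Per-CS synchrony events and levels

`sync_events()` makes every CS of every group PC the reference of one event:
its level is k/x, where x is the group size and k counts the group PCs
(reference included, so levels start at 1/x) with at least one CS onset
within +/-5 ms of the reference onset. A non-reference PC counts at most once
per event - the level counts *cells*, not spikes.

### Inhibition as a function of synchrony level

For each synchrony level, `inhibition_by_level()` builds one CS-triggered
histogram per PC from that PC's CSs at that level, averages the per-PC rate
profiles without weighting (so prolific cells do not dominate), and measures
the percent change of the mean rate in the response window relative to the
pre-CS baseline (default -55 to -5 ms; -30 to -5 ms is exposed for sessions
whose correlograms are flat over a shorter stretch).

The response window comes from the all-CS group histogram: the start is the
center of the first post-0 bin whose centered 3-bin moving average falls
below baseline, the end the first later bin whose moving average returns to
baseline. With k-bin smoothing the detected end lags the true edge by up to
half the smoothing window; this is accepted rather than corrected, because
the same window is applied to every level. Re-detecting the window per level
(`method = "PER_LEVEL"`) is supported with a 6-bin fallback for sparse
histograms, but is noise-dominated wherever the trough is shallow, so the
fixed all-CS window is the default for effect quantification.

Sparse top levels are merged by `collapse_high_levels()`: the topmost levels
are collapsed downward until every PC has at least 10 events in the merged
bin, and the merged bin is assigned the event-count-weighted average of the
merged level values. PCs that cannot reach 10 events even after a full merge
are excluded from per-PC analyses.

Supporting analyses: `baseline_vs_level()` checks that per-level baselines
(already normalized per trigger) do not themselves drift with level;
`per_pc_comparison()` contrasts each PC's all-CS effect with its
high-synchrony effect (Wilcoxon signed-rank); `extrapolate_single_pc()`
evaluates the fitted effect-versus-level regression at the population
fraction a single PC represents (0.01-0.02 under 50-100 converging PCs) with
its prediction standard error; `long_latency_analysis()` finds supra-baseline
periods in the +/-1000 ms correlogram (baseline = whole-range mean, 50 ms
moving average, contiguous run containing the smoothed maximum in the pre-CS
range -1000..-50 ms and the post-CS range +100..+1000 ms) and correlates the
per-level change inside those fixed periods with level. The 50 ms smoothing
width is a documented parameter standing in for a judgment otherwise made
visually.

### Temporal precision: window sweep, cusum, donut

`sweep_sync_windows()` re-classifies high-synchrony events (k at or above the
collapse threshold) with windows expanding from +/-5 ms in 5 ms steps. The
annulus count at window W is the number of events qualifying at W but at no
smaller window; the cusum is its running sum. The effect curve uses all
events qualifying at windows up to W (pooled across reference PCs). The
*cusum-doubling window* is the first whose cusum reaches twice the +/-5 ms
count; the *donut* set holds the events qualifying at the doubling window but
not at +/-5 ms. An event is excluded from the donut exactly when it qualifies
at +/-5 ms (the natural reading of removing "the most precisely synchronized
events"; membership of every constituent CS in the central window is not
required). Comparing single-CS, +/-5 ms, cusum-window and donut effects -
optionally after subtracting the single-CS effect - separates the
contribution of precise synchrony from that of temporally dispersed
coincidences.

## The synthetic generator

`simulate_session()` draws, from one integer seed:

* **Layout**: a 4 x 8 grid at 250 um pitch; the n_presyn presynaptic PCs
  occupy one ML column (the anatomically expected arrangement), the remaining
  PCs random positions.
* **CS trains**: shared network events (the inferior-olive analog) as a
  Poisson process (0.8 Hz); each PC joins each event independently
  (presynaptic 0.35, others 0.05) and fires one CS at the event time plus
  truncated Gaussian jitter (SD 2 ms, cut at +/-5 ms); independent background
  CSs (0.2 Hz) are superimposed; a 10 ms per-cell CS refractory period drops
  the later of two close events. Defaults put per-PC CS rates near 0.5 Hz -
  the low end of the ~1 Hz range typical of these cells - and DCN rates at
  35 Hz, within the reported range for nuclear neurons.
* **DCN train**: an inhomogeneous Poisson process (exact thinning over the
  piecewise rate, 1 ms absolute refractory) whose rate is the 35 Hz base
  multiplied by the active kernels. Every surviving presynaptic CS of an
  event with synchrony fraction s (presynaptic recruits / n_presyn)
  contributes a factor (1 - max_fraction * s)^(1/k), k the event's recruit
  count, so the combined event factor is exactly 1 - max_fraction * s:
  inhibition depth is linear in synchrony. Background presynaptic CSs count
  as single-cell events (s = 1/x). Multiplicative (not subtractive) kernels
  guarantee non-negative rates and clean scaling.

The kernel starts 1.5 ms after the CS onset, drops *immediately to half its
depth*, deepens linearly to full depth over rise_ms (10 ms), holds until
67 ms, then switches off. The two-phase shape is deliberate: the sharp
initial IPSP makes the correlogram fall below baseline right at the
monosynaptic delay (so onset-latency recovery is meaningful), while the
summation phase makes it continue declining through the 3-13 ms window that
the slope test examines - a pure step would hide the entire decline in the
0-3 ms gap between the test's windows. Optional components: long-latency
excitation windows around each event (-414..-136 ms and +146..+456 ms,
rate x (1 + gain * s), off by default) and a brief excitation around each
presynaptic CS (off by default) to exercise the excitation-aware branch of
the slope test.

What the generator does *not* emulate: the ~10 Hz rhythmicity of CS activity
(which in real data produces a secondary annulus peak at 80-120 ms windows),
simple-spike activity and its post-CS modulation, DCN bistability or rebound
bursting, nonstationary rates, and electrode artifacts. Passing recovery
tests therefore demonstrates that the analysis code measures what it claims
to measure under the stated point-process model - not that the model captures
every property of real recordings.

## Numerical conventions and edge cases

* Times are seconds in double precision; file I/O serializes at 1 us.
* Bins are half-open [k, k+1) ms, labeled by centers; two events in one bin
  binarize to a single 1; the trailing partial bin is kept, so durations
  taken from a config (preferred, deterministic) or from the data round up.
* Correlogram triggers near the recording edges contribute without
  correction; sessions are long relative to the +/-1 s lag range.
* `c0()` errors on empty or constant binarized trains (zero variance).
* Noiseless correlograms with zero residual variance in the slope windows
  give t = +/-Inf (p = 0) when the slopes differ and t = 0 (p = 1) when they
  coincide.
* The permutation percentile uses mid-p tie handling (see above); the
  permutation RNG is seeded independently of the session RNG.
* All generator randomness flows from the single config seed; identical
  config and seed reproduce sessions and pipeline reports byte-identically.

## Statistical power at the default study conditions

The default synthetic conditions are deliberately conservative: ~580 CSs per
PC and a mean event synchrony fraction of 0.46 produce an average post-CS
modulation of only ~34% of the 35 Hz baseline. Under these conditions the
two-slope connectivity test has low per-cell power (the correlogram declines
by ~0.6 Hz/ms across the post window against a ~0.77 Hz/ms slope standard
error, a noncentrality near 1), so sensitivity for individual connections is
far below 1 even though its false-positive rate is calibrated at alpha.
Roughly tenfold more triggers or threefold deeper average modulation would be
needed for 90% per-cell sensitivity. Recovery analyses of kernel properties
(onset latency, effect-versus-level scaling, precision dependence) therefore
run on the generator's ground-truth presynaptic group, which is exactly what
ground truth is for; identification quality is reported separately. For the
same reason `run_pipeline()` accepts `use_ground_truth_group = TRUE` and
otherwise skips group analyses when fewer than 4 PCs are identified.

## Problem sizes used by the test suite

Unit tests run on 200-600 s sessions; recovery suites use 10-25 full-length
(1200 s) sessions, 20-seed onset recovery, 500 kernel-free PC-DCN pairs for
false-positive calibration, 200 replicates x 1000 permutations for the
percentile calibration, and 20 pairs of 10,000 s trains for the C(0) null.
These sizes keep each property's sampling error well inside its assertion
margin while the whole suite completes in a few minutes on one CPU.

## Known limitations

* The slope test's power depends steeply on trigger counts and modulation
  depth (above); on weakly modulated cells the identified group will be a
  conservative subset.
* Response-window end detection inherits a half-smoothing-window lag and, on
  shallow troughs, is noise-dominated - duration-versus-level conclusions are
  only meaningful for well-populated, clearly inhibited levels.
* The donut analysis is undefined when the cusum never doubles within the
  sweep range (e.g. with perfectly precise synchrony and little background),
  and the result is flagged rather than extrapolated.
* C(0) uses the full recording; no provision is made for excluding unstable
  segments.
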