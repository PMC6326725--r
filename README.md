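# olivosync

Analysis of how complex-spike (CS) synchrony among cerebellar Purkinje cells
(PCs) modulates the firing of the deep cerebellar nuclear (DCN) neuron they
converge on, from multi-electrode spike-time recordings.

Each PC fires CSs at only ~1 Hz, but the gap-junction-coupled inferior olive
synchronizes CSs across PCs. Since dozens of PCs inhibit each DCN neuron, the
question this package addresses is population-level: *how much of the PC-to-DCN
inhibitory effect is carried by synchronous, temporally precise CS activity?*
It is written for electrophysiologists analysing paired PC-array/DCN
recordings, and ships a seeded synthetic generator with ground truth so that
every stage of the analysis can be validated by parameter recovery.

## What the pipeline computes

1. **Connectivity** (`identify_presynaptic`): presynaptic PCs are identified
   from CS-triggered correlograms of DCN activity (1 ms bins) by comparing the
   regression slopes of the histogram just before the CS (−10..0 ms, or
   −15..−5 ms if an excitatory deflection is visible) and just after it
   (3..13 ms) with a pooled-variance t test (df = n₁+n₂−4), gated on a
   monosynaptic onset latency (0 < t ≤ 5 ms) and the absence of a broad
   pre-CS trough.
2. **Spatial check** (`spatial_permutation_test`): the mediolateral
   restriction of the identified group is tested against 1000 random
   same-size groups on the occupied electrode positions (mid-p percentile).
3. **Pairwise synchrony** (`c0`): the zero-lag correlation of the binarized
   (1 ms) trains,
   C(0) = Σ V·W / √(Σ V² Σ W²) with V, W the mean-centered zero-one trains —
   1 for perfect synchrony, 0 for independence.
4. **Synchrony events** (`sync_events`): every CS is assigned a level k/x —
   the fraction of the x presynaptic PCs (reference included) firing a CS
   within ±5 ms of it.
5. **Inhibition vs synchrony** (`inhibition_by_level`): per-level CS-triggered
   histograms (per-PC, then unweighted group average), percent change of DCN
   rate in the response window relative to the −55..−5 ms baseline, with the
   response window detected from the all-CS histogram by a 3-bin
   moving-average baseline-crossing rule; sparse top levels are collapsed by
   an event-weighted average until every PC has ≥10 high-synchrony events.
6. **Precision sweep** (`sweep_sync_windows`, `donut_comparison`): the
   synchrony window is widened in ±5 ms steps; annulus counts, their cusum,
   the cusum-doubling window and the "donut" event set (doubling window minus
   the precise ±5 ms events) quantify how much of the inhibition is carried by
   precisely synchronized events.

`run_pipeline()` sequences everything into one JSON-serializable report;
`simulate_session()` generates ground-truth sessions (shared network events,
per-cell recruitment and jitter, multiplicative inhibition kernels whose depth
is linear in the event's synchrony fraction).

## Worked example

```r
library(olivosync)

cfg     <- synth_config(seed = 42)          # 1200 s, 20 PCs, 6 presynaptic
session <- simulate_session(cfg)
session
#> <recording_session> 20 PCs + 1 DCN ('dcn1'), 1200.0 s
#>   synthetic; 6 ground-truth presynaptic PCs

events <- sync_events(session$pcs[session$ground_truth$presyn_ids])
mod    <- inhibition_by_level(session, session$ground_truth$presyn_ids, events)
mod
#> <modulation_result> 5 levels, all-CS change -26.4% in [1.5, 72.5] ms
#>    level    n percent_change duration_ms
#> 1 0.1667 1680         -10.31          39
#> 2 0.3333  651         -31.68          71
#> 3 0.5000  642         -44.64          71
#> 4 0.6667  283         -59.23          73
#> 5 0.8584   93         -57.60          16

spatial_permutation_test(session$ground_truth$presyn_ids, session$layout,
                         "ML", seed = 1)
#> <spatial_test_result> ML: observed 0.0 um, percentile 0.1 (n_perm=1000)
```

Reading the output: the response window detected from the all-CS histogram
starts 1.5 ms after the CS (the monosynaptic latency) and the inhibition
deepens from −10% when a reference PC fires alone (level 1/6) to about −60%
at high synchrony — the injected kernels scale linearly with the event's
synchrony fraction, and the measured curve recovers that. The top level
(0.858, a weighted merge of the sparse 5/6 and 6/6 levels) rests on only 93
events, so its estimate is noisier, and its 16 ms "duration" illustrates why
per-level window detection is unreliable on sparse histograms (the fixed
all-CS window is used for the effect values). The ground-truth presynaptic
group sits in one mediolateral column, far below the 5th percentile of random
groups.

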