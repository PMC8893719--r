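# hierseq

Simulation and analysis of electrocorticography (ECoG) recordings under
the auditory **local-global** oddball paradigm, for researchers studying
hierarchical predictive processing in auditory cortex.

Five-tone sequences carry regularities at two time scales: a deviant 5th
tone (xxxxY, "xY") violates the *local* (tone-to-tone) expectation, while
a rare sequence type violates the *global* (sequence-to-sequence)
expectation established during habituation — e.g. `xx|xY` denotes an xx
sequence presented in a block habituated to xY. Omission sequences
(`x_`) silence the 5th tone and isolate top-down prediction from
bottom-up input. Around the 5th-tone slot, ECoG shows an early gamma
power increase in auditory core (the 1st-level prediction error, PE1), a
late gamma increase in belt/parabelt and superior temporal channels (the
2nd-level prediction error, PE2), and a long-lasting beta (12–30 Hz)
decrease in frontal channels (the prediction update, PRED).

The package implements the complete analysis chain, plus a ground-truthed
synthetic generator so every statistical property can be verified by
injection/recovery:

1. **Paradigm** — exact trial/block/run generation for the ECoG (850 ms
   sequences) and fMRI (650 ms) protocol variants.
2. **Synthetic recordings** — 96-channel (configurable) 1/f background
   with condition-locked gamma bursts and beta suppressions, with
   configurable latencies, amplitudes, and within-/across-trial
   couplings, all recorded as ground truth.
3. **Preprocessing** — epoching, zero-phase band-pass (1–240 Hz, order
   5), resampling to 500 Hz, 50 Hz notch, robust channel/trial
   rejection, common-average reference, run exclusion.
4. **Multitaper TFR** — 10–140 Hz × (−0.3 … +0.8 s after the 5th tone),
   4-cycle windows with 0.5·f spectral smoothing (3 Slepian tapers at
   every frequency), relative-change baseline correction.
5. **Cluster statistics** — per channel, pointwise two-sample t maps
   thresholded at α = 0.05, 4-connected same-sign clusters scored by
   mass `m = Σt`, tested against a max-|m| permutation null
   (`p = (1 + #{null ≥ |m|}) / (n_perm + 1)`).
6. **Components** — significant clusters classified into PE1/PE2/PRED;
   each component's spatio-spectro-temporal pattern is a rank-1 PARAFAC
   model `X ≈ λ · a ⊗ b ⊗ c` (channel × frequency × time loadings,
   alternating least squares); the per-trial contribution is the
   least-squares projection `⟨X_trial, a⊗b⊗c⟩ / ‖a⊗b⊗c‖²`.
7. **Correlations** — Pearson correlations of contributions within
   trials and across deviant → post-deviant-standard pairs, with
   frontal/auditory electrode-set rules.

## Worked example

Simulate one xx-task run with the default PE1/PE2/PRED trio injected on
its `xY|xx` deviants, then run the full pipeline:

```r
library(hierseq)

cfg <- default_config()
cfg$tfr$fstep <- 5            # coarser grid for a quick look
cfg$stats$n_perm <- 200L
cfg$rules$pe_band_min_hz <- 25

layout <- electrode_layout(16L)
run <- build_run("xx", "xY|xx", paradigm_config("ecog"), seed = 6)
rec <- simulate_recording(run, layout, default_components("xY|xx"),
                          fs = 1000, seed = 6)
bundle <- run_full_analysis(list(rec), cfg)

cluster_tab <- bundle$cluster_tables$local_and_global
subset(cluster_tab, p < 0.05)
```

```
    channel sign   mass        p f_min f_max onset_ms peak_ms n_cells
20        1    1  524.9 0.004975    45   140       40      60      70
47        2    1  510.6 0.004975    45   140       40      80      67
114       3    1  726.8 0.004975    30   140      140     240     120
155       4    1  677.4 0.004975    30   140      200     240     111
196       5    1  648.5 0.004975    35   140      180     240     106
237       6    1  791.7 0.004975    30   140      180     240     118
268       7   -1 -248.9 0.004975    15    55      160     380      89
304       8   -1 -261.9 0.004975    10    45       60     260      97
379       9   -1 -242.9 0.004975    15    45      160     440      78
417      10   -1 -315.0 0.004975    15    50       80     280     104
...
```

Channels 1–2 (auditory core) carry the early gamma increase peaking
60–80 ms after the 5th tone (PE1, injected at 74 ms); channels 3–6
(belt/parabelt and STR) the late gamma increase peaking 240 ms (PE2,
injected at 242 ms); frontal channels 7–10 long negative beta clusters
(PRED, injected as a 400 ms suppression from 150 ms). The component
report and per-trial contributions:

```r
bundle$component_report$PE1[c("channels", "freq_window_hz",
                              "explained_variance")]
```

```
$channels
[1] 1 2

$freq_window_hz
[1]  45 140

$explained_variance
[1] 0.9767332
```

```r
g <- rec$ground_truth[rec$ground_truth$component == "PE1", ]
sel <- match(g$trial_index, bundle$tfr_pooled$trial_meta$trial_index)
cor(g$amplitude, bundle$contributions$PE1[sel])
#> [1] 0.86
```

The fitted pattern explains ~98% of the trial-averaged masked power, and
the per-trial contributions recover the injected burst amplitudes at
r ≈ 0.86 across the 15 deviant trials.

The numbered drivers under `analysis/` run the same machinery as a
narrative workflow: `01_simulate.R` (five sessions: xx task, xY task,
rare omissions in each task, expected-omission block), `02_run_pipeline.R`
(contrasts,
components, correlation panel → `results/bundle/`),
`03_latency_recovery.R` (injection/recovery of the three reported
latencies), `04_fwer_calibration.R` (null calibration of the cluster
test).

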