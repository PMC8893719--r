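---
title: "Methods: simulating and analysing hierarchical auditory sequence ECoG"
author: "hierseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing hierarchical auditory sequence ECoG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In the auditory local-global paradigm, five-tone sequences set up
regularities at two nested time scales. Locally (tone to tone, ~150 ms), a
fifth tone that differs from the first four (xxxxY, written `xY`) violates
the within-sequence expectation. Globally (sequence to sequence, ~3 s), a
habituated sequence type becomes the standard, so a rare alternative
sequence violates the between-sequence expectation even when it is locally
regular (an `xx` sequence in a block habituated to `xY`, written `xx|xY`).
Omission sequences (`x_`) silence the fifth tone, isolating top-down
prediction from bottom-up input. Under hierarchical predictive coding,
electrocorticography (ECoG) over auditory and frontal cortex shows three
signatures around the fifth-tone slot:

* **PE1** — an early gamma-band (>40 Hz) power increase in auditory core,
  peaking tens of milliseconds after a locally deviant tone: the tone-level
  prediction error.
* **PE2** — a later gamma increase in belt/parabelt and superior temporal
  channels (~240 ms) to sequence-level violations: the sequence-level
  prediction error.
* **PRED** — a long-lasting (>300 ms) beta-band (12-30 Hz) power decrease
  in frontal (and auditory) channels: the top-down prediction update.

`hierseq` reimplements the full analysis chain for this design — trial
sequence generation, preprocessing, multitaper time-frequency analysis,
cluster-based permutation statistics, rank-1 PARAFAC component patterns and
per-trial contributions, and within-/across-trial contribution
correlations — together with a ground-truthed synthetic ECoG generator, so
that every statistical property of the chain can be validated by
injection/recovery instead of relying on inaccessible raw recordings.

## Paradigm generation

`paradigm_config()` carries the two protocol presets: the ECoG protocol
(50 ms tones, 150 ms gaps, 850 ms sequences, 3 s onset asynchrony,
707/4000 Hz) and the fMRI protocol (100 ms gaps, 650 ms sequences, 3.5 s,
800/6000 Hz). A run is 20 habituation presentations of the task's standard
followed by three test blocks of 25 trials with 20% deviants.

The design constrains deviant placement — every deviant is followed by at
least one standard — but not the sampler. We draw deviant positions
uniformly among all placements with no two adjacent deviants and none in
the block-final slot, via the classical gap transform, which makes the
admissible sets exactly equiprobable. Deviants may occupy the first
test-block position immediately after habituation; nothing in the design
forbids it. Habituation trials are labeled and excluded from all
statistics. Run time starts at zero with the first habituation sequence;
the fMRI protocol's leading rest is carried as metadata only.

## The synthetic recording generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's claims are verified.

* **Background**: independent per-channel 1/f (pink, exponent 1) Gaussian
  noise built by spectral shaping in the Fourier domain, unit standard
  deviation per channel, with an optional 50 Hz mains sinusoid. The default
  96-channel layout partitions electrodes into 12 auditory core, 16
  belt/parabelt, 8 STR, 24 frontal, and 36 other channels; smaller arrays
  scale these proportions.
* **Bursts** (PE1, PE2, omission gamma): band-limited Gaussian noise under
  a Gaussian envelope (duration = +-2 SD), added to the target-ROI
  channels. A noise carrier rather than a pure sinusoid avoids
  time-frequency ringing that would bias latency estimates. The carrier is
  re-normalized under the envelope so each burst's injected energy tracks
  its realized amplitude exactly; without this, the few effective degrees
  of freedom of a 60 ms band-limited carrier would randomize the injected
  energy by tens of percent and the recorded ground truth would not
  describe what entered the signal.
* **Suppression** (PRED): the ongoing beta-band content is multiplied by a
  sub-unity plateau envelope (multiplicative, so power stays nonnegative —
  the natural reading of a power decrease relative to baseline). Depth is
  clipped to [0, 0.95]. Because the suppression acts on stochastic
  background content, its realized effect retains sampling variance that no
  normalization can remove; per-trial recovery of suppression depth is
  accordingly weaker than burst-amplitude recovery (r ~ 0.6-0.7 versus
  >= 0.8 under default settings).
* **Default injection values**: PE1 60-90 Hz, peak 74 ms after the
  fifth-tone slot, 60 ms envelope; PE2 40-80 Hz, peak 242 ms, 100 ms
  envelope; PRED 12-30 Hz, onset 150 ms, 400 ms plateau, depth 0.6. Burst
  amplitude 1 (equal to the background SD) with across-trial SD 0.25;
  depth SD 0.1. Latency jitter defaults to zero so recovery studies have a
  sharp target; both the envelope center and the envelope start are
  recorded, so either peak- or onset-latency can be the recovery target.
* **Couplings**: within a deviant trial, the realized PE1 amplitude
  deviation feeds PE2 through a dimensionless gain; across trials, the
  realized PRED depth on a deviant feeds the PE amplitudes on the
  immediately following standard of the same block (the pairing the
  correlation analysis uses). When an across-trial gain is nonzero, PE
  bursts are also injected on those post-deviant standards — otherwise
  standards stay clean so that deviant-vs-standard contrasts are pure.

What the generator does **not** emulate: evoked-potential waveforms,
volume conduction and inter-channel correlation, non-stationary background
(drowsiness, movement), or realistic artifact morphologies. Passing
recovery tests therefore validates the statistical machinery, not its
robustness to every pathology of real recordings.

## Preprocessing

The chain is epoch (-1 to 2 s around each first tone) -> zero-phase
order-5 Butterworth band-pass 1-240 Hz -> polyphase resampling to 500 Hz
-> narrow 50 Hz notch -> channel rejection -> trial rejection ->
common-average reference, linear detrend, demean -> run exclusion when
fewer than five deviant trials survive (applied to deviant-bearing runs;
a dedicated expected-omission control block has no deviants by design and
is not subject to the rule). Zero-phase (forward-backward)
filtering is used throughout so filter delay cannot bias latency
estimates.

The original workflow rejected artifact trials by eye; for reproducibility
both rejection steps are robust-z surrogates. A channel is removed when
its 70-240 Hz RMS exceeds the per-trial median + 5 MAD across channels on
more than 60% of trials. A trial is removed when its peak amplitude or
sub-2 Hz power exceeds the across-trial median + 15 MAD. The trial
threshold is deliberately conservative: the distribution of per-trial peak
amplitudes is tight, deviant trials legitimately carry injected bursts,
and with exactly five deviants per block a single false rejection discards
a whole run under the five-deviant exclusion rule. A 15 MAD threshold
still removes the gross step artifacts that visual inspection targets.
The common average is computed over retained channels only, after channel
rejection.

## Multitaper time-frequency analysis

The grid spans 10-140 Hz in 1 Hz steps and -0.3 s before the first tone to
0.8 s after the fifth-tone slot in 20 ms steps. At frequency f the window
is 4 cycles (4/f s) and the spectral half-bandwidth is 0.5 f; the
time-half-bandwidth product is then 2 at every frequency, which fixes
`floor(2*2) - 1 = 3` Slepian tapers throughout — the only reading under
which the two stated smoothing parameters are jointly coherent. Slepian
tapers are computed exactly from the classical symmetric tridiagonal
eigenproblem. Power is scaled as a one-sided spectral density so that
frequency-integrated power matches signal variance (checked to 10% on
band-limited probes). Grid cells whose window would leave the epoch are
set to missing and excluded from statistics, never zero-filled or
extrapolated.

Baseline correction is relative change against the mean over -0.3-0 s
before the first tone, per trial, channel, and frequency; per-trial
correction is required downstream, where single-trial TFRs are projected
onto component patterns. A dB mode is available.

Note one visible consequence of proportional-bandwidth smoothing: energy
at 70 Hz spreads roughly +-35 Hz, so significant gamma clusters routinely
extend below 40 Hz, and a pure tone's spectral argmax can sit a few hertz
off. Classification rules (below) expose their band floor for this reason.

## Cluster-based permutation statistics

Per channel, an independent-sample t statistic (pooled variance by
default; Welch available) is computed at every frequency-time cell between
deviant and standard trials. Cells with |t| above the two-sided critical
value at the 0.05 cluster-forming level are grouped into maximal
4-connected components of uniform sign; a cluster's mass is its summed t.
The null distribution is the maximum |mass| over clusters under label
shuffles (1000 by default; zero when a replicate forms no cluster), and
cluster p = (1 + #{null >= |mass|}) / (n_perm + 1), with a relative
tolerance on the comparison so that replicates that happen to redraw the
observed labeling count as ties rather than being lost to floating-point
rounding. Correction is over frequency and time within each channel, as
the design prescribes; no correction across channels is applied. A single
two-sided max-|mass| null serves both signs, since gamma increases and
beta decreases come from one procedure. Cluster onset and peak latencies
are the earliest cell time and the max-|t| cell time minus the fifth-tone
onset.

Under the global null the per-channel family-wise error is calibrated at
the nominal level (0.05 +- 0.02 over 500 simulated datasets), and
Monte-Carlo p values match exhaustive enumeration on 3-vs-3 toy data.

## Components and per-trial contributions

Significant clusters are classified by rule: PE1 — positive, gamma band,
peak before 150 ms after the fifth-tone slot; PE2 — positive, gamma band,
peak at or after 150 ms; PRED — negative, overlapping 12-30 Hz, lasting at
least 300 ms. The 150 ms boundary sits between the 74 ms and 242 ms
peaks; all rule parameters are configuration-exposed (in particular the
gamma floor, nominally 40 Hz, which smoothing argues for relaxing to
~25 Hz when classifying bounding boxes). Unmatched clusters are labeled
OTHER and retained in reports.

Each component's spatio-spectro-temporal pattern is a rank-1 PARAFAC model
(channel x frequency x time loadings) fitted by alternating least squares
with ten seeded random restarts on the trial-averaged baseline-corrected
power of the component's defining trial type, over the union bounding
windows of its clusters. Averaging before fitting is the literal reading
of projecting trial TFRs onto one fixed pattern; a trial-stacked 4-way
model is out of scope. Rank is fixed at 1 because a single contribution
value per trial is wanted. Loadings are unit-norm, with sign pushed so
frequency and time loadings sum nonnegative. The per-trial contribution is
the least-squares scalar fit of the pattern to that trial's masked TFR,
with missing cells excluded from both inner products; it is linear in the
trial TFR and recovers exact rank-1 scaling.

## Correlation panel

Within-trial correlations relate two components' contributions across
trials of one condition; across-trial correlations pair each deviant with
the immediately following same-block standard and relate PRED depth on the
deviant to PE contribution on the standard. Electrode-set rules mirror the
original pairing: frontal PRED against PE from all significant gamma
electrodes, auditory PRED against PE from auditory electrodes only;
restricted patterns are refitted on the restricted channel set. All p
values are two-sided Pearson tests at 0.05 with no multiplicity correction
across the panel (a Benjamini-Hochberg option exists but is off by
default, matching the original analysis); pairwise deletion handles
missing contributions and n is always reported.

## Numerical and design choices

* Every stochastic step draws from a named child seed derived from the
  caller's seed; no package code touches global RNG state.
* The permutation indicator matrix is shared across channels within one
  test (each replicate relabels whole trials), matching the exchangeability
  unit.
* ALS convergence: relative change of the pattern scale below 1e-8, at
  most 200 iterations, best of 10 restarts; non-convergence returns the
  best iterate flagged.
* Zero variance in both groups at a cell gives t = 0; an all-zero tensor
  under a mask is a hard error; an all-missing trial yields a missing
  contribution.
* Cluster labelling and the permutation null run in compiled code; the
  rest is vectorized R.
* Recovery-latency estimator: per channel the strongest significant
  positive gamma cluster defines that channel's latency, and the run-level
  estimate is the median across channels — the across-electrode
  aggregation used for group latencies, robust to the occasional
  false-positive channel that per-channel correction admits by design
  (~5% of channels under the null).

## Problem sizes used in the shipped studies

The validation studies in `analysis/` and `scripts/acceptance.R` run at
desk scale, chosen once: 16-channel arrays, one test block per simulated
run, a 2 Hz frequency step (5 Hz in the test suite), 200-500 permutations,
20 simulated runs per latency scenario, and 300-500 null datasets for
calibration. These sizes keep each study in the minutes range while
leaving the Monte-Carlo error well inside the +-20 ms latency and
0.05 +- 0.02 calibration tolerances the studies check.

## Known limitations

* Conjunction contrasts intersect significant channels (with matching
  cluster sign) in channel space — a transplant of imaging conjunction
  logic that the bundle flags; no joint statistic is computed.
* Suppression-depth recovery is bounded by the stochasticity of the
  background the suppression acts on (see above).
* The gamma-floor classification rule interacts with proportional
  smoothing; bounding-box-based classification is coarse by construction.
* The fMRI arm of the original design is mirrored only in paradigm timing
  and contrast logic; no imaging statistics are implemented.
* Correction across channels, TFCE, 4-way PARAFAC, and directed
  connectivity measures are out of scope.
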