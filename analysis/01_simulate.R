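#!/usr/bin/env Rscript

# Step 1 — simulate the study's recording sessions.
#
# Builds local-global runs for both task contexts plus a dedicated
# expected-omission block, injects the PE1/PE2/PRED component trio with
# within- and across-trial couplings switched on, and writes the
# ground-truthed recordings (signal containers under scratch/, event
# tables under results/).

suppressPackageStartupMessages(library(hierseq))

seed <- 20260925L
layout <- electrode_layout(16L)
cfg <- paradigm_config("ecog")
coup <- coupling_spec(pe1_to_pe2_gain = 1, pred_to_next_pe1_gain = 3,
                      pred_to_next_pe2_gain = 3)

sessions <- list(
  xx_task = list(task = "xx", deviant = "xY|xx"),
  xY_task = list(task = "xY", deviant = "xx|xY"),
  omission_xx = list(task = "xx", deviant = "x_|xx"),
  omission_xY = list(task = "xY", deviant = "x_|xY"),
  omission_block = list(task = "omission_block", deviant = NULL)
)

dir.create("scratch/recordings", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

for (nm in names(sessions)) {
  s <- sessions[[nm]]
  run <- build_run(s$task, s$deviant, cfg, seed = child_seed(seed, nm))
  comps <- switch(
    nm,
    xx_task = default_components("xY|xx"),
    xY_task = default_components("xx|xY"),
    omission_xY = list(OM = component_spec(
      "OM", band_hz = c(60, 90), latency_mean_s = 0.048,
      envelope_duration_s = 0.15, target_rois = "auditory_core",
      active_conditions = "x_|xY", latency_anchor = "start")),
    omission_xx = list(OM = component_spec(
      "OM", band_hz = c(40, 80), latency_mean_s = 0.151,
      envelope_duration_s = 0.13,
      target_rois = c("auditory_belt_parabelt", "STR"),
      active_conditions = "x_|xx", latency_anchor = "start")),
    omission_block = list())
  rec <- simulate_recording(run, layout, comps, coup, fs = 1000,
                            seed = child_seed(seed, paste0(nm, "_rec")))
  write_recording(rec, file.path("scratch/recordings", nm))
  write_events(rec$events, file.path("results",
                                     paste0("events_", nm, ".tsv")))
  message(sprintf(
    "%-14s %2d trials (%d deviant), %d channels, %d components injected",
    nm, nrow(trial_meta(run)), sum(trial_meta(run)$role == "deviant"),
    nrow(layout), nrow(rec$ground_truth)))
}
message("recordings in scratch/recordings/, event tables in results/")
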