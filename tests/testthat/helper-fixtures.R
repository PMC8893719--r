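# Shared fixtures, built once per test session and cached.

.fix <- new.env(parent = emptyenv())

# 8-channel layout with every ROI represented
test_layout <- function() {
  electrode_layout(8L, c(auditory_core = 2L, auditory_belt_parabelt = 2L,
                         STR = 1L, frontal = 2L, other = 1L))
}

# miniature paradigm: 1 block of 10 trials (2 deviants), 4 habituation
test_paradigm <- function(n_test_blocks = 1L) {
  paradigm_config("ecog", n_habituation = 4L, block_size = 10L,
                  deviant_fraction = 0.2,
                  n_test_blocks = as.integer(n_test_blocks))
}

# preprocessed small recording + coarse TFR, shared across test files
small_tfr <- function() {
  if (!is.null(.fix$small_tfr)) return(.fix$small_tfr)
  rec <- fixture_small()
  ts <- preprocess_run(rec, min_deviants = 2)
  grid <- tfr_grid(0.8, fstep = 5)
  .fix$small_tfr <- baseline_correct(tfr_multitaper(ts, grid))
  .fix$small_tfr
}

# raw (uncorrected) TFR of a deterministic 2-channel sinusoid trial set
make_trial_set <- function(data, fs, window_s, roles = NULL,
                           conditions = NULL) {
  d <- dim(data)
  structure(list(
    data = data, fs = fs, window_s = window_s,
    trial_meta = data.frame(
      trial_index = seq_len(d[1]), block = 1L,
      condition = conditions %||% rep("xY|xx", d[1]),
      role = roles %||% rep("deviant", d[1]),
      onset_s = 0),
    channel_meta = data.frame(name = sprintf("ch%02d", seq_len(d[2])),
                              roi = rep("other", d[2])),
    rejected_trials = data.frame(), rejected_channels = data.frame()),
    class = "trial_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# wrap an array (trials x ch x f x t) as a tfr_set for the stats layer
make_tfr_set <- function(pow, grid, roles = "deviant", rois = NULL) {
  d <- dim(pow)
  structure(list(
    power = pow, grid = grid, baseline_window_s = c(-0.3, 0),
    trial_meta = data.frame(trial_index = seq_len(d[1]), block = 1L,
                            condition = "xY|xx",
                            role = rep(roles, length.out = d[1]),
                            onset_s = 0),
    channel_meta = data.frame(name = sprintf("ch%02d", seq_len(d[2])),
                              roi = rois %||% rep("other", d[2]))),
    class = "tfr_set")
}
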