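#' @useDynLib hierseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif median mad sd var cor cor.test qt pt lm coef
#' @importFrom utils read.delim write.table
NULL

#' Condition labels of the local-global paradigm
#'
#' Sequence type before the bar, habituated task context after it:
#' `"xY|xx"` is a locally deviant xxxxY sequence presented in a block
#' habituated to xxxxx. `"x_"` sequences omit the 5th tone;
#' `"xxxx_expected"` is the frequent omission sequence of a dedicated
#' omission block, where the absent 5th tone is expected.
#'
#' @export
CONDITIONS <- c("xx|xx", "xY|xx", "xx|xY", "xY|xY",
                "x_|xx", "x_|xY", "xxxx_expected")

#' Paradigm timing configuration
#'
#' Timing and tone parameters of the local-global paradigm. The two
#' protocol presets reflect the two acquisition setups: the ECoG protocol
#' uses 50 ms tones separated by 150 ms silent gaps (850 ms sequences,
#' 3 s onset asynchrony, 707/4000 Hz tones); the fMRI protocol uses
#' 100 ms gaps (650 ms sequences, 3.5 s onset asynchrony, 800/6000 Hz).
#'
#' @param protocol `"ecog"` or `"fmri"`; selects the default timing set.
#' @param tone_duration_s tone duration in seconds.
#' @param inter_tone_interval_s silent gap between tone offset and the
#'   next tone onset, seconds.
#' @param inter_sequence_onset_s onset-to-onset interval between
#'   successive sequences, seconds.
#' @param freq_x_hz,freq_y_hz frequencies of the standard (x) and
#'   deviant (Y) tones, Hz.
#' @param n_habituation number of habituation sequences preceding the
#'   test blocks.
#' @param block_size trials per test block.
#' @param deviant_fraction fraction of deviant trials per test block;
#'   `block_size * deviant_fraction` must be an integer.
#' @param n_test_blocks number of test blocks per run.
#' @param leading_rest_s optional initial rest period (metadata only;
#'   trial onsets start at t = 0 regardless).
#' @return A list of class `paradigm_config`.
#' @export
paradigm_config <- function(protocol = c("ecog", "fmri"),
                            tone_duration_s = NULL,
                            inter_tone_interval_s = NULL,
                            inter_sequence_onset_s = NULL,
                            freq_x_hz = NULL, freq_y_hz = NULL,
                            n_habituation = 20L,
                            block_size = 25L,
                            deviant_fraction = 0.2,
                            n_test_blocks = 3L,
                            leading_rest_s = 0) {
  protocol <- match.arg(protocol)
  defaults <- if (protocol == "ecog") {
    list(tone = 0.050, iti = 0.150, isi = 3.0, fx = 707, fy = 4000)
  } else {
    list(tone = 0.050, iti = 0.100, isi = 3.5, fx = 800, fy = 6000)
  }
  cfg <- list(
    protocol = protocol,
    tone_duration_s = tone_duration_s %||% defaults$tone,
    inter_tone_interval_s = inter_tone_interval_s %||% defaults$iti,
    inter_sequence_onset_s = inter_sequence_onset_s %||% defaults$isi,
    freq_x_hz = freq_x_hz %||% defaults$fx,
    freq_y_hz = freq_y_hz %||% defaults$fy,
    n_habituation = as.integer(n_habituation),
    block_size = as.integer(block_size),
    deviant_fraction = deviant_fraction,
    n_test_blocks = as.integer(n_test_blocks),
    leading_rest_s = leading_rest_s
  )
  stopifnot(cfg$tone_duration_s > 0, cfg$inter_tone_interval_s >= 0,
            cfg$deviant_fraction > 0, cfg$deviant_fraction < 1,
            cfg$block_size >= 2, cfg$n_test_blocks >= 1)
  n_dev <- cfg$block_size * cfg$deviant_fraction
  if (abs(n_dev - round(n_dev)) > 1e-9) {
    stop("block_size * deviant_fraction must be an integer (got ",
         n_dev, ")")
  }
  class(cfg) <- "paradigm_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Onset of the 5th-tone slot relative to the 1st-tone onset
#'
#' Position-k tones start at (k-1) * (tone_duration + inter_tone_interval);
#' the slot exists (and anchors omission latencies) even when the 5th tone
#' is omitted.
#'
#' @param config a [paradigm_config()].
#' @return Seconds.
#' @export
fifth_tone_onset <- function(config) {
  4 * (config$tone_duration_s + config$inter_tone_interval_s)
}

#' Build the five-tone event list for one sequence
#'
#' Positions 1-4 carry the x tone; position 5 carries the x tone (`xx`
#' sequences), the Y tone (`xY` sequences), or is omitted (`x_` and
#' `xxxx_expected` sequences). An omitted tone is retained as an event
#' with `frequency_hz = 0` (zero amplitude) so that downstream timing is
#' anchored at the expected 5th-tone slot.
#'
#' @param condition one of [CONDITIONS].
#' @param config a [paradigm_config()].
#' @return A `trial_spec`: list with `condition`, `role` (unset, `NA`),
#'   `tones` (data.frame: onset_s, duration_s, frequency_hz, position),
#'   `sequence_onset_s` and `duration_s` (the closed-form sequence
#'   duration `5*tone + 4*gap`).
#' @export
build_sequence <- function(condition, config) {
  if (!condition %in% CONDITIONS) {
    stop("unknown condition '", condition, "'; valid conditions are: ",
         paste(CONDITIONS, collapse = ", "))
  }
  local_type <- if (condition == "xxxx_expected") "x_" else
    strsplit(condition, "|", fixed = TRUE)[[1]][1]
  step <- config$tone_duration_s + config$inter_tone_interval_s
  onsets <- (0:4) * step
  freq5 <- switch(local_type,
                  "xx" = config$freq_x_hz,
                  "xY" = config$freq_y_hz,
                  "x_" = 0)
  tones <- data.frame(
    onset_s = onsets,
    duration_s = rep(config$tone_duration_s, 5),
    frequency_hz = c(rep(config$freq_x_hz, 4), freq5),
    position = 1:5
  )
  structure(
    list(condition = condition, role = NA_character_, tones = tones,
         sequence_onset_s = 0,
         duration_s = 5 * config$tone_duration_s +
           4 * config$inter_tone_interval_s),
    class = "trial_spec")
}

standard_condition <- function(task) {
  switch(task, xx = "xx|xx", xY = "xY|xY", omission_block = "xxxx_expected",
         stop("unknown task '", task, "'"))
}

valid_deviants <- function(task) {
  switch(task, xx = c("xY|xx", "x_|xx"), xY = c("xx|xY", "x_|xY"),
         omission_block = character(0))
}

# Uniform sample of n_dev deviant slots among 1..(block_size-1) with no two
# adjacent (so every deviant is followed by >= 1 standard, and none falls in
# the block-final position). Classical gap transform: sorted draws q from
# 1..(block_size-1-(n_dev-1)) map to p_i = q_i + (i-1).
sample_deviant_positions <- function(block_size, n_dev) {
  m <- (block_size - 1L) - (n_dev - 1L)
  if (m < n_dev) stop("cannot place ", n_dev,
                      " non-adjacent deviants in a block of ", block_size)
  q <- sort(sample.int(m, n_dev))
  q + seq_len(n_dev) - 1L
}

#' Build a full recording run of the local-global paradigm
#'
#' A run is `n_habituation` habituation presentations of the task's
#' standard sequence followed by `n_test_blocks` test blocks of
#' `block_size` trials, each holding `block_size * deviant_fraction`
#' deviants placed uniformly at random among positions satisfying the
#' constraint that every deviant is immediately followed by at least one
#' standard (hence never block-final). Omission-block runs contain only
#' the expected-omission sequence. Identical arguments yield identical
#' runs.
#'
#' @param task `"xx"`, `"xY"` or `"omission_block"`.
#' @param deviant_type the deviant condition, consistent with `task`
#'   (ignored for omission blocks).
#' @param config a [paradigm_config()].
#' @param seed integer seed controlling deviant placement.
#' @return A `run_spec`: list with `task`, `deviant_type`, `habituation`
#'   and `blocks` (lists of `trial_spec`), `config`, `seed`.
#' @export
build_run <- function(task, deviant_type = NULL, config = paradigm_config(),
                      seed = 1L) {
  std <- standard_condition(task)
  if (task == "omission_block") {
    deviant_type <- NA_character_
  } else {
    if (is.null(deviant_type) || !deviant_type %in% valid_deviants(task)) {
      stop("deviant_type must be one of ",
           paste(valid_deviants(task), collapse = ", "), " for task ", task)
    }
  }
  n_dev <- as.integer(round(config$block_size * config$deviant_fraction))
  isi <- config$inter_sequence_onset_s
  idx <- 0L
  make_trial <- function(condition, role) {
    tr <- build_sequence(condition, config)
    tr$role <- role
    tr$sequence_onset_s <- idx * isi
    idx <<- idx + 1L
    tr
  }
  habituation <- replicate(config$n_habituation,
                           make_trial(std, "habituation"), simplify = FALSE)
  blocks <- with_seed(child_seed(seed, "deviant_placement"), {
    lapply(seq_len(config$n_test_blocks), function(b) {
      roles <- rep("standard", config$block_size)
      if (task != "omission_block" && n_dev > 0) {
        roles[sample_deviant_positions(config$block_size, n_dev)] <- "deviant"
      }
      lapply(roles, function(r) {
        make_trial(if (r == "deviant") deviant_type else std, r)
      })
    })
  })
  structure(list(task = task, deviant_type = deviant_type,
                 habituation = habituation, blocks = blocks,
                 config = config, seed = as.integer(seed)),
            class = "run_spec")
}

run_trials <- function(run) {
  c(run$habituation, do.call(c, run$blocks))
}

#' Per-trial metadata of a run
#'
#' @param run a `run_spec` from [build_run()].
#' @return data.frame: trial_index, block (0 = habituation), condition,
#'   role, onset_s.
#' @export
trial_meta <- function(run) {
  trials <- run_trials(run)
  blocks <- c(rep(0L, length(run$habituation)),
              rep(seq_along(run$blocks),
                  vapply(run$blocks, length, integer(1))))
  data.frame(
    trial_index = seq_along(trials),
    block = blocks,
    condition = vapply(trials, function(t) t$condition, character(1)),
    role = vapply(trials, function(t) t$role, character(1)),
    onset_s = vapply(trials, function(t) t$sequence_onset_s, numeric(1))
  )
}

#' Flatten a run into a tone-event table
#'
#' One row per tone event (five per trial; omitted tones are retained
#' with `frequency = 0`). Onsets are in run time.
#'
#' @param run a `run_spec` from [build_run()].
#' @return data.frame with columns onset, duration, frequency, position,
#'   condition, role, block, trial_index.
#' @export
events_table <- function(run) {
  meta <- trial_meta(run)
  trials <- run_trials(run)
  do.call(rbind, lapply(seq_along(trials), function(i) {
    tn <- trials[[i]]$tones
    data.frame(
      onset = meta$onset_s[i] + tn$onset_s,
      duration = tn$duration_s,
      frequency = tn$frequency_hz,
      position = tn$position,
      condition = meta$condition[i],
      role = meta$role[i],
      block = meta$block[i],
      trial_index = meta$trial_index[i]
    )
  }))
}

EVENT_COLUMNS <- c("onset", "duration", "frequency", "position",
                   "condition", "role", "block", "trial_index")

#' Write / read an event table as tab-separated values
#'
#' @param events data.frame from [events_table()].
#' @param path file path.
#' @return `read_events` returns the event table; a missing required
#'   column raises an error naming it.
#' @export
write_events <- function(events, path) {
  stopifnot(all(EVENT_COLUMNS %in% names(events)))
  write.table(events[, EVENT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(EVENT_COLUMNS, names(ev))
  if (length(missing)) {
    stop("event table is missing column(s): ", paste(missing, collapse = ", "))
  }
  ev
}
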