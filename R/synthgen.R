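#' Electrode layout with region-of-interest labels
#'
#' The default 96-channel layout partitions channels into the ROI groups
#' used by the analysis: 12 auditory core, 16 auditory belt/parabelt,
#' 8 superior temporal rostral (STR), 24 frontal, 36 other. Other channel
#' counts scale these proportions (largest-remainder rounding).
#'
#' @param n_channels number of channels (>= 2).
#' @param roi_counts optional named integer vector over
#'   `c("auditory_core","auditory_belt_parabelt","STR","frontal","other")`
#'   summing to `n_channels`; overrides the scaled default.
#' @return data.frame with columns `name`, `roi`.
#' @export
electrode_layout <- function(n_channels = 96L, roi_counts = NULL) {
  stopifnot(n_channels >= 2)
  rois <- c(auditory_core = 12, auditory_belt_parabelt = 16, STR = 8,
            frontal = 24, other = 36)
  if (is.null(roi_counts)) {
    exact <- rois / sum(rois) * n_channels
    counts <- floor(exact)
    rem <- n_channels - sum(counts)
    if (rem > 0) {
      top <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
      counts[top] <- counts[top] + 1
    }
    roi_counts <- counts
  }
  stopifnot(sum(roi_counts) == n_channels,
            all(names(roi_counts) %in% names(rois)))
  roi <- rep(names(roi_counts), roi_counts)
  data.frame(name = sprintf("ch%03d", seq_len(n_channels)), roi = roi)
}

#' Specification of one condition-locked oscillatory component
#'
#' Describes a band-limited power modulation locked to the 5th-tone slot:
#' `increase` components are injected as band-limited noise bursts under a
#' Gaussian envelope; `decrease` components multiplicatively suppress the
#' ongoing band-limited background under a long plateau envelope (power
#' stays nonnegative). The canonical trio is an early gamma burst (PE1,
#' the tone-level prediction error), a late gamma burst (PE2, the
#' sequence-level prediction error), and a long-lasting beta suppression
#' (PRED, the top-down prediction update).
#'
#' @param name component name (`"PE1"`, `"PE2"`, `"PRED"`, or custom).
#' @param band_hz numeric length-2 frequency band, Hz.
#' @param latency_mean_s mean latency after the 5th-tone slot onset,
#'   seconds. Interpreted at the envelope `latency_anchor`.
#' @param latency_sd_s across-trial latency jitter SD, seconds.
#' @param envelope_duration_s effective envelope duration: for bursts the
#'   full width (+- 2 SD) of the Gaussian envelope; for suppressions the
#'   plateau length.
#' @param amplitude_mean,amplitude_sd across-trial amplitude mean / SD.
#'   For suppressions the amplitude is the suppression depth (fraction of
#'   band-limited amplitude removed; clipped to `[0, 0.95]`).
#' @param sign `"increase"` or `"decrease"`.
#' @param target_rois ROI labels receiving the component.
#' @param active_conditions conditions on which the component is injected.
#' @param latency_anchor `"center"` (envelope center at the latency, the
#'   peak-latency reading) or `"start"` (envelope start at the latency,
#'   the onset-latency reading).
#' @return list of class `component_spec`.
#' @export
component_spec <- function(name, band_hz, latency_mean_s,
                           latency_sd_s = 0,
                           envelope_duration_s = 0.06,
                           amplitude_mean = 1, amplitude_sd = 0.25,
                           sign = c("increase", "decrease"),
                           target_rois = "auditory_core",
                           active_conditions = "xY|xx",
                           latency_anchor = c("center", "start")) {
  sign <- match.arg(sign)
  latency_anchor <- match.arg(latency_anchor)
  stopifnot(length(band_hz) == 2, band_hz[1] > 0, band_hz[2] > band_hz[1],
            envelope_duration_s > 0, latency_sd_s >= 0)
  structure(list(name = name, band_hz = band_hz,
                 latency_mean_s = latency_mean_s,
                 latency_sd_s = latency_sd_s,
                 envelope_duration_s = envelope_duration_s,
                 amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, sign = sign,
                 target_rois = target_rois,
                 active_conditions = active_conditions,
                 latency_anchor = latency_anchor),
            class = "component_spec")
}

#' Default component trio for a local-deviant (xY|xx) run
#'
#' PE1: 60-90 Hz burst peaking 74 ms after the 5th tone in auditory core;
#' PE2: 40-80 Hz burst peaking 242 ms after the 5th tone in belt/parabelt
#' and STR; PRED: 12-30 Hz suppression starting 150 ms after the 5th tone
#' and lasting 400 ms in frontal (and auditory core) channels.
#'
#' @param active_conditions conditions carrying the components.
#' @return named list of [component_spec()]s.
#' @export
default_components <- function(active_conditions = "xY|xx") {
  list(
    PE1 = component_spec("PE1", band_hz = c(60, 90), latency_mean_s = 0.074,
                         latency_sd_s = 0, envelope_duration_s = 0.06,
                         amplitude_mean = 1, amplitude_sd = 0.25,
                         sign = "increase", target_rois = "auditory_core",
                         active_conditions = active_conditions),
    PE2 = component_spec("PE2", band_hz = c(40, 80), latency_mean_s = 0.242,
                         latency_sd_s = 0, envelope_duration_s = 0.10,
                         amplitude_mean = 1, amplitude_sd = 0.25,
                         sign = "increase",
                         target_rois = c("auditory_belt_parabelt", "STR"),
                         active_conditions = active_conditions),
    PRED = component_spec("PRED", band_hz = c(12, 30), latency_mean_s = 0.15,
                          latency_sd_s = 0, envelope_duration_s = 0.40,
                          amplitude_mean = 0.6, amplitude_sd = 0.1,
                          sign = "decrease",
                          target_rois = c("frontal", "auditory_core"),
                          active_conditions = active_conditions,
                          latency_anchor = "start")
  )
}

#' Across-trial and within-trial amplitude coupling specification
#'
#' Within a deviant trial the realized PE1 amplitude deviation feeds the
#' PE2 amplitude through `pe1_to_pe2_gain`; across trials the realized
#' PRED depth on a deviant feeds the PE1/PE2 amplitudes on the
#' immediately following standard trial of the same block through the
#' `pred_to_next_*` gains. With all gains zero, amplitudes are
#' independent and standards receive no PE injection.
#'
#' @param pe1_to_pe2_gain,pred_to_next_pe1_gain,pred_to_next_pe2_gain
#'   dimensionless gains applied to the source component's amplitude
#'   deviation from its mean.
#' @param noise_sd extra independent amplitude noise added wherever a
#'   nonzero gain applies.
#' @return list of class `coupling_spec`.
#' @export
coupling_spec <- function(pe1_to_pe2_gain = 0, pred_to_next_pe1_gain = 0,
                          pred_to_next_pe2_gain = 0, noise_sd = 0) {
  stopifnot(is.finite(pe1_to_pe2_gain), is.finite(pred_to_next_pe1_gain),
            is.finite(pred_to_next_pe2_gain), noise_sd >= 0)
  structure(list(pe1_to_pe2_gain = pe1_to_pe2_gain,
                 pred_to_next_pe1_gain = pred_to_next_pe1_gain,
                 pred_to_next_pe2_gain = pred_to_next_pe2_gain,
                 noise_sd = noise_sd),
            class = "coupling_spec")
}

#' Simulate multichannel 1/f background activity
#'
#' Spectrally shaped Gaussian noise (power spectral density proportional
#' to 1/f^exponent), independently per channel, plus an optional mains
#' sinusoid.
#'
#' @param layout an [electrode_layout()].
#' @param duration_s recording duration, seconds (> 0).
#' @param fs sampling rate, Hz.
#' @param exponent spectral exponent (0 = white, 1 = pink).
#' @param noise_sd per-channel signal standard deviation.
#' @param line_hz mains frequency, Hz.
#' @param line_amplitude mains sinusoid amplitude (0 disables it).
#' @param seed integer seed.
#' @return channels x samples numeric matrix.
#' @export
simulate_background <- function(layout, duration_s, fs, exponent = 1,
                                noise_sd = 1, line_hz = 50,
                                line_amplitude = 0, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  n <- round(duration_s * fs)
  nch <- nrow(layout)
  freqs <- c(0, seq_len(n - 1)) / n * fs
  freqs <- pmin(freqs, fs - freqs)  # two-sided |f|
  scale <- rep(0, n)
  nz <- freqs > 0
  scale[nz] <- freqs[nz]^(-exponent / 2)
  sig <- with_seed(child_seed(seed, "background"), {
    t(vapply(seq_len(nch), function(ch) {
      x <- fft(stats::rnorm(n)) * scale
      Re(fft(x, inverse = TRUE)) / n
    }, numeric(n)))
  })
  sig <- sig / apply(sig, 1, stats::sd) * noise_sd
  if (line_amplitude > 0) {
    line <- line_amplitude * sin(2 * pi * line_hz * (seq_len(n) - 1) / fs)
    sig <- sweep(sig, 2, line, "+")
  }
  sig
}

band_limited_noise <- function(n, band_hz, fs, seed_state_free = TRUE) {
  # FFT-masked white noise; exact band limitation, no filter transients.
  pad <- max(n, round(fs))  # >= 1 s for fine frequency resolution
  white <- stats::rnorm(pad)
  f <- (seq_len(pad) - 1) / pad * fs
  f <- pmin(f, fs - f)
  mask <- f >= band_hz[1] & f <= band_hz[2]
  x <- Re(fft(fft(white) * mask, inverse = TRUE)) / pad
  x <- x[seq_len(n)]
  x / sqrt(mean(x^2))
}

bandpass_segment <- function(x, band_hz, fs) {
  # zero-phase band-pass of a short segment via FFT masking
  n <- length(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  mask <- f >= band_hz[1] & f <= band_hz[2]
  Re(fft(fft(x) * mask, inverse = TRUE)) / n
}

#' Inject condition-locked components into a background signal
#'
#' Realizes each active component on each eligible trial: bursts
#' (`increase`) add band-limited noise under a Gaussian envelope centered
#' at the realized latency; suppressions (`decrease`) multiply the
#' ongoing component-band content by a sub-unity plateau envelope.
#' Realized amplitude = `amplitude_mean` + coupling contributions +
#' Gaussian noise (`amplitude_sd`). When a `pred_to_next_*` gain is
#' nonzero, PE components are additionally injected on the standard trial
#' immediately following each PRED-carrying deviant, with their amplitude
#' coupled to the deviant's realized PRED depth.
#'
#' @param background channels x samples matrix from
#'   [simulate_background()].
#' @param run a `run_spec`.
#' @param layout the [electrode_layout()] matching `background`.
#' @param components list of [component_spec()]s.
#' @param coupling a [coupling_spec()].
#' @param fs sampling rate of `background`, Hz.
#' @param t_start_s run time of the first sample (negative values leave
#'   room for pre-stimulus epoch windows).
#' @param seed integer seed.
#' @return A `synthetic_recording`: list with `signal`, `fs`,
#'   `t_start_s`, `events`, `layout`, `ground_truth` (one row per
#'   realized trial x component: trial_index, condition, component,
#'   amplitude, center_s, start_s — latencies in seconds after that
#'   trial's 5th-tone slot onset).
#' @export
inject_components <- function(background, run, layout,
                              components = default_components(),
                              coupling = coupling_spec(), fs = 1000,
                              t_start_s = -2, seed = 1L) {
  nyq <- fs / 2
  for (cmp in components) {
    if (cmp$band_hz[2] >= nyq) {
      stop("component band [", cmp$band_hz[1], ",", cmp$band_hz[2],
           "] exceeds the Nyquist frequency ", nyq, " Hz")
    }
  }
  meta <- trial_meta(run)
  ft <- fifth_tone_onset(run$config)
  sig <- background
  n <- ncol(sig)
  gt <- list()
  with_seed(child_seed(seed, "inject"), {
    # pass 1: realized amplitudes/latencies trial by trial (coupling needs
    # the previous trial's PRED realization)
    realized <- list()
    prev_pred <- NULL  # PRED realization on the previous trial, if deviant
    for (i in seq_len(nrow(meta))) {
      cond <- meta$condition[i]
      this_pred <- NULL
      post_deviant <- !is.null(prev_pred) && meta$role[i] == "standard" &&
        meta$block[i] == prev_pred$block
      for (cmp in components) {
        active <- cond %in% cmp$active_conditions
        coupled_in <- post_deviant && cmp$name %in% c("PE1", "PE2") &&
          ((cmp$name == "PE1" && coupling$pred_to_next_pe1_gain != 0) ||
           (cmp$name == "PE2" && coupling$pred_to_next_pe2_gain != 0))
        if (!active && !coupled_in) next
        amp <- cmp$amplitude_mean + stats::rnorm(1, 0, cmp$amplitude_sd)
        if (coupled_in) {
          gain <- if (cmp$name == "PE1") coupling$pred_to_next_pe1_gain
                  else coupling$pred_to_next_pe2_gain
          amp <- amp + gain * (prev_pred$amplitude - prev_pred$mean) +
            stats::rnorm(1, 0, coupling$noise_sd)
        }
        if (active && cmp$name == "PE2" && coupling$pe1_to_pe2_gain != 0) {
          pe1 <- Filter(function(r) r$component == "PE1",
                        realized[[as.character(i)]] %||% list())
          if (length(pe1)) {
            amp <- amp + coupling$pe1_to_pe2_gain *
              (pe1[[1]]$amplitude - pe1[[1]]$mean) +
              stats::rnorm(1, 0, coupling$noise_sd)
          }
        }
        lat <- cmp$latency_mean_s + stats::rnorm(1, 0, cmp$latency_sd_s)
        center <- if (cmp$latency_anchor == "center") lat else
          lat + cmp$envelope_duration_s / 2
        start <- center - cmp$envelope_duration_s / 2
        rec <- list(trial = i, condition = cond, component = cmp$name,
                    amplitude = amp, mean = cmp$amplitude_mean,
                    center = center, start = start, spec = cmp)
        key <- as.character(i)
        realized[[key]] <- c(realized[[key]] %||% list(), list(rec))
        if (cmp$name == "PRED" && active && meta$role[i] == "deviant") {
          this_pred <- list(amplitude = amp, mean = cmp$amplitude_mean,
                            block = meta$block[i])
        }
      }
      prev_pred <- this_pred
    }
    # pass 2: write components into the signal
    ch_idx <- function(rois) which(layout$roi %in% rois)
    for (key in names(realized)) for (r in realized[[key]]) {
      i <- r$trial
      cmp <- r$spec
      chans <- ch_idx(cmp$target_rois)
      if (!length(chans)) next
      t5 <- meta$onset_s[i] + ft
      if (cmp$sign == "increase") {
        sigma <- cmp$envelope_duration_s / 4
        half <- round(3 * sigma * fs)
        c0 <- round((t5 + r$center - t_start_s) * fs) + 1
        idx <- (c0 - half):(c0 + half)
        keep <- idx >= 1 & idx <= n
        idx <- idx[keep]
        if (!length(idx)) next
        tt <- (idx - c0) / fs
        env <- exp(-tt^2 / (2 * sigma^2))
        for (ch in chans) {
          carrier <- band_limited_noise(length(idx), cmp$band_hz, fs)
          # normalize under the envelope so the injected energy tracks the
          # realized amplitude exactly (the carrier draw itself would
          # otherwise randomize each burst's energy)
          carrier <- carrier /
            sqrt(sum(env^2 * carrier^2) / sum(env^2))
          sig[ch, idx] <- sig[ch, idx] + r$amplitude * env * carrier
        }
      } else {
        depth <- min(max(r$amplitude, 0), 0.95)
        pad <- round(0.25 * fs)
        s0 <- round((t5 + r$start - t_start_s) * fs) + 1
        s1 <- s0 + round(cmp$envelope_duration_s * fs)
        idx <- max(1, s0 - pad):min(n, s1 + pad)
        if (length(idx) < 8) next
        tt <- (idx - 1) / fs + t_start_s  # run time of samples
        t_on <- t5 + r$start
        t_off <- t_on + cmp$envelope_duration_s
        ramp <- 0.05
        env <- pmin(1, pmax(0, (tt - t_on) / ramp)) *
          pmin(1, pmax(0, (t_off - tt) / ramp))
        for (ch in chans) {
          band <- bandpass_segment(sig[ch, idx], cmp$band_hz, fs)
          sig[ch, idx] <- sig[ch, idx] - depth * env * band
        }
      }
      gt[[length(gt) + 1]] <- data.frame(
        trial_index = i, condition = r$condition, component = r$component,
        amplitude = r$amplitude, center_s = r$center, start_s = r$start)
    }
  })
  ground_truth <- if (length(gt)) do.call(rbind, gt) else
    data.frame(trial_index = integer(0), condition = character(0),
               component = character(0), amplitude = numeric(0),
               center_s = numeric(0), start_s = numeric(0))
  ground_truth <- ground_truth[order(ground_truth$trial_index), ]
  rownames(ground_truth) <- NULL
  structure(list(signal = sig, fs = fs, t_start_s = t_start_s,
                 events = events_table(run), layout = layout,
                 ground_truth = ground_truth, run = run, seed = seed),
            class = "synthetic_recording")
}

#' Simulate a complete ground-truthed recording of one run
#'
#' Convenience wrapper: builds the 1/f background long enough to cover
#' the run (plus padding for epoch windows) and injects the configured
#' components.
#'
#' @inheritParams inject_components
#' @param exponent,noise_sd,line_hz,line_amplitude background parameters,
#'   see [simulate_background()].
#' @param pad_s padding before the first and after the last sequence
#'   onset, seconds.
#' @return A `synthetic_recording`.
#' @export
simulate_recording <- function(run, layout = electrode_layout(),
                               components = default_components(),
                               coupling = coupling_spec(), fs = 1000,
                               exponent = 1, noise_sd = 1, line_hz = 50,
                               line_amplitude = 0, pad_s = 2, seed = 1L) {
  meta <- trial_meta(run)
  duration <- max(meta$onset_s) + run$config$inter_sequence_onset_s + 2 * pad_s
  bg <- simulate_background(layout, duration, fs, exponent = exponent,
                            noise_sd = noise_sd, line_hz = line_hz,
                            line_amplitude = line_amplitude,
                            seed = child_seed(seed, "bg"))
  inject_components(bg, run, layout, components, coupling, fs = fs,
                    t_start_s = -pad_s, seed = child_seed(seed, "inj"))
}
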