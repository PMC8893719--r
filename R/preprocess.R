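#' Epoch a recording around sequence onsets
#'
#' Extracts one fixed-length window per sequence onset (closed-open
#' `[start, end)` in samples). Trials whose window falls outside the
#' recording are dropped with a reason code and a warning.
#'
#' @param rec a `synthetic_recording` (or any list with `signal`, `fs`,
#'   `t_start_s`, `events`, `layout`).
#' @param window_s epoch window relative to the 1st-tone onset, seconds.
#' @return A `trial_set`: list with `data` (trials x channels x samples
#'   array), `fs`, `window_s`, `trial_meta`, `channel_meta`,
#'   `rejected_trials`, `rejected_channels`.
#' @export
epoch <- function(rec, window_s = c(-1, 2)) {
  stopifnot(window_s[2] > window_s[1])
  ev1 <- rec$events[rec$events$position == 1, ]
  nsamp <- round((window_s[2] - window_s[1]) * rec$fs)
  ntotal <- ncol(rec$signal)
  start_idx <- round((ev1$onset + window_s[1] - rec$t_start_s) * rec$fs) + 1
  ok <- start_idx >= 1 & (start_idx + nsamp - 1) <= ntotal
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) dropped: epoch window outside recording")
  }
  kept <- which(ok)
  data <- array(NA_real_, c(length(kept), nrow(rec$signal), nsamp))
  for (i in seq_along(kept)) {
    idx <- start_idx[kept[i]] + 0:(nsamp - 1)
    data[i, , ] <- rec$signal[, idx]
  }
  meta <- data.frame(trial_index = ev1$trial_index[kept],
                     block = ev1$block[kept],
                     condition = ev1$condition[kept],
                     role = ev1$role[kept],
                     onset_s = ev1$onset[kept])
  rejected <- if (any(!ok)) {
    data.frame(trial_index = ev1$trial_index[!ok],
               reason = "epoch_out_of_bounds", statistic = NA_real_)
  } else empty_rejection("trial_index")
  structure(list(data = data, fs = rec$fs, window_s = window_s,
                 trial_meta = meta, channel_meta = rec$layout,
                 rejected_trials = rejected,
                 rejected_channels = empty_rejection("channel")),
            class = "trial_set")
}

empty_rejection <- function(id) {
  df <- data.frame(x = integer(0), reason = character(0),
                   statistic = numeric(0))
  names(df)[1] <- id
  df
}

filt_epochs <- function(data, flt) {
  out <- data
  for (tr in seq_len(dim(data)[1])) for (ch in seq_len(dim(data)[2])) {
    out[tr, ch, ] <- signal::filtfilt(flt, data[tr, ch, ])
  }
  out
}

#' Band-pass filter, resample, and notch-filter epoched trials
#'
#' Zero-phase (forward-backward) Butterworth band-pass of the stated
#' order, polyphase resampling to `target_fs`, then a narrow zero-phase
#' notch at the mains frequency. Zero-phase filtering keeps latency
#' estimates free of filter delay.
#'
#' @param ts a `trial_set`.
#' @param band pass band, Hz; `band[2]` is truncated below the target
#'   Nyquist with a warning if necessary.
#' @param order Butterworth order.
#' @param target_fs output sampling rate, Hz.
#' @param notch mains frequency to remove, Hz (`NULL` disables).
#' @param notch_halfwidth_hz half-width of the stop band, Hz.
#' @return The filtered, resampled `trial_set`.
#' @export
filter_resample <- function(ts, band = c(1, 240), order = 5,
                            target_fs = 500, notch = 50,
                            notch_halfwidth_hz = 2) {
  if (band[2] <= band[1]) stop("band must be increasing")
  if (band[2] >= target_fs / 2) {
    warning("band upper edge ", band[2], " Hz truncated to below the ",
            "target Nyquist ", target_fs / 2, " Hz")
    band[2] <- target_fs / 2 * 0.99
  }
  bp <- signal::butter(order, band / (ts$fs / 2), type = "pass")
  data <- filt_epochs(ts$data, bp)
  if (target_fs != ts$fs) {
    gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
    g <- gcd(round(target_fs), round(ts$fs))
    pq <- c(round(target_fs) / g, round(ts$fs) / g)
    n_out <- ceiling(dim(data)[3] * pq[1] / pq[2])
    out <- array(NA_real_, c(dim(data)[1:2], n_out))
    for (tr in seq_len(dim(data)[1])) for (ch in seq_len(dim(data)[2])) {
      out[tr, ch, ] <- signal::resample(data[tr, ch, ], pq[1], pq[2])
    }
    data <- out
    ts$fs <- target_fs
  }
  if (!is.null(notch)) {
    nf <- signal::butter(2, c(notch - notch_halfwidth_hz,
                              notch + notch_halfwidth_hz) / (ts$fs / 2),
                         type = "stop")
    data <- filt_epochs(data, nf)
  }
  ts$data <- data
  ts
}

band_rms <- function(x, band_hz, fs) {
  sqrt(mean(bandpass_segment(x, band_hz, fs)^2))
}

#' Remove channels with persistent high-frequency noise
#'
#' A channel is removed when the fraction of trials on which its
#' high-frequency-band RMS exceeds a robust per-trial threshold
#' (median + `z_thresh` * MAD across channels) is greater than
#' `trial_fraction`.
#'
#' @param ts a `trial_set`.
#' @param hf_band high-frequency band used as the noise signature, Hz.
#' @param z_thresh robust z threshold.
#' @param trial_fraction fraction of flagged trials above which a
#'   channel is removed.
#' @return The `trial_set` with noisy channels removed and recorded in
#'   `rejected_channels`.
#' @export
reject_channels <- function(ts, hf_band = c(70, 240), z_thresh = 5,
                            trial_fraction = 0.6) {
  d <- dim(ts$data)
  if (d[2] < 2) stop("need at least 2 channels")
  hf_band[2] <- min(hf_band[2], ts$fs / 2 * 0.999)
  rms <- matrix(NA_real_, d[1], d[2])
  for (tr in seq_len(d[1])) for (ch in seq_len(d[2])) {
    rms[tr, ch] <- band_rms(ts$data[tr, ch, ], hf_band, ts$fs)
  }
  flagged <- t(apply(rms, 1, function(r) {
    r > stats::median(r) + z_thresh * stats::mad(r)
  }))
  frac <- colMeans(flagged)
  bad <- which(frac > trial_fraction)
  if (length(bad) == d[2]) stop("all channels rejected")
  if (length(bad)) {
    ts$rejected_channels <- rbind(
      ts$rejected_channels,
      data.frame(channel = bad, reason = "high_frequency_noise",
                 statistic = frac[bad]))
    ts$data <- ts$data[, -bad, , drop = FALSE]
    ts$channel_meta <- ts$channel_meta[-bad, ]
  }
  ts
}

#' Remove trials with amplitude or slow-wave artifacts
#'
#' Automated surrogate for visual trial rejection: a trial is removed
#' when its peak absolute amplitude over channels, or its mean
#' low-frequency (< 2 Hz) power, exceeds median + `amp_thresh_z` * MAD
#' across trials.
#'
#' @param ts a `trial_set`.
#' @param amp_thresh_z robust z threshold (`Inf` disables rejection).
#' @param lf_cutoff_hz slow-wave upper frequency, Hz.
#' @return The `trial_set` with artifact trials removed and recorded.
#' @export
reject_trials <- function(ts, amp_thresh_z = 15, lf_cutoff_hz = 2) {
  d <- dim(ts$data)
  peak <- apply(abs(ts$data), 1, max)
  lfp <- vapply(seq_len(d[1]), function(tr) {
    mean(vapply(seq_len(d[2]), function(ch) {
      mean(bandpass_segment(ts$data[tr, ch, ],
                            c(1e-6, lf_cutoff_hz), ts$fs)^2)
    }, numeric(1)))
  }, numeric(1))
  robust_flag <- function(x) {
    if (!is.finite(amp_thresh_z)) return(rep(FALSE, length(x)))
    x > stats::median(x) + amp_thresh_z * stats::mad(x)
  }
  bad <- which(robust_flag(peak) | robust_flag(lfp))
  if (length(bad)) {
    ts$rejected_trials <- rbind(
      ts$rejected_trials,
      data.frame(trial_index = ts$trial_meta$trial_index[bad],
                 reason = "amplitude_or_slow_wave",
                 statistic = peak[bad]))
    ts$data <- ts$data[-bad, , , drop = FALSE]
    ts$trial_meta <- ts$trial_meta[-bad, ]
  }
  ts
}

#' Common-average re-reference, detrend, and demean
#'
#' Per sample, subtracts the mean over retained channels; per trial and
#' channel, removes the best-fit line and the mean. Idempotent.
#'
#' @param ts a `trial_set`.
#' @return The re-referenced `trial_set`.
#' @export
rereference_detrend <- function(ts) {
  d <- dim(ts$data)
  for (tr in seq_len(d[1])) {
    x <- ts$data[tr, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    x <- sweep(x, 2, colMeans(x))           # CAR over retained channels
    tt <- seq_len(d[3]) - (d[3] + 1) / 2    # centered time axis
    slope <- (x %*% tt) / sum(tt^2)
    x <- x - slope %*% t(tt)
    x <- x - rowMeans(x)
    ts$data[tr, , ] <- x
  }
  ts
}

#' Drop habituation trials from a trial set
#'
#' Statistics are computed on the testing period; removing habituation
#' epochs before the time-frequency step saves their decomposition.
#'
#' @param ts a `trial_set`.
#' @return The `trial_set` without habituation trials.
#' @export
drop_habituation <- function(ts) {
  keep <- ts$trial_meta$role != "habituation"
  ts$data <- ts$data[keep, , , drop = FALSE]
  ts$trial_meta <- ts$trial_meta[keep, ]
  ts
}

#' Exclude a run with too few surviving deviant trials
#'
#' @param ts a `trial_set`.
#' @param min_deviants minimum number of surviving deviant trials.
#' @return `ts`, or an `excluded_run` marker when fewer than
#'   `min_deviants` deviants survive.
#' @export
exclude_run_if_sparse <- function(ts, min_deviants = 5) {
  n_dev <- sum(ts$trial_meta$role == "deviant")
  if (n_dev < min_deviants) {
    return(structure(list(reason = sprintf(
      "only %d deviant trials survive (< %d)", n_dev, min_deviants)),
      class = "excluded_run"))
  }
  ts
}

#' @rdname exclude_run_if_sparse
#' @param x object to test.
#' @export
is_excluded <- function(x) inherits(x, "excluded_run")

#' Run the full preprocessing chain on one recording
#'
#' epoch -> band-pass/resample/notch -> channel rejection -> trial
#' rejection -> common-average reference/detrend/demean -> sparse-run
#' exclusion.
#'
#' @param rec a `synthetic_recording`.
#' @param window_s epoch window, seconds.
#' @param band,order,target_fs,notch see [filter_resample()].
#' @param hf_band,z_thresh,trial_fraction see [reject_channels()].
#' @param amp_thresh_z see [reject_trials()].
#' @param min_deviants see [exclude_run_if_sparse()].
#' @return A `trial_set`, or an `excluded_run` marker.
#' @export
preprocess_run <- function(rec, window_s = c(-1, 2), band = c(1, 240),
                           order = 5, target_fs = 500, notch = 50,
                           hf_band = c(70, 240), z_thresh = 5,
                           trial_fraction = 0.6, amp_thresh_z = 15,
                           min_deviants = 5) {
  ts <- epoch(rec, window_s)
  ts <- filter_resample(ts, band, order, target_fs, notch)
  ts <- reject_channels(ts, hf_band, z_thresh, trial_fraction)
  ts <- reject_trials(ts, amp_thresh_z)
  ts <- rereference_detrend(ts)
  exclude_run_if_sparse(ts, min_deviants)
}
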