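#' Time-frequency analysis grid
#'
#' The analysis grid spans 10-140 Hz in 1 Hz steps and, in time, from
#' 0.3 s before the 1st-tone onset to 0.8 s after the 5th-tone slot in
#' 20 ms steps. The spectral window at frequency f is `window_cycles / f`
#' seconds long and the multitaper half-bandwidth is
#' `smoothing_factor * f`; with 4 cycles and a factor of 0.5 the
#' time-half-bandwidth product is 2 at every frequency, fixing 3 Slepian
#' tapers throughout.
#'
#' @param fifth_tone_onset_s onset of the 5th-tone slot relative to the
#'   1st tone, seconds (0.8 for the ECoG protocol).
#' @param fmin,fmax,fstep frequency range and step, Hz.
#' @param tmin,tmax,tstep time range (relative to 1st-tone onset) and
#'   step, seconds.
#' @param window_cycles spectral window length in cycles of f.
#' @param smoothing_factor half-bandwidth as a multiple of f.
#' @return list of class `tfr_grid` with `freqs_hz`, `times_s`,
#'   `window_cycles`, `smoothing_factor`, `fifth_tone_onset_s`.
#' @export
tfr_grid <- function(fifth_tone_onset_s = 0.8, fmin = 10, fmax = 140,
                     fstep = 1, tmin = -0.3,
                     tmax = fifth_tone_onset_s + 0.8, tstep = 0.02,
                     window_cycles = 4, smoothing_factor = 0.5) {
  stopifnot(fmin > 0, fmax > fmin, tmax > tmin)
  structure(list(freqs_hz = seq(fmin, fmax, by = fstep),
                 times_s = round(seq(tmin, tmax, by = tstep), 10),
                 window_cycles = window_cycles,
                 smoothing_factor = smoothing_factor,
                 fifth_tone_onset_s = fifth_tone_onset_s),
            class = "tfr_grid")
}

#' Number of Slepian tapers for a window / half-bandwidth pair
#'
#' `floor(2 * window_s * half_bandwidth_hz) - 1`, floored at one taper
#' (with a warning when the time-bandwidth product is below one).
#'
#' @param window_s window length, seconds.
#' @param half_bandwidth_hz spectral smoothing half-bandwidth, Hz.
#' @return integer taper count.
#' @export
dpss_taper_count <- function(window_s, half_bandwidth_hz) {
  p <- 2 * window_s * half_bandwidth_hz
  if (p < 1) warning("time-bandwidth product ", signif(p, 3),
                     " < 1; clamping to a single taper")
  # tolerance: products like 2 * (4/f) * (0.5 f) land at 4 - eps in
  # floating point for some f and must still count as 4
  max(1L, as.integer(floor(p + 1e-9) - 1L))
}

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed exactly as the leading eigenvectors of the classical
#' symmetric tridiagonal matrix whose eigenvectors are the Slepian
#' sequences; tapers are unit-energy.
#'
#' @param n window length, samples.
#' @param w normalized half-bandwidth (half-bandwidth in Hz / sampling
#'   rate), in (0, 0.5).
#' @param k number of tapers.
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, w, k) {
  key <- paste(n, signif(w, 12), k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  stopifnot(n >= 2, w > 0, w < 0.5, k >= 1, k <= n)
  i <- seq_len(n)
  diag_v <- ((n - 1 - 2 * (i - 1)) / 2)^2 * cos(2 * pi * w)
  off_v <- (i * (n - i) / 2)[-n]
  m <- matrix(0, n, n)
  m[cbind(i, i)] <- diag_v
  m[cbind(i[-n], i[-n] + 1)] <- off_v
  m[cbind(i[-n] + 1, i[-n])] <- off_v
  e <- eigen(m, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper time-frequency decomposition of epoched trials
#'
#' At each grid frequency f, trials are convolved with `k` Slepian
#' tapers of length `window_cycles / f` modulated at f (complex
#' demodulation); power is the taper-averaged squared magnitude, scaled
#' as a one-sided spectral density (2 / fs with unit-energy tapers) so
#' that power integrated over frequency approximates signal variance.
#' Grid times whose window extends beyond the epoch are set to `NA`,
#' never extrapolated.
#'
#' @param ts a `trial_set`.
#' @param grid a [tfr_grid()].
#' @return A `tfr_set`: list with `power` (trials x channels x freqs x
#'   times), `grid`, `baseline_window_s` (`NULL` until
#'   [baseline_correct()]), `trial_meta`, `channel_meta`, `fs`.
#' @export
tfr_multitaper <- function(ts, grid) {
  fs <- ts$fs
  if (max(grid$freqs_hz) > fs / 2) {
    stop("grid frequency ", max(grid$freqs_hz),
         " Hz exceeds the Nyquist frequency ", fs / 2, " Hz")
  }
  d <- dim(ts$data)
  ntr <- d[1]; nch <- d[2]; nsamp <- d[3]
  nf <- length(grid$freqs_hz); nt <- length(grid$times_s)
  x <- matrix(ts$data, nrow = ntr * nch)  # signals x samples
  pow <- array(NA_real_, c(ntr, nch, nf, nt))
  t_samp <- round((grid$times_s - ts$window_s[1]) * fs) + 1
  for (fi in seq_len(nf)) {
    f <- grid$freqs_hz[fi]
    half <- floor(grid$window_cycles / f * fs / 2)
    n_w <- 2 * half + 1
    k <- dpss_taper_count(n_w / fs, grid$smoothing_factor * f)
    tap <- dpss_tapers(n_w, grid$smoothing_factor * f / fs, k)
    tau <- (-half:half) / fs
    carrier <- exp(-2i * pi * f * tau)
    kern <- tap * carrier  # n_w x k complex
    valid <- which(t_samp - half >= 1 & t_samp + half <= nsamp)
    if (!length(valid)) next
    idx <- outer(-half:half, t_samp[valid], "+")  # n_w x nt_valid
    m <- x[, as.vector(idx), drop = FALSE]        # signals x (n_w*ntv)
    a <- array(m, c(nrow(m), n_w, length(valid)))
    a <- aperm(a, c(1, 3, 2))
    dim(a) <- c(nrow(m) * length(valid), n_w)
    cre <- a %*% Re(kern)
    cim <- a %*% Im(kern)
    p <- rowMeans(cre^2 + cim^2) * 2 / fs
    pow[, , fi, valid] <- array(p, c(ntr, nch, length(valid)))
  }
  structure(list(power = pow, grid = grid, baseline_window_s = NULL,
                 trial_meta = ts$trial_meta, channel_meta = ts$channel_meta,
                 fs = fs),
            class = "tfr_set")
}

#' Baseline-correct a raw-power TFR
#'
#' Per trial, channel, and frequency, expresses power relative to the
#' mean over the baseline window: relative change
#' `(power - baseline) / baseline`, or `db`
#' `10 * log10(power / baseline)`.
#'
#' @param tfr a raw-power `tfr_set`.
#' @param window baseline window relative to the 1st-tone onset, seconds.
#' @param mode `"relchange"` or `"db"`.
#' @return The baseline-corrected `tfr_set`.
#' @export
baseline_correct <- function(tfr, window = c(-0.3, 0),
                             mode = c("relchange", "db")) {
  mode <- match.arg(mode)
  tsel <- tfr$grid$times_s >= window[1] & tfr$grid$times_s <= window[2]
  if (!any(tsel)) stop("empty baseline window")
  base <- rowMeans(tfr$power[, , , tsel, drop = FALSE], dims = 3,
                   na.rm = TRUE)
  tfr$power <- if (mode == "relchange") {
    (tfr$power - c(base)) / c(base)
  } else {
    10 * log10(tfr$power / c(base))
  }
  tfr$baseline_window_s <- window
  tfr
}

#' Subset a TFR set by trial
#'
#' @param tfr a `tfr_set`.
#' @param idx logical or integer trial selector (rows of `trial_meta`).
#' @return The subsetted `tfr_set`.
#' @export
subset_trials <- function(tfr, idx) {
  tfr$power <- tfr$power[idx, , , , drop = FALSE]
  tfr$trial_meta <- tfr$trial_meta[idx, ]
  tfr
}
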