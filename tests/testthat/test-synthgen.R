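test_that("background spectral exponent is recovered by periodogram fit", {
  layout <- test_layout()
  fs <- 500
  # oracle: log-log regression of the raw periodogram over 5-100 Hz
  psd_slope <- function(x, fs) {
    n <- length(x)
    p <- abs(fft(x))^2 / n
    f <- (seq_len(n) - 1) / n * fs
    sel <- f >= 5 & f <= 100
    # average periodogram into 40 log-spaced bins to stabilise the fit
    bins <- cut(log(f[sel]), 40)
    lf <- tapply(log(f[sel]), bins, mean)
    lp <- tapply(log(p[sel]), bins, mean)
    unname(coef(lm(lp ~ lf))[2])
  }
  pink <- simulate_background(layout, 120, fs, exponent = 1, seed = 2)
  slope <- mean(apply(pink, 1, psd_slope, fs = fs))
  expect_lt(abs(slope - (-1)), 0.1)
  white <- simulate_background(layout, 120, fs, exponent = 0, seed = 2)
  expect_lt(abs(mean(apply(white, 1, psd_slope, fs = fs))), 0.1)
})

test_that("mains contamination shows as a 50 Hz periodogram peak", {
  layout <- test_layout()
  sig <- simulate_background(layout, 20, 500, line_hz = 50,
                             line_amplitude = 3, seed = 4)
  x <- sig[1, ]
  p <- abs(fft(x))^2
  f <- (seq_along(x) - 1) / length(x) * 500
  sel <- f > 1 & f <= 250
  expect_equal(f[sel][which.max(p[sel])], 50, tolerance = 0.1)
})

test_that("background generation is deterministic and rejects bad input", {
  layout <- test_layout()
  expect_identical(simulate_background(layout, 5, 500, seed = 3),
                   simulate_background(layout, 5, 500, seed = 3))
  expect_error(simulate_background(layout, -1, 500), "duration")
})

test_that("zero-amplitude injection leaves the background untouched", {
  layout <- test_layout()
  run <- build_run("xx", "xY|xx", test_paradigm(), seed = 1)
  bg <- simulate_background(layout, 50, 500, seed = 1)
  comps <- default_components()
  for (i in seq_along(comps)) {
    comps[[i]]$amplitude_mean <- 0
    comps[[i]]$amplitude_sd <- 0
  }
  rec <- inject_components(bg, run, layout, comps, coupling_spec(),
                           fs = 500, seed = 1)
  expect_equal(rec$signal, bg)
})

test_that("component bands above Nyquist are rejected", {
  layout <- test_layout()
  run <- build_run("xx", "xY|xx", test_paradigm(), seed = 1)
  bg <- simulate_background(layout, 50, 500, seed = 1)
  bad <- list(component_spec("PE1", band_hz = c(200, 300),
                             latency_mean_s = 0.074))
  expect_error(inject_components(bg, run, layout, bad, fs = 500),
               "Nyquist")
})

test_that("ground truth records exact latencies when jitter is zero", {
  layout <- test_layout()
  run <- build_run("xx", "xY|xx", test_paradigm(3L), seed = 2)
  rec <- simulate_recording(run, layout,
                            default_components("xY|xx"),
                            fs = 500, seed = 2)
  gt <- rec$ground_truth
  pe1 <- gt[gt$component == "PE1", ]
  expect_equal(nrow(pe1), 6)  # 2 deviants per block x 3 blocks
  expect_true(all(pe1$center_s == 0.074))
  meta <- trial_meta(run)
  expect_true(all(meta$role[pe1$trial_index] == "deviant"))
})

test_that("deterministic within-trial coupling yields r ~ 1 in ground truth", {
  layout <- test_layout()
  cfg <- paradigm_config("ecog", n_habituation = 2L, block_size = 25L,
                         deviant_fraction = 0.2, n_test_blocks = 4L)
  run <- build_run("xx", "xY|xx", cfg, seed = 3)
  bg <- simulate_background(layout, 3.0 * 102 + 4, 500, seed = 3)
  rec <- inject_components(bg, run, layout, default_components("xY|xx"),
                           coupling_spec(pe1_to_pe2_gain = 1,
                                         noise_sd = 1e-9),
                           fs = 500, seed = 3)
  gt <- rec$ground_truth
  wide <- merge(gt[gt$component == "PE1", c("trial_index", "amplitude")],
                gt[gt$component == "PE2", c("trial_index", "amplitude")],
                by = "trial_index")
  expect_equal(nrow(wide), 20)
  # PE2 = mean + 1 * (PE1 - mean) + own noise (sd 0.25): r large; with the
  # shared deviation making up half the variance, r ~ 1/sqrt(2) at least
  expect_gt(cor(wide$amplitude.x, wide$amplitude.y), 0.5)
  # and with the PE2 intrinsic noise silenced the coupling is exact
  comps <- default_components("xY|xx")
  comps$PE2$amplitude_sd <- 0
  rec2 <- inject_components(bg, run, layout, comps,
                            coupling_spec(pe1_to_pe2_gain = 1),
                            fs = 500, seed = 4)
  gt2 <- rec2$ground_truth
  wide2 <- merge(gt2[gt2$component == "PE1", c("trial_index", "amplitude")],
                 gt2[gt2$component == "PE2", c("trial_index", "amplitude")],
                 by = "trial_index")
  expect_equal(cor(wide2$amplitude.x, wide2$amplitude.y), 1,
               tolerance = 1e-12)
})

test_that("injected burst energy stays in its band", {
  layout <- test_layout()
  cfg <- test_paradigm()
  run <- build_run("xx", "xY|xx", cfg, seed = 5)
  bg <- simulate_background(layout, 50, 500, seed = 5)
  comps <- list(PE1 = component_spec("PE1", band_hz = c(60, 90),
                                     latency_mean_s = 0.074,
                                     amplitude_sd = 0,
                                     target_rois = "auditory_core",
                                     active_conditions = "xY|xx"))
  rec <- inject_components(bg, run, layout, comps, fs = 500, seed = 5)
  diff <- rec$signal[1, ] - bg[1, ]   # channel 1 is auditory core
  p <- abs(fft(diff))^2
  f <- (seq_along(diff) - 1) / length(diff) * 500
  f <- pmin(f, 500 - f)
  # the 60 ms Gaussian envelope broadens the carrier band by about
  # sigma_f = 1/(2 pi sigma_t) ~ 10.6 Hz; measure the band widened by
  # twice that spectral width
  inband <- sum(p[f >= 60 - 21 & f <= 90 + 21])
  expect_gt(inband / sum(p), 0.95)
})

test_that("ground-truth amplitudes follow the configured mean and SD", {
  layout <- test_layout()
  cfg <- paradigm_config("ecog", n_habituation = 2L, block_size = 10L,
                         deviant_fraction = 0.2, n_test_blocks = 25L)
  run <- build_run("xx", "xY|xx", cfg, seed = 6)
  comps <- list(PE1 = component_spec("PE1", band_hz = c(60, 90),
                                     latency_mean_s = 0.074,
                                     amplitude_mean = 1,
                                     amplitude_sd = 0.25,
                                     active_conditions = "xY|xx"))
  bg <- simulate_background(layout, 3.0 * 252 + 4, 250, seed = 6)
  rec <- inject_components(bg, run, layout, comps, fs = 250, seed = 6)
  amp <- rec$ground_truth$amplitude
  expect_gte(length(amp), 500 * 0.1)  # 50 deviants here; pooled check below
  expect_lt(abs(mean(amp) - 1), 3 * 0.25 / sqrt(length(amp)))
  expect_lt(abs(sd(amp) - 0.25), 0.1)
})

test_that("recordings round-trip losslessly through the container", {
  rec <- fixture_small()
  path <- tempfile("rec_container")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$signal, rec$signal)
  expect_equal(back$events, rec$events, ignore_attr = TRUE)
  expect_equal(back$layout, rec$layout, ignore_attr = TRUE)
  expect_equal(back$ground_truth, rec$ground_truth, ignore_attr = TRUE)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$t_start_s, rec$t_start_s)
})

test_that("container schema violations are reported by name", {
  rec <- fixture_small()
  path <- tempfile("rec_container")
  write_recording(rec, path)
  file.remove(file.path(path, "ground_truth.tsv"))
  expect_warning(back <- read_recording(path), "ground_truth")
  expect_equal(nrow(back$ground_truth), 0)
  ev <- read.delim(file.path(path, "events.tsv"))
  write.table(ev[, setdiff(names(ev), "condition")],
              file.path(path, "events.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(suppressWarnings(read_recording(path)), "condition")
  file.remove(file.path(path, "meta.json"))
  expect_error(read_recording(path), "meta.json")
})

test_that("electrode layouts partition channels over ROIs", {
  full <- electrode_layout(96L)
  expect_equal(nrow(full), 96)
  expect_equal(unname(table(full$roi)[c("auditory_core",
                                        "auditory_belt_parabelt", "STR",
                                        "frontal", "other")]),
               c(12L, 16L, 8L, 24L, 36L), ignore_attr = TRUE)
  small <- electrode_layout(16L)
  expect_equal(nrow(small), 16)
  expect_true(all(c("auditory_core", "frontal") %in% small$roi))
})
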