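test_that("contrast specifications encode the study comparisons", {
  ln <- contrast_spec("local_novelty")
  expect_equal(ln$combine, "conjunction")
  expect_equal(ln$sub, list(c("xY|xx", "xx|xx"), c("xY|xY", "xx|xY")))
  expect_equal(contrast_spec("global_only")$sub, list(c("xx|xY", "xY|xY")))
  expect_equal(contrast_spec("omission_xY")$sub,
               list(c("x_|xY", "xxxx_expected")))
  expect_error(contrast_spec("banana"), "unknown contrast")
})

test_that("conjunction responsiveness is the same-sign channel intersection", {
  grid <- tfr_grid(0.2, fmin = 10, fmax = 30, fstep = 10, tmin = 0,
                   tmax = 0.08, tstep = 0.02)
  set.seed(61)
  mk <- function(effect_ch, n = 8, sgn = 1) {
    pow <- array(rnorm(n * 3 * 3 * 5), c(n, 3, 3, 5))
    for (ch in effect_ch) pow[, ch, 2, 2:4] <- pow[, ch, 2, 2:4] + sgn * 4
    make_tfr_set(pow, grid)
  }
  tfrs <- list("xY|xx" = mk(c(1, 2)), "xx|xx" = mk(integer(0)),
               "xY|xY" = mk(c(2, 3)), "xx|xY" = mk(integer(0)))
  res <- run_contrast(contrast_spec("local_novelty"), tfrs, n_perm = 200,
                      seed = 2)
  expect_s3_class(res, "conjunction_result")
  sub_resp <- lapply(res$sub_results, `[[`, "responsive_channels")
  expect_true(all(res$responsive_channels %in% sub_resp[[1]]))
  expect_true(all(res$responsive_channels %in% sub_resp[[2]]))
  expect_true(2 %in% res$responsive_channels)
  expect_false(1 %in% res$responsive_channels)
  # opposite signs in the two sub-contrasts do not conjoin
  tfrs2 <- tfrs
  tfrs2[["xY|xY"]] <- mk(2, sgn = -1)
  res2 <- run_contrast(contrast_spec("local_novelty"), tfrs2,
                       n_perm = 200, seed = 2)
  expect_false(2 %in% res2$responsive_channels)
  expect_error(run_contrast(contrast_spec("global_only"),
                            tfrs[c("xx|xx")], n_perm = 50),
               "needs condition")
})

test_that("pooling runs keeps shared channels and tags trial provenance", {
  grid <- tfr_grid(0.2, fmin = 10, fmax = 20, fstep = 10, tmin = 0,
                   tmax = 0.04, tstep = 0.02)
  a <- make_tfr_set(array(1, c(3, 3, 2, 3)), grid)
  b <- make_tfr_set(array(2, c(4, 3, 2, 3)), grid)
  b$channel_meta <- b$channel_meta[c(1, 3, 2), ]  # same names, reordered
  pooled <- pool_tfrs(list(a, b))
  expect_equal(dim(pooled$power)[1], 7)
  expect_equal(pooled$trial_meta$run, c(rep(1, 3), rep(2, 4)))
  expect_equal(pooled$channel_meta$name, a$channel_meta$name)
  # channel alignment is by name, not position
  expect_true(all(pooled$power[4:7, , , ] == 2))
})

test_that("the full pipeline detects injected components and is reproducible", {
  cfg <- default_config()
  cfg$tfr$fstep <- 5
  cfg$stats$n_perm <- 200L
  cfg$rules$pe_band_min_hz <- 25  # 0.5 f smoothing smears gamma downward
  layout <- electrode_layout(16L)
  run <- build_run("xx", "xY|xx", paradigm_config("ecog"), seed = 6)
  rec <- simulate_recording(run, layout, default_components("xY|xx"),
                            fs = 1000, seed = 6)
  b <- run_full_analysis(list(rec), cfg)
  expect_true(all(c("PE1", "PRED") %in% names(b$component_report)))
  expect_equal(names(b$contrast_results), "local_and_global")
  # PE1 sits on auditory-core channels and peaks early in the gamma band
  pe1 <- b$component_report$PE1
  expect_true(all(b$tfr_pooled$channel_meta$roi[pe1$channels] ==
                    "auditory_core"))
  expect_gt(pe1$freq_window_hz[2], 40)
  # per-trial PE1 contributions track the injected burst amplitudes
  gt <- rec$ground_truth
  g <- gt[gt$component == "PE1", ]
  sel <- match(g$trial_index, b$tfr_pooled$trial_meta$trial_index)
  r <- cor(g$amplitude, b$contributions$PE1[sel])
  expect_gt(r, 0.8)
  # determinism: the same inputs give bit-identical reports
  b2 <- run_full_analysis(list(rec), cfg)
  expect_identical(b$cluster_tables, b2$cluster_tables)
  expect_identical(b$contributions, b2$contributions)
  expect_identical(b$correlation_panel, b2$correlation_panel)
  # bundle artifacts land on disk
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "clusters_local_and_global.tsv")))
  expect_true(file.exists(file.path(dir, "components.json")))
  expect_true(file.exists(file.path(dir, "provenance.json")))
  expect_true(file.exists(file.path(dir, "qc.tsv")))
})

test_that("a components-off run yields no dominant response", {
  cfg <- default_config()
  cfg$tfr$fstep <- 5
  cfg$stats$n_perm <- 200L
  layout <- test_layout()
  run <- build_run("xx", "xY|xx", test_paradigm(3L), seed = 31)
  comps <- default_components("xY|xx")
  for (i in seq_along(comps)) {
    comps[[i]]$amplitude_mean <- 0
    comps[[i]]$amplitude_sd <- 0
  }
  cfg$preprocess$min_deviants <- 2L
  rec <- simulate_recording(run, layout, comps, fs = 1000, seed = 31)
  b <- run_full_analysis(list(rec), cfg)
  res <- b$contrast_results$local_and_global
  # per-channel family-wise control: at most a stray channel or two can
  # reach significance on an 8-channel null run
  expect_lte(length(res$responsive_channels), 2)
})

test_that("excluded runs are logged and zero usable runs is a hard error", {
  cfg <- default_config()
  cfg$preprocess$min_deviants <- 50L  # impossible
  rec <- fixture_small()
  expect_error(run_full_analysis(list(rec), cfg), "no usable recording")
})
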