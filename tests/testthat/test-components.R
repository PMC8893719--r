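rank1_tensor <- function(a, b, c) {
  outer(a, as.vector(outer(b, c))) |>
    array(c(length(a), length(b), length(c)))
}

fake_result <- function(clusters, alpha = 0.05, grid = NULL) {
  grid <- grid %||% tfr_grid(0.8, fmin = 10, fmax = 140, fstep = 2)
  structure(list(clusters = clusters, alpha = alpha, grid = grid),
            class = "cluster_result")
}

cluster_row <- function(channel, sign, peak_s, f_min, f_max, t_min_idx,
                        t_max_idx, p = 0.01, mass = sign * 100) {
  data.frame(channel = channel, sign = sign, mass = mass, p = p,
             f_min_hz = f_min, f_max_hz = f_max,
             f_min_idx = 1, f_max_idx = 2,
             t_min_idx = t_min_idx, t_max_idx = t_max_idx,
             onset_s = NA_real_, peak_s = peak_s, n_cells = 10)
}

test_that("clusters are classified by band, latency, sign, and duration", {
  grid <- tfr_grid(0.8, fstep = 2)
  t_at <- function(s) which.min(abs(grid$times_s - s))
  cl <- rbind(
    cluster_row(1, 1, 0.074, 60, 90, t_at(0.82), t_at(0.92)),   # PE1
    cluster_row(2, 1, 0.242, 44, 80, t_at(1.0), t_at(1.1)),     # PE2
    cluster_row(3, -1, 0.3, 12, 30, t_at(0.95), t_at(1.35)),    # PRED
    cluster_row(4, 1, 0.05, 12, 20, t_at(0.82), t_at(0.9)),     # OTHER
    cluster_row(5, 1, 0.08, 60, 90, t_at(0.82), t_at(0.9), p = 0.5))
  masks <- classify_clusters(fake_result(cl, grid = grid))
  expect_setequal(names(masks), c("PE1", "PE2", "PRED"))
  expect_equal(masks$PE1$channels, 1)   # the p = 0.5 cluster is ignored
  expect_equal(masks$PE2$channels, 2)
  expect_equal(masks$PRED$channels, 3)
  asn <- attr(masks, "assignments")
  expect_equal(asn$component[asn$channel == 4], "OTHER")
  # short beta decrease is not PRED
  cl2 <- cluster_row(1, -1, 0.3, 12, 30, t_at(0.95), t_at(1.05))
  expect_false("PRED" %in% names(classify_clusters(fake_result(cl2,
                                                               grid = grid))))
})

test_that("an exact rank-1 tensor is recovered with explained variance 1", {
  set.seed(41)
  a <- rnorm(5); b <- abs(rnorm(4)); cc <- abs(rnorm(6))
  x <- rank1_tensor(a, b, cc)
  grid <- tfr_grid(0.8, fmin = 10, fmax = 40, fstep = 10,
                   tmin = 0, tmax = 0.1, tstep = 0.02)
  pow <- array(NA_real_, c(2, 5, 4, 6))
  pow[1, , , ] <- x; pow[2, , , ] <- x
  tfr <- make_tfr_set(pow, grid)
  mask <- structure(list(name = "PE1", channels = 1:5,
                         freq_window_hz = c(10, 40),
                         time_window_s = c(0, 0.1)),
                    class = "component_mask")
  model <- fit_pattern(tfr, mask, seed = 1)
  expect_gt(model$fit_quality, 1 - 1e-8)
  cos_sim <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  expect_gt(cos_sim(model$loadings$a, a), 1 - 1e-8)
  expect_gt(cos_sim(model$loadings$b, b), 1 - 1e-8)
  expect_gt(cos_sim(model$loadings$c, cc), 1 - 1e-8)
  # sign convention: frequency and time loadings sum nonnegative
  expect_gte(sum(model$loadings$b), 0)
  expect_gte(sum(model$loadings$c), 0)
  # independent oracle: dominant left singular vector of the matricized
  # tensor equals the channel loading for a rank-1 model
  sv <- svd(matrix(x, 5))$u[, 1]
  expect_gt(cos_sim(model$loadings$a, sv), 1 - 1e-8)
})

test_that("rank-1 plus small noise is recovered to cosine >= 0.99", {
  set.seed(42)
  a <- rnorm(6); b <- abs(rnorm(5)) + 0.5; cc <- abs(rnorm(7)) + 0.5
  x <- rank1_tensor(a, b, cc)
  xn <- x + rnorm(length(x), sd = 0.02 * sd(x))
  grid <- tfr_grid(0.8, fmin = 10, fmax = 50, fstep = 10,
                   tmin = 0, tmax = 0.12, tstep = 0.02)
  pow <- array(NA_real_, c(2, 6, 5, 7)); pow[1, , , ] <- xn
  pow[2, , , ] <- xn
  tfr <- make_tfr_set(pow, grid)
  mask <- structure(list(name = "PE1", channels = 1:6,
                         freq_window_hz = c(10, 50),
                         time_window_s = c(0, 0.12)),
                    class = "component_mask")
  model <- fit_pattern(tfr, mask, seed = 2)
  cos_sim <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  expect_gt(cos_sim(model$loadings$a, a), 0.99)
  expect_gt(cos_sim(model$loadings$b, b), 0.99)
  expect_gt(cos_sim(model$loadings$c, cc), 0.99)
})

test_that("degenerate masks and tensors are rejected", {
  grid <- tfr_grid(0.8, fmin = 10, fmax = 40, fstep = 10,
                   tmin = 0, tmax = 0.1, tstep = 0.02)
  pow <- array(0, c(2, 5, 4, 6))
  tfr <- make_tfr_set(pow, grid)
  mask <- structure(list(name = "x", channels = 1:5,
                         freq_window_hz = c(10, 40),
                         time_window_s = c(0, 0.1)),
                    class = "component_mask")
  expect_error(fit_pattern(tfr, mask), "all-zero")
  mask1 <- mask; mask1$channels <- 1
  expect_error(fit_pattern(tfr, mask1), "2 entries")
})

test_that("contributions are the least-squares scale of the pattern", {
  set.seed(43)
  a <- rnorm(4); b <- abs(rnorm(3)); cc <- abs(rnorm(5))
  x <- rank1_tensor(a, b, cc)
  grid <- tfr_grid(0.8, fmin = 10, fmax = 30, fstep = 10,
                   tmin = 0, tmax = 0.08, tstep = 0.02)
  pow <- array(NA_real_, c(3, 4, 3, 5))
  pow[1, , , ] <- 2.5 * x
  # a trial orthogonal to the pattern: swap sign on half the channels
  orth <- x; orth[1:2, , ] <- -x[1:2, , ] *
    sum(x[3:4, , ]^2) / sum(x[1:2, , ]^2)
  pow[2, , , ] <- orth
  pow[3, , , ] <- x + orth
  tfr <- make_tfr_set(pow, grid)
  mask <- structure(list(name = "PE1", channels = 1:4,
                         freq_window_hz = c(10, 30),
                         time_window_s = c(0, 0.08)),
                    class = "component_mask")
  model <- fit_pattern(tfr, mask, trial_sel = 1, seed = 3)
  contrib <- trial_contributions(tfr, model)
  scale_unit <- contrib[1] / 2.5   # lambda absorbs the pattern scale
  expect_equal(contrib[2], 0, tolerance = 1e-8)
  # linearity: contributions(x1 + x2) = contributions(x1) + contributions(x2)
  expect_equal(contrib[3], contrib[1] / 2.5 + contrib[2],
               tolerance = 1e-8)
  expect_equal(contrib[1] / scale_unit, 2.5, tolerance = 1e-8)
})

test_that("pattern fitting is channel-permutation equivariant", {
  set.seed(44)
  a <- rnorm(5); b <- abs(rnorm(4)); cc <- abs(rnorm(6))
  x <- rank1_tensor(a, b, cc) + rnorm(120, sd = 0.01)
  grid <- tfr_grid(0.8, fmin = 10, fmax = 40, fstep = 10,
                   tmin = 0, tmax = 0.1, tstep = 0.02)
  pow <- array(NA_real_, c(2, 5, 4, 6)); pow[1, , , ] <- x
  pow[2, , , ] <- x
  mask <- structure(list(name = "PE1", channels = 1:5,
                         freq_window_hz = c(10, 40),
                         time_window_s = c(0, 0.1)),
                    class = "component_mask")
  m1 <- fit_pattern(make_tfr_set(pow, grid), mask, seed = 5)
  perm <- c(3, 1, 5, 2, 4)
  m2 <- fit_pattern(make_tfr_set(pow[, perm, , , drop = FALSE], grid),
                    mask, seed = 5)
  align <- sign(sum(m1$loadings$a[perm] * m2$loadings$a))
  expect_equal(align * m2$loadings$a, m1$loadings$a[perm],
               tolerance = 1e-6)
})

test_that("missing cells are excluded from the projection", {
  a <- c(1, 2); b <- c(1, 1); cc <- c(1, 1, 1)
  x <- rank1_tensor(a, b, cc)
  grid <- tfr_grid(0.8, fmin = 10, fmax = 20, fstep = 10,
                   tmin = 0, tmax = 0.04, tstep = 0.02)
  pow <- array(NA_real_, c(2, 2, 2, 3))
  pow[1, , , ] <- 3 * x
  pow[1, 1, 1, 1] <- NA  # one missing cell: projection still exact
  pow[2, , , ] <- NA     # all-missing trial
  tfr <- make_tfr_set(pow, grid)
  mask <- structure(list(name = "PE1", channels = 1:2,
                         freq_window_hz = c(10, 20),
                         time_window_s = c(0, 0.04)),
                    class = "component_mask")
  model <- fit_pattern(tfr, mask, trial_sel = 1, seed = 1)
  contrib <- trial_contributions(tfr, model)
  expect_true(is.finite(contrib[1]))
  expect_gt(contrib[1], 0)
  expect_true(is.na(contrib[2]))
})
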