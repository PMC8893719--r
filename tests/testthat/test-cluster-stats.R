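tiny_grid <- function(nf = 4, nt = 5) {
  tfr_grid(0.2, fmin = 10, fmax = 10 * nf, fstep = 10, tmin = 0,
           tmax = (nt - 1) * 0.02, tstep = 0.02)
}

test_that("pointwise t statistics match a hand-computed oracle", {
  grid <- tiny_grid()
  a_vals <- c(1.0, 1.4, 0.8)
  b_vals <- c(2.1, 2.5, 2.0)
  pa <- array(0, c(3, 1, 4, 5)); pa[, 1, 2, 3] <- a_vals
  pb <- array(0, c(3, 1, 4, 5)); pb[, 1, 2, 3] <- b_vals
  tm <- tmap(pa, pb)
  # textbook pooled two-sample t computed directly
  sp2 <- (2 * var(a_vals) + 2 * var(b_vals)) / 4
  t_exp <- (mean(a_vals) - mean(b_vals)) / sqrt(sp2 * (2 / 3))
  expect_equal(tm$t[1, 2, 3], t_exp, tolerance = 1e-12)
  expect_equal(tm$df, 4)
  # identical groups: t = 0 everywhere (zero-variance cells flagged to 0)
  tm0 <- tmap(pa, pa)
  expect_true(all(tm0$t == 0))
  # sign of t follows the sign of the mean difference
  expect_lt(tm$t[1, 2, 3], 0)
  expect_gt(tmap(pb, pa)$t[1, 2, 3], 0)
  expect_error(tmap(pa[1, , , , drop = FALSE], pb), "2 trials")
})

test_that("cluster formation respects 4-connectivity and sign", {
  df <- 10
  thr <- qt(0.975, df)
  tm <- matrix(0, 5, 5)
  tm[2, 2] <- thr + 1
  cl <- form_clusters(tm, df)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_cells, 1)
  expect_equal(cl$mass, thr + 1)
  # diagonal cells are separate clusters
  tm2 <- matrix(0, 5, 5)
  tm2[2, 2] <- thr + 1; tm2[3, 3] <- thr + 1
  expect_equal(nrow(form_clusters(tm2, df)), 2)
  # a 3x3 supra-threshold block with an opposite-sign centre splits by sign
  tm3 <- matrix(0, 5, 5)
  tm3[2:4, 2:4] <- thr + 1
  tm3[3, 3] <- -(thr + 1)
  cl3 <- form_clusters(tm3, df)
  expect_equal(nrow(cl3), 2)
  expect_equal(sort(cl3$sign), c(-1, 1))
  # R flood-fill oracle for the component count of the positive part
  count_components <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask)); k <- 0L
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || lab[i, j]) next
      k <- k + 1L
      q <- list(c(i, j)); lab[i, j] <- k
      while (length(q)) {
        c0 <- q[[1]]; q <- q[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          p <- c0 + d
          if (all(p >= 1) && p[1] <= nrow(mask) && p[2] <= ncol(mask) &&
              mask[p[1], p[2]] && !lab[p[1], p[2]]) {
            lab[p[1], p[2]] <- k
            q <- c(q, list(p))
          }
        }
      }
    }
    k
  }
  expect_equal(sum(form_clusters(tm3, df)$sign == 1),
               count_components(tm3 > thr))
  # no supra-threshold cells: empty result
  expect_equal(nrow(form_clusters(matrix(0, 4, 4), df)), 0)
})

test_that("Monte-Carlo cluster p matches exhaustive 3-vs-3 enumeration", {
  grid <- tiny_grid(3, 4)
  set.seed(31)
  pa <- array(rnorm(3 * 1 * 3 * 4, mean = 1.5), c(3, 1, 3, 4))
  pb <- array(rnorm(3 * 1 * 3 * 4), c(3, 1, 3, 4))
  ta <- make_tfr_set(pa, grid)
  tb <- make_tfr_set(pb, grid)
  n_perm <- 4000
  res <- permutation_test(ta, tb, n_perm = n_perm, seed = 7)
  expect_gt(nrow(res$clusters), 0)
  # oracle: enumerate all choose(6,3) = 20 label assignments
  x <- array(NA_real_, c(6, 1, 3, 4))
  x[1:3, , , ] <- pa; x[4:6, , , ] <- pb
  thr <- qt(0.975, 4)
  all_max <- apply(combn(6, 3), 2, function(ix) {
    tm <- tmap(x[ix, , , , drop = FALSE],
               x[-ix, , , , drop = FALSE])
    cl <- form_clusters(matrix(tm$t[1, , ], 3, 4), 4)
    if (nrow(cl)) max(abs(cl$mass)) else 0
  })
  for (i in seq_len(nrow(res$clusters))) {
    p_exact <- mean(all_max >= abs(res$clusters$mass[i]))
    p_mc <- res$clusters$p[i]
    mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm) + 1 / n_perm
    expect_lt(abs(p_mc - p_exact), 2 * mc_se + 2 / n_perm)
  }
})

test_that("an overwhelming effect reaches the smallest attainable p", {
  grid <- tiny_grid(3, 4)
  set.seed(32)
  pa <- array(rnorm(8 * 1 * 3 * 4, mean = 50), c(8, 1, 3, 4))
  pb <- array(rnorm(8 * 1 * 3 * 4), c(8, 1, 3, 4))
  res <- permutation_test(make_tfr_set(pa, grid), make_tfr_set(pb, grid),
                          n_perm = 500, seed = 3)
  # no null replicate beats the observed mass; a replicate that happens to
  # redraw the observed labeling ties with it, so p is at most 2/(n+1)
  expect_lte(min(res$clusters$p), 2 / 501)
})

test_that("permuting trial order leaves observed clusters unchanged", {
  grid <- tiny_grid(3, 4)
  set.seed(33)
  pa <- array(rnorm(6 * 2 * 3 * 4, mean = 1), c(6, 2, 3, 4))
  pb <- array(rnorm(6 * 2 * 3 * 4), c(6, 2, 3, 4))
  r1 <- permutation_test(make_tfr_set(pa, grid), make_tfr_set(pb, grid),
                         n_perm = 200, seed = 5)
  perm <- sample(6)
  r2 <- permutation_test(make_tfr_set(pa[perm, , , , drop = FALSE], grid),
                         make_tfr_set(pb, grid), n_perm = 200, seed = 5)
  expect_equal(r1$clusters$mass, r2$clusters$mass)
  expect_equal(r1$clusters$channel, r2$clusters$channel)
})

test_that("scaling an injected effect up never raises its cluster p", {
  grid <- tiny_grid(3, 4)
  set.seed(34)
  noise_a <- array(rnorm(6 * 1 * 3 * 4), c(6, 1, 3, 4))
  noise_b <- array(rnorm(6 * 1 * 3 * 4), c(6, 1, 3, 4))
  effect <- array(0, c(6, 1, 3, 4)); effect[, 1, 2, 2:3] <- 1
  p_at <- vapply(c(1, 2.5, 6), function(s) {
    res <- permutation_test(make_tfr_set(noise_a + s * effect, grid),
                            make_tfr_set(noise_b, grid), n_perm = 300,
                            seed = 11)
    if (nrow(res$clusters)) min(res$clusters$p) else 1
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
})

test_that("cluster latencies are onset/peak relative to the 5th tone", {
  lat <- latency_estimates(list(times_s = c(0.90, 0.92, 1.10),
                                t = c(3, 7, 4)), 0.8)
  expect_equal(lat$onset_s, 0.10)
  expect_equal(lat$peak_s, 0.12)
  single <- latency_estimates(list(times_s = 0.96, t = 5), 0.8)
  expect_equal(single$onset_s, single$peak_s)
  expect_error(permutation_test(make_tfr_set(array(1, c(2, 1, 3, 4)),
                                             tiny_grid(3, 4)),
                                make_tfr_set(array(1, c(2, 1, 3, 4)),
                                             tiny_grid(3, 4)),
                                n_perm = 0), "n_perm")
})
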