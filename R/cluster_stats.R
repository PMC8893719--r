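#' Two-sample t map over channels, frequencies, and times
#'
#' Independent-sample t statistic at every (channel, frequency, time)
#' cell between two trial groups. Cells with zero variance in both
#' groups get t = 0; `NA` cells propagate.
#'
#' @param pow_a,pow_b power arrays (trials x channels x freqs x times)
#'   on identical grids, at least 2 trials each.
#' @param var_type `"pooled"` (classical equal-variance t) or
#'   `"welch"`.
#' @return list with `t` (channels x freqs x times array), `df`
#'   (degrees of freedom; for Welch an array), `n_a`, `n_b`.
#' @export
tmap <- function(pow_a, pow_b, var_type = c("pooled", "welch")) {
  var_type <- match.arg(var_type)
  na <- dim(pow_a)[1]; nb <- dim(pow_b)[1]
  if (na < 2 || nb < 2) stop("need at least 2 trials per group")
  stopifnot(all(dim(pow_a)[-1] == dim(pow_b)[-1]))
  ma <- colMeans(pow_a, dims = 1)
  mb <- colMeans(pow_b, dims = 1)
  va <- (colMeans(pow_a^2, dims = 1) - ma^2) * na / (na - 1)
  vb <- (colMeans(pow_b^2, dims = 1) - mb^2) * nb / (nb - 1)
  if (var_type == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  t[se == 0] <- 0  # zero variance in both groups
  list(t = t, df = df, n_a = na, n_b = nb)
}

#' Form signed 4-connected clusters on one channel's t map
#'
#' Supra-threshold cells (|t| above the two-sided critical value at
#' `cluster_alpha` for the given degrees of freedom) are partitioned
#' into maximal 4-connected components of uniform sign; a cluster's mass
#' is the sum of its t values.
#'
#' @param tmat freqs x times t-value matrix for one channel.
#' @param df degrees of freedom of the t statistics.
#' @param cluster_alpha two-sided cluster-forming level.
#' @return data.frame (one row per cluster): `sign`, `mass`, `n_cells`,
#'   `f_min_idx`, `f_max_idx`, `t_min_idx`, `t_max_idx`, `peak_t_idx`
#'   (time index of max |t|), plus a `cells` list column of cell index
#'   matrices.
#' @export
form_clusters <- function(tmat, df, cluster_alpha = 0.05) {
  thresh <- stats::qt(1 - cluster_alpha / 2, df)
  lab <- cluster_label_cpp(tmat, thresh)
  n <- length(lab$mass)
  if (n == 0) {
    return(data.frame(sign = integer(0), mass = numeric(0),
                      n_cells = integer(0), f_min_idx = integer(0),
                      f_max_idx = integer(0), t_min_idx = integer(0),
                      t_max_idx = integer(0), peak_t_idx = integer(0)))
  }
  out <- lapply(seq_len(n), function(i) {
    cells <- which(lab$labels == i, arr.ind = TRUE)
    tv <- tmat[cells]
    peak <- cells[which.max(abs(tv)), 2]
    df_row <- data.frame(sign = lab$sign[i], mass = lab$mass[i],
                         n_cells = nrow(cells),
                         f_min_idx = min(cells[, 1]),
                         f_max_idx = max(cells[, 1]),
                         t_min_idx = min(cells[, 2]),
                         t_max_idx = max(cells[, 2]),
                         peak_t_idx = peak)
    df_row$cells <- list(cells)
    df_row
  })
  do.call(rbind, out)
}

#' Onset and peak latency of a cluster relative to the 5th-tone slot
#'
#' Onset is the earliest cluster time minus the 5th-tone onset; peak is
#' the time of the maximum |t| within the cluster minus the 5th-tone
#' onset.
#'
#' @param cluster list with `times_s` (cluster cell times) and `t`
#'   (matching t values).
#' @param fifth_tone_onset_s 5th-tone slot onset in grid time, seconds.
#' @return list with `onset_s` and `peak_s`.
#' @export
latency_estimates <- function(cluster, fifth_tone_onset_s) {
  list(onset_s = min(cluster$times_s) - fifth_tone_onset_s,
       peak_s = cluster$times_s[which.max(abs(cluster$t))] -
         fifth_tone_onset_s)
}

#' Cluster-based permutation test of deviant vs standard TFRs
#'
#' Per channel, pointwise two-sample t statistics over the
#' frequency-time grid are thresholded at `cluster_alpha` (two-sided),
#' 4-connected same-sign clusters are formed, and each observed
#' cluster's |mass| (sum of t) is compared against a max-statistic null
#' distribution obtained by shuffling the trial labels `n_perm` times
#' (replicates without clusters contribute 0). Cluster
#' p = (1 + #{null >= |mass|}) / (n_perm + 1); correction is over
#' frequency and time within each channel.
#'
#' @param tfr_dev,tfr_std baseline-corrected `tfr_set`s on the same grid
#'   (deviant and standard trials).
#' @param n_perm number of label permutations (>= 1).
#' @param alpha cluster-corrected significance level.
#' @param cluster_alpha cluster-forming level.
#' @param var_type t-statistic variance handling, see [tmap()].
#' @param seed integer seed for the label shuffles.
#' @return A `cluster_result`: list with `clusters` (data.frame:
#'   channel, sign, mass, p, f_min_hz, f_max_hz, onset_s, peak_s,
#'   n_cells, cells), `tmap` (channels x freqs x times), `null_max`
#'   (n_perm x channels), `n_perm`, `alpha`, `cluster_alpha`,
#'   `responsive_channels`, `grid`, `channel_meta`.
#' @export
permutation_test <- function(tfr_dev, tfr_std, n_perm = 1000, alpha = 0.05,
                             cluster_alpha = 0.05,
                             var_type = c("pooled", "welch"), seed = 1L) {
  var_type <- match.arg(var_type)
  if (n_perm < 1) stop("n_perm must be >= 1")
  na <- dim(tfr_dev$power)[1]; nb <- dim(tfr_std$power)[1]
  if (na + nb < 4) stop("need at least 4 trials in total")
  grid <- tfr_dev$grid
  nch <- dim(tfr_dev$power)[2]
  nf <- length(grid$freqs_hz); nt <- length(grid$times_s)
  obs <- tmap(tfr_dev$power, tfr_std$power, var_type)
  thresh_df <- if (var_type == "pooled") obs$df else na + nb - 2
  n <- na + nb
  x <- array(NA_real_, c(n, nch, nf, nt))
  x[seq_len(na), , , ] <- tfr_dev$power
  x[na + seq_len(nb), , , ] <- tfr_std$power
  perm_ind <- with_seed(child_seed(seed, "perm_labels"), {
    t(vapply(seq_len(n_perm), function(p) {
      ind <- numeric(n)
      ind[sample.int(n, na)] <- 1
      ind
    }, numeric(n)))
  })
  thresh <- stats::qt(1 - cluster_alpha / 2, na + nb - 2)
  null_max <- matrix(0, n_perm, nch)
  for (ch in seq_len(nch)) {
    xc <- matrix(x[, ch, , ], n)                 # n x (nf*nt), f fastest
    s <- colSums(xc); q <- colSums(xc^2)
    s1 <- perm_ind %*% xc
    q1 <- perm_ind %*% xc^2
    m1 <- s1 / na
    m2 <- sweep(-s1, 2, s, "+") / nb
    ss1 <- q1 - na * m1^2
    ss2 <- sweep(-q1, 2, q, "+") - nb * m2^2
    se <- if (var_type == "pooled") {
      sqrt((ss1 + ss2) / (n - 2) * (1 / na + 1 / nb))
    } else {
      sqrt(ss1 / (na - 1) / na + ss2 / (nb - 1) / nb)
    }
    tp <- (m1 - m2) / se
    tp[se == 0] <- 0
    null_max[, ch] <- max_cluster_mass_cpp(tp, nf, nt, thresh)
  }
  clusters <- list()
  for (ch in seq_len(nch)) {
    cl <- form_clusters(matrix(obs$t[ch, , ], nf, nt),
                        if (length(thresh_df) > 1) na + nb - 2 else thresh_df,
                        cluster_alpha)
    if (!nrow(cl)) next
    cl$p <- vapply(cl$mass, function(m) {
      # tolerance: permutations reproducing the observed labeling tie
      # with the observed mass up to floating-point rounding
      (1 + sum(null_max[, ch] >= abs(m) * (1 - 1e-10))) / (n_perm + 1)
    }, numeric(1))
    cl$channel <- ch
    clusters[[length(clusters) + 1]] <- cl
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else NULL
  if (!is.null(clusters)) {
    clusters$f_min_hz <- grid$freqs_hz[clusters$f_min_idx]
    clusters$f_max_hz <- grid$freqs_hz[clusters$f_max_idx]
    lat <- lapply(seq_len(nrow(clusters)), function(i) {
      cells <- clusters$cells[[i]]
      latency_estimates(
        list(times_s = grid$times_s[cells[, 2]],
             t = obs$t[cbind(clusters$channel[i], cells)]),
        grid$fifth_tone_onset_s)
    })
    clusters$onset_s <- vapply(lat, `[[`, numeric(1), "onset_s")
    clusters$peak_s <- vapply(lat, `[[`, numeric(1), "peak_s")
    responsive <- sort(unique(clusters$channel[clusters$p < alpha]))
  } else {
    clusters <- data.frame(sign = integer(0), mass = numeric(0),
                           n_cells = integer(0), p = numeric(0),
                           channel = integer(0), f_min_hz = numeric(0),
                           f_max_hz = numeric(0), onset_s = numeric(0),
                           peak_s = numeric(0))
    responsive <- integer(0)
  }
  structure(list(clusters = clusters, tmap = obs$t, null_max = null_max,
                 n_perm = n_perm, alpha = alpha,
                 cluster_alpha = cluster_alpha,
                 responsive_channels = responsive, grid = grid,
                 channel_meta = tfr_dev$channel_meta,
                 n_dev = na, n_std = nb),
            class = "cluster_result")
}

#' Flat cluster table for reporting
#'
#' @param result a `cluster_result`.
#' @return data.frame: channel, sign, mass, p, f_min, f_max, onset_ms,
#'   peak_ms, n_cells.
#' @export
cluster_table <- function(result) {
  cl <- result$clusters
  data.frame(channel = cl$channel, sign = cl$sign, mass = cl$mass,
             p = cl$p, f_min = cl$f_min_hz, f_max = cl$f_max_hz,
             onset_ms = 1000 * cl$onset_s, peak_ms = 1000 * cl$peak_s,
             n_cells = cl$n_cells)
}
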