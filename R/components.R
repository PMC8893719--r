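#' Classification rules for significant clusters
#'
#' Defaults: PE1 = positive cluster entirely above `pe_band_min_hz`
#' peaking before `pe_boundary_s` after the 5th-tone slot; PE2 = same
#' but peaking at or after the boundary; PRED = negative cluster
#' overlapping `pred_band_hz` and lasting at least
#' `pred_min_duration_s`. The boundary sits between the early (~74 ms)
#' and late (~242 ms) gamma peaks.
#'
#' @param pe_band_min_hz minimum band floor for gamma (PE) clusters, Hz.
#' @param pe_boundary_s PE1/PE2 peak-latency boundary, seconds after the
#'   5th-tone slot.
#' @param pred_band_hz beta band that a PRED cluster must overlap, Hz.
#' @param pred_min_duration_s minimum PRED cluster duration, seconds.
#' @return list of rule parameters.
#' @export
component_rules <- function(pe_band_min_hz = 40, pe_boundary_s = 0.15,
                            pred_band_hz = c(12, 30),
                            pred_min_duration_s = 0.3) {
  list(pe_band_min_hz = pe_band_min_hz, pe_boundary_s = pe_boundary_s,
       pred_band_hz = pred_band_hz,
       pred_min_duration_s = pred_min_duration_s)
}

#' Classify significant clusters into PE1 / PE2 / PRED components
#'
#' Applies [component_rules()] to the significant clusters of a
#' [permutation_test()] result and returns one mask per detected
#' component: the significant channels and the union bounding windows in
#' frequency and time of the owning clusters. Clusters matching no rule
#' are labeled `OTHER` and retained in the `assignments` attribute.
#'
#' @param result a `cluster_result`.
#' @param rules a [component_rules()] list.
#' @return named list of `component_mask`s (`name`, `channels`,
#'   `freq_window_hz`, `time_window_s` in grid time), with the per-cluster
#'   assignment table attached as attribute `assignments`.
#' @export
classify_clusters <- function(result, rules = component_rules()) {
  cl <- result$clusters
  sig <- cl[cl$p < result$alpha, , drop = FALSE]
  grid <- result$grid
  if (!nrow(sig)) {
    out <- list()
    attr(out, "assignments") <- cbind(sig, component = character(0))
    return(out)
  }
  duration <- grid$times_s[sig$t_max_idx] - grid$times_s[sig$t_min_idx]
  label <- rep("OTHER", nrow(sig))
  is_gamma <- sig$sign > 0 & sig$f_min_hz >= rules$pe_band_min_hz
  label[is_gamma & sig$peak_s < rules$pe_boundary_s] <- "PE1"
  label[is_gamma & sig$peak_s >= rules$pe_boundary_s] <- "PE2"
  overlaps_beta <- sig$f_min_hz <= rules$pred_band_hz[2] &
    sig$f_max_hz >= rules$pred_band_hz[1]
  label[sig$sign < 0 & overlaps_beta &
          duration >= rules$pred_min_duration_s] <- "PRED"
  sig$component <- label
  masks <- lapply(setdiff(unique(label), "OTHER"), function(nm) {
    rows <- sig[sig$component == nm, ]
    structure(list(
      name = nm,
      channels = sort(unique(rows$channel)),
      freq_window_hz = c(min(rows$f_min_hz), max(rows$f_max_hz)),
      time_window_s = c(min(grid$times_s[rows$t_min_idx]),
                        max(grid$times_s[rows$t_max_idx]))),
      class = "component_mask")
  })
  names(masks) <- vapply(masks, `[[`, character(1), "name")
  attr(masks, "assignments") <- sig[, c("channel", "sign", "mass", "p",
                                        "f_min_hz", "f_max_hz", "onset_s",
                                        "peak_s", "component")]
  masks
}

mask_indices <- function(tfr, mask) {
  list(ch = mask$channels,
       f = which(tfr$grid$freqs_hz >= mask$freq_window_hz[1] &
                   tfr$grid$freqs_hz <= mask$freq_window_hz[2]),
       t = which(tfr$grid$times_s >= mask$time_window_s[1] &
                   tfr$grid$times_s <= mask$time_window_s[2]))
}

mode_product <- function(x, mode, u, v) {
  # <X, . (x) u (x) v> along the given mode of a 3-way array
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  dim(xp) <- c(dim(x)[perm][1], prod(dim(x)[perm][-1]))
  as.vector(xp %*% as.vector(outer(u, v)))
}

#' Fit a rank-1 spatio-spectro-temporal PARAFAC pattern
#'
#' Builds the 3-way tensor (mask channels x mask frequencies x mask
#' times) from the trial-averaged baseline-corrected power of the
#' selected trials and fits a rank-1 PARAFAC model by alternating least
#' squares with multiple seeded random restarts, keeping the best fit.
#' Loadings are unit-norm with sign pushed so that the frequency and
#' time loadings each sum to a nonnegative value.
#'
#' @param tfr a baseline-corrected `tfr_set`.
#' @param mask a `component_mask` from [classify_clusters()].
#' @param trial_sel logical or integer selector of the defining trials
#'   (default: all trials in `tfr`).
#' @param n_restarts number of random initializations.
#' @param tol relative fit-change convergence tolerance.
#' @param max_iter maximum ALS iterations per restart.
#' @param seed integer seed for the restarts.
#' @return A `component_model`: list with `mask`, `loadings` (`a`
#'   channel, `b` frequency, `c` time; unit-norm), `lambda` (pattern
#'   scale), `fit_quality` (explained-variance fraction), `converged`,
#'   `indices` (tensor indices into the TFR grid).
#' @export
fit_pattern <- function(tfr, mask, trial_sel = NULL, n_restarts = 10,
                        tol = 1e-8, max_iter = 200, seed = 1L) {
  idx <- mask_indices(tfr, mask)
  if (length(idx$ch) < 2 || length(idx$f) < 2 || length(idx$t) < 2) {
    stop("mask must span at least 2 entries along each tensor axis")
  }
  if (is.null(trial_sel)) trial_sel <- seq_len(dim(tfr$power)[1])
  sub <- tfr$power[trial_sel, idx$ch, idx$f, idx$t, drop = FALSE]
  x <- colMeans(sub, dims = 1, na.rm = TRUE)
  x[!is.finite(x)] <- 0
  normx2 <- sum(x^2)
  if (normx2 == 0) stop("degenerate all-zero tensor under the mask")
  best <- NULL
  with_seed(child_seed(seed, "parafac"), {
    for (r in seq_len(n_restarts)) {
      b <- stats::rnorm(dim(x)[2]); b <- b / sqrt(sum(b^2))
      cc <- stats::rnorm(dim(x)[3]); cc <- cc / sqrt(sum(cc^2))
      a <- rep(1 / sqrt(dim(x)[1]), dim(x)[1])
      lambda_old <- 0; converged <- FALSE
      for (it in seq_len(max_iter)) {
        a <- mode_product(x, 1, b, cc); a <- a / sqrt(sum(a^2))
        b <- mode_product(x, 2, a, cc); b <- b / sqrt(sum(b^2))
        cc <- mode_product(x, 3, a, b)
        lambda <- sqrt(sum(cc^2)); cc <- cc / lambda
        if (abs(lambda - lambda_old) <= tol * max(lambda, 1e-300)) {
          converged <- TRUE; break
        }
        lambda_old <- lambda
      }
      if (is.null(best) || lambda > best$lambda) {
        best <- list(a = a, b = b, c = cc, lambda = lambda,
                     converged = converged)
      }
    }
  })
  if (sum(best$b) < 0) { best$b <- -best$b; best$a <- -best$a }
  if (sum(best$c) < 0) { best$c <- -best$c; best$a <- -best$a }
  structure(list(mask = mask,
                 loadings = list(a = best$a, b = best$b, c = best$c),
                 lambda = best$lambda,
                 fit_quality = best$lambda^2 / normx2,
                 converged = best$converged, indices = idx),
            class = "component_model")
}

#' Per-trial scalar contributions of a fitted component
#'
#' Least-squares projection of each trial's masked TFR onto the fixed
#' rank-1 pattern: `<X_trial, P> / ||P||^2` with `P = a (x) b (x) c`,
#' excluding missing cells from both inner products. A trial with no
#' valid mask cells gets `NA`.
#'
#' @param tfr a baseline-corrected `tfr_set` (same grid the model was
#'   fitted on).
#' @param model a `component_model`.
#' @return numeric vector, one contribution per trial in `tfr`.
#' @export
trial_contributions <- function(tfr, model) {
  idx <- model$indices
  p <- outer(model$loadings$a,
             as.vector(outer(model$loadings$b, model$loadings$c)))
  pv <- as.vector(p)
  sub <- tfr$power[, idx$ch, idx$f, idx$t, drop = FALSE]
  ntr <- dim(sub)[1]
  m <- matrix(sub, nrow = ntr)
  vapply(seq_len(ntr), function(i) {
    xi <- m[i, ]
    ok <- is.finite(xi)
    if (!any(ok)) return(NA_real_)
    sum(xi[ok] * pv[ok]) / sum(pv[ok]^2)
  }, numeric(1))
}
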