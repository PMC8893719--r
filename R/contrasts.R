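#' Built-in condition contrasts
#'
#' The six comparisons orchestrated by the pipeline:
#' `local_novelty` — conjunction of (xY|xx vs xx|xx) and (xY|xY vs
#' xx|xY), the tone-level mismatch present in both tasks;
#' `global_only` — xx|xY vs xY|xY, a sequence-level violation without a
#' tone-level one; `local_and_global` — xY|xx vs xx|xx, violating both
#' levels; `omission_xx` / `omission_xY` — rare omissions against the
#' expected omissions of a dedicated xxxx block; `omission_diff` —
#' x_|xY vs x_|xx.
#'
#' @param name one of the six contrast names.
#' @return A `contrast_spec`: list with `name`, `combine` (`"single"`
#'   or `"conjunction"`), and `sub`, a list of `(group_a, group_b)`
#'   condition pairs.
#' @export
contrast_spec <- function(name) {
  sub <- switch(
    name,
    local_novelty = list(c("xY|xx", "xx|xx"), c("xY|xY", "xx|xY")),
    global_only = list(c("xx|xY", "xY|xY")),
    local_and_global = list(c("xY|xx", "xx|xx")),
    omission_xx = list(c("x_|xx", "xxxx_expected")),
    omission_xY = list(c("x_|xY", "xxxx_expected")),
    omission_diff = list(c("x_|xY", "x_|xx")),
    stop("unknown contrast '", name, "'; valid contrasts: local_novelty, ",
         "global_only, local_and_global, omission_xx, omission_xY, ",
         "omission_diff"))
  structure(list(name = name,
                 combine = if (length(sub) > 1) "conjunction" else "single",
                 sub = sub),
            class = "contrast_spec")
}

#' Extract the trials of one condition from a TFR set
#'
#' Habituation trials are excluded: statistics are computed on the
#' testing period only.
#'
#' @param tfr a `tfr_set`.
#' @param condition condition label.
#' @return The subsetted `tfr_set`; errors if no trial matches.
#' @export
condition_tfr <- function(tfr, condition) {
  sel <- tfr$trial_meta$condition == condition &
    tfr$trial_meta$role != "habituation"
  if (!any(sel)) stop("no testing-period trials with condition '",
                      condition, "'")
  subset_trials(tfr, sel)
}

#' Pool TFR sets across recording runs
#'
#' Concatenates trials of several runs, restricted to the channels (by
#' name) retained in every run. Adds a `run` column to the pooled trial
#' metadata.
#'
#' @param tfrs list of `tfr_set`s on identical grids.
#' @return A pooled `tfr_set`.
#' @export
pool_tfrs <- function(tfrs) {
  if (length(tfrs) == 1) {
    tfrs[[1]]$trial_meta$run <- 1L
    return(tfrs[[1]])
  }
  common <- Reduce(intersect, lapply(tfrs, function(x) x$channel_meta$name))
  if (!length(common)) stop("no channel retained in every run")
  parts <- lapply(seq_along(tfrs), function(i) {
    x <- tfrs[[i]]
    keep <- match(common, x$channel_meta$name)
    x$power <- x$power[, keep, , , drop = FALSE]
    x$channel_meta <- x$channel_meta[keep, ]
    x$trial_meta$run <- i
    x
  })
  out <- parts[[1]]
  out$power <- do.call(abind1, lapply(parts, `[[`, "power"))
  out$trial_meta <- do.call(rbind, lapply(parts, `[[`, "trial_meta"))
  out
}

abind1 <- function(...) {
  arrays <- list(...)
  d <- dim(arrays[[1]])
  total <- sum(vapply(arrays, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(total, d[-1]))
  at <- 0
  for (a in arrays) {
    out[at + seq_len(dim(a)[1]), , , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Run one condition contrast
#'
#' Single contrasts run one [permutation_test()]; conjunctions run every
#' sub-contrast and declare a channel responsive only when it owns
#' significant same-sign clusters in all of them (significant-channel
#' intersection; the formal conjunction inference of the imaging
#' literature transplanted to channel space, flagged as such in the
#' bundle).
#'
#' @param spec a [contrast_spec()].
#' @param tfr_by_condition named list mapping condition labels to
#'   baseline-corrected `tfr_set`s.
#' @param n_perm,alpha,cluster_alpha,var_type,seed see
#'   [permutation_test()].
#' @return For single contrasts a `cluster_result`; for conjunctions a
#'   `conjunction_result` (list `sub_results`, `responsive_channels`).
#' @export
run_contrast <- function(spec, tfr_by_condition, n_perm = 1000,
                         alpha = 0.05, cluster_alpha = 0.05,
                         var_type = "pooled", seed = 1L) {
  results <- lapply(seq_along(spec$sub), function(i) {
    pair <- spec$sub[[i]]
    for (cond in pair) {
      if (is.null(tfr_by_condition[[cond]])) {
        stop("contrast '", spec$name, "' needs condition '", cond,
             "' but no trials were provided for it")
      }
    }
    permutation_test(tfr_by_condition[[pair[1]]],
                     tfr_by_condition[[pair[2]]],
                     n_perm = n_perm, alpha = alpha,
                     cluster_alpha = cluster_alpha, var_type = var_type,
                     seed = child_seed(seed, paste0(spec$name, "_", i)))
  })
  if (spec$combine == "single") return(results[[1]])
  signed_responsive <- lapply(results, function(r) {
    sig <- r$clusters[r$clusters$p < r$alpha, , drop = FALSE]
    unique(paste(sig$channel, sig$sign))
  })
  common <- Reduce(intersect, signed_responsive)
  responsive <- sort(unique(as.integer(
    vapply(strsplit(common, " "), `[[`, character(1), 1))))
  structure(list(sub_results = results, responsive_channels = responsive,
                 name = spec$name),
            class = "conjunction_result")
}
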