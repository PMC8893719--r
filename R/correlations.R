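#' Pearson correlation between two components within the same trials
#'
#' Pairwise-deletes missing contributions; with fewer than 3 complete
#' pairs the coefficient is reported but the p value is undefined.
#'
#' @param contrib_a,contrib_b per-trial contribution vectors indexed by
#'   the same trials.
#' @param pair name of the tested pair (free-text label).
#' @param trial_type condition context (label only).
#' @return A `correlation_report`: one-row data.frame with `pair`,
#'   `mode`, `trial_type`, `n`, `r`, `p`.
#' @export
within_trial_corr <- function(contrib_a, contrib_b, pair = "A~B",
                              trial_type = NA_character_) {
  stopifnot(length(contrib_a) == length(contrib_b))
  ok <- is.finite(contrib_a) & is.finite(contrib_b)
  n <- sum(ok)
  if (n >= 3) {
    ct <- stats::cor.test(contrib_a[ok], contrib_b[ok])
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- if (n == 2) stats::cor(contrib_a[ok], contrib_b[ok]) else NA_real_
    p <- NA_real_
  }
  data.frame(pair = pair, mode = "within_trial", trial_type = trial_type,
             n = n, r = r, p = p)
}

#' Pair each deviant trial with the immediately following standard
#'
#' A deviant is paired with the next trial iff that trial is a standard
#' in the same block; unpaired deviants are dropped (and reported in the
#' `dropped` attribute).
#'
#' @param meta a trial metadata data.frame (columns `trial_index`,
#'   `block`, `role`), ordered by presentation.
#' @return data.frame with columns `deviant_idx`, `next_standard_idx`
#'   (values of `trial_index`); dropped deviants in attribute
#'   `dropped`.
#' @export
pair_deviant_to_next <- function(meta) {
  meta <- meta[order(meta$trial_index), ]
  dev_pos <- which(meta$role == "deviant")
  ok <- dev_pos + 1 <= nrow(meta) &
    meta$role[pmin(dev_pos + 1, nrow(meta))] == "standard" &
    meta$block[pmin(dev_pos + 1, nrow(meta))] == meta$block[dev_pos]
  pairs <- data.frame(deviant_idx = meta$trial_index[dev_pos[ok]],
                      next_standard_idx = meta$trial_index[dev_pos[ok] + 1])
  attr(pairs, "dropped") <- meta$trial_index[dev_pos[!ok]]
  pairs
}

#' Correlation of the prediction depth on deviants with prediction-error
#' amplitude on the following standards
#'
#' The electrode-set rule mirrors the pairing used in the analysis: a
#' frontal prediction component is correlated with PE contributions from
#' all significant gamma electrodes (`frontal_pred_vs_all_pe`), while an
#' auditory prediction component is correlated with PE contributions
#' from auditory significant gamma electrodes only
#' (`auditory_pred_vs_auditory_pe`). The caller supplies contribution
#' vectors already computed under the corresponding electrode masks;
#' this function validates the rule, aligns the deviant/post-deviant
#' pairs, and reports the Pearson correlation.
#'
#' @param pred_on_deviants named numeric vector of PRED contributions,
#'   names = deviant `trial_index`.
#' @param pe_on_standards named numeric vector of PE contributions,
#'   names = standard `trial_index`.
#' @param pairs pairing table from [pair_deviant_to_next()].
#' @param electrode_rule `"frontal_pred_vs_all_pe"` or
#'   `"auditory_pred_vs_auditory_pe"`.
#' @param pair label of the tested component pair.
#' @param trial_type condition context label.
#' @return A `correlation_report` row (`mode = "across_trial"`, with the
#'   electrode rule recorded).
#' @export
across_trial_corr <- function(pred_on_deviants, pe_on_standards, pairs,
                              electrode_rule = c(
                                "frontal_pred_vs_all_pe",
                                "auditory_pred_vs_auditory_pe"),
                              pair = "PRED~PE",
                              trial_type = NA_character_) {
  electrode_rule <- match.arg(electrode_rule)
  if (!length(pred_on_deviants) || !length(pe_on_standards)) {
    stop("empty electrode set under rule '", electrode_rule, "'")
  }
  a <- pred_on_deviants[as.character(pairs$deviant_idx)]
  b <- pe_on_standards[as.character(pairs$next_standard_idx)]
  out <- within_trial_corr(unname(a), unname(b), pair = pair,
                           trial_type = trial_type)
  out$mode <- "across_trial"
  out$electrode_rule <- electrode_rule
  out
}

#' Restrict a component mask to one set of ROIs
#'
#' @param mask a `component_mask`.
#' @param channel_meta the channel table (columns `name`, `roi`) indexed
#'   like the mask's channels.
#' @param rois ROI labels to keep.
#' @return The restricted mask; errors if no channel survives.
#' @export
restrict_mask_rois <- function(mask, channel_meta, rois) {
  keep <- mask$channels[channel_meta$roi[mask$channels] %in% rois]
  if (!length(keep)) {
    stop("no '", mask$name, "' channels left after restricting to ROIs: ",
         paste(rois, collapse = ", "))
  }
  mask$channels <- keep
  mask
}
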