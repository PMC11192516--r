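# N400 analysis: per-subject condition ERPs, ROI window-mean congruency
# contrasts, and point-wise paired contrasts with Benjamini-Hochberg FDR
# over the joint electrode x time family. Inference is subject-level
# (paired across subjects), and window means use half-open [start, end)
# sample selections, consistent with the epoching convention.

#' Per-condition ERPs for one subject
#'
#' Averages retained epochs within each condition.
#'
#' @param es An `epoch_set` whose condition labels distinguish the
#'   experimental conditions (e.g. `"congruent"` / `"incongruent"`).
#' @param conditions Conditions that must be present (default both
#'   congruency conditions).
#' @return A `subject_erps` list: `erp` (named list of channels x samples
#'   matrices), `n_epochs`, `channel_labels`, `fs_hz`, `t0_offset_s`.
#' @export
condition_erps <- function(es, conditions = c("congruent", "incongruent")) {
  erp <- list(); n_ep <- integer()
  for (cond in conditions) {
    keep <- which(es$retained & es$conditions == cond)
    if (!length(keep))
      stop_entrainr("missing_condition",
                    paste("no retained epochs for condition", cond))
    m <- colMeans(es$data[keep, , , drop = FALSE])
    rownames(m) <- es$channel_labels
    erp[[cond]] <- m
    n_ep[[cond]] <- length(keep)
  }
  structure(list(erp = erp, n_epochs = n_ep,
                 channel_labels = es$channel_labels, fs_hz = es$fs_hz,
                 t0_offset_s = es$t0_offset_s),
            class = "subject_erps")
}

erp_time_axis <- function(se) {
  se$t0_offset_s + (seq_len(ncol(se$erp[[1]])) - 1L) / se$fs_hz
}

# per-subject ROI x window mean for one condition
roi_window_mean <- function(se, roi_idx, sel, cond) {
  mean(se$erp[[cond]][roi_idx, sel, drop = FALSE])
}

#' Per-subject ROI window means
#'
#' ROI-channel and time-window average of each condition's ERP for a
#' single subject, plus their difference (`deviant - reference`).
#'
#' @inheritParams roi_window_effect
#' @param se A `subject_erps`.
#' @return Named list: per-condition means (uV) and `effect_uv`.
#' @export
roi_window_means <- function(se, roi_labels = roi_channels(),
                             win_ms = c(300, 500),
                             conditions = c("congruent", "incongruent")) {
  roi_idx <- match(roi_labels, se$channel_labels)
  if (anyNA(roi_idx))
    stop_entrainr("missing_channel",
                  paste("ROI channels absent:",
                        paste(roi_labels[is.na(roi_idx)], collapse = ", ")))
  t_ms <- erp_time_axis(se) * 1000
  sel <- t_ms >= win_ms[1] & t_ms < win_ms[2]
  if (!any(sel)) stop_entrainr("empty_window", "window contains no samples")
  out <- lapply(conditions, roi_window_mean, se = se, roi_idx = roi_idx,
                sel = sel)
  names(out) <- conditions
  out$effect_uv <- out[[conditions[2]]] - out[[conditions[1]]]
  out
}

#' ROI window-mean congruency effect
#'
#' For every subject, averages each condition's ERP over the ROI channels
#' and the time window, then tests the incongruent-minus-congruent
#' difference across subjects with a two-tailed paired t test and reports
#' the 95 % confidence interval of the mean difference.
#'
#' @param erps_list List of `subject_erps`, one per subject.
#' @param roi_labels ROI channel labels (default [roi_channels()]).
#' @param win_ms Length-2 window in ms, half-open (default `c(300, 500)`).
#' @param conditions Length-2 conditions: `c(reference, deviant)`; the
#'   effect is `deviant - reference`.
#' @return An `erp_effect` list: `window_ms`, per-subject condition means,
#'   `effect_uv`, `mean_effect_uv`, `t_statistic`, `df`, `p_two_tailed`,
#'   `ci95`.
#' @export
roi_window_effect <- function(erps_list, roi_labels = roi_channels(),
                              win_ms = c(300, 500),
                              conditions = c("congruent", "incongruent")) {
  se1 <- erps_list[[1]]
  roi_idx <- match(roi_labels, se1$channel_labels)
  if (anyNA(roi_idx))
    stop_entrainr("missing_channel",
                  paste("ROI channels absent:",
                        paste(roi_labels[is.na(roi_idx)], collapse = ", ")))
  t_ms <- erp_time_axis(se1) * 1000
  sel <- t_ms >= win_ms[1] & t_ms < win_ms[2]
  if (!any(sel)) stop_entrainr("empty_window", "window contains no samples")
  ref <- vapply(erps_list, roi_window_mean, 0, roi_idx = roi_idx,
                sel = sel, cond = conditions[1])
  dev <- vapply(erps_list, roi_window_mean, 0, roi_idx = roi_idx,
                sel = sel, cond = conditions[2])
  tt <- paired_t(dev, ref, alternative = "two.sided")
  structure(list(window_ms = win_ms, reference_uv = ref, deviant_uv = dev,
                 effect_uv = dev - ref, mean_effect_uv = tt$mean_diff,
                 t_statistic = tt$t, df = tt$df, p_two_tailed = tt$p,
                 ci95 = tt$ci95),
            class = "erp_effect")
}

#' @export
print.erp_effect <- function(x, ...) {
  cat(sprintf("ROI effect %g-%g ms: %.3f uV, t(%d) = %.2f, p = %.4g, CI95 = [%.2f, %.2f]\n",
              x$window_ms[1], x$window_ms[2], x$mean_effect_uv, x$df,
              x$t_statistic, x$p_two_tailed, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Point-wise congruency map with FDR correction
#'
#' Paired t test at every (electrode, sample) across subjects, with
#' Benjamini-Hochberg control at level `q` over the joint electrode x
#' time family.
#'
#' @param erps_list List of `subject_erps`.
#' @param q FDR level (default 0.05).
#' @param conditions Length-2 conditions (`deviant - reference`).
#' @return A `pointwise_map` list: `t`, `p`, `mask` (channels x samples),
#'   `times_s`, `channel_labels`, `q`.
#' @export
pointwise_fdr_map <- function(erps_list, q = 0.05,
                              conditions = c("congruent", "incongruent")) {
  if (length(erps_list) < 2L)
    stop_entrainr("bad_spec", "need at least two subjects")
  nsub <- length(erps_list)
  dims <- dim(erps_list[[1]]$erp[[1]])
  diffs <- vapply(erps_list,
                  function(se) se$erp[[conditions[2]]] - se$erp[[conditions[1]]],
                  matrix(0, dims[1], dims[2]))
  m <- rowMeans(diffs, dims = 2)
  s <- sqrt(pmax(rowSums((diffs - as.vector(m))^2, dims = 2), 0) /
              (nsub - 1))
  tmat <- m / (s / sqrt(nsub))
  tmat[s == 0] <- 0
  pmat <- 2 * stats::pt(-abs(tmat), df = nsub - 1L)
  mask <- matrix(bh_fdr(as.vector(pmat), q), dims[1], dims[2])
  structure(list(t = tmat, p = pmat, mask = mask,
                 times_s = erp_time_axis(erps_list[[1]]),
                 channel_labels = erps_list[[1]]$channel_labels, q = q),
            class = "pointwise_map")
}

#' Earliest sustained FDR-significant time on a channel subset
#'
#' Returns the onset of the first run of at least `min_run_ms` of
#' consecutive significant samples (on any of the scanned channels).
#' Requiring a sustained run guards against the isolated false positives
#' that FDR control tolerates by design.
#'
#' @param map A `pointwise_map`.
#' @param roi_labels Channel labels to scan (default [roi_channels()]).
#' @param after_s Only consider times at or after this point (default 0,
#'   the lock event).
#' @param min_run_ms Minimum run length in ms (default 20).
#' @return Earliest sustained significant time in seconds, or `NA` if
#'   none.
#' @export
earliest_significant_time <- function(map, roi_labels = roi_channels(),
                                      after_s = 0, min_run_ms = 20) {
  idx <- match(intersect(roi_labels, map$channel_labels),
               map$channel_labels)
  if (!length(idx))
    stop_entrainr("missing_channel", "no ROI channels in the map")
  sig <- apply(map$mask[idx, , drop = FALSE], 2L, any)
  sig <- sig & map$times_s >= after_s
  need <- max(1L, round(min_run_ms / 1000 * diff(map$times_s[1:2])^-1))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(NA_real_)
  map$times_s[starts[min(ok)]]
}
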