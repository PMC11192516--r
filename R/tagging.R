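# Evoked power analysis: trial-averaged ("evoked") spectra, neighbor-bin
# normalization, and the group-level one-tailed peak test at the tagged
# sentential/phrasal/syllabic bins. Because every tagged rate completes an
# integer number of cycles in the analysis epoch, no taper is applied and
# spectral leakage is structurally zero. The DC bin is excluded from all
# statistics; dB conversion precedes neighbor subtraction (a difference in
# dB is a power ratio).

#' Trial-averaged (evoked) activity
#'
#' @param es An `epoch_set` with at least one retained epoch.
#' @return Channels x samples matrix: the mean over retained epochs.
#' @export
evoked_average <- function(es) {
  keep <- which(es$retained)
  if (!length(keep))
    stop_entrainr("no_retained_epochs", "no retained epochs to average")
  avg <- colMeans(es$data[keep, , , drop = FALSE])
  rownames(avg) <- es$channel_labels
  avg
}

#' Evoked power spectrum
#'
#' One-sided DFT amplitude spectrum of the trial-averaged signal. For a
#' non-DC bin `k` the power is `(2 * |X_k| / N)^2` (so a unit-amplitude
#' sinusoid that tiles the epoch yields exactly 1 uV^2), converted to
#' decibels as `10 * log10(power / 1 uV^2)`. Bin `k` sits at `k / T` Hz
#' where `T` is the epoch duration; the DC bin is dropped.
#'
#' @param avg Channels x samples matrix from [evoked_average()].
#' @param fs_hz Sampling rate in Hz.
#' @param spec Optional [paradigm_spec()]; when given, the sample count
#'   must equal the paradigm epoch length.
#' @return A `spectrum_set` with `frequencies` (Hz), `power_uv2`,
#'   `power_db` (channels x bins), and `channel_labels`.
#' @export
evoked_power <- function(avg, fs_hz, spec = NULL) {
  avg <- as.matrix(avg)
  n <- ncol(avg)
  if (!is.null(spec)) {
    expect <- round(epoch_duration(spec) * fs_hz)
    if (n != expect)
      stop_entrainr("length_mismatch",
                    sprintf("expected %d samples for the paradigm epoch, got %d",
                            expect, n))
  }
  nb <- floor(n / 2)
  X <- t(stats::mvfft(t(avg)))
  amp <- 2 * Mod(X[, 1L + seq_len(nb), drop = FALSE]) / n
  if (n %% 2L == 0L) amp[, nb] <- amp[, nb] / 2   # Nyquist bin is unpaired
  power <- amp^2
  structure(list(frequencies = seq_len(nb) * fs_hz / n,
                 power_uv2 = power,
                 power_db = 10 * log10(pmax(power, .Machine$double.xmin)),
                 normalized_db = NULL,
                 channel_labels = rownames(avg) %||%
                   paste0("ch", seq_len(nrow(avg)))),
            class = "spectrum_set")
}

#' Neighbor-bin normalization of a spectrum
#'
#' Subtracts, per channel and bin, the mean dB power of the `k` flanking
#' bins on each side (four bins for the default `k = 2`), removing the
#' local noise floor. Boundary bins lacking a full neighbor set are `NA`.
#'
#' @param ss A `spectrum_set` from [evoked_power()].
#' @param k Neighbors per side (default 2).
#' @return The `spectrum_set` with `normalized_db` filled.
#' @export
neighbor_normalize <- function(ss, k = 2L) {
  p <- ss$power_db
  nbin <- ncol(p)
  # centered moving sum over 2k+1 bins; subtracting the center leaves the
  # neighbor sum, NA at the boundaries by construction
  win <- rep(1, 2 * k + 1)
  S <- t(apply(p, 1L, function(row)
    as.numeric(stats::filter(row, win, sides = 2))))
  if (nrow(p) == 1L) S <- matrix(S, 1L, nbin)
  ss$normalized_db <- p - (S - p) / (2 * k)
  ss
}

#' Per-subject peak and neighbor-mean power
#'
#' Averages `power_db` over the retained electrode set, then reads the
#' value at the tagged bin and the mean over its `2 * k` neighbors. The
#' pair feeds the group-level paired test.
#'
#' @param ss A `spectrum_set`.
#' @param rate_bin Tagged bin index (see [bin_index()]).
#' @param electrodes Optional label subset; default all channels.
#' @param k Neighbors per side (default 2).
#' @return Named numeric vector `c(peak_db, neighbor_db)`.
#' @export
subject_peak_pair <- function(ss, rate_bin, electrodes = NULL, k = 2L) {
  sel <- if (is.null(electrodes)) seq_along(ss$channel_labels) else {
    idx <- match(electrodes, ss$channel_labels)
    if (anyNA(idx))
      stop_entrainr("missing_channel",
                    paste("electrodes absent from spectrum:",
                          paste(electrodes[is.na(idx)], collapse = ", ")))
    idx
  }
  nbin <- ncol(ss$power_db)
  if (rate_bin < 1L || rate_bin > nbin || rate_bin - k < 1L ||
      rate_bin + k > nbin)
    stop_entrainr("undefined_bin",
                  sprintf("bin %d lacks %d valid neighbors per side", rate_bin, k))
  spec_db <- colMeans(ss$power_db[sel, , drop = FALSE])
  c(peak_db = spec_db[[rate_bin]],
    neighbor_db = mean(spec_db[neighbor_bins(rate_bin, k)]))
}

#' Group-level peak test at a tagged rate
#'
#' One-tailed paired t test across subjects of peak-bin power against the
#' mean power of the flanking bins, with the directional alternative that
#' the peak exceeds its neighbors. With zero variance the p value reflects
#' the common sign of the differences (0 if all positive, 1 if all
#' negative, 0.5 if all zero).
#'
#' @param peak_db Per-subject peak power (dB).
#' @param neighbor_db Per-subject neighbor-mean power (dB).
#' @param alternative `"greater"` (peak > neighbors, default) or
#'   `"two.sided"`.
#' @param alpha Significance level (default 0.05).
#' @param rate Optional rate label carried into the result.
#' @return A `peak_test_result` list: `rate`, `t_statistic`, `df`,
#'   `p_value`, `mean_diff_db`, `significant`, `peak_db`, `neighbor_db`.
#' @export
group_peak_test <- function(peak_db, neighbor_db, alternative = "greater",
                            alpha = 0.05, rate = NA_character_) {
  if (length(peak_db) != length(neighbor_db))
    stop_entrainr("length_mismatch", "peak and neighbor vectors differ in length")
  n <- length(peak_db)
  if (n < 2L) stop_entrainr("bad_spec", "need at least two subjects")
  d <- peak_db - neighbor_db
  if (stats::sd(d) == 0) {
    p <- if (all(d > 0)) 0 else if (all(d < 0)) 1 else 0.5
    tval <- if (all(d == 0)) 0 else sign(mean(d)) * Inf
  } else {
    tt <- stats::t.test(peak_db, neighbor_db, paired = TRUE,
                        alternative = alternative)
    tval <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(rate = rate, t_statistic = tval, df = n - 1L,
                 p_value = p, mean_diff_db = mean(d),
                 significant = p < alpha,
                 peak_db = peak_db, neighbor_db = neighbor_db),
            class = "peak_test_result")
}

#' @export
print.peak_test_result <- function(x, ...) {
  cat(sprintf("peak test [%s]: t(%d) = %.3f, one-tailed p = %.4g, mean diff = %.2f dB%s\n",
              x$rate, x$df, x$t_statistic, x$p_value, x$mean_diff_db,
              if (x$significant) " *" else ""))
  invisible(x)
}
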