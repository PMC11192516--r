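# Preprocessing shared by the tagging and ERP analyses: zero-phase FIR
# band-pass filtering, re-referencing, channel exclusion/interpolation,
# event-locked epoching, amplitude-threshold artifact rejection, and
# baseline correction. Sample windows are half-open [start, end) and
# event indices are 0-based throughout.

# --- FIR design and application -------------------------------------------

# Hamming-windowed sinc band-pass. Order ceil(3.3 / (tw / fs)) with
# transition width tw = min(lo, 0.1 * hi); cutoffs sit at the band edges
# (half-amplitude points). Applied forward-backward for zero net phase.
design_fir_bandpass <- function(lo_hz, hi_hz, fs_hz) {
  tw <- min(lo_hz, 0.1 * hi_hz)
  order <- ceiling(3.3 / (tw / fs_hz))
  if (order %% 2L == 1L) order <- order + 1L
  n <- order + 1L
  m <- seq_len(n) - 1L - order / 2
  sinc <- function(fc) {
    h <- 2 * fc / fs_hz * ifelse(m == 0, 1,
                                 sin(2 * pi * fc / fs_hz * m) /
                                   (2 * pi * fc / fs_hz * m))
    h
  }
  h <- sinc(hi_hz) - sinc(lo_hz)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / order)
  h * w
}

# Zero-phase application: the forward-backward cascade of a linear-phase
# FIR equals a single circular convolution with the squared-magnitude
# response, so all channels are filtered in one FFT batch with edge
# reflection absorbing the transients. x is channels x samples.
apply_fir_zerophase <- function(x, h) {
  n <- ncol(x); m <- length(h)
  pad <- min(m, n - 1L)
  xp <- cbind(x[, pad:1 + 1L, drop = FALSE], x,
              x[, n - seq_len(pad), drop = FALSE])
  nfft <- stats::nextn(ncol(xp) + 2L * m, c(2L, 3L, 5L))
  X <- stats::mvfft(rbind(t(xp), matrix(0, nfft - ncol(xp), nrow(x))))
  H2 <- Mod(stats::fft(c(h, numeric(nfft - m))))^2
  y <- Re(stats::mvfft(X * H2, inverse = TRUE)) / nfft
  t(y[pad + seq_len(n), , drop = FALSE])
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed sinc design applied forward-backward (zero net phase)
#' to every channel. The transition width is `min(lo_hz, 0.1 * hi_hz)` and
#' the order follows the 3.3/(transition width / fs) rule, so passband gain
#' is within 1 % of unity and stopband attenuation exceeds 40 dB one
#' transition width beyond the band edges.
#'
#' @param rec An `eeg_recording`.
#' @param lo_hz High-pass edge in Hz (0 < `lo_hz` < `hi_hz`).
#' @param hi_hz Low-pass edge in Hz (< Nyquist).
#' @return The filtered recording.
#' @export
fir_bandpass <- function(rec, lo_hz, hi_hz) {
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < rec$fs_hz / 2))
    stop_entrainr("bad_band",
                  sprintf("need 0 < lo (%g) < hi (%g) < fs/2 (%g)",
                          lo_hz, hi_hz, rec$fs_hz / 2))
  h <- design_fir_bandpass(lo_hz, hi_hz, rec$fs_hz)
  out <- rec
  out$data <- apply_fir_zerophase(rec$data, h)
  dimnames(out$data) <- dimnames(rec$data)
  out
}

# --- referencing and channel bookkeeping ----------------------------------

#' Re-reference a recording
#'
#' `common_average` subtracts the instantaneous mean over all channels from
#' every channel; `linked_mastoids` subtracts the mean of the two named
#' mastoid channels.
#'
#' @param rec An `eeg_recording`.
#' @param scheme `"common_average"` or `"linked_mastoids"`.
#' @param mastoid_labels Two channel labels (linked-mastoid scheme only).
#' @return The re-referenced recording.
#' @export
rereference <- function(rec, scheme = c("common_average", "linked_mastoids"),
                        mastoid_labels = c("TP9", "TP10")) {
  scheme <- match.arg(scheme)
  out <- rec
  if (scheme == "common_average") {
    ref <- colMeans(rec$data)
  } else {
    idx <- match(mastoid_labels, rec$channel_labels)
    if (anyNA(idx))
      stop_entrainr("missing_channel",
                    paste("mastoid channels absent:",
                          paste(mastoid_labels[is.na(idx)], collapse = ", ")))
    ref <- colMeans(rec$data[idx, , drop = FALSE])
  }
  out$data <- sweep(rec$data, 2L, ref, "-")
  out
}

#' Drop channels from a recording
#'
#' Used for the fixed exclusion of temporally noisy channels (T7, T8, TP7,
#' TP8) and of designated frontal channels standing in for ocular-artifact
#' removal. Labels absent from the recording are ignored.
#'
#' @param rec An `eeg_recording`.
#' @param labels Channel labels to remove.
#' @return The reduced recording.
#' @export
drop_channels <- function(rec, labels) {
  keep <- !(rec$channel_labels %in% labels)
  if (all(keep)) return(rec)
  out <- rec
  out$data <- rec$data[keep, , drop = FALSE]
  out$channel_labels <- rec$channel_labels[keep]
  out
}

# --- Delaunay neighbors and interpolation ---------------------------------

# Brute-force Delaunay triangulation by the empty-circumcircle property;
# adequate for <= 64 electrode layouts. Returns a neighbor list.
delaunay_neighbors <- function(x, y) {
  n <- length(x)
  nb <- vector("list", n)
  if (n < 3L) {
    for (i in seq_len(n)) nb[[i]] <- setdiff(seq_len(n), i)
    return(nb)
  }
  eps <- 1e-12 * (diff(range(x))^2 + diff(range(y))^2 + 1)
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next  # collinear
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    inside <- (x - ux)^2 + (y - uy)^2 < r2 - eps
    inside[c(i, j, k)] <- FALSE
    if (!any(inside)) {
      nb[[i]] <- union(nb[[i]], c(j, k))
      nb[[j]] <- union(nb[[j]], c(i, k))
      nb[[k]] <- union(nb[[k]], c(i, j))
    }
  }
  nb
}

#' Interpolate bad channels by triangulation
#'
#' Each bad channel is replaced by the inverse-distance-weighted mean of
#' its Delaunay-triangulation neighbors among the good channels, using the
#' montage's 2-D layout coordinates. All bad channels are interpolated
#' from the original (pre-interpolation) data.
#'
#' @param rec An `eeg_recording`.
#' @param bad_labels Channel labels to rebuild.
#' @param montage An `eeg_montage` covering the recording's channels.
#' @return The recording with bad channels replaced.
#' @export
interpolate_channels <- function(rec, bad_labels, montage) {
  if (!length(bad_labels)) return(rec)
  idx <- match(rec$channel_labels, montage$label)
  if (anyNA(idx))
    stop_entrainr("missing_channel",
                  "montage does not cover all recording channels")
  xy <- montage[idx, c("x", "y")]
  bad <- which(rec$channel_labels %in% bad_labels)
  if (!length(bad)) return(rec)
  nb <- delaunay_neighbors(xy$x, xy$y)
  out <- rec
  src <- rec$data
  for (b in bad) {
    good_nb <- setdiff(nb[[b]], bad)
    if (!length(good_nb))
      stop_entrainr("island_channel",
                    paste("no good neighbors for channel",
                          rec$channel_labels[b]))
    d <- sqrt((xy$x[good_nb] - xy$x[b])^2 + (xy$y[good_nb] - xy$y[b])^2)
    w <- 1 / pmax(d, 1e-9)
    w <- w / sum(w)
    out$data[b, ] <- as.numeric(crossprod(w, src[good_nb, , drop = FALSE]))
  }
  out
}

# --- epoching --------------------------------------------------------------

#' Construct an epoch set
#'
#' Container for segmented data: epochs x channels x samples, with the
#' sampling rate, the time of sample 0 relative to the lock event, one
#' condition label and one retained flag per epoch.
#'
#' @param data Numeric array, epochs x channels x samples.
#' @param fs_hz Sampling rate in Hz.
#' @param t0_offset_s Time of sample 0 relative to the lock event (s).
#' @param conditions Character vector, one label per epoch.
#' @param retained Logical vector, one flag per epoch.
#' @param channel_labels Character vector, one label per channel.
#' @return An object of class `epoch_set`.
#' @export
new_epoch_set <- function(data, fs_hz, t0_offset_s, conditions, retained,
                          channel_labels) {
  structure(list(data = data, fs_hz = fs_hz, t0_offset_s = t0_offset_s,
                 conditions = conditions, retained = retained,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs (%d retained) x %d channels x %d samples @ %g Hz, t0 = %g s\n",
              d[1], sum(x$retained), d[2], d[3], x$fs_hz, x$t0_offset_s))
  invisible(x)
}

#' Epoch a recording around events
#'
#' Cuts half-open sample windows `[round(e + tmin * fs), round(e + tmax *
#' fs))` around each event whose label is in `labels`. Epochs that overrun
#' the recording are dropped with a warning. Entrainment trials drop the
#' onset sentence simply by passing `tmin_s = sentence_duration(spec)`.
#'
#' @param rec An `eeg_recording`.
#' @param labels Event labels to epoch around.
#' @param tmin_s Window start relative to the event, seconds.
#' @param tmax_s Window end (exclusive) relative to the event, seconds.
#' @return An `epoch_set`; condition labels are the event labels, all
#'   epochs initially retained.
#' @export
epoch_by_events <- function(rec, labels, tmin_s, tmax_s) {
  if (tmin_s >= tmax_s)
    stop_entrainr("bad_spec", "tmin_s must be < tmax_s")
  ev <- rec$events[rec$events$label %in% labels, , drop = FALSE]
  if (!nrow(ev))
    stop_entrainr("no_events",
                  paste("no events with labels:", paste(labels, collapse = ", ")))
  fs <- rec$fs_hz
  start <- round(ev$sample + tmin_s * fs)
  end <- round(ev$sample + tmax_s * fs)   # exclusive
  ok <- start >= 0 & end <= ncol(rec$data)
  if (!all(ok))
    warning(sprintf("dropping %d epoch(s) overrunning the recording",
                    sum(!ok)))
  if (!any(ok))
    stop_entrainr("no_events", "all epochs overrun the recording")
  start <- start[ok]; end <- end[ok]
  len <- unique(end - start)
  stopifnot(length(len) == 1L)
  nch <- nrow(rec$data)
  data <- array(0, dim = c(length(start), nch, len))
  for (i in seq_along(start))
    data[i, , ] <- rec$data[, (start[i] + 1L):end[i], drop = FALSE]
  new_epoch_set(data, fs, tmin_s,
                conditions = as.character(ev$label[ok]),
                retained = rep(TRUE, length(start)),
                channel_labels = rec$channel_labels)
}

#' Reject epochs exceeding an amplitude threshold
#'
#' An epoch is retained iff the absolute value over all channels and
#' samples stays at or below `threshold_uv`. Already-rejected epochs stay
#' rejected (the operation is idempotent and order-independent). The
#' rejected fraction among previously retained epochs is attached as
#' attribute `rejected_fraction`.
#'
#' @param es An `epoch_set`.
#' @param threshold_uv Positive amplitude threshold in microvolts
#'   (default 75).
#' @return The `epoch_set` with updated `retained` flags.
#' @export
reject_epochs <- function(es, threshold_uv = 75) {
  if (threshold_uv <= 0)
    stop_entrainr("bad_spec", "threshold_uv must be > 0")
  peak <- apply(abs(es$data), 1L, max)
  keep <- peak <= threshold_uv
  was <- es$retained
  es$retained <- was & keep
  frac <- if (any(was)) sum(was & !keep) / sum(was) else 0
  attr(es, "rejected_fraction") <- frac
  es
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per epoch and channel, the mean over the time window
#' `[win_start_s, win_end_s)` measured relative to the lock event.
#'
#' @param es An `epoch_set`.
#' @param win_start_s Window start in seconds (e.g. -0.1).
#' @param win_end_s Window end in seconds (e.g. 0).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(es, win_start_s = -0.1, win_end_s = 0) {
  t <- epoch_times(es)
  sel <- t >= win_start_s & t < win_end_s
  if (!any(sel))
    stop_entrainr("empty_window", "baseline window contains no samples")
  base <- rowMeans(es$data[, , sel, drop = FALSE], dims = 2)
  es$data <- es$data - array(base, dim = dim(es$data))
  es
}

# time axis of an epoch set (seconds relative to the lock event)
epoch_times <- function(es) {
  es$t0_offset_s + (seq_len(dim(es$data)[3]) - 1L) / es$fs_hz
}
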