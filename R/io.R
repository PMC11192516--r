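# Recording container and on-disk formats. A recording is stored as three
# files sharing a prefix: <prefix>.json (header), <prefix>.dat (raw
# float32, little-endian, channel-major), <prefix>.events.tsv (0-based
# sample index + label). Event times are sample indices, never seconds.

#' Construct a continuous multi-channel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs_hz Sampling rate in Hz.
#' @param channel_labels Character vector, one label per data row.
#' @param events Data frame with columns `sample` (0-based integer sample
#'   index) and `label`; may have zero rows.
#' @param units Unit string, `"uV"`.
#' @param metadata Free-form named list.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, fs_hz, channel_labels,
                          events = data.frame(sample = integer(),
                                              label = character()),
                          units = "uV", metadata = list()) {
  data <- as.matrix(data)
  rec <- structure(list(data = data, fs_hz = as.numeric(fs_hz),
                        channel_labels = as.character(channel_labels),
                        units = units,
                        events = as.data.frame(events),
                        metadata = metadata),
                   class = "eeg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (nrow(rec$data) != length(rec$channel_labels))
    stop_entrainr("format", "data row count must equal channel label count")
  if (!is.finite(rec$fs_hz) || rec$fs_hz <= 0)
    stop_entrainr("format", "fs_hz must be > 0")
  if (anyDuplicated(rec$channel_labels))
    stop_entrainr("format", "duplicate channel labels")
  ev <- rec$events
  if (nrow(ev)) {
    if (!all(c("sample", "label") %in% names(ev)))
      stop_entrainr("format", "events need 'sample' and 'label' columns")
    if (any(ev$sample < 0L) || any(ev$sample >= ncol(rec$data)))
      stop_entrainr("format", "event sample indices out of range")
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs_hz, x$units, nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Write a recording to disk
#'
#' Layout: `<prefix>.json` header (fs_hz, channel_labels, units, n_samples,
#' dtype float32, little-endian, channel-major), `<prefix>.dat` raw binary,
#' `<prefix>.events.tsv` tab-separated events with header `sample  label`.
#'
#' @param rec An `eeg_recording`.
#' @param prefix File-path prefix (without extension).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  validate_recording(rec)
  header <- list(fs_hz = rec$fs_hz, channel_labels = rec$channel_labels,
                 units = rec$units, n_samples = ncol(rec$data),
                 n_channels = nrow(rec$data), dtype = "float32",
                 byte_order = "little", layout = "channel-major",
                 metadata = rec$metadata)
  jsonlite::write_json(header, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  # channel-major: all samples of channel 1, then channel 2, ...
  writeBin(as.numeric(t(rec$data)), con, size = 4L, endian = "little")
  ev <- rec$events
  utils::write.table(data.frame(sample = as.integer(ev$sample),
                                label = as.character(ev$label)),
                     paste0(prefix, ".events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix File-path prefix used when writing.
#' @return An `eeg_recording` (float32 precision).
#' @export
read_recording <- function(prefix) {
  hpath <- paste0(prefix, ".json")
  dpath <- paste0(prefix, ".dat")
  epath <- paste0(prefix, ".events.tsv")
  if (!file.exists(hpath) || !file.exists(dpath))
    stop_entrainr("format", paste("missing recording files for prefix", prefix))
  header <- jsonlite::fromJSON(hpath)
  if (!identical(header$dtype, "float32"))
    stop_entrainr("unknown_dialect",
                  paste("unsupported dtype:", header$dtype))
  if (!identical(header$byte_order, "little"))
    stop_entrainr("unknown_dialect",
                  paste("unsupported byte order:", header$byte_order))
  nch <- as.integer(header$n_channels)
  ns <- as.integer(header$n_samples)
  expected <- nch * ns
  actual <- file.size(dpath) / 4
  if (actual != expected)
    stop_entrainr("format",
                  sprintf("data size mismatch: header promises %d values, file holds %g",
                          expected, actual))
  con <- file(dpath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = expected, size = 4L,
                  endian = "little")
  data <- t(matrix(vals, nrow = ns, ncol = nch))
  events <- if (file.exists(epath)) {
    ev <- utils::read.table(epath, header = TRUE, sep = "\t",
                            colClasses = c("integer", "character"))
    if (nrow(ev) && (any(ev$sample < 0L) || any(ev$sample >= ns)))
      stop_entrainr("format", "events TSV contains out-of-range sample indices")
    ev
  } else data.frame(sample = integer(), label = character())
  new_recording(data, header$fs_hz, header$channel_labels, events,
                units = header$units,
                metadata = as.list(header$metadata %||% list()))
}

# epoch sets share the header + binary + TSV style -------------------------

#' Write an epoch set to disk
#'
#' Same header + float32 binary + TSV style as recordings; the TSV carries
#' one row per epoch with its condition label and retained flag. Data are
#' stored epoch-major, channel-major within epoch.
#'
#' @param es An `epoch_set` (see [epoch_by_events()]).
#' @param prefix File-path prefix.
#' @return `prefix`, invisibly.
#' @export
write_epochs <- function(es, prefix) {
  d <- dim(es$data)
  header <- list(fs_hz = es$fs_hz, t0_offset_s = es$t0_offset_s,
                 n_epochs = d[1], n_channels = d[2], n_samples = d[3],
                 channel_labels = es$channel_labels, dtype = "float32",
                 byte_order = "little", layout = "epoch-channel-major")
  jsonlite::write_json(header, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(es$data, c(3, 2, 1))), con, size = 4L,
           endian = "little")
  utils::write.table(data.frame(epoch = seq_len(d[1]) - 1L,
                                condition = es$conditions,
                                retained = es$retained),
                     paste0(prefix, ".epochs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param prefix File-path prefix used when writing.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(prefix) {
  header <- jsonlite::fromJSON(paste0(prefix, ".json"))
  dpath <- paste0(prefix, ".dat")
  n <- header$n_epochs * header$n_channels * header$n_samples
  if (file.size(dpath) / 4 != n)
    stop_entrainr("format", "epoch data size mismatch")
  con <- file(dpath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  data <- aperm(array(vals, dim = c(header$n_samples, header$n_channels,
                                    header$n_epochs)), c(3, 2, 1))
  tsv <- utils::read.table(paste0(prefix, ".epochs.tsv"), header = TRUE,
                           sep = "\t")
  new_epoch_set(data, header$fs_hz, header$t0_offset_s,
                conditions = as.character(tsv$condition),
                retained = as.logical(tsv$retained),
                channel_labels = header$channel_labels)
}

# cohort tables -------------------------------------------------------------

#' Write a cohort table as TSV
#'
#' One row per subject with tracking, N400, and behavioral measures.
#'
#' @param table Data frame with a unique `subject_id` column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  if (anyDuplicated(table$subject_id))
    stop_entrainr("format", "duplicate subject_id in cohort table")
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a cohort table TSV
#'
#' @param path TSV path written by [write_cohort_table()].
#' @return Data frame.
#' @export
read_cohort_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
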