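# Electrode montage: 64-channel 10-10 label set with schematic 2-D layout
# coordinates and per-channel source gain maps. The oscillatory gain map
# (fronto-central, auditory steady-state topography) scales the tagged
# sinusoids; the ERP gain map (centro-parietal, classic N400 topography)
# scales the semantic-violation deflection. Outer-ring electrodes
# (9/10 positions, including the mastoid stand-ins TP9/TP10) carry zero
# source gain so the mastoid reference is signal-free by construction.

MONTAGE64 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
  "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
  "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6", "FT9", "FT7", "FC3",
  "FC4", "FT8", "FT10", "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4",
  "TP8", "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8")

#' Region-of-interest channels for the N400 analysis
#'
#' Fourteen central and centro-posterior electrodes over which ERP
#' amplitudes are averaged.
#'
#' @return Character vector of channel labels.
#' @export
roi_channels <- function() {
  c("C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6")
}

# schematic 10-10 layout: row letter -> anterior-posterior coordinate,
# numeric index -> laterality (odd left, even right), z -> midline
electrode_positions <- function(labels) {
  row_y <- c(Fp = 0.85, AF = 0.65, F = 0.45, FT = 0.22, FC = 0.22,
             T = 0, C = 0, TP = -0.22, CP = -0.22, P = -0.45,
             PO = -0.65, O = -0.85)
  lat_x <- c(0.15, 0.35, 0.55, 0.75, 0.95)
  m <- regmatches(labels, regexec("^([A-Za-z]+?)(z|[0-9]+)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop_entrainr("bad_label",
                  paste("unparseable channel labels:",
                        paste(labels[bad], collapse = ", ")))
  prefix <- vapply(m, `[`, "", 2L)
  idx <- vapply(m, `[`, "", 3L)
  if (!all(prefix %in% names(row_y)))
    stop_entrainr("bad_label",
                  paste("unknown electrode rows:",
                        paste(unique(prefix[!prefix %in% names(row_y)]),
                              collapse = ", ")))
  y <- row_y[prefix]
  x <- numeric(length(labels))
  ring <- integer(length(labels))
  num <- suppressWarnings(as.integer(idx))
  is_num <- !is.na(num)
  step <- ifelse(is_num, ceiling(num / 2), 0L)
  side <- ifelse(is_num & num %% 2L == 1L, -1, 1)
  x[is_num] <- side[is_num] * lat_x[step[is_num]]
  ring <- step
  data.frame(label = labels, x = unname(x), y = unname(y),
             ring = as.integer(ring), stringsAsFactors = FALSE)
}

gaussian_gain <- function(x, y, cx, cy, sigma) {
  g <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
  pmin(pmax(g, 0), 1)
}

#' Build an electrode montage
#'
#' Returns a montage table with schematic 2-D layout coordinates and the
#' per-channel gain maps used by the synthetic generators: `osc_gain`
#' (fronto-central, scales the frequency-tagged sinusoids) and `erp_gain`
#' (centro-parietal, scales the N400 deflection), both in \[0, 1\].
#' Outer-ring electrodes (10-10 positions numbered 9/10, which include the
#' mastoid stand-ins TP9/TP10) are assigned zero gain.
#'
#' @param preset `"full64"` (complete 64-channel 10-10 set) or `"desk24"`
#'   (24-channel working subset: the 14 ROI channels plus Fp1/Fp2, Fz, Pz,
#'   T7/T8/TP7/TP8 and the mastoids TP9/TP10), ignored when `channels` is
#'   given.
#' @param channels Optional explicit character vector of labels.
#' @return A `data.frame` of class `eeg_montage` with columns `label`,
#'   `x`, `y`, `osc_gain`, `erp_gain`.
#' @examples
#' m <- make_montage("desk24")
#' subset(m, label == "Cz")
#' @export
make_montage <- function(preset = c("full64", "desk24"), channels = NULL) {
  if (is.null(channels)) {
    preset <- match.arg(preset)
    channels <- switch(preset,
      full64 = MONTAGE64,
      desk24 = c(roi_channels(), "Fp1", "Fp2", "Fz", "Pz",
                 "T7", "T8", "TP7", "TP8", "TP9", "TP10"))
  }
  if (anyDuplicated(channels))
    stop_entrainr("bad_label", "duplicate channel labels in montage")
  pos <- electrode_positions(channels)
  # focal fronto-central oscillatory source: most channels carry little
  # gain, so a common-average reference removes only a small coherent mean
  osc <- gaussian_gain(pos$x, pos$y, 0, 0.20, 0.30)
  erp <- gaussian_gain(pos$x, pos$y, 0, -0.20, 0.40)
  outer_ring <- pos$ring >= 5L
  osc[outer_ring] <- 0
  erp[outer_ring] <- 0
  structure(data.frame(label = pos$label, x = pos$x, y = pos$y,
                       osc_gain = osc, erp_gain = erp,
                       stringsAsFactors = FALSE),
            class = c("eeg_montage", "data.frame"))
}
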