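# Paradigm arithmetic for the hierarchical frequency-tagging design:
# isochronous syllables tile words, phrases and sentences, so each
# linguistic level is tagged at an exact harmonic of the sentence rate.
# Durations are carried internally as integer milliseconds so that tag
# frequencies land exactly on DFT bins of the trial epoch by construction.

#' Frequency-tagging paradigm specification
#'
#' Describes the timing structure of the tagging experiment: syllable
#' duration, syllables (monosyllabic words) per sentence, sentences per
#' trial, number of trials, whether the first sentence of each trial is
#' discarded from analysis (to avoid the auditory onset transient), and
#' the EEG sampling rate.
#'
#' The defaults encode the standard design: 320 ms syllables, four-word
#' sentences (1.28 s, i.e. a 0.78125 Hz sentence rate), twelve sentences
#' per trial, thirty trials, first sentence dropped, 500 Hz sampling.
#'
#' @param syllable_dur_s Syllable duration in seconds (default 0.320).
#' @param words_per_sentence Monosyllabic words per sentence; must be even
#'   (phrases are word pairs) and at least 2 (default 4).
#' @param sentences_per_trial Sentences presented per trial (default 12).
#' @param n_trials Number of trials per participant (default 30).
#' @param drop_first_sentence Drop the first sentence of each trial when
#'   epoching (default `TRUE`).
#' @param fs_hz EEG sampling rate in Hz (default 500). Must exceed twice
#'   the syllabic rate.
#' @return An object of class `paradigm_spec`.
#' @examples
#' spec <- paradigm_spec()
#' sentence_duration(spec)   # 1.28 s
#' epoch_duration(spec)      # 14.08 s
#' tag_frequencies(spec)     # 0.78125 / 1.5625 / 3.125 Hz
#' @export
paradigm_spec <- function(syllable_dur_s = 0.320,
                          words_per_sentence = 4L,
                          sentences_per_trial = 12L,
                          n_trials = 30L,
                          drop_first_sentence = TRUE,
                          fs_hz = 500) {
  spec <- structure(list(
    syllable_dur_s = as.numeric(syllable_dur_s),
    words_per_sentence = as.integer(words_per_sentence),
    sentences_per_trial = as.integer(sentences_per_trial),
    n_trials = as.integer(n_trials),
    drop_first_sentence = isTRUE(drop_first_sentence),
    fs_hz = as.numeric(fs_hz)
  ), class = "paradigm_spec")
  validate_paradigm_spec(spec)
  spec
}

validate_paradigm_spec <- function(spec) {
  with(spec, {
    if (!is.finite(syllable_dur_s) || syllable_dur_s <= 0)
      stop_entrainr("bad_spec", "syllable_dur_s must be > 0")
    if (words_per_sentence < 2L || words_per_sentence %% 2L != 0L)
      stop_entrainr("bad_spec",
                    "words_per_sentence must be even and >= 2 (phrases are word pairs)")
    if (sentences_per_trial < 1L)
      stop_entrainr("bad_spec", "sentences_per_trial must be >= 1")
    if (drop_first_sentence && sentences_per_trial < 2L)
      stop_entrainr("bad_spec",
                    "sentences_per_trial must be >= 2 when the first sentence is dropped")
    if (n_trials < 1L)
      stop_entrainr("bad_spec", "n_trials must be >= 1")
    syllabic_hz <- 1 / syllable_dur_s
    if (!is.finite(fs_hz) || fs_hz <= 2 * syllabic_hz)
      stop_entrainr("bad_spec", "fs_hz must exceed twice the syllabic rate")
  })
  invisible(spec)
}

# integer-millisecond internals keeping bin alignment exact
syllable_ms <- function(spec) round(spec$syllable_dur_s * 1000)
sentence_ms <- function(spec) syllable_ms(spec) * spec$words_per_sentence
epoch_ms <- function(spec) {
  kept <- spec$sentences_per_trial - as.integer(spec$drop_first_sentence)
  kept * sentence_ms(spec)
}

#' Sentence duration
#'
#' @param spec A [paradigm_spec()].
#' @return Sentence duration in seconds (syllable duration times words per
#'   sentence); 1.28 s for the default design.
#' @export
sentence_duration <- function(spec) sentence_ms(spec) / 1000

#' Tag frequencies of the paradigm
#'
#' The sentential rate is the reciprocal of the sentence duration; the
#' phrasal rate is its second harmonic (two-word phrases) and the syllabic
#' rate its fourth (four monosyllabic words). For the default design these
#' are exactly 0.78125, 1.5625, and 3.125 Hz.
#'
#' @param spec A [paradigm_spec()].
#' @return A `tag_frequencies` list with elements `sentential_hz`,
#'   `phrasal_hz`, `syllabic_hz`.
#' @export
tag_frequencies <- function(spec) {
  f1 <- 1000 / sentence_ms(spec)
  structure(list(sentential_hz = f1,
                 phrasal_hz = 2 * f1,
                 syllabic_hz = 4 * f1),
            class = "tag_frequencies")
}

#' @export
format.tag_frequencies <- function(x, digits = 2, ...) {
  # half-to-even rounding at the printed precision (base round())
  sprintf("sentential %s Hz, phrasal %s Hz, syllabic %s Hz",
          round(x$sentential_hz, digits), round(x$phrasal_hz, digits),
          round(x$syllabic_hz, digits))
}

#' @export
print.tag_frequencies <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' Analysis epoch duration
#'
#' Duration of one analysed trial epoch: the number of retained sentences
#' (all sentences minus the dropped first one) times the sentence duration.
#' 14.08 s for the default design.
#'
#' @param spec A [paradigm_spec()].
#' @return Epoch duration in seconds.
#' @export
epoch_duration <- function(spec) epoch_ms(spec) / 1000

#' Spectral resolution of the trial epoch
#'
#' @param spec A [paradigm_spec()].
#' @return Frequency resolution in Hz, the reciprocal of
#'   [epoch_duration()]; 1/14.08 = 0.071 Hz for the default design.
#' @export
frequency_resolution <- function(spec) 1000 / epoch_ms(spec)

#' Map a frequency onto a DFT bin of the trial epoch
#'
#' Tagged rates tile the analysis epoch with an integer number of cycles,
#' so each falls exactly on a DFT bin. Bins are indexed by cycle count
#' (bin 1 = the frequency-resolution bin); the DC bin is not addressable.
#'
#' @param freq_hz Frequency in Hz (> 0).
#' @param spec A [paradigm_spec()].
#' @param tol Maximum allowed distance, in cycles, between
#'   `freq_hz * epoch_duration(spec)` and the nearest integer
#'   (default 1e-6).
#' @return Integer bin index.
#' @export
bin_index <- function(freq_hz, spec, tol = 1e-6) {
  if (!is.finite(freq_hz) || freq_hz <= 0)
    stop_entrainr("bad_spec", "freq_hz must be > 0")
  cycles <- freq_hz * epoch_ms(spec) / 1000
  b <- round(cycles)
  if (abs(cycles - b) > tol)
    stop_entrainr("misaligned_frequency",
                  sprintf("%g Hz does not fall on a DFT bin of the %g s epoch (%.6f cycles)",
                          freq_hz, epoch_duration(spec), cycles))
  as.integer(b)
}

#' Neighboring frequency bins of a peak bin
#'
#' Returns the `k` bins on each side of `bin`, excluding the bin itself.
#' These flanking bins estimate the local noise floor that is subtracted
#' from the peak in neighbor-bin normalization.
#'
#' @param bin Integer bin index (cycle count).
#' @param k Number of neighbors on each side (default 2, i.e. four bins).
#' @return Integer vector of length `2 * k`.
#' @export
neighbor_bins <- function(bin, k = 2L) {
  bin <- as.integer(bin); k <- as.integer(k)
  if (k < 1L) stop_entrainr("bad_spec", "k must be >= 1")
  if (bin - k < 1L)
    stop_entrainr("out_of_range",
                  sprintf("bin %d has fewer than %d lower neighbors", bin, k))
  c((bin - k):(bin - 1L), (bin + 1L):(bin + k))
}

#' Serialize a paradigm specification to JSON
#'
#' @param spec A [paradigm_spec()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
paradigm_to_json <- function(spec, path = NULL) {
  json <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Read a paradigm specification from JSON
#'
#' @param x A file path or a JSON string with keys `syllable_dur_s`,
#'   `words_per_sentence`, `sentences_per_trial`, `n_trials`,
#'   `drop_first_sentence`, `fs_hz`.
#' @return A [paradigm_spec()].
#' @export
paradigm_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  keys <- c("syllable_dur_s", "words_per_sentence", "sentences_per_trial",
            "n_trials", "drop_first_sentence", "fs_hz")
  missing <- setdiff(keys, names(obj))
  if (length(missing))
    stop_entrainr("config", paste("missing paradigm keys:",
                                  paste(missing, collapse = ", ")))
  do.call(paradigm_spec, obj[keys])
}
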