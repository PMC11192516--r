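# Shared fixtures: reduced-scale paradigms, montages, and subjects used
# across the suite. Simulation studies run on these desk-scale problem
# sizes; the statistical properties under test do not depend on the full
# recording dimensions.

# default timing, 4 trials, 100 Hz: cheap but bin-exact (bins 11/22/44)
tiny_spec <- function(n_trials = 4L, fs_hz = 100) {
  paradigm_spec(n_trials = n_trials, fs_hz = fs_hz)
}

# eight inner 10-10 channels + mastoid stand-ins; covers a 6-channel ROI
mini_montage <- function() {
  make_montage(channels = c("FC1", "FC2", "Cz", "C1", "C2",
                            "CP1", "CP2", "Pz", "TP9", "TP10"))
}

mini_roi <- function() c("Cz", "C1", "C2", "CP1", "CP2")

# a layout where interpolation geometry is known exactly: equilateral
# triangle around a central channel
triangle_montage <- function() {
  ang <- c(90, 210, 330) * pi / 180
  structure(data.frame(label = c("A", "B", "C", "M"),
                       x = c(cos(ang), 0), y = c(sin(ang), 0),
                       osc_gain = 1, erp_gain = 1,
                       stringsAsFactors = FALSE),
            class = c("eeg_montage", "data.frame"))
}

quick_subject <- function(seed = 1L, ...) {
  subject_params(sprintf("S%03d", seed), seed = seed, ...)
}

# per-subject normalized peak-minus-neighbor estimate from a simulated
# tagging recording, at reduced scale and without the FIR stage
quick_peak_pairs <- function(sp, spec, montage) {
  rec <- simulate_entrainment(sp, spec, montage)
  process_entrainment_subject(rec, spec, montage,
                              exclude_channels = character(),
                              frontal_exclude = character(),
                              filter = FALSE)$pairs
}

expect_equal_tol <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) <= tol)
}

# brute-force O(N^2) DFT oracle for the one-sided amplitude-power spectrum
brute_power <- function(x) {
  n <- length(x)
  nb <- floor(n / 2)
  p <- vapply(seq_len(nb), function(kk) {
    re <- sum(x * cos(2 * pi * kk * (0:(n - 1)) / n))
    im <- -sum(x * sin(2 * pi * kk * (0:(n - 1)) / n))
    (2 * sqrt(re^2 + im^2) / n)^2
  }, 0)
  if (n %% 2 == 0) p[nb] <- p[nb] / 4
  p
}
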