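# Synthetic EEG generator with known ground truth. Neural tracking is
# modeled as phase-locked sinusoids at exactly the tagged rates (the
# analysis only interrogates those bins, so this gives analytically known
# spectral ground truth); the N400 is a Gaussian-windowed deflection (SD
# 80 ms) on ERP-gain channels whose congruency difference is calibrated so
# that the ROI-mean window effect equals the requested value in the
# noise-free limit. Background activity is 1/f ("pink") noise; occasional
# large boxcar excursions emulate movement/ocular artifacts. Every
# generator is a pure function of its parameters and seed.

# 1/f noise via spectral shaping of white Gaussian noise; unit power
# density slope -1 on log-log axes, scaled to the requested RMS. The
# matrix variant shapes all channels in one pass (columns = channels);
# FFTs are padded to a fast length and truncated.
pink_noise_matrix <- function(n, nch, rms = 1) {
  if (n < 4L) return(matrix(stats::rnorm(n * nch, sd = rms), nch, n))
  n2 <- stats::nextn(n, c(2L, 3L, 5L))
  white <- matrix(stats::rnorm(n2 * nch), n2, nch)
  X <- stats::mvfft(white)
  k <- seq_len(n2) - 1L
  f <- pmin(k, n2 - k)          # symmetric frequency index
  scale <- c(0, 1 / sqrt(f[-1]))
  x <- Re(stats::mvfft(X * scale, inverse = TRUE)) / n2
  x <- x[seq_len(n), , drop = FALSE]
  x <- sweep(x, 2L, colMeans(x), "-")
  x <- sweep(x, 2L, sqrt(colMeans(x^2)), "/")
  t(x) * rms                     # channels x samples; rms may be a vector
}

pink_noise <- function(n, rms = 1) {
  as.vector(pink_noise_matrix(n, 1L, rms))
}

#' Per-subject ground-truth parameters
#'
#' Latent quantities whose estimates the analysis pipeline produces:
#' phase-locked amplitudes at the three tagged rates, the N400 congruency
#' effect (ROI-mean incongruent-minus-congruent amplitude over the
#' 300-700 ms window; negative is the canonical direction) and its
#' latency, the 1/f background RMS, and the per-epoch artifact rate.
#'
#' @param subject_id Subject label.
#' @param group Group label, `"NL"` (native) or `"SL"` (second language).
#' @param amp_sentential,amp_phrasal,amp_syllabic Sinusoid amplitudes in
#'   microvolts (>= 0).
#' @param phase_sentential,phase_phrasal,phase_syllabic Phases in radians.
#' @param n400_effect Congruency effect in microvolts (negative =
#'   canonical N400).
#' @param n400_latency_ms Center of the deflection in ms, in (0, 700).
#' @param noise_scale 1/f background RMS in microvolts (> 0).
#' @param artifact_rate Per-epoch artifact probability in \[0, 1\].
#' @param comprehension_rating,question_accuracy,listening_score
#'   Behavioral measures (0-4 rating; proportions).
#' @param seed Integer RNG seed for this subject's recordings.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(subject_id, group = "NL",
                           amp_sentential = 1.0, amp_phrasal = 1.2,
                           amp_syllabic = 1.5,
                           phase_sentential = 0, phase_phrasal = 0,
                           phase_syllabic = 0,
                           n400_effect = -1.2, n400_latency_ms = 400,
                           noise_scale = 10, artifact_rate = 0.123,
                           comprehension_rating = 3.7,
                           question_accuracy = 0.95,
                           listening_score = 0.95,
                           seed = 1L) {
  sp <- structure(list(subject_id = as.character(subject_id), group = group,
                       amp_sentential = amp_sentential,
                       amp_phrasal = amp_phrasal, amp_syllabic = amp_syllabic,
                       phase_sentential = phase_sentential,
                       phase_phrasal = phase_phrasal,
                       phase_syllabic = phase_syllabic,
                       n400_effect = n400_effect,
                       n400_latency_ms = n400_latency_ms,
                       noise_scale = noise_scale,
                       artifact_rate = artifact_rate,
                       comprehension_rating = comprehension_rating,
                       question_accuracy = question_accuracy,
                       listening_score = listening_score,
                       seed = as.integer(seed)),
                  class = "subject_params")
  validate_subject_params(sp)
  sp
}

validate_subject_params <- function(sp) {
  with(sp, {
    if (min(amp_sentential, amp_phrasal, amp_syllabic) < 0)
      stop_entrainr("bad_spec", "amplitudes must be >= 0")
    if (!is.finite(noise_scale) || noise_scale <= 0)
      stop_entrainr("bad_spec", "noise_scale must be > 0")
    if (artifact_rate < 0 || artifact_rate > 1)
      stop_entrainr("bad_spec", "artifact_rate must be in [0, 1]")
    if (n400_latency_ms <= 0 || n400_latency_ms >= 700)
      stop_entrainr("bad_spec", "n400_latency_ms must be in (0, 700)")
  })
  invisible(sp)
}

#' Cohort specification for the synthetic generator
#'
#' Describes one group of subjects: sample size, the target rank
#' correlation between sentential tracking amplitude and N400 effect
#' magnitude (realized through a Gaussian copula), and the parameter
#' distributions. Group defaults encode the qualitative contrast between
#' native (NL) and second-language (SL) listeners: NL track all three
#' rates and show an earlier (400 ms), larger N400; SL carry essentially
#' no sentential amplitude, a later (450 ms), smaller N400, and lower
#' behavioral scores.
#'
#' @param group `"NL"` or `"SL"`.
#' @param n_subjects Subjects in the group (default 22; >= 3).
#' @param coupling_rho Target Spearman correlation between
#'   `amp_sentential` and `|n400_effect|` (default 0.45, within \[-1, 1\]).
#' @param dists Named list of marginal distributions overriding the group
#'   defaults; see [default_group_dists()].
#' @param master_seed Integer master seed (cohort draws and subject seeds
#'   derive from it).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group = c("NL", "SL"), n_subjects = 22L,
                        coupling_rho = 0.45, dists = list(),
                        master_seed = 1L) {
  group <- match.arg(group)
  if (n_subjects < 3L) stop_entrainr("bad_spec", "n_subjects must be >= 3")
  if (abs(coupling_rho) > 1)
    stop_entrainr("bad_spec", "|coupling_rho| must be <= 1")
  d <- utils::modifyList(default_group_dists(group), dists)
  bad_sd <- vapply(d, function(e) !is.null(e$sd) && e$sd < 0, TRUE)
  if (any(bad_sd))
    stop_entrainr("degenerate_distribution",
                  paste("negative SD for:",
                        paste(names(d)[bad_sd], collapse = ", ")))
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 coupling_rho = coupling_rho, dists = d,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Default marginal parameter distributions per group
#'
#' Amplitude-like quantities (`amp_*`, `n400_magnitude`, `noise_scale`)
#' are log-normal with the stated median and log-SD; latencies and
#' behavioral scores are normal (scores clipped to their ranges);
#' `artifact_rate` is a fixed constant.
#'
#' @param group `"NL"` or `"SL"`.
#' @return Named list of distribution descriptors.
#' @export
default_group_dists <- function(group = c("NL", "SL")) {
  group <- match.arg(group)
  if (group == "NL") {
    list(amp_sentential = list(median = 1.0, sdlog = 0.35),
         amp_phrasal = list(median = 1.2, sdlog = 0.35),
         amp_syllabic = list(median = 1.5, sdlog = 0.35),
         n400_magnitude = list(median = 1.2, sdlog = 0.35),
         n400_latency_ms = list(mean = 400, sd = 15),
         noise_scale = list(median = 10, sdlog = 0.15),
         artifact_rate = list(value = 0.123),
         comprehension_rating = list(mean = 3.68, sd = 0.30),
         question_accuracy = list(mean = 0.95, sd = 0.03),
         listening_score = list(mean = 0.97, sd = 0.02))
  } else {
    list(amp_sentential = list(median = 0.02, sdlog = 0.35),
         amp_phrasal = list(median = 1.0, sdlog = 0.35),
         amp_syllabic = list(median = 1.5, sdlog = 0.35),
         n400_magnitude = list(median = 0.9, sdlog = 0.35),
         n400_latency_ms = list(mean = 450, sd = 15),
         noise_scale = list(median = 10, sdlog = 0.15),
         artifact_rate = list(value = 0.123),
         comprehension_rating = list(mean = 2.95, sd = 0.45),
         question_accuracy = list(mean = 0.90, sd = 0.04),
         listening_score = list(mean = 0.86, sd = 0.07))
  }
}

#' Draw a cohort of subject parameter sets
#'
#' Samples `n_subjects` parameter sets from the group's marginal
#' distributions. The sentential tracking amplitude and the N400 effect
#' magnitude are coupled through a Gaussian copula whose parameter is
#' `2 * sin(pi * coupling_rho / 6)`, so the population Spearman
#' correlation between `amp_sentential` and `|n400_effect|` equals
#' `coupling_rho`; both marginals are log-normal, and the reported effect
#' keeps the canonical negative sign. Deterministic given `master_seed`.
#'
#' @param cs A [cohort_spec()].
#' @return List of [subject_params()].
#' @export
draw_cohort <- function(cs) {
  set.seed(cs$master_seed)
  n <- cs$n_subjects
  d <- cs$dists
  # Gaussian copula: convert the target Spearman rho to the Pearson
  # parameter of the latent bivariate normal
  r <- 2 * sin(pi * cs$coupling_rho / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  u1 <- stats::pnorm(z1); u2 <- stats::pnorm(z2)
  amp_sent <- stats::qlnorm(u1, meanlog = log(d$amp_sentential$median),
                            sdlog = d$amp_sentential$sdlog)
  n400_mag <- stats::qlnorm(u2, meanlog = log(d$n400_magnitude$median),
                            sdlog = d$n400_magnitude$sdlog)
  rln <- function(e) stats::qlnorm(stats::runif(n), meanlog = log(e$median),
                                   sdlog = e$sdlog)
  rno <- function(e, lo = -Inf, hi = Inf)
    pmin(pmax(stats::rnorm(n, e$mean, e$sd), lo), hi)
  amp_phr <- rln(d$amp_phrasal)
  amp_syl <- rln(d$amp_syllabic)
  lat <- rno(d$n400_latency_ms, 100, 650)
  noise <- rln(d$noise_scale)
  rating <- rno(d$comprehension_rating, 0, 4)
  acc <- rno(d$question_accuracy, 0, 1)
  listen <- rno(d$listening_score, 0, 1)
  phases <- matrix(stats::runif(3 * n, 0, 2 * pi), n, 3)
  seeds <- as.integer((as.numeric(cs$master_seed) + 7919 * seq_len(n)) %%
                        .Machine$integer.max)
  lapply(seq_len(n), function(i) subject_params(
    subject_id = sprintf("%s%02d", cs$group, i), group = cs$group,
    amp_sentential = amp_sent[i], amp_phrasal = amp_phr[i],
    amp_syllabic = amp_syl[i],
    phase_sentential = phases[i, 1], phase_phrasal = phases[i, 2],
    phase_syllabic = phases[i, 3],
    n400_effect = -n400_mag[i], n400_latency_ms = lat[i],
    noise_scale = noise[i], artifact_rate = d$artifact_rate$value,
    comprehension_rating = rating[i], question_accuracy = acc[i],
    listening_score = listen[i], seed = seeds[i]))
}

#' Simulate a continuous tagging-experiment recording
#'
#' Builds `spec$n_trials` trials separated by `gap_s` of silence. Within
#' each trial, channel `c` carries
#' `sum_k amp_k * osc_gain(c) * sin(2 * pi * f_k * t + phase_k)` over the
#' three tagged rates (`t` relative to trial onset), on top of 1/f noise
#' at the subject's RMS. Events mark every trial onset (`"trial"`) and
#' sentence onset (`"sentence"`). Reproducible given `sp$seed`.
#'
#' @param sp A [subject_params()].
#' @param spec A [paradigm_spec()].
#' @param montage An `eeg_montage`.
#' @param gap_s Inter-trial silence in seconds (default 1).
#' @param noise Set `FALSE` for a noise-free recording.
#' @return An `eeg_recording`.
#' @export
simulate_entrainment <- function(sp, spec = paradigm_spec(),
                                 montage = make_montage(), gap_s = 1,
                                 noise = TRUE) {
  set.seed(sp$seed)
  fs <- spec$fs_hz
  sent_n <- round(sentence_duration(spec) * fs)
  trial_n <- spec$sentences_per_trial * sent_n
  gap_n <- round(gap_s * fs)
  onsets <- gap_n + (seq_len(spec$n_trials) - 1L) * (trial_n + gap_n)
  total <- gap_n + spec$n_trials * (trial_n + gap_n)
  tf <- tag_frequencies(spec)
  tt <- (seq_len(trial_n) - 1L) / fs
  wave <- sp$amp_sentential * sin(2 * pi * tf$sentential_hz * tt +
                                    sp$phase_sentential) +
    sp$amp_phrasal * sin(2 * pi * tf$phrasal_hz * tt + sp$phase_phrasal) +
    sp$amp_syllabic * sin(2 * pi * tf$syllabic_hz * tt + sp$phase_syllabic)
  nch <- nrow(montage)
  data <- matrix(0, nch, total)
  tile <- outer(montage$osc_gain, wave)
  for (o in onsets)
    data[, o + seq_len(trial_n)] <- data[, o + seq_len(trial_n)] + tile
  if (noise)
    data <- data + pink_noise_matrix(total, nch, sp$noise_scale)
  sent_onsets <- as.vector(outer(0:(spec$sentences_per_trial - 1L) * sent_n,
                                 onsets, `+`))
  events <- rbind(
    data.frame(sample = onsets, label = "trial"),
    data.frame(sample = sort(sent_onsets), label = "sentence"))
  events <- events[order(events$sample), ]
  new_recording(data, fs, montage$label, events,
                metadata = list(subject_id = sp$subject_id,
                                group = sp$group, seed = sp$seed,
                                kind = "entrainment"))
}

# discrete mean of the deflection template over the effect window,
# matching the half-open sample selection used by the analysis
n400_template_window_mean <- function(latency_s, sd_s, fs_hz, window_s) {
  j <- 0:(ceiling(window_s[2] * fs_hz) + 1L)
  t <- j / fs_hz
  sel <- t >= window_s[1] & t < window_s[2]
  mean(exp(-(t[sel] - latency_s)^2 / (2 * sd_s^2)))
}

#' Simulate a continuous N400-experiment recording
#'
#' One critical-word marker per sentence, labeled `"congruent"` or
#' `"incongruent"` (balanced, order randomized under `schedule_seed`).
#' Each marker adds a Gaussian-windowed deflection (SD `template_sd_s`)
#' centered at the subject's N400 latency, scaled by the montage's ERP
#' gain map. The congruent condition receives a baseline deflection whose
#' ROI-mean amplitude over `effect_window_s` equals `congruent_window_uv`;
#' the incongruent amplitude is offset so that the ROI-mean
#' incongruent-minus-congruent window amplitude equals `sp$n400_effect` in
#' the noise-free limit (the discrete template/window overlap is corrected
#' for by construction).
#'
#' @param sp A [subject_params()].
#' @param n_sentences_per_condition Sentences per congruency condition
#'   (default 53).
#' @param montage An `eeg_montage`.
#' @param fs_hz Sampling rate (default 500).
#' @param soa_s Stimulus-onset asynchrony between critical words
#'   (default 2.5).
#' @param lead_s Silence before the first marker (default 1).
#' @param roi_labels ROI used for the calibration (default
#'   [roi_channels()]), intersected with the montage.
#' @param effect_window_s Calibration window in seconds (default
#'   `c(0.3, 0.7)`).
#' @param congruent_window_uv ROI-mean window amplitude of the congruent
#'   deflection (default -0.5).
#' @param template_sd_s Gaussian template SD in seconds (default 0.08).
#' @param schedule_seed Seed for the condition order; defaults to
#'   `sp$seed` so that different noise seeds can share a schedule.
#' @param noise Set `FALSE` for a noise-free recording.
#' @return An `eeg_recording`.
#' @export
simulate_n400 <- function(sp, n_sentences_per_condition = 53L,
                          montage = make_montage(), fs_hz = 500,
                          soa_s = 2.5, lead_s = 1,
                          roi_labels = roi_channels(),
                          effect_window_s = c(0.3, 0.7),
                          congruent_window_uv = -0.5,
                          template_sd_s = 0.08,
                          schedule_seed = NULL, noise = TRUE) {
  if (n_sentences_per_condition < 1L)
    stop_entrainr("bad_spec", "need at least one sentence per condition")
  set.seed(schedule_seed %||% sp$seed)
  conds <- sample(rep(c("congruent", "incongruent"),
                      each = n_sentences_per_condition))
  set.seed(sp$seed + 1L)
  nsent <- length(conds)
  onsets <- round((lead_s + (seq_len(nsent) - 1L) * soa_s) * fs_hz)
  lat_s <- sp$n400_latency_ms / 1000
  support <- 0:round((lat_s + 5 * template_sd_s) * fs_hz)
  g <- exp(-(support / fs_hz - lat_s)^2 / (2 * template_sd_s^2))
  roi <- intersect(roi_labels, montage$label)
  if (!length(roi))
    stop_entrainr("missing_channel", "montage contains no ROI channels")
  gain <- montage$erp_gain
  roi_gain <- mean(gain[match(roi, montage$label)])
  wmean <- n400_template_window_mean(lat_s, template_sd_s, fs_hz,
                                     effect_window_s)
  a_cong <- congruent_window_uv / (wmean * roi_gain)
  a_inc <- a_cong + sp$n400_effect / (wmean * roi_gain)
  total <- max(onsets) + length(support) + round(fs_hz)
  nch <- nrow(montage)
  data <- matrix(0, nch, total)
  tile_c <- outer(gain, a_cong * g)
  tile_i <- outer(gain, a_inc * g)
  for (i in seq_len(nsent)) {
    idx <- onsets[i] + support + 1L
    data[, idx] <- data[, idx] +
      (if (conds[i] == "congruent") tile_c else tile_i)
  }
  if (noise)
    data <- data + pink_noise_matrix(total, nch, sp$noise_scale)
  new_recording(data, fs_hz, montage$label,
                data.frame(sample = onsets, label = conds),
                metadata = list(subject_id = sp$subject_id,
                                group = sp$group, seed = sp$seed,
                                kind = "n400"))
}

#' Inject boxcar artifacts into a recording
#'
#' With probability `sp$artifact_rate` per event-aligned segment, adds a
#' boxcar excursion of amplitude drawn uniformly from +/-(100, 300)
#' microvolts over a random 200 ms sub-interval of the segment on a random
#' subset of inner-layout channels (the outer ring, including the mastoid
#' stand-ins, is spared so reference channels stay clean). Ground-truth
#' positions are recorded in `metadata$artifact_events` (0-based indices
#' into the event table).
#'
#' @param rec An `eeg_recording` with events.
#' @param sp A [subject_params()] (uses `artifact_rate` and a seed derived
#'   from `sp$seed`).
#' @param tmin_s,tmax_s Segment window around each event in seconds
#'   (defaults -0.1 / 0.7, the ERP epoch).
#' @return The contaminated recording.
#' @export
inject_artifacts <- function(rec, sp, tmin_s = -0.1, tmax_s = 0.7) {
  if (sp$artifact_rate == 0) return(rec)
  set.seed(as.integer((sp$seed + 104729) %% .Machine$integer.max))
  fs <- rec$fs_hz
  nev <- nrow(rec$events)
  hit <- stats::runif(nev) < sp$artifact_rate
  pos <- electrode_positions(rec$channel_labels)
  eligible <- which(pos$ring < 5L)
  out <- rec
  dur_n <- round(0.2 * fs)
  for (i in which(hit)) {
    e <- rec$events$sample[i]
    win0 <- round(e + tmin_s * fs)
    win1 <- round(e + tmax_s * fs) - dur_n
    if (win1 <= win0) next
    s0 <- win0 + sample.int(win1 - win0, 1L)
    chs <- eligible[sample.int(length(eligible),
                               sample.int(min(6L, length(eligible)), 1L))]
    amp <- sample(c(-1, 1), 1L) * stats::runif(1L, 100, 300)
    idx <- pmax(1L, s0 + 1L):pmin(ncol(out$data), s0 + dur_n)
    out$data[chs, idx] <- out$data[chs, idx] + amp
  }
  out$metadata$artifact_events <- which(hit) - 1L
  out
}
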