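# End-to-end orchestration: simulate -> preprocess -> tagging -> ERP ->
# group statistics -> correlations, driven by a JSON config. Stage outputs
# are a cohort table (TSV) and per-stage JSON reports; everything is a
# pure function of the config and master seed.

#' Default pipeline configuration
#'
#' The bundled defaults run two 22-subject groups (NL / SL) at the study
#' sampling rate with a 24-channel working montage, 10 tagging trials and
#' 16 sentences per congruency condition per subject -- a problem size
#' chosen so a complete cohort run finishes in minutes on one CPU while
#' exercising every stage at full fidelity (see the methods vignette).
#'
#' @return Named list mirroring the JSON config schema.
#' @export
default_config <- function() {
  list(
    master_seed = 20240603L,
    paradigm = list(syllable_dur_s = 0.320, words_per_sentence = 4L,
                    sentences_per_trial = 12L, n_trials = 10L,
                    drop_first_sentence = TRUE, fs_hz = 500),
    montage = list(preset = "desk24"),
    cohort = list(n_subjects = 22L, coupling_rho = 0.45,
                  groups = c("NL", "SL")),
    n400 = list(n_sentences_per_condition = 16L, soa_s = 2.5),
    preprocess = list(entrainment_band_hz = c(0.1, 25),
                      n400_band_hz = c(0.1, 30),
                      reject_threshold_uv = 75,
                      exclude_channels = c("T7", "T8", "TP7", "TP8"),
                      frontal_exclude = c("Fp1", "Fp2"),
                      mastoids = c("TP9", "TP10"),
                      bad_channels = character()),
    erp = list(roi = roi_channels(),
               windows_ms = list(c(300, 500), c(500, 700)),
               fdr_q = 0.05),
    correlation = list(group = "SL",
                       pairs = list(c("sentential_db", "listening_score"),
                                    c("sentential_db", "n400_late_uv"),
                                    c("sentential_db", "comprehension_rating")))
  )
}

#' Read and validate a pipeline configuration
#'
#' Unknown keys are rejected and missing required keys reported with their
#' full path. Values omitted from the file fall back to
#' [default_config()].
#'
#' @param path JSON config path, or a named list already in memory.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path))
      stop_entrainr("config", paste("config file not found:", path))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else path
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop_entrainr("config", paste("unknown config keys:",
                                  paste(unknown, collapse = ", ")))
  required <- list(c("master_seed"),
                   c("paradigm", "fs_hz"),
                   c("paradigm", "syllable_dur_s"))
  merged <- utils::modifyList(def, cfg)
  for (keypath in required) {
    node <- cfg
    for (k in keypath) node <- node[[k]]
    if (is.null(node) && length(keypath) > 1L) {
      # tolerate omission of a whole section (defaults apply), but an
      # explicitly present section must carry its required keys
      sect <- cfg[[keypath[1]]]
      if (!is.null(sect) && is.null(sect[[keypath[2]]]))
        stop_entrainr("config",
                      paste("config missing required key:",
                            paste(keypath, collapse = ".")))
    }
    if (length(keypath) == 1L && is.null(cfg[[keypath]]))
      stop_entrainr("config",
                    paste("config missing required key:", keypath))
  }
  if (is.list(merged$erp$windows_ms) == FALSE)
    merged$erp$windows_ms <- split(merged$erp$windows_ms,
                                   seq_len(nrow(merged$erp$windows_ms)))
  if (is.matrix(merged$correlation$pairs))
    merged$correlation$pairs <- split(merged$correlation$pairs,
                                      seq_len(nrow(merged$correlation$pairs)))
  merged
}

#' Tagging-experiment analysis for one subject
#'
#' Filter (zero-phase FIR band-pass), exclude the fixed noisy/frontal
#' channels, common-average re-reference, interpolate configured bad
#' channels, epoch trials (dropping the first sentence when the paradigm
#' says so), average, and compute the neighbor-normalized evoked power and
#' the peak/neighbor pair at each tagged rate.
#'
#' @param rec Entrainment `eeg_recording` (events labeled `"trial"`).
#' @param spec A [paradigm_spec()].
#' @param montage The recording's `eeg_montage`.
#' @param band_hz Band-pass edges (default `c(0.1, 25)`).
#' @param exclude_channels,frontal_exclude Labels removed before
#'   referencing.
#' @param bad_channels Labels interpolated after referencing.
#' @param filter Apply the FIR band-pass (default `TRUE`; reduced-scale
#'   simulation studies may skip it).
#' @return List with `spectrum` (`spectrum_set`) and `pairs` (data frame
#'   of `rate`, `peak_db`, `neighbor_db`).
#' @export
process_entrainment_subject <- function(rec, spec, montage,
                                        band_hz = c(0.1, 25),
                                        exclude_channels = c("T7", "T8", "TP7", "TP8"),
                                        frontal_exclude = c("Fp1", "Fp2"),
                                        bad_channels = character(),
                                        filter = TRUE) {
  if (filter) rec <- fir_bandpass(rec, band_hz[1], band_hz[2])
  rec <- drop_channels(rec, c(exclude_channels, frontal_exclude))
  rec <- rereference(rec, "common_average")
  if (length(bad_channels))
    rec <- interpolate_channels(rec, bad_channels, montage)
  tmin <- if (spec$drop_first_sentence) sentence_duration(spec) else 0
  tmax <- spec$sentences_per_trial * sentence_duration(spec)
  es <- epoch_by_events(rec, "trial", tmin, tmax)
  avg <- evoked_average(es)
  ss <- evoked_power(avg, spec$fs_hz, spec)
  ss <- neighbor_normalize(ss)
  tf <- tag_frequencies(spec)
  rates <- c(sentential = tf$sentential_hz, phrasal = tf$phrasal_hz,
             syllabic = tf$syllabic_hz)
  pairs <- do.call(rbind, lapply(names(rates), function(r) {
    pp <- subject_peak_pair(ss, bin_index(rates[[r]], spec))
    data.frame(rate = r, peak_db = pp[["peak_db"]],
               neighbor_db = pp[["neighbor_db"]])
  }))
  list(spectrum = ss, pairs = pairs)
}

#' N400 analysis for one subject
#'
#' Filter, linked-mastoid re-reference, drop excluded/mastoid channels,
#' epoch -100..700 ms around critical words, baseline-correct to the
#' pre-stimulus window, reject epochs exceeding the amplitude threshold,
#' and average per condition.
#'
#' @param rec N400 `eeg_recording` (events labeled by condition).
#' @param band_hz Band-pass edges (default `c(0.1, 30)`).
#' @param mastoids Mastoid reference labels.
#' @param exclude_channels,frontal_exclude Labels removed after
#'   referencing.
#' @param threshold_uv Rejection threshold (default 75).
#' @param tmin_s,tmax_s Epoch window (defaults -0.1 / 0.7 s).
#' @param filter Apply the FIR band-pass (default `TRUE`).
#' @return List with `erps` (`subject_erps`) and `rejected_fraction`.
#' @export
process_n400_subject <- function(rec, band_hz = c(0.1, 30),
                                 mastoids = c("TP9", "TP10"),
                                 exclude_channels = c("T7", "T8", "TP7", "TP8"),
                                 frontal_exclude = c("Fp1", "Fp2"),
                                 threshold_uv = 75,
                                 tmin_s = -0.1, tmax_s = 0.7,
                                 filter = TRUE) {
  if (filter) rec <- fir_bandpass(rec, band_hz[1], band_hz[2])
  rec <- rereference(rec, "linked_mastoids", mastoid_labels = mastoids)
  rec <- drop_channels(rec, c(exclude_channels, frontal_exclude, mastoids))
  es <- epoch_by_events(rec, c("congruent", "incongruent"), tmin_s, tmax_s)
  es <- baseline_correct(es, tmin_s, 0)
  es <- reject_epochs(es, threshold_uv)
  list(erps = condition_erps(es),
       rejected_fraction = attr(es, "rejected_fraction"))
}

run_group <- function(group, cfg, spec, montage, verbose = FALSE) {
  cs <- cohort_spec(group = group, n_subjects = cfg$cohort$n_subjects,
                    coupling_rho = cfg$cohort$coupling_rho,
                    master_seed = cfg$master_seed +
                      match(group, c("NL", "SL")) * 1000L)
  subjects <- draw_cohort(cs)
  pp <- cfg$preprocess
  rows <- list(); erps_list <- list()
  for (i in seq_along(subjects)) {
    sp <- subjects[[i]]
    log_msg("INFO", sprintf("subject %s (seed %d)", sp$subject_id, sp$seed),
            verbose = verbose)
    rec <- simulate_entrainment(sp, spec, montage)
    ent <- process_entrainment_subject(
      rec, spec, montage, band_hz = pp$entrainment_band_hz,
      exclude_channels = pp$exclude_channels,
      frontal_exclude = pp$frontal_exclude,
      bad_channels = pp$bad_channels)
    rm(rec)
    rec4 <- simulate_n400(sp, cfg$n400$n_sentences_per_condition, montage,
                          fs_hz = spec$fs_hz, soa_s = cfg$n400$soa_s)
    rec4 <- inject_artifacts(rec4, sp)
    n4 <- process_n400_subject(
      rec4, band_hz = pp$n400_band_hz, mastoids = pp$mastoids,
      exclude_channels = pp$exclude_channels,
      frontal_exclude = pp$frontal_exclude,
      threshold_uv = pp$reject_threshold_uv)
    rm(rec4)
    erps_list[[i]] <- n4$erps
    wins <- cfg$erp$windows_ms
    eff <- vapply(wins, function(w) {
      roi_window_means(n4$erps, roi_labels = cfg$erp$roi,
                       win_ms = w)$effect_uv
    }, 0)
    pr <- ent$pairs
    rows[[i]] <- data.frame(
      subject_id = sp$subject_id, group = group,
      sentential_db = pr$peak_db[pr$rate == "sentential"] -
        pr$neighbor_db[pr$rate == "sentential"],
      phrasal_db = pr$peak_db[pr$rate == "phrasal"] -
        pr$neighbor_db[pr$rate == "phrasal"],
      syllabic_db = pr$peak_db[pr$rate == "syllabic"] -
        pr$neighbor_db[pr$rate == "syllabic"],
      n400_early_uv = eff[1], n400_late_uv = eff[2],
      rejected_fraction = n4$rejected_fraction,
      comprehension_rating = sp$comprehension_rating,
      question_accuracy = sp$question_accuracy,
      listening_score = sp$listening_score,
      peak_sentential_db = pr$peak_db[pr$rate == "sentential"],
      neighbor_sentential_db = pr$neighbor_db[pr$rate == "sentential"],
      peak_phrasal_db = pr$peak_db[pr$rate == "phrasal"],
      neighbor_phrasal_db = pr$neighbor_db[pr$rate == "phrasal"],
      peak_syllabic_db = pr$peak_db[pr$rate == "syllabic"],
      neighbor_syllabic_db = pr$neighbor_db[pr$rate == "syllabic"])
  }
  list(table = do.call(rbind, rows), erps = erps_list)
}

#' Run the full analysis pipeline
#'
#' Simulates both cohorts, runs the tagging and N400 analyses per subject,
#' computes the group peak tests at the three tagged rates, the ROI window
#' contrasts, the point-wise FDR maps, the behavioral group comparisons,
#' and the correlations, and writes the cohort table (TSV) plus per-stage
#' JSON reports to `out_dir`. Fully reproducible given the master seed.
#'
#' @param config Config path (JSON) or list; see [default_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Optional integer overriding the config's `master_seed`.
#' @param verbose Log progress to standard error.
#' @return List with `cohort_table` and `reports` (invisible when written).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         seed = NULL, verbose = FALSE) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$master_seed <- as.integer(seed)
  log_msg("INFO", sprintf("pipeline start, master seed %d", cfg$master_seed),
          verbose = verbose)
  spec <- do.call(paradigm_spec, cfg$paradigm)
  montage <- make_montage(preset = cfg$montage$preset %||% "full64",
                          channels = cfg$montage$channels)
  groups <- cfg$cohort$groups
  res <- lapply(groups, run_group, cfg = cfg, spec = spec,
                montage = montage, verbose = verbose)
  names(res) <- groups
  table <- do.call(rbind, lapply(res, `[[`, "table"))
  rownames(table) <- NULL

  tf <- tag_frequencies(spec)
  entrainment <- lapply(groups, function(g) {
    tb <- res[[g]]$table
    tests <- lapply(c("sentential", "phrasal", "syllabic"), function(r) {
      pt <- group_peak_test(tb[[paste0("peak_", r, "_db")]],
                            tb[[paste0("neighbor_", r, "_db")]], rate = r)
      pt[c("rate", "t_statistic", "df", "p_value", "mean_diff_db",
           "significant")]
    })
    names(tests) <- c("sentential", "phrasal", "syllabic")
    tests
  })
  names(entrainment) <- groups

  n400 <- lapply(groups, function(g) {
    erps <- res[[g]]$erps
    wins <- cfg$erp$windows_ms
    effects <- lapply(wins, function(w) {
      e <- roi_window_effect(erps, roi_labels = cfg$erp$roi, win_ms = w)
      list(window_ms = w, mean_effect_uv = e$mean_effect_uv,
           t_statistic = e$t_statistic, df = e$df,
           p_two_tailed = e$p_two_tailed, ci95 = e$ci95)
    })
    map <- pointwise_fdr_map(erps, q = cfg$erp$fdr_q)
    list(windows = effects,
         mean_rejected_fraction =
           mean(res[[g]]$table$rejected_fraction),
         earliest_sig_roi_ms =
           1000 * earliest_significant_time(map, cfg$erp$roi))
  })
  names(n400) <- groups

  behavior <- if (length(groups) == 2L) {
    t1 <- res[[groups[1]]]$table; t2 <- res[[groups[2]]]$table
    list(comprehension_rating = independent_t(t1$comprehension_rating,
                                              t2$comprehension_rating),
         question_accuracy = independent_t(t1$question_accuracy,
                                           t2$question_accuracy))
  } else NULL

  corr_group <- cfg$correlation$group
  correlation <- if (corr_group %in% groups) {
    lapply(correlate_measures(res[[corr_group]]$table,
                              pairs = cfg$correlation$pairs),
           function(cr) list(pair = cr$labels, rho = cr$rho, n = cr$n,
                             p_two_tailed = cr$p))
  } else NULL

  reports <- list(entrainment = entrainment, n400 = n400,
                  behavior = behavior, correlation = correlation,
                  master_seed = cfg$master_seed)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "reports"), recursive = TRUE,
               showWarnings = FALSE)
    write_cohort_table(table, file.path(out_dir, "cohort_table.tsv"))
    for (nm in c("entrainment", "n400", "behavior", "correlation"))
      jsonlite::write_json(reports[[nm]],
                           file.path(out_dir, "reports",
                                     paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
    log_msg("INFO", paste("reports written to", out_dir), verbose = verbose)
  }
  out <- list(cohort_table = table, reports = reports)
  if (is.null(out_dir)) out else invisible(out)
}
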