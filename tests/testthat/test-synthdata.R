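test_that("generators are pure functions of parameters and seed", {
  spec <- tiny_spec(2)
  m <- mini_montage()
  sp <- quick_subject(101)
  r1 <- simulate_entrainment(sp, spec, m)
  r2 <- simulate_entrainment(sp, spec, m)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)

  n1 <- simulate_n400(sp, 4, m, fs_hz = 100)
  n2 <- simulate_n400(sp, 4, m, fs_hz = 100)
  expect_identical(n1$data, n2$data)

  # different noise seed, shared schedule seed: same marker sequence
  spA <- quick_subject(102)
  spB <- quick_subject(103)
  nA <- simulate_n400(spA, 6, m, fs_hz = 100, schedule_seed = 77)
  nB <- simulate_n400(spB, 6, m, fs_hz = 100, schedule_seed = 77)
  expect_identical(nA$events$label, nB$events$label)
  expect_false(identical(nA$data, nB$data))
})

test_that("noise-free trials put power only at the tagged bins", {
  spec <- tiny_spec(1)
  m <- mini_montage()
  sp <- quick_subject(5, phase_sentential = 0.9, phase_phrasal = 2.2,
                      phase_syllabic = 4.1)
  rec <- simulate_entrainment(sp, spec, m, noise = FALSE)
  es <- epoch_by_events(rec, "trial", sentence_duration(spec),
                        spec$sentences_per_trial * sentence_duration(spec))
  ss <- evoked_power(evoked_average(es), spec$fs_hz, spec)
  tagged <- vapply(unlist(tag_frequencies(spec)), bin_index, 1L,
                   spec = spec)
  peak <- max(ss$power_uv2[, tagged])
  expect_lt(max(ss$power_uv2[, -tagged]) / peak, 1e-9)
  # per-channel power matches amp^2 * gain^2 exactly
  cz <- which(m$label == "Cz")
  expect_equal(ss$power_uv2[cz, tagged],
               (c(sp$amp_sentential, sp$amp_phrasal, sp$amp_syllabic) *
                  m$osc_gain[cz])^2,
               tolerance = 1e-9)
})

test_that("background noise has 1/f spectral slope over 0.5-20 Hz", {
  set.seed(55)
  fs <- 250; n <- 4096
  pxx <- 0
  for (i in 1:120) {
    x <- entrainr:::pink_noise(n, 1)
    pxx <- pxx + Mod(fft(x)[2:(n / 2)])^2
  }
  f <- (1:(n / 2 - 1)) * fs / n
  sel <- f >= 0.5 & f <= 20
  slope <- coef(lm(log10(pxx[sel]) ~ log10(f[sel])))[2]
  expect_gte(slope, -1.3)
  expect_lte(slope, -0.7)
})

test_that("N400 generator recovers the injected effect in the noise-free limit", {
  m <- mini_montage()
  sp <- quick_subject(12, n400_effect = -1.0)
  rec <- simulate_n400(sp, 5, m, noise = FALSE)
  n4 <- process_n400_subject(rec)
  r <- roi_window_means(n4$erps, roi_labels = mini_roi(),
                        win_ms = c(300, 700))
  expect_lt(abs(r$effect_uv - sp$n400_effect) / abs(sp$n400_effect), 0.02)

  # zero effect: the two condition ERPs coincide
  sp0 <- quick_subject(13, n400_effect = 0)
  rec0 <- simulate_n400(sp0, 5, m, noise = FALSE)
  erps0 <- process_n400_subject(rec0, filter = FALSE)$erps
  expect_equal(erps0$erp$congruent, erps0$erp$incongruent,
               tolerance = 1e-9)
})

test_that("artifact injection matches its rate and drives rejection", {
  m <- mini_montage()
  sp0 <- quick_subject(20, artifact_rate = 0)
  rec <- simulate_n400(sp0, 10, m, fs_hz = 100, soa_s = 1)
  expect_identical(inject_artifacts(rec, sp0)$data, rec$data)

  sp1 <- quick_subject(21, artifact_rate = 1, noise_scale = 1)
  rec1 <- simulate_n400(sp1, 10, m, fs_hz = 100, soa_s = 1)
  art1 <- inject_artifacts(rec1, sp1)
  expect_length(art1$metadata$artifact_events, 20L)
  es <- epoch_by_events(art1, c("congruent", "incongruent"), -0.1, 0.7)
  es <- baseline_correct(es, -0.1, 0)
  es <- reject_epochs(es, 75)
  expect_identical(sum(es$retained), 0L)

  # binomial check at the study's rate over 1000 event-aligned segments
  sp2 <- quick_subject(22, artifact_rate = 0.12, noise_scale = 1)
  rec2 <- new_recording(matrix(0, 2, 1000 * 100 + 200), 100,
                        c("Cz", "Pz"),
                        events = data.frame(
                          sample = as.integer(seq(50, by = 100,
                                                  length.out = 1000)),
                          label = "word"))
  art2 <- inject_artifacts(rec2, sp2)
  frac <- length(art2$metadata$artifact_events) / 1000
  expect_gte(frac, 0.09)
  expect_lte(frac, 0.15)

  # ground truth equals the rejected set when the clean signal is small
  es2 <- epoch_by_events(art2, "word", -0.1, 0.7)
  es2 <- reject_epochs(es2, 75)
  expect_identical(which(!es2$retained) - 1L,
                   art2$metadata$artifact_events)
})

test_that("copula cohorts realize the target rank coupling", {
  # comonotone limit: perfectly co-ranked
  cs1 <- cohort_spec("NL", n_subjects = 40, coupling_rho = 1,
                     master_seed = 3)
  co1 <- draw_cohort(cs1)
  amp <- vapply(co1, `[[`, 0, "amp_sentential")
  mag <- abs(vapply(co1, `[[`, 0, "n400_effect"))
  expect_equal(cor(amp, mag, method = "spearman"), 1)

  # independence limit at large n (Monte-Carlo tolerance)
  cs0 <- cohort_spec("NL", n_subjects = 1000, coupling_rho = 0,
                     master_seed = 4)
  co0 <- draw_cohort(cs0)
  amp0 <- vapply(co0, `[[`, 0, "amp_sentential")
  mag0 <- abs(vapply(co0, `[[`, 0, "n400_effect"))
  expect_lt(abs(cor(amp0, mag0, method = "spearman")), 0.07)

  # determinism
  expect_identical(draw_cohort(cs1), draw_cohort(cs1))

  expect_error(cohort_spec("NL",
                           dists = list(n400_latency_ms =
                                          list(mean = 400, sd = -1))),
               class = "entrainr_degenerate_distribution")
})

test_that("group defaults encode the NL/SL contrast", {
  nl <- default_group_dists("NL"); sl <- default_group_dists("SL")
  expect_lt(sl$amp_sentential$median, 0.1)
  expect_gt(nl$amp_sentential$median, 0.5)
  expect_lt(nl$n400_latency_ms$mean, sl$n400_latency_ms$mean)
  expect_gt(nl$n400_magnitude$median, sl$n400_magnitude$median)
  expect_equal(nl$artifact_rate$value, 0.123)
})

test_that("subject parameter invariants are enforced", {
  expect_error(quick_subject(1, amp_phrasal = -1),
               class = "entrainr_bad_spec")
  expect_error(quick_subject(1, noise_scale = 0),
               class = "entrainr_bad_spec")
  expect_error(quick_subject(1, artifact_rate = 1.5),
               class = "entrainr_bad_spec")
  expect_error(quick_subject(1, n400_latency_ms = 800),
               class = "entrainr_bad_spec")
})
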