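test_that("the trial average behaves like a mean", {
  set.seed(2)
  x <- array(rnorm(1 * 2 * 30), c(1, 2, 30))
  es <- new_epoch_set(x, 100, 0, "a", TRUE, c("c1", "c2"))
  expect_equal(unname(evoked_average(es)), x[1, , ])

  x2 <- array(0, c(2, 2, 30))
  x2[1, , ] <- x[1, , ]; x2[2, , ] <- -x[1, , ]
  es2 <- new_epoch_set(x2, 100, 0, c("a", "a"), c(TRUE, TRUE),
                       c("c1", "c2"))
  expect_equal(unname(evoked_average(es2)), matrix(0, 2, 30))

  es3 <- es
  es3$retained <- FALSE
  expect_error(evoked_average(es3), class = "entrainr_no_retained_epochs")
})

test_that("averaging shrinks independent noise like 1/sqrt(n)", {
  set.seed(43)
  template <- sin(2 * pi * 4 * (0:199) / 100)
  rms <- vapply(c(4, 16, 64), function(n) {
    reps <- vapply(1:40, function(r) {
      x <- array(0, c(n, 1, 200))
      for (i in seq_len(n)) x[i, 1, ] <- template + rnorm(200)
      es <- new_epoch_set(x, 100, 0, rep("a", n), rep(TRUE, n), "c1")
      sqrt(mean((evoked_average(es)[1, ] - template)^2))
    }, 0)
    mean(reps)
  }, 0)
  expect_equal(rms[1] / rms[2], 2, tolerance = 0.25)
  expect_equal(rms[2] / rms[3], 2, tolerance = 0.25)
})

test_that("evoked power is exact for bin-aligned sinusoids", {
  spec <- paradigm_spec()
  fs <- spec$fs_hz
  n <- round(epoch_duration(spec) * fs)     # 7040
  t <- (0:(n - 1)) / fs
  avg <- rbind(sin(2 * pi * 3.125 * t), 2 * sin(2 * pi * 3.125 * t))
  rownames(avg) <- c("a", "b")
  ss <- evoked_power(avg, fs, spec)
  b44 <- bin_index(3.125, spec)
  expect_equal(unname(ss$power_uv2[1, b44]), 1.0, tolerance = 1e-9)
  expect_equal(unname(ss$power_db[1, b44]), 0, tolerance = 1e-6)
  expect_lt(max(ss$power_uv2[1, -b44]), 1e-12)
  expect_equal(unname(ss$power_db[2, b44]), 10 * log10(4), tolerance = 1e-6)

  expect_error(evoked_power(avg[, 1:100], fs, spec),
               class = "entrainr_length_mismatch")
})

test_that("the FFT path equals the brute-force DFT oracle", {
  set.seed(47)
  small <- paradigm_spec(sentences_per_trial = 2, fs_hz = 100)  # 128 samples
  n <- round(epoch_duration(small) * 100)
  for (i in 1:10) {
    x <- rnorm(n)
    ss <- evoked_power(rbind(x), 100, small)
    expect_equal(as.vector(ss$power_uv2), brute_power(x),
                 tolerance = 1e-9)
  }
})

test_that("two-sided power accounting satisfies Parseval", {
  set.seed(53)
  for (n in c(128, 249)) {
    x <- rnorm(n)
    p <- as.vector(evoked_power(rbind(x), 100)$power_uv2)
    nb <- floor(n / 2)
    recon <- mean(x)^2 + sum(p[seq_len(nb - 1)]) / 2 +
      if (n %% 2 == 0) p[nb] else p[nb] / 2
    expect_equal(recon, mean(x^2), tolerance = 1e-9)
  }
})

test_that("neighbor normalization subtracts the local floor", {
  flat <- matrix(3, 1, 20)
  ss <- list(power_db = flat, frequencies = 1:20, channel_labels = "a")
  class(ss) <- "spectrum_set"
  nn <- neighbor_normalize(ss)
  expect_true(all(nn$normalized_db[1, 3:18] == 0))
  expect_true(all(is.na(nn$normalized_db[1, c(1, 2, 19, 20)])))

  peaky <- flat; peaky[1, 10] <- 13    # +10 dB over the floor
  ss$power_db <- peaky
  nn2 <- neighbor_normalize(ss)
  expect_equal(nn2$normalized_db[1, 10], 10)
  expect_equal(nn2$normalized_db[1, 9], -2.5)
  expect_equal(nn2$normalized_db[1, 11], -2.5)
})

test_that("white-noise spectra have zero expected normalized power", {
  set.seed(59)
  # average over all interior bins and 200 simulated subjects: the
  # neighbor contrast has zero expectation on a flat spectrum
  vals <- vapply(1:200, function(i) {
    x <- rnorm(256)
    ss <- neighbor_normalize(evoked_power(rbind(x), 100))
    mean(ss$normalized_db[1, ], na.rm = TRUE)
  }, 0)
  expect_lt(abs(mean(vals)), 0.2)
})

test_that("peak pairs aggregate electrodes in dB before the contrast", {
  freqs <- 1:30
  one <- matrix(rep(c(rep(0, 9), 4, rep(0, 20)), 1), 1, 30, byrow = TRUE)
  ss1 <- structure(list(power_db = one, frequencies = freqs,
                        channel_labels = "a"), class = "spectrum_set")
  both <- rbind(one, one)
  ss2 <- structure(list(power_db = both, frequencies = freqs,
                        channel_labels = c("a", "b")),
                   class = "spectrum_set")
  expect_equal(subject_peak_pair(ss1, 10L), subject_peak_pair(ss2, 10L))

  two <- rbind(one, one); two[1, 10] <- 4; two[2, 10] <- 6
  ss3 <- structure(list(power_db = two, frequencies = freqs,
                        channel_labels = c("a", "b")),
                   class = "spectrum_set")
  expect_equal(unname(subject_peak_pair(ss3, 10L)["peak_db"]), 5)

  expect_error(subject_peak_pair(ss1, 2L), class = "entrainr_undefined_bin")
  expect_error(subject_peak_pair(ss1, 10L, electrodes = "zz"),
               class = "entrainr_missing_channel")
})

test_that("a noise-free peak towers over the machine floor", {
  spec <- tiny_spec(1)
  m <- make_montage(channels = c("Cz", "C1", "C2"))
  sp <- quick_subject(3, amp_sentential = 1, amp_phrasal = 0,
                      amp_syllabic = 0)
  rec <- simulate_entrainment(sp, spec, m, noise = FALSE)
  es <- epoch_by_events(rec, "trial", sentence_duration(spec),
                        spec$sentences_per_trial * sentence_duration(spec))
  ss <- evoked_power(evoked_average(es), spec$fs_hz, spec)
  pp <- subject_peak_pair(ss, bin_index(0.78125, spec))
  expect_gt(pp["peak_db"] - pp["neighbor_db"], 100)
})

test_that("the group peak test follows the paired-t arithmetic", {
  r0 <- group_peak_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r0$t_statistic, 0)
  expect_identical(r0$p_value, 0.5)

  r <- group_peak_test(c(2, 3, 4), c(1, 1, 1), rate = "sentential")
  expect_equal(r$t_statistic, 2 / (1 / sqrt(3)), tolerance = 1e-4)
  expect_identical(r$df, 2L)
  expect_equal(r$p_value, pt(2 / (1 / sqrt(3)), 2, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(round(r$p_value, 4), 0.0371)

  rpos <- group_peak_test(c(2, 3, 4), c(1, 2, 3))
  expect_identical(rpos$p_value, 0)
  rneg <- group_peak_test(c(1, 2, 3), c(2, 3, 4))
  expect_identical(rneg$p_value, 1)
})

test_that("raising an amplitude raises its normalized peak (signal regime)", {
  spec <- tiny_spec(6)
  m <- mini_montage()
  prev <- -Inf
  # noise held fixed by the shared seed; amplitudes span the regime where
  # the tagged signal exceeds the per-bin noise floor
  for (amp in c(0.5, 1, 2, 4)) {
    sp <- quick_subject(91, amp_sentential = amp, noise_scale = 2)
    pr <- quick_peak_pairs(sp, spec, m)
    cur <- pr$peak_db[pr$rate == "sentential"] -
      pr$neighbor_db[pr$rate == "sentential"]
    expect_gt(cur, prev)
    prev <- cur
  }
})
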