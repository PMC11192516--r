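test_that("the band-pass passes in-band tones and kills DC and stopband", {
  fs <- 500
  t <- (0:9999) / fs
  rec <- new_recording(rbind(sin(2 * pi * 3.125 * t),
                             rep(10, length(t)),
                             sin(2 * pi * 50 * t)),
                       fs, c("tone", "dc", "hum"))
  out <- fir_bandpass(rec, 0.1, 25)
  mid <- 3000:7000   # steady state, edges trimmed
  expect_gte(max(abs(out$data[1, mid])), 0.99)
  expect_lte(max(abs(out$data[1, mid])), 1.01)
  expect_lt(max(abs(out$data[2, mid])), 0.5)
  expect_lt(20 * log10(max(abs(out$data[3, mid]))), -40)
})

test_that("filtering is linear to numerical precision", {
  set.seed(3)
  fs <- 200; n <- 2000
  x <- rnorm(n); y <- rnorm(n)
  h <- entrainr:::design_fir_bandpass(1, 40, fs)
  fx <- entrainr:::apply_fir_zerophase(rbind(x), h)
  fy <- entrainr:::apply_fir_zerophase(rbind(y), h)
  fxy <- entrainr:::apply_fir_zerophase(rbind(2 * x - 3 * y), h)
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-9)
})

test_that("band edges are validated", {
  rec <- new_recording(matrix(0, 1, 100), 100, "a")
  expect_error(fir_bandpass(rec, 30, 10), class = "entrainr_bad_band")
  expect_error(fir_bandpass(rec, 1, 60), class = "entrainr_bad_band")
})

test_that("re-referencing follows the reference algebra", {
  set.seed(11)
  rec <- new_recording(matrix(rnorm(4 * 300), 4, 300), 100,
                       c("a", "b", "TP9", "TP10"))
  car <- rereference(rec, "common_average")
  expect_lt(max(abs(colMeans(car$data))), 1e-10)

  two <- new_recording(matrix(rnorm(2 * 50), 2, 50), 100, c("L", "R"))
  lm2 <- rereference(two, "linked_mastoids", mastoid_labels = c("L", "R"))
  expect_equal(lm2$data[1, ], (two$data[1, ] - two$data[2, ]) / 2)
  expect_equal(lm2$data[2, ], -lm2$data[1, ])

  expect_error(rereference(two, "linked_mastoids",
                           mastoid_labels = c("L", "M99")),
               class = "entrainr_missing_channel")
})

test_that("triangulation interpolation reconstructs known geometries", {
  m <- triangle_montage()
  s <- sin(2 * pi * 3 * (0:99) / 100)
  # all neighbors carry the same signal -> the bad channel becomes it
  rec <- new_recording(rbind(s, s, s, rnorm(100)), 100, m$label)
  fixed <- interpolate_channels(rec, "M", m)
  expect_equal(fixed$data[4, ], s, tolerance = 1e-12)

  # equilateral layout: the center is the unweighted mean of the corners
  set.seed(21)
  rec2 <- new_recording(matrix(rnorm(4 * 80), 4, 80), 100, m$label)
  fixed2 <- interpolate_channels(rec2, "M", m)
  expect_equal(fixed2$data[4, ], colMeans(rec2$data[1:3, ]),
               tolerance = 1e-9)

  expect_error(interpolate_channels(rec2, m$label, m),
               class = "entrainr_island_channel")
})

test_that("epoching uses half-open windows and drops overruns", {
  fs <- 500
  rec <- new_recording(matrix(rnorm(2 * 5000), 2, 5000), fs, c("a", "b"),
                       events = data.frame(sample = c(10L, 1000L, 2000L),
                                           label = "word"))
  expect_warning(es <- epoch_by_events(rec, "word", -0.1, 0.7),
                 "overrunning")
  expect_identical(dim(es$data), c(2L, 2L, 400L))   # 0.8 s x 500 Hz
  expect_identical(es$t0_offset_s, -0.1)

  spec <- paradigm_spec()
  m <- make_montage(channels = c("Cz", "Pz"))
  sp <- quick_subject(2)
  rec2 <- simulate_entrainment(sp, spec, m, noise = FALSE)
  es2 <- epoch_by_events(rec2, "trial", sentence_duration(spec),
                         spec$sentences_per_trial * sentence_duration(spec))
  expect_identical(dim(es2$data)[3], 7040L)         # 14.08 s x 500 Hz
  expect_identical(dim(es2$data)[1], spec$n_trials)

  expect_error(epoch_by_events(rec, "absent", -0.1, 0.7),
               class = "entrainr_no_events")
})

test_that("amplitude rejection is threshold-exact, idempotent, order-free", {
  set.seed(33)
  data <- array(runif(6 * 2 * 50, -74, 74), c(6, 2, 50))
  data[2, 1, 10] <- 80          # single sample above threshold
  data[5, 2, 3] <- -90
  es <- new_epoch_set(data, 100, 0, rep("x", 6), rep(TRUE, 6),
                      c("a", "b"))
  r1 <- reject_epochs(es, 75)
  expect_identical(r1$retained, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(attr(r1, "rejected_fraction"), 2 / 6)

  r2 <- reject_epochs(r1, 75)   # idempotent
  expect_identical(r2$retained, r1$retained)
  expect_equal(attr(r2, "rejected_fraction"), 0)

  perm <- c(4, 2, 6, 1, 3, 5)
  es_p <- new_epoch_set(data[perm, , , drop = FALSE], 100, 0,
                        rep("x", 6), rep(TRUE, 6), c("a", "b"))
  expect_identical(reject_epochs(es_p, 75)$retained, r1$retained[perm])
})

test_that("baseline correction zeroes the window mean", {
  fs <- 500
  n <- 400
  tt <- -0.1 + (0:(n - 1)) / fs
  ramp <- matrix(rep(tt, each = 2), nrow = 2)
  data <- array(0, c(2, 2, n))
  data[1, , ] <- ramp
  data[2, , ] <- 5              # constant epoch
  es <- new_epoch_set(data, fs, -0.1, rep("x", 2), rep(TRUE, 2),
                      c("a", "b"))
  out <- baseline_correct(es, -0.1, 0)
  sel <- tt >= -0.1 & tt < 0
  expect_lt(max(abs(apply(out$data[, , sel], c(1, 2), mean))), 1e-10)
  expect_equal(out$data[2, 1, ], rep(0, n))
  # a linear ramp is shifted by exactly the baseline-sample mean time
  expect_equal(out$data[1, 1, ], tt - mean(tt[sel]), tolerance = 1e-12)
  expect_error(baseline_correct(es, 10, 11), class = "entrainr_empty_window")
})

test_that("noisy-channel exclusion happens before the common average", {
  spec <- tiny_spec()
  m <- make_montage(channels = c("Cz", "C1", "C2", "T7"))
  sp <- quick_subject(8, noise_scale = 1)
  rec <- simulate_entrainment(sp, spec, m)
  clean <- process_entrainment_subject(rec, spec, m,
                                       exclude_channels = "T7",
                                       frontal_exclude = character(),
                                       filter = FALSE)
  # corrupt the excluded channel massively: results must not change
  rec2 <- rec
  rec2$data[rec2$channel_labels == "T7", ] <- 1e4
  dirty <- process_entrainment_subject(rec2, spec, m,
                                       exclude_channels = "T7",
                                       frontal_exclude = character(),
                                       filter = FALSE)
  expect_equal(dirty$pairs, clean$pairs, tolerance = 1e-12)
})
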