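make_rec <- function(signal, sr = 1000, channel_names = NULL, events = NULL) {
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(signal)))
  }
  new_recording(signal, sr, events = events, channel_names = channel_names)
}

test_that("filtering attenuates line noise, removes DC and preserves the passband", {
  sr <- 1000
  t <- (0:(5 * sr - 1)) / sr
  mid <- seq(sr, 4 * sr)  # avoid edge transients when measuring gain
  sig <- rbind(
    50 * sin(2 * pi * 60 * t),      # line noise
    rep(100, length(t)),            # DC offset
    10 * sin(2 * pi * 10 * t)       # in-band signal
  )
  rec <- bandpass_notch(make_rec(sig, sr))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(rec$signal[1, ]), 0.1 * rms(sig[1, ]))     # >= 20 dB notch
  expect_lt(abs(mean(rec$signal[2, ])), 1e-6)              # DC removed
  gain10 <- rms(rec$signal[3, mid]) / rms(sig[3, mid])
  expect_lt(abs(gain10 - 1), 0.05)                         # passband intact
  expect_error(bandpass_notch(make_rec(sig, sr), lp = 600),
               "invalid-filter")
})

test_that("bad-channel rules flag flat and high-variance channels only", {
  set.seed(8)
  sig <- rbind(
    rep(0, 2000),                 # SD 0: flat
    rnorm(2000, sd = 500),        # way above 120 uV
    rnorm(2000, sd = 20)          # healthy
  )
  rec <- make_rec(sig)
  expect_identical(detect_bad_channels(rec), c("ch1", "ch2"))
  all_flat <- make_rec(matrix(0, 2, 100))
  expect_error(detect_bad_channels(all_flat), "data-quality")
})

test_that("average re-reference zeroes the channel mean and matches the closed form", {
  set.seed(9)
  sig <- matrix(rnorm(8 * 1000, sd = 30), 8, 1000)
  rec <- rereference_average(make_rec(sig))
  expect_lt(max(abs(colMeans(rec$signal))), 1e-9)
  # brute-force subtract-column-mean oracle
  oracle <- sweep(sig, 2, colMeans(sig))
  expect_equal(unname(rec$signal), oracle, tolerance = 1e-12)
  # idempotence
  rec2 <- rereference_average(rec)
  expect_equal(rec2$signal, rec$signal, tolerance = 1e-12)
  # two-channel closed form
  two <- rereference_average(make_rec(matrix(c(4, 10, 2, 6), 2, 2,
                                             byrow = TRUE)))
  expect_equal(unname(two$signal[1, ]), c(1, 2))
  expect_equal(unname(two$signal[2, ]), c(-1, -2))
  expect_error(rereference_average(make_rec(matrix(0, 1, 10,
    dimnames = list("a", NULL)))), "invalid-input")
})

test_that("artifact removal is conservative without blinks and effective with them", {
  sub <- data.frame(group = "control", age = 16)
  sess <- generate_session(seed = 5, reps_per_position = 1)
  # no blinks: output essentially unchanged
  rec <- simulate_recording(sub, sess,
                            noise = noise_spec(pink_noise_sd = 10,
                                               blink_rate = 0),
                            seed = 21)
  r0 <- rereference_average(flag_bad_channels(rec))
  r1 <- remove_artifact_components(r0)
  rel <- sqrt(mean((r1$signal - r0$signal)^2)) / sqrt(mean(r0$signal^2))
  expect_lt(rel, 0.01)
  # strong blinks: frontal amplitude at blink times cut by at least half
  recb <- simulate_recording(sub, sess,
                             noise = noise_spec(pink_noise_sd = 10,
                                                blink_rate = 10,
                                                blink_amp = 150),
                             seed = 22)
  blinks <- attr(recb, "blink_onsets")
  expect_gt(length(blinks), 0)
  rb0 <- rereference_average(flag_bad_channels(recb))
  rb1 <- remove_artifact_components(rb0)
  idx <- unlist(lapply(blinks, function(x) {
    max(1, x - 50):min(ncol(rb0$signal), x + 50)
  }))
  before <- sqrt(mean(rb0$signal["Fp1", idx]^2))
  after <- sqrt(mean(rb1$signal["Fp1", idx]^2))
  expect_lt(after, 0.5 * before)
  # pure template, no noise: evoked unchanged within 1% RMS at Cz
  recc <- simulate_recording(sub, sess, noise = noise_spec(0, 0, 0, 0, 0, 0, 0),
                             seed = 23)
  rc <- remove_artifact_components(rereference_average(recc))
  evc <- average_by_class(crop_and_baseline(epoch_recording(rc)))
  tpl <- erp_template(sub, "S1")["Cz", ]
  relc <- sqrt(mean((evc$S1$data["Cz", ] - tpl)^2)) / sqrt(mean(tpl^2))
  expect_lt(relc, 0.01)
})

test_that("epoching yields one epoch per event with the right time axis", {
  sub <- data.frame(group = "control", age = 16)
  sess <- generate_session(seed = 6)  # default 450 events
  rec <- simulate_recording(sub, sess, noise = noise_spec(0, 0, 0, 0, 0, 0, 0),
                            seed = 31)
  ep <- epoch_recording(rec)
  expect_identical(length(ep$stim_class), 180L)
  expect_true(all(table(ep$stim_class) == 60))
  expect_equal(ep$time_ms[1], -1000)
  expect_equal(ep$time_ms[length(ep$time_ms)], 999)
  expect_equal(diff(ep$time_ms)[1], 1)
  expect_error(epoch_recording(rec, classes = "nonexistent"),
               "empty-selection")
})

test_that("events too close to the recording edge are skipped and counted", {
  sig <- matrix(rnorm(2 * 3000, sd = 10), 2, 3000,
                dimnames = list(c("Cz", "FCz"), NULL))
  events <- data.frame(onset_sample = c(100, 1500),
                       stim_class = c("S1", "S1"))
  rec <- new_recording(sig, 1000, events)
  expect_message(ep <- epoch_recording(rec), "skipped")
  expect_identical(length(ep$stim_class), 1L)
  expect_identical(attr(ep, "n_skipped"), 1L)
})

test_that("epoch rejection matches a brute-force threshold scan", {
  set.seed(12)
  n_ep <- 100
  dat <- array(rnorm(n_ep * 3 * 400, sd = 55), c(n_ep, 3, 400))
  ep <- new_epoch_set(dat, seq(-199, 200), rep(c("S1", "SPrecDev", "Dev"),
                                               length.out = n_ep),
                      c("Cz", "FCz", "Pz"))
  out <- reject_epochs(ep, limit = 200)
  oracle <- vapply(seq_len(n_ep), function(e) {
    !any(abs(dat[e, , ]) > 200)
  }, TRUE)
  expect_identical(out$keep_mask, oracle)
  # a single 250 uV sample rejects the epoch
  dat2 <- array(0, c(2, 1, 10))
  dat2[1, 1, 4] <- 250
  ep2 <- new_epoch_set(dat2, 1:10, c("S1", "S1"), "Cz")
  out2 <- reject_epochs(ep2)
  expect_identical(out2$keep_mask, c(FALSE, TRUE))
  # all-zero epochs are all kept
  ep3 <- new_epoch_set(array(0, c(4, 1, 10)), 1:10, rep("S1", 4), "Cz")
  expect_true(all(reject_epochs(ep3)$keep_mask))
})

test_that("baseline correction zeroes the baseline and matches the hand oracle", {
  # constant epochs become zero
  epc <- new_epoch_set(array(7, c(2, 1, 800)), seq(-200, 599),
                       c("S1", "S1"), "Cz", window = c(-200, 600))
  out <- crop_and_baseline(epc, c(-200, 600), c(-200, 0))
  expect_true(all(out$data == 0))
  # random input: baseline mean exactly 0, and equals x - mean(x[baseline])
  set.seed(13)
  dat <- array(rnorm(3 * 2 * 800), c(3, 2, 800))
  ep <- new_epoch_set(dat, seq(-200, 599), rep("S1", 3), c("Cz", "FCz"),
                      window = c(-200, 600))
  out2 <- crop_and_baseline(ep, c(-200, 600), c(-200, 0))
  bsel <- out2$time_ms >= -200 & out2$time_ms < 0
  expect_lt(max(abs(apply(out2$data[, , bsel], c(1, 2), mean))), 1e-9)
  for (e in 1:3) for (ch in 1:2) {
    oracle <- dat[e, ch, ] - mean(dat[e, ch, bsel])
    expect_equal(out2$data[e, ch, ], oracle, tolerance = 1e-12)
  }
  # idempotence: re-applying baseline correction changes nothing
  out3 <- crop_and_baseline(out2, c(-200, 600), c(-200, 0))
  expect_equal(out3$data, out2$data, tolerance = 1e-12)
  expect_error(crop_and_baseline(ep, c(-200, 600), c(-400, 0)),
               "invalid-config")
})

test_that("the noise-free full chain preserves the template at Cz within 2% RMS", {
  sub <- data.frame(group = "control", age = 16)
  sess <- generate_session(seed = 5, reps_per_position = 1)
  rec <- simulate_recording(sub, sess, noise = noise_spec(0, 0, 0, 0, 0, 0, 0),
                            seed = 11)
  ep <- preprocess_recording(rec, sd_lo = 0)  # noise-free channels are quiet
  ev <- average_by_class(ep)
  for (cl in c("S1", "SPrecDev", "Dev")) {
    tpl <- erp_template(sub, cl)["Cz", ]
    got <- ev[[cl]]$data["Cz", ]
    expect_lt(sqrt(mean((got - tpl)^2)) / sqrt(mean(tpl^2)), 0.02)
  }
})
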