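test_that("EOG regression recovers known leakage and decorrelates", {
  set.seed(5)
  n <- 512 * 60
  # independent signals: coefficients ~ 0
  eeg0 <- matrix(rnorm(16 * n), 16, n)
  eog0 <- matrix(rnorm(3 * n), 3, n)
  rec0 <- eeg_recording(eeg0, eog0)
  expect_lt(max(abs(estimate_eog_coefficients(rec0))), 0.05)
  # planted single-coefficient mixing
  clean <- matrix(rnorm(16 * n, sd = 2), 16, n)
  eog <- matrix(rnorm(3 * n, sd = 5), 3, n)
  mixed <- clean
  mixed[4, ] <- mixed[4, ] + 0.7 * eog[1, ]
  B <- estimate_eog_coefficients(eeg_recording(mixed, eog))
  expect_equal(unname(B[1, 4]), 0.7, tolerance = 0.02)
  # cleaned signals have near-zero cross-covariance with EOG
  cleaned <- mixed - t(B) %*% eog
  cc <- stats::cov(t(eog), t(cleaned))
  expect_lt(max(abs(cc)), 0.05)
})

test_that("preprocessing is a causal 1-12 Hz band-pass with 50 Hz notch", {
  fs <- 512
  n <- fs * 4
  tt <- (0:(n - 1)) / fs
  mk <- function(x) eeg_recording(matrix(x, 16, n, byrow = TRUE),
                                  matrix(0, 3, n))
  # out-of-band 25 Hz tone attenuated by at least 20 dB
  tone <- sin(2 * pi * 25 * tt)
  out <- preprocess(mk(tone))$eeg[1, ]
  expect_lt(sd(out[fs:(n - 1)]) / sd(tone), 10^(-20 / 20))
  # 50 Hz line tone crushed by the notch + band-pass
  line <- sin(2 * pi * 50 * tt)
  out50 <- preprocess(mk(line))$eeg[1, ]
  expect_lt(sd(out50[fs:(n - 1)]) / sd(line), 10^(-40 / 20))
  # in-band 6 Hz tone survives
  inband <- sin(2 * pi * 6 * tt)
  out6 <- preprocess(mk(inband))$eeg[1, ]
  expect_gt(sd(out6[fs:(n - 1)]) / sd(inband), 0.5)
  # causality: impulse response is zero before the impulse
  imp <- rep(0, n); imp[fs] <- 1
  outi <- preprocess(mk(imp))$eeg[1, ]
  expect_true(all(outi[1:(fs - 1)] == 0))
  # DC rejected after the transient
  outdc <- preprocess(mk(rep(1, n)))$eeg[1, ]
  expect_lt(max(abs(outdc[(3 * fs):n])), 1e-3)
})

test_that("epoching applies the class windows and MAD rejection", {
  fs <- 512
  mk_trial <- function(label, rt = NA, dur = 4) {
    n <- fs * dur
    ev <- data.frame(time = c(0, dur), kind = c("motion_onset", "trial_end"))
    if (label == "erroneous")
      ev <- rbind(ev, data.frame(time = rt, kind = "release"))
    eeg_recording(matrix(rnorm(16 * n), 16, n), matrix(0, 3, n),
                  events = ev[order(ev$time), ], label = label)
  }
  # release RTs {1, 1, 1.05, 3.5}: the far outlier is MAD-rejected
  trials <- list(mk_trial("erroneous", 1.0), mk_trial("erroneous", 1.0),
                 mk_trial("erroneous", 1.05), mk_trial("erroneous", 3.5),
                 mk_trial("correct"), mk_trial("correct"))
  ep <- epoch_trials(trials)
  expect_equal(ep$rejected, 4L)
  expect_equal(sum(ep$labels == "erroneous"), 3L)
  # all epochs are 0.5 s = 256 samples; correct window starts at 1.5 s
  expect_true(all(vapply(ep$epochs, ncol, 0L) == 256L))
  # identical RTs: zero MAD rejects nothing
  same <- list(mk_trial("erroneous", 1.2), mk_trial("erroneous", 1.2),
               mk_trial("erroneous", 1.2), mk_trial("correct"))
  expect_length(epoch_trials(same)$rejected, 0L)
  # an epoch that would run past the recording end is skipped
  short <- list(mk_trial("erroneous", 1.0), mk_trial("erroneous", 1.0),
                mk_trial("erroneous", 3.8), mk_trial("correct"))
  eps <- epoch_trials(short)
  expect_true(3L %in% eps$rejected)
})

test_that("correct-trial epochs reproduce the monitoring-window content", {
  fs <- 512; dur <- 3
  n <- fs * dur
  x <- matrix(seq_len(16 * n), 16, n)   # deterministic ramp per channel
  rec <- eeg_recording(x, matrix(0, 3, n),
                       events = data.frame(time = c(0, dur),
                                           kind = c("motion_onset", "trial_end")),
                       label = "correct")
  err <- eeg_recording(x, matrix(0, 3, n),
                       events = data.frame(time = c(0, 1.0, dur),
                                           kind = c("motion_onset", "release",
                                                    "trial_end")),
                       label = "erroneous")
  ep <- epoch_trials(list(rec, err, err))
  i0 <- round(1.5 * fs) + 1
  expect_equal(ep$epochs[[1]], x[, i0:(i0 + 255)], ignore_attr = TRUE)
  j0 <- round(1.0 * fs) + 1
  expect_equal(ep$epochs[[2]], x[, j0:(j0 + 255)], ignore_attr = TRUE)
})
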