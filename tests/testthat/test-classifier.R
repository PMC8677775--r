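test_that("diagonal LDA posterior follows the logistic discriminant", {
  # zero weights: posterior 1/2 everywhere
  m0 <- structure(list(w = rep(0, 4), b = 0), class = "dlda_model")
  expect_equal(predict_posterior(m0, matrix(rnorm(12), 3, 4)),
               rep(0.5, 3))
  # hand-computed 1-D dLDA on a 4-point separable dataset
  x <- matrix(c(0, 1, 4, 5), ncol = 1)
  labs <- c("correct", "correct", "erroneous", "erroneous")
  m <- fit_classifier(x, labs)
  # raw dLDA: w0 = (mu1 - mu0) / v, b0 = -w0 (mu1 + mu0) / 2; the
  # temperature rescaling divides both by q90(|z|)/4, leaving the
  # boundary and the w:b ratio unchanged
  mu1 <- 4.5; mu0 <- 0.5; v <- (0.5 + 0.5) / 2
  w0 <- (mu1 - mu0) / v
  b0 <- -w0 * (mu1 + mu0) / 2
  z0 <- abs(w0 * c(0, 1, 4, 5) + b0)
  temp <- max(1, unname(quantile(z0, 0.9)) / 4)
  expect_equal(unname(m$w), w0 / temp)
  expect_equal(m$b, b0 / temp)
  expect_equal(m$b / m$w, -2.5)       # decision boundary at x = 2.5
  p <- predict_posterior(m, x)
  expect_true(all(p[labs == "erroneous"] > 0.5))
  expect_true(all(p[labs == "correct"] < 0.5))
  expect_true(all(p > 0 & p < 1))
  # class-swap symmetry negates weights and bias
  m_sw <- fit_classifier(x, c("erroneous", "erroneous", "correct", "correct"))
  expect_equal(m_sw$w, -m$w)
  expect_equal(m_sw$b, -m$b)
})

test_that("sliding-window timing follows the 32 Hz grid from 0.25 s", {
  # number of windows for a trial of duration Td: floor((Td-0.75)*32)+1
  syn <- make_synthetic_epochs(4, 8, seed = 3)
  pl <- errpirl:::fit_pipeline(syn$epochs, syn$labels)
  mk_rec <- function(dur) {
    n <- round(512 * dur)
    eeg_recording(matrix(rnorm(16 * n), 16, n), matrix(0, 3, n),
                  events = data.frame(time = c(0, dur),
                                      kind = c("motion_onset", "trial_end")))
  }
  for (dur in c(0.75, 1.3, 3.75)) {
    tr <- errpirl:::raw_trace(pl, mk_rec(dur))
    # oracle: enumerate admissible window starts
    starts <- c(); k <- 0
    repeat {
      t0 <- 0.25 + k / 32
      if (t0 + 0.5 > dur + 1e-9) break
      starts <- c(starts, t0); k <- k + 1
    }
    expect_length(tr$raw, length(starts))
    expect_equal(tr$times, starts + 0.25)
  }
  expect_length(errpirl:::raw_trace(pl, mk_rec(3.75))$raw,
                floor((3.75 - 0.75) * 32) + 1)
  # trial shorter than 0.75 s yields an empty trace and no decision
  dec <- errpirl:::trace_decisions(list(times = numeric(), raw = numeric()),
                                   4, 0.5, 10)
  expect_false(dec$decision)
  expect_true(is.na(dec$decision_time))
})

test_that("threshold crossing fires at the first exceeding window", {
  tr <- list(times = 0.5 + (0:9) / 32, raw = rep(0.9, 10))
  d <- errpirl:::trace_decisions(tr, 1, 0.5, 10)
  expect_true(d$decision)
  expect_equal(d$decision_time, tr$times[1] + 0.25)
  # recalibrated trace crosses 0.5 exactly where the raw trace crosses theta
  tr2 <- list(times = 0.5 + (0:9) / 32,
              raw = c(0.2, 0.3, 0.4, 0.55, 0.7, 0.7, 0.2, 0.2, 0.9, 0.1))
  for (theta in c(0.35, 0.5, 0.65)) {
    d2 <- errpirl:::trace_decisions(tr2, 1, theta, 7)
    expect_equal(d2$smoothed > theta, d2$recalibrated > 0.5)
  }
})

test_that("MCC grid has 16 x 101 cells and the argmax matches a re-scan", {
  set.seed(9)
  n <- 40
  labels <- rep(c("erroneous", "correct"), each = n / 2)
  folds <- rep(1:4, length.out = n)
  # traces separable at theta = 0.7 after smoothing with h = 3
  traces <- lapply(seq_len(n), function(i) {
    base <- runif(30, 0, if (labels[i] == "erroneous") 1 else 0.65)
    if (labels[i] == "erroneous") base[10:14] <- 0.95
    base
  })
  hp <- optimize_hyperparameters(traces, labels, folds)
  expect_equal(dim(hp$mcc_grid), c(16L, 101L))
  expect_equal(hp$mcc, 1)
  # brute-force re-scan over all 1616 pairs with an independent loop
  best <- -Inf; arg <- c(NA, NA)
  thetas <- seq(0, 1, 0.01)
  for (h in 1:16) for (ti in seq_along(thetas)) {
    vals <- c()
    for (f in unique(folds)) {
      idx <- which(folds == f)
      pred <- vapply(traces[idx], function(r) {
        sm <- vapply(seq_along(r), function(j)
          mean(r[max(1, j - h + 1):j]), 0)
        any(sm > thetas[ti])
      }, TRUE)
      err <- labels[idx] == "erroneous"
      vals <- c(vals, mcc(matrix(c(sum(pred & err), sum(pred & !err),
                                   sum(!pred & err), sum(!pred & !err)), 2)))
    }
    v <- mean(vals)
    if (v > best + 1e-12) { best <- v; arg <- c(h, thetas[ti]) }
  }
  expect_equal(max(hp$mcc_grid), best)
  expect_equal(hp$mcc_grid[hp$h, as.character(hp$theta)], best)
})

test_that("decoder JSON persistence preserves the decision function", {
  syn <- make_synthetic_epochs(6, 12, seed = 8)
  pl <- errpirl:::fit_pipeline(syn$epochs, syn$labels)
  dec <- structure(list(pipeline = pl, coeffs = synthetic_leakage(),
                        h = 3L, theta = 0.42, sigmoid_slope = 12,
                        mcc = 0.9, mcc_grid = NULL, cv = NULL),
                   class = "errp_decoder")
  f <- tempfile(fileext = ".json")
  save_decoder(dec, f)
  dec2 <- load_decoder(f)
  x <- extract_features(syn$epochs[[1]], dec$pipeline$features)
  x2 <- extract_features(syn$epochs[[1]], dec2$pipeline$features)
  expect_equal(x2, x, tolerance = 1e-12)
  expect_equal(predict_posterior(dec2$pipeline$classifier, x2),
               predict_posterior(dec$pipeline$classifier, x),
               tolerance = 1e-12)
  expect_equal(dec2$h, 3L)
  expect_equal(dec2$theta, 0.42)
})

test_that("confusion matrices conserve trial counts and timelock latency is 0.5 s", {
  syn <- make_synthetic_epochs(8, 16, seed = 12)
  pl <- errpirl:::fit_pipeline(syn$epochs, syn$labels)
  dec <- structure(list(pipeline = pl, coeffs = NULL, h = 1L, theta = 0.5,
                        sigmoid_slope = 10, mcc = NA, mcc_grid = NULL,
                        cv = NULL),
                   class = "errp_decoder")
  td <- timelock_decode(dec, syn$epochs[[1]])
  expect_equal(td$latency, 0.5)
  cm <- errpirl:::confusion_2x2(syn$labels == "erroneous",
                                rep(c(TRUE, FALSE), 12))
  expect_equal(sum(cm), 24)
})
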