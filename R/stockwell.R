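#' Discrete Stockwell transform
#'
#' S-transform of a real signal: a continuous-wavelet-style
#' time-frequency map with a frequency-dependent Gaussian window of
#' standard deviation `1/|f|` in time, retaining absolutely referenced
#' phase. Computed via the frequency-domain formulation (FFT of the
#' signal, shifted and multiplied by a Gaussian `exp(-2 pi^2 m^2 / n^2)`
#' over frequency offsets `m`, inverse FFT per voice), which is
#' O(N log N) per frequency; the direct time-domain convolution is the
#' small-n test oracle. Requested frequencies snap to the nearest DFT
#' bin. `f = 0` returns the signal mean, constant over time.
#'
#' @param signal Real numeric vector.
#' @param fs Sample rate (Hz).
#' @param freqs Frequencies to evaluate (Hz), >= 0.
#' @return An object of class `tf_map`: `times` (s), `freqs` (Hz, the
#'   snapped values), and `values` (complex matrix, frequencies x times).
#' @export
stockwell <- function(signal, fs, freqs) {
  signal <- as.numeric(signal)
  if (!length(signal)) stop("stockwell: empty signal")
  if (!all(is.finite(signal))) stop("stockwell: signal must be finite")
  stopifnot(all(freqs >= 0))
  N <- length(signal)
  X <- stats::fft(signal)
  m <- 0:(N - 1)
  m_alias <- ifelse(m > N / 2, m - N, m)   # two-sided frequency offsets
  vals <- matrix(0 + 0i, length(freqs), N)
  snapped <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    n <- round(freqs[k] * N / fs)
    snapped[k] <- n * fs / N
    if (n == 0) {
      vals[k, ] <- mean(signal)
      next
    }
    G <- exp(-2 * pi^2 * m_alias^2 / n^2)
    Xs <- X[((m + n) %% N) + 1L]
    vals[k, ] <- stats::fft(Xs * G, inverse = TRUE) / N
  }
  structure(list(times = (0:(N - 1)) / fs, freqs = snapped, values = vals),
            class = "tf_map")
}

#' Direct time-domain S-transform (reference implementation)
#'
#' Literal discretization of the S-transform integral: Gaussian window
#' of width `1/f` centered at each time, modulated by the absolutely
#' referenced complex exponential. O(N^2) per frequency; used as the
#' oracle for [stockwell()] at small n.
#'
#' @inheritParams stockwell
#' @return A `tf_map` with complex values.
#' @export
stockwell_direct <- function(signal, fs, freqs) {
  signal <- as.numeric(signal)
  if (!length(signal)) stop("stockwell_direct: empty signal")
  N <- length(signal)
  tt <- (0:(N - 1)) / fs
  vals <- matrix(0 + 0i, length(freqs), N)
  snapped <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    f <- round(freqs[k] * N / fs) * fs / N   # same bin snapping
    snapped[k] <- f
    if (f == 0) { vals[k, ] <- mean(signal); next }
    for (j in seq_len(N)) {
      tau <- tt[j]
      # periodic window matches the circular frequency-domain formulation
      dt0 <- (tau - tt)
      w <- 0
      for (p in -1:1) {
        d <- dt0 + p * N / fs
        w <- w + exp(-d^2 * f^2 / 2)
      }
      vals[k, j] <- sum(abs(f) / sqrt(2 * pi) * w *
                          exp(-2i * pi * f * tt) * signal) / fs
    }
  }
  structure(list(times = tt, freqs = snapped, values = vals),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d frequencies x %d times (%s)\n",
              length(x$freqs), length(x$times),
              if (is.complex(x$values)) "complex S-transform" else "real, dB"))
  invisible(x)
}

#' Event-related spectral perturbation re a correct-trial baseline
#'
#' For each epoch a 2nd order causal 1 Hz Butterworth high-pass removes
#' baseline drift, then the S-transform power `|S|^2` is averaged over
#' erroneous epochs (the event-related spectrum). The baseline `nu(f)` is
#' the average power of correct epochs restricted to their monitoring
#' window, and the map is `ERSP(f, t) = 10 log10(ERS(f, t) / nu(f))` in
#' dB over `t` in `[-0.5, 1.0]` s re release and `f` in `[1, 30]` Hz
#' (1 Hz steps). Frequencies with zero baseline are masked as `NA`.
#'
#' @param erroneous_epochs List of numeric vectors: single-channel
#'   (e.g. FCz) epochs spanning `[-0.5, 1.0]` s around release.
#' @param correct_epochs List of numeric vectors: single-channel correct
#'   epochs spanning `[1.0, 2.5]` s re motion onset.
#' @param fs Sample rate (Hz).
#' @param freqs Frequency grid (Hz).
#' @param baseline_window Window (s, re motion onset) over which the
#'   correct-trial power is averaged.
#' @param correct_epoch_start Start time (s, re motion onset) of the
#'   correct epochs.
#' @return A `tf_map` with real dB values and `times` relative to
#'   release.
#' @export
ersp <- function(erroneous_epochs, correct_epochs, fs = 512,
                 freqs = 1:30, baseline_window = c(1.5, 2.0),
                 correct_epoch_start = 1.0) {
  stopifnot(length(erroneous_epochs) >= 1, length(correct_epochs) >= 1)
  hp <- signal::butter(2, 1 / (fs / 2), type = "high")
  prep <- function(x) as.numeric(signal::filter(hp, as.numeric(x)))
  pow <- function(x) abs(stockwell(prep(x), fs, freqs)$values)^2
  ers <- Reduce(`+`, lapply(erroneous_epochs, pow)) / length(erroneous_epochs)
  n_c <- length(correct_epochs[[1]])
  tc <- correct_epoch_start + (0:(n_c - 1)) / fs
  sel <- tc >= baseline_window[1] & tc <= baseline_window[2]
  base <- Reduce(`+`, lapply(correct_epochs, pow)) / length(correct_epochs)
  nu <- rowMeans(base[, sel, drop = FALSE])
  vals <- matrix(NA_real_, length(freqs), ncol(ers))
  ok <- nu > 0
  vals[ok, ] <- 10 * log10(ers[ok, , drop = FALSE] / nu[ok])
  n_e <- length(erroneous_epochs[[1]])
  structure(list(times = -0.5 + (0:(n_e - 1)) / fs,
                 freqs = stockwell(erroneous_epochs[[1]], fs, freqs)$freqs,
                 values = vals),
            class = "tf_map")
}

#' Write a time-frequency map as CSV
#'
#' First column `freq_hz`, remaining columns one per time point with
#' `t_<seconds>` headers.
#'
#' @param map A `tf_map` (real-valued; complex maps are written as
#'   modulus).
#' @param file File path.
#' @export
write_tfmap_csv <- function(map, file) {
  v <- if (is.complex(map$values)) abs(map$values) else map$values
  df <- data.frame(freq_hz = map$freqs, v)
  names(df)[-1] <- sprintf("t_%.4f", map$times)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
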