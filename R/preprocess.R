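#' Estimate EOG-regression coefficients
#'
#' Linear ocular-artifact removal: from a dedicated artifact recording
#' with deliberate eye movements and blinks, the 3 x 16 coefficient
#' matrix `B = C_oo^-1 C_oe` is computed from the joint (lag-0)
#' autocovariance of the EOG and EEG channels, so that
#' `eeg_clean = eeg - t(B) %*% eog`.
#'
#' @param artifact_recording An [eeg_recording()] of the artifact run
#'   (90 s protocol).
#' @return 3 x 16 numeric coefficient matrix.
#' @export
estimate_eog_coefficients <- function(artifact_recording) {
  stopifnot(inherits(artifact_recording, "eeg_recording"))
  eog <- artifact_recording$eog
  eeg <- artifact_recording$eeg
  Coo <- stats::cov(t(eog))
  Coe <- stats::cov(t(eog), t(eeg))
  ok <- tryCatch({
    B <- solve(Coo, Coe); TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    warning("estimate_eog_coefficients: singular EOG covariance, regularizing")
    B <- solve(Coo + diag(1e-8 * sum(diag(Coo)) / 3, 3), Coe)
  }
  dimnames(B) <- list(rownames(eog), rownames(eeg))
  B
}

# causal IIR filtering along rows of a channels x samples matrix. Each
# row is padded with 1 s of its first sample before filtering and the
# pad discarded, emulating a filter that has been running on the ongoing
# recording (no per-segment startup step); output at t still depends
# only on data at or before t.
filter_rows <- function(x, flt, fs) {
  pad <- max(1L, round(fs))
  out <- t(apply(x, 1, function(r) {
    y <- as.numeric(signal::filter(flt, c(rep(r[1], pad), r)))
    y[-seq_len(pad)]
  }))
  dimnames(out) <- dimnames(x)
  out
}

#' Preprocess an EEG recording for ErrP decoding
#'
#' EOG regression with the supplied coefficients, a 50 Hz software notch
#' (2nd order Butterworth band-stop, 48-52 Hz), and a 4th order causal
#' Butterworth band-pass with cut-offs 1-12 Hz. All filters are applied
#' in the forward direction only, so the output at time t depends only on
#' samples at or before t.
#'
#' @param recording An [eeg_recording()].
#' @param coeffs 3 x 16 matrix from [estimate_eog_coefficients()], or
#'   `NULL` to skip EOG regression.
#' @param band Band-pass cut-offs (Hz).
#' @return The preprocessed [eeg_recording()] (EOG channels passed
#'   through unchanged).
#' @export
preprocess <- function(recording, coeffs = NULL, band = c(1, 12)) {
  stopifnot(inherits(recording, "eeg_recording"))
  eeg <- recording$eeg
  if (!is.null(coeffs)) {
    stopifnot(all(dim(coeffs) == c(3L, 16L)))
    eeg <- eeg - t(coeffs) %*% recording$eog
  }
  fs <- recording$fs
  notch <- signal::butter(2, c(48, 52) / (fs / 2), type = "stop")
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  eeg <- filter_rows(filter_rows(eeg, notch, fs), bp, fs)
  eeg_recording(eeg, recording$eog, fs = fs, events = recording$events,
                label = recording$label)
}

#' Epoch calibration trials for decoder training
#'
#' Erroneous trials are epoched in `[0, 0.5]` s relative to joystick
#' release; correct trials in `[1.5, 2.0]` s relative to motion onset
#' (both 256 samples at 512 Hz). Erroneous trials whose release reaction
#' time deviates from the subject's median by more than 3 median absolute
#' deviations are rejected as joystick mis-operations; when the MAD is
#' zero, only strictly deviating trials are rejected. Trials whose epoch
#' would extend past the recording end are skipped.
#'
#' @param trials List of preprocessed [eeg_recording()] objects, each
#'   with a `motion_onset` event (erroneous ones also with `release`).
#' @return List with `epochs` (list of `n_channels x n_samples`
#'   matrices), `labels` (character), `trial_index` (index into
#'   `trials`), and `rejected` (indices of MAD-rejected or truncated
#'   trials).
#' @export
epoch_trials <- function(trials) {
  stopifnot(length(trials) > 0)
  labels_in <- vapply(trials, function(tr) tr$label, "")
  rts <- vapply(trials, function(tr) {
    r <- event_time(tr, "release"); o <- event_time(tr, "motion_onset")
    if (is.na(r)) NA_real_ else r - o
  }, 0)
  err_idx <- which(labels_in == "erroneous" & !is.na(rts))
  rejected <- integer()
  if (length(err_idx)) {
    rt <- rts[err_idx]
    med <- stats::median(rt)
    mad <- stats::median(abs(rt - med))
    bad <- if (mad > 0) abs(rt - med) / mad > 3 else abs(rt - med) > 0
    rejected <- err_idx[bad]
  }
  epochs <- list(); labels <- character(); trial_index <- integer()
  for (i in seq_along(trials)) {
    if (i %in% rejected) next
    tr <- trials[[i]]
    fs <- tr$fs
    onset <- event_time(tr, "motion_onset")
    win <- if (labels_in[i] == "erroneous")
      event_time(tr, "release") + c(0, 0.5) else onset + c(1.5, 2.0)
    i0 <- round(win[1] * fs) + 1L
    i1 <- i0 + round(diff(win) * fs) - 1L
    if (is.na(i0) || i1 > ncol(tr$eeg)) {
      rejected <- c(rejected, i)
      next
    }
    epochs[[length(epochs) + 1L]] <- tr$eeg[, i0:i1, drop = FALSE]
    labels <- c(labels, labels_in[i])
    trial_index <- c(trial_index, i)
  }
  list(epochs = epochs, labels = labels, trial_index = trial_index,
       rejected = sort(unique(rejected)))
}
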