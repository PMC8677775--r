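#' EEG channel montage
#'
#' The fixed 16-channel fronto-central montage (10/10 system) used by the
#' decoder, in canonical order, plus approximate planar electrode
#' coordinates (x toward the right ear, y toward the nasion) used by the
#' synthetic generator for topographies and spatial correlation.
#'
#' @return `eeg_montage()` returns a data.frame with columns `channel`,
#'   `x`, `y`.
#' @export
eeg_montage <- function() {
  data.frame(
    channel = c("Fz", "FC3", "FC1", "FCz", "FC2", "FC4",
                "C3", "C1", "Cz", "C2", "C4",
                "CP3", "CP1", "CPz", "CP2", "CP4"),
    x = c(0, -0.45, -0.20, 0, 0.20, 0.45,
          -0.45, -0.20, 0, 0.20, 0.45,
          -0.45, -0.20, 0, 0.20, 0.45),
    y = c(0.60, 0.30, 0.30, 0.30, 0.30, 0.30,
          0, 0, 0, 0, 0,
          -0.30, -0.30, -0.30, -0.30, -0.30),
    stringsAsFactors = FALSE)
}

#' Multichannel EEG recording
#'
#' Container for one recording segment: 16 EEG channels (fixed montage
#' order), 3 EOG channels, sample rate and event markers. Amplitudes are
#' in microvolts.
#'
#' @param eeg 16 x n numeric matrix (uV), rows in [eeg_montage()] order.
#' @param eog 3 x n numeric matrix (uV).
#' @param fs Sample rate (Hz), nominally 512.
#' @param events data.frame with columns `time` (s, relative to segment
#'   start) and `kind` (one of `motion_onset`, `release`, `trial_end`).
#' @param label Optional trial label, `"erroneous"` or `"correct"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(eeg, eog, fs = 512,
                          events = data.frame(time = numeric(),
                                              kind = character()),
                          label = NA_character_) {
  eeg <- rbind(eeg); eog <- rbind(eog)
  if (nrow(eeg) != 16L) stop("eeg_recording: eeg must have 16 rows")
  if (nrow(eog) != 3L) stop("eeg_recording: eog must have 3 rows")
  if (ncol(eeg) != ncol(eog)) stop("eeg_recording: eeg/eog length mismatch")
  stopifnot(fs > 0)
  dur <- ncol(eeg) / fs
  if (nrow(events) && any(events$time < 0 | events$time > dur))
    stop("eeg_recording: event times outside recording span")
  rownames(eeg) <- eeg_montage()$channel
  rownames(eog) <- c("EOG1", "EOG2", "EOG3")
  structure(list(eeg = eeg, eog = eog, fs = fs, events = events,
                 label = label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> 16+3 channels, %.2f s at %g Hz, %d events%s\n",
              ncol(x$eeg) / x$fs, x$fs, nrow(x$events),
              if (!is.na(x$label)) sprintf(" [%s]", x$label) else ""))
  invisible(x)
}

event_time <- function(recording, kind) {
  ev <- recording$events
  t <- ev$time[ev$kind == kind]
  if (length(t)) t[1] else NA_real_
}

#' Write / read an EEG recording as a plain-text bundle
#'
#' Documented on-disk schema for a single recording: a directory holding
#' `eeg.csv` (n_samples x 16, header = channel names in montage order),
#' `eog.csv` (n_samples x 3), and `events.json` (`fs`, `label`, and an
#' `events` array of `{time, kind}`).
#'
#' @param recording An [eeg_recording()].
#' @param dir Directory to create/read.
#' @return `write_eeg_bundle` returns `dir` invisibly; `read_eeg_bundle`
#'   returns an [eeg_recording()].
#' @export
write_eeg_bundle <- function(recording, dir) {
  stopifnot(inherits(recording, "eeg_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(t(recording$eeg)),
                   file.path(dir, "eeg.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(t(recording$eog)),
                   file.path(dir, "eog.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fs = recording$fs, label = recording$label,
         events = recording$events),
    file.path(dir, "events.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_eeg_bundle
#' @export
read_eeg_bundle <- function(dir) {
  eeg <- t(as.matrix(utils::read.csv(file.path(dir, "eeg.csv"))))
  eog <- t(as.matrix(utils::read.csv(file.path(dir, "eog.csv"))))
  meta <- jsonlite::read_json(file.path(dir, "events.json"),
                              simplifyVector = TRUE)
  ev <- if (length(meta$events)) as.data.frame(meta$events) else
    data.frame(time = numeric(), kind = character())
  eeg_recording(eeg, eog, fs = meta$fs, events = ev,
                label = if (is.null(meta$label)) NA_character_ else meta$label)
}
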