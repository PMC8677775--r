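#' Configuration of a closed-loop run
#'
#' @param seed Master seed; all randomness in the run derives from it.
#' @param experiment 1 (left-right single obstacle, 2 conditions) or 2
#'   (pick-and-place: 4 targets x grasp/no-grasp = 8 conditions).
#' @param batch_size Number of random-parameter demonstrations used to
#'   initialize the IRL for each condition; 3 or 5.
#' @param n_calibration Calibration trials.
#' @param n_adaptation Adaptation trials per condition.
#' @param user A [user_model()].
#' @param snr ErrP template scale for synthetic EEG.
#' @param decoder `"eeg"` (train and use the ErrP decoder) or `"oracle"`
#'   (weights derived directly from the simulated user's decisions;
#'   trajectory-only, no EEG synthesized).
#' @param out_dir Output directory for artifacts, or `NULL` to keep the
#'   run in memory only.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, experiment = 1, batch_size = 5,
                       n_calibration = 400, n_adaptation = 10,
                       user = user_model(), snr = 1,
                       decoder = c("eeg", "oracle"), out_dir = NULL) {
  stopifnot(experiment %in% c(1, 2), batch_size %in% c(3, 5),
            n_calibration >= 20, n_adaptation >= 1)
  decoder <- match.arg(decoder)
  structure(list(seed = seed, experiment = experiment,
                 batch_size = batch_size, n_calibration = n_calibration,
                 n_adaptation = n_adaptation, user = user, snr = snr,
                 decoder = decoder, out_dir = out_dir),
            class = "run_config")
}

run_scenes <- function(config) {
  if (config$experiment == 1)
    list(left_to_right = canonical_scene("left_to_right"),
         right_to_left = canonical_scene("right_to_left"))
  else pick_place_scenes()
}

#' Run the decoder-calibration phase
#'
#' Generates the synthetic calibration session (random modulation
#' parameters, simulated user, synthetic EEG unless the oracle decoder
#' is configured), estimates EOG-regression coefficients from a
#' synthetic artifact run, trains the ErrP decoder with 10-fold
#' cross-validated hyperparameter search, and summarizes the
#' Offline-Timelock and Offline-Continuous confusion matrices.
#'
#' @param config A [run_config()].
#' @return List with `dataset`, `decoder` (NULL for the oracle
#'   configuration), `coeffs`, and `report`. Written as JSON under
#'   `config$out_dir` when set.
#' @export
run_calibration <- function(config) {
  stopifnot(inherits(config, "run_config"))
  with_eeg <- config$decoder == "eeg"
  dataset <- generate_calibration_dataset(
    user = config$user, n_trials = config$n_calibration,
    seed = config$seed, snr = config$snr, with_eeg = with_eeg)
  labs <- vapply(dataset$trials, `[[`, "", "label")
  if (length(unique(labs)) < 2L)
    stop("run_calibration: calibration produced a single class")
  decoder <- NULL; coeffs <- NULL
  report <- list(seed = config$seed,
                 n_trials = length(labs),
                 n_erroneous = sum(labs == "erroneous"),
                 correction_rate = mean(labs == "erroneous"))
  if (with_eeg) {
    artifact <- generate_eog_artifact_recording(seed = config$seed + 1)
    coeffs <- estimate_eog_coefficients(artifact)
    decoder <- train_decoder(dataset, coeffs, seed = config$seed)
    off_tl <- evaluate_decoder(decoder, mode = "offline", manner = "timelock")
    off_ct <- evaluate_decoder(decoder, mode = "offline", manner = "continuous")
    if (off_tl$balanced_accuracy < 0.5)
      warning("run_calibration: decoder below chance on CV; continuing")
    report$offline_timelock <- off_tl
    report$offline_continuous <- off_ct
    report$h <- decoder$h; report$theta <- decoder$theta
    report$cv_mcc <- decoder$mcc
  }
  out <- list(dataset = dataset, decoder = decoder, coeffs = coeffs,
              report = report, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    ser <- report
    for (k in c("offline_timelock", "offline_continuous"))
      if (!is.null(ser[[k]]))
        ser[[k]] <- list(confusion = as.vector(ser[[k]]$confusion),
                         accuracy = ser[[k]]$accuracy,
                         balanced_accuracy = ser[[k]]$balanced_accuracy)
    jsonlite::write_json(ser, file.path(config$out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(decoder))
      save_decoder(decoder, file.path(config$out_dir, "decoder.json"))
  }
  out
}

# weight of one adaptation trial: 1 - the decoder's decision value
trial_weight <- function(decoder, recording, released) {
  if (is.null(decoder)) {
    # oracle decoder: posterior 0.95 when the user released, 0.05 if not
    return(if (released) 1 - 0.95 else 1 - 0.05)
  }
  trace <- continuous_decode(decoder, recording)
  if (!length(trace$recalibrated)) return(0.5)
  1 - max(trace$recalibrated)
}

#' Run the trajectory-adaptation phase
#'
#' For each condition of the configured experiment: an initial batch of
#' `batch_size` trials with random modulation parameters, each weighted
#' by `1 - p(ErrP)` from the continuous decoder (or by the oracle), the
#' weighted GP-IRL fit, the simplex parameter search, then
#' `n_adaptation` trials executed with the learned parameters under
#' continued user supervision, retraining on a sliding window of the
#' latest five demonstrations after every trial. If an IRL fit fails the
#' previous parameters are kept and the failure logged.
#'
#' @param config A [run_config()].
#' @param calibration The output of [run_calibration()] (provides the
#'   decoder and EOG coefficients; optional for the oracle decoder).
#' @return List with `log` (one data.frame row per trial: condition,
#'   phase, rho, eta, weight, corrected, release_time, min_clearance),
#'   `learned` (final [modulation_params()] per condition), and
#'   `recordings` (the per-trial synthetic EEG when the ErrP decoder is
#'   configured, aligned with the log rows).
#' @export
run_adaptation <- function(config, calibration = NULL) {
  stopifnot(inherits(config, "run_config"))
  decoder <- if (!is.null(calibration)) calibration$decoder else NULL
  if (config$decoder == "eeg" && is.null(decoder))
    stop("run_adaptation: eeg decoder configured but no trained decoder given")
  scenes <- run_scenes(config)
  set.seed(config$seed + 7)
  log_rows <- list()
  recordings <- list()
  learned <- list()
  for (cond in names(scenes)) {
    sc <- scenes[[cond]]
    basis <- ebf_basis(sc$scene)
    seeds <- sample.int(2^30, 3 * (config$batch_size + config$n_adaptation))
    demos <- list()
    run_trial <- function(params, sd_user, sd_eeg) {
      preview <- integrate_trajectory(sc$start, sc$scene, params)
      dec <- simulate_user(preview, config$user, sc$scene, seed = sd_user)
      path <- if (dec$release)
        integrate_trajectory(sc$start, sc$scene, params,
                             release_time = dec$release_time)
      else preview
      rec <- NULL
      if (config$decoder == "eeg") {
        rec <- generate_eeg_trial(
          if (dec$release) "erroneous" else "correct",
          max(path$times) + 1 / 512, snr = config$snr, seed = sd_eeg,
          release_time = dec$release_time)
      }
      w <- trial_weight(decoder, rec, dec$release)
      list(demo = demonstration(path, w, sc$scene), corrected = dec$release,
           release_time = dec$release_time, weight = w,
           clearance = min_clearance(path, sc$scene), recording = rec)
    }
    params <- modulation_params(1.5, 1.4)
    k <- 0L
    for (i in seq_len(config$batch_size)) {
      k <- k + 1L
      p <- modulation_params(stats::runif(1, 0.5, 3), stats::runif(1, 0.8, 2))
      tr <- run_trial(p, seeds[2 * k - 1], seeds[2 * k])
      demos[[length(demos) + 1L]] <- tr$demo
      recordings[[length(recordings) + 1L]] <- tr$recording
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        condition = cond, phase = "batch", trial = i,
        rho = p$rho, eta = p$eta, weight = tr$weight,
        corrected = tr$corrected, release_time = tr$release_time,
        min_clearance = tr$clearance)
    }
    for (j in seq_len(config$n_adaptation)) {
      k <- k + 1L
      recent <- demos[max(1, length(demos) - 4L):length(demos)]
      m <- tryCatch(fit_reward_model(recent, basis, seed = config$seed + j),
                    error = function(e) NULL)
      if (!is.null(m)) {
        params <- optimize_modulation(m, sc$scene, sc$start,
                                      init = params,
                                      seed = config$seed + j)
      }  # on failure: fall back to the previous parameters
      tr <- run_trial(params, seeds[2 * k - 1], seeds[2 * k])
      demos[[length(demos) + 1L]] <- tr$demo
      recordings[[length(recordings) + 1L]] <- tr$recording
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        condition = cond, phase = "adaptation", trial = j,
        rho = params$rho, eta = params$eta, weight = tr$weight,
        corrected = tr$corrected, release_time = tr$release_time,
        min_clearance = tr$clearance, irl_ok = !is.null(m))
    }
    learned[[cond]] <- params
  }
  log <- do.call(rbind, lapply(log_rows, function(r) {
    if (!"irl_ok" %in% names(r)) r$irl_ok <- NA
    r
  }))
  out <- list(log = log, learned = learned, config = config,
              recordings = recordings)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(log, file.path(config$out_dir, "adaptation_log.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(learned, function(p) list(rho = p$rho, eta = p$eta)),
      file.path(config$out_dir, "learned_params.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Summarize a completed run directory
#'
#' Collects the calibration report, adaptation log and learned
#' parameters from a run directory into a single summary (correction
#' rates per phase, learned parameter table, decoder matrices when
#' present, KL/Hellinger cluster analyses when the log contains both
#' corrected and accepted trials). Stages with missing artifacts are
#' listed as absent. Pure function of the directory contents:
#' re-running it is idempotent.
#'
#' @param run_dir Run directory.
#' @return List summary (also written as `report.json` in `run_dir`).
#' @export
run_report <- function(run_dir) {
  out <- list(absent = character())
  calib_file <- file.path(run_dir, "calibration.json")
  if (file.exists(calib_file)) {
    out$calibration <- jsonlite::read_json(calib_file, simplifyVector = TRUE)
  } else out$absent <- c(out$absent, "calibration")
  log_file <- file.path(run_dir, "adaptation_log.csv")
  if (file.exists(log_file)) {
    log <- utils::read.csv(log_file)
    out$correction_rate_batch <-
      correction_rate(data.frame(corrected = log$corrected,
                                 phase = log$phase), "batch")
    out$correction_rate_adaptation <-
      correction_rate(data.frame(corrected = log$corrected,
                                 phase = log$phase), "adaptation")
    corr <- log[log$corrected & log$phase == "batch", c("rho", "eta")]
    acc <- log[!log$corrected & log$phase == "batch", c("rho", "eta")]
    lear <- log[log$phase == "adaptation", c("rho", "eta")]
    if (nrow(corr) >= 2 && nrow(acc) >= 2 && nrow(lear) >= 2) {
      dists <- list(erroneous = param_distribution(corr, "erroneous"),
                    correct = param_distribution(acc, "correct"),
                    learned = param_distribution(lear, "learned"))
      out$kl_learned_vs_correct <- kl_gaussian(dists$learned, dists$correct)
      out$kl_learned_vs_erroneous <- kl_gaussian(dists$learned,
                                                 dists$erroneous)
      out$hellinger_map <- hellinger_map(dists)
    }
  } else out$absent <- c(out$absent, "adaptation")
  learned_file <- file.path(run_dir, "learned_params.json")
  if (file.exists(learned_file)) {
    out$learned <- jsonlite::read_json(learned_file, simplifyVector = TRUE)
  } else out$absent <- c(out$absent, "learned_params")
  jsonlite::write_json(out, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  out
}
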