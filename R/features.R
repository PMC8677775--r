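# --- SPD helpers (6x6 matrices; eigen-based matrix functions) ---------------

spd_fun <- function(M, f, require_pd = TRUE) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- e$values
  if (require_pd && any(v <= 0))
    stop("spd_fun: matrix is not positive definite")
  e$vectors %*% diag(f(v)) %*% t(e$vectors)
}

spd_logm <- function(M) spd_fun(M, log)
spd_expm <- function(M) spd_fun(M, exp, require_pd = FALSE)
spd_invsqrtm <- function(M) spd_fun(M, function(v) 1 / sqrt(v))

ensure_spd <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) <= 0) {
    warning("covariance not positive definite; adding jitter")
    C <- C + diag(1e-10 * sum(diag(C)) + 1e-12, nrow(C))
  }
  C
}

# upper-triangle vectorization of a symmetric matrix, off-diagonal * sqrt(2)
# (isometry between the tangent space and R^21 for 6x6 matrices)
upper_vec <- function(S) {
  d <- nrow(S)
  idx <- upper.tri(S, diag = TRUE)
  w <- matrix(sqrt(2), d, d); diag(w) <- 1
  (S * w)[idx]
}

#' Fit the CCA spatial filter
#'
#' Canonical-correlation spatial filtering for event-related potentials:
#' single-trial epochs (stacked over time) are canonically correlated with
#' their class-average time courses, and the first three canonical
#' directions on the single-trial side form the 16-to-3 channel
#' projection. The template is the grand average of erroneous training
#' epochs in component space. Covariances are regularized by
#' `1e-6 * trace`.
#'
#' @param epochs List of 16 x s epoch matrices (preprocessed).
#' @param labels Character vector, `"erroneous"` / `"correct"`.
#' @return An object of class `spatial_filter_model` with `projection`
#'   (16 x 3), `template` (3 x s), and `canonical_cor` (length 3).
#' @export
fit_spatial_filter <- function(epochs, labels) {
  stopifnot(length(epochs) == length(labels))
  classes <- c("erroneous", "correct")
  if (!all(classes %in% labels) || any(table(factor(labels, classes)) < 2))
    stop("fit_spatial_filter: need at least 2 trials of each class")
  s <- ncol(epochs[[1]])
  avg <- lapply(classes, function(cl)
    Reduce(`+`, epochs[labels == cl]) / sum(labels == cl))
  names(avg) <- classes
  # stack trials over time: X single trials, Y matched class averages
  X <- do.call(rbind, lapply(epochs, t))
  Y <- do.call(rbind, lapply(labels, function(l) t(avg[[l]])))
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  n <- nrow(X)
  Cxx <- crossprod(X) / n; Cyy <- crossprod(Y) / n; Cxy <- crossprod(X, Y) / n
  reg <- function(C) C + diag(1e-6 * sum(diag(C)), nrow(C))
  Cxx <- reg(Cxx); Cyy <- reg(Cyy)
  M <- solve(Cxx, Cxy) %*% solve(Cyy, t(Cxy))
  e <- eigen(M)
  ord <- order(Re(e$values), decreasing = TRUE)[1:3]
  W <- Re(e$vectors[, ord, drop = FALSE])
  # normalize each filter to unit variance of its component
  for (k in 1:3) {
    v <- sqrt(as.numeric(t(W[, k]) %*% Cxx %*% W[, k]))
    W[, k] <- W[, k] / v
    # sign convention: positive correlation with the erroneous average
    pattern <- as.numeric(t(W[, k]) %*% avg$erroneous)
    if (sum(pattern^3) < 0) W[, k] <- -W[, k]
  }
  template <- t(W) %*% avg$erroneous
  structure(list(projection = W, template = template,
                 canonical_cor = sqrt(pmin(1, pmax(0, Re(e$values[ord]))))),
            class = "spatial_filter_model")
}

#' Project an epoch to component space
#'
#' @param epoch 16 x s matrix.
#' @param model A `spatial_filter_model`.
#' @return 3 x s matrix.
#' @export
apply_spatial_filter <- function(epoch, model) {
  stopifnot(inherits(model, "spatial_filter_model"))
  if (nrow(epoch) != nrow(model$projection))
    stop("apply_spatial_filter: epoch must have 16 channels")
  t(model$projection) %*% epoch
}

# augmented template covariance C_Z of Z = [X; T] (components x samples)
template_covariance <- function(compX, template) {
  Z <- rbind(compX, template)
  (Z %*% t(Z)) / ncol(Z)
}

#' Feature-extraction model
#'
#' Bundles everything needed to map a preprocessed 0.5 s epoch to the
#' 84-dimensional feature vector: the spatial filter and template, the
#' tangent-space reference (log-Euclidean mean of calibration augmented
#' covariances), and the calibration min-max normalization bounds.
#'
#' @param spatial_filter A `spatial_filter_model`.
#' @param tangent_ref 6 x 6 SPD reference matrix.
#' @param bounds 84 x 2 matrix (`min`, `max`) or `NULL` for raw features.
#' @param fs Sample rate (Hz).
#' @return An object of class `feature_model`.
#' @export
feature_model <- function(spatial_filter, tangent_ref, bounds = NULL,
                          fs = 512) {
  structure(list(spatial_filter = spatial_filter,
                 tangent_ref = ensure_spd(tangent_ref),
                 ref_invsqrt = spd_invsqrtm(ensure_spd(tangent_ref)),
                 bounds = bounds, fs = fs),
            class = "feature_model")
}

#' Log-Euclidean mean of SPD matrices
#'
#' Deterministic closed-form mean `expm(mean(logm(C_i)))`, used as the
#' tangent-space reference computed from the calibration set only.
#'
#' @param mats List of SPD matrices.
#' @return SPD matrix of the same dimension.
#' @export
logeuclid_mean <- function(mats) {
  spd_expm(Reduce(`+`, lapply(mats, function(C) spd_logm(ensure_spd(C)))) /
             length(mats))
}

# PSD band powers: Hann-window periodogram over the 0.5 s epoch,
# 5 bands per component spanning the 1-12 Hz passband
psd_bands <- list(c(1, 3), c(3, 5), c(5, 7), c(7, 9), c(9, 12))

features_from_components <- function(compX, model) {
  s <- ncol(compX)
  fs <- model$fs
  # temporal: components downsampled to 32 Hz by block averaging
  dec <- fs / 32
  blocks <- matrix(seq_len(s), nrow = dec)
  temporal <- as.numeric(t(apply(compX, 1, function(r)
    colMeans(matrix(r, nrow = dec)))))
  # psd: Hann periodogram band powers
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(s - 1)) / (s - 1))
  freqs <- (0:(s - 1)) * fs / s
  P <- abs(stats::mvfft(t(compX * rep(h, each = nrow(compX)))))^2
  psd <- as.numeric(vapply(seq_len(nrow(compX)), function(k)
    vapply(psd_bands, function(b)
      sum(P[freqs > b[1] & freqs <= b[2], k]), 0), numeric(5)))
  # covariance: template-augmented covariance in the tangent space
  C <- ensure_spd(template_covariance(compX, model$spatial_filter$template))
  S <- model$ref_invsqrt %*% C %*% model$ref_invsqrt
  covf <- upper_vec(spd_logm(S))
  out <- c(temporal, psd, covf)
  if (!is.null(model$bounds)) {
    rng <- model$bounds[, 2] - model$bounds[, 1]
    rng[rng <= 0] <- 1
    out <- pmin(1, pmax(0, (out - model$bounds[, 1]) / rng))
  }
  names(out) <- c(paste0("t", seq_along(temporal)),
                  paste0("p", 1:15), paste0("c", 1:21))
  out
}

#' Extract the 84-dimensional feature vector of an epoch
#'
#' Projects the epoch to the 3 CCA components and concatenates three
#' blocks: 48 temporal features (components downsampled to 32 Hz), 15
#' spectral features (5 band powers per component over 1-12 Hz), and 21
#' covariance features (upper triangle of the tangent-space projection of
#' the template-augmented 6 x 6 covariance). When the model carries
#' calibration bounds the vector is min-max normalized to [0, 1] with
#' out-of-range values clipped.
#'
#' @param epoch 16 x 256 preprocessed epoch (0.5 s at 512 Hz).
#' @param model A [feature_model()].
#' @return Named numeric vector of length 84.
#' @export
extract_features <- function(epoch, model) {
  stopifnot(inherits(model, "feature_model"))
  if (nrow(epoch) != 16L)
    stop("extract_features: epoch must have 16 channels")
  if (ncol(epoch) != round(0.5 * model$fs))
    stop("extract_features: epoch must span 0.5 s")
  features_from_components(apply_spatial_filter(epoch, model$spatial_filter),
                           model)
}
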