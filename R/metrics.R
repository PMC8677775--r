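#' Matthews correlation coefficient
#'
#' Standard MCC of a 2 x 2 confusion matrix with rows = truth and
#' columns = predicted (`[1, 1]` = TP, `[1, 2]` = FN, `[2, 1]` = FP,
#' `[2, 2]` = TN, i.e. `matrix(c(TP, FP, FN, TN), 2, 2)`). Defined as 0
#' whenever any marginal is zero.
#'
#' @param confusion 2 x 2 nonnegative count matrix.
#' @return Scalar in [-1, 1].
#' @export
mcc <- function(confusion) {
  stopifnot(all(dim(confusion) == c(2L, 2L)), all(confusion >= 0))
  tp <- confusion[1, 1]; fn <- confusion[1, 2]
  fp <- confusion[2, 1]; tn <- confusion[2, 2]
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Gaussian cluster of modulation parameters
#'
#' Fits a bivariate Gaussian to a set of (rho, eta) pairs, with a small
#' ridge (1e-8) on the covariance for near-degenerate clusters.
#'
#' @param params n x 2 matrix (columns rho, eta) or data.frame.
#' @param label Cluster label (`"erroneous"`, `"correct"`, `"learned"`).
#' @return An object of class `param_distribution` with `mean` and
#'   `cov`.
#' @export
param_distribution <- function(params, label = NA_character_) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 2L, nrow(params) >= 2L)
  S <- stats::cov(params) + diag(1e-8, 2)
  structure(list(mean = colMeans(params), cov = S, label = label,
                 n = nrow(params)),
            class = "param_distribution")
}

check_pd <- function(S, what) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) <= 0) stop(what, ": covariance must be positive definite")
  invisible(TRUE)
}

as_gauss <- function(x) {
  if (inherits(x, "param_distribution")) list(mean = x$mean, cov = x$cov)
  else {
    stopifnot(is.list(x), !is.null(x$mean), !is.null(x$cov))
    list(mean = as.numeric(x$mean), cov = as.matrix(x$cov))
  }
}

#' Kullback-Leibler divergence between multivariate Gaussians
#'
#' Closed form
#' `KL(p || q) = 0.5 * (tr(Sq^-1 Sp) + (mq - mp)' Sq^-1 (mq - mp) - d +
#' log(det(Sq) / det(Sp)))`. Asymmetric; nonnegative.
#'
#' @param p,q Gaussians: [param_distribution()] objects or lists with
#'   `mean` and `cov`.
#' @return Scalar >= 0.
#' @export
kl_gaussian <- function(p, q) {
  p <- as_gauss(p); q <- as_gauss(q)
  check_pd(p$cov, "kl_gaussian"); check_pd(q$cov, "kl_gaussian")
  d <- length(p$mean)
  iSq <- solve(q$cov)
  dm <- q$mean - p$mean
  as.numeric(0.5 * (sum(diag(iSq %*% p$cov)) +
                      as.numeric(t(dm) %*% iSq %*% dm) - d +
                      determinant(q$cov)$modulus -
                      determinant(p$cov)$modulus))
}

#' Squared Hellinger distance between multivariate Gaussians
#'
#' Closed form
#' `H^2 = 1 - det(Sp)^(1/4) det(Sq)^(1/4) / det((Sp + Sq)/2)^(1/2) *
#' exp(-(mp - mq)' ((Sp + Sq)/2)^-1 (mp - mq) / 8)`.
#' Bounded in [0, 1]: 0 for identical distributions, approaching 1 as
#' the supports stop overlapping.
#'
#' @inheritParams kl_gaussian
#' @return Scalar in [0, 1].
#' @export
hellinger2_gaussian <- function(p, q) {
  p <- as_gauss(p); q <- as_gauss(q)
  check_pd(p$cov, "hellinger2_gaussian")
  check_pd(q$cov, "hellinger2_gaussian")
  Sbar <- (p$cov + q$cov) / 2
  dm <- p$mean - q$mean
  ldp <- as.numeric(determinant(p$cov)$modulus)
  ldq <- as.numeric(determinant(q$cov)$modulus)
  ldb <- as.numeric(determinant(Sbar)$modulus)
  coef <- exp(0.25 * ldp + 0.25 * ldq - 0.5 * ldb)
  1 - coef * exp(-as.numeric(t(dm) %*% solve(Sbar, dm)) / 8)
}

#' Correction rate of a trial log
#'
#' Ratio of corrected (released) trials over all trials of a phase.
#'
#' @param trial_log data.frame with logical column `corrected` and
#'   column `phase`.
#' @param phase Phase label to select (`"calibration"`, `"adaptation"`);
#'   `NULL` uses all rows.
#' @return Scalar rate, or `NA` with a warning for an empty phase.
#' @export
correction_rate <- function(trial_log, phase = NULL) {
  rows <- if (is.null(phase)) trial_log else
    trial_log[trial_log$phase == phase, , drop = FALSE]
  if (!nrow(rows)) {
    warning("correction_rate: no trials in phase '", phase, "'")
    return(NA_real_)
  }
  mean(rows$corrected)
}

#' Pairwise squared Hellinger distance map
#'
#' @param dists Named list of [param_distribution()] objects.
#' @return Symmetric matrix of squared Hellinger distances.
#' @export
hellinger_map <- function(dists) {
  n <- length(dists)
  M <- matrix(0, n, n, dimnames = list(names(dists), names(dists)))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) M[i, j] <- hellinger2_gaussian(dists[[i]], dists[[j]])
  M
}

#' Discrete Frechet distance between two planar paths
#'
#' Coupling-based similarity of ordered point sequences, computed by the
#' standard dynamic program over the pairwise distance matrix.
#'
#' @param a,b n x 2 / m x 2 matrices of points (or `trajectory_path`
#'   objects).
#' @return Scalar distance (m).
#' @export
frechet_distance <- function(a, b) {
  if (inherits(a, "trajectory_path")) a <- a$states
  if (inherits(b, "trajectory_path")) b <- b$states
  a <- rbind(a); b <- rbind(b)
  n <- nrow(a); m <- nrow(b)
  D <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  ca <- matrix(Inf, n, m)
  ca[1, 1] <- D[1, 1]
  for (j in 2:m) ca[1, j] <- max(ca[1, j - 1], D[1, j])
  for (i in 2:n) {
    ca[i, 1] <- max(ca[i - 1, 1], D[i, 1])
    for (j in 2:m)
      ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                      D[i, j])
  }
  ca[n, m]
}
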