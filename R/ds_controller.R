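#' Linear attractor field
#'
#' First-order autonomous dynamical system `xi_dot = g * (target - xi)`:
#' a linear vector field with a single equilibrium at the target, so every
#' integral curve is a straight line toward it.
#'
#' @param state Numeric 2-vector, current end-effector position (m).
#' @param scene A [scene_spec()].
#' @param gain Positive scalar gain `g` (1/s).
#' @return Numeric 2-vector velocity (m/s).
#' @export
linear_field <- function(state, scene, gain = 1) {
  state <- as.numeric(state)
  if (length(state) != 2L || !all(is.finite(state)))
    stop("linear_field: state must be a finite 2-vector")
  stopifnot(inherits(scene, "scene_spec"), gain > 0)
  gain * (scene$target - state)
}

#' Obstacle-avoidance modulation matrix
#'
#' Builds the local modulation `M` around the obstacle. With
#' `xi_t = state - obstacle_center`, `Gamma = (2 * |xi_t| / (eta * r_o))^(2 rho)`
#' and the orthonormal basis `E = [n, t]` (unit radial `n` and its 90-degree
#' rotation `t`), the matrix is `M = E diag(1 - 1/Gamma, 1 + 1/Gamma) E'`.
#' `Gamma = 1` on the safety sphere of radius `eta * r_o / 2`, where the
#' radial eigenvalue vanishes; far away `Gamma -> Inf` and `M -> I`.
#'
#' @param state Numeric 2-vector (m); must not coincide with the obstacle
#'   center.
#' @param scene A [scene_spec()].
#' @param params A [modulation_params()].
#' @return A 2x2 numeric matrix.
#' @export
modulation_matrix <- function(state, scene, params) {
  state <- as.numeric(state)
  if (length(state) != 2L || !all(is.finite(state)))
    stop("modulation_matrix: state must be a finite 2-vector")
  stopifnot(inherits(scene, "scene_spec"), inherits(params, "modulation_params"))
  xt <- state - scene$obstacle_center
  d <- sqrt(sum(xt^2))
  if (d == 0)
    stop("modulation_matrix: state coincides with the obstacle center (degenerate geometry)")
  gamma <- (2 * d / (params$eta * scene$obstacle_diameter))^(2 * params$rho)
  n <- xt / d
  tg <- c(-n[2], n[1])
  E <- cbind(n, tg)
  E %*% diag(c(1 - 1 / gamma, 1 + 1 / gamma)) %*% t(E)
}

#' Modulated vector field
#'
#' Applies the obstacle-avoidance modulation to the linear attractor field:
#' `xi_dot = M(xi) f(xi)`. The deformation is local: far from the obstacle
#' the field is unchanged, while on the safety sphere the velocity component
#' toward the obstacle center is exactly zero, which makes the sphere
#' impenetrable in continuous time.
#'
#' @inheritParams modulation_matrix
#' @param gain Linear field gain (1/s).
#' @return Numeric 2-vector velocity (m/s).
#' @export
modulated_field <- function(state, scene, params, gain = 1) {
  M <- modulation_matrix(state, scene, params)
  as.numeric(M %*% linear_field(state, scene, gain))
}

#' Timed planar trajectory
#'
#' Container for a rolled-out trajectory: strictly increasing times,
#' positions (states), velocities (actions), and release/collision
#' metadata. Consecutive states satisfy
#' `states[i + 1] = states[i] + (times[i + 1] - times[i]) * actions[i, ]`.
#'
#' @param times Numeric vector (s), strictly increasing.
#' @param states n x 2 matrix of positions (m).
#' @param actions n x 2 matrix of velocities (m/s).
#' @param release_time Optional scalar (s) or `NULL`.
#' @param collided Logical flag.
#' @param converged Logical; `FALSE` if the rollout hit the duration cap
#'   before reaching the goal tolerance.
#' @param params The [modulation_params()] used (pre-release).
#' @param scene_id Condition label.
#' @return An object of class `trajectory_path`.
#' @export
trajectory_path <- function(times, states, actions, release_time = NULL,
                            collided = FALSE, converged = TRUE,
                            params = NULL, scene_id = NA_character_) {
  states <- rbind(states); actions <- rbind(actions)
  n <- length(times)
  stopifnot(nrow(states) == n, nrow(actions) == n,
            ncol(states) == 2L, ncol(actions) == 2L)
  if (n == 0L) stop("trajectory_path: empty path")
  if (n > 1L && any(diff(times) <= 0))
    stop("trajectory_path: times must be strictly increasing")
  structure(list(times = as.numeric(times), states = states,
                 actions = actions,
                 release_time = if (is.null(release_time)) NULL else as.numeric(release_time),
                 collided = isTRUE(collided), converged = isTRUE(converged),
                 params = params, scene_id = scene_id),
            class = "trajectory_path")
}

#' @export
print.trajectory_path <- function(x, ...) {
  cat(sprintf("<trajectory_path> %d samples, %.2f s, %s%s%s\n",
              length(x$times), max(x$times) - min(x$times),
              if (x$converged) "converged" else "NOT converged",
              if (!is.null(x$release_time)) sprintf(", release at %.2f s", x$release_time) else "",
              if (x$collided) ", COLLIDED" else ""))
  invisible(x)
}

#' Roll out the modulated dynamical system
#'
#' Fixed-step Euler rollout of [modulated_field()] from `start` until the
#' state is within `tol_goal` of the target or `max_duration` is reached.
#' If `release_time` is given, the modulation switches to `params_safe`
#' from that time onward (the safety behavior triggered by releasing the
#' joystick), producing the characteristic elbow away from the obstacle.
#' A collision is flagged whenever a state enters the physical obstacle
#' sphere of radius `obstacle_diameter / 2` (possible when `eta < 1`).
#'
#' When the start, obstacle center and target are exactly collinear the
#' saddle on the obstacle axis is broken by a deterministic 1e-3 rad
#' counter-clockwise rotation of the attractor field, applied only while
#' the field is radially aligned near the obstacle.
#'
#' @param start Numeric 2-vector inside the workspace (m).
#' @param scene A [scene_spec()].
#' @param params A [modulation_params()].
#' @param dt Integration step (s).
#' @param release_time Optional scalar (s): time at which the safety
#'   parameters take over.
#' @param params_safe [modulation_params()] used after release.
#' @param gain Linear field gain (1/s).
#' @param speed_cap End-effector speed limit (m/s); the modulated
#'   velocity direction is kept and its magnitude saturated, emulating a
#'   robot arm cruising at constant speed except during the final
#'   approach. `Inf` disables the cap.
#' @param tol_goal Goal tolerance (m).
#' @param max_duration Duration cap (s); non-convergence is reported in
#'   the `converged` field, not as an error.
#' @return A [trajectory_path()].
#' @export
integrate_trajectory <- function(start, scene, params, dt = 0.02,
                                 release_time = NULL,
                                 params_safe = modulation_params(1.0, 2.5),
                                 gain = 3, speed_cap = 0.25,
                                 tol_goal = 5e-3,
                                 max_duration = 15) {
  start <- as.numeric(start)
  stopifnot(length(start) == 2L, all(is.finite(start)), dt > 0)
  ws <- scene$workspace
  if (start[1] < ws[1] || start[1] > ws[2] || start[2] < ws[3] || start[2] > ws[4])
    stop("integrate_trajectory: start outside workspace")
  n_max <- ceiling(max_duration / dt) + 1L
  times <- numeric(n_max); states <- matrix(NA_real_, n_max, 2)
  actions <- matrix(NA_real_, n_max, 2)
  x <- start
  collided <- FALSE
  released <- FALSE
  rphys <- scene$obstacle_diameter / 2
  i <- 1L
  repeat {
    t <- (i - 1L) * dt
    p <- if (!is.null(release_time) && t >= release_time) {
      released <- TRUE; params_safe
    } else params
    f <- linear_field(x, scene, gain)
    xt <- x - scene$obstacle_center
    d <- sqrt(sum(xt^2))
    # saddle tie-break: rotate f slightly when anti-parallel to the radial
    # direction close to the obstacle
    if (d > 0 && d < 4 * p$eta * rphys) {
      nf <- sqrt(sum(f^2))
      if (nf > 0 && abs(xt[1] * f[2] - xt[2] * f[1]) < 1e-9 * d * nf &&
          sum(xt * f) < 0) {
        a <- 1e-3
        f <- c(cos(a) * f[1] - sin(a) * f[2], sin(a) * f[1] + cos(a) * f[2])
      }
    }
    v <- as.numeric(modulation_matrix(x, scene, p) %*% f)
    sp <- sqrt(sum(v^2))
    if (is.finite(speed_cap) && sp > speed_cap) v <- v * speed_cap / sp
    times[i] <- t; states[i, ] <- x; actions[i, ] <- v
    if (d < rphys) collided <- TRUE
    if (sqrt(sum((x - scene$target)^2)) < tol_goal || i >= n_max) break
    x <- x + dt * v
    i <- i + 1L
  }
  converged <- sqrt(sum((states[i, ] - scene$target)^2)) < tol_goal
  trajectory_path(times[seq_len(i)], states[seq_len(i), , drop = FALSE],
                  actions[seq_len(i), , drop = FALSE],
                  release_time = if (released) release_time else NULL,
                  collided = collided, converged = converged,
                  params = params, scene_id = scene$condition_id)
}

#' Minimum clearance of a path from the physical obstacle
#'
#' `min` over all states of `|xi - obstacle_center| - obstacle_diameter / 2`;
#' negative exactly when the path entered the physical sphere.
#'
#' @param path A [trajectory_path()] (or an n x 2 state matrix).
#' @param scene A [scene_spec()].
#' @return Scalar clearance (m).
#' @export
min_clearance <- function(path, scene) {
  states <- if (inherits(path, "trajectory_path")) path$states else rbind(path)
  if (is.null(states) || nrow(states) == 0L)
    stop("min_clearance: empty path")
  d <- sqrt((states[, 1] - scene$obstacle_center[1])^2 +
              (states[, 2] - scene$obstacle_center[2])^2)
  min(d) - scene$obstacle_diameter / 2
}

#' Write / read a trajectory as CSV
#'
#' Columns `t,x,y,vx,vy` preceded by `#`-prefixed metadata lines
#' (scene id, rho, eta, release_time, collided).
#'
#' @param path A [trajectory_path()].
#' @param file File path.
#' @return `write_trajectory_csv` returns `file` invisibly;
#'   `read_trajectory_csv` returns a [trajectory_path()].
#' @export
write_trajectory_csv <- function(path, file) {
  stopifnot(inherits(path, "trajectory_path"))
  con <- file(file, "w"); on.exit(close(con))
  meta <- c(sprintf("# scene_id: %s", path$scene_id),
            sprintf("# rho: %s", if (is.null(path$params)) NA else path$params$rho),
            sprintf("# eta: %s", if (is.null(path$params)) NA else path$params$eta),
            sprintf("# release_time: %s",
                    if (is.null(path$release_time)) "NA" else path$release_time),
            sprintf("# collided: %s", path$collided),
            sprintf("# converged: %s", path$converged))
  writeLines(meta, con)
  utils::write.csv(data.frame(t = path$times, x = path$states[, 1],
                              y = path$states[, 2], vx = path$actions[, 1],
                              vy = path$actions[, 2]),
                   con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), meta_lines, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  rho <- suppressWarnings(as.numeric(kv("rho")))
  eta <- suppressWarnings(as.numeric(kv("eta")))
  rt <- suppressWarnings(as.numeric(kv("release_time")))
  trajectory_path(df$t, cbind(df$x, df$y), cbind(df$vx, df$vy),
                  release_time = if (is.na(rt)) NULL else rt,
                  collided = identical(kv("collided"), "TRUE"),
                  converged = identical(kv("converged"), "TRUE"),
                  params = if (is.na(rho) || is.na(eta)) NULL else
                    modulation_params(rho, eta),
                  scene_id = kv("scene_id"))
}
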