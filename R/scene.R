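#' Scene specification for a planar reaching task
#'
#' A scene holds the target position of the end-effector, a single
#' spherical obstacle (center and diameter), the rectangular workspace and
#' a condition label. All geometry is planar and in meters.
#'
#' @param target Numeric 2-vector, attractor position of the dynamical
#'   system (m).
#' @param obstacle_center Numeric 2-vector, center of the obstacle (m).
#' @param obstacle_diameter Positive scalar, diameter of the sphere that
#'   bounds the obstacle (m).
#' @param workspace Numeric 4-vector `c(xmin, xmax, ymin, ymax)` (m).
#' @param condition_id Character label identifying the experimental
#'   condition (e.g. `"left_to_right"`).
#' @return An object of class `scene_spec`.
#' @examples
#' sc <- scene_spec(target = c(0.9, 0.3), obstacle_center = c(0.5, 0.3),
#'                  obstacle_diameter = 0.1,
#'                  workspace = c(0, 1, 0, 0.6), condition_id = "demo")
#' @export
scene_spec <- function(target, obstacle_center, obstacle_diameter,
                       workspace, condition_id = "default") {
  target <- as.numeric(target)
  obstacle_center <- as.numeric(obstacle_center)
  stopifnot(length(target) == 2L, length(obstacle_center) == 2L,
            length(workspace) == 4L, is.numeric(obstacle_diameter),
            length(obstacle_diameter) == 1L)
  if (!all(is.finite(c(target, obstacle_center, obstacle_diameter, workspace))))
    stop("scene_spec: all geometry must be finite")
  if (obstacle_diameter <= 0)
    stop("scene_spec: obstacle_diameter must be > 0")
  if (workspace[1] >= workspace[2] || workspace[3] >= workspace[4])
    stop("scene_spec: degenerate workspace")
  if (sqrt(sum((target - obstacle_center)^2)) <= obstacle_diameter / 2)
    stop("scene_spec: target must lie outside the obstacle sphere")
  inside <- obstacle_center[1] > workspace[1] && obstacle_center[1] < workspace[2] &&
    obstacle_center[2] > workspace[3] && obstacle_center[2] < workspace[4]
  if (!inside) stop("scene_spec: obstacle center must lie inside the workspace")
  structure(list(target = target, obstacle_center = obstacle_center,
                 obstacle_diameter = obstacle_diameter,
                 workspace = as.numeric(workspace),
                 condition_id = as.character(condition_id)),
            class = "scene_spec")
}

#' Modulation parameters of the obstacle-avoidance controller
#'
#' The two tunable parameters of the local modulation: the reactivity
#' `rho`, controlling how sharply the modulation decays with distance
#' from the obstacle, and the safety factor `eta`, which scales the
#' radius of the avoided region (effective safety radius
#' `eta * obstacle_diameter / 2`).
#'
#' @param rho Positive scalar, reactivity.
#' @param eta Positive scalar, safety factor.
#' @return An object of class `modulation_params`.
#' @export
modulation_params <- function(rho, eta) {
  stopifnot(is.numeric(rho), is.numeric(eta), length(rho) == 1L,
            length(eta) == 1L)
  if (!is.finite(rho) || !is.finite(eta) || rho <= 0 || eta <= 0)
    stop("modulation_params: rho and eta must be finite and > 0")
  structure(list(rho = rho, eta = eta), class = "modulation_params")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec '%s'> target (%.3f, %.3f) m, obstacle (%.3f, %.3f) m, d = %.3f m\n",
              x$condition_id, x$target[1], x$target[2],
              x$obstacle_center[1], x$obstacle_center[2], x$obstacle_diameter))
  invisible(x)
}

#' @export
print.modulation_params <- function(x, ...) {
  cat(sprintf("<modulation_params> rho = %.3f, eta = %.3f\n", x$rho, x$eta))
  invisible(x)
}

#' Canonical single-obstacle scene
#'
#' The table-top layout used throughout: the end-effector crosses the table
#' from one side to the other while an obstacle sits on the midline between
#' the two target positions, so straight-line motion would pass through it.
#'
#' @param direction `"left_to_right"` or `"right_to_left"`; swaps start and
#'   target.
#' @param obstacle_diameter Obstacle diameter (m); default 0.10 m
#'   (a table-top object such as a glass).
#' @return A list with elements `scene` (a [scene_spec()]) and `start`
#'   (2-vector, the trial's start position).
#' @export
canonical_scene <- function(direction = c("left_to_right", "right_to_left"),
                            obstacle_diameter = 0.10) {
  direction <- match.arg(direction)
  a <- c(0.10, 0.30)
  b <- c(0.90, 0.30)
  if (direction == "left_to_right") {
    start <- a; target <- b
  } else {
    start <- b; target <- a
  }
  list(scene = scene_spec(target = target,
                          obstacle_center = c(0.50, 0.30),
                          obstacle_diameter = obstacle_diameter,
                          workspace = c(-0.2, 1.2, -0.4, 1.0),
                          condition_id = direction),
       start = start)
}

#' Scene set for the pick-and-place protocol
#'
#' Eight conditions: four target positions crossed with a grasp /
#' no-grasp state. The grasp state changes the condition label (and hence
#' which demonstrations are pooled during adaptation) but not the planar
#' obstacle geometry, which differs per target pair.
#'
#' @param obstacle_diameter Obstacle diameter (m).
#' @return Named list of 8 lists, each with `scene` and `start`.
#' @export
pick_place_scenes <- function(obstacle_diameter = 0.10) {
  targets <- list(T1 = c(0.15, 0.15), T2 = c(0.85, 0.15),
                  T3 = c(0.15, 0.55), T4 = c(0.85, 0.55))
  center <- c(0.5, 0.35)
  out <- list()
  for (tn in names(targets)) {
    for (g in c("grasp", "nograsp")) {
      id <- paste(tn, g, sep = "_")
      tgt <- targets[[tn]]
      # segment center -> target passes near the mid-table obstacle
      obs <- center + 0.45 * (tgt - center)
      out[[id]] <- list(
        scene = scene_spec(target = tgt, obstacle_center = obs,
                           obstacle_diameter = obstacle_diameter,
                           workspace = c(-0.2, 1.2, -0.4, 1.0),
                           condition_id = id),
        start = center)
    }
  }
  out
}

#' Read / write a scene as YAML
#'
#' @param scene A [scene_spec()].
#' @param path File path.
#' @return `write_scene_yaml` returns `path` invisibly; `read_scene_yaml`
#'   returns a [scene_spec()].
#' @export
write_scene_yaml <- function(scene, path) {
  stopifnot(inherits(scene, "scene_spec"))
  yaml::write_yaml(list(
    target = scene$target,
    obstacle = list(center = scene$obstacle_center,
                    diameter = scene$obstacle_diameter),
    workspace = scene$workspace,
    condition_id = scene$condition_id), path)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  scene_spec(target = y$target, obstacle_center = y$obstacle$center,
             obstacle_diameter = y$obstacle$diameter,
             workspace = y$workspace, condition_id = y$condition_id)
}
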