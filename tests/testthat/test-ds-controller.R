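cs <- canonical_scene()

test_that("linear field is an attractor field with the configured gain", {
  expect_equal(linear_field(cs$scene$target, cs$scene), c(0, 0))
  sc <- scene_spec(target = c(1, 0), obstacle_center = c(0.5, 0.2),
                   obstacle_diameter = 0.1, workspace = c(-1, 2, -1, 1))
  expect_equal(linear_field(c(0, 0), sc, gain = 1), c(1, 0))
  set.seed(1)
  for (i in 1:20) {
    xi <- runif(2, -0.1, 1.1)
    g <- runif(1, 0.5, 3)
    v <- linear_field(xi, cs$scene, gain = g)
    dir <- cs$scene$target - xi
    expect_equal(v, g * dir)                       # parallel, magnitude g*|d|
    expect_equal(sqrt(sum(v^2)), g * sqrt(sum(dir^2)))
  }
  expect_error(linear_field(c(NA, 0), cs$scene), "finite")
})

test_that("modulation matches the analytic construction and its limits", {
  p <- modulation_params(1.5, 1.2)
  # far from the obstacle the field is unchanged
  far <- cs$scene$obstacle_center + c(0, 10)
  expect_equal(modulated_field(far, cs$scene, p),
               linear_field(far, cs$scene),
               tolerance = 1e-6)
  # on the safety boundary the radial component vanishes
  r_safe <- p$eta * cs$scene$obstacle_diameter / 2
  bpt <- cs$scene$obstacle_center + r_safe * c(cos(0.7), sin(0.7))
  v <- modulated_field(bpt, cs$scene, p)
  nrm <- (bpt - cs$scene$obstacle_center) / r_safe
  expect_lt(abs(sum(v * nrm)), 1e-10)
  # independent matrix-assembly oracle at random states and parameters
  set.seed(7)
  for (i in 1:25) {
    pp <- modulation_params(runif(1, 0.3, 4), runif(1, 0.5, 3))
    xi <- cs$scene$obstacle_center + runif(1, 0.02, 0.5) *
      c(cos(runif(1, 0, 2 * pi)), sin(runif(1, 0, 2 * pi)))
    xt <- xi - cs$scene$obstacle_center
    d <- sqrt(sum(xt^2))
    gam <- (2 * d / (pp$eta * cs$scene$obstacle_diameter))^(2 * pp$rho)
    n_ <- xt / d; t_ <- c(-n_[2], n_[1])
    E <- cbind(n_, t_)
    M_oracle <- E %*% diag(c(1 - 1 / gam, 1 + 1 / gam)) %*% t(E)
    f <- linear_field(xi, cs$scene)
    expect_equal(modulated_field(xi, cs$scene, pp),
                 as.numeric(M_oracle %*% f), tolerance = 1e-12)
  }
  expect_error(modulated_field(cs$scene$obstacle_center, cs$scene, p),
               "degenerate")
})

test_that("rollouts reach the goal, avoid the safety sphere, and flag collisions", {
  # obstacle on the straight segment, eta >= 1: no collision; dense oracle
  p <- modulation_params(1.5, 1.0)
  tr <- integrate_trajectory(cs$start, cs$scene, p)
  expect_true(tr$converged)
  # at eta exactly 1 the fixed step may graze the sphere within one step
  # of discretization slack; the dense rollout oracle must stay outside
  dense <- integrate_trajectory(cs$start, cs$scene, p, dt = 1e-3)
  expect_false(dense$collided)
  dmin <- min(sqrt(rowSums(sweep(dense$states, 2,
                                 cs$scene$obstacle_center)^2)))
  expect_gte(dmin, cs$scene$obstacle_diameter / 2 - 1e-9)
  # with any real margin the default step never touches the sphere
  tr11 <- integrate_trajectory(cs$start, cs$scene, modulation_params(1.5, 1.1))
  expect_false(tr11$collided)
  # eta < 1 admits light contact with the physical sphere
  tr_low <- integrate_trajectory(cs$start, cs$scene, modulation_params(1.5, 0.8))
  expect_true(tr_low$collided)
  expect_lt(min_clearance(tr_low, cs$scene), 0)
  # consecutive states are consistent with the stored actions
  dt <- diff(tr$times)
  pred <- tr$states[-nrow(tr$states), ] + dt * tr$actions[-nrow(tr$actions), ]
  expect_equal(pred, tr$states[-1, ], tolerance = 1e-12)
})

test_that("release switches to the safety modulation and widens the pass", {
  p <- modulation_params(1.8, 0.9)
  no_rel <- integrate_trajectory(cs$start, cs$scene, p)
  rel <- integrate_trajectory(cs$start, cs$scene, p, release_time = 1.1)
  expect_equal(rel$release_time, 1.1)
  expect_gt(min_clearance(rel, cs$scene), min_clearance(no_rel, cs$scene))
})

test_that("min_clearance matches its definition and a brute-force scan", {
  single <- trajectory_path(0, rbind(cs$scene$obstacle_center + c(0.15, 0)),
                            rbind(c(0, 0)))
  expect_equal(min_clearance(single, cs$scene),
               0.15 - cs$scene$obstacle_diameter / 2)
  tr <- integrate_trajectory(cs$start, cs$scene, modulation_params(1, 1.4))
  brute <- min(apply(tr$states, 1, function(s)
    sqrt(sum((s - cs$scene$obstacle_center)^2)))) -
    cs$scene$obstacle_diameter / 2
  expect_equal(min_clearance(tr, cs$scene), brute)
  expect_error(min_clearance(matrix(numeric(), 0, 2), cs$scene), "empty")
})

test_that("every start outside the obstacle converges to the target", {
  set.seed(11)
  n_ok <- 0L
  for (i in 1:200) {
    repeat {
      s0 <- c(runif(1, -0.1, 1.1), runif(1, -0.3, 0.9))
      if (sqrt(sum((s0 - cs$scene$obstacle_center)^2)) >
          1.1 * cs$scene$obstacle_diameter / 2) break
    }
    tr <- integrate_trajectory(s0, cs$scene, modulation_params(runif(1, 0.5, 3),
                                                               runif(1, 1, 2)))
    n_ok <- n_ok + tr$converged
  }
  expect_equal(n_ok, 200L)
})

test_that("modulation strength decays faster with distance as rho grows", {
  pt <- cs$scene$obstacle_center + c(0.09, 0.05)  # outside safety sphere
  norms <- sapply(c(0.5, 1, 1.5, 2, 3), function(rho) {
    M <- modulation_matrix(pt, cs$scene, modulation_params(rho, 1.2))
    sqrt(sum((M - diag(2))^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("scene YAML and trajectory CSV round-trip", {
  f <- tempfile(fileext = ".yaml")
  write_scene_yaml(cs$scene, f)
  sc2 <- read_scene_yaml(f)
  expect_equal(sc2$target, cs$scene$target)
  expect_equal(sc2$obstacle_diameter, cs$scene$obstacle_diameter)
  expect_equal(sc2$condition_id, cs$scene$condition_id)

  tr <- integrate_trajectory(cs$start, cs$scene, modulation_params(1.2, 1.1),
                             release_time = 1.2)
  g <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, g)
  tr2 <- read_trajectory_csv(g)
  expect_equal(tr2$states, tr$states, ignore_attr = TRUE)
  expect_equal(tr2$release_time, tr$release_time)
  expect_equal(tr2$collided, tr$collided)
  expect_equal(tr2$params$eta, 1.1)
})

test_that("degenerate scenes are rejected", {
  expect_error(scene_spec(c(0.5, 0.3), c(0.5, 0.3), 0.2, c(0, 1, 0, 1)),
               "outside the obstacle")
  expect_error(scene_spec(c(0.9, 0.3), c(2, 0.3), 0.1, c(0, 1, 0, 1)),
               "inside the workspace")
  expect_error(modulation_params(-1, 1))
})
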