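cs <- default_scene
basis <- ebf_basis(cs$scene)

test_that("EBF features follow the Gaussian quadratic form", {
  expect_equal(ebf_features(basis$center, basis), rep(1, 3))
  expect_lt(max(ebf_features(basis$center + c(5, 5), basis)), 1e-10)
  set.seed(3)
  for (i in 1:10) {
    xi <- basis$center + rnorm(2, 0, 0.2)
    oracle <- vapply(seq_along(basis$zetas), function(k)
      exp(-basis$zetas[k] / 2 *
            as.numeric(t(xi - basis$center) %*% basis$lambdas[[k]] %*%
                         (xi - basis$center))), 0)
    expect_equal(ebf_features(xi, basis), oracle, tolerance = 1e-12)
    expect_true(all(oracle > 0 & oracle <= 1))
  }
  expect_error(ebf_basis(cs$scene, lambdas = list(diag(2), -diag(2), diag(2))),
               "positive definite")
})

test_that("GP kernel keeps beta on the diagonal and matches a loop oracle", {
  set.seed(8)
  F5 <- matrix(runif(15), 5, 3)
  lam <- c(0.7, 2.1, 0.3); beta <- 1.8; s2 <- 0.05
  K <- gp_kernel(F5, lam, beta, s2)
  expect_equal(diag(K), rep(beta, 5))
  expect_equal(K, t(K))
  oracle <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    acc <- 0
    for (k in 1:3)
      acc <- acc + lam[k] * ((F5[i, k] - F5[j, k])^2 + (i != j) * s2)
    oracle[i, j] <- beta * exp(-acc / 2)
  }
  expect_equal(K, oracle, tolerance = 1e-12)
  # lambda = 0: every entry collapses to beta
  expect_true(all(abs(gp_kernel(F5, c(0, 0, 0), beta, s2) - beta) < 1e-12))
})

test_that("weighted objective is linear in the demonstration weights", {
  d1 <- arc_demo(0.08, 1.0)
  model <- fit_reward_model(list(d1), basis, seed = 1)
  # a zero-weight demonstration contributes exactly nothing
  d0 <- arc_demo(0.12, 0)
  expect_equal(weighted_log_likelihood(list(d1, d0), model),
               weighted_log_likelihood(list(d1), model))
  # two identical demos with weights 0.3 and 0.7 equal one with weight 1
  d37a <- arc_demo(0.08, 0.3); d37b <- arc_demo(0.08, 0.7)
  expect_equal(weighted_log_likelihood(list(d37a, d37b), model),
               weighted_log_likelihood(list(d1), model),
               tolerance = 1e-9)
  # single demonstration with w = 1: equals the unweighted block formula
  ind <- errpirl:::inducing_set(list(d1), basis, model$cap)
  K <- gp_kernel(ind$F, model$lambda, model$beta, model$sigma2)
  K <- K + diag(1e-8 * mean(diag(K)), nrow(K))
  y <- model$y
  prior <- -0.5 * sum(solve(K)^2) - sum(log(model$lambda + 1))
  oracle <- -0.5 * as.numeric(t(y) %*% solve(K, y)) -
    0.5 * as.numeric(determinant(K)$modulus) + prior
  expect_equal(weighted_log_likelihood(list(d1), model), oracle,
               tolerance = 1e-6)
})

test_that("posterior-mean reward matches dense linear algebra and is linear in y", {
  d <- list(arc_demo(0.07, 0.9), arc_demo(0.1, 0.2))
  m <- fit_reward_model(d, basis, seed = 2)
  set.seed(5)
  for (i in 1:5) {
    xi <- basis$center + rnorm(2, 0, 0.1)
    Ks <- gp_kernel(rbind(ebf_features(xi, basis)), m$lambda, m$beta,
                    m$sigma2, F2 = m$F)
    K <- gp_kernel(m$F, m$lambda, m$beta, m$sigma2)
    tau2 <- 1 / (2 * m$anchor)
    oracle <- as.numeric(Ks %*% solve(K + diag(tau2, nrow(K)) +
                                        diag(1e-8 * m$beta, nrow(K)),
                                      m$point_weights))
    expect_equal(reward_at(m, xi), oracle, tolerance = 1e-4)
  }
  # y = 0 model: reward identically zero; doubling alpha doubles reward
  m0 <- m; m0$alpha <- m$alpha * 0
  expect_equal(reward_at(m0, basis$center + c(0.1, 0)), 0)
  m2 <- m; m2$alpha <- m$alpha * 2
  expect_equal(reward_at(m2, basis$center + c(0.1, 0)),
               2 * reward_at(m, basis$center + c(0.1, 0)))
  # trajectory reward inherits both properties
  expect_equal(trajectory_reward(c(1.5, 1.4), m0, cs$scene, cs$start), 0)
  expect_equal(trajectory_reward(c(1.5, 1.4), m2, cs$scene, cs$start),
               2 * trajectory_reward(c(1.5, 1.4), m, cs$scene, cs$start))
})

test_that("reward model fitting is deterministic and persists to JSON", {
  d <- list(arc_demo(0.08, 0.9), arc_demo(0.11, 0.1), arc_demo(0.09, 0.8))
  m1 <- fit_reward_model(d, basis, seed = 4)
  m2 <- fit_reward_model(d, basis, seed = 4)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$y, m2$y)
  f <- tempfile(fileext = ".json")
  save_reward_model(m1, f)
  m3 <- load_reward_model(f)
  xi <- basis$center + c(0.09, 0.02)
  expect_equal(reward_at(m3, xi), reward_at(m1, xi), tolerance = 1e-12)
  # identical high-weight demos: reward at their points beats far field
  same <- list(arc_demo(0.09, 1), arc_demo(0.09, 1), arc_demo(0.09, 1))
  ms <- fit_reward_model(same, basis, seed = 1)
  on_ring <- basis$center + c(0, 0.09)
  far <- basis$center + c(0, 0.09 + 2 * 0.05)
  expect_gt(reward_at(ms, on_ring), reward_at(ms, far))
})

test_that("fitted hyperparameters beat random draws from the search box", {
  d <- list(arc_demo(0.08, 0.9), arc_demo(0.12, 0.1))
  m <- fit_reward_model(d, basis, seed = 3)
  ind <- errpirl:::inducing_set(d, basis, m$cap)
  best <- errpirl:::gpirl_objective(ind, m$lambda, m$beta, m$sigma2,
                                    m$anchor)$value
  set.seed(99)
  for (i in 1:100) {
    lam <- exp(runif(3, log(40), log(120)))
    bet <- exp(runif(1, log(0.5), log(2)))
    expect_lte(errpirl:::gpirl_objective(ind, lam, bet, m$sigma2,
                                         m$anchor)$value,
               best + 1e-6)
  }
})

test_that("finite-difference gradients match a central-difference oracle", {
  d <- list(arc_demo(0.08, 0.9), arc_demo(0.11, 0.15))
  m <- fit_reward_model(d, basis, seed = 1)
  p <- modulation_params(1.4, 1.5)
  eps <- 1e-3
  # a fine integration step keeps the rollout reward smooth at the eps
  # scale, so the finite differences measure the field, not step jitter
  g <- modulation_gradients(p, m, cs$scene, cs$start, eps = eps, dt = 0.002)
  cd_rho <- (trajectory_reward(modulation_params(p$rho - eps, p$eta), m,
                               cs$scene, cs$start, dt = 0.002) -
               trajectory_reward(modulation_params(p$rho + eps, p$eta), m,
                                 cs$scene, cs$start, dt = 0.002)) / (2 * eps)
  cd_eta <- (trajectory_reward(modulation_params(p$rho, p$eta - eps), m,
                               cs$scene, cs$start, dt = 0.002) -
               trajectory_reward(modulation_params(p$rho, p$eta + eps), m,
                                 cs$scene, cs$start, dt = 0.002)) / (2 * eps)
  expect_equal(unname(g["g_rho"]), cd_rho, tolerance = 0.1)
  expect_equal(unname(g["g_eta"]), cd_eta, tolerance = 0.1)
})

test_that("a flat reward leaves the parameters at their initial value", {
  d <- list(arc_demo(0.08, 0.9))
  m <- fit_reward_model(d, basis, seed = 1)
  m$alpha <- m$alpha * 0   # reward identically zero
  init <- modulation_params(1.33, 1.27)
  out <- optimize_modulation(m, cs$scene, cs$start, init = init, seed = 1,
                             efficiency = 0)
  expect_equal(out$rho, init$rho, tolerance = 1e-6)
  expect_equal(out$eta, init$eta, tolerance = 1e-6)
})

test_that("zero-weight demonstrations do not change the optimized parameters", {
  d <- list(rollout_demo(1.5, 1.7, 0.9), rollout_demo(2, 1.8, 0.85),
            rollout_demo(1.2, 1.0, 0.1))
  dz <- c(d, list(rollout_demo(2.5, 1.3, 0)))
  m1 <- fit_reward_model(d, basis, seed = 5)
  m2 <- fit_reward_model(dz, basis, seed = 5)
  expect_equal(m1$objective, m2$objective)
  o1 <- optimize_modulation(m1, cs$scene, cs$start, seed = 2)
  o2 <- optimize_modulation(m2, cs$scene, cs$start, seed = 2)
  expect_equal(c(o1$rho, o1$eta), c(o2$rho, o2$eta))
})

test_that("a planted reward ring is recovered by the parameter search", {
  r0 <- cs$scene$obstacle_diameter / 2
  cstar <- 0.03
  demos <- list(arc_demo(r0 + cstar, 0.95),
                arc_demo(r0 + cstar + 0.002, 0.9),
                arc_demo(r0 + cstar - 0.018, 0.08),
                arc_demo(r0 + cstar + 0.018, 0.08))
  m <- fit_reward_model(demos, basis, seed = 1)
  opt <- optimize_modulation(m, cs$scene, cs$start, seed = 1)
  cl <- min_clearance(integrate_trajectory(cs$start, cs$scene, opt), cs$scene)
  expect_lt(abs(cl - cstar) / cstar, 0.10)
})

test_that("demonstrations round-trip through CSV + JSON sidecar", {
  d <- rollout_demo(1.4, 1.3, 0.62)
  stem <- tempfile()
  write_demonstration(d, stem)
  d2 <- read_demonstration(stem, cs$scene)
  expect_equal(d2$weight, 0.62)
  expect_equal(d2$points, d$points, tolerance = 1e-9)
})
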