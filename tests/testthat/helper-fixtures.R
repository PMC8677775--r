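# shared fixtures, built in code

default_scene <- canonical_scene()

# small labeled epoch set with a planted evoked response: one fixed
# spatial pattern carries a deterministic waveform on erroneous trials
make_synthetic_epochs <- function(n_err = 8, n_corr = 16, seed = 42,
                                  amp = 6, s = 256, fs = 512) {
  set.seed(seed)
  pattern <- errp_template()$topography
  tt <- (0:(s - 1)) / fs
  wave <- sin(2 * pi * 3 * tt) * exp(-((tt - 0.2) / 0.12)^2)
  epochs <- list(); labels <- character()
  for (i in seq_len(n_err + n_corr)) {
    e <- matrix(stats::rnorm(16 * s, sd = 3), 16, s)
    lab <- if (i <= n_err) "erroneous" else "correct"
    if (lab == "erroneous") e <- e + amp * outer(pattern, wave)
    epochs[[i]] <- e
    labels <- c(labels, lab)
  }
  list(epochs = epochs, labels = labels, pattern = pattern, wave = wave)
}

# arc-shaped demonstration at a fixed radius around the canonical obstacle
arc_demo <- function(radius, weight, scene = default_scene$scene, n = 60) {
  th <- seq(pi * 0.15, pi * 0.85, length.out = n)
  st <- cbind(scene$obstacle_center[1] + radius * cos(th),
              scene$obstacle_center[2] + radius * sin(th))
  demonstration(trajectory_path(seq(0, by = 0.02, length.out = n), st,
                                matrix(0, n, 2)),
                weight, scene)
}

# demonstration generated by the DS controller
rollout_demo <- function(rho, eta, weight, release_time = NULL,
                         cs = default_scene) {
  demonstration(integrate_trajectory(cs$start, cs$scene,
                                     modulation_params(rho, eta),
                                     release_time = release_time),
                weight, cs$scene)
}
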