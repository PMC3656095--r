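# Shared fixtures: everything is generated in code at test time.

gaussian_kernel5 <- function() force_kernel(niche_shape("gaussian", 5))

# count stable points (down-crossings) of a sampled 1-D field
n_stable_1d <- function(field) {
  cen <- find_stable_points_1d(field, c(0, field$range))
  sum(cen$classification == "stable")
}

# crossing count of a finite population's force on a grid
pop_crossings <- function(K, R = 100, sigma = 5, seed = NULL) {
  cfg <- rein_config(K = K, essential_range = R, niche_width = sigma,
                     seed = seed)
  pop <- sample_population(cfg)
  x <- seq(0, R, by = sigma / 4)
  f <- reinworld:::.force_on_grid_1d(pop, x)
  s <- sign(f)
  sum(s[-length(s)] > 0 & s[-1] < 0)
}

# a hand-built staircase trajectory for the plateau detector
staircase_trajectory <- function(dt = 0.1, tau = 1) {
  t1 <- seq(0, 40, by = dt)
  t2 <- seq(40 + dt, 45, by = dt)
  t3 <- seq(45 + dt, 100, by = dt)
  E <- c(rep(20, length(t1)),
         20 + (t2 - 40) / 5 * 20,
         rep(40, length(t3)))
  tms <- c(t1, t2, t3)
  n <- length(tms)
  structure(list(times = tms, env = matrix(E, ncol = 1),
                 perturbation = matrix(0.01 * tms, ncol = 1),
                 force = matrix(-0.01 * tms, ncol = 1),
                 abundances = NULL,
                 config = rein_config(tau_env = tau), protocol = NULL,
                 method = "rk4"),
            class = "rein_trajectory")
}
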