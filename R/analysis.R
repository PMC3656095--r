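# Internal fixed-step RK4 relaxation of dE/dt = (P + F(E)) / tau on a
# sampled field or callable force, with escape and settling detection.
# Returns list(E, status, t) with status "settled" | "escaped" | "timeout".
.relax <- function(ffun, E0, R, P = 0, tau = 1, dt = NULL, t_max = 1000,
                   margin = 0, settle_tol = 1e-7) {
  n <- length(E0)
  P <- rep_len(P, n)
  if (is.null(dt)) dt <- 0.05 * tau * max(1, R / 20)
  f <- function(E) (P + ffun(pmin(pmax(E, 0), R))) / tau
  E <- E0
  t <- 0
  quiet <- 0L
  while (t < t_max) {
    k1 <- f(E); k2 <- f(E + dt / 2 * k1); k3 <- f(E + dt / 2 * k2)
    k4 <- f(E + dt * k3)
    dE <- dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    E <- E + dE
    t <- t + dt
    if (any(E < -margin) || any(E > R + margin))
      return(list(E = E, status = "escaped", t = t))
    if (sqrt(sum(dE^2)) < settle_tol * R) {
      quiet <- quiet + 1L
      if (quiet >= 10L) return(list(E = E, status = "settled", t = t))
    } else quiet <- 0L
  }
  list(E = E, status = "timeout", t = t)
}

#' Probability of relaxing to a stable point inside the essential range
#'
#' Estimates the chance that a randomly initialised system reaches a
#' homeostatic stable point without any environmental variable ever
#' leaving the essential range. Each trial draws a fresh large-K force
#' field, starts the environment uniformly inside `[0, R]^n_env` with no
#' external forcing, and integrates until it settles, escapes, or times
#' out (timeouts are reported separately and count as non-survival).
#'
#' @param n_env number of environmental variables.
#' @param config a [rein_config()] supplying `R`, the niche shape and
#'   `tau_env`.
#' @param n_trials number of Monte-Carlo trials.
#' @param seed run seed (each trial forks its own stream).
#' @param margin how far outside `[0, R]` a variable may stray before the
#'   trial counts as escaped; the default 0 is the strict essential range.
#' @param h field grid spacing; defaults to `width/4`, coarsened to
#'   `width/2` for `n_env >= 3` to keep the covariance factorisation small.
#' @param t_max,dt integration horizon and step.
#' @param conf_level confidence level of the binomial interval.
#' @param force_factory optional function `seed -> force` overriding the
#'   default fresh-field draw per trial (e.g. a fixed analytic force, or a
#'   finite population sampler).
#' @return an object of class `survival_estimate`: the point estimate, a
#'   binomial confidence interval, and the trial breakdown.
#' @export
#' @examples
#' \donttest{
#' survival_probability(1, rein_config(), n_trials = 20, seed = 1)
#' }
survival_probability <- function(n_env, config = rein_config(),
                                 n_trials = 100, seed = NULL, margin = 0,
                                 h = NULL, t_max = 2000, dt = NULL,
                                 conf_level = 0.95, force_factory = NULL) {
  stopifnot(n_trials >= 1)
  R <- config$essential_range
  shape <- .shape_from_config(config)
  if (is.null(h)) h <- if (n_env >= 3L) shape$width / 2 else shape$width / 4
  kernel <- force_kernel(shape)
  if (is.null(dt)) dt <- 0.25 * config$tau_env
  n_surv <- 0L; n_esc <- 0L; n_time <- 0L
  for (i in seq_len(n_trials)) {
    si <- if (is.null(seed)) NULL else fork_seed(seed, paste0("trial:", i))
    frc <- if (is.null(force_factory))
      sample_force_field(kernel, n_env = n_env, range = R, h = h,
                         seed = si)
    else force_factory(si)
    ffun <- .as_force_fun(frc)
    E0 <- with_seed(if (is.null(si)) NULL else fork_seed(si, "E0"),
                    runif(n_env, 0, R))
    res <- .relax(ffun, E0, R,
                  tau = config$tau_env, dt = dt, t_max = t_max,
                  margin = margin)
    if (res$status == "settled") n_surv <- n_surv + 1L
    else if (res$status == "escaped") n_esc <- n_esc + 1L
    else n_time <- n_time + 1L
  }
  bt <- stats::binom.test(n_surv, n_trials, conf.level = conf_level)
  structure(list(estimate = n_surv / n_trials,
                 ci = as.numeric(bt$conf.int), conf_level = conf_level,
                 n_trials = n_trials, n_survived = n_surv,
                 n_escaped = n_esc, n_unsettled = n_time, n_env = n_env),
            class = "survival_estimate")
}

#' @export
print.survival_estimate <- function(x, ...) {
  cat(sprintf(
    "<survival_estimate> n_env=%d: %.3f (%d%% CI %.3f-%.3f), %d trials",
    x$n_env, x$estimate, round(100 * x$conf_level), x$ci[1L], x$ci[2L],
    x$n_trials), "\n")
  if (x$n_unsettled > 0)
    cat("  note:", x$n_unsettled, "trials did not settle within t_max\n")
  invisible(x)
}

#' Map the basins of attraction of a force field
#'
#' Integrates the unforced dynamics from a grid of initial conditions over
#' `[0, R]^n_env` and labels each cell by the stable point it relaxes to,
#' or as escaped when a trajectory leaves the essential range (the white
#' regions of a phase portrait).
#'
#' @param force a `gp_force_field`, `biotic_population` or function.
#' @param census optional precomputed [find_fixed_points_nd()] output.
#' @param range essential range `R`.
#' @param n_env dimensionality (required for callable forces).
#' @param resolution number of initial conditions per axis.
#' @param margin escape margin outside `[0, R]` (default 0: strict).
#' @param match_tol endpoint-to-stable-point matching tolerance (default
#'   `0.02 * R`).
#' @param tau,dt,t_max integration parameters.
#' @return an object of class `basin_map`: the grid axes, an integer label
#'   array (`> 0`: row of the stable point in the census, `-1`: escaped,
#'   `0`: unresolved), and the census.
#' @export
basin_map <- function(force, census = NULL, range = 100, n_env = NULL,
                      resolution = 21L, margin = 0, match_tol = NULL,
                      tau = 1, dt = NULL, t_max = 2000) {
  R <- range[length(range)]
  n_env <- if (!is.null(n_env)) n_env else .force_n_env(force)
  if (is.null(n_env)) stop("'n_env' is required for a callable force")
  if (is.null(match_tol)) match_tol <- 0.02 * R
  ffun <- .as_force_fun(force)
  if (is.null(census))
    census <- if (n_env == 1L) {
      cs <- find_stable_points_1d(force, c(0, R))
      names(cs)[1L] <- "E_1"
      cs
    } else find_fixed_points_nd(force, R, n_env = n_env)
  sp <- census[census$classification == "stable", , drop = FALSE]
  sp_loc <- as.matrix(sp[, seq_len(n_env), drop = FALSE])
  axes <- rep(list(seq(0, R, length.out = resolution)), n_env)
  starts <- as.matrix(expand.grid(axes))
  labels <- integer(nrow(starts))
  for (r in seq_len(nrow(starts))) {
    res <- .relax(ffun, starts[r, ], R, tau = tau, dt = dt, t_max = t_max,
                  margin = margin)
    if (res$status == "escaped") { labels[r] <- -1L; next }
    if (res$status == "timeout") { labels[r] <- 0L; next }
    if (nrow(sp_loc) == 0L) { labels[r] <- 0L; next }
    d <- sqrt(rowSums((sp_loc - matrix(res$E, nrow(sp_loc), n_env,
                                       byrow = TRUE))^2))
    labels[r] <- if (min(d) < match_tol) which.min(d) else 0L
  }
  structure(list(axes = axes, labels = array(labels,
                                             rep(resolution, n_env)),
                 census = census, resolution = resolution, range = R,
                 margin = margin, match_tol = match_tol),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  n_esc <- sum(x$labels == -1L)
  cat("<basin_map>", length(x$labels), "initial conditions,",
      sum(x$census$classification == "stable"), "stable points,",
      n_esc, "escaped cells\n")
  invisible(x)
}

#' @export
plot.basin_map <- function(x, ...) {
  if (length(x$axes) != 2L)
    stop("plotting is implemented for 2-D basin maps")
  cols <- c("white", "grey80", hcl.colors(max(1, max(x$labels)), "Dark 3"))
  image(x$axes[[1L]], x$axes[[2L]], x$labels,
        col = cols, breaks = seq(-1.5, max(x$labels) + 0.5),
        xlab = "E_1", ylab = "E_2", ...)
  sp <- x$census[x$census$classification == "stable", ]
  points(sp$E_1, sp$E_2, pch = 21, bg = "black")
  invisible(x)
}

#' Quasi-static hysteresis sweep of a 1-D system
#'
#' Slowly ramps the external forcing from `p_range[1]` to `p_range[2]` and
#' back, letting the environment relax to its local stable point at every
#' step, and records the occupied branch `E*(P)` in both directions.
#' Because several homeostatic points coexist for a given forcing, the
#' upward and downward branches need not coincide: the sweep jumps to a
#' different branch when the occupied stable point is annihilated at a
#' fold, and recovering the old state requires backtracking the forcing
#' past the original transition - an open hysteresis loop.
#'
#' @param force a 1-D `gp_force_field`, `biotic_population` or function.
#' @param p_range forcing interval swept, `c(lo, hi)`.
#' @param n_steps number of forcing steps per branch.
#' @param E0 starting state; defaults to the lowest stable point at
#'   `P = p_range[1]`.
#' @param range essential range scanned for that default.
#' @param jump_tol jump size in `E` that counts as a branch transition
#'   (default: the kernel/niche width, else `0.05 * range`).
#' @param tau,dt,t_max relaxation parameters.
#' @return an object of class `hysteresis_sweep` with the two branches,
#'   the detected transitions, and the enclosed loop area.
#' @export
hysteresis_sweep <- function(force, p_range = c(-2, 2), n_steps = 101L,
                             E0 = NULL, range = 100, jump_tol = NULL,
                             tau = 1, dt = NULL, t_max = 2000) {
  R <- range[length(range)]
  if (is.null(jump_tol))
    jump_tol <- if (inherits(force, "gp_force_field"))
      force$kernel$width
    else if (inherits(force, "biotic_population")) force$shape$width
    else 0.05 * R
  ffun <- .as_force_fun(force)
  if (!is.null(.force_n_env(force)) && .force_n_env(force) != 1L)
    stop("hysteresis_sweep is defined for 1-D systems")
  P_up <- seq(p_range[1L], p_range[2L], length.out = n_steps)
  if (is.null(E0)) {
    cen <- find_stable_points_1d(function(E) ffun(E) + P_up[1L], c(0, R))
    st <- cen$location[cen$classification == "stable"]
    E0 <- if (length(st)) min(st) else R / 2
  }
  run_branch <- function(Ps, E_start) {
    E <- numeric(length(Ps))
    cur <- E_start
    for (i in seq_along(Ps)) {
      res <- .relax(ffun, cur, R, P = Ps[i], tau = tau, dt = dt,
                    t_max = t_max, margin = 0.5 * R)
      cur <- res$E
      E[i] <- cur
    }
    E
  }
  E_up <- run_branch(P_up, E0)
  P_down <- rev(P_up)
  E_down <- run_branch(P_down, E_up[n_steps])
  find_jumps <- function(P, E, direction) {
    j <- which(abs(diff(E)) > jump_tol)
    if (!length(j)) return(data.frame())
    data.frame(direction = direction, P_at_jump = P[j + 1L],
               E_from = E[j], E_to = E[j + 1L])
  }
  transitions <- rbind(find_jumps(P_up, E_up, "up"),
                       find_jumps(P_down, E_down, "down"))
  dP <- diff(P_up)
  loop_area <- abs(sum((E_up[-1L] + E_up[-n_steps]) / 2 * dP) -
                     sum((rev(E_down)[-1L] + rev(E_down)[-n_steps]) / 2 * dP))
  structure(list(P_up = P_up, E_up = E_up, P_down = P_down,
                 E_down = E_down, transitions = transitions,
                 loop_area = loop_area, jump_tol = jump_tol),
            class = "hysteresis_sweep")
}

#' @export
print.hysteresis_sweep <- function(x, ...) {
  cat("<hysteresis_sweep>", length(x$P_up), "forcing steps,",
      nrow(x$transitions), "transitions, loop area",
      format(x$loop_area, digits = 4), "\n")
  if (nrow(x$transitions)) print(x$transitions)
  invisible(x)
}

#' @export
plot.hysteresis_sweep <- function(x, ...) {
  plot(x$P_up, x$E_up, type = "l", col = "firebrick", xlab = "P",
       ylab = "E*", ...)
  lines(x$P_down, x$E_down, col = "steelblue")
  legend("topleft", legend = c("up", "down"), lty = 1,
         col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
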