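#' Rate of change of the environmental variables
#'
#' `dE_i/dt = (P_i + F_i(E)) / tau_env`: the environment relaxes under the
#' sum of the external perturbation and the total biotic force. A fixed
#' point of the coupled system is exactly a point where `F = -P`.
#'
#' @param E numeric vector of environmental values.
#' @param pop a `biotic_population` (may be empty).
#' @param P numeric vector of external forcing, same length as `E`.
#' @param tau_env positive environmental timescale.
#' @return numeric vector `dE/dt`.
#' @export
env_derivative <- function(E, pop, P, tau_env) {
  if (tau_env <= 0) stop("'tau_env' must be positive")
  if (length(P) != length(E)) stop("P and E must have the same length")
  (P + total_biotic_force(pop, E)) / tau_env
}

#' Rate of change of the abundances
#'
#' Linear relaxation of each abundance towards its environment-determined
#' steady state: `d alpha/dt = (alpha_star - alpha) / tau_biotic`.
#'
#' @param alpha current abundances.
#' @param alpha_star steady-state abundances (niche values at the current
#'   environment).
#' @param tau_biotic positive biotic timescale.
#' @return numeric vector `d alpha/dt`.
#' @export
biotic_derivative <- function(alpha, alpha_star, tau_biotic) {
  if (tau_biotic <= 0) stop("'tau_biotic' must be positive")
  if (length(alpha) != length(alpha_star))
    stop("alpha and alpha_star must have the same length")
  (alpha_star - alpha) / tau_biotic
}

#' Apply an instantaneous shock to the environment
#'
#' @param E environmental state vector.
#' @param shock displacement vector of the same length.
#' @return the displaced state `E + shock`.
#' @export
apply_shock <- function(E, shock) {
  if (length(shock) != length(E)) stop("shock must have length n_env")
  E + shock
}

# Turn a force source (population, sampled field, or plain function) into
# a function E -> force vector.
.as_force_fun <- function(force) {
  if (inherits(force, "biotic_population"))
    return(function(E) total_biotic_force(force, E))
  if (inherits(force, "gp_force_field")) {
    # dynamics treat a sampled field as constant beyond its grid hull
    # (silent clamped extension); escapes are detected by the callers
    lo <- force$grid[[1L]][1L]
    hi <- force$grid[[1L]][length(force$grid[[1L]])]
    return(function(E) field_at(force, pmin(pmax(E, lo), hi)))
  }
  if (is.function(force)) return(force)
  stop("'force' must be a biotic_population, gp_force_field or function")
}

.force_n_env <- function(force, default = NULL) {
  if (inherits(force, "biotic_population")) return(force$n_env)
  if (inherits(force, "gp_force_field")) return(force$n_env)
  default
}

#' Integrate the coupled biota-environment dynamics
#'
#' Runs the model forward in time under a perturbation protocol. In the
#' default quasi-steady regime the abundances are pinned to their
#' environment-determined steady state at every step and only the
#' environmental variables are integrated; with
#' `config$quasi_steady_biota = FALSE` (and `force` a population) the full
#' `K + n_env` dimensional system is integrated with explicit abundance
#' relaxation. The integrator is fixed-step classical Runge-Kutta
#' (`method = "rk4"`, default) or forward Euler, with step `config$dt`.
#' A `shock` protocol displaces the state instantaneously at its shock
#' time and integration resumes.
#'
#' @param force a `biotic_population`, a [sample_force_field()] field, or a
#'   function `E -> force vector` (quasi-steady only for non-populations).
#' @param E0 initial environmental state (length `n_env`).
#' @param protocol a [perturbation()]; default no forcing.
#' @param config a [rein_config()] supplying `tau_env`, `dt` and the
#'   operating regime.
#' @param t_end end time (`> 0`).
#' @param stride keep every `stride`-th integration step in the returned
#'   trajectory.
#' @param method `"rk4"` or `"euler"`.
#' @param record_abundances also store the abundance matrix (populations
#'   only).
#' @return an object of class `rein_trajectory` with elements `times`,
#'   `env`, `perturbation`, `force` (matrices `time x n_env`) and
#'   optionally `abundances`.
#' @export
#' @examples
#' cfg <- rein_config(K = 20, seed = 1, dt = 0.05)
#' pop <- sample_population(cfg)
#' tr <- rein_simulate(pop, E0 = 50, config = cfg, t_end = 5)
#' tr
rein_simulate <- function(force, E0, protocol = NULL, config = rein_config(),
                          t_end = 100, stride = 1L,
                          method = c("rk4", "euler"),
                          record_abundances = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(config, "rein_config"), t_end > 0)
  n_env <- length(E0)
  ne <- .force_n_env(force)
  if (!is.null(ne) && ne != n_env)
    stop("E0 must have length n_env = ", ne)
  if (is.null(protocol)) protocol <- perturbation("constant", n_env = n_env)
  if (protocol$n_env != n_env) stop("protocol n_env does not match E0")
  dt <- config$dt
  tau <- config$tau_env
  full <- !config$quasi_steady_biota
  if (full && !inherits(force, "biotic_population"))
    stop("full (non-quasi-steady) integration requires a biotic_population")
  ffun <- .as_force_fun(force)

  deriv_qs <- function(t, y, parms) {
    list((perturbation_at(protocol, t)[1L, ] + ffun(y)) / tau)
  }
  deriv_full <- function(t, y, parms) {
    E <- y[seq_len(n_env)]
    alpha <- y[-seq_len(n_env)]
    dE <- (perturbation_at(protocol, t)[1L, ] +
             drop(crossprod(force$effect, alpha))) / tau
    dalpha <- biotic_derivative(alpha, abundances(force, E),
                                config$tau_biotic)
    list(c(dE, dalpha))
  }
  deriv <- if (full) deriv_full else deriv_qs
  y0 <- if (full) c(E0, abundances(force, E0)) else E0

  run_segment <- function(y, t0, t1) {
    times <- seq(t0, t1, by = dt)
    if (tail(times, 1L) < t1) times <- c(times, t1)
    deSolve::ode(y = y, times = times, func = deriv, parms = NULL,
                 method = method)
  }

  tsh <- protocol$shock_time
  if (identical(protocol$kind, "shock") && !is.null(tsh) &&
      tsh > 0 && tsh < t_end) {
    seg1 <- run_segment(y0, 0, tsh)
    y_mid <- as.numeric(seg1[nrow(seg1), -1L])
    y_mid[seq_len(n_env)] <- apply_shock(y_mid[seq_len(n_env)],
                                         protocol$shock)
    seg2 <- run_segment(y_mid, tsh, t_end)
    out <- rbind(seg1, seg2[-1L, , drop = FALSE])
  } else {
    out <- run_segment(y0, 0, t_end)
  }

  if (any(!is.finite(out))) {
    bad <- which(apply(!is.finite(out), 1L, any))[1L]
    stop(sprintf("non-finite state encountered at time %.6g", out[bad, 1L]))
  }

  keep <- unique(c(seq(1L, nrow(out), by = max(1L, as.integer(stride))),
                   nrow(out)))
  times <- out[keep, 1L]
  env <- out[keep, 1L + seq_len(n_env), drop = FALSE]
  P <- perturbation_at(protocol, times)
  if (full) {
    alpha <- out[keep, -(seq_len(n_env + 1L)), drop = FALSE]
    F <- alpha %*% force$effect
    ab <- if (record_abundances) alpha else NULL
  } else {
    F <- t(vapply(seq_along(times), function(i) ffun(env[i, ]),
                  numeric(n_env)))
    if (n_env == 1L) F <- matrix(F, ncol = 1L)
    ab <- if (record_abundances && inherits(force, "biotic_population"))
      t(vapply(seq_along(times), function(i) abundances(force, env[i, ]),
               numeric(force$K))) else NULL
  }
  colnames(env) <- paste0("E_", seq_len(n_env))
  structure(list(times = times, env = env, perturbation = P, force = F,
                 abundances = ab, config = config, protocol = protocol,
                 method = method),
            class = "rein_trajectory")
}

#' @export
print.rein_trajectory <- function(x, ...) {
  n <- ncol(x$env)
  cat("<rein_trajectory>", length(x$times), "samples, t in [",
      format(x$times[1L]), ",", format(tail(x$times, 1L)), "],",
      n, if (n == 1L) "environmental variable\n" else
        "environmental variables\n")
  cat("  final E:", paste(format(x$env[nrow(x$env), ], digits = 5),
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.rein_trajectory <- function(x, ...) {
  n <- ncol(x$env)
  d <- data.frame(t = x$times, x$env, x$perturbation, x$force)
  names(d) <- c("t", paste0("E_", seq_len(n)), paste0("P_", seq_len(n)),
                paste0("F_", seq_len(n)))
  if (!is.null(x$abundances)) {
    a <- as.data.frame(x$abundances)
    names(a) <- paste0("a_", seq_len(ncol(a)))
    d <- cbind(d, a)
  }
  d
}

#' @export
plot.rein_trajectory <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  matplot(x$times, x$env, type = "l", lty = 1, xlab = "time", ylab = "E",
          ...)
  matplot(x$times, cbind(x$perturbation, x$force), type = "l",
          lty = rep(c(2, 1), each = ncol(x$env)), xlab = "time",
          ylab = "P (dashed), F (solid)", ...)
  invisible(x)
}

#' Time after which a trajectory has settled
#'
#' A trajectory counts as settled once `||dE/dt||` stays below
#' `tol * R / tau_env` for a full window of duration `window` (defaults:
#' `tol = 1e-6`, window `10 * tau_env`).
#'
#' @param traj a `rein_trajectory`.
#' @param tol relative derivative tolerance.
#' @param window window duration.
#' @return the first time the criterion holds, or `NA` if it never does.
#' @export
settling_time <- function(traj, tol = 1e-6, window = NULL) {
  cfg <- traj$config
  if (is.null(window)) window <- 10 * cfg$tau_env
  thr <- tol * cfg$essential_range / cfg$tau_env
  dt <- diff(traj$times)
  speed <- sqrt(rowSums((diff(traj$env) / dt)^2))
  ok <- speed < thr
  if (!any(ok)) return(NA_real_)
  w <- max(2L, ceiling(window / stats::median(dt)))
  if (length(ok) < w) return(NA_real_)
  run <- zoo::rollapply(ok, w, all, align = "left")
  i <- which(run)[1L]
  if (is.na(i)) NA_real_ else traj$times[i]
}

#' Write a trajectory as delimited text plus a JSON metadata sidecar
#'
#' The text file has header `t, E_1..E_N, P_1..P_N, F_1..F_N` (plus
#' abundance columns when recorded) under commented metadata lines; the
#' sidecar (`<path>.json`) carries the full configuration and protocol.
#'
#' @param traj a `rein_trajectory`.
#' @param path output text file; the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  d <- as.data.frame(traj)
  hdr <- sprintf("# reinworld trajectory: %d samples, n_env=%d, method=%s",
                 nrow(d), ncol(traj$env), traj$method)
  con <- file(path, "w")
  writeLines(hdr, con)
  write.csv(d, con, row.names = FALSE)
  close(con)
  meta <- list(config = unclass(traj$config),
               protocol = unclass(traj$protocol),
               n_samples = nrow(d))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
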