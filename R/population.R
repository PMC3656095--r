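#' Model configuration
#'
#' Collects every tunable parameter of the biota-environment model. The
#' defaults are the standard setup used throughout the package's analyses:
#' an essential range of 100, a niche width of 5, effects drawn uniformly
#' from `[-1, 1]`, and biotic components that relax so much faster than the
#' environment that they are treated as quasi-steady.
#'
#' @param K number of biotic components (positive integer).
#' @param n_env number of environmental variables.
#' @param essential_range width `R` of the interval of environmental values
#'   compatible with life; niche optima are initialised inside `[0, R]` on
#'   every axis (environmental variables themselves are never clipped).
#' @param niche_width characteristic niche width `sigma`; must be smaller
#'   than `essential_range`.
#' @param effect_bound half-width of the symmetric uniform distribution the
#'   per-variable effects are drawn from. The model is scale-invariant in
#'   this bound (it rescales the biotic force and the perturbation jointly).
#' @param tau_env timescale of the environmental variables.
#' @param tau_biotic timescale of the biotic components; only used when
#'   `quasi_steady_biota = FALSE`, and then defaults to `tau_env / 100` so
#'   the biota remain the fastest-responding elements.
#' @param quasi_steady_biota if `TRUE` (default) abundances are pinned to
#'   their environment-determined steady state and only the environment is
#'   integrated.
#' @param dt integrator step; defaults to `0.01 * tau_env`.
#' @param seed integer seed for every stochastic stage of a run.
#' @param niche_family,shape_params niche family shared by all components
#'   and optional family-specific parameters passed to [niche_shape()].
#' @return an object of class `rein_config` (a validated named list).
#' @export
#' @examples
#' cfg <- rein_config(K = 100, seed = 1)
#' cfg$essential_range
rein_config <- function(K = 100L, n_env = 1L, essential_range = 100,
                        niche_width = 5, effect_bound = 1,
                        tau_env = 1, tau_biotic = NULL,
                        quasi_steady_biota = TRUE, dt = NULL, seed = NULL,
                        niche_family = "gaussian", shape_params = list()) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  K <- as.integer(K); n_env <- as.integer(n_env)
  if (is.na(K) || K < 0L) stop("'K' must be a non-negative integer")
  if (is.na(n_env) || n_env < 1L) stop("'n_env' must be a positive integer")
  chk_pos(essential_range, "essential_range")
  chk_pos(niche_width, "niche_width")
  chk_pos(effect_bound, "effect_bound")
  chk_pos(tau_env, "tau_env")
  if (essential_range <= niche_width)
    stop("'essential_range' must exceed 'niche_width'")
  if (!quasi_steady_biota && is.null(tau_biotic)) tau_biotic <- tau_env / 100
  if (!is.null(tau_biotic)) chk_pos(tau_biotic, "tau_biotic")
  if (is.null(dt)) dt <- 0.01 * tau_env
  chk_pos(dt, "dt")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(K = K, n_env = n_env, essential_range = essential_range,
                 niche_width = niche_width, effect_bound = effect_bound,
                 tau_env = tau_env, tau_biotic = tau_biotic,
                 quasi_steady_biota = isTRUE(quasi_steady_biota), dt = dt,
                 seed = seed, niche_family = niche_family,
                 shape_params = shape_params),
            class = "rein_config")
}

#' @export
print.rein_config <- function(x, ...) {
  cat("<rein_config> K =", x$K, " n_env =", x$n_env,
      " R =", x$essential_range, " sigma =", x$niche_width, "\n")
  cat("  effect_bound =", x$effect_bound, " tau_env =", x$tau_env,
      if (x$quasi_steady_biota) " (quasi-steady biota)"
      else paste0(" tau_biotic = ", x$tau_biotic), "\n")
  if (!is.null(x$seed)) cat("  seed =", x$seed, "\n")
  invisible(x)
}

.shape_from_config <- function(config) {
  do.call(niche_shape, c(list(family = config$niche_family,
                              width = config$niche_width),
                         config$shape_params))
}

#' Draw a random biotic population
#'
#' Each of the `K` components receives a niche optimum with coordinates
#' uniform on `[0, R]` (the essential range) and an effect vector with
#' entries uniform on `[-effect_bound, +effect_bound]`; traits are fixed for
#' the lifetime of the population. Identical seed and configuration give a
#' bit-identical population.
#'
#' @param config a [rein_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return an object of class `biotic_population` with elements `optimum`
#'   (`K x n_env` matrix), `effect` (`K x n_env` matrix), `shape`
#'   ([niche_shape()]), `K` and `n_env`.
#' @export
#' @examples
#' pop <- sample_population(rein_config(K = 10, seed = 1))
#' pop
sample_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "rein_config"))
  if (config$K < 1L) stop("'K' must be at least 1 to sample a population")
  K <- config$K; n <- config$n_env; R <- config$essential_range
  with_seed(seed, {
    optimum <- matrix(runif(K * n, 0, R), K, n)
    effect <- matrix(runif(K * n, -config$effect_bound, config$effect_bound),
                     K, n)
    new_population(optimum, effect, .shape_from_config(config))
  })
}

#' Assemble a population from explicit traits
#'
#' @param optimum `K x n_env` matrix (or vector for `n_env = 1`) of niche
#'   optima.
#' @param effect matrix of the same shape with per-variable effects.
#' @param shape a [niche_shape()] shared by all components.
#' @return a `biotic_population`.
#' @export
new_population <- function(optimum, effect, shape) {
  optimum <- as.matrix(optimum); effect <- as.matrix(effect)
  if (!identical(dim(optimum), dim(effect)))
    stop("'optimum' and 'effect' must have identical dimensions")
  if (!all(is.finite(optimum)) || !all(is.finite(effect)))
    stop("population traits must be finite")
  stopifnot(inherits(shape, "niche_shape"))
  structure(list(optimum = optimum, effect = effect, shape = shape,
                 K = nrow(optimum), n_env = ncol(optimum)),
            class = "biotic_population")
}

#' @export
print.biotic_population <- function(x, ...) {
  cat("<biotic_population> K =", x$K, " n_env =", x$n_env,
      " niche:", x$shape$family, "width", format(x$shape$width), "\n")
  invisible(x)
}

#' @export
c.biotic_population <- function(...) {
  pops <- list(...)
  stopifnot(all(vapply(pops, inherits, TRUE, "biotic_population")))
  n_env <- unique(vapply(pops, function(p) p$n_env, 1L))
  if (length(n_env) != 1L) stop("populations must share n_env")
  new_population(do.call(rbind, lapply(pops, `[[`, "optimum")),
                 do.call(rbind, lapply(pops, `[[`, "effect")),
                 pops[[1L]]$shape)
}

#' @export
`[.biotic_population` <- function(x, i) {
  new_population(x$optimum[i, , drop = FALSE], x$effect[i, , drop = FALSE],
                 x$shape)
}

#' @export
as.data.frame.biotic_population <- function(x, ...) {
  d <- data.frame(x$optimum, x$effect)
  names(d) <- c(paste0("opt_", seq_len(x$n_env)),
                paste0("eff_", seq_len(x$n_env)))
  d$width <- x$shape$width
  d$family <- x$shape$family
  d
}

#' Steady-state abundances of every component
#'
#' Evaluates each component's niche function at the environment `E`; the
#' result is the vector of quasi-steady abundances, each in `[0, 1]`.
#'
#' @param pop a `biotic_population`.
#' @param E numeric vector of length `n_env`.
#' @return numeric vector of length `K`.
#' @export
abundances <- function(pop, E) {
  stopifnot(inherits(pop, "biotic_population"))
  if (length(E) != pop$n_env)
    stop("E must have length n_env = ", pop$n_env)
  if (pop$K == 0L) return(numeric(0))
  a <- .niche_response(pop$shape, pop$optimum[, 1L] - E[1L])
  if (pop$n_env > 1L)
    for (j in 2L:pop$n_env)
      a <- a * .niche_response(pop$shape, pop$optimum[, j] - E[j])
  a
}

#' Total biotic force on the environment
#'
#' The force on environmental variable `i` is the sum over components of
#' `effect[j, i] * abundance[j]` at the current environment: the collective
#' push the biota exert. It is linear in the population (the force of a
#' union of populations is the sum of their forces) and its sign structure
#' is what creates rein-control stable points.
#'
#' @inheritParams abundances
#' @return numeric vector of length `n_env`; zeros for an empty population.
#' @export
total_biotic_force <- function(pop, E) {
  stopifnot(inherits(pop, "biotic_population"))
  if (length(E) != pop$n_env)
    stop("E must have length n_env = ", pop$n_env)
  if (pop$K == 0L) return(numeric(length(E)))
  drop(crossprod(pop$effect, abundances(pop, E)))
}

# Force evaluated at many points: `points` is an n x n_env matrix.
# Returns an n x n_env matrix. Used by grid scans and crossing censuses.
.force_on_grid <- function(pop, points) {
  points <- as.matrix(points)
  if (pop$n_env == 1L)
    return(matrix(.force_on_grid_1d(pop, points[, 1L]), ncol = 1L))
  out <- matrix(0, nrow(points), pop$n_env)
  for (r in seq_len(nrow(points)))
    out[r, ] <- total_biotic_force(pop, points[r, ])
  out
}

# Fast 1-D special case: outer() over components x grid.
.force_on_grid_1d <- function(pop, x) {
  if (pop$K == 0L) return(numeric(length(x)))
  resp <- .niche_response(pop$shape, outer(pop$optimum[, 1L], x, "-"))
  drop(crossprod(resp, pop$effect[, 1L]))
}

#' Write / read a population as delimited text or JSON
#'
#' The text format has one row per component (optimum coordinates, effect
#' coordinates, width, family) with full float precision, plus commented
#' header metadata carrying the shape parameters; the JSON document carries
#' the same content structured. Both round-trip losslessly.
#'
#' @param pop a `biotic_population`.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly ([write_population()]); a `biotic_population`
#'   ([read_population()]).
#' @export
write_population <- function(pop, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(pop, "biotic_population"))
  sp <- pop$shape$shape_params
  if (format == "json") {
    jsonlite::write_json(
      list(K = pop$K, n_env = pop$n_env,
           family = pop$shape$family, width = pop$shape$width,
           shape_params = sp,
           optimum = pop$optimum, effect = pop$effect),
      path, digits = I(17), auto_unbox = TRUE)
    return(invisible(path))
  }
  n <- pop$n_env
  hdr <- c(sprintf("# reinworld population K=%d n_env=%d", pop$K, n),
           sprintf("# shape_params: %s", jsonlite::toJSON(sp, auto_unbox = TRUE,
                                                          digits = NA)))
  cols <- c(paste0("opt_", seq_len(n)), paste0("eff_", seq_len(n)),
            "width", "family")
  num <- cbind(pop$optimum, pop$effect, rep(pop$shape$width, pop$K))
  body <- paste(apply(num, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ",")),
    pop$shape$family, sep = ",")
  writeLines(c(hdr, paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    shape <- do.call(niche_shape, c(list(family = d$family, width = d$width),
                                    as.list(d$shape_params)))
    return(new_population(matrix(d$optimum, d$K, d$n_env),
                          matrix(d$effect, d$K, d$n_env), shape))
  }
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  sp <- list()
  spl <- grep("^# shape_params:", meta, value = TRUE)
  if (length(spl))
    sp <- as.list(jsonlite::fromJSON(sub("^# shape_params: ", "", spl[1L])))
  d <- read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  n <- sum(grepl("^opt_", names(d)))
  shape <- do.call(niche_shape, c(list(family = d$family[1L],
                                       width = d$width[1L]), sp))
  new_population(unname(as.matrix(d[paste0("opt_", seq_len(n))])),
                 unname(as.matrix(d[paste0("eff_", seq_len(n))])), shape)
}
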