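.config_keys <- c("K", "n_env", "essential_range", "niche_width",
                  "effect_bound", "tau_env", "tau_biotic",
                  "quasi_steady_biota", "dt", "seed", "niche_family",
                  "shape_params")
.protocol_keys <- c("kind", "base", "rate", "shock_time", "shock", "times",
                    "values", "n_env")

#' Load a run configuration from YAML
#'
#' Reads a flat `key: value` configuration file with optional nested
#' `protocol:` and `analysis:` sections, fills every unset model parameter
#' with the standard defaults (essential range 100, niche width 5, ...),
#' validates the result, and errors on any unknown key rather than
#' silently ignoring it.
#'
#' @param path YAML file.
#' @return a list with elements `config` (a [rein_config()]), `protocol`
#'   (a [perturbation()] or `NULL`) and `analysis` (a plain list of
#'   analysis options).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(.config_keys, "protocol", "analysis")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  proto <- NULL
  if (!is.null(raw$protocol)) {
    upk <- setdiff(names(raw$protocol), .protocol_keys)
    if (length(upk))
      stop("unknown protocol key(s): ", paste(upk, collapse = ", "))
    p <- raw$protocol
    if (is.null(p$n_env) && !is.null(raw$n_env)) p$n_env <- raw$n_env
    proto <- do.call(perturbation, p)
  }
  analysis <- if (is.null(raw$analysis)) list() else raw$analysis
  cfg <- do.call(rein_config, raw[intersect(names(raw), .config_keys)])
  list(config = cfg, protocol = proto, analysis = analysis)
}

#' Write a configuration (with optional protocol) back to YAML
#'
#' `write_config(load_config(f)$...)` followed by another [load_config()]
#' reproduces the same normalised configuration: the round trip is the
#' identity on the validated representation.
#'
#' @param config a [rein_config()].
#' @param path output YAML file.
#' @param protocol optional [perturbation()].
#' @param analysis optional list of analysis options.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, protocol = NULL, analysis = NULL) {
  stopifnot(inherits(config, "rein_config"))
  out <- Filter(Negate(is.null), unclass(config))
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "perturbation"))
    out$protocol <- Filter(Negate(is.null), unclass(protocol))
  }
  if (!is.null(analysis) && length(analysis)) out$analysis <- analysis
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Canned scenarios for the standard experiments
#'
#' Builds ready-to-run scenario objects for the package's reference
#' experiments, deterministic in `seed`:
#' \describe{
#'   \item{`fig2_ramp`}{one environmental variable, `K = 100`, `R = 100`,
#'     `sigma = 5`, environment initialised at 10 and forced by a slow
#'     linear ramp - the rein-control staircase experiment.}
#'   \item{`fig3_shock`}{four environmental variables (all initialised at
#'     50) with a large population; a shock of magnitude `5 sigma` in a
#'     random direction hits at `t = 50`.}
#'   \item{`fig5_sweep`}{parameters of the stable-point saturation sweep
#'     over the number of components, for niche widths 5 and 10.}
#'   \item{`fig6_shapes`}{matched-width niche families for the
#'     shape-invariance comparison.}
#'   \item{`fig7_portrait`}{a sampled two-variable large-K force field for
#'     phase-portrait / basin analysis.}
#'   \item{`fig9_hysteresis`}{a one-variable large-K field with at least
#'     three stable points and a forcing window spanning its folds.}
#' }
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @param dir if given, scenario files (config + population/field) are
#'   written there and listed in the result.
#' @return an object of class `rein_fixture`: a list with the scenario's
#'   `config`, and (depending on the scenario) `population`, `field`,
#'   `protocol`, `E0`, `t_end` and sweep parameters.
#' @export
#' @examples
#' fx <- make_fixture("fig2_ramp", seed = 1)
#' fx$config$K
make_fixture <- function(name, seed = 1L, dir = NULL) {
  valid <- c("fig2_ramp", "fig3_shock", "fig5_sweep", "fig6_shapes",
             "fig7_portrait", "fig9_hysteresis")
  if (!name %in% valid)
    stop("unknown fixture '", name, "'; valid fixtures: ",
         paste(valid, collapse = ", "))
  seed <- as.integer(seed)
  fx <- switch(name,
    fig2_ramp = {
      cfg <- rein_config(K = 100L, n_env = 1L, essential_range = 100,
                         niche_width = 5, seed = fork_seed(seed, name),
                         dt = 0.1)
      list(config = cfg,
           population = sample_population(cfg),
           protocol = perturbation("linear_ramp", base = 0, rate = 5e-4),
           E0 = 10, t_end = 10000, stride = 5L)
    },
    fig3_shock = {
      cfg <- rein_config(K = 20000L, n_env = 4L, essential_range = 100,
                         niche_width = 5, seed = fork_seed(seed, name),
                         dt = 0.05)
      shock <- with_seed(fork_seed(seed, "fig3:shock"), {
        v <- rnorm(4)
        5 * cfg$niche_width * v / sqrt(sum(v^2))
      })
      list(config = cfg,
           population = sample_population(cfg),
           protocol = perturbation("shock", shock_time = 50, shock = shock,
                                   n_env = 4L),
           E0 = rep(50, 4), t_end = 100, stride = 5L)
    },
    fig5_sweep = {
      list(config = rein_config(seed = fork_seed(seed, name)),
           K_values = c(1L, 2L, 5L, 10L, 20L, 50L, 100L, 200L, 500L,
                        1000L),
           n_pops = 100L, widths = c(5, 10))
    },
    fig6_shapes = {
      list(config = rein_config(seed = fork_seed(seed, name)),
           shapes = list(gaussian = niche_shape("gaussian", 5),
                         skewed = niche_shape("skewed", 5),
                         bimodal = niche_shape("bimodal", 5),
                         fat_tailed = niche_shape("fat_tailed", 5)),
           n_fields = 300L)
    },
    fig7_portrait = {
      cfg <- rein_config(n_env = 2L, seed = fork_seed(seed, name))
      kr <- force_kernel(.shape_from_config(cfg))
      list(config = cfg,
           field = sample_force_field(kr, n_env = 2L, range = 100,
                                      seed = cfg$seed))
    },
    fig9_hysteresis = {
      cfg <- rein_config(n_env = 1L, seed = fork_seed(seed, name))
      kr <- force_kernel(.shape_from_config(cfg))
      fld <- NULL
      for (i in seq_len(200L)) {
        cand <- sample_force_field(kr, n_env = 1L, range = 100,
                                   seed = fork_seed(cfg$seed,
                                                    paste0("try:", i)))
        cen <- find_stable_points_1d(cand, c(0, 100))
        if (sum(cen$classification == "stable") >= 3L) { fld <- cand; break }
      }
      if (is.null(fld))
        stop("could not realise a field with >= 3 stable points")
      fr <- range(fld$samples)
      list(config = cfg, field = fld,
           p_range = -rev(fr) + c(-0.25, 0.25) * diff(fr),
           n_steps = 121L)
    })
  fx$name <- name
  fx$seed <- seed
  if (!is.null(dir)) {
    if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
    files <- character(0)
    cfgf <- file.path(dir, paste0(name, "_config.yaml"))
    write_config(fx$config, cfgf, protocol = fx$protocol)
    files <- cfgf
    if (!is.null(fx$population)) {
      f <- file.path(dir, paste0(name, "_population.csv"))
      write_population(fx$population, f)
      files <- c(files, f)
    }
    if (!is.null(fx$field)) {
      f <- file.path(dir, paste0(name, "_field.csv"))
      write_field(fx$field, f)
      files <- c(files, f, paste0(f, ".json"))
    }
    fx$files <- files
  }
  structure(fx, class = "rein_fixture")
}

#' @export
print.rein_fixture <- function(x, ...) {
  cat("<rein_fixture>", x$name, " seed:", x$seed, "\n")
  invisible(x)
}

#' Check that an output directory exists before any compute
#'
#' @param dir directory path.
#' @return `dir`, invisibly; errors when missing.
#' @export
ensure_outdir <- function(dir) {
  if (!dir.exists(dir))
    stop("output directory does not exist: ", dir, call. = FALSE)
  invisible(dir)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the resolved
#' configuration, the seed, the package version, wall-clock stamps and the
#' list of produced files with their MD5 checksums. Re-running the same
#' configuration and seed reproduces deterministic outputs checksum for
#' checksum.
#'
#' @param outputs character vector of files produced by the run.
#' @param path manifest file to write (JSON).
#' @param config optional [rein_config()].
#' @param seed optional run seed.
#' @param started optional POSIXct start stamp.
#' @return the manifest list, invisibly.
#' @export
emit_manifest <- function(outputs, path, config = NULL, seed = NULL,
                          started = NULL) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("manifest lists files that were not produced: ",
         paste(missing, collapse = ", "))
  man <- list(
    package = "reinworld",
    version = as.character(packageVersion("reinworld")),
    seed = seed,
    config = if (is.null(config)) NULL else unclass(config),
    started = if (is.null(started)) NULL else format(started,
                                                     "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(man)
}

#' Write an analysis summary as JSON
#'
#' Thin wrapper fixing the conventions used throughout the package:
#' unboxed scalars and full float precision.
#'
#' @param x a list of results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
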