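#' Covariance kernel of the large-K total biotic force
#'
#' As the number of biotic components grows, the total biotic force at any
#' environment becomes a sum of many independent bounded bumps with
#' symmetric random signs; by the central limit theorem it converges to a
#' zero-mean stationary Gaussian random field. Its covariance is the
#' autocorrelation of the niche response: for a Gaussian niche of width
#' `sigma` the kernel is exactly a Gaussian of width `sigma * sqrt(2)`
#' per axis (the convolution of two width-`sigma` Gaussians); for the other
#' families it is computed by numerical autocorrelation of the 1-D response
#' and applied separably across axes.
#'
#' @param shape a [niche_shape()].
#' @param config optional [rein_config()] (only consulted for defaults).
#' @param variance_scale marginal variance `k(0)` of the field. The census
#'   analyses use only the sign structure of the field, so the default 1 is
#'   a pure normalisation; the finite-K scale matters only when a field is
#'   mixed with explicit perturbations.
#' @return an object of class `force_kernel` with the per-axis correlation
#'   function, the length scale `sqrt(-k(0)/k''(0))` and the implied 1-D
#'   down-crossing rate per unit length.
#' @export
#' @examples
#' kr <- force_kernel(niche_shape("gaussian", 5))
#' kernel_cov(kr, 5 * sqrt(2)) / kernel_cov(kr, 0)  # exp(-1/2)
force_kernel <- function(shape, config = NULL, variance_scale = 1) {
  stopifnot(inherits(shape, "niche_shape"))
  if (variance_scale <= 0) stop("'variance_scale' must be positive")
  if (shape$family == "gaussian") {
    s2 <- shape$width^2
    corr <- function(d) exp(-d^2 / (4 * s2))
    curv <- 1 / (2 * s2) # -k''(0)/k(0)
  } else {
    # numerical autocorrelation of the response on a fine grid
    lim <- 30 * shape$width
    m <- 16384L
    x <- seq(-lim, lim, length.out = m)
    dx <- x[2L] - x[1L]
    n <- .niche_response(shape, x)
    ac <- stats::convolve(n, n, type = "open") * dx
    lag <- (seq_along(ac) - m) * dx
    keep <- abs(lag) <= 20 * shape$width
    af <- stats::approxfun(lag[keep], ac[keep] / max(ac), yleft = 0,
                           yright = 0)
    corr <- function(d) af(d)
    dn <- diff(n) / dx
    curv <- sum(dn^2) / sum(((n[-1L] + n[-m]) / 2)^2) # -k''(0)/k(0)
  }
  structure(list(family = shape$family, width = shape$width, shape = shape,
                 variance_scale = variance_scale, corr = corr,
                 length_scale = 1 / sqrt(curv), curvature = curv,
                 crossing_rate = sqrt(curv) / (2 * pi)),
            class = "force_kernel")
}

#' Evaluate a force kernel
#'
#' Covariance between two points of the field separated by displacement
#' `delta` (a vector with one entry per environmental axis, or a scalar for
#' 1-D). The kernel is even and separable across axes.
#'
#' @param kernel a [force_kernel()].
#' @param delta displacement; rows of a matrix are evaluated independently.
#' @return covariance value(s).
#' @export
kernel_cov <- function(kernel, delta) {
  stopifnot(inherits(kernel, "force_kernel"))
  if (is.matrix(delta))
    return(kernel$variance_scale *
             apply(delta, 1L, function(d) prod(kernel$corr(d))))
  kernel$variance_scale * prod(kernel$corr(delta))
}

#' @export
print.force_kernel <- function(x, ...) {
  cat("<force_kernel>", x$family, " width:", format(x$width),
      " length scale:", format(x$length_scale, digits = 4),
      " k(0):", format(x$variance_scale), "\n")
  invisible(x)
}

# Cholesky factor of the 1-D grid covariance with diagonal jitter.
.chol_jitter <- function(K, jitter) {
  k0 <- K[1L, 1L]
  L <- tryCatch(chol(K + jitter * k0 * diag(nrow(K))), error = function(e) e)
  if (inherits(L, "error")) {
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(paste0("covariance not positive definite after jitter ",
                        "%.1e (smallest eigenvalue %.3e)"), jitter, ev))
  }
  L
}

# Multiply array A by matrix M along dimension d: result has same dims.
.tensor_mult <- function(A, M, d) {
  dm <- dim(A)
  perm <- c(d, setdiff(seq_along(dm), d))
  A <- aperm(A, perm)
  A <- matrix(A, nrow = dm[d])
  A <- M %*% A
  A <- array(A, dm[perm])
  aperm(A, order(perm))
}

#' Sample a realisation of the large-K force field
#'
#' Draws each environmental axis's force as an independent realisation of
#' the stationary Gaussian field defined by `kernel`, on a rectilinear grid
#' over `[0, R]^n_env` with spacing `h`, by Cholesky factorisation of the
#' grid covariance (with a small diagonal jitter for conditioning). For the
#' separable kernels used here the tensor-grid factor is the Kronecker
#' product of the per-axis factors, which keeps 2-D and 3-D grids cheap;
#' the direct dense factorisation is available for cross-checking.
#'
#' @param kernel a [force_kernel()].
#' @param n_env number of environmental variables (= independent field
#'   components).
#' @param range essential range `R` (grid covers `[0, R]` per axis).
#' @param h grid spacing; default `width / 4`, the resolution at which
#'   crossing censuses are grid-artefact free. A warning is issued beyond
#'   half the kernel length scale.
#' @param seed integer seed; the same seed reproduces the field exactly.
#' @param method `"separable"` (default, exact for product kernels) or
#'   `"direct"` dense factorisation of the full tensor covariance.
#' @param jitter relative diagonal jitter added before factorisation.
#' @return an object of class `gp_force_field`: grid axes, an array of
#'   samples with one slice per field component, the kernel and the seed.
#' @export
#' @examples
#' kr <- force_kernel(niche_shape("gaussian", 5))
#' fld <- sample_force_field(kr, n_env = 1, range = 100, seed = 1)
#' field_at(fld, 50)
sample_force_field <- function(kernel, n_env = 1L, range = 100,
                               h = kernel$width / 4, seed = NULL,
                               method = c("separable", "direct"),
                               jitter = 1e-10) {
  stopifnot(inherits(kernel, "force_kernel"))
  method <- match.arg(method)
  n_env <- as.integer(n_env)
  R <- range[length(range)]
  if (h > kernel$length_scale / 2)
    warning("grid spacing exceeds half the kernel length scale; ",
            "crossing counts may be resolution limited")
  ncell <- max(1L, ceiling(R / h))
  h <- R / ncell                      # keep the grid exactly uniform
  x <- seq(0, R, length.out = ncell + 1L)
  m <- length(x)
  grid <- rep(list(x), n_env)
  K1 <- kernel$variance_scale * outer(x, x, function(a, b) kernel$corr(a - b))
  samples <- with_seed(seed, {
    if (method == "direct" || n_env == 1L) {
      pts <- as.matrix(expand.grid(grid))
      n_tot <- nrow(pts)
      if (n_env == 1L) {
        L <- .chol_jitter(K1, jitter)
        arr <- vapply(seq_len(n_env),
                      function(i) drop(crossprod(L, rnorm(m))), numeric(m))
        array(arr, c(m, n_env))
      } else {
        Kf <- matrix(1, n_tot, n_tot)
        for (d in seq_len(n_env))
          Kf <- Kf * outer(pts[, d], pts[, d],
                           function(a, b) kernel$corr(a - b))
        Kf <- kernel$variance_scale * Kf
        L <- .chol_jitter(Kf, jitter)
        arr <- vapply(seq_len(n_env),
                      function(i) drop(crossprod(L, rnorm(n_tot))),
                      numeric(n_tot))
        array(arr, c(rep(m, n_env), n_env))
      }
    } else {
      # separable: field = (L' x L' x ...) z, scaled to variance k(0)
      K1c <- K1 / kernel$variance_scale
      L <- .chol_jitter(K1c, jitter)
      arr <- array(0, c(rep(m, n_env), n_env))
      idx <- as.matrix(expand.grid(rep(list(seq_len(m)), n_env)))
      for (comp in seq_len(n_env)) {
        Z <- array(rnorm(m^n_env), rep(m, n_env))
        for (d in seq_len(n_env)) Z <- .tensor_mult(Z, t(L), d)
        arr[cbind(idx, comp)] <- sqrt(kernel$variance_scale) * Z[idx]
      }
      arr
    }
  })
  structure(list(grid = grid, h = x[2L] - x[1L], n_env = n_env,
                 range = R, samples = samples, kernel = kernel,
                 seed = seed, method = method),
            class = "gp_force_field")
}

#' @export
print.gp_force_field <- function(x, ...) {
  cat("<gp_force_field>", x$n_env, "axis field on [0,", x$range,
      "] grid h =", format(x$h, digits = 4), "(",
      paste(rep(length(x$grid[[1L]]), x$n_env), collapse = " x "),
      "nodes )\n")
  cat("  kernel:", x$kernel$family, "width", format(x$kernel$width),
      if (!is.null(x$seed)) paste(" seed", x$seed), "\n")
  invisible(x)
}

# Multilinear interpolation of all field components at points E
# (matrix n x n_env). Exact at grid nodes.
.field_interp <- function(field, E, strict = FALSE) {
  E <- if (is.matrix(E)) E else matrix(E, ncol = field$n_env)
  n_env <- field$n_env
  x0 <- field$grid[[1L]][1L]
  h <- field$h
  m <- length(field$grid[[1L]])
  if (any(E < x0 - 1e-9) || any(E > field$grid[[1L]][m] + 1e-9)) {
    if (strict) stop("point outside the field grid hull")
    warning("point outside the field grid hull; clamping to the boundary")
    E <- pmin(pmax(E, x0), field$grid[[1L]][m])
  }
  u <- (E - x0) / h
  i0 <- pmin(pmax(floor(u), 0), m - 2L)        # lower node index (0-based)
  tt <- u - i0                                  # in [0, 1]
  np <- nrow(E)
  out <- matrix(0, np, n_env)
  corners <- as.matrix(expand.grid(rep(list(0:1), n_env)))
  strides <- cumprod(c(1L, rep(m, n_env - 1L)))
  comp_off <- m^n_env
  for (r in seq_len(nrow(corners))) {
    cn <- corners[r, ]
    w <- rep(1, np)
    for (d in seq_len(n_env))
      w <- w * (if (cn[d] == 1L) tt[, d] else 1 - tt[, d])
    lin <- rep(1, np)
    for (d in seq_len(n_env))
      lin <- lin + (i0[, d] + cn[d]) * strides[d]
    for (comp in seq_len(n_env))
      out[, comp] <- out[, comp] +
        w * field$samples[lin + (comp - 1L) * comp_off]
    }
  out
}

#' Interpolate a sampled force field
#'
#' Multilinear interpolation of each field component; exact at grid nodes.
#' Points outside the grid hull are clamped to the boundary with a warning
#' (or rejected with `strict = TRUE`).
#'
#' @param field a [sample_force_field()] object.
#' @param E a point (length `n_env`) or a matrix of points (rows).
#' @param strict error instead of clamping outside the hull.
#' @return the force vector at `E`, or a matrix of forces for matrix input.
#' @export
field_at <- function(field, E, strict = FALSE) {
  stopifnot(inherits(field, "gp_force_field"))
  if (is.matrix(E)) return(.field_interp(field, E, strict))
  drop(.field_interp(field, matrix(E, 1L), strict))
}

#' Write / read a sampled force field
#'
#' Delimited text with one row per grid node (coordinates then one column
#' per field component) under commented metadata; a JSON sidecar
#' (`<path>.json`) carries the kernel family, width, variance, spacing and
#' seed so the field can be reconstructed exactly.
#'
#' @param field a `gp_force_field`.
#' @param path output text file.
#' @return `path` invisibly ([write_field()]); a `gp_force_field`
#'   ([read_field()]).
#' @export
write_field <- function(field, path) {
  pts <- as.matrix(expand.grid(field$grid))
  comp_off <- length(field$grid[[1L]])^field$n_env
  vals <- vapply(seq_len(field$n_env),
                 function(comp) field$samples[seq_len(comp_off) +
                                                (comp - 1L) * comp_off],
                 numeric(comp_off))
  d <- cbind(pts, vals)
  colnames(d) <- c(paste0("E_", seq_len(field$n_env)),
                   paste0("F_", seq_len(field$n_env)))
  con <- file(path, "w")
  writeLines(sprintf("# reinworld force field n_env=%d h=%.17g",
                     field$n_env, field$h), con)
  writeLines(paste(colnames(d), collapse = ","), con)
  writeLines(apply(d, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = ",")), con)
  close(con)
  meta <- list(family = field$kernel$family, width = field$kernel$width,
               shape_params = field$kernel$shape$shape_params,
               variance_scale = field$kernel$variance_scale,
               n_env = field$n_env, range = field$range, h = field$h,
               seed = field$seed, method = field$method)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lines <- readLines(path)
  d <- read.csv(text = lines[!grepl("^#", lines)])
  n_env <- meta$n_env
  m <- round(meta$range / meta$h) + 1L
  shape <- do.call(niche_shape, c(list(family = meta$family,
                                       width = meta$width),
                                  as.list(meta$shape_params)))
  kernel <- force_kernel(shape, variance_scale = meta$variance_scale)
  samples <- array(as.matrix(d[paste0("F_", seq_len(n_env))]),
                   c(rep(m, n_env), n_env))
  structure(list(grid = rep(list(seq(0, meta$range, by = meta$h)), n_env),
                 h = meta$h, n_env = n_env, range = meta$range,
                 samples = samples, kernel = kernel,
                 seed = if (is.null(meta$seed)) NULL else meta$seed,
                 method = meta$method),
            class = "gp_force_field")
}
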