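#' Rice-formula oracle for expected down-crossings
#'
#' Expected number of downward zero crossings of a stationary zero-mean
#' Gaussian process over an interval of length `range`:
#' `range * sqrt(-k''(0)/k(0)) / (2 pi)`. Each such crossing of the total
#' biotic force is a homeostatic stable point, so this is the independent
#' oracle for the expected 1-D stable-point count in the large-K limit.
#'
#' @param kernel a [force_kernel()].
#' @param range interval length (the essential range `R`).
#' @return expected number of down-crossings.
#' @export
#' @examples
#' rice_crossings(force_kernel(niche_shape("gaussian", 5)), 100)
rice_crossings <- function(kernel, range) {
  stopifnot(inherits(kernel, "force_kernel"), range > 0)
  range * kernel$crossing_rate
}

# E|det G| for an n x n matrix of iid standard normals:
# prod_k sqrt(2) Gamma((k+1)/2) / Gamma(k/2).
.edet_gaussian <- function(n) {
  k <- seq_len(n)
  prod(sqrt(2) * gamma((k + 1) / 2) / gamma(k / 2))
}

.stable_frac_cache <- new.env(parent = emptyenv())

# |det|-weighted probability that an n x n iid Gaussian Jacobian has all
# eigenvalue real parts negative. Exact for n <= 2; estimated once by a
# fixed-seed Monte-Carlo for larger n and cached.
.stable_fraction <- function(n) {
  if (n == 1L) return(0.5)
  if (n == 2L) return(0.25)
  key <- as.character(n)
  if (!is.null(.stable_frac_cache[[key]])) return(.stable_frac_cache[[key]])
  val <- with_seed(20130516, {
    nrep <- 200000L
    s <- 0; w <- 0
    for (b in seq_len(nrep %/% 1000L)) {
      G <- matrix(rnorm(1000L * n * n), 1000L)
      for (i in seq_len(1000L)) {
        g <- matrix(G[i, ], n)
        d <- abs(det(g))
        w <- w + d
        if (all(Re(eigen(g, only.values = TRUE)$values) < 0)) s <- s + d
      }
    }
    s / w
  })
  .stable_frac_cache[[key]] <- val
  val
}

#' Expected number of stable points in the large-K limit
#'
#' Kac-Rice expectation for the number of stable fixed points of the
#' large-K total biotic force over `[0, R]^n_env` with a Gaussian niche of
#' characteristic width `width`:
#' `(R / (2 width sqrt(pi)))^n_env * E|det G| * q(n_env)`,
#' where `E|det G|` is the mean absolute determinant of an iid Gaussian
#' matrix and `q` the determinant-weighted probability that all its
#' eigenvalues have negative real part (`1/2` in 1-D, `1/4` in 2-D). In
#' 1-D this reduces to the Rice down-crossing count
#' `R / (2 sqrt(2) pi width)`; the count grows exponentially with the
#' number of environmental variables and depends on `R` and `width` only
#' through their ratio.
#'
#' @param n_env number of environmental variables.
#' @param R essential range.
#' @param width niche characteristic width (`0 < width < R`).
#' @return expected stable-point count.
#' @export
#' @examples
#' expected_stable_points(1, 100, 5)   # ~2.25
#' expected_stable_points(2, 100, 5)   # ~7.96
expected_stable_points <- function(n_env, R, width) {
  stopifnot(n_env >= 1, R > width, width > 0)
  n_env <- as.integer(n_env)
  (R / (2 * width * sqrt(pi)))^n_env * .edet_gaussian(n_env) *
    .stable_fraction(n_env)
}

#' Diversity threshold for saturation of the stable-point count
#'
#' The number of biotic components beyond which the expected stable-point
#' count of a finite population is within a few percent of its large-K
#' (Gaussian-field) limit. Saturation requires every neighbourhood of the
#' essential range to be covered by several overlapping niches, giving
#' `K* = 4 * (R / (width * sqrt(2 pi)))^n_env` - about four components per
#' effective niche support per environmental axis. The threshold falls as
#' niches widen and grows with the essential range and exponentially with
#' the number of environmental variables.
#'
#' @inheritParams expected_stable_points
#' @return approximate threshold number of components.
#' @export
#' @examples
#' threshold_K(100, 5)   # ~32
threshold_K <- function(R, width, n_env = 1L) {
  stopifnot(n_env >= 1, R > width, width > 0)
  4 * (R / (width * sqrt(2 * pi)))^as.integer(n_env)
}

#' Probability that two random components form a rein pair
#'
#' Two biotic components bound an environmental variable by rein control
#' when the one with the lower niche optimum pushes the variable up
#' (positive effect) and the one with the higher optimum pushes it down.
#' With independent uniform optima and independent symmetric effect signs
#' the probability is exactly `1/4`.
#'
#' @param mode `"analytic"` (closed form) or `"monte_carlo"`.
#' @param n_trials number of Monte-Carlo trials.
#' @param seed optional seed for the Monte-Carlo mode.
#' @param prob_positive probability that a component's effect is positive;
#'   `0.5` for the symmetric model. Forcing it to 1 (all effects push up)
#'   makes opposing pairs impossible.
#' @return the pair probability (exact, or a Monte-Carlo estimate).
#' @export
#' @examples
#' rein_pair_probability()                                # 0.25
#' rein_pair_probability("monte_carlo", 1e4, seed = 1)
rein_pair_probability <- function(mode = c("analytic", "monte_carlo"),
                                  n_trials = 1e5, seed = NULL,
                                  prob_positive = 0.5) {
  mode <- match.arg(mode)
  stopifnot(prob_positive >= 0, prob_positive <= 1)
  if (mode == "analytic") return(prob_positive * (1 - prob_positive))
  stopifnot(n_trials >= 1)
  with_seed(seed, {
    u1 <- runif(n_trials); u2 <- runif(n_trials)
    s1 <- ifelse(runif(n_trials) < prob_positive, 1, -1)
    s2 <- ifelse(runif(n_trials) < prob_positive, 1, -1)
    pair <- (u1 < u2 & s1 > 0 & s2 < 0) | (u2 < u1 & s2 > 0 & s1 < 0)
    mean(pair)
  })
}

# -- 1-D census ------------------------------------------------------------

#' Census of the 1-D stable and unstable points of a force curve
#'
#' Scans the force over `[range[1], range[2]]` for zero crossings: a
#' crossing from positive to negative (left to right) is a homeostatic
#' stable point, a negative-to-positive crossing is unstable. Each crossing
#' is refined by bisection to `1e-6 * R`. For a sampled field the stored
#' grid values are used directly (the interpolant crosses exactly where
#' its samples change sign).
#'
#' @param force a function `E -> force`, a `biotic_population`, or a 1-D
#'   `gp_force_field`.
#' @param range interval scanned, `c(lo, hi)` or a single upper bound.
#' @param h scan grid spacing (default: field spacing, or `R/400`).
#' @return a `stable_points` data frame with columns `location` and
#'   `classification`; zero rows when the force never crosses zero.
#' @export
#' @examples
#' find_stable_points_1d(function(E) -(E - 50), c(0, 100))
find_stable_points_1d <- function(force, range = c(0, 100), h = NULL) {
  if (length(range) == 1L) range <- c(0, range)
  lo <- range[1L]; hi <- range[2L]
  R <- hi - lo
  if (inherits(force, "gp_force_field")) {
    stopifnot(force$n_env == 1L)
    x <- force$grid[[1L]]
    fx <- as.numeric(force$samples[, 1L])
    f <- function(E) field_at(force, E)
  } else {
    f0 <- .as_force_fun(force)
    f <- function(E) f0(E)[1L]
    if (is.null(h)) h <- R / 400
    x <- seq(lo, hi, by = h)
    if (tail(x, 1L) < hi) x <- c(x, hi)
    fx <- vapply(x, f, numeric(1L))
  }
  s <- sign(fx)
  loc <- numeric(0); cls <- character(0)
  n <- length(x)
  for (i in seq_len(n - 1L)) {
    if (s[i] == 0) { # exact zero at a node
      if (i > 1L && s[i - 1L] != 0 && s[i + 1L] != 0 && s[i - 1L] != s[i + 1L]) {
        loc <- c(loc, x[i])
        cls <- c(cls, if (s[i - 1L] > 0) "stable" else "unstable")
      }
      next
    }
    if (s[i + 1L] != 0 && s[i] != s[i + 1L]) {
      root <- uniroot(f, c(x[i], x[i + 1L]), tol = 1e-6 * R)$root
      loc <- c(loc, root)
      cls <- c(cls, if (s[i] > 0) "stable" else "unstable")
    }
  }
  structure(data.frame(location = loc,
                       classification = factor(cls, levels = c(
                         "stable", "unstable", "saddle", "degenerate"))),
            class = c("stable_points", "data.frame"))
}

# -- N-D census ------------------------------------------------------------

# logical cell array: does A change sign among the 2^N corners of each cell?
.cells_with_sign_change <- function(A) {
  m <- dim(A); N <- length(m)
  corners <- as.matrix(expand.grid(rep(list(0:1), N)))
  mx <- NULL; mn <- NULL
  for (r in seq_len(nrow(corners))) {
    idx <- lapply(seq_len(N),
                  function(d) seq_len(m[d] - 1L) + corners[r, d])
    sub <- do.call(`[`, c(list(A), idx, list(drop = FALSE)))
    mx <- if (is.null(mx)) sub else pmax(mx, sub)
    mn <- if (is.null(mn)) sub else pmin(mn, sub)
  }
  mx >= 0 & mn <= 0
}

# Multilinear value and Jacobian (w.r.t. local coords) from corner values.
# V: 2^N x n_comp matrix of corner values (corner order = expand.grid(0:1)).
.cell_eval <- function(V, t, corners) {
  N <- length(t)
  w <- rep(1, nrow(corners))
  for (d in seq_len(N))
    w <- w * ifelse(corners[, d] == 1L, t[d], 1 - t[d])
  f <- drop(crossprod(V, w))
  J <- matrix(0, ncol(V), N)
  for (d in seq_len(N)) {
    wd <- ifelse(corners[, d] == 1L, 1, -1)
    for (dd in seq_len(N)) if (dd != d)
      wd <- wd * ifelse(corners[, dd] == 1L, t[dd], 1 - t[dd])
    J[, d] <- drop(crossprod(V, wd))
  }
  list(f = f, J = J)
}

.classify_eigen <- function(J, deg_tol = 1e-8) {
  re <- Re(eigen(J, only.values = TRUE)$values)
  if (any(abs(re) < deg_tol)) return("degenerate")
  if (all(re < 0)) return("stable")
  if (all(re > 0)) return("unstable")
  "saddle"
}

#' Census of the fixed points of an N-dimensional force field
#'
#' Finds all zeros of the force field over `[0, R]^n_env` and classifies
#' each by the eigenvalues of the Jacobian: stable when all real parts are
#' negative, unstable when all positive, saddle otherwise; near-zero
#' eigenvalues are flagged degenerate and excluded from stable counts.
#'
#' For a sampled field the search is exhaustive at the grid resolution:
#' a multilinear interpolant is extremal at cell corners, so every cell in
#' which each component takes both signs is polished by Newton iteration on
#' the (analytic) in-cell interpolant. For a callable force the same
#' corner prefilter runs on a seed grid and Newton polishing uses
#' finite-difference Jacobians. Duplicate roots are merged within
#' `merge_tol`.
#'
#' @param force a `gp_force_field`, `biotic_population`, or function
#'   `E -> force vector`.
#' @param range upper bound `R` of the scanned hypercube (or `c(lo, hi)`).
#' @param n_env dimensionality (required for callable forces).
#' @param h seed grid spacing for callable forces (default `R/40`).
#' @param merge_tol duplicate-merge distance (default `1e-3 * R`).
#' @param jac_step finite-difference step (default `1e-5 * R`).
#' @param deg_tol eigenvalue magnitude below which a root is degenerate.
#' @return a `stable_points` data frame with one `E_i` column per axis and
#'   a `classification` column.
#' @export
#' @examples
#' find_fixed_points_nd(function(E) -(E - 50), range = 100, n_env = 2)
find_fixed_points_nd <- function(force, range = 100, n_env = NULL, h = NULL,
                                 merge_tol = NULL, jac_step = NULL,
                                 deg_tol = 1e-8) {
  if (length(range) == 1L) range <- c(0, range)
  lo <- range[1L]; R <- range[2L] - lo
  if (is.null(merge_tol)) merge_tol <- 1e-3 * R
  if (is.null(jac_step)) jac_step <- 1e-5 * R
  is_field <- inherits(force, "gp_force_field")
  if (is_field) {
    n_env <- force$n_env
    x <- force$grid[[1L]]
    hh <- force$h
    m <- length(x)
    comps <- lapply(seq_len(n_env), function(comp) {
      array(force$samples[seq_len(m^n_env) + (comp - 1L) * m^n_env],
            rep(m, n_env))
    })
  } else {
    n_env <- if (!is.null(n_env)) n_env else .force_n_env(force)
    if (is.null(n_env))
      stop("'n_env' is required for a callable force")
    if (is.null(h)) h <- R / 40
    x <- seq(lo, lo + R, by = h)
    if (tail(x, 1L) < lo + R) x <- c(x, lo + R)
    hh <- NULL # non-uniform tail possible; handled per cell
    m <- length(x)
    f0 <- .as_force_fun(force)
    pts <- as.matrix(expand.grid(rep(list(x), n_env)))
    vals <- t(apply(pts, 1L, f0))
    if (n_env == 1L) vals <- matrix(vals, ncol = 1L)
    comps <- lapply(seq_len(n_env),
                    function(comp) array(vals[, comp], rep(m, n_env)))
  }
  empty <- function() {
    out <- data.frame(matrix(numeric(0), 0, n_env),
                      classification = factor(character(0), levels = c(
                        "stable", "unstable", "saddle", "degenerate")))
    names(out) <- c(paste0("E_", seq_len(n_env)), "classification")
    structure(out, class = c("stable_points", "data.frame"))
  }
  cand <- Reduce(`&`, lapply(comps, .cells_with_sign_change))
  idx <- which(cand, arr.ind = TRUE)
  if (length(idx) == 0L) return(empty())
  if (!is.matrix(idx)) idx <- matrix(idx, ncol = n_env)
  corners <- as.matrix(expand.grid(rep(list(0:1), n_env)))
  roots <- NULL; jacs <- list()
  for (r in seq_len(nrow(idx))) {
    i0 <- idx[r, ]
    V <- vapply(comps, function(A)
      A[corners + matrix(i0, nrow(corners), n_env, byrow = TRUE)],
      numeric(nrow(corners)))
    V <- matrix(V, nrow(corners), n_env)
    cw <- x[i0 + 1L] - x[i0] # cell widths per axis
    t <- rep(0.5, n_env)
    ok <- FALSE
    for (it in seq_len(50L)) {
      ev <- .cell_eval(V, t, corners)
      step <- tryCatch(solve(ev$J, ev$f), error = function(e) NULL)
      if (is.null(step)) break
      t <- t - step
      if (sum(abs(step)) < 1e-13) { ok <- TRUE; break }
      if (any(abs(t - 0.5) > 2)) break
    }
    if (!ok || any(t < -1e-9) || any(t > 1 + 1e-9)) next
    root <- x[i0] + t * cw
    ev <- .cell_eval(V, t, corners)
    roots <- rbind(roots, root)
    jacs[[nrow(roots)]] <- sweep(ev$J, 2L, cw, `/`)
  }
  if (is.null(roots)) return(empty())
  # polish callable-force roots on the true force, not the grid samples
  if (!is_field) {
    for (r in seq_len(nrow(roots))) {
      z <- roots[r, ]
      for (it in seq_len(30L)) {
        fz <- f0(z)
        J <- .fd_jacobian(f0, z, jac_step)
        step <- tryCatch(solve(J, fz), error = function(e) NULL)
        if (is.null(step) || any(!is.finite(step))) break
        z <- z - step
        if (sum(abs(step)) < 1e-12 * R) break
      }
      roots[r, ] <- z
      jacs[[r]] <- .fd_jacobian(f0, z, jac_step)
    }
  }
  # merge duplicates
  keep <- rep(TRUE, nrow(roots))
  for (r in seq_len(nrow(roots))) {
    if (!keep[r]) next
    if (r < nrow(roots)) {
      d <- sqrt(rowSums((roots[(r + 1L):nrow(roots), , drop = FALSE] -
                           matrix(roots[r, ], nrow(roots) - r, n_env,
                                  byrow = TRUE))^2))
      keep[(r + 1L):nrow(roots)][d < merge_tol] <- FALSE
    }
  }
  roots <- roots[keep, , drop = FALSE]
  jacs <- jacs[keep]
  cls <- vapply(jacs, .classify_eigen, character(1L), deg_tol = deg_tol)
  out <- data.frame(roots, classification = factor(cls, levels = c(
    "stable", "unstable", "saddle", "degenerate")))
  names(out) <- c(paste0("E_", seq_len(n_env)), "classification")
  rownames(out) <- NULL
  structure(out, class = c("stable_points", "data.frame"))
}

.fd_jacobian <- function(f, x, step) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (d in seq_len(n)) {
    e <- numeric(n); e[d] <- step
    J[, d] <- (f(x + e) - f(x - e)) / (2 * step)
  }
  J
}

#' @export
print.stable_points <- function(x, ...) {
  cat("<stable_points>", nrow(x), "fixed points:",
      paste(names(table(x$classification)[table(x$classification) > 0]),
            table(x$classification)[table(x$classification) > 0],
            sep = "=", collapse = ", "), "\n")
  NextMethod()
}

# -- plateau detection -----------------------------------------------------

#' Detect homeostatic plateaus in a ramp trajectory
#'
#' A plateau is a stretch of a (1-D) trajectory during which the
#' environmental variable is effectively pinned while the external forcing
#' keeps changing - the signature of rein control under a slow ramp.
#' Operationally: every sliding window of duration `window` whose range of
#' `E` is below `eps` belongs to a plateau; overlapping windows are merged.
#'
#' @param traj a `rein_trajectory` with one environmental variable.
#' @param window window duration (default `10 * tau_env`).
#' @param eps maximum `E` range within a window (default
#'   `0.5 * niche_width`).
#' @return a data frame with one row per plateau: `t_start`, `t_end`,
#'   `duration`, `E_mean`, `P_change` (forcing traversed during the
#'   plateau) and `max_imbalance` (largest `|P + F|` inside it).
#' @export
detect_plateaus <- function(traj, window = NULL, eps = NULL) {
  stopifnot(inherits(traj, "rein_trajectory"), ncol(traj$env) == 1L)
  cfg <- traj$config
  if (is.null(window)) window <- 10 * cfg$tau_env
  if (is.null(eps)) eps <- 0.5 * cfg$niche_width
  tms <- traj$times
  E <- traj$env[, 1L]
  n <- length(E)
  dt <- stats::median(diff(tms))
  w <- max(2L, ceiling(window / dt))
  if (n < w) return(data.frame())
  rng <- zoo::rollapply(E, w, function(z) max(z) - min(z), align = "left")
  ok <- rng < eps
  # a time belongs to a plateau when it STARTS a passing window; this keeps
  # the fast pre-transition edge (where E accelerates away) out of the
  # plateau interval. The first window-length of each run is trimmed too:
  # it holds the decelerating landing transient of the preceding
  # transition, whose windowed range is small although the system is still
  # moving. Runs shorter than one window are transition pauses, not
  # plateaus, and are dropped.
  cov <- rep(FALSE, n)
  cov[seq_along(ok)][ok] <- TRUE
  rr <- rle(cov)
  e2 <- cumsum(rr$lengths); s2 <- e2 - rr$lengths + 1L
  keep <- which(rr$values & (rr$lengths > w))
  out <- do.call(rbind, lapply(keep, function(j) {
    a <- s2[j] + w
    i <- a:e2[j]
    data.frame(t_start = tms[a], t_end = tms[e2[j]],
               duration = tms[e2[j]] - tms[a],
               E_mean = mean(E[i]),
               P_change = traj$perturbation[e2[j], 1L] -
                 traj$perturbation[a, 1L],
               max_imbalance = max(abs(traj$perturbation[i, 1L] +
                                         traj$force[i, 1L])))
  }))
  if (is.null(out)) data.frame() else out
}
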