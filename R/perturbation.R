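#' External perturbation protocols
#'
#' A perturbation protocol is the external abiotic forcing `P(t)` applied to
#' the environmental variables - the analogue of slowly brightening
#' insolation (ramp) or a sudden displacement (shock) in Daisyworld-type
#' experiments.
#'
#' Kinds:
#' * `constant`: `P(t) = base`.
#' * `linear_ramp`: `P(t) = base + rate * t` per variable.
#' * `shock`: constant forcing `base`, plus an instantaneous displacement of
#'   the *state* `E` by `shock` at `shock_time` (applied by
#'   [rein_simulate()] via [apply_shock()]).
#' * `piecewise`: right-continuous step function through (`times`,
#'   `values`).
#'
#' @param kind protocol kind.
#' @param base baseline forcing, recycled to `n_env`.
#' @param rate ramp rate in units of `E` per unit time, recycled to `n_env`.
#' @param shock_time time of the instantaneous shock.
#' @param shock displacement vector added to `E` at `shock_time`.
#' @param times,values breakpoints and levels for `piecewise` (values may be
#'   a matrix with `n_env` columns).
#' @param n_env number of environmental variables the protocol drives.
#' @return an object of class `perturbation`.
#' @export
#' @examples
#' pr <- perturbation("linear_ramp", rate = 0.01)
#' perturbation_at(pr, c(0, 100))
perturbation <- function(kind = c("constant", "linear_ramp", "shock",
                                  "piecewise"),
                         base = 0, rate = 0, shock_time = NULL, shock = NULL,
                         times = NULL, values = NULL, n_env = 1L) {
  kind <- match.arg(kind)
  n_env <- as.integer(n_env)
  base <- rep_len(base, n_env)
  rate <- rep_len(rate, n_env)
  if (kind == "shock") {
    if (is.null(shock_time) || is.null(shock))
      stop("'shock' protocols need 'shock_time' and 'shock'")
    shock <- rep_len(shock, n_env)
  }
  if (kind == "piecewise") {
    if (is.null(times) || is.null(values))
      stop("'piecewise' protocols need 'times' and 'values'")
    values <- as.matrix(values)
    if (ncol(values) == 1L && n_env > 1L)
      values <- values[, rep(1L, n_env), drop = FALSE]
    stopifnot(nrow(values) == length(times), ncol(values) == n_env)
  }
  structure(list(kind = kind, base = base, rate = rate,
                 shock_time = shock_time, shock = shock,
                 times = times, values = values, n_env = n_env),
            class = "perturbation")
}

#' Evaluate a perturbation protocol
#'
#' @param protocol a [perturbation()].
#' @param t vector of times (`>= 0`).
#' @return a `length(t) x n_env` matrix of forcing values; piecewise
#'   protocols are right-continuous at their breakpoints.
#' @export
perturbation_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "perturbation"))
  n <- protocol$n_env
  switch(protocol$kind,
    constant = ,
    shock = matrix(protocol$base, length(t), n, byrow = TRUE),
    linear_ramp = matrix(protocol$base, length(t), n, byrow = TRUE) +
      outer(t, protocol$rate),
    piecewise = {
      out <- matrix(0, length(t), n)
      for (j in seq_len(n)) {
        f <- stats::approxfun(protocol$times, protocol$values[, j],
                              method = "constant", f = 0, rule = 2)
        out[, j] <- f(t)
      }
      out
    })
}

#' @export
print.perturbation <- function(x, ...) {
  cat("<perturbation>", x$kind, " n_env =", x$n_env, "\n")
  if (x$kind == "linear_ramp")
    cat("  base =", x$base, " rate =", x$rate, "\n")
  if (x$kind == "shock")
    cat("  shock of", format(x$shock), "at t =", x$shock_time, "\n")
  invisible(x)
}
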