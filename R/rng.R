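#' Derive a stage seed from a run seed and a stable label
#'
#' All stochastic stages of a run draw from seeds forked off a single run
#' seed by a stable text label, so adding a stage never perturbs the draws
#' of another stage. The fork is a small deterministic hash of the label
#' folded into the seed, kept below 2^31.
#'
#' @param seed integer run seed.
#' @param label character stage label, e.g. `"population"` or `"field:3"`.
#' @return an integer seed.
#' @export
#' @examples
#' fork_seed(1, "population")
fork_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  seed <- as.double(seed)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(seed) * 7919 + h) %% 2147483629 + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# `seed = NULL` leaves the global stream untouched (and uses it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
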