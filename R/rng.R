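#' Derive a substream seed
#'
#' All stochastic operations in the package take an explicit integer seed.
#' Module-level orchestration derives one seed per named substream (e.g.
#' "trials", "observer", "neural") from a single run seed, so that changing
#' the number of draws in one stage never perturbs another.
#'
#' @param seed integer master seed.
#' @param stream character substream name.
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  stopifnot(is.character(stream), length(stream) == 1)
  h <- as.double(abs(seed)) %% 2147483647
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h + 1)
}

#' Evaluate an expression under a fixed seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards. A NULL seed is an error: every stochastic
#' operation must be explicitly seeded.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("an explicit seed is required for stochastic operations")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
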