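# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed popdecode error
#'
#' All user-facing validation failures raise conditions with a package-specific
#' class so callers (and tests) can distinguish failure modes.
#' @noRd
pd_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "popdecode_error", "error", "condition")))
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded helpers do not perturb
#' the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Every stochastic stage of a pipeline run receives its own logged sub-seed so
#' that stages can be re-run in isolation.
#' @param seed master seed (integer).
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(n), n >= 1)
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    pd_stop("popdecode_invalid_argument",
            sprintf("`%s` must be a single integer >= %s", name, min))
  }
  invisible(as.integer(x))
}
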