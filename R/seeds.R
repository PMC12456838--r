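#' Derive a named sub-seed from a master seed
#'
#' Splits one master seed into independent named streams (e.g. `"gamma"`,
#' `"beta"`, `"coupling"`, `"init"`, `"input"`) so that changing how one
#' stream is consumed does not perturb draws in the others. The split is a
#' deterministic integer hash of `(seed, stream)`; the result is always a
#' valid 32-bit seed.
#'
#' @param seed Integer master seed.
#' @param stream Character stream name.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' sub_seed(1L, "gamma")
#' sub_seed(1L, "coupling") # differs from the gamma stream
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (k in utf8ToInt(stream)) {
    # 31-bit multiplicative string hash, kept in double precision range
    h <- (h * 31 + k) %% m
    h <- (h * 69069 + 1) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. seed = NULL uses (and advances) the global stream.
with_rng <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

abort_param <- function(msg, ...) {
  rlang::abort(msg, class = "hetnetdyn_parameter_error", ...)
}
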