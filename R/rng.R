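# Deterministic seed derivation so each pipeline stage draws from its own
# reproducible stream while all randomness flows from one master seed.

#' Derive a stage-specific seed from a master seed
#'
#' Hashes the master seed together with one or more stage labels/counters into
#' a 31-bit integer suitable for `set.seed()`. Different labels give
#' (effectively) independent streams; the same label always gives the same
#' stream, so stages are independently reproducible.
#'
#' @param seed Master integer seed.
#' @param ... Stage labels (character) and/or counters (integers), hashed in
#'   order.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "panel")
#' derive_seed(1L, "gwas", 7L)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(as.double(seed)) %% m)
  for (part in list(...)) {
    codes <- if (is.character(part)) {
      as.double(utf8ToInt(paste(part, collapse = "|")))
    } else {
      abs(as.double(part))
    }
    for (v in codes) h <- ((h * 48271) %% m + (v %% m)) %% m
    h <- (h * 16807) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' library code never perturbs user-level randomness.
#'
#' @param seed Integer seed passed to `set.seed()`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
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
  })
  set.seed(seed)
  expr
}
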