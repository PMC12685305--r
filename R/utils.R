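#' @keywords internal
"_PACKAGE"

# 32-bit mixing arithmetic done in doubles: all intermediates stay below
# 2^53 so the modular reductions are exact.
MOD31 <- 2147483647

#' Stable 32-bit integer hash of an integer vector
#'
#' Deterministic multiplicative mix used for fingerprint keys and seed
#' derivation; platform-independent (pure double arithmetic).
#'
#' @param x integer vector
#' @return a single integer in [0, 2^31 - 2]
#' @keywords internal
hash_mix <- function(x) {
  h <- 5381
  for (v in as.numeric(x)) {
    h <- (h * 33 + (v %% MOD31)) %% MOD31
  }
  as.integer(h)
}

#' Derive a per-stage seed from a global seed
#'
#' One global seed fans out to independent per-stage streams via a
#' stable hash of (seed, stage label), so stages are reproducible in
#' isolation. Result always fits a 32-bit R integer.
#'
#' @param seed global integer seed
#' @param stage character stage label
#' @return integer seed
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- hash_mix(c(as.integer(seed), utf8ToInt(stage)))
  as.integer(h %% (MOD31 - 1L) + 1L)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores .Random.seed so library calls never perturb the
#' caller's stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort2 <- function(msg, class) {
  stop(structure(class = c(class, "cavigrow_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
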