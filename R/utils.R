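# Internal utilities: deterministic seeding, rounding conventions, validation.

#' @keywords internal
"_PACKAGE"

# The six basic emotions, in the fixed order used throughout the package.
ear_emotions <- function() {
  c("happiness", "surprise", "sadness", "anger", "fear", "disgust")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.  `seed = NULL` runs under the ambient state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based substreams: every sampling stage derives its own 31-bit seed
# from the master seed so stages can be re-run independently yet reproducibly.
substream_seed <- function(seed, stream) {
  seed <- as.double(seed) %% 2147483647
  as.integer((seed * 69621 + as.double(stream) * 1013904223) %% 2147483647)
}

# Round half away from zero (the convention used by the published correction
# grids; base round() goes half to even).  A small guard absorbs binary
# floating-point representation error before the halfway comparison.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}

#' Display rounding for adjustment factors
#'
#' Values pass through a (digits+1)-decimal intermediate before the final
#' rounding, halves away from zero at both steps, reproducing how the
#' published correction grids display their entries
#' (e.g. -1.5545 -> -1.555 -> -1.56).
#'
#' @param x Numeric vector.
#' @param digits Final number of decimals (default 2).
#' @return Rounded vector.
#' @export
display_round <- function(x, digits = 2) {
  round_half_away(round_half_away(x, digits + 1), digits)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
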