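#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

.datatable.aware <- TRUE

#' Half-up rounding to integer percent
#'
#' Rounds `100 * x` to the nearest integer, with ties going up (0.5 -> 1),
#' the convention used for all reported integer percentages. Base `round()`
#' rounds ties to even, which does not match printed tables.
#'
#' @param x fraction(s) in \[0, 1\].
#' @return integer percent(s).
#' @export
percent <- function(x) {
  stats::setNames(as.integer(floor(100 * x + 0.5)), names(x))
}

# Derive a reproducible sub-seed for an isolated random stream.
# Keeps results of one analysis stage invariant to seed use in another.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629 + 1)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG state is untouched.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}
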