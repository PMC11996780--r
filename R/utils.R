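# Small shared helpers.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for all formatted epidemiological output (base `round()`
#' rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

is_probability <- function(x) {
  is.numeric(x) && length(x) >= 1 && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Escape regex metacharacters in a literal string.
regex_escape <- function(x) gsub("([.^$*+?()\\[\\]{}|\\\\-])", "\\\\\\1", x, perl = TRUE)
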