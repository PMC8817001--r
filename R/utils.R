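#' Round half away from zero
#'
#' Decimal rounding with the "round half up" convention used when reporting
#' statistics such as strategy rates (e.g. 5/8 is reported as 0.63, not 0.62).
#' Base R's \code{round} rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to \code{digits} places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Draw `n` independent sub-seeds from a master seed without disturbing the
# caller's RNG state. Sub-seeds stay within the 32-bit integer range.
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate `expr` under a temporary RNG seed (NULL seed = use current stream).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
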