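# Internal helpers shared across the pipeline.

#' @noRd
nf_stop <- function(..., class = "neurofuse_error") {
  stop(errorCondition(paste0(...), class = c(class, "neurofuse_error")))
}

# Deterministic child seeds from a master seed. Lehmer-style mix kept inside
# the 32-bit signed range so set.seed() accepts the result.
#' @noRd
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) + 1
  v <- (s * 48271 + as.double(offset) * 16807 + 12345) %% 2147483647
  as.integer(v)
}

# Run code under a temporary RNG state without disturbing the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
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
  force(code)
}

#' @noRd
is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= min
}

#' @noRd
is_number <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x)
}
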