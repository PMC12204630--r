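#' @importFrom rlang abort warn inform .data
#' @importFrom stats fft kmeans prcomp rexp rlnorm rnorm runif sd t.test
#' @importFrom utils head tail
NULL

# Evaluate code under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

# Extraction-frame geometry shared by detection and parameterization:
# 2 ms total, 0.5 ms before the alignment extremum, which sits at index i0.
frame_geometry <- function(rate) {
  pre <- round(0.0005 * rate)
  len <- round(0.002 * rate)
  list(pre = pre, len = len, i0 = pre + 1L, post = len - pre - 1L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
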