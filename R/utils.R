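#' @useDynLib mcfsomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards so library calls never perturb user-level randomness.
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and an index, kept inside 32-bit
# integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %%
    2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept either a plain numeric matrix or an omics_matrix.
as_values <- function(x) {
  if (inherits(x, "omics_matrix")) {
    return(x$values)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.matrix(x), is.numeric(x))
  x
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
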