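#' @importFrom rlang abort warn .data
#' @importFrom stats sd var cor pt qt rnorm runif aov t.test TukeyHSD predict
#' @importFrom utils head
NULL

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All stochastic generator/fold functions route
# through this so that identical seeds give bit-identical output regardless of
# surrounding RNG use.
with_rng <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ..., class = "nirmilk_error") {
  abort(sprintf(fmt, ...), class = class)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)
}

as_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  x
}
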