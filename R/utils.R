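#' @import data.table
#' @importFrom stats dhyper p.adjust rnorm runif rbinom cor.test wilcox.test
#' @importFrom stats pnorm dnorm setNames sd
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_int <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x))
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  if (!is.null(min) && x < min)
    stop(sprintf("`%s` must be >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
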