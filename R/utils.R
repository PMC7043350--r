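#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
#' @examples
#' with_seed(1, rnorm(2))
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

#' Derive reproducible child seeds from one master seed
#'
#' One global seed fans out to independent per-stage seeds so that pipeline
#' stages (genotypes, scores, phenotypes, subsampling, ...) are individually
#' reproducible. Seeds are kept within the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
#' @examples
#' child_seeds(1, 3)
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# internal: stop() with a consistent prefix-free message, sprintf-style
fu_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

fu_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# internal: message unless suppressed
fu_log <- function(fmt, ...) message(sprintf(fmt, ...))
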