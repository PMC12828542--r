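# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator locally and restores the caller's RNG state on exit,
#' so generator functions are reproducible without clobbering the session.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop2 <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop2(sprintf("'%s' must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  x
}

# Default chromosome names treated as sex chromosomes when exclusion is on.
SEX_CHROMS <- c("chrX", "chrY", "X", "Y")
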