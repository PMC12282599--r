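#' @keywords internal
"_PACKAGE"

logit <- function(p) log(p) - log1p(-p)

expit <- function(x) stats::plogis(x)

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, then restores the caller's RNG state so
#' library code never clobbers the user's random stream. With `seed = NULL`
#' the expression runs on the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

# Round half away from zero (spreadsheet convention), unlike base round()'s
# round-half-to-even.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
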