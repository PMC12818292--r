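# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; clinical score tables and
#' percentage summaries in this field conventionally round half up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @export
#' @examples
#' round_half_up(34.0625, 0) # 34
#' round_half_up(32.45, 1)   # 32.5
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` uses the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  expr
}

# Derive a child seed from a parent seed and a stage label, staying well
# below .Machine$integer.max so downstream set.seed() calls are valid.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(cohort = 11L, match = 23L, session = 37L, language = 53L,
               return = 71L, threshold = 89L)
  off <- offsets[[stage]] %||% 101L
  (as.integer(seed) * 1009L + off) %% 2147483587L
}

stop_olf <- function(..., class = "olfdyad_error") {
  stop(structure(
    class = c(class, "olfdyad_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
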