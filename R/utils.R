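# internal helpers

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded package internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

stop_panfc <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_panfc(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper)
    stop_panfc(sprintf("'%s' must be in [%s, %s], got %s", name,
                       format(lower), format(upper), format(x)))
  if (integer && x != round(x))
    stop_panfc(sprintf("'%s' must be an integer, got %s", name, format(x)))
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_panfc(sprintf("'%s' must be TRUE or FALSE", name))
  invisible(x)
}

# mean/sd summary used in metric tables; undefined metrics (single-class
# splits) are dropped from the aggregate
mean_sd <- function(x) {
  if (all(is.na(x))) return(c(mean = NA_real_, sd = NA_real_))
  c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
}
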