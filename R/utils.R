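# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
abort <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "superexon_error")))
}

#' @keywords internal
#' @noRd
skip_signal <- function(msg) {
  warning(warningCondition(msg, class = c("superexon_skip", "superexon_warning")))
  invisible(NULL)
}

# log(sum(exp(x))) without overflow
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Seed handling: functions that take `seed` set it locally and restore the
# caller's RNG state on exit, so library code never clobbers a user's stream.
#' @keywords internal
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
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
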