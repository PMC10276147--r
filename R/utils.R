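#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the RNG state locally, restoring it on exit of the caller
#' @keywords internal
#' @noRd
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

#' Derive a reproducible child seed from a base seed and a stream label
#' @keywords internal
#' @noRd
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  # keep within 32-bit signed range
  (as.double(seed) * 1000003 + as.double(stream) * 7919) %% 2147483647
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_input(msg)
  invisible(TRUE)
}
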