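#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats approx coef median rnorm sd setNames uniroot vcov
#' @importFrom utils head tail
NULL

# classed condition helper so callers can catch specific failure modes
stop_raseff <- function(message, class) {
  rlang::abort(message, class = c(paste0("raseffector_error_", class), "raseffector_error"))
}

warn_raseff <- function(message, class) {
  rlang::warn(message, class = c(paste0("raseffector_warning_", class), "raseffector_warning"))
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# blank insertion code / altloc normalised to ""
blank_to_empty <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == " "] <- ""
  x
}
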