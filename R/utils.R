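#' @importFrom methods new validObject is slot slotNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed conditions: every user-facing failure carries a class so callers
## (and the CLI) can react without string matching.
dtStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "dynatrack_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

dtConfigError    <- function(fmt, ...) dtStop("dt_config_semantics_error", fmt, ...)
dtSyntaxError    <- function(fmt, ...) dtStop("dt_config_syntax_error", fmt, ...)
dtRegionError    <- function(fmt, ...) dtStop("dt_region_syntax_error", fmt, ...)
dtFormatError    <- function(fmt, ...) dtStop("dt_format_error", fmt, ...)
dtIOError        <- function(fmt, ...) dtStop("dt_io_error", fmt, ...)
dtContractError  <- function(fmt, ...) dtStop("dt_contract_error", fmt, ...)

## Evaluate expr under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

gcdInt <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0
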