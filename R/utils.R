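#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef predict rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

# Round half away from zero (base round() is round-half-even, which would
# disagree with printed table values at .5 boundaries).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed) || seed != trunc(seed))
    stopf("an explicit integer 'seed' is required")
  as.integer(seed)
}
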