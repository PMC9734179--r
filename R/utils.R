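## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; displayed percentages here follow
#' the half-up convention (e.g. 52.5 -> 53).
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @keywords internal
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## stopf: sprintf-style stop without call noise
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Check a scalar probability-like parameter lies in (0, 1].
checkProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 1)
    stopf("'%s' must be a single value in (0, 1], got %s", name,
          paste(format(x), collapse = ", "))
  invisible(x)
}

## Coerce '.'/NA strand to '*' for GRanges construction.
fixStrand <- function(s) {
  s <- as.character(s)
  s[is.na(s) | s == "."] <- "*"
  s
}
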