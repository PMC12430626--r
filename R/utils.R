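#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used in the reported tables
#' (base [round()] rounds half to even, which differs on exact .5 cases).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.675, 2) # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# path to a packaged data file
forcarb_file <- function(...) {
  system.file("extdata", ..., package = "forcarb", mustWork = TRUE)
}

# normalize a free-text token before synonym lookup: lower case, trim,
# collapse separators, strip botanical abbreviation dots
normalize_token <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\.", "", x)
  x <- gsub("[ _\\-]+", " ", x)
  x
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}
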