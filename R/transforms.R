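#' Arcsine square-root transform of germination proportions
#'
#' Variance-stabilising transform applied to germination proportions before
#' any t test or ANOVA: `asin(sqrt(p))`, in radians.  Monotone increasing on
#' \[0, 1\], mapping 0 to 0 and 1 to pi/2.
#'
#' @param p Numeric vector of proportions in \[0, 1\].  `NA` passes through.
#' @return Numeric vector of transformed values in \[0, pi/2\] (radians).
#' @examples
#' arcsine_transform(c(0, 0.5, 1))
#' @export
arcsine_transform <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("proportions outside [0, 1]: ", paste(utils::head(p[bad], 3), collapse = ", "))
  }
  asin(sqrt(p))
}
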