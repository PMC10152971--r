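# Box-Cox power transform and its inverse. The amplitude ratio is strictly
# positive and right-skewed; the transform maps it to an (approximately)
# Gaussian scale on which the age-varying mean and SD are modeled.

#' Box-Cox transform
#'
#' `((y + shift)^lambda - 1) / lambda` for `lambda != 0`, `log(y + shift)`
#' for `lambda == 0`; continuous in `lambda` at 0.
#'
#' @param y Positive values (after adding `shift`).
#' @param lambda Power parameter.
#' @param shift Location shift added before transforming (default 0).
#' @return Transformed values, same length as `y`.
#' @examples
#' boxcox(3, 1)    # 2
#' boxcox(1, 0)    # 0
#' boxcox(4, 0.5)  # 2
#' @export
boxcox <- function(y, lambda, shift = 0) {
  stopifnot(is.numeric(y), length(lambda) == 1L, is.finite(lambda))
  z <- y + shift
  if (any(z <= 0, na.rm = TRUE))
    stop("Box-Cox transform requires y + shift > 0", call. = FALSE)
  if (abs(lambda) < 1e-12) log(z) else (z^lambda - 1) / lambda
}

#' Inverse Box-Cox transform
#'
#' Maps a transformed value back to the original measurement scale. When
#' `lambda * b + 1 <= 0` the inverse is undefined; the result is clamped to
#' `-shift` (i.e. zero on the unshifted scale) with a warning.
#'
#' @param b Values on the transformed scale.
#' @param lambda Power parameter.
#' @param shift Location shift used in the forward transform.
#' @return Values on the original scale.
#' @export
inv_boxcox <- function(b, lambda, shift = 0) {
  stopifnot(is.numeric(b), length(lambda) == 1L, is.finite(lambda))
  if (abs(lambda) < 1e-12) return(exp(b) - shift)
  arg <- lambda * b + 1
  bad <- !is.na(arg) & arg <= 0
  if (any(bad)) {
    warning("inverse Box-Cox argument outside range; clamping to zero",
            call. = FALSE)
    arg[bad] <- 0
  }
  arg^(1 / lambda) - shift
}
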