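#' Standard normal variate transform
#'
#' Per-spectrum standardisation (subtract the spectrum mean, divide by its
#' SD), removing multiplicative scatter and additive offsets. Invariant to
#' affine transforms of the input.
#'
#' @param spectrum numeric vector, or a pixels x bands matrix (applied
#'   row-wise).
#' @return transformed spectrum/matrix with row mean 0 and SD 1.
#' @export
snv <- function(spectrum) {
  if (is.matrix(spectrum)) {
    return(t(apply(spectrum, 1, snv)))
  }
  s <- stats::sd(spectrum)
  if (!is.finite(s) || s == 0) stop("SNV undefined for constant spectrum")
  (spectrum - mean(spectrum)) / s
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed onto a reference spectrum
#' (`x ~ a + b * ref`, ordinary least squares) and corrected to
#' `(x - a) / b`, inverting additive and multiplicative scatter.
#'
#' @param spectra pixels x bands matrix, at least 2 rows.
#' @param reference reference spectrum; defaults to the column mean.
#' @return corrected matrix of the same shape.
#' @export
msc <- function(spectra, reference = colMeans(spectra)) {
  stopifnot(is.matrix(spectra), nrow(spectra) >= 2,
            length(reference) == ncol(spectra))
  ref_c <- reference - mean(reference)
  denom <- sum(ref_c^2)
  # per-row OLS: b = cov(x, ref)/var(ref), a = mean(x) - b*mean(ref)
  b <- as.vector((spectra - rowMeans(spectra)) %*% ref_c) / denom
  a <- rowMeans(spectra) - b * mean(reference)
  if (any(abs(b) < 1e-12)) {
    stop("MSC slope ~0 for spectra: ",
         paste(which(abs(b) < 1e-12), collapse = ", "))
  }
  (spectra - a) / b
}
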