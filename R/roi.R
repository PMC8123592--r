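#' Extract stain regions of interest at a single band
#'
#' Stains are segmented on the image of the grid band nearest the target
#' wavelength (540 nm by default, where hemoglobin and the red confusers
#' all absorb strongly): the band image is thresholded (Otsu by default),
#' the low-reflectance side is taken as stain on bright substrates, and
#' connected components above a minimum area become the stain mask.
#'
#' @param cube a reflectance [hypercube()].
#' @param wavelength segmentation wavelength in nm.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold reflectance cutoff when `method = "fixed"`.
#' @param min_area minimum component area in pixels.
#' @return object of class `stain_mask`: list with `mask` (logical matrix)
#'   and `components` (integer matrix, 0 = background, k = stain id).
#'   Empty masks produce a warning, not an error (blind scenes may contain
#'   stain-free regions).
#' @export
extract_roi <- function(cube, wavelength = 540, method = c("otsu", "fixed"),
                        threshold = NULL, min_area = 20L) {
  method <- match.arg(method)
  band <- cube$data[, , nearest_band(cube$wavelength, wavelength)]
  cutoff <- if (method == "otsu") {
    rng <- range(band)
    if (diff(rng) < 1e-12) rng[1] - 1  # uniform image: nothing below cutoff
    else EBImage::otsu(EBImage::Image(band), range = rng)
  } else {
    if (is.null(threshold)) stop("fixed method needs a threshold")
    threshold
  }
  mask <- band < cutoff
  comp <- EBImage::bwlabel(EBImage::Image(mask))
  comp <- matrix(as.integer(comp), nrow(mask), ncol(mask))
  sizes <- tabulate(comp[comp > 0L])
  keep <- which(sizes >= min_area)
  comp[!comp %in% keep] <- 0L
  comp <- match(comp, c(0L, keep)) - 1L
  comp <- matrix(as.integer(comp), nrow(mask), ncol(mask))
  if (!any(comp > 0L)) warning("empty stain mask")
  structure(list(mask = comp > 0L, components = comp,
                 n_stains = length(keep), wavelength = wavelength),
            class = "stain_mask")
}

#' Pixel spectra under a mask
#'
#' @param cube a [hypercube()].
#' @param mask logical matrix (or a `stain_mask`).
#' @return pixels x bands matrix, rows in column-major pixel order.
#' @export
mask_spectra <- function(cube, mask) {
  if (inherits(mask, "stain_mask")) mask <- mask$mask
  d <- dim(cube$data)
  matrix(cube$data, d[1] * d[2], d[3])[as.vector(mask), , drop = FALSE]
}

#' Crop a stain-centred window from a hypercube
#'
#' Reproduces the convention of reducing each stain capture to a fixed
#' window (100 x 100 spatial pixels by default) centred on the stain.
#'
#' @param cube a [hypercube()].
#' @param center `c(row, col)` stain centre.
#' @param size `c(rows, cols)` of the crop.
#' @return cropped [hypercube()].
#' @export
crop_cube <- function(cube, center, size = c(100L, 100L)) {
  d <- dim(cube$data)
  half <- floor(size / 2)
  r0 <- min(max(1L, center[1] - half[1]), d[1] - size[1] + 1L)
  c0 <- min(max(1L, center[2] - half[2]), d[2] - size[2] + 1L)
  hypercube(cube$data[r0:(r0 + size[1] - 1L), c0:(c0 + size[2] - 1L), ,
                      drop = FALSE],
            cube$wavelength, cube$metadata)
}
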