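#' Default VNIR wavelength grid
#'
#' The camera emulated by the synthetic generator samples 224 bands uniformly
#' over 397-1003 nm (mean spacing about 2.7 nm), matching a pushbroom VNIR
#' line scanner.
#'
#' @param n number of bands.
#' @param from,to first and last band centre in nm.
#' @return numeric vector of band centres (nm), strictly increasing.
#' @examples
#' grid <- wavelength_grid()
#' length(grid)       # 224
#' range(grid)        # 397 1003
#' mean(diff(grid))   # ~2.72 nm
#' @export
wavelength_grid <- function(n = 224L, from = 397, to = 1003) {
  stopifnot(n >= 2L, from < to)
  seq(from, to, length.out = n)
}

#' Index of the grid band nearest a target wavelength
#'
#' @param grid numeric wavelength vector (nm).
#' @param wavelength target in nm; must lie within the grid range.
#' @return integer index into `grid`.
#' @export
nearest_band <- function(grid, wavelength) {
  if (wavelength < min(grid) || wavelength > max(grid)) {
    stop("wavelength ", wavelength, " nm outside grid range [",
         min(grid), ", ", max(grid), "]")
  }
  which.min(abs(grid - wavelength))
}
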