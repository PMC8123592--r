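#' Savitzky-Golay filter specification
#'
#' The spectral feature-enhancement workhorse: a sliding local
#' least-squares polynomial fit whose centre evaluation yields smoothed
#' values (`deriv = 0`) or analytic derivatives. The defaults (13-point
#' window, order-3 polynomial, second derivative) are the setting that
#' turns the weak oxyhemoglobin alpha/beta reflectance dips into prominent
#' curvature features.
#'
#' @param window odd window length in samples.
#' @param polyorder polynomial order, `< window`.
#' @param deriv derivative order, `<= polyorder`.
#' @return object of class `sg_spec`.
#' @export
sg_spec <- function(window = 13L, polyorder = 3L, deriv = 2L) {
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (deriv > polyorder) stop("deriv must be <= polyorder")
  if (deriv < 0 || polyorder < 0) stop("negative order")
  structure(list(window = window, polyorder = as.integer(polyorder),
                 deriv = as.integer(deriv)),
            class = "sg_spec")
}

# Least-squares design pieces for one window: V is the Vandermonde matrix
# on offsets -h..h (sample units), P = (V'V)^{-1} V' maps window samples to
# polynomial coefficients a_0..a_p (y ~ sum a_k x^k).
sg_poly_solver <- function(spec) {
  h <- (spec$window - 1L) / 2L
  x <- seq(-h, h)
  v <- outer(x, 0:spec$polyorder, `^`)
  list(x = x, P = solve(crossprod(v), t(v)))
}

#' Savitzky-Golay convolution kernel
#'
#' Weights `w` such that `w . y` equals the `deriv`-th derivative, at the
#' window centre, of the least-squares polynomial through the window
#' samples. The derivative is scaled by `spacing^(-deriv)` so a reflectance
#' spectrum on a nm grid yields units of reflectance per nm^deriv.
#'
#' @param spec an [sg_spec()].
#' @param spacing sample spacing (nm per sample); use 1 for per-index
#'   units.
#' @return numeric weight vector of length `spec$window`.
#' @examples
#' # classical 5-point quadratic smoothing weights
#' sg_coefficients(sg_spec(5, 2, 0))  # (-3, 12, 17, 12, -3) / 35
#' @export
sg_coefficients <- function(spec, spacing = 1) {
  stopifnot(inherits(spec, "sg_spec"), spacing > 0)
  s <- sg_poly_solver(spec)
  # d-th derivative at x = 0 is d! * a_d
  factorial(spec$deriv) * s$P[spec$deriv + 1L, ] / spacing^spec$deriv
}

# Full window x window evaluation matrix: row j gives the deriv-th
# derivative of the window's fitted polynomial evaluated at offset x_j.
# Interior filtering uses only the centre row; edge handling re-uses the
# first/last window's fit at the edge offsets (no shrinkage).
sg_window_matrix <- function(spec, spacing = 1) {
  s <- sg_poly_solver(spec)
  p <- spec$polyorder; d <- spec$deriv
  k <- d:p
  coef_scale <- factorial(k) / factorial(k - d)
  e <- outer(s$x, k - d, `^`) * rep(coef_scale, each = spec$window)
  (e %*% s$P[k + 1L, , drop = FALSE]) / spacing^d
}

#' Band-to-band Savitzky-Golay filter matrix
#'
#' Returns the `n x n` linear map `F` with `sg_filter(y) == F %*% y`;
#' applying it as one matrix product is how whole pixel tables are
#' filtered efficiently.
#'
#' @param n spectrum length (`>= spec$window`).
#' @param spec an [sg_spec()].
#' @param spacing sample spacing (nm).
#' @return `n x n` matrix.
#' @export
sg_filter_matrix <- function(n, spec, spacing = 1) {
  stopifnot(inherits(spec, "sg_spec"))
  if (n < spec$window) stop("spectrum shorter than the filter window")
  h <- (spec$window - 1L) / 2L
  wm <- sg_window_matrix(spec, spacing)
  f <- matrix(0, n, n)
  centre <- wm[h + 1L, ]
  for (i in (h + 1L):(n - h)) f[i, (i - h):(i + h)] <- centre
  # edges: refit polynomial on the first/last full window
  for (j in 1:h) {
    f[j, 1:spec$window] <- wm[j, ]
    f[n - h + j, (n - spec$window + 1L):n] <- wm[h + 1L + j, ]
  }
  f
}

#' Apply a Savitzky-Golay filter to one spectrum
#'
#' Interior points are the kernel convolution; the first and last
#' half-window points are evaluated from the polynomial fitted to the
#' first/last full window, so the output has the same length as the input.
#' The map is linear in its input.
#'
#' @param spectrum numeric vector, length `>= spec$window`.
#' @param spec an [sg_spec()].
#' @param spacing sample spacing (nm); for a uniform wavelength grid use
#'   `mean(diff(grid))`.
#' @return filtered spectrum, same length.
#' @export
sg_filter <- function(spectrum, spec, spacing = 1) {
  if (length(spectrum) < spec$window) {
    stop("spectrum (length ", length(spectrum),
         ") shorter than the filter window (", spec$window, ")")
  }
  as.vector(sg_filter_matrix(length(spectrum), spec, spacing) %*% spectrum)
}

#' Apply a Savitzky-Golay filter to a pixel table
#'
#' @param x pixels x bands matrix.
#' @param spec an [sg_spec()].
#' @param spacing sample spacing (nm).
#' @return filtered matrix, same shape.
#' @export
sg_filter_rows <- function(x, spec, spacing = 1) {
  x %*% t(sg_filter_matrix(ncol(x), spec, spacing))
}
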