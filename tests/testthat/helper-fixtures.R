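# Shared fixtures, built once per test run and cached. Small diameters keep
# stains at ~30-60 pixels, which preserves every structural property of the
# full-size design at a fraction of the cost.

.fixtures <- new.env(parent = emptyenv())

small_design <- function(seed = 42L) {
  key <- paste0("design_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_full_design(seed = seed,
                                             diameter_px = c(6, 9))
  }
  .fixtures[[key]]
}

small_pixels <- function(seed = 42L) {
  key <- paste0("pixels_", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- as_pixel_table(small_design(seed))
  }
  .fixtures[[key]]
}

# A tiny two-stain scene: one blood disc, one confuser disc on white tile.
two_stain_design <- function(day = 1L, diameter = 9) {
  scene_design("white_tile", day,
               data.frame(substance = c("blood", "red_ink"),
                          donor = c(1L, NA_integer_),
                          row = c(15, 15), col = c(15, 40),
                          diameter = diameter),
               cube_shape = c(30L, 55L))
}

grid224 <- wavelength_grid()

# brute-force Savitzky-Golay oracle: fit a polynomial by least squares in
# each window and evaluate its deriv-th derivative at the in-window
# position (edge windows are the first/last full window)
sg_oracle <- function(y, window, polyorder, deriv, spacing = 1) {
  n <- length(y)
  h <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1, i - h), n - window + 1)
    idx <- lo:(lo + window - 1)
    x <- (idx - i) * spacing
    fit <- stats::lm(y[idx] ~ poly(x, polyorder, raw = TRUE))
    cf <- stats::coef(fit)
    out[i] <- factorial(deriv) * cf[deriv + 1]
  }
  out
}

# brute-force lattice count of a rendered disc footprint
disc_area_oracle <- function(diameter) {
  r <- diameter / 2
  k <- floor(r)
  n <- 0L
  for (a in -k:k) for (b in -k:k) if (a^2 + b^2 <= r^2) n <- n + 1L
  n
}
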