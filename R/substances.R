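#' Parametric substance spectral model
#'
#' A substance is modelled on the absorbance scale as a sum of Gaussian
#' bands, converted to reflectance through a Beer-Lambert-style relation
#' `R(lambda) = B(lambda) * 10^(-A(lambda))` where `B` is the substrate
#' baseline. Band positions and qualitative shapes follow the visible
#' phenomenology of dried blood (Soret band near 415 nm, oxyhemoglobin
#' beta/alpha bands at 540/577 nm, a hemichrome/methemoglobin-driven
#' positive reflectance slope over 600-650 nm that decays with aging) and
#' of common red confuser substances.
#'
#' Each band belongs to an aging group: `"fixed"` bands are age-invariant,
#' `"aging"` and `"slope"` bands shrink day-over-day (oxyhemoglobin decay),
#' and `"met"` bands grow (methemoglobin/hemichrome formation). The aging
#' model maps each group to three per-day depth multipliers.
#'
#' @param name substance label.
#' @param class `"blood"` or `"non_blood"`.
#' @param bands data.frame with columns `center` (nm), `width` (nm, Gaussian
#'   sigma), `depth` (absorbance units), `group`.
#' @param nir_trough optional `c(center, width, depth)` for a faint
#'   near-infrared absorption around 920-930 nm.
#' @param aging_model named list mapping band groups to length-3 numeric
#'   multipliers (days 1-3).
#' @return object of class `substance_spec`.
#' @export
substance_spec <- function(name, class = c("non_blood", "blood"), bands,
                           nir_trough = NULL,
                           aging_model = list()) {
  class <- match.arg(class)
  stopifnot(is.data.frame(bands),
            all(c("center", "width", "depth", "group") %in% names(bands)),
            all(bands$depth >= 0), all(bands$width > 0))
  if (!is.null(nir_trough)) {
    stopifnot(length(nir_trough) == 3)
    bands <- rbind(bands, data.frame(center = nir_trough[1],
                                     width = nir_trough[2],
                                     depth = nir_trough[3],
                                     group = "fixed"))
  }
  defaults <- list(fixed = c(1, 1, 1))
  aging_model <- utils::modifyList(defaults, aging_model)
  for (g in unique(bands$group)) {
    if (is.null(aging_model[[g]])) aging_model[[g]] <- c(1, 1, 1)
    stopifnot(length(aging_model[[g]]) == 3, all(aging_model[[g]] >= 0))
  }
  structure(list(name = name, class = class, bands = bands,
                 has_nir_trough = !is.null(nir_trough),
                 aging_model = aging_model),
            class = "substance_spec")
}

#' @export
print.substance_spec <- function(x, ...) {
  cat("<substance_spec>", x$name, sprintf("(%s)\n", x$class))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Built-in library of blood and red confuser substances
#'
#' Returns nine parametric substance models: dried blood plus the eight
#' red-hued confusers used throughout the experimental design (ketchup,
#' rust/red/brown acrylic paint, red/rust nail polish, fake blood, red
#' ink). All confusers absorb strongly below ~600 nm so their raw
#' reflectance resembles blood; they differ in band structure: the rust
#' acrylic paint carries two flanking bands producing a reflectance hump
#' near 510 nm, and both nail polishes carry faint near-infrared troughs
#' around 925 nm. Only blood has the narrow 540/577 nm oxyhemoglobin pair
#' and an aging model.
#'
#' @return named list of nine [substance_spec()] objects; element `"blood"`
#'   is the only one with `class == "blood"`.
#' @examples
#' lib <- substance_library()
#' names(lib)
#' sum(vapply(lib, function(s) s$class == "blood", logical(1)))  # 1
#' @export
substance_library <- function() {
  band <- function(center, width, depth, group = "fixed") {
    data.frame(center = center, width = width, depth = depth, group = group)
  }
  blood <- substance_spec(
    "blood", "blood",
    rbind(band(415, 20, 1.00),                 # Soret, deepest
          band(540, 12, 0.45, "aging"),        # beta oxyhemoglobin
          band(577, 10, 0.40, "aging"),        # alpha oxyhemoglobin
          band(560, 40, 0.60),                 # broad oxy envelope: 600-650 slope
          band(630, 40, 0.10, "met"),          # methemoglobin/hemichrome
          band(450, 80, 0.30, "browning")),    # broad oxidative browning
    aging_model = list(aging = c(1.0, 0.7, 0.45),
                       met = c(1.0, 1.3, 1.6),
                       browning = c(0.0, 0.5, 1.0)))
  confusers <- list(
    ketchup = rbind(band(490, 55, 0.90), band(590, 50, 0.35)),
    rust_acrylic_paint = rbind(band(430, 30, 0.50), band(470, 25, 0.60),
                               band(555, 30, 0.50)),
    red_acrylic_paint = rbind(band(430, 40, 0.60), band(520, 45, 0.95)),
    brown_acrylic_paint = rbind(band(500, 80, 0.70), band(650, 80, 0.15)),
    red_nail_polish = rbind(band(440, 35, 0.70), band(530, 40, 0.90)),
    rust_nail_polish = rbind(band(475, 30, 0.55), band(560, 35, 0.50)),
    fake_blood = rbind(band(420, 30, 0.60), band(545, 55, 0.95)),
    red_ink = rbind(band(460, 40, 0.80), band(550, 35, 1.00)))
  troughs <- list(red_nail_polish = c(925, 12, 0.06),
                  rust_nail_polish = c(928, 12, 0.05))
  lib <- c(list(blood = blood),
           lapply(names(confusers), function(nm) {
             substance_spec(nm, "non_blood", confusers[[nm]],
                            nir_trough = troughs[[nm]])
           }))
  names(lib) <- c("blood", names(confusers))
  lib
}

#' Substrate reflectance baseline
#'
#' White cotton fabric is the most absorbing of the three backgrounds
#' (baseline ~0.55); white tile and PVC wall sheet are bright. Baselines
#' carry a gentle spectral tilt so they are not artificially flat.
#'
#' @param grid wavelength vector (nm).
#' @param substrate one of `"white_fabric"`, `"white_tile"`, `"wall_sheet"`.
#' @return reflectance baseline per band, in (0, 1].
#' @export
substrate_baseline <- function(grid,
                               substrate = c("white_fabric", "white_tile",
                                             "wall_sheet")) {
  substrate <- match.arg(substrate)
  t <- (grid - min(grid)) / (max(grid) - min(grid))
  switch(substrate,
         white_fabric = 0.52 + 0.06 * t,
         white_tile   = 0.92 - 0.02 * t,
         wall_sheet   = 0.85 - 0.04 * t)
}

#' Absorbance spectrum of a substance model
#'
#' Sums the Gaussian bands with each band depth scaled by its aging-group
#' multiplier for the requested day.
#'
#' @param spec a [substance_spec()].
#' @param grid wavelength vector (nm).
#' @param day aging day, 1-3.
#' @return absorbance per band centre.
#' @export
substance_absorbance <- function(spec, grid, day = 1L) {
  stopifnot(inherits(spec, "substance_spec"))
  if (!day %in% 1:3) stop("day must be 1, 2, or 3")
  a <- numeric(length(grid))
  for (i in seq_len(nrow(spec$bands))) {
    b <- spec$bands[i, ]
    mult <- spec$aging_model[[b$group]][day]
    a <- a + mult * b$depth * exp(-(grid - b$center)^2 / (2 * b$width^2))
  }
  a
}

#' Model reflectance of a substance on a substrate
#'
#' `R = donor_factor * B(lambda) * 10^(-A(lambda))`: the donor factor is a
#' multiplicative baseline-level shift (donor-to-donor variation moves the
#' overall level, not the band centres).
#'
#' @inheritParams substance_absorbance
#' @param substrate substrate label, see [substrate_baseline()].
#' @param donor_factor multiplicative baseline scale (1 = nominal).
#' @return reflectance spectrum in (0, 1.2].
#' @export
substance_reflectance <- function(spec, grid, day = 1L,
                                  substrate = "white_tile",
                                  donor_factor = 1) {
  b <- substrate_baseline(grid, substrate)
  donor_factor * b * 10^(-substance_absorbance(spec, grid, day))
}

#' Noise-free blood reflectance for a donor, day, and substrate
#'
#' The donor seed draws a single multiplicative baseline factor in
#' [0.9, 1.1] (donors show level shifts with band centres fixed); the same
#' seed always yields the same spectrum.
#'
#' @param grid wavelength vector (nm).
#' @param day aging day 1-3; later days have shallower alpha/beta dips and
#'   a flatter 600-650 nm slope.
#' @param donor_seed integer identifying the donor.
#' @param substrate substrate label.
#' @return reflectance spectrum (length of `grid`).
#' @export
blood_reflectance <- function(grid, day = 1L, donor_seed = 1L,
                              substrate = "white_tile") {
  if (!day %in% 1:3) stop("day must be 1, 2, or 3")
  spec <- substance_library()$blood
  substance_reflectance(spec, grid, day, substrate,
                        donor_factor = donor_baseline_factor(donor_seed))
}

#' @rdname blood_reflectance
#' @param shift half-width of the donor baseline perturbation (0.1 gives
#'   factors in [0.9, 1.1]; 0 disables donor variation).
#' @export
donor_baseline_factor <- function(donor_seed, shift = 0.1) {
  with_seed(child_seed(donor_seed, "donor"),
            1 + shift * stats::runif(1, -1, 1))
}

#' Depth of a reflectance dip relative to its shoulders
#'
#' Measures how far reflectance at the band centre sits below the linear
#' interpolation between two shoulder wavelengths; used to quantify the
#' alpha (577 nm) and beta (540 nm) oxyhemoglobin dips.
#'
#' @param grid wavelength vector (nm).
#' @param spectrum reflectance values.
#' @param center dip centre (nm).
#' @param shoulders length-2 shoulder wavelengths bracketing the dip.
#' @return non-negative depth (reflectance units); 0 if no dip.
#' @export
dip_depth <- function(grid, spectrum, center,
                      shoulders = center + c(-20, 20)) {
  i <- nearest_band(grid, center)
  l <- nearest_band(grid, shoulders[1])
  r <- nearest_band(grid, shoulders[2])
  w <- (grid[i] - grid[l]) / (grid[r] - grid[l])
  shoulder <- (1 - w) * spectrum[l] + w * spectrum[r]
  max(0, shoulder - spectrum[i])
}
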