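#' Pixel-noise parameters for the synthetic generator
#'
#' Per-pixel variation has three components, emulating the pixel-value
#' spread and baseline shifts seen within real stains: a multiplicative
#' factor `N(1, multiplicative^2)` (illumination/thickness), a constant
#' per-pixel baseline offset `N(0, offset^2)`, and additive heteroscedastic
#' noise `N(0, (additive * R)^2)` per band (shot-like, proportional to
#' signal).
#'
#' @param additive relative SD of additive noise (fraction of reflectance).
#' @param multiplicative SD of the per-pixel multiplicative factor.
#' @param offset SD of the per-pixel baseline offset (reflectance units).
#' @param scale convenience multiplier applied to all three SDs; `scale = 0`
#'   gives noise-free pixels.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(additive = 0.01, multiplicative = 0.03,
                         offset = 0.01, scale = 1) {
  stopifnot(additive >= 0, multiplicative >= 0, offset >= 0, scale >= 0)
  structure(list(additive = additive * scale,
                 multiplicative = multiplicative * scale,
                 offset = offset * scale),
            class = "noise_params")
}

#' Simulate pixel spectra for one stain
#'
#' @param spec [substance_spec()] of the stain substance.
#' @param n number of pixels.
#' @param grid wavelength vector.
#' @param day aging day 1-3.
#' @param substrate substrate label.
#' @param donor_factor baseline factor (see [donor_baseline_factor()]).
#' @param noise [noise_params()].
#' @param seed integer seed; identical seeds give identical pixels.
#' @return `n x length(grid)` reflectance matrix, clipped to (0, 1.2].
#' @keywords internal
simulate_pixels <- function(spec, n, grid, day, substrate, donor_factor,
                            noise = noise_params(), seed = 1L) {
  mu <- substance_reflectance(spec, grid, day, substrate, donor_factor)
  with_seed(seed, {
    mult <- stats::rnorm(n, 1, noise$multiplicative)
    off <- stats::rnorm(n, 0, noise$offset)
    x <- outer(mult, mu) + off
    if (noise$additive > 0) {
      x <- x + matrix(stats::rnorm(n * length(mu), 0, 1), n) *
        rep(noise$additive * mu, each = n)
    }
    pmin(pmax(x, 1e-6), 1.2)
  })
}

#' Background (substrate-only) pixel spectra
#' @keywords internal
simulate_background <- function(n, grid, substrate, noise = noise_params(),
                                seed = 1L) {
  bg <- substance_spec("substrate", "non_blood",
                       data.frame(center = 500, width = 1, depth = 0,
                                  group = "fixed"))
  simulate_pixels(bg, n, grid, 1L, substrate, 1, noise, seed)
}

#' Construct a stain record
#'
#' The unit of sample-based splitting: one stain's pixel spectra plus its
#' labels (class, substance, donor, aging day, substrate, stain id).
#'
#' @param spectra `n x bands` reflectance matrix.
#' @param class `"blood"` or `"non_blood"`.
#' @param substance substance name.
#' @param donor donor id (integer) for blood, `NA` otherwise.
#' @param day aging day.
#' @param substrate substrate label.
#' @param stain_id unique stain identifier.
#' @return object of class `stain_record`.
#' @export
stain_record <- function(spectra, class, substance, donor, day, substrate,
                         stain_id) {
  structure(list(spectra = spectra, class = class, substance = substance,
                 donor = donor, day = day, substrate = substrate,
                 stain_id = stain_id),
            class = "stain_record")
}

#' Flatten stain records into a pixel table
#'
#' @param records list of [stain_record()]s (or a `stain_dataset`).
#' @return list with `spectra` (pixels x bands matrix) and `meta`
#'   (data.frame with class, substance, donor, day, substrate, stain_id per
#'   pixel row).
#' @export
as_pixel_table <- function(records) {
  spectra <- do.call(rbind, lapply(records, function(r) r$spectra))
  meta <- do.call(rbind, lapply(records, function(r) {
    n <- nrow(r$spectra)
    data.frame(class = rep(r$class, n), substance = r$substance,
               donor = r$donor, day = r$day, substrate = r$substrate,
               stain_id = r$stain_id, stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  list(spectra = spectra, meta = meta)
}

#' Generate the full labelled experimental design
#'
#' Emulates the reference sampling campaign: on each of 3 substrates (white cotton
#' fabric, white tile, PVC wall sheet) and each of 3 aging days, 9
#' bloodstains (3 donors x 3 replicates) and 16 non-blood stains (8
#' confuser substances x 2 replicates) — 25 stains per substrate-day,
#' hence 225 stain cubes in total: 81 blood and 144 non-blood. Each stain
#' corresponds to one hypercube cropped to the stain region; here each is
#' represented by its pixel spectra (per-stain pixel counts vary because
#' stain diameters vary).
#'
#' @param seed master seed; fixes donors, diameters, and all pixel noise.
#' @param grid wavelength vector.
#' @param diameter_px range of stain diameters in pixels; the default
#'   yields roughly 150-300 pixels per stain (about 200 on average),
#'   emulating ~1 cm stains after region-of-interest cropping.
#' @param noise [noise_params()].
#' @param donor_shift donor baseline perturbation half-width (see
#'   [donor_baseline_factor()]); 0 makes all donors spectrally identical.
#' @return object of class `stain_dataset`: a list of 225
#'   [stain_record()]s with the generator provenance in attributes.
#' @examples
#' ds <- generate_full_design(seed = 1, diameter_px = c(6, 8))
#' length(ds)                                   # 225
#' sum(vapply(ds, function(r) r$class == "blood", logical(1)))  # 81
#' @export
generate_full_design <- function(seed = 1L, grid = wavelength_grid(),
                                 diameter_px = c(14, 19.5),
                                 noise = noise_params(),
                                 donor_shift = 0.1) {
  lib <- substance_library()
  substrates <- c("white_fabric", "white_tile", "wall_sheet")
  confusers <- setdiff(names(lib), "blood")
  records <- list()
  for (substrate in substrates) {
    for (day in 1:3) {
      for (donor in 1:3) {
        for (rep in 1:3) {
          sid <- sprintf("%s_day%d_blood_donor%d_rep%d",
                         substrate, day, donor, rep)
          records[[sid]] <- make_stain(lib$blood, grid, day, substrate,
                                       donor, sid, seed, diameter_px, noise,
                                       donor_shift)
        }
      }
      for (substance in confusers) {
        for (rep in 1:2) {
          sid <- sprintf("%s_day%d_%s_rep%d", substrate, day, substance, rep)
          records[[sid]] <- make_stain(lib[[substance]], grid, day, substrate,
                                       NA_integer_, sid, seed, diameter_px,
                                       noise)
        }
      }
    }
  }
  structure(records, class = "stain_dataset", grid = grid, seed = seed,
            noise = noise)
}

#' @keywords internal
make_stain <- function(spec, grid, day, substrate, donor, sid, seed,
                       diameter_px, noise, donor_shift = 0.1) {
  s <- child_seed(seed, sid)
  d <- with_seed(child_seed(s, "diam"),
                 stats::runif(1, diameter_px[1], diameter_px[2]))
  n <- disc_area(d)
  donor_factor <- if (!is.na(donor))
    donor_baseline_factor(donor, donor_shift) else 1
  stain_record(simulate_pixels(spec, n, grid, day, substrate, donor_factor,
                               noise, s),
               spec$class, spec$name, donor, day, substrate, sid)
}

#' Number of lattice pixels inside a disc of given diameter
#' @keywords internal
disc_area <- function(diameter) {
  r <- diameter / 2
  k <- floor(r)
  xs <- seq(-k, k)
  sum(outer(xs, xs, function(a, b) a^2 + b^2) <= r^2)
}

#' @export
print.stain_dataset <- function(x, ...) {
  cls <- vapply(x, function(r) r$class, character(1))
  cat("<stain_dataset>", length(x), "stains (",
      sum(cls == "blood"), "blood /", sum(cls == "non_blood"),
      "non-blood ),",
      sum(vapply(x, function(r) nrow(r$spectra), integer(1))), "pixels\n")
  invisible(x)
}

#' Subset a stain dataset by label
#'
#' @param dataset a `stain_dataset`.
#' @param substrate,day optional filters.
#' @return filtered `stain_dataset`.
#' @export
filter_stains <- function(dataset, substrate = NULL, day = NULL) {
  keep <- vapply(dataset, function(r) {
    (is.null(substrate) || r$substrate %in% substrate) &&
      (is.null(day) || r$day %in% day)
  }, logical(1))
  structure(dataset[keep], class = "stain_dataset",
            grid = attr(dataset, "grid"), seed = attr(dataset, "seed"),
            noise = attr(dataset, "noise"))
}

#' Scene design for a rendered hypercube
#'
#' @param substrate substrate label.
#' @param day aging day.
#' @param stains data.frame with columns `substance`, `donor` (NA for
#'   non-blood), `row`, `col` (disc centre, pixels), `diameter` (pixels).
#' @param cube_shape `c(rows, cols)` spatial shape.
#' @return object of class `scene_design`.
#' @export
scene_design <- function(substrate, day, stains, cube_shape) {
  stopifnot(all(c("substance", "donor", "row", "col", "diameter") %in%
                  names(stains)),
            length(cube_shape) == 2)
  r <- stains$diameter / 2
  if (any(stains$row - r < 1 | stains$row + r > cube_shape[1] |
          stains$col - r < 1 | stains$col + r > cube_shape[2])) {
    stop("stain footprint extends outside the cube")
  }
  structure(list(substrate = substrate, day = day, stains = stains,
                 cube_shape = cube_shape),
            class = "scene_design")
}

#' Render a scene design into a hypercube with ground-truth labels
#'
#' Background pixels carry the substrate spectrum plus pixel noise; stain
#' pixels carry their substance spectrum under the same noise model. The
#' label image marks each stain footprint with its row index in
#' `design$stains` (0 = background).
#'
#' @param design a [scene_design()].
#' @param noise [noise_params()].
#' @param seed integer seed.
#' @param grid wavelength vector.
#' @return list with `cube` (a [hypercube()]) and `labels` (integer matrix
#'   rows x cols).
#' @export
render_scene <- function(design, noise = noise_params(), seed = 1L,
                         grid = wavelength_grid()) {
  stopifnot(inherits(design, "scene_design"))
  nr <- design$cube_shape[1]; nc <- design$cube_shape[2]
  labels <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(design$stains))) {
    st <- design$stains[i, ]
    r <- st$diameter / 2
    rows <- max(1, floor(st$row - r)):min(nr, ceiling(st$row + r))
    cols <- max(1, floor(st$col - r)):min(nc, ceiling(st$col + r))
    for (rr in rows) for (cc in cols) {
      if ((rr - st$row)^2 + (cc - st$col)^2 <= r^2) {
        if (labels[rr, cc] != 0L) stop("overlapping stains at (",
                                       rr, ", ", cc, ")")
        labels[rr, cc] <- i
      }
    }
  }
  lib <- substance_library()
  flat <- matrix(NA_real_, nr * nc, length(grid))
  bg_idx <- which(labels == 0L)
  flat[bg_idx, ] <- simulate_background(length(bg_idx), grid,
                                        design$substrate, noise,
                                        child_seed(seed, "background"))
  for (i in seq_len(nrow(design$stains))) {
    st <- design$stains[i, ]
    idx <- which(labels == i)
    donor_factor <- if (!is.na(st$donor)) donor_baseline_factor(st$donor)
                    else 1
    flat[idx, ] <- simulate_pixels(lib[[st$substance]], length(idx), grid,
                                   design$day, design$substrate,
                                   donor_factor, noise,
                                   child_seed(seed, "stain", i))
  }
  cube <- hypercube(array(flat, c(nr, nc, length(grid))), grid,
                    metadata = list(substrate = design$substrate,
                                    day = design$day, seed = seed))
  list(cube = cube, labels = labels)
}

#' Generate a blind-test scene
#'
#' One full-frame scene (410 x 512 x 224 by default) per substrate: two
#' bloodstains from a donor never used in [generate_full_design()]
#' (different aging days), placed in the top row region, plus four
#' non-blood stains drawn from the confuser library. Stain identities and
#' locations are returned as ground truth for scoring only.
#'
#' @param substrate substrate label.
#' @param seed integer seed.
#' @param blind_donor donor id for the unseen donor (the full design uses
#'   donors 1-3).
#' @param cube_shape spatial shape; default `c(410, 512)`.
#' @param diameter_px stain diameter in pixels.
#' @param noise [noise_params()].
#' @param grid wavelength vector.
#' @return list with `cube`, `labels` (integer matrix), and `stains`
#'   (data.frame: id, substance, class, donor, day).
#' @export
generate_blind_scene <- function(substrate, seed = 1L, blind_donor = 4L,
                                 cube_shape = c(410L, 512L),
                                 diameter_px = 20, noise = noise_params(),
                                 grid = wavelength_grid()) {
  stopifnot(!blind_donor %in% 1:3)
  confusers <- setdiff(names(substance_library()), "blood")
  picks <- with_seed(child_seed(seed, "confusers", substrate),
                     sample(confusers, 4))
  nc <- cube_shape[2]
  xs <- round(seq(nc / 7, nc - nc / 7, length.out = 6))
  stains <- data.frame(
    substance = c("blood", "blood", picks),
    donor = c(blind_donor, blind_donor, rep(NA_integer_, 4)),
    row = c(rep(round(cube_shape[1] * 0.18), 2),
            rep(round(cube_shape[1] * 0.65), 4)),
    col = c(xs[c(2, 5)], xs[c(1, 3, 4, 6)]),
    diameter = diameter_px,
    day = c(1L, 3L, rep(1L, 4)),
    stringsAsFactors = FALSE)
  # render day-by-day so the two blood stains can carry different aging
  nr <- cube_shape[1]
  labels <- matrix(0L, nr, cube_shape[2])
  flat <- matrix(NA_real_, nr * cube_shape[2], length(grid))
  bg_idx <- seq_len(nr * cube_shape[2])
  lib <- substance_library()
  for (i in seq_len(nrow(stains))) {
    st <- stains[i, ]
    r <- st$diameter / 2
    rows <- floor(st$row - r):ceiling(st$row + r)
    cols <- floor(st$col - r):ceiling(st$col + r)
    for (rr in rows) for (cc in cols) {
      if ((rr - st$row)^2 + (cc - st$col)^2 <= r^2) labels[rr, cc] <- i
    }
    idx <- which(labels == i)
    donor_factor <- if (!is.na(st$donor)) donor_baseline_factor(st$donor)
                    else 1
    flat[idx, ] <- simulate_pixels(lib[[st$substance]], length(idx), grid,
                                   st$day, substrate, donor_factor, noise,
                                   child_seed(seed, "blind", substrate, i))
  }
  bg_idx <- which(labels == 0L)
  flat[bg_idx, ] <- simulate_background(length(bg_idx), grid, substrate,
                                        noise,
                                        child_seed(seed, "blindbg",
                                                   substrate))
  cube <- hypercube(array(flat, c(nr, cube_shape[2], length(grid))), grid,
                    metadata = list(substrate = substrate, blind = TRUE,
                                    seed = seed))
  stains$id <- sprintf("%s_blind_%d_%s", substrate, seq_len(nrow(stains)),
                       stains$substance)
  stains$class <- ifelse(stains$substance == "blood", "blood", "non_blood")
  list(cube = cube, labels = labels, stains = stains)
}

#' Write a stain-dataset manifest
#'
#' One CSV row per stain: id, class, substance, donor, day, substrate, and
#' pixel count.
#'
#' @param dataset a `stain_dataset`.
#' @param path output CSV path.
#' @return the manifest data.frame, invisibly.
#' @export
write_manifest <- function(dataset, path) {
  m <- do.call(rbind, lapply(dataset, function(r) {
    data.frame(stain_id = r$stain_id, class = r$class,
               substance = r$substance, donor = r$donor, day = r$day,
               substrate = r$substrate, n_pixels = nrow(r$spectra),
               stringsAsFactors = FALSE)
  }))
  rownames(m) <- NULL
  utils::write.csv(m, path, row.names = FALSE)
  invisible(m)
}
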