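test_that("substance library has one blood and eight red confusers", {
  lib <- substance_library()
  expect_length(lib, 9)
  expect_equal(sum(vapply(lib, function(s) s$class == "blood",
                          logical(1))), 1)
  expect_true(lib$blood$class == "blood")
  # confusers absorb strongly somewhere below 600 nm (red-hued)
  for (nm in setdiff(names(lib), "blood")) {
    a <- substance_absorbance(lib[[nm]], grid224)
    expect_gt(max(a[grid224 < 600]), 0.4, label = nm)
  }
  # at least two confusers carry a faint NIR trough near 925 nm
  n_trough <- sum(vapply(lib, function(s) isTRUE(s$has_nir_trough),
                         logical(1)))
  expect_gte(n_trough, 2)
})

test_that("blood has local reflectance minima at the alpha and beta bands", {
  r <- blood_reflectance(grid224, day = 1, donor_seed = 1)
  for (target in c(540, 577)) {
    i <- nearest_band(grid224, target)
    expect_lt(r[i], r[i - 2])
    expect_lt(r[i], r[i + 2])
  }
  # Soret band is the deepest absorbance feature
  a <- substance_absorbance(substance_library()$blood, grid224)
  expect_equal(grid224[which.max(a)], 415, tolerance = 3)
})

test_that("rust acrylic paint shows a reflectance hump near 510 nm", {
  r <- substance_reflectance(substance_library()$rust_acrylic_paint,
                             grid224)
  w <- which(grid224 >= 500 & grid224 <= 520)
  i <- w[which.max(r[w])]
  expect_gt(r[i], r[i - 4])
  expect_gt(r[i], r[i + 4])
})

test_that("aging shrinks alpha/beta dips and the 600-650 nm slope", {
  for (donor in c(1L, 5L)) {
    b <- lapply(1:3, function(d) blood_reflectance(grid224, d, donor))
    alpha <- vapply(b, function(x) dip_depth(grid224, x, 577), numeric(1))
    beta <- vapply(b, function(x) dip_depth(grid224, x, 540), numeric(1))
    expect_true(all(diff(alpha) < 0))
    expect_true(all(diff(beta) < 0))
    seg <- grid224 >= 600 & grid224 <= 650
    slopes <- vapply(b, function(x) {
      unname(stats::coef(stats::lm(x[seg] ~ grid224[seg]))[2])
    }, numeric(1))
    expect_true(all(slopes > 0))
    expect_true(all(diff(slopes) < 0))
  }
})

test_that("fitted 600-650 nm slope matches the generating model's closed form", {
  # oracle: analytic least-squares slope computed from the model equation
  # directly (Gaussian-band absorbance -> reflectance), independent of the
  # generator's code path for days/donors
  spec <- substance_library()$blood
  seg <- which(grid224 >= 600 & grid224 <= 650)
  x <- grid224[seg]
  oracle_slope <- function(day) {
    a <- numeric(length(x))
    for (i in seq_len(nrow(spec$bands))) {
      b <- spec$bands[i, ]
      a <- a + spec$aging_model[[b$group]][day] * b$depth *
        exp(-(x - b$center)^2 / (2 * b$width^2))
    }
    baseline <- 0.92 - 0.02 * (x - 397) / (1003 - 397)
    y <- baseline * 10^(-a)
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  for (day in 1:3) {
    r <- substance_reflectance(spec, grid224, day, "white_tile")
    fit <- unname(stats::coef(stats::lm(r[seg] ~ grid224[seg]))[2])
    expect_equal(fit, oracle_slope(day), tolerance = 1e-10)
  }
})

test_that("generation is deterministic under a fixed seed", {
  r1 <- blood_reflectance(grid224, 2, donor_seed = 7, "white_fabric")
  r2 <- blood_reflectance(grid224, 2, donor_seed = 7, "white_fabric")
  expect_identical(r1, r2)
  d1 <- generate_full_design(seed = 5, diameter_px = c(5, 6))
  d2 <- generate_full_design(seed = 5, diameter_px = c(5, 6))
  expect_identical(d1, d2)
  expect_error(blood_reflectance(grid224, 4, 1), "day")
})

test_that("white fabric is darker than tile and wall sheet", {
  expect_true(all(substrate_baseline(grid224, "white_fabric") <
                    substrate_baseline(grid224, "white_tile")))
  expect_true(all(substrate_baseline(grid224, "white_fabric") <
                    substrate_baseline(grid224, "wall_sheet")))
})

test_that("all generated reflectances are finite and inside (0, 1.2]", {
  px <- small_pixels()
  expect_false(anyNA(px$spectra))
  expect_true(all(px$spectra > 0))
  expect_true(all(px$spectra <= 1.2))
})

test_that("full design reproduces the experimental-design counts", {
  ds <- small_design()
  expect_length(ds, 225)
  cls <- vapply(ds, function(r) r$class, character(1))
  expect_equal(sum(cls == "blood"), 81)
  expect_equal(sum(cls == "non_blood"), 144)
  meta <- small_pixels()$meta
  stains <- unique(meta[, c("substrate", "day", "class", "stain_id")])
  tab <- table(stains$substrate, stains$day)
  expect_true(all(tab == 25))  # 9 blood + 16 non-blood per substrate-day
  # per-stain pixel counts vary
  expect_gt(length(unique(table(meta$stain_id))), 1)
})

test_that("rendered scenes honour noise, footprints, and overlap rules", {
  des <- two_stain_design()
  sc0 <- render_scene(des, noise = noise_params(scale = 0), seed = 1)
  # zero noise: every pixel of a stain has the identical spectrum
  for (k in 1:2) {
    px <- matrix(sc0$cube$data, prod(dim(sc0$cube$data)[1:2]), 224)[
      which(sc0$labels == k), ]
    expect_equal(max(apply(px, 2, function(v) diff(range(v)))), 0)
  }
  # label footprint equals the rendered disc area
  expect_equal(sum(sc0$labels == 1), disc_area_oracle(9))
  # overlapping stains refuse to render
  bad <- scene_design("white_tile", 1,
                      data.frame(substance = c("blood", "red_ink"),
                                 donor = c(1L, NA), row = c(15, 15),
                                 col = c(15, 18), diameter = 9),
                      cube_shape = c(30L, 40L))
  expect_error(render_scene(bad), "overlap")
  # footprint outside the cube refuses to construct
  expect_error(scene_design("white_tile", 1,
                            data.frame(substance = "blood", donor = 1L,
                                       row = 2, col = 15, diameter = 9),
                            cube_shape = c(30L, 40L)),
               "outside")
})

test_that("stain means converge to the model spectrum across seeds", {
  des <- two_stain_design()
  mu <- substance_reflectance(substance_library()$blood, grid224, 1,
                              "white_tile", donor_baseline_factor(1))
  means <- sapply(1:20, function(s) {
    sc <- render_scene(des, seed = s)
    colMeans(matrix(sc$cube$data, prod(dim(sc$cube$data)[1:2]), 224)[
      which(sc$labels == 1), ])
  })
  mc_err <- abs(rowMeans(means) - mu)
  # mean over 20 seeds x ~60 px: Monte-Carlo error ~ sd/sqrt(1200)
  expect_lt(max(mc_err / mu), 0.01)
})

test_that("blind scenes carry 2 unseen-donor blood and 4 non-blood stains", {
  sc <- generate_blind_scene("white_tile", seed = 3,
                             cube_shape = c(120L, 160L), diameter_px = 10)
  expect_equal(sum(sc$stains$class == "blood"), 2)
  expect_equal(sum(sc$stains$class == "non_blood"), 4)
  expect_true(all(sc$stains$donor[sc$stains$class == "blood"] == 4))
  expect_false(any(sc$stains$donor %in% 1:3))
  # truth labels partition all stain pixels between the six stains
  expect_equal(sort(unique(as.vector(sc$labels))), 0:6)
  for (i in 1:6) expect_gt(sum(sc$labels == i), 0)
  # the two blood stains sit in the top region, with different aging
  blood <- sc$stains[sc$stains$class == "blood", ]
  expect_true(all(blood$row < 120 * 0.5))
  expect_equal(sort(blood$day), c(1L, 3L))
})

test_that("second-derivative spectra separate blood from every confuser", {
  # premise of the band-selection criterion: with default noise, the mean
  # derivative spectra of blood and each confuser differ by > 5 SE
  # somewhere in 470-770 nm
  px <- small_pixels()
  f <- sg_filter_matrix(224, sg_spec(13, 3, 2), mean(diff(grid224)))
  d2 <- px$spectra %*% t(f)
  w <- which(grid224 >= 470 & grid224 <= 770)
  day1 <- px$meta$day == 1
  blood <- d2[day1 & px$meta$class == "blood", w]
  mb <- colMeans(blood)
  vb <- apply(blood, 2, stats::var) / nrow(blood)
  for (nm in setdiff(names(substance_library()), "blood")) {
    conf <- d2[day1 & px$meta$substance == nm, w]
    se <- sqrt(vb + apply(conf, 2, stats::var) / nrow(conf))
    z <- abs(mb - colMeans(conf)) / se
    expect_gt(max(z), 5, label = paste("blood vs", nm))
  }
})

test_that("manifest records one labelled row per stain", {
  ds <- small_design()
  path <- withr::local_tempfile(fileext = ".csv")
  m <- write_manifest(ds, path)
  expect_equal(nrow(m), 225)
  back <- utils::read.csv(path)
  expect_equal(back$stain_id, m$stain_id)
  expect_equal(sum(back$class == "blood"), 81)
})
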