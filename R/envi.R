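#' Hypercube container
#'
#' A hypercube couples a 3-D array (rows x cols x bands; rows are scan
#' lines, cols are across-track samples) with its wavelength grid and
#' free-form acquisition metadata. Values are reflectance after
#' calibration, or encoded radiance before.
#'
#' @param data numeric 3-D array, `dim = c(rows, cols, bands)`.
#' @param wavelength numeric band centres (nm), length = bands.
#' @param metadata named list of provenance key-values.
#' @return object of class `hypercube`.
#' @export
hypercube <- function(data, wavelength, metadata = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            dim(data)[3] == length(wavelength))
  structure(list(data = data, wavelength = as.numeric(wavelength),
                 metadata = metadata),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1], d[2], d[3], min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

envi_dtype <- function(code) {
  # ENVI data type -> (what, size, mode)
  switch(as.character(code),
         "1" = list(what = "integer", size = 1L, signed = FALSE),
         "2" = list(what = "integer", size = 2L, signed = TRUE),
         "3" = list(what = "integer", size = 4L, signed = TRUE),
         "4" = list(what = "numeric", size = 4L, signed = TRUE),
         "5" = list(what = "numeric", size = 8L, signed = TRUE),
         "12" = list(what = "integer", size = 2L, signed = FALSE),
         stop("unsupported ENVI data type: ", code))
}

#' Parse an ENVI header file
#'
#' Handles `key = value` pairs and brace-delimited multi-line blocks
#' (`wavelength = {...}`).
#'
#' @param header_path path to the `.hdr` text file.
#' @return named list of header fields (values as strings or numeric
#'   vectors for brace blocks).
#' @export
read_envi_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^ENVI", lines[1])) {
    stop("not an ENVI header (missing ENVI magic): ", header_path)
  }
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  rx <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                 txt, perl = TRUE)[[1]]
  starts <- as.integer(rx)
  lens <- attr(rx, "match.length")
  for (i in seq_along(starts)) {
    if (starts[i] < 0) next
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    key <- trimws(sub("=.*$", "", piece))
    val <- trimws(sub("^[^=]*=", "", piece))
    if (grepl("^\\{", val)) {
      val <- gsub("[{}]", "", val)
      val <- trimws(strsplit(val, ",")[[1]])
      num <- suppressWarnings(as.numeric(val))
      if (!anyNA(num)) val <- num
    }
    out[[tolower(key)]] <- val
  }
  out
}

#' Read an ENVI hypercube
#'
#' Accepts the three standard interleaves (bil, bip, bsq); the wavelength
#' block in the header becomes the cube's grid.
#'
#' @param header_path path to the `.hdr` file.
#' @param data_path path to the flat binary file; defaults to
#'   `header_path` without the `.hdr` extension.
#' @return a [hypercube()].
#' @export
read_envi <- function(header_path, data_path = sub("\\.hdr$", "",
                                                   header_path)) {
  h <- read_envi_header(header_path)
  for (k in c("samples", "lines", "bands", "data type", "interleave")) {
    if (is.null(h[[k]])) stop("ENVI header missing required key: ", k)
  }
  if (is.null(h[["wavelength"]])) {
    stop("ENVI header missing required key: wavelength")
  }
  samples <- as.integer(h$samples); lines <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  interleave <- tolower(h$interleave)
  if (!interleave %in% c("bil", "bip", "bsq")) {
    stop("unsupported interleave: ", interleave)
  }
  dt <- envi_dtype(h[["data type"]])
  endian <- if (identical(trimws(h[["byte order"]] %||% "0"), "1"))
    "big" else "little"
  n <- samples * lines * bands
  expected <- n * dt$size + as.integer(h[["header offset"]] %||% 0)
  actual <- file.size(data_path)
  if (is.na(actual) || actual < expected) {
    stop("ENVI data file size mismatch: expected >= ", expected,
         " bytes, found ", actual, " (", data_path, ")")
  }
  con <- file(data_path, "rb")
  on.exit(close(con))
  off <- as.integer(h[["header offset"]] %||% 0)
  if (off > 0) readBin(con, "raw", off)
  raw <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                 endian = endian)
  arr <- switch(interleave,
                bsq = aperm(array(raw, c(samples, lines, bands)), c(2, 1, 3)),
                bil = aperm(array(raw, c(samples, bands, lines)), c(3, 1, 2)),
                bip = aperm(array(raw, c(bands, samples, lines)), c(3, 2, 1)))
  wl <- as.numeric(h$wavelength)
  if (length(wl) != bands) {
    stop("wavelength block length (", length(wl),
         ") does not match bands (", bands, ")")
  }
  hypercube(arr, wl, metadata = list(source = data_path,
                                     interleave = interleave))
}

#' Write a hypercube as ENVI header + flat binary
#'
#' Emits `ENVI` magic, `data type = 4` (float32), `byte order = 0`, and the
#' wavelength list in nm.
#'
#' @param cube a [hypercube()].
#' @param data_path output binary path; the header is written to
#'   `paste0(data_path, ".hdr")`.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @return `data_path`, invisibly.
#' @export
write_envi <- function(cube, data_path, interleave = c("bil", "bip", "bsq")) {
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  hdr <- c("ENVI",
           "description = {synthetic hypercube}",
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           paste0("interleave = ", interleave),
           "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = {",
                  paste(format(cube$wavelength, trim = TRUE), collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(data_path, ".hdr"))
  arr <- switch(interleave,
                bsq = aperm(cube$data, c(2, 1, 3)),
                bil = aperm(cube$data, c(2, 3, 1)),
                bip = aperm(cube$data, c(3, 2, 1)))
  con <- file(data_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(data_path)
}

#' Average reference line-frames
#'
#' A pushbroom scanner records dark and white references as repeated
#' line-frames (columns x bands); the calibration reference is their
#' per-pixel, per-band arithmetic mean.
#'
#' @param frames either a `frames x cols x bands` array or a list of
#'   `cols x bands` matrices.
#' @return a single `cols x bands` matrix.
#' @export
average_reference <- function(frames) {
  if (is.list(frames)) {
    stopifnot(length(frames) >= 1)
    return(Reduce(`+`, frames) / length(frames))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3, dim(frames)[1] >= 1)
  apply(frames, c(2, 3), mean)
}

#' Raw pushbroom capture awaiting calibration
#'
#' @param specimen radiance [hypercube()] (rows x cols x bands).
#' @param dark_frames,white_frames reference captures: `frames x cols x
#'   bands` arrays (or pre-averaged `cols x bands` matrices).
#' @return object of class `raw_capture`.
#' @export
raw_capture <- function(specimen, dark_frames, white_frames) {
  stopifnot(inherits(specimen, "hypercube"))
  norm <- function(x) if (is.matrix(x)) x else average_reference(x)
  dark <- norm(dark_frames); white <- norm(white_frames)
  d <- dim(specimen$data)
  stopifnot(all(dim(dark) == c(d[2], d[3])),
            all(dim(white) == c(d[2], d[3])))
  structure(list(specimen = specimen, dark = dark, white = white),
            class = "raw_capture")
}

#' Empirical-line reflectance calibration
#'
#' Converts encoded radiance to reflectance per pixel and band:
#' `R = (S - D) / (W - D)` with the averaged dark (`D`) and white (`W`)
#' reference lines broadcast along the scan axis (one reference value per
#' across-track column and band, as a line scanner provides). The ratio is
#' invariant to any common affine re-encoding of the three signals.
#' Out-of-range values are clipped to `clip` and the clipped count recorded
#' in the result metadata.
#'
#' @param raw a [raw_capture()].
#' @param clip length-2 retention range for reflectance.
#' @return reflectance [hypercube()]; `metadata$n_clipped` counts clipped
#'   values.
#' @export
calibrate_reflectance <- function(raw, clip = c(-0.05, 1.5)) {
  stopifnot(inherits(raw, "raw_capture"))
  denom <- raw$white - raw$dark
  bad <- which(denom == 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("zero white-dark denominator at column/band pairs: ",
         paste(sprintf("(%d,%d)", bad[, 1], bad[, 2])[seq_len(min(5,
               nrow(bad)))], collapse = " "))
  }
  d <- dim(raw$specimen$data)
  s <- matrix(aperm(raw$specimen$data, c(2, 3, 1)), d[2] * d[3], d[1])
  refl <- (s - as.vector(raw$dark)) / as.vector(denom)
  n_clipped <- sum(refl < clip[1] | refl > clip[2])
  refl <- pmin(pmax(refl, clip[1]), clip[2])
  arr <- aperm(array(refl, c(d[2], d[3], d[1])), c(3, 1, 2))
  meta <- raw$specimen$metadata
  meta$n_clipped <- n_clipped
  meta$calibration <- "empirical_line"
  hypercube(arr, raw$specimen$wavelength, meta)
}
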