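#' Select wavelength bands in a closed interval
#'
#' The derivative spectra of blood and the red confusers differ most
#' prominently between 470 and 770 nm, so that range is the default
#' feature window for classification.
#'
#' @param grid wavelength vector (nm).
#' @param lower,upper interval bounds in nm (closed interval).
#' @return object of class `band_selection`: list with `lower`, `upper`,
#'   and sorted `indices` into `grid`.
#' @examples
#' sel <- select_bands(wavelength_grid())
#' length(sel$indices)  # ~110 bands between 470 and 770 nm
#' @export
select_bands <- function(grid, lower = 470, upper = 770) {
  stopifnot(lower < upper)
  idx <- which(grid >= lower & grid <= upper)
  if (length(idx) == 0) {
    stop("no band centres inside [", lower, ", ", upper, "] nm")
  }
  structure(list(lower = lower, upper = upper, indices = sort(idx),
                 centers = grid[sort(idx)]),
            class = "band_selection")
}

#' @export
print.band_selection <- function(x, ...) {
  cat(sprintf("<band_selection> %d bands in [%g, %g] nm\n",
              length(x$indices), x$lower, x$upper))
  invisible(x)
}

#' Feature table: observations x features with per-pixel labels
#'
#' @param x numeric matrix, observations x features.
#' @param meta data.frame of per-observation labels (class, substance,
#'   donor, day, substrate, stain_id).
#' @param feature_info character vector naming each feature (band nm or PC
#'   index).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(x, meta, feature_info = colnames(x)) {
  stopifnot(is.matrix(x), nrow(x) == nrow(meta), !anyNA(x))
  structure(list(x = x, meta = meta,
                 feature_info = feature_info %||%
                   paste0("f", seq_len(ncol(x)))),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d observations x %d features\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Pipeline specification for feature construction
#'
#' @param snv,msc logical: apply SNV / MSC before filtering.
#' @param sg an [sg_spec()] or `NULL` to skip filtering. The
#'   identification pipeline uses the second derivative (13-point,
#'   order 3).
#' @param bands a [select_bands()] selection or `NULL` for all bands.
#' @param pca integer number of principal components, or `NULL`. When set,
#'   PCA replaces band selection as the feature reducer.
#' @param normalize min-max normalize features to [0, 1] using
#'   training-row statistics.
#' @return list of class `pipeline_spec`.
#' @export
pipeline_spec <- function(snv = FALSE, msc = FALSE,
                          sg = sg_spec(13, 3, 2), bands = NULL,
                          pca = NULL, normalize = TRUE) {
  structure(list(snv = snv, msc = msc, sg = sg, bands = bands, pca = pca,
                 normalize = normalize),
            class = "pipeline_spec")
}

#' Build a normalized feature table from pixel spectra
#'
#' Applies the configured pre-treatment per pixel spectrum (SNV and/or
#' MSC, then the Savitzky-Golay pass over the full grid so band-edge
#' artefacts never reach the selected window), selects features (band
#' window or principal components), and min-max normalizes each feature to
#' [0, 1] using statistics from the training rows only — held-out rows may
#' fall outside [0, 1].
#'
#' @param pixels a pixel table from [as_pixel_table()] (list with
#'   `spectra` and `meta`).
#' @param grid wavelength vector matching the spectra columns.
#' @param pipeline a [pipeline_spec()].
#' @param train_rows integer indices of training rows used for
#'   normalization and PCA fitting; defaults to all rows.
#' @return a [feature_table()]; attributes `normalization` and `pca`
#'   record the fitted statistics for reuse via [apply_pipeline()].
#' @export
build_feature_table <- function(pixels, grid, pipeline = pipeline_spec(),
                                train_rows = NULL) {
  x <- pixels$spectra
  stopifnot(ncol(x) == length(grid))
  train_rows <- train_rows %||% seq_len(nrow(x))
  x <- pretreat(x, grid, pipeline)
  pca_fit <- NULL
  if (!is.null(pipeline$pca)) {
    pca_fit <- fit_pca(x[train_rows, , drop = FALSE], pipeline$pca)
    x <- project_pca(pca_fit, x)
    info <- paste0("PC", seq_len(ncol(x)))
  } else if (!is.null(pipeline$bands)) {
    x <- x[, pipeline$bands$indices, drop = FALSE]
    info <- sprintf("%.1fnm", pipeline$bands$centers)
  } else {
    info <- sprintf("%.1fnm", grid)
  }
  norm <- NULL
  if (isTRUE(pipeline$normalize)) {
    norm <- list(min = apply(x[train_rows, , drop = FALSE], 2, min),
                 max = apply(x[train_rows, , drop = FALSE], 2, max))
    rng <- pmax(norm$max - norm$min, 1e-12)
    x <- sweep(sweep(x, 2, norm$min), 2, rng, "/")
  }
  ft <- feature_table(x, pixels$meta, info)
  attr(ft, "normalization") <- norm
  attr(ft, "pca") <- pca_fit
  attr(ft, "pipeline") <- pipeline
  attr(ft, "grid") <- grid
  ft
}

#' @keywords internal
pretreat <- function(x, grid, pipeline) {
  if (isTRUE(pipeline$snv)) x <- snv(x)
  if (isTRUE(pipeline$msc)) x <- msc(x)
  if (!is.null(pipeline$sg)) {
    x <- sg_filter_rows(x, pipeline$sg, spacing = mean(diff(grid)))
  }
  x
}

#' Apply a fitted feature pipeline to new pixel spectra
#'
#' Re-uses the pre-treatment, PCA projection, and min-max statistics
#' fitted by [build_feature_table()] so held-out or blind-scene pixels are
#' transformed exactly as the training pixels were.
#'
#' @param fitted a [feature_table()] returned by [build_feature_table()].
#' @param spectra new pixels x bands matrix.
#' @return feature matrix for the new pixels.
#' @export
apply_pipeline <- function(fitted, spectra) {
  pipeline <- attr(fitted, "pipeline")
  grid <- attr(fitted, "grid")
  x <- pretreat(spectra, grid, pipeline)
  if (!is.null(attr(fitted, "pca"))) {
    x <- project_pca(attr(fitted, "pca"), x)
  } else if (!is.null(pipeline$bands)) {
    x <- x[, pipeline$bands$indices, drop = FALSE]
  }
  norm <- attr(fitted, "normalization")
  if (!is.null(norm)) {
    rng <- pmax(norm$max - norm$min, 1e-12)
    x <- sweep(sweep(x, 2, norm$min), 2, rng, "/")
  }
  x
}

#' @keywords internal
fit_pca <- function(x, n_components) {
  stopifnot(n_components <= min(dim(x)))
  if (all(apply(x, 2, stats::sd) < 1e-12)) stop("zero-variance input to PCA")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  ev <- p$sdev^2
  list(center = p$center, rotation = p$rotation,
       explained_variance = ev[seq_len(n_components)] / sum(ev))
}

#' @keywords internal
project_pca <- function(fit, x) {
  sweep(x, 2, fit$center) %*% fit$rotation
}

#' Reduce a feature table to its leading principal components
#'
#' Mean-centred projection onto the top principal axes, fitted on training
#' rows only; the returned table records explained-variance fractions and
#' the projection is reusable on held-out rows via [apply_pipeline()] when
#' used inside [build_feature_table()].
#'
#' @param ft a [feature_table()].
#' @param n_components number of components.
#' @param train_rows rows used to fit the projection (default all).
#' @return a [feature_table()] of scores with attribute `pca` holding the
#'   fit (centre, rotation, explained variance).
#' @export
pca_reduce <- function(ft, n_components = 3L, train_rows = NULL) {
  train_rows <- train_rows %||% seq_len(nrow(ft$x))
  fit <- fit_pca(ft$x[train_rows, , drop = FALSE], n_components)
  out <- feature_table(project_pca(fit, ft$x), ft$meta,
                       paste0("PC", seq_len(n_components)))
  attr(out, "pca") <- fit
  out
}
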