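#' Fit and score one split/pipeline/model combination
#'
#' @param pixels pixel table ([as_pixel_table()]).
#' @param grid wavelength vector.
#' @param plan a `split_plan`.
#' @param pipeline a [pipeline_spec()].
#' @param spec a [model_spec()].
#' @param label_col metadata column used as the class label.
#' @return list with `model`, `report` (external-test
#'   [compute_metrics()]), `internal_report`, and the fitted
#'   `feature_table`.
#' @export
fit_and_score <- function(pixels, grid, plan, pipeline, spec,
                          label_col = "class") {
  ft <- build_feature_table(pixels, grid, pipeline,
                            train_rows = plan$train)
  y <- pixels$meta[[label_col]]
  model <- train_model(spec,
                       ft$x[plan$train, , drop = FALSE], y[plan$train],
                       ft$x[plan$internal_val, , drop = FALSE],
                       y[plan$internal_val])
  classes <- sort(unique(y))
  score <- function(rows) {
    pred <- predict(model, ft$x[rows, , drop = FALSE])
    compute_metrics(confusion(y[rows], as.character(pred), classes))
  }
  list(model = model, report = score(plan$external_test),
       internal_report = score(plan$internal_val), features = ft)
}

#' Binary blood vs. non-blood experiment
#'
#' Runs the identification pipeline per substrate (derivative features,
#' 470-770 nm, min-max normalization by default), splits by the chosen
#' scheme, trains every requested model family, and scores the external
#' test partition.
#'
#' @param dataset a `stain_dataset` from [generate_full_design()].
#' @param scheme `"sample_based"` or `"pixel_based"`.
#' @param pipeline a [pipeline_spec()]; the default is the identification
#'   pipeline (SG second derivative, 13-point window, order 3, 470-770 nm
#'   bands, min-max normalization).
#' @param model_specs named list of [model_spec()]s.
#' @param substrates substrates to run; `NULL` pools all substrates into
#'   one run (reported as substrate `"all"`).
#' @param seed split seed.
#' @return list with `table` (one [metrics_row()] per substrate x model)
#'   and `runs` (the fitted objects, keyed `substrate.model`).
#' @export
run_binary_experiment <- function(dataset,
                                  scheme = c("sample_based", "pixel_based"),
                                  pipeline = NULL, model_specs = NULL,
                                  substrates = c("white_fabric",
                                                 "white_tile",
                                                 "wall_sheet"),
                                  seed = 1L) {
  scheme <- match.arg(scheme)
  grid <- attr(dataset, "grid")
  pipeline <- pipeline %||%
    pipeline_spec(sg = sg_spec(13, 3, 2), bands = select_bands(grid))
  model_specs <- model_specs %||% default_model_specs(seed)
  groups <- if (is.null(substrates)) list(all = dataset)
            else {
              g <- lapply(substrates, function(s) filter_stains(dataset, s))
              names(g) <- substrates
              g
            }
  rows <- list(); runs <- list()
  for (s in names(groups)) {
    pixels <- as_pixel_table(groups[[s]])
    splitter <- if (scheme == "sample_based") split_sample_based
                else split_pixel_based
    plan <- splitter(pixels$meta, seed = child_seed(seed, "split", s))
    for (m in names(model_specs)) {
      res <- fit_and_score(pixels, grid, plan, pipeline, model_specs[[m]])
      rows[[paste(s, m)]] <- metrics_row(res$report, substrate = s,
                                         model = m, scheme = scheme,
                                         n_features = ncol(res$features$x))
      runs[[paste(s, m, sep = ".")]] <- res
    }
  }
  list(table = do.call(rbind, rows), runs = runs)
}

#' Multi-class experiment: donors and substances as separate classes
#'
#' Eleven classes (3 blood donors + 8 confuser substances) on the
#' requested aging day, using full-spectrum (all 224 bands) derivative
#' features. Reports overall accuracy, average accuracy (macro recall),
#' and Cohen's kappa per model.
#'
#' @param dataset a `stain_dataset`.
#' @param day aging day subset (1-3).
#' @param pipeline defaults to the derivative pipeline on the full grid.
#' @param model_specs named list of [model_spec()]s.
#' @param scheme splitting scheme.
#' @param seed split seed.
#' @return list with `table` (model, OA, AA, kappa) and `runs`.
#' @export
run_multiclass_experiment <- function(dataset, day = 1L, pipeline = NULL,
                                      model_specs = NULL,
                                      scheme = "sample_based", seed = 1L) {
  grid <- attr(dataset, "grid")
  pipeline <- pipeline %||% pipeline_spec(sg = sg_spec(13, 3, 2))
  model_specs <- model_specs %||% default_model_specs(seed)
  subset <- filter_stains(dataset, day = day)
  pixels <- as_pixel_table(subset)
  pixels$meta$multiclass <- ifelse(
    pixels$meta$class == "blood",
    paste0("donor_", pixels$meta$donor), pixels$meta$substance)
  if (length(unique(pixels$meta$multiclass)) != 11) {
    stop("expected 11 classes (3 donors + 8 substances), found ",
         length(unique(pixels$meta$multiclass)))
  }
  splitter <- if (scheme == "sample_based") split_sample_based
              else split_pixel_based
  plan <- splitter(pixels$meta, seed = child_seed(seed, "mc"))
  rows <- list(); runs <- list()
  for (m in names(model_specs)) {
    res <- fit_and_score(pixels, grid, plan, pipeline, model_specs[[m]],
                         label_col = "multiclass")
    rows[[m]] <- data.frame(model = m, n_features = ncol(res$features$x),
                            oa = res$report$oa, aa = res$report$aa,
                            kappa = res$report$kappa)
    runs[[m]] <- res
  }
  list(table = do.call(rbind, rows), runs = runs)
}

#' Train the identification pipeline on a full dataset
#'
#' Convenience wrapper used ahead of blind testing: fits the feature
#' pipeline and one classifier on all pixels of `dataset` (with an
#' internal-validation split for k-NN tuning).
#'
#' @param dataset a `stain_dataset`.
#' @param spec a [model_spec()].
#' @param pipeline a [pipeline_spec()]; default as in
#'   [run_binary_experiment()].
#' @param seed split seed for the internal-validation holdout.
#' @return list with `model` and fitted `features` (for
#'   [apply_pipeline()]).
#' @export
train_full <- function(dataset, spec = model_spec("svm_linear"),
                       pipeline = NULL, seed = 1L) {
  grid <- attr(dataset, "grid")
  pipeline <- pipeline %||%
    pipeline_spec(sg = sg_spec(13, 3, 2), bands = select_bands(grid))
  pixels <- as_pixel_table(dataset)
  plan <- split_pixel_based(pixels$meta, train_frac = 1,
                            internal_frac = 0.2,
                            seed = child_seed(seed, "trainfull"))
  ft <- build_feature_table(pixels, grid, pipeline,
                            train_rows = plan$train)
  y <- pixels$meta$class
  model <- train_model(spec, ft$x[plan$train, , drop = FALSE],
                       y[plan$train],
                       ft$x[plan$internal_val, , drop = FALSE],
                       y[plan$internal_val])
  list(model = model, features = ft)
}

#' Blind-scene prediction and blood extraction rate
#'
#' Extracts stain regions from a blind scene (thresholding at 540 nm),
#' classifies every stain pixel with a trained model, renders a
#' prediction map, and calls each detected stain by majority vote over
#' its pixels. The blood extraction rate is the fraction of ground-truth
#' blood stains whose majority-vote call is blood.
#'
#' @param trained result of [train_full()] (model + fitted pipeline).
#' @param scene result of [generate_blind_scene()] (or a list with `cube`
#'   and optionally `labels`/`stains` for scoring).
#' @param roi_wavelength segmentation wavelength (nm).
#' @return list with `map` (character matrix: `"background"`, `"blood"`,
#'   `"non_blood"`), `calls` (per detected stain: majority label and pixel
#'   votes), and `extraction_rate` (NA if the scene holds no truth blood
#'   stains or the mask is empty).
#' @export
run_blind_test <- function(trained, scene, roi_wavelength = 540) {
  cube <- scene$cube
  roi <- extract_roi(cube, roi_wavelength)
  map <- matrix("background", nrow(roi$mask), ncol(roi$mask))
  if (roi$n_stains == 0) {
    warning("no stains detected; extraction rate undefined")
    return(list(map = map, calls = NULL, extraction_rate = NA_real_))
  }
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  idx <- which(roi$mask)
  feats <- apply_pipeline(trained$features, flat[idx, , drop = FALSE])
  pred <- as.character(predict(trained$model, feats))
  map[idx] <- pred
  comp <- roi$components[idx]
  calls <- do.call(rbind, lapply(seq_len(roi$n_stains), function(k) {
    votes <- pred[comp == k]
    data.frame(stain = k, n_pixels = length(votes),
               blood_votes = sum(votes == "blood"),
               call = names(sort(table(votes), decreasing = TRUE))[1],
               stringsAsFactors = FALSE)
  }))
  rate <- NA_real_
  if (!is.null(scene$labels) && !is.null(scene$stains)) {
    truth_blood <- which(scene$stains$class == "blood")
    if (length(truth_blood) > 0) {
      hit <- vapply(truth_blood, function(i) {
        px <- which(scene$labels == i & roi$mask)
        if (length(px) == 0) return(FALSE)
        votes <- map[px]
        names(sort(table(votes), decreasing = TRUE))[1] == "blood"
      }, logical(1))
      rate <- mean(hit)
    }
  }
  list(map = map, calls = calls, extraction_rate = rate, roi = roi)
}

#' Compare PCA-based and derivative-based feature reduction
#'
#' Reproduces the baseline comparison: smoothing followed by three
#' principal components feeding an SVM, versus smoothing plus the
#' second-derivative band-window features feeding each classifier
#' family. Columns: accuracy, sensitivity, specificity, F1, precision,
#' kappa.
#'
#' @param dataset a `stain_dataset` (enrich with aged samples via
#'   [filter_stains()] upstream if desired).
#' @param model_specs families for the derivative rows.
#' @param scheme splitting scheme.
#' @param seed split seed.
#' @return data.frame, one row per method.
#' @export
run_comparison <- function(dataset,
                           model_specs = default_model_specs(
                             families = c("svm_linear", "ann", "knn",
                                          "dt", "rf")),
                           scheme = "sample_based", seed = 1L) {
  grid <- attr(dataset, "grid")
  pixels <- as_pixel_table(dataset)
  splitter <- if (scheme == "sample_based") split_sample_based
              else split_pixel_based
  plan <- splitter(pixels$meta, seed = child_seed(seed, "cmp"))
  pca_pipe <- pipeline_spec(sg = sg_spec(13, 3, 0), pca = 3L)
  deriv_pipe <- pipeline_spec(sg = sg_spec(13, 3, 2),
                              bands = select_bands(grid))
  rows <- list()
  res <- fit_and_score(pixels, grid, plan, pca_pipe,
                       model_spec("svm_linear", seed = seed))
  rows[["pca_svm"]] <- metrics_row(res$report,
                                   method = "smoothing+PCA(3)+SVM")
  for (m in names(model_specs)) {
    res <- fit_and_score(pixels, grid, plan, deriv_pipe, model_specs[[m]])
    rows[[m]] <- metrics_row(res$report,
                             method = paste0("smoothing+derivative+", m))
  }
  out <- do.call(rbind, rows)
  out[, c("method", "oa", "sensitivity", "specificity", "f1", "precision",
          "kappa")]
}
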