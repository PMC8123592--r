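#' Sample-based train/validation/test split
#'
#' Stains are the sampling unit: within every (class, day, substrate)
#' stratum the stains are shuffled, 70% go to the training pool and 30% to
#' the external test set; 20% of the training-pool stains become the
#' internal validation set. All pixels of one stain travel together, so no
#' stain ever appears in two partitions.
#'
#' @param meta per-pixel label data.frame (from [as_pixel_table()]) with
#'   columns `class`, `day`, `substrate`, `stain_id`.
#' @param train_frac fraction of stains in the training pool.
#' @param internal_frac fraction of the training pool held out for
#'   internal validation.
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `scheme`, integer row
#'   indices `train`, `internal_val`, `external_test`, and `seed`.
#' @export
split_sample_based <- function(meta, train_frac = 0.7, internal_frac = 0.2,
                               seed = 1L) {
  stains <- unique(meta[, c("class", "day", "substrate", "stain_id")])
  strata <- split(stains$stain_id,
                  interaction(stains$class, stains$day, stains$substrate,
                              drop = TRUE))
  pool_ids <- character(); test_ids <- character()
  for (nm in names(strata)) {
    ids <- strata[[nm]]
    if (length(ids) < 2) {
      stop("stratum ", nm, " has fewer than 2 stains")
    }
    ids <- with_seed(child_seed(seed, "stratum", nm), sample(ids))
    n_pool <- round(train_frac * length(ids))
    pool_ids <- c(pool_ids, ids[seq_len(n_pool)])
    test_ids <- c(test_ids, ids[setdiff(seq_along(ids), seq_len(n_pool))])
  }
  pool_ids <- with_seed(child_seed(seed, "pool"), sample(pool_ids))
  n_int <- round(internal_frac * length(pool_ids))
  int_ids <- pool_ids[seq_len(n_int)]
  train_ids <- pool_ids[setdiff(seq_along(pool_ids), seq_len(n_int))]
  structure(list(scheme = "sample_based",
                 train = which(meta$stain_id %in% train_ids),
                 internal_val = which(meta$stain_id %in% int_ids),
                 external_test = which(meta$stain_id %in% test_ids),
                 seed = seed),
            class = "split_plan")
}

#' Pixel-based train/validation/test split
#'
#' Pixels are shuffled within every stain: 30% (floor, remainder to the
#' training side) become external test, then 20% of the training pool
#' (floor) becomes internal validation. Every stain therefore contributes
#' pixels to all three partitions.
#'
#' @inheritParams split_sample_based
#' @return a `split_plan` (see [split_sample_based()]).
#' @export
split_pixel_based <- function(meta, train_frac = 0.7, internal_frac = 0.2,
                              seed = 1L) {
  train <- integer(); internal <- integer(); test <- integer()
  for (sid in unique(meta$stain_id)) {
    rows <- which(meta$stain_id == sid)
    if (length(rows) < 5) stop("stain ", sid, " has fewer than 5 pixels")
    rows <- with_seed(child_seed(seed, "pix", sid), sample(rows))
    n_test <- floor((1 - train_frac) * length(rows))
    test <- c(test, rows[seq_len(n_test)])
    pool <- rows[setdiff(seq_along(rows), seq_len(n_test))]
    n_int <- floor(internal_frac * length(pool))
    internal <- c(internal, pool[seq_len(n_int)])
    train <- c(train, pool[setdiff(seq_along(pool), seq_len(n_int))])
  }
  structure(list(scheme = "pixel_based", train = sort(train),
                 internal_val = sort(internal), external_test = sort(test),
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %s: %d train / %d internal-val / %d test\n",
              x$scheme, length(x$train), length(x$internal_val),
              length(x$external_test)))
  invisible(x)
}

#' Per-substrate pixel accounting for a split plan
#'
#' Tallies training-pool (training + internal validation) and external-test
#' pixels per substrate and class, the layout used to report data splits:
#' the four cells of each substrate row sum to that substrate's pixel
#' total.
#'
#' @param meta per-pixel label data.frame.
#' @param plan a `split_plan`.
#' @return data.frame with columns `substrate`, `blood_train`,
#'   `blood_test`, `non_blood_train`, `non_blood_test`, `total`.
#' @export
split_accounting <- function(meta, plan) {
  part <- rep(NA_character_, nrow(meta))
  part[c(plan$train, plan$internal_val)] <- "train"
  part[plan$external_test] <- "test"
  out <- lapply(unique(meta$substrate), function(s) {
    in_s <- meta$substrate == s
    cell <- function(cls, p) sum(in_s & meta$class == cls & part == p,
                                 na.rm = TRUE)
    data.frame(substrate = s,
               blood_train = cell("blood", "train"),
               blood_test = cell("blood", "test"),
               non_blood_train = cell("non_blood", "train"),
               non_blood_test = cell("non_blood", "test"),
               total = sum(in_s), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Confusion matrix
#'
#' Rows are truth, columns are prediction, in the supplied class order.
#'
#' @param truth,predicted label vectors of equal length.
#' @param classes class order; defaults to sorted union of truth labels.
#' @return object of class `confusion_matrix` (an integer matrix with
#'   class labels).
#' @export
confusion <- function(truth, predicted, classes = sort(unique(truth))) {
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(predicted)) stop("length mismatch")
  truth <- as.character(truth); predicted <- as.character(predicted)
  unknown <- setdiff(c(truth, predicted), classes)
  if (length(unknown) > 0) {
    stop("labels outside class order: ", paste(unknown, collapse = ", "))
  }
  cm <- table(factor(truth, classes), factor(predicted, classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest counts for each class
#'
#' @param cm a [confusion()] matrix.
#' @return data.frame with TP, FP, FN, TN per class.
#' @export
ovr_counts <- function(cm) {
  total <- sum(cm)
  data.frame(class = rownames(cm),
             TP = diag(cm),
             FP = colSums(cm) - diag(cm),
             FN = rowSums(cm) - diag(cm),
             TN = total - rowSums(cm) - colSums(cm) + diag(cm),
             row.names = NULL, stringsAsFactors = FALSE)
}

safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' Classification metrics from a confusion matrix
#'
#' Overall accuracy is the fraction of correctly classified observations
#' (trace over total). Cohen's kappa is `(Po - Pe)/(1 - Pe)` with observed
#' agreement `Po` equal to the overall accuracy and chance agreement
#' `Pe = sum_i (row_i * col_i) / N^2` from the full matrix (for binary
#' problems `Pe = PY + PN` with the standard products of marginal rates).
#' Precision, sensitivity (recall), and specificity are computed one-vs-
#' rest per class and macro-averaged over the `C` classes; the F1 score is
#' the harmonic mean of the macro precision and macro recall. Average
#' accuracy (AA) is the macro-averaged per-class recall. Degenerate
#' denominators yield `NA`, never 0.
#'
#' @param cm a [confusion()] matrix.
#' @param positive positive class for the per-class breakdown ordering
#'   (binary convention: blood).
#' @return object of class `metrics_report`: list with `oa`, `aa`,
#'   `kappa`, `po`, `pe`, `precision`, `sensitivity`, `specificity`, `f1`
#'   (macro values), `per_class` data.frame, and `n`.
#' @export
compute_metrics <- function(cm, positive = "blood") {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  counts <- ovr_counts(cm)
  if (positive %in% counts$class) {
    counts <- counts[order(counts$class != positive), ]
  }
  per_class <- within(counts, {
    specificity <- safe_div(TN, TN + FP)
    sensitivity <- safe_div(TP, TP + FN)
    precision <- safe_div(TP, TP + FP)
  })
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  macro <- function(v) mean(v, na.rm = FALSE)
  precision <- macro(per_class$precision)
  sensitivity <- macro(per_class$sensitivity)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) NA_real_
        else 2 * precision * sensitivity / (precision + sensitivity)
  structure(list(
    oa = po,
    aa = sensitivity,
    kappa = if (pe == 1) NA_real_ else (po - pe) / (1 - pe),
    po = po, pe = pe,
    precision = precision,
    sensitivity = sensitivity,
    specificity = macro(per_class$specificity),
    f1 = f1,
    per_class = per_class,
    n = n, n_classes = nrow(cm)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<metrics_report> n=%d, C=%d\n  OA=%.*f  kappa=%.*f  precision=%.*f  sensitivity=%.*f  specificity=%.*f  F1=%.*f\n",
    x$n, x$n_classes, digits, x$oa, digits, x$kappa, digits, x$precision,
    digits, x$sensitivity, digits, x$specificity, digits, x$f1))
  invisible(x)
}

#' Serialize a metrics report as a one-row data.frame
#'
#' Columns mirror the reporting layout used throughout: Sensitivity,
#' Specificity, F1-Score, Precision, OA, Kappa (fractions, not
#' percentages).
#'
#' @param report a [compute_metrics()] result.
#' @param ... name-value pairs prepended as identifier columns.
#' @return one-row data.frame.
#' @export
metrics_row <- function(report, ...) {
  cbind(data.frame(..., stringsAsFactors = FALSE),
        data.frame(sensitivity = report$sensitivity,
                   specificity = report$specificity,
                   f1 = report$f1, precision = report$precision,
                   oa = report$oa, kappa = report$kappa))
}
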