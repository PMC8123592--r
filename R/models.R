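#' Classifier specification
#'
#' Seven model families are supported: three support-vector machines
#' (linear, radial-basis, and cubic-polynomial kernels), k-nearest
#' neighbours with k tuned on internal validation over 1-20, a dense
#' neural network (three hidden layers of 30 rectified-linear units,
#' softmax output, adaptive-moment optimiser, batch 128, 50 epochs), a
#' decision tree (entropy criterion, maximum depth 10), and a random
#' forest (500 trees).
#'
#' @param family one of `"svm_linear"`, `"svm_rbf"`, `"svm_cubic"`,
#'   `"knn"`, `"ann"`, `"dt"`, `"rf"`.
#' @param seed integer seed for the stochastic families.
#' @param knn_k candidate neighbour counts.
#' @param ann_hidden hidden-layer widths.
#' @param ann_epochs training epochs.
#' @param dt_maxdepth maximum tree depth.
#' @param rf_ntree number of trees.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(family = c("svm_linear", "svm_rbf", "svm_cubic",
                                  "knn", "ann", "dt", "rf"),
                       seed = 1L, knn_k = 1:20,
                       ann_hidden = c(30L, 30L, 30L), ann_epochs = 50L,
                       dt_maxdepth = 10L, rf_ntree = 500L) {
  family <- match.arg(family)
  stopifnot(all(knn_k >= 1 & knn_k <= 20), dt_maxdepth <= 10,
            rf_ntree >= 1)
  structure(list(family = family, seed = seed, knn_k = knn_k,
                 ann_hidden = ann_hidden, ann_epochs = ann_epochs,
                 dt_maxdepth = dt_maxdepth, rf_ntree = rf_ntree),
            class = "model_spec")
}

#' All default model specifications
#'
#' @param seed integer seed shared by the stochastic families.
#' @param families subset of family names.
#' @return named list of [model_spec()]s.
#' @export
default_model_specs <- function(seed = 1L,
                                families = c("svm_linear", "svm_rbf",
                                             "svm_cubic", "knn", "ann",
                                             "dt", "rf")) {
  specs <- lapply(families, model_spec, seed = seed)
  names(specs) <- families
  specs
}

#' Train a classifier
#'
#' @param spec a [model_spec()].
#' @param x training feature matrix (min-max normalized).
#' @param y training labels (coerced to factor).
#' @param x_val,y_val internal-validation data; required for `knn` (k is
#'   chosen by validation accuracy), ignored by the other families.
#' @return object of class `hs_model` with a [predict][predict.hs_model]
#'   method.
#' @export
train_model <- function(spec, x, y, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(spec, "model_spec"), is.matrix(x))
  y <- factor(y)
  if (nlevels(y) < 2) stop("training set contains a single class")
  fit <- switch(spec$family,
    svm_linear = e1071::svm(x, y, kernel = "linear", scale = FALSE),
    svm_rbf = e1071::svm(x, y, kernel = "radial", scale = FALSE),
    svm_cubic = e1071::svm(x, y, kernel = "polynomial", degree = 3,
                           scale = FALSE),
    knn = fit_knn(spec, x, y, x_val, y_val),
    ann = with_seed(child_seed(spec$seed, "ann"),
                    mlp_fit(x, y, spec$ann_hidden, spec$ann_epochs)),
    dt = fit_dt(spec, x, y),
    rf = with_seed(child_seed(spec$seed, "rf"),
                   randomForest::randomForest(x, y,
                                              ntree = spec$rf_ntree)))
  structure(list(spec = spec, fit = fit, levels = levels(y)),
            class = "hs_model")
}

#' @export
print.hs_model <- function(x, ...) {
  cat("<hs_model>", x$spec$family, "over classes:",
      paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Predict labels with a trained classifier
#'
#' @param object an `hs_model` from [train_model()].
#' @param newdata feature matrix transformed by the same pipeline as the
#'   training data.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.hs_model <- function(object, newdata, ...) {
  fit <- object$fit
  out <- switch(object$spec$family,
    svm_linear = , svm_rbf = , svm_cubic = predict(fit, newdata),
    knn = knn_predict(fit, newdata),
    ann = mlp_predict(fit, newdata),
    dt = predict(fit, as.data.frame(newdata), type = "class"),
    rf = predict(fit, newdata))
  factor(as.character(out), levels = object$levels)
}

fit_dt <- function(spec, x, y) {
  df <- as.data.frame(x)
  df$.y <- y
  rpart::rpart(.y ~ ., df, method = "class",
               parms = list(split = "information"),
               control = rpart::rpart.control(maxdepth = spec$dt_maxdepth,
                                              cp = 1e-4))
}

# --- k-nearest neighbours ---------------------------------------------
# Neighbour search is done once for the largest candidate k (blocked
# BLAS distance computation), then every k in the candidate set is scored
# on the internal-validation split from the same neighbour table.

knn_neighbours <- function(train_x, query_x, kmax, block = 1024L) {
  tn <- rowSums(train_x^2)
  out <- matrix(0L, nrow(query_x), kmax)
  i <- 1L
  while (i <= nrow(query_x)) {
    j <- min(i + block - 1L, nrow(query_x))
    q <- query_x[i:j, , drop = FALSE]
    d2 <- outer(rowSums(q^2), tn, `+`) - 2 * tcrossprod(q, train_x)
    for (r in seq_len(nrow(d2))) {
      out[i + r - 1L, ] <- order(d2[r, ])[seq_len(kmax)]
    }
    i <- j + 1L
  }
  out
}

knn_vote <- function(labels, nb, k) {
  apply(nb[, seq_len(k), drop = FALSE], 1, function(idx) {
    tab <- table(labels[idx])
    # ties broken toward the nearest neighbour's class
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1) {
      as.character(labels[idx][labels[idx] %in% winners][1])
    } else winners
  })
}

fit_knn <- function(spec, x, y, x_val, y_val) {
  if (is.null(x_val) || is.null(y_val) || length(y_val) == 0) {
    stop("knn requires internal-validation data to tune k")
  }
  kmax <- max(spec$knn_k)
  nb <- knn_neighbours(x, x_val, kmax)
  acc <- vapply(spec$knn_k, function(k) {
    mean(knn_vote(y, nb, k) == as.character(y_val))
  }, numeric(1))
  k <- spec$knn_k[which.max(acc)]
  list(x = x, y = y, k = k, tuning = data.frame(k = spec$knn_k, acc = acc))
}

knn_predict <- function(fit, newdata) {
  nb <- knn_neighbours(fit$x, newdata, fit$k)
  knn_vote(fit$y, nb, fit$k)
}

# --- dense neural network ---------------------------------------------
# Feed-forward network: rectified-linear hidden layers, softmax output,
# cross-entropy loss, Adam updates, mini-batches of 128.

mlp_fit <- function(x, y, hidden, epochs, batch = 128L, lr = 1e-3) {
  classes <- levels(y)
  sizes <- c(ncol(x), hidden, length(classes))
  nl <- length(sizes) - 1L
  w <- lapply(seq_len(nl), function(l) {
    matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                        sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L])
  })
  b <- lapply(seq_len(nl), function(l) numeric(sizes[l + 1L]))
  mw <- lapply(w, function(m) m * 0); vw <- mw
  mb <- lapply(b, function(v) v * 0); vb <- mb
  yi <- as.integer(y)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      # forward
      acts <- vector("list", nl + 1L)
      acts[[1L]] <- xb
      for (l in seq_len(nl)) {
        z <- sweep(acts[[l]] %*% w[[l]], 2, b[[l]], `+`)
        acts[[l + 1L]] <- if (l < nl) pmax(z, 0) else z
      }
      z <- acts[[nl + 1L]]
      z <- z - apply(z, 1, max)
      p <- exp(z); p <- p / rowSums(p)
      # backward
      delta <- p
      delta[cbind(seq_along(idx), yi[idx])] <-
        delta[cbind(seq_along(idx), yi[idx])] - 1
      delta <- delta / length(idx)
      t <- t + 1
      for (l in nl:1) {
        gw <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(w[[l]])) * (acts[[l]] > 0)
        }
        mw[[l]] <- beta1 * mw[[l]] + (1 - beta1) * gw
        vw[[l]] <- beta2 * vw[[l]] + (1 - beta2) * gw^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        w[[l]] <- w[[l]] - lr * (mw[[l]] / (1 - beta1^t)) /
          (sqrt(vw[[l]] / (1 - beta2^t)) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - beta1^t)) /
          (sqrt(vb[[l]] / (1 - beta2^t)) + eps)
      }
    }
  }
  list(w = w, b = b, classes = classes)
}

mlp_predict <- function(fit, x) {
  a <- x
  nl <- length(fit$w)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% fit$w[[l]], 2, fit$b[[l]], `+`)
    a <- if (l < nl) pmax(z, 0) else z
  }
  fit$classes[max.col(a, ties.method = "first")]
}
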