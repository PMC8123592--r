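fake_meta <- function(n_stains = 10, px = 20, classes = c("blood",
                                                          "non_blood")) {
  do.call(rbind, lapply(seq_len(n_stains), function(i) {
    data.frame(class = classes[1 + (i %% length(classes))],
               substance = "x", donor = NA, day = 1L,
               substrate = "white_tile",
               stain_id = sprintf("s%02d", i),
               stringsAsFactors = FALSE)[rep(1, px), ]
  }))
}

test_that("sample-based splits keep whole stains together at 70/30", {
  meta <- fake_meta(n_stains = 20, px = 30)
  plan <- split_sample_based(meta, seed = 1)
  parts <- list(plan$train, plan$internal_val, plan$external_test)
  # disjoint and exhaustive
  expect_equal(sort(unlist(parts)), seq_len(nrow(meta)))
  # no stain id in two partitions
  ids <- lapply(parts, function(p) unique(meta$stain_id[p]))
  expect_length(intersect(ids[[1]], ids[[3]]), 0)
  expect_length(intersect(ids[[2]], ids[[3]]), 0)
  expect_length(intersect(ids[[1]], ids[[2]]), 0)
  # 10 stains per class stratum: 7 to the pool, 3 to test; 1-2 internal
  expect_length(ids[[3]], 6)  # 3 per stratum x 2 strata
  expect_true(length(ids[[2]]) %in% c(2, 3, 4))
  # deterministic under a fixed seed
  expect_identical(plan, split_sample_based(meta, seed = 1))
  expect_false(identical(plan$external_test,
                         split_sample_based(meta, seed = 2)$external_test))
})

test_that("sample-based splitting refuses single-stain strata", {
  meta <- fake_meta(n_stains = 3, classes = c("blood", "non_blood",
                                              "non_blood"))
  expect_error(split_sample_based(meta), "fewer than 2")
})

test_that("pixel-based splits cut every stain 56/14/30", {
  meta <- fake_meta(n_stains = 6, px = 100)
  plan <- split_pixel_based(meta, seed = 3)
  expect_equal(sort(c(plan$train, plan$internal_val, plan$external_test)),
               seq_len(nrow(meta)))
  for (sid in unique(meta$stain_id)) {
    rows <- which(meta$stain_id == sid)
    expect_length(intersect(rows, plan$external_test), 30)
    expect_length(intersect(rows, plan$internal_val), 14)
    expect_length(intersect(rows, plan$train), 56)
  }
  expect_error(split_pixel_based(fake_meta(2, px = 4)), "fewer than 5")
})

test_that("pixel-split totals match a brute-force per-stain count", {
  px <- small_pixels()
  meta <- px$meta
  plan <- split_pixel_based(meta, seed = 5)
  exp_test <- exp_int <- exp_train <- 0L
  for (sid in unique(meta$stain_id)) {
    n <- sum(meta$stain_id == sid)
    nt <- floor(0.3 * n)
    ni <- floor(0.2 * (n - nt))
    exp_test <- exp_test + nt
    exp_int <- exp_int + ni
    exp_train <- exp_train + (n - nt - ni)
  }
  expect_length(plan$external_test, exp_test)
  expect_length(plan$internal_val, exp_int)
  expect_length(plan$train, exp_train)
})

test_that("split accounting is additive per substrate", {
  px <- small_pixels()
  for (plan in list(split_sample_based(px$meta, seed = 2),
                    split_pixel_based(px$meta, seed = 2))) {
    acc <- split_accounting(px$meta, plan)
    expect_equal(acc$blood_train + acc$blood_test + acc$non_blood_train +
                   acc$non_blood_test, acc$total)
    expect_equal(sum(acc$total), nrow(px$meta))
  }
})

test_that("confusion matrices count truth rows against prediction columns", {
  expect_equal(diag(confusion(c("a", "b", "a"), c("a", "b", "a"))),
               c(a = 2, b = 1))
  expect_true(all(confusion(letters[1:3], letters[1:3])[
    upper.tri(diag(3)) | lower.tri(diag(3))] == 0))
  # binary truth 40 P / 60 N with 10 P and 20 N flipped
  truth <- c(rep("blood", 40), rep("non_blood", 60))
  pred <- c(rep("blood", 30), rep("non_blood", 10),
            rep("blood", 20), rep("non_blood", 40))
  cm <- confusion(truth, pred, c("blood", "non_blood"))
  counts <- ovr_counts(cm)
  blood <- counts[counts$class == "blood", ]
  expect_equal(c(blood$TP, blood$FN, blood$FP, blood$TN), c(30, 10, 20, 40))
  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion("a", "z", classes = c("a", "b")), "outside")
  expect_error(confusion(c("a", "b"), "a"), "mismatch")
})

test_that("one-vs-rest counts conserve the total for every class", {
  set.seed(31)
  truth <- sample(letters[1:4], 200, replace = TRUE)
  pred <- sample(letters[1:4], 200, replace = TRUE)
  cm <- confusion(truth, pred, letters[1:4])
  expect_equal(sum(cm), 200)
  counts <- ovr_counts(cm)
  expect_true(all(counts$TP + counts$FP + counts$FN + counts$TN == 200))
})

test_that("metrics reproduce hand-computed values on a fixed 2x2 table", {
  cm <- confusion(c(rep("blood", 50), rep("non_blood", 50)),
                  c(rep("blood", 40), rep("non_blood", 10),
                    rep("blood", 20), rep("non_blood", 30)),
                  c("blood", "non_blood"))
  m <- compute_metrics(cm)
  # TP 40, FN 10, FP 20, TN 30: Po = 0.7; PY = 0.5*0.6, PN = 0.5*0.4
  expect_equal(m$po, 0.7)
  expect_equal(m$pe, 0.5)
  expect_equal(m$kappa, 0.4)
  expect_equal(m$oa, 0.7)
  # macro averages over the two one-vs-rest problems
  expect_equal(m$precision, (40 / 60 + 30 / 40) / 2)
  expect_equal(m$sensitivity, (40 / 50 + 30 / 50) / 2)
  expect_equal(m$specificity, (30 / 50 + 40 / 50) / 2)
  expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                 (m$precision + m$sensitivity))
})

test_that("perfect, chance-level, and degenerate cases behave", {
  perfect <- confusion(rep(c("blood", "non_blood"), each = 50),
                       rep(c("blood", "non_blood"), each = 50))
  m <- compute_metrics(perfect)
  expect_equal(unlist(m[c("oa", "kappa", "precision", "sensitivity",
                          "specificity", "f1")]),
               c(oa = 1, kappa = 1, precision = 1, sensitivity = 1,
                 specificity = 1, f1 = 1))
  # all-one-class prediction on balanced truth: kappa 0, NA precision for
  # the never-predicted class
  one <- confusion(rep(c("blood", "non_blood"), each = 50),
                   rep("blood", 100), c("blood", "non_blood"))
  m1 <- compute_metrics(one)
  expect_equal(m1$kappa, 0)
  expect_true(is.na(m1$precision))
  expect_error(compute_metrics(structure(matrix(0L, 2, 2,
    dimnames = list(truth = c("a", "b"), predicted = c("a", "b"))),
    class = c("confusion_matrix", "matrix"))), "empty")
})

test_that("kappa agrees with a permutation-based chance estimate", {
  set.seed(32)
  truth <- sample(c("blood", "non_blood"), 400, replace = TRUE,
                  prob = c(0.3, 0.7))
  pred <- ifelse(stats::runif(400) < 0.8, truth,
                 sample(c("blood", "non_blood"), 400, replace = TRUE))
  m <- compute_metrics(confusion(truth, pred, c("blood", "non_blood")))
  # oracle: chance agreement from label permutations
  pe_mc <- mean(replicate(400, mean(truth == sample(pred))))
  expect_equal(m$pe, pe_mc, tolerance = 0.02)
  expect_equal(m$kappa, (m$po - pe_mc) / (1 - pe_mc), tolerance = 0.05)
})

test_that("metrics rows serialize in the reporting column layout", {
  cm <- confusion(c("blood", "non_blood"), c("blood", "non_blood"))
  row <- metrics_row(compute_metrics(cm), model = "svm_linear")
  expect_equal(names(row), c("model", "sensitivity", "specificity", "f1",
                             "precision", "oa", "kappa"))
})
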