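test_that("one-vs-rest collapse recovers TP/FP/FN/TN from the matrix", {
  m2 <- as_confusion_matrix(matrix(c(97, 3, 6, 94), 2, byrow = TRUE),
                            c("A", "B"))
  expect_identical(derive_binary(m2, "A"),
                   c(TP = 97L, FP = 6L, FN = 3L, TN = 94L))

  m3 <- as_confusion_matrix(
    matrix(c(100, 0, 0, 2, 98, 0, 1, 0, 99), 3, byrow = TRUE),
    c("A", "D", "E"))
  expect_identical(derive_binary(m3, "A"),
                   c(TP = 100L, FP = 3L, FN = 0L, TN = 197L))

  perfect <- as_confusion_matrix(diag(20, 5), LETTERS[1:5])
  for (cl in LETTERS[1:5]) {
    b <- derive_binary(perfect, cl)
    expect_identical(unname(b[c("FP", "FN")]), c(0L, 0L))
  }
  expect_error(derive_binary(m2, "Z"), "unknown")
})

test_that("metric formulas match a brute-force counting oracle", {
  set.seed(31)
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    labels <- LETTERS[1:k]
    original <- sample(labels, 40, replace = TRUE)
    predicted <- sample(labels, 40, replace = TRUE)
    m <- confusion_matrix(original, predicted, labels)
    pos <- sample(labels, 1)
    ours <- confusion_metrics(m, positive_class = pos)
    ref <- oracle_metrics(original, predicted, pos)
    expect_identical(c(TP = ours$TP, FP = ours$FP, FN = ours$FN, TN = ours$TN),
                     ref$counts)
    expect_equal(ours$accuracy, unname(ref$accuracy))
    expect_equal(ours$precision, unname(ref$precision))
    expect_equal(ours$recall, unname(ref$recall))
    expect_equal(ours$specificity, unname(ref$specificity))
    expect_equal(ours$npv, unname(ref$npv))
    expect_equal(ours$f_score, ref$f_score)
    # overall accuracy is the trace ratio, and matches direct counting
    expect_equal(overall_accuracy(m), 100 * mean(original == predicted))
  }
})

test_that("count identities hold: trace, row and column sums", {
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    m <- as_confusion_matrix(matrix(rpois(k * k, 10), k), LETTERS[1:k])
    tps <- vapply(LETTERS[1:k], function(cl) derive_binary(m, cl)[["TP"]],
                  integer(1))
    expect_identical(sum(tps), sum(diag(unclass(m))))
    for (i in seq_len(k)) {
      b <- derive_binary(m, LETTERS[i])
      expect_identical(b[["TP"]] + b[["FN"]], sum(m[i, ]))
      expect_identical(b[["TP"]] + b[["FP"]], sum(m[, i]))
      expect_identical(sum(b), sum(m))
    }
  }
})

test_that("two-class one-vs-rest accuracy equals overall; multiclass does not", {
  m2 <- as_confusion_matrix(matrix(c(88, 12, 28, 72), 2, byrow = TRUE),
                            c("C", "D"))
  met <- confusion_metrics(m2)
  expect_equal(met$accuracy[met$class == "C"], overall_accuracy(m2))
  expect_equal(met$accuracy[met$class == "D"], overall_accuracy(m2))

  m3 <- as_confusion_matrix(
    matrix(c(60, 0, 0, 0, 50, 10, 0, 12, 48), 3, byrow = TRUE), LETTERS[1:3])
  met3 <- confusion_metrics(m3)
  expect_false(isTRUE(all.equal(met3$accuracy[1], overall_accuracy(m3))))
})

test_that("zero denominators yield explicit undefined markers, not NaN", {
  m <- as_confusion_matrix(matrix(c(0, 10, 0, 10), 2, byrow = TRUE),
                           c("A", "B"))
  met <- confusion_metrics(m, positive_class = "A")
  expect_true(is.na(met$precision))     # TP + FP = 0
  expect_true(is.na(met$f_score))
  expect_false(any(is.nan(unlist(met[vapply(met, is.numeric, TRUE)]))))
  empty <- as_confusion_matrix(matrix(0L, 2, 2), c("A", "B"))
  expect_error(confusion_metrics(empty), "> 0")
})

test_that("fold plans are disjoint, exhaustive and stratified", {
  set.seed(13)
  for (rep in 1:10) {
    k <- sample(c(5, 10), 1)
    sizes <- sample(k:(k + 13), sample(2:4, 1), replace = TRUE)
    labels <- rep(LETTERS[seq_along(sizes)], sizes)
    plan <- make_folds(labels, k = k, seed = rep)
    expect_length(plan$assignments, length(labels))
    expect_setequal(unique(plan$assignments), seq_len(k))
    for (cl in unique(labels)) {
      per_fold <- tabulate(plan$assignments[labels == cl], k)
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
  expect_error(make_folds(rep(c("A", "B"), each = 20), k = 1), ">= 2")
  expect_error(make_folds(rep(c("A", "B"), c(5, 20)), k = 10), "smaller than k")
  p1 <- make_folds(rep(c("A", "B"), each = 20), k = 5, seed = 4)
  p2 <- make_folds(rep(c("A", "B"), each = 20), k = 5, seed = 4)
  expect_identical(p1$assignments, p2$assignments)
})

test_that("fold counts reproduce the per-fold split table for 2-5 classes", {
  expected <- data.frame(classes = 2:5,
                         train = c(144L, 216L, 288L, 360L),
                         validation = c(36L, 54L, 72L, 90L),
                         test = c(20L, 30L, 40L, 50L))
  for (i in seq_len(nrow(expected))) {
    labels <- rep(LETTERS[seq_len(expected$classes[i])], each = 100)
    fc <- fold_counts(make_folds(labels, k = 10, seed = 1))
    expect_true(all(fc$train == expected$train[i]))
    expect_true(all(fc$validation == expected$validation[i]))
    expect_true(all(fc$test == expected$test[i]))
  }
})

test_that("cross-validation tests each segment exactly once", {
  ae <- fixture_ae_images(n_per_class = 20)
  small <- eeg_dataset(ae$dataset$segments, classes = c("A", "E"))
  cv <- run_cv(small, train_cfg = train_config(epochs = 1, learning_rate = 1,
                                               seed = 5),
               k = 10, seed = 7, images = ae$images)
  expect_identical(sum(cv$confusion), 40L)
  expect_identical(unname(rowSums(cv$confusion)), c(20, 20))
  expect_length(cv$fold_confusions, 10)
  # aggregation is the elementwise sum of the per-fold matrices
  agg <- Reduce(`+`, lapply(cv$fold_confusions, unclass))
  expect_identical(unclass(cv$confusion), matrix(as.integer(agg), 2,
                   dimnames = dimnames(cv$confusion)))
  expect_identical(nrow(cv$histories), 10L)
})

test_that("a seeded cross-validation run is exactly reproducible", {
  ae <- fixture_ae_images(n_per_class = 20)
  run <- function() {
    run_cv(ae$dataset,
           train_cfg = train_config(epochs = 1, learning_rate = 1),
           k = 5, seed = 3, images = ae$images)
  }
  cv1 <- run()
  cv2 <- run()
  expect_identical(cv1$confusion, cv2$confusion)
  expect_identical(cv1$histories, cv2$histories)
})

test_that("reports round-trip the confusion matrix and metrics", {
  ae <- fixture_ae_images(n_per_class = 20)
  cv <- run_cv(ae$dataset,
               train_cfg = train_config(epochs = 1, learning_rate = 1),
               k = 5, seed = 9, images = ae$images)
  dir <- withr::local_tempdir()
  files <- write_cv_report(cv, dir, prefix = "A-E")
  expect_true(all(file.exists(files)))

  back <- utils::read.csv(files[1], row.names = 1)
  expect_identical(matrix(as.integer(as.matrix(back)), 2),
                   matrix(as.integer(unclass(cv$confusion)), 2))
  metr <- utils::read.csv(files[2])
  expect_identical(nrow(metr), 3L) # 2 classes + overall
  record <- jsonlite::read_json(files[4], simplifyVector = TRUE)
  expect_equal(record$overall_accuracy, overall_accuracy(cv$confusion))
  expect_identical(as.integer(record$confusion),
                   as.integer(unclass(cv$confusion)))
})
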