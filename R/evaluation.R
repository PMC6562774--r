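## Evaluation: stratified k-fold cross-validation orchestration,
## confusion-matrix accumulation across folds, and the full metric suite with
## every labelling convention used in the published result tables.

#' Build a confusion matrix from label vectors
#'
#' @param original true labels.
#' @param predicted predicted labels.
#' @param labels ordered class labels; default sorted union.
#' @return An object of class `"confusion_matrix"`: square integer matrix
#'   indexed `[original, predicted]`.
#' @export
confusion_matrix <- function(original, predicted, labels = NULL) {
  if (is.null(labels)) labels <- sort(unique(c(original, predicted)))
  m <- table(factor(original, levels = labels),
             factor(predicted, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(original = labels, predicted = labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Coerce a plain matrix of counts to a confusion matrix
#'
#' @param counts square numeric matrix `[original, predicted]`.
#' @param labels class labels; default from dimnames or LETTERS.
#' @return A `"confusion_matrix"`.
#' @export
as_confusion_matrix <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop_validation("counts must be square")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_validation("counts must be non-negative integers")
  }
  if (is.null(labels)) {
    labels <- rownames(counts) %||% LETTERS[seq_len(nrow(counts))]
  }
  m <- matrix(as.integer(counts), nrow = nrow(counts),
              dimnames = list(original = labels, predicted = labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = original, cols = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' One-vs-rest collapse of a confusion matrix
#'
#' For the designated positive class: `TP` is its diagonal entry, `FN` its
#' off-diagonal row sum, `FP` its off-diagonal column sum and `TN` the
#' remainder, so `TP + FP + FN + TN` equals the grand total.
#'
#' @param m a [confusion_matrix()].
#' @param positive_class label of the positive class.
#' @return Named numeric vector `c(TP, FP, FN, TN)`.
#' @examples
#' m <- as_confusion_matrix(matrix(c(97, 3, 6, 94), 2, byrow = TRUE),
#'                          c("A", "B"))
#' derive_binary(m, "A")
#' @export
derive_binary <- function(m, positive_class) {
  stopifnot(inherits(m, "confusion_matrix"))
  labels <- rownames(m)
  p <- match(positive_class, labels)
  if (is.na(p)) stop_validation("unknown positive class: ", positive_class)
  tp <- m[p, p]
  fn <- sum(m[p, -p])
  fp <- sum(m[-p, p])
  tn <- sum(m) - tp - fn - fp
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# percentage with NA (undefined marker) on zero denominator
.pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Metric suite of a confusion matrix
#'
#' Computes, per class (one-vs-rest) and overall, every metric convention the
#' published result tables use:
#' \describe{
#'   \item{accuracy}{`(TP + TN) / (TP + FP + FN + TN)` -- the standard
#'     one-vs-rest accuracy.}
#'   \item{accuracy_cc}{`(TP + TNd) / (TP + TNd + FP + FN)` with `TNd` the sum
#'     of the *other diagonal entries* (only correctly-classified negatives
#'     counted); this is the per-class accuracy convention of the published
#'     multiclass tables.}
#'   \item{sensitivity_ppv}{`TP / (TP + FP)` -- the "sensitivity" printed in
#'     the published binary tables (identical to precision).}
#'   \item{recall}{`TP / (TP + FN)` -- the "sensitivity" of the published
#'     multiclass tables.}
#'   \item{specificity}{`TN / (FP + TN)`.}
#'   \item{specificity_cc}{`TNd / (FP + TNd)` -- the multiclass tables'
#'     specificity convention.}
#'   \item{npv}{`TN / (TN + FN)` -- what the published *binary* tables print
#'     as "specificity".}
#'   \item{precision, f_score}{`TP / (TP + FP)` and
#'     `2 * precision * recall / (precision + recall)`; the f-score is 0 when
#'     precision + recall is 0, and `NA` when a component is undefined.}
#' }
#' All values are percentages in `[0, 100]` at full precision; zero
#' denominators yield `NA` (an explicit undefined marker). The overall row
#' carries the multiclass accuracy `trace / total`. In the two-class case
#' the one-vs-rest accuracy of either class equals the overall accuracy; for
#' more classes it does not, and only the overall row is the multiclass
#' accuracy.
#'
#' @param m a [confusion_matrix()].
#' @param positive_class optional single class; default all classes plus the
#'   overall row.
#' @return A data frame of class `"metric_report"`, one row per class and an
#'   `"overall"` row, with the count and metric columns above.
#' @examples
#' m <- as_confusion_matrix(matrix(c(88, 12, 28, 72), 2, byrow = TRUE),
#'                          c("C", "D"))
#' confusion_metrics(m)
#' @export
confusion_metrics <- function(m, positive_class = NULL) {
  stopifnot(inherits(m, "confusion_matrix"))
  total <- sum(m)
  if (total == 0) stop_validation("confusion matrix total must be > 0")
  labels <- rownames(m)
  classes <- positive_class %||% labels
  rows <- lapply(classes, function(cl) {
    b <- derive_binary(m, cl)
    p <- match(cl, labels)
    tnd <- sum(diag(unclass(m))[-p])
    precision <- .pct(b["TP"], b["TP"] + b["FP"])
    recall <- .pct(b["TP"], b["TP"] + b["FN"])
    f <- if (is.na(precision) || is.na(recall)) NA_real_
         else if (precision + recall == 0) 0
         else 2 * precision * recall / (precision + recall)
    data.frame(
      class = cl, TP = b[["TP"]], FP = b[["FP"]], FN = b[["FN"]],
      TN = b[["TN"]],
      accuracy = .pct(b["TP"] + b["TN"], total),
      accuracy_cc = .pct(b["TP"] + tnd, b["TP"] + tnd + b["FP"] + b["FN"]),
      sensitivity_ppv = precision,
      recall = recall,
      specificity = .pct(b["TN"], b["FP"] + b["TN"]),
      specificity_cc = .pct(tnd, b["FP"] + tnd),
      npv = .pct(b["TN"], b["TN"] + b["FN"]),
      precision = precision,
      f_score = f)
  })
  out <- do.call(rbind, rows)
  if (is.null(positive_class)) {
    overall <- out[1, ]
    overall[1, ] <- NA
    overall$class <- "overall"
    overall$accuracy <- 100 * sum(diag(unclass(m))) / total
    out <- rbind(out, overall)
  }
  rownames(out) <- NULL
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Overall multiclass accuracy of a confusion matrix
#'
#' @param m a [confusion_matrix()].
#' @return `100 * trace / total`.
#' @export
overall_accuracy <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  100 * sum(diag(unclass(m))) / sum(m)
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) &
    !names(y) %in% c("TP", "FP", "FN", "TN")
  y[num] <- lapply(y[num], round_half_up, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

## ---- fold plans -----------------------------------------------------------

#' Stratified k-fold plan
#'
#' Assigns every segment to exactly one of `k` folds so that the folds
#' partition the dataset and each fold's per-class test count differs from
#' `n_class / k` by at most one. For each fold, the training pool is all
#' out-of-fold segments, from which a stratified `validation_fraction` is
#' earmarked during training for monitoring.
#'
#' @param dataset an [eeg_dataset()], or a character vector of labels.
#' @param k number of folds (>= 2; default 10).
#' @param validation_fraction fraction of each training pool earmarked for
#'   validation (default 0.20).
#' @param seed integer seed.
#' @return An object of class `"fold_plan"`: `assignments` (fold index per
#'   segment), `labels`, `k`, `validation_fraction`, `seed`.
#' @examples
#' labs <- rep(c("A", "E"), each = 100)
#' plan <- make_folds(labs, k = 10, seed = 1)
#' fold_counts(plan)[1, ]
#' @export
make_folds <- function(dataset, k = 10, validation_fraction = 0.20, seed = 1) {
  labels <- if (inherits(dataset, "eeg_dataset")) {
    vapply(dataset$segments, function(s) s$class_label, character(1))
  } else as.character(dataset)
  if (k < 2) stop_validation("k must be >= 2")
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small) > 0L) {
    stop_validation("class(es) smaller than k = ", k, ": ",
                    paste(small, collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "fold-plan"))
  assignments <- integer(length(labels))
  for (cl in names(counts)) {
    members <- sample(which(labels == cl))
    assignments[members] <- rep_len(seq_len(k), length(members))
  }
  structure(list(assignments = assignments, labels = labels, k = as.integer(k),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Per-fold train/validation/test counts of a fold plan
#'
#' The validation count mirrors the in-training stratified split: per class,
#' `round(pool_size * validation_fraction)` items of the training pool.
#'
#' @param plan a [make_folds()] plan.
#' @return Data frame with columns `fold`, `train`, `validation`, `test`.
#' @export
fold_counts <- function(plan) {
  stopifnot(inherits(plan, "fold_plan"))
  classes <- sort(unique(plan$labels))
  out <- data.frame(fold = seq_len(plan$k), train = 0L, validation = 0L,
                    test = 0L)
  for (f in seq_len(plan$k)) {
    test <- plan$assignments == f
    pool_labels <- plan$labels[!test]
    n_val <- sum(vapply(classes, function(cl) {
      round(sum(pool_labels == cl) * plan$validation_fraction)
    }, numeric(1)))
    out$test[f] <- sum(test)
    out$validation[f] <- as.integer(n_val)
    out$train[f] <- as.integer(sum(!test) - n_val)
  }
  out
}

## ---- cross-validation -----------------------------------------------------

#' Cross-validated training and evaluation of the full pipeline
#'
#' Converts every segment to its scalogram input image once (the transform is
#' deterministic), then trains one classifier per fold from scratch on the
#' out-of-fold images and evaluates it on the fold's test images. Each
#' segment is tested exactly once, and the aggregated confusion matrix is the
#' elementwise sum of the per-fold test confusion matrices, so its row sums
#' equal the full per-class counts. Per-fold training seeds are derived from
#' the plan seed, making the whole run reproducible from one integer.
#'
#' @param dataset an [eeg_dataset()] (>= 2 classes).
#' @param scalogram_cfg a [scalogram_config()].
#' @param train_cfg a [train_config()]; its `seed` is replaced per fold by a
#'   derived seed.
#' @param plan a [make_folds()] plan, or `NULL` to build one with `k` folds.
#' @param k,seed fold count and seed used when `plan` is `NULL`.
#' @param spec optional [model_spec()]; default sized to the dataset.
#' @param images optional precomputed list of input images in dataset order
#'   (skips the scalogram stage).
#' @return An object of class `"scalocnn_cv"`: aggregated `confusion`,
#'   per-fold confusion matrices and training histories, the `metrics` report
#'   of the aggregated matrix, and all configurations and seeds.
#' @export
run_cv <- function(dataset, scalogram_cfg = scalogram_config(),
                   train_cfg = train_config(), plan = NULL, k = 10, seed = 1,
                   spec = NULL, images = NULL) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  classes <- dataset$classes
  if (length(classes) < 2L) stop_validation("need >= 2 classes for CV")
  if (is.null(plan)) {
    plan <- make_folds(dataset, k = k,
                       validation_fraction = train_cfg$validation_fraction,
                       seed = seed)
  }
  labels <- vapply(dataset$segments, function(s) s$class_label, character(1))
  if (is.null(images)) {
    images <- dataset_to_inputs(dataset, scalogram_cfg)
  }
  if (is.null(spec)) {
    spec <- model_spec(length(classes), channels = scalogram_cfg$channels)
  }

  fold_conf <- vector("list", plan$k)
  histories <- vector("list", plan$k)
  agg <- matrix(0L, length(classes), length(classes),
                dimnames = list(original = classes, predicted = classes))
  for (f in seq_len(plan$k)) {
    test_idx <- which(plan$assignments == f)
    train_idx <- which(plan$assignments != f)
    cfg_f <- train_cfg
    cfg_f$seed <- derive_seed(plan$seed, paste0("fold-", f, "-train"))
    log_info(sprintf("stage=cv fold=%d/%d n_train_pool=%d n_test=%d",
                     f, plan$k, length(train_idx), length(test_idx)))
    model <- tryCatch(
      cnn_fit(images[train_idx], labels = labels[train_idx], spec = spec,
              config = cfg_f),
      error = function(e) {
        stop("cross-validation failed in fold ", f, ": ",
             conditionMessage(e))
      })
    pred <- predict(model, images[test_idx])
    cm <- confusion_matrix(labels[test_idx], pred, labels = classes)
    fold_conf[[f]] <- cm
    histories[[f]] <- cbind(fold = f, model$history)
    agg <- agg + unclass(cm)
  }
  agg <- structure(matrix(as.integer(agg), nrow = length(classes),
                          dimnames = dimnames(agg)),
                   class = c("confusion_matrix", "matrix"))
  structure(list(confusion = agg, fold_confusions = fold_conf,
                 histories = do.call(rbind, histories),
                 metrics = confusion_metrics(agg), plan = plan,
                 classes = classes, spec = spec, train_config = train_cfg,
                 scalogram_config = scalogram_cfg, seed = plan$seed),
            class = "scalocnn_cv")
}

#' @export
print.scalocnn_cv <- function(x, ...) {
  cat(sprintf("<scalocnn_cv> %d-fold CV over %d segments, classes %s\n",
              x$plan$k, length(x$plan$assignments),
              paste(x$classes, collapse = "-")))
  cat(sprintf("  overall accuracy: %.2f%%\n",
              overall_accuracy(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Write the reports of a cross-validated run
#'
#' Emits `confusion.csv` (the aggregated matrix), `metrics.csv` (per-class
#' and overall metrics, every convention labelled), `fold_histories.csv`,
#' and `run.json` (full run record: configurations, seeds, fold assignments,
#' matrix and metrics), from which the run is reconstructible.
#'
#' @param cv a [run_cv()] result.
#' @param dir output directory (created if needed).
#' @param prefix optional file-name prefix, e.g. the class-subset name
#'   `"A-D-E"`.
#' @return Invisible character vector of the files written.
#' @export
write_cv_report <- function(cv, dir, prefix = NULL) {
  stopifnot(inherits(cv, "scalocnn_cv"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- if (is.null(prefix)) "" else paste0(prefix, "_")
  f_conf <- file.path(dir, paste0(tag, "confusion.csv"))
  f_metr <- file.path(dir, paste0(tag, "metrics.csv"))
  f_hist <- file.path(dir, paste0(tag, "fold_histories.csv"))
  f_json <- file.path(dir, paste0(tag, "run.json"))
  utils::write.csv(as.data.frame(unclass(cv$confusion)), f_conf)
  utils::write.csv(as.data.frame(cv$metrics), f_metr, row.names = FALSE)
  utils::write.csv(cv$histories, f_hist, row.names = FALSE)
  record <- list(
    classes = cv$classes, seed = cv$seed,
    fold_plan = list(k = cv$plan$k, seed = cv$plan$seed,
                     validation_fraction = cv$plan$validation_fraction,
                     assignments = cv$plan$assignments),
    scalogram_config = unclass(cv$scalogram_config),
    train_config = unclass(cv$train_config),
    model_spec = cv$spec[c("n_classes", "channels", "conv1_filters",
                           "conv2_filters", "kernel", "pool", "fc_units",
                           "input_size")],
    confusion = unclass(cv$confusion),
    metrics = as.data.frame(cv$metrics),
    overall_accuracy = overall_accuracy(cv$confusion))
  jsonlite::write_json(record, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(f_conf, f_metr, f_hist, f_json))
}

#' Published reference confusion matrices
#'
#' The aggregated 10-fold confusion matrices published for every class-subset
#' run of the reference scalogram-CNN study on the public five-set EEG corpus,
#' shipped as a plain-text fixture. Used to verify the metric suite's
#' arithmetic against the printed result tables.
#'
#' @param subset optional subset name such as `"A-E"` or `"A-B-C-D-E"`.
#' @return Named list of [confusion_matrix()] objects (or a single one).
#' @export
reference_confusion_matrices <- function(subset = NULL) {
  path <- system.file("extdata", "reference_confusion_matrices.csv",
                      package = "scalocnn", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_df <- split(df, df$subset)
  out <- lapply(split_df, function(d) {
    labels <- strsplit(d$subset[1], "-")[[1]]
    m <- matrix(0L, length(labels), length(labels),
                dimnames = list(original = labels, predicted = labels))
    for (i in seq_len(nrow(d))) m[d$original[i], d$predicted[i]] <- d$count[i]
    as_confusion_matrix(m, labels)
  })
  if (!is.null(subset)) {
    if (!subset %in% names(out)) stop_validation("unknown subset: ", subset)
    return(out[[subset]])
  }
  out
}
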