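#' Confusion counts and classification metrics
#'
#' Computes the confusion matrix (positive class = `"stressed"`) and the
#' derived proportions: accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity
#' `TP/(FN+TP)`, specificity `TN/(TN+FP)` and precision `TP/(TP+FP)`.
#' A metric whose denominator is zero is reported as `NaN` and flagged in
#' `undefined`, never silently zeroed.
#'
#' @param labels True labels (`"stressed"`/`"non_stressed"`, factor, or 0/1).
#' @param predictions Predicted labels, same conventions and length.
#' @return Object of class `confusion_metrics`: list with `counts` (named
#'   TP/FP/TN/FN), `accuracy`, `sensitivity`, `specificity`, `precision`,
#'   `n`, and `undefined` (character vector of NaN metrics).
#' @export
evaluate_predictions <- function(labels, predictions) {
  y <- as_binary_labels(labels)
  p <- as_binary_labels(predictions)
  if (length(y) != length(p))
    stop("labels and predictions must have the same length", call. = FALSE)
  tp <- sum(y == 1 & p == 1)
  tn <- sum(y == 0 & p == 0)
  fp <- sum(y == 0 & p == 1)
  fn <- sum(y == 1 & p == 0)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  out <- list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
              n = length(y),
              accuracy = ratio(tp + tn, tp + tn + fp + fn),
              sensitivity = ratio(tp, fn + tp),
              specificity = ratio(tn, tn + fp),
              precision = ratio(tp, tp + fp))
  out$undefined <- names(Filter(is.nan, out[c("accuracy", "sensitivity",
                                              "specificity", "precision")]))
  class(out) <- "confusion_metrics"
  out
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> n=%d  TP=%d FP=%d TN=%d FN=%d\n",
              x$n, x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  precision %.1f%%\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$precision))
  if (length(x$undefined))
    cat("  undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

# stratified sampling helper: draws size indices from idx, seeded upstream
sample_strat <- function(idx, size) idx[sample.int(length(idx), size)]

#' Build a train/validation/test split
#'
#' Three regimes over an encoded `image_set`:
#' * `person_specific`: all images from one subject, stratified by class
#'   into 70/15/15 train/validation/test (floor rounding, remainder to
#'   train). `chronological = TRUE` splits each class by window position
#'   instead of randomly, which avoids overlapping-window leakage between
#'   train and test.
#' * `generic`: every image of `test_subjects` goes to test; the remaining
#'   subjects' pooled images are split 85/15 into train/validation,
#'   stratified by class.
#' * `calibrated_generic`: as `generic`, then exactly
#'   `floor(calibration_fraction * n)` images per test subject per class are
#'   moved from test to train (the calibration set).
#'
#' @param images An `image_set`.
#' @param regime One of `"person_specific"`, `"generic"`,
#'   `"calibrated_generic"`.
#' @param test_subjects Character vector of held-out subject ids
#'   (generic/calibrated regimes).
#' @param proportions Person-specific train/val/test proportions.
#' @param train_val Generic-pool train/validation proportions.
#' @param calibration_fraction Fraction of each test subject's images moved
#'   to training in the calibrated regime (default 0.20).
#' @param chronological Person-specific split by window position rather than
#'   at random.
#' @param seed Integer seed for all sampling.
#' @return Object of class `split_spec` with disjoint integer index vectors
#'   `train`, `val`, `test` and `calibration` (subset of `train`).
#' @export
make_split <- function(images,
                       regime = c("person_specific", "generic", "calibrated_generic"),
                       test_subjects = NULL,
                       proportions = c(0.70, 0.15, 0.15),
                       train_val = c(0.85, 0.15),
                       calibration_fraction = 0.20,
                       chronological = FALSE, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(inherits(images, "image_set"))
  info <- images$info
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  train <- val <- test <- calibration <- integer(0)

  if (regime == "person_specific") {
    subj <- unique(info$subject_id)
    if (length(subj) != 1L)
      stop("person_specific split requires images of exactly one subject; got: ",
           paste(subj, collapse = ", "), call. = FALSE)
    if (abs(sum(proportions) - 1) > 1e-8)
      stop("proportions must sum to 1", call. = FALSE)
    for (cond in unique(info$condition)) {
      idx <- which(info$condition == cond)
      n <- length(idx)
      n_val <- floor(n * proportions[2L])
      n_test <- floor(n * proportions[3L])
      if (n_val < 1L || n_test < 1L || n - n_val - n_test < 1L)
        stop(sprintf("subject %s has too few '%s' images (%d) for a %d/%d/%d split",
                     subj, cond, n, round(100 * proportions[1L]),
                     round(100 * proportions[2L]), round(100 * proportions[3L])),
             call. = FALSE)
      if (chronological) {
        idx <- idx[order(info$start_index[idx])]
        train <- c(train, idx[seq_len(n - n_val - n_test)])
        val <- c(val, idx[seq.int(n - n_val - n_test + 1L, n - n_test)])
        test <- c(test, idx[seq.int(n - n_test + 1L, n)])
      } else {
        idx <- idx[sample.int(n)]
        test <- c(test, idx[seq_len(n_test)])
        val <- c(val, idx[seq.int(n_test + 1L, n_test + n_val)])
        train <- c(train, idx[seq.int(n_test + n_val + 1L, n)])
      }
    }
  } else {
    if (is.null(test_subjects) || !length(test_subjects))
      stop("test_subjects is required for the generic regimes", call. = FALSE)
    missing_subj <- setdiff(test_subjects, info$subject_id)
    if (length(missing_subj))
      stop("test subject(s) not present in the image set: ",
           paste(missing_subj, collapse = ", "), call. = FALSE)
    is_test_subj <- info$subject_id %in% test_subjects
    test <- which(is_test_subj)
    pool <- which(!is_test_subj)
    if (!length(pool))
      stop("no training subjects remain after holding out the test subjects",
           call. = FALSE)
    for (cond in unique(info$condition[pool])) {
      idx <- pool[info$condition[pool] == cond]
      n <- length(idx)
      n_val <- floor(n * train_val[2L])
      idx <- idx[sample.int(n)]
      val <- c(val, idx[seq_len(n_val)])
      train <- c(train, idx[seq.int(n_val + 1L, n)])
    }
    if (regime == "calibrated_generic") {
      for (s in test_subjects) {
        for (cond in unique(info$condition[info$subject_id == s])) {
          idx <- which(info$subject_id == s & info$condition == cond)
          n_cal <- floor(length(idx) * calibration_fraction)
          if (n_cal > 0L) {
            cal <- sample_strat(idx, n_cal)
            calibration <- c(calibration, cal)
            train <- c(train, cal)
            test <- setdiff(test, cal)
          }
        }
      }
    }
  }
  out <- list(regime = regime, train = sort(train), val = sort(val),
              test = sort(test), calibration = sort(calibration),
              test_subjects = test_subjects,
              calibration_fraction = if (regime == "calibrated_generic")
                calibration_fraction else NA_real_,
              chronological = chronological, seed = as.integer(seed))
  class(out) <- "split_spec"
  validate_split(out, n_images(images))
  out
}

validate_split <- function(split, n_total) {
  sets <- split[c("train", "val", "test")]
  if (length(intersect(sets$train, sets$val)) ||
      length(intersect(sets$train, sets$test)) ||
      length(intersect(sets$val, sets$test)))
    stop("split sets are not pairwise disjoint", call. = FALSE)
  if (any(unlist(sets) < 1L) || any(unlist(sets) > n_total))
    stop("split indices out of range", call. = FALSE)
  invisible(split)
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %s: %d train / %d val / %d test",
              x$regime, length(x$train), length(x$val), length(x$test)))
  if (length(x$calibration))
    cat(sprintf(" (%d calibration images in train)", length(x$calibration)))
  cat("\n")
  invisible(x)
}

#' Quantify window-overlap leakage across a split
#'
#' With stride-1 windows, images whose start positions are fewer than
#' `window` beats apart share source beats. This reports, for each of the
#' validation and test sets, how many images share at least one source beat
#' with some training image of the same subject and condition.
#'
#' @param split A [make_split()] result.
#' @param images The `image_set` the split was built on.
#' @return Data frame with columns `set`, `n`, `n_overlapping`.
#' @export
leakage_report <- function(split, images) {
  info <- images$info
  w <- images$window
  overlap_count <- function(idx) {
    if (!length(idx)) return(0L)
    n_ov <- 0L
    for (i in idx) {
      same <- split$train[info$subject_id[split$train] == info$subject_id[i] &
                          info$condition[split$train] == info$condition[i]]
      if (length(same) &&
          any(abs(info$start_index[same] - info$start_index[i]) < w))
        n_ov <- n_ov + 1L
    }
    n_ov
  }
  data.frame(set = c("val", "test"),
             n = c(length(split$val), length(split$test)),
             n_overlapping = c(overlap_count(split$val),
                               overlap_count(split$test)))
}

#' Run one evaluation regime end to end
#'
#' Filters the cohort's sequences to the physiologic range, fits the
#' regime-appropriate binning scheme (person-specific: on the subject's
#' combined conditions; generic/calibrated: on the pooled training
#' subjects' durations, applied unchanged to test subjects), encodes the
#' windows in the requested image domain, builds the split, trains the CNN
#' and evaluates the held-out test set.
#'
#' @param cohort List of [ibi_sequence()] objects (e.g.
#'   [cohort_sequences()] of a synthetic cohort, or sequences read from
#'   disk).
#' @param regime `"person_specific"`, `"generic"` or `"calibrated_generic"`.
#' @param domain `"spatial"` or `"frequency"`.
#' @param config A [cnn_config()]; its `epochs`, `batch_size` etc. are used
#'   for training.
#' @param subject Subject id for the person-specific regime.
#' @param test_subjects Held-out subject ids for the generic regimes.
#' @param window,stride Encoder window and stride (defaults 28 and 1).
#' @param bin_method Binning method passed to [fit_bins()].
#' @param filter_range Physiologic range in seconds.
#' @param calibration_fraction Calibrated-generic fraction (default 0.20).
#' @param chronological Person-specific chronological split option.
#' @param seed Seed for splitting; training uses `config$seed`.
#' @return Object of class `eval_report`: accuracies for train/val/test,
#'   test confusion counts and metrics, the split sizes, training history,
#'   and provenance (regime, domain, bins, seeds).
#' @export
run_regime <- function(cohort, regime = c("person_specific", "generic",
                                          "calibrated_generic"),
                       domain = c("spatial", "frequency"),
                       config = cnn_config(), subject = NULL,
                       test_subjects = NULL, window = 28L, stride = 1L,
                       bin_method = "quantile", filter_range = c(0.6, 1.2),
                       calibration_fraction = 0.20, chronological = FALSE,
                       seed = config$seed) {
  regime <- match.arg(regime)
  domain <- match.arg(domain)
  stopifnot(length(cohort) >= 1L,
            all(vapply(cohort, inherits, TRUE, "ibi_sequence")))
  cohort <- lapply(cohort, filter_physiologic,
                   low = filter_range[1], high = filter_range[2])
  subj_of <- vapply(cohort, `[[`, "", "subject_id")

  if (regime == "person_specific") {
    if (is.null(subject)) {
      if (length(unique(subj_of)) != 1L)
        stop("specify `subject` for the person-specific regime", call. = FALSE)
      subject <- subj_of[1L]
    }
    cohort <- cohort[subj_of == subject]
    if (!length(cohort)) stop("no sequences for subject ", subject, call. = FALSE)
    bin_source <- unlist(lapply(cohort, `[[`, "durations"))
  } else {
    if (is.null(test_subjects))
      stop("specify `test_subjects` for the generic regimes", call. = FALSE)
    bin_source <- unlist(lapply(cohort[!(subj_of %in% test_subjects)],
                                `[[`, "durations"))
  }
  bins <- fit_bins(bin_source, k = window, method = bin_method,
                   range = filter_range)
  images <- bind_image_sets(lapply(cohort, make_images, bins = bins,
                                   window = window, stride = stride))
  if (domain == "frequency") images <- to_frequency_images(images)

  split <- make_split(images, regime, test_subjects = test_subjects,
                      calibration_fraction = calibration_fraction,
                      chronological = chronological, seed = seed)

  model <- build_model(config)
  model <- train_cnn(model, images[split$train], x_val = images[split$val])

  acc_of <- function(idx) {
    if (!length(idx)) return(NA_real_)
    pred <- predict(model, images[idx], type = "label")
    mean(pred == images$info$condition[idx])
  }
  test_pred <- predict(model, images[split$test], type = "label")
  cm <- evaluate_predictions(images$info$condition[split$test], test_pred)

  out <- list(regime = regime, domain = domain,
              subject = subject, test_subjects = test_subjects,
              n = c(train = length(split$train), val = length(split$val),
                    test = length(split$test)),
              accuracy = c(train = acc_of(split$train), val = acc_of(split$val),
                           test = cm$accuracy),
              metrics = cm, split = split, bins = bins,
              history = model$history, config = config, seed = seed)
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v) | is.nan(v), "-",
                            formatC(100 * v, format = "f", digits = 1))
  who <- if (x$regime == "person_specific") x$subject
         else paste(x$test_subjects, collapse = ",")
  cat(sprintf("<eval_report> %s / %s (%s)\n", x$regime, x$domain, who))
  hdr <- c("Train %", "Valid %", "Test %", "Sensitivity %", "Specificity %",
           "Precision %")
  vals <- c(pct(x$accuracy["train"]), pct(x$accuracy["val"]),
            pct(x$accuracy["test"]), pct(x$metrics$sensitivity),
            pct(x$metrics$specificity), pct(x$metrics$precision))
  cat(sprintf("  %s\n", paste(sprintf("%-14s", hdr), collapse = "")))
  cat(sprintf("  %s\n", paste(sprintf("%-14s", vals), collapse = "")))
  invisible(x)
}

#' Turn evaluation reports into a table
#'
#' @param reports List of `eval_report` objects.
#' @return Data frame with one row per report, columns mirroring the
#'   printed layout (percentages rounded to one decimal).
#' @export
report_table <- function(reports) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(x) {
    data.frame(regime = x$regime, domain = x$domain,
               subjects = if (x$regime == "person_specific") x$subject
                          else paste(x$test_subjects, collapse = ","),
               train = round(100 * x$accuracy[["train"]], 1),
               valid = round(100 * x$accuracy[["val"]], 1),
               test = round(100 * x$accuracy[["test"]], 1),
               sensitivity = round(100 * x$metrics$sensitivity, 1),
               specificity = round(100 * x$metrics$specificity, 1),
               precision = round(100 * x$metrics$precision, 1),
               stringsAsFactors = FALSE)
  }))
}

#' Stratified k-fold cross-validation
#'
#' Partitions a labeled image pool into `k` class-stratified folds; each
#' fold serves once as the validation set for a classifier trained on the
#' rest. The classifier is pluggable (any
#' `function(x_train, y_train, x_new) -> labels`) and defaults to the
#' package CNN.
#'
#' @param x Images (`k x k x n` array or `image_set`).
#' @param y Labels (defaults to the image set's conditions).
#' @param k Number of folds, at least 2.
#' @param classifier Classification function as above; `NULL` uses the CNN.
#' @param config [cnn_config()] for the default CNN classifier.
#' @param seed Seed for fold assignment.
#' @return List with `folds` (per-fold data frame: fold, n, accuracy),
#'   `mean_accuracy`, `sd_accuracy`, and `assignments` (fold id per image).
#' @export
kfold_cv <- function(x, y = NULL, k = 5L, classifier = NULL,
                     config = cnn_config(), seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (is.null(y) && inherits(x, "image_set")) y <- x$info$condition
  pixels <- if (inherits(x, "image_set")) x$pixels else x
  y_chr <- if (is.character(y) || is.factor(y)) as.character(y)
           else ifelse(as_binary_labels(y) == 1, "stressed", "non_stressed")
  n <- length(y_chr)
  if (dim(pixels)[3L] != n) stop("labels must match images", call. = FALSE)
  if (length(unique(y_chr)) < 2L)
    stop("the pool must contain both classes", call. = FALSE)
  if (min(table(y_chr)) < k)
    stop("each class needs at least k members for stratified folding",
         call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cls in unique(y_chr)) {
    idx <- which(y_chr == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  if (is.null(classifier)) {
    classifier <- function(x_train, y_train, x_new) {
      cfg <- config
      model <- build_model(cfg)
      model <- suppressWarnings(train_cnn(model, x_train, y_train))
      predict(model, x_new, type = "label")
    }
  }
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    pred <- classifier(pixels[, , tr, drop = FALSE], y_chr[tr],
                       pixels[, , te, drop = FALSE])
    acc[f] <- mean(as.character(pred) == y_chr[te])
  }
  list(folds = data.frame(fold = seq_len(k), n = as.integer(table(fold)),
                          accuracy = acc),
       mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
       assignments = fold)
}
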