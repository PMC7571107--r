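test_that("confusion metrics match the worked examples", {
  labels <- c(rep("stressed", 100), rep("non_stressed", 100))
  preds <- c(rep("stressed", 96), rep("non_stressed", 4),
             rep("non_stressed", 98), rep("stressed", 2))
  m <- evaluate_predictions(labels, preds)
  expect_equal(unname(m$counts), c(96L, 2L, 98L, 4L))  # TP FP TN FN
  expect_equal(m$sensitivity, 0.96)
  expect_equal(m$specificity, 0.98)
  expect_equal(m$accuracy, 0.97)
  # all-correct predictions give perfect metrics
  all_good <- evaluate_predictions(labels, labels)
  expect_equal(all_good$accuracy, 1)
  expect_equal(all_good$sensitivity, 1)
  expect_equal(all_good$specificity, 1)
  expect_equal(all_good$precision, 1)
  expect_error(evaluate_predictions(labels, preds[-1]), "same length")
})

test_that("zero denominators surface as flagged NaN, never silent zero", {
  m <- evaluate_predictions(rep("non_stressed", 5), rep("non_stressed", 5))
  expect_true(is.nan(m$sensitivity))
  expect_true(is.nan(m$precision))
  expect_setequal(m$undefined, c("sensitivity", "precision"))
  expect_equal(m$specificity, 1)
})

test_that("person-specific splits honor stratified 70/15/15 proportions", {
  imgs <- bind_image_sets(list(
    random_onehot_set(500, seed = 1, condition = "stressed"),
    random_onehot_set(500, seed = 2, condition = "non_stressed")))
  split <- make_split(imgs, "person_specific", seed = 4)
  expect_length(split$train, 700L)
  expect_length(split$val, 150L)
  expect_length(split$test, 150L)
  cond <- imgs$info$condition
  expect_equal(sum(cond[split$test] == "stressed"), 75L)
  expect_equal(sum(cond[split$val] == "stressed"), 75L)
  expect_length(intersect(split$train, c(split$val, split$test)), 0L)
  # chronological mode keeps early windows in train, late ones in test
  chron <- make_split(imgs, "person_specific", chronological = TRUE, seed = 4)
  expect_lt(max(imgs$info$start_index[chron$train]),
            min(imgs$info$start_index[chron$test]))
  # too few images: error names the subject
  tiny <- random_onehot_set(4, seed = 3)
  expect_error(make_split(tiny, "person_specific"), "S1")
})

test_that("generic splits keep test subjects strictly out of train and val", {
  sets <- list()
  for (s in 1:6) {
    a <- random_onehot_set(40, seed = s, condition = "stressed")
    b <- random_onehot_set(40, seed = 100 + s, condition = "non_stressed")
    a$info$subject_id <- b$info$subject_id <- paste0("S", s)
    sets <- c(sets, list(a, b))
  }
  imgs <- bind_image_sets(sets)
  split <- make_split(imgs, "generic", test_subjects = c("S2", "S4", "S6"),
                      seed = 17)
  subj <- imgs$info$subject_id
  expect_setequal(unique(subj[split$test]), c("S2", "S4", "S6"))
  expect_length(intersect(unique(subj[c(split$train, split$val)]),
                          c("S2", "S4", "S6")), 0L)
  # train/val is an 85/15 stratified split of the remaining pool
  expect_equal(length(split$val), 2L * floor(120 * 0.15))
  expect_equal(length(split$train) + length(split$val), 240L)
  expect_error(make_split(imgs, "generic"), "test_subjects")
  expect_error(make_split(imgs, "generic", test_subjects = "S99"), "S99")
})

test_that("calibration moves exactly the floored fraction per subject per class", {
  sets <- list()
  for (s in 1:4) {
    a <- random_onehot_set(250, seed = s, condition = "stressed")
    b <- random_onehot_set(250, seed = 50 + s, condition = "non_stressed")
    a$info$subject_id <- b$info$subject_id <- paste0("S", s)
    sets <- c(sets, list(a, b))
  }
  imgs <- bind_image_sets(sets)
  split <- make_split(imgs, "calibrated_generic", test_subjects = "S3",
                      calibration_fraction = 0.2, seed = 8)
  expect_length(split$calibration, 100L)   # floor(0.2 * 250) per class
  expect_length(split$test, 400L)
  expect_true(all(split$calibration %in% split$train))
  expect_length(intersect(split$calibration, split$test), 0L)
  subj <- imgs$info$subject_id
  cond <- imgs$info$condition
  expect_equal(sum(subj[split$calibration] == "S3" &
                   cond[split$calibration] == "stressed"), 50L)
  # leakage contract: train/val touch the test subject only via calibration
  in_train_s3 <- split$train[subj[split$train] == "S3"]
  expect_setequal(in_train_s3, split$calibration)
})

test_that("leakage report quantifies window overlap and chronological splits reduce it", {
  durs <- runif(400, 0.65, 1.15)
  bins <- fit_bins(durs, method = "quantile")
  seqs <- list(make_seq(durs[1:200], condition = "stressed"),
               make_seq(durs[201:400], condition = "non_stressed"))
  imgs <- bind_image_sets(lapply(seqs, make_images, bins = bins))
  rand_split <- make_split(imgs, "person_specific", seed = 3)
  chron_split <- make_split(imgs, "person_specific", chronological = TRUE,
                            seed = 3)
  rand_leak <- leakage_report(rand_split, imgs)
  chron_leak <- leakage_report(chron_split, imgs)
  expect_gt(rand_leak$n_overlapping[rand_leak$set == "test"], 0L)
  expect_lt(chron_leak$n_overlapping[chron_leak$set == "test"],
            rand_leak$n_overlapping[rand_leak$set == "test"])
})

test_that("stratified k-fold partitions each image into exactly one validation fold", {
  imgs <- bind_image_sets(list(
    random_onehot_set(50, seed = 1, condition = "stressed"),
    random_onehot_set(50, seed = 2, condition = "non_stressed")))
  rule <- function(x_train, y_train, x_new)   # fold-independent fixed rule
    ifelse(apply(x_new, 3L, function(m) mean(apply(m, 2L, which.max))) < 14.5,
           "stressed", "non_stressed")
  cv <- kfold_cv(imgs, k = 5, classifier = rule, seed = 31)
  expect_equal(cv$folds$n, rep(20L, 5))
  expect_equal(sort(unique(cv$assignments)), 1:5)
  expect_equal(tabulate(cv$assignments), rep(20L, 5))
  # with a fold-independent classifier the fold-mean equals pooled accuracy
  pooled <- mean(rule(NULL, NULL, imgs$pixels) == imgs$info$condition)
  expect_equal(cv$mean_accuracy, pooled)
  expect_error(kfold_cv(imgs, k = 1), "at least 2")
  expect_error(kfold_cv(imgs[c(1:3, 51:53)], k = 5), "at least k")
  expect_error(kfold_cv(imgs[1:6], k = 5), "both classes")
})

test_that("report tables mirror the regime/domain layout with one-decimal percents", {
  rep1 <- structure(list(regime = "generic", domain = "spatial",
                         subject = NULL, test_subjects = c("S2", "S3"),
                         n = c(train = 10, val = 5, test = 5),
                         accuracy = c(train = 0.987, val = 0.9, test = 0.61),
                         metrics = evaluate_predictions(
                           c("stressed", "stressed", "non_stressed"),
                           c("stressed", "non_stressed", "non_stressed"))),
                    class = "eval_report")
  tab <- report_table(rep1)
  expect_equal(tab$test, 61.0)
  expect_equal(tab$train, 98.7)
  expect_equal(tab$subjects, "S2,S3")
})
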