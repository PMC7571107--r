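test_that("cohort specs are validated", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(mu_stressed = 0.9, mu_nonstressed = 0.85),
               "stress raises heart rate")
  expect_error(cohort_spec(sd_stressed = 0.2, sd_nonstressed = 0.08),
               "stress lowers HRV")
  expect_error(cohort_spec(ar_coefficient = 1), "0, 1")
  expect_error(generate_subject(cohort_spec(n_subjects = 2), 3),
               "1..n_subjects", fixed = TRUE)
})

test_that("zero-noise limit produces constant sequences at the condition means", {
  spec <- cohort_spec(n_subjects = 1, beats_per_condition = 50,
                      sd_nonstressed = 0, sd_stressed = 0, subject_shift_sd = 0)
  pair <- generate_subject(spec, 1)
  expect_equal(pair$stressed$durations, rep(spec$mu_stressed, 50))
  expect_equal(pair$non_stressed$durations, rep(spec$mu_nonstressed, 50))
})

test_that("generation is reproducible per (seed, subject) and differs across seeds", {
  spec <- cohort_spec(n_subjects = 3, beats_per_condition = 200, seed = 9)
  a <- generate_subject(spec, 2)
  b <- generate_subject(spec, 2)
  expect_identical(a, b)
  spec2 <- cohort_spec(n_subjects = 3, beats_per_condition = 200, seed = 10)
  expect_false(identical(generate_subject(spec2, 2)$stressed$durations,
                         a$stressed$durations))
  # different subjects under one seed are different too
  expect_false(identical(generate_subject(spec, 1)$stressed$durations,
                         a$stressed$durations))
})

test_that("sample means track the condition mean within AR(1) standard error", {
  n <- 4000
  spec <- cohort_spec(n_subjects = 1, beats_per_condition = n,
                      subject_shift_sd = 0, seed = 21)
  pair <- generate_subject(spec, 1)
  phi <- spec$ar_coefficient
  se_ns <- spec$sd_nonstressed * sqrt((1 + phi) / (1 - phi) / n)
  expect_lt(abs(mean(pair$non_stressed$durations) - spec$mu_nonstressed),
            3 * se_ns)
  se_s <- spec$sd_stressed * sqrt((1 + phi) / (1 - phi) / n)
  # stressed mean sits closer to the clipping floor; allow the clip bias
  expect_lt(abs(mean(pair$stressed$durations) - spec$mu_stressed),
            3 * se_s + 0.005)
})

test_that("a windowed-mean threshold separates the conditions almost perfectly", {
  # with no subject heterogeneity the generator's class signal must be strong
  spec <- cohort_spec(n_subjects = 3, beats_per_condition = 500,
                      subject_shift_sd = 0, seed = 5)
  cohort <- generate_cohort(spec)
  threshold <- (spec$mu_stressed + spec$mu_nonstressed) / 2
  correct <- total <- 0
  for (pair in cohort) {
    for (seq in pair) {
      wm <- vapply(seq_len(length(seq) - 27L),
                   function(s) mean(seq$durations[s:(s + 27L)]), 0)
      pred_stressed <- wm < threshold
      correct <- correct + sum(pred_stressed == (seq$condition == "stressed"))
      total <- total + length(wm)
    }
  }
  expect_gt(correct / total, 0.99)
})

test_that("subject heterogeneity increases between-subject mean spread", {
  mean_spread <- function(shift_sd, seed) {
    spec <- cohort_spec(n_subjects = 12, beats_per_condition = 300,
                        subject_shift_sd = shift_sd, seed = seed)
    means <- vapply(generate_cohort(spec),
                    function(p) mean(p$non_stressed$durations), 0)
    stats::var(means)
  }
  expect_gt(mean_spread(0.08, 31), mean_spread(0.01, 31))
})

test_that("contamination inserts out-of-range beats that filtering removes", {
  spec <- cohort_spec(n_subjects = 1, beats_per_condition = 400,
                      contamination = 0.2, seed = 13)
  seq <- generate_subject(spec, 1)$non_stressed
  n_bad <- sum(seq$durations < 0.6 | seq$durations > 1.2)
  expect_gt(n_bad, 20)
  kept <- filter_physiologic(seq)
  expect_equal(length(kept), 400L - n_bad)
  expect_true(all(kept$durations >= 0.6 & kept$durations <= 1.2))
  # without contamination, clipping makes filtering a no-op
  spec0 <- cohort_spec(n_subjects = 1, beats_per_condition = 400, seed = 13)
  seq0 <- generate_subject(spec0, 1)$non_stressed
  expect_equal(length(filter_physiologic(seq0)), 400L)
})

test_that("cohorts have the requested shape and write/read as IBI files", {
  spec <- cohort_spec(n_subjects = 15, beats_per_condition = 40, seed = 2)
  cohort <- generate_cohort(spec)
  expect_length(cohort, 15L)
  expect_setequal(names(cohort[[1]]), c("stressed", "non_stressed"))
  seqs <- cohort_sequences(cohort)
  expect_length(seqs, 30L)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, spec = spec)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_ibi_file(file.path(dir, "S3_stressed.csv"), "S3", "stressed")
  expect_equal(back$durations, cohort[[3]]$stressed$durations,
               tolerance = 1e-12)
})
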