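#' Specification of a synthetic IBI cohort
#'
#' Defines the statistical structure of a simulated multi-subject study in
#' which acute stress shortens the mean inter-beat interval and reduces its
#' variability, and subjects differ by a stable individual offset in mean
#' IBI. Within a sequence, beats follow a stationary first-order
#' autoregressive (AR(1)) process, mimicking the beat-to-beat smoothness of
#' real heart-period series; generated durations are clipped to the
#' physiologic range so that range filtering is a no-op unless contamination
#' is requested.
#'
#' @param n_subjects Number of subjects (default 15, a typical laboratory
#'   stress-study cohort size).
#' @param beats_per_condition Beats generated per subject per condition.
#' @param mu_nonstressed,mu_stressed Condition mean IBI in seconds; stress
#'   must shorten the beat (`mu_stressed < mu_nonstressed`).
#' @param sd_nonstressed,sd_stressed Condition marginal IBI standard
#'   deviation in seconds; stress must reduce variability.
#' @param ar_coefficient AR(1) coefficient in `[0, 1)`. The default 0.45
#'   keeps beat-to-beat smoothness while preserving the generator's core
#'   contract that 28-beat window means separate the two conditions almost
#'   perfectly when subjects are homogeneous (the variance of a window mean
#'   grows with `(1+ar)/(1-ar)`, so strong autocorrelation would wash the
#'   class signal out of short windows).
#' @param subject_shift_sd Standard deviation (seconds) of the per-subject
#'   mean-IBI offset shared by both conditions; the knob controlling how much
#'   generic (cross-subject) models degrade.
#' @param contamination Fraction of beats replaced by out-of-range artifacts,
#'   to exercise [filter_physiologic()] (default 0).
#' @param range Physiologic clipping range in seconds.
#' @param seed Integer master seed; all randomness derives from it.
#' @return A validated object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 15L, beats_per_condition = 1000L,
                        mu_nonstressed = 0.85, mu_stressed = 0.70,
                        sd_nonstressed = 0.08, sd_stressed = 0.04,
                        ar_coefficient = 0.45, subject_shift_sd = 0.05,
                        contamination = 0, range = c(0.6, 1.2), seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               beats_per_condition = as.integer(beats_per_condition),
               mu_nonstressed = mu_nonstressed, mu_stressed = mu_stressed,
               sd_nonstressed = sd_nonstressed, sd_stressed = sd_stressed,
               ar_coefficient = ar_coefficient,
               subject_shift_sd = subject_shift_sd,
               contamination = contamination, range = as.numeric(range),
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
    if (beats_per_condition < 1L) stop("beats_per_condition must be >= 1", call. = FALSE)
    if (!(mu_stressed < mu_nonstressed))
      stop("mu_stressed must be below mu_nonstressed (stress raises heart rate)",
           call. = FALSE)
    if (sd_stressed > sd_nonstressed)
      stop("sd_stressed must not exceed sd_nonstressed (stress lowers HRV)",
           call. = FALSE)
    if (ar_coefficient < 0 || ar_coefficient >= 1)
      stop("ar_coefficient must lie in [0, 1)", call. = FALSE)
    if (subject_shift_sd < 0) stop("subject_shift_sd must be >= 0", call. = FALSE)
    if (contamination < 0 || contamination >= 1)
      stop("contamination must lie in [0, 1)", call. = FALSE)
    if (length(range) != 2L || range[1] >= range[2])
      stop("range must be c(low, high) with low < high", call. = FALSE)
  })
  invisible(spec)
}

# Per-subject RNG stream: deterministic in (seed, subject_index), independent
# of generation order. Kept below 2^31 - 1.
subject_seed <- function(seed, subject_index) {
  as.integer((as.double(seed) * 48271 + subject_index * 104729) %% 2147483647)
}

ar1_series <- function(n, mu, sd, phi) {
  if (sd == 0) return(rep(mu, n))
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1L] <- rnorm(1L, mu, sd)  # stationary start
  eps <- rnorm(n - 1L, 0, innov_sd)
  for (t in seq_len(n - 1L)) x[t + 1L] <- mu + phi * (x[t] - mu) + eps[t]
  x
}

#' Generate one synthetic subject
#'
#' Draws the subject's mean-IBI offset once, then simulates a stressed and a
#' non-stressed AR(1) duration sequence around the shifted condition means,
#' clips to the physiologic range, and (optionally) injects out-of-range
#' artifact beats. Fully reproducible from `(spec$seed, subject_index)`.
#'
#' @param spec A [cohort_spec()].
#' @param subject_index Integer in `1..spec$n_subjects`.
#' @return Named list with elements `stressed` and `non_stressed`, each an
#'   [ibi_sequence()] with subject id `S<subject_index>`.
#' @export
generate_subject <- function(spec, subject_index) {
  validate_cohort_spec(spec)
  if (subject_index < 1L || subject_index > spec$n_subjects)
    stop("subject_index must lie in 1..n_subjects", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subject_seed(spec$seed, subject_index))
  offset <- if (spec$subject_shift_sd > 0) rnorm(1L, 0, spec$subject_shift_sd) else 0
  n <- spec$beats_per_condition
  make_cond <- function(condition, mu, sd) {
    x <- ar1_series(n, mu + offset, sd, spec$ar_coefficient)
    x <- pmin(pmax(x, spec$range[1]), spec$range[2])
    if (spec$contamination > 0) {
      bad <- runif(n) < spec$contamination
      if (any(bad)) {
        n_bad <- sum(bad)
        lowside <- runif(n_bad) < 0.5
        x[bad] <- ifelse(lowside,
                         runif(n_bad, spec$range[1] / 3, spec$range[1] * 0.99),
                         runif(n_bad, spec$range[2] * 1.01, spec$range[2] * 2))
      }
    }
    ibi_sequence(paste0("S", subject_index), condition,
                 timestamps = cumsum(x), durations = x)
  }
  list(stressed = make_cond("stressed", spec$mu_stressed, spec$sd_stressed),
       non_stressed = make_cond("non_stressed", spec$mu_nonstressed,
                                spec$sd_nonstressed))
}

# save/restore the global RNG state so generation does not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a labeled synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return List of length `spec$n_subjects`; each element is the
#'   stressed/non-stressed pair returned by [generate_subject()].
#' @seealso [cohort_sequences()] to flatten the pairs into one list,
#'   [write_cohort()] to persist the cohort as IBI CSV files.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  lapply(seq_len(spec$n_subjects), function(i) generate_subject(spec, i))
}

#' Flatten a cohort into a plain list of sequences
#'
#' @param cohort Result of [generate_cohort()].
#' @return Unnamed list of [ibi_sequence()] objects (two per subject).
#' @export
cohort_sequences <- function(cohort) {
  unlist(cohort, recursive = FALSE, use.names = FALSE)
}

#' Write a cohort as IBI CSV files plus a manifest
#'
#' One file per subject per condition (`<subject>_<condition>.csv`) in the
#' dialect of [write_ibi_file()], plus `manifest.json` recording the true
#' generating parameters.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param spec The [cohort_spec()] used, stored in the manifest (optional).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (pair in cohort) {
    for (seq in pair) {
      f <- file.path(dir, sprintf("%s_%s.csv", seq$subject_id, seq$condition))
      write_ibi_file(seq, f)
      files <- c(files, basename(f))
    }
  }
  manifest <- list(files = files)
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
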