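#' Labeled inter-beat-interval sequence
#'
#' Container for one subject's ordered beat durations in one experimental
#' condition, as exported by wrist-worn PPG devices (one row per detected
#' beat: a timestamp in seconds since session start and the beat-to-beat
#' duration in seconds).
#'
#' `boundaries` records segment joins created by [merge_stress_segments()]:
#' `boundaries = c(50)` means beats 1..50 come from the first segment and
#' beats 51..n from the second. Sliding windows built by [make_images()]
#' never span a recorded boundary.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param condition Either `"stressed"` or `"non_stressed"`.
#' @param timestamps Numeric vector, seconds since session start, strictly
#'   increasing.
#' @param durations Numeric vector of beat durations in seconds, positive,
#'   same length as `timestamps`.
#' @param boundaries Integer vector of cumulative segment lengths (see above).
#' @return An object of class `ibi_sequence`.
#' @export
ibi_sequence <- function(subject_id, condition, timestamps, durations,
                         boundaries = integer(0)) {
  condition <- match.arg(condition, c("stressed", "non_stressed"))
  subject_id <- as.character(subject_id)
  timestamps <- as.numeric(timestamps)
  durations <- as.numeric(durations)
  boundaries <- as.integer(boundaries)
  if (length(timestamps) != length(durations))
    stop("timestamps and durations must have the same length", call. = FALSE)
  if (length(durations) && any(durations <= 0))
    stop("all beat durations must be > 0", call. = FALSE)
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (length(boundaries) &&
      (any(boundaries <= 0) || any(boundaries >= length(durations)) ||
       is.unsorted(boundaries, strictly = TRUE)))
    stop("boundaries must be strictly increasing indices inside the sequence",
         call. = FALSE)
  structure(
    list(subject_id = subject_id, condition = condition,
         timestamps = timestamps, durations = durations,
         boundaries = boundaries),
    class = "ibi_sequence"
  )
}

#' @export
print.ibi_sequence <- function(x, ...) {
  cat(sprintf("<ibi_sequence> subject %s, %s: %d beats",
              x$subject_id, x$condition, length(x$durations)))
  if (length(x$durations))
    cat(sprintf(", mean IBI %.3f s", mean(x$durations)))
  if (length(x$boundaries))
    cat(sprintf(", %d segment boundar%s", length(x$boundaries),
                if (length(x$boundaries) == 1) "y" else "ies"))
  cat("\n")
  invisible(x)
}

#' @export
length.ibi_sequence <- function(x) length(x$durations)

# 1-based start index of each unbroken segment, and its length
segment_table <- function(seq) {
  n <- length(seq$durations)
  starts <- c(1L, seq$boundaries + 1L)
  ends <- c(seq$boundaries, n)
  data.frame(start = starts, end = ends, length = ends - starts + 1L)
}

#' Read an IBI file
#'
#' Parses a two-column comma-separated IBI file (timestamp, beat duration in
#' seconds). The Empatica E4 dialect, whose first line carries the session
#' start epoch and the literal token `IBI`, is detected and the header line
#' skipped; plain numeric two-column CSV is accepted as-is.
#'
#' @param path Path to the file.
#' @param subject_id Subject identifier to attach.
#' @param condition `"stressed"` or `"non_stressed"`.
#' @return An [ibi_sequence()].
#' @seealso [write_ibi_file()] for the inverse operation.
#' @export
read_ibi_file <- function(path, subject_id, condition) {
  if (!file.exists(path))
    stop(sprintf("cannot read IBI file '%s': no such file", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first_data <- 1L
  if (length(lines)) {
    fields <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(trimws(fields)))
    if (length(fields) != 2L || anyNA(vals)) first_data <- 2L  # header line
  }
  data_lines <- lines[seq_along(lines) >= first_data]
  if (!length(data_lines))
    stop(sprintf("IBI file '%s' contains no data rows", path), call. = FALSE)
  parsed <- lapply(seq_along(data_lines), function(i) {
    fields <- strsplit(data_lines[[i]], ",", fixed = TRUE)[[1L]]
    vals <- suppressWarnings(as.numeric(trimws(fields)))
    if (length(vals) != 2L || anyNA(vals))
      stop(sprintf("IBI file '%s': cannot parse line %d ('%s') as two numbers",
                   path, i + first_data - 1L, data_lines[[i]]), call. = FALSE)
    vals
  })
  m <- do.call(rbind, parsed)
  boundaries <- integer(0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$boundaries)) boundaries <- as.integer(meta$boundaries)
    if (missing(subject_id) && !is.null(meta$subject_id)) subject_id <- meta$subject_id
    if (missing(condition) && !is.null(meta$condition)) condition <- meta$condition
  }
  ibi_sequence(subject_id, condition, m[, 1L], m[, 2L], boundaries)
}

#' Write an IBI sequence to disk
#'
#' Serializes in the same two-column CSV dialect accepted by
#' [read_ibi_file()], with an optional E4-style header line, plus a JSON
#' sidecar (`<path>.json`) holding the subject, condition and segment
#' boundaries.
#'
#' @param seq An [ibi_sequence()].
#' @param path Output file path.
#' @param header Write an E4-style first line (default `TRUE`).
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_ibi_file <- function(seq, path, header = TRUE, sidecar = TRUE) {
  stopifnot(inherits(seq, "ibi_sequence"))
  rows <- sprintf("%s,%s",
                  formatC(seq$timestamps, digits = 17, format = "g", width = 1),
                  formatC(seq$durations, digits = 17, format = "g", width = 1))
  if (header) rows <- c("0.000000, IBI", rows)
  writeLines(rows, path)
  if (sidecar) {
    jsonlite::write_json(
      list(subject_id = seq$subject_id, condition = seq$condition,
           boundaries = seq$boundaries),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Keep only physiologically plausible beats
#'
#' Drops beats whose duration falls outside `[low, high]` seconds; the
#' default 0.6-1.2 s window corresponds to resting heart rates of 50-100
#' beats per minute. Order and the pairing of timestamps with their beats
#' are preserved, and recorded segment boundaries are remapped to the
#' retained beats. Idempotent.
#'
#' @param seq An [ibi_sequence()].
#' @param low,high Inclusive bounds in seconds, `low < high`.
#' @return A filtered [ibi_sequence()] (possibly with zero beats).
#' @export
filter_physiologic <- function(seq, low = 0.6, high = 1.2) {
  stopifnot(inherits(seq, "ibi_sequence"), low < high)
  keep <- seq$durations >= low & seq$durations <= high
  kept_before <- cumsum(keep)
  new_bounds <- if (length(seq$boundaries)) kept_before[seq$boundaries] else integer(0)
  n_new <- sum(keep)
  new_bounds <- unique(new_bounds[new_bounds > 0L & new_bounds < n_new])
  ibi_sequence(seq$subject_id, seq$condition,
               seq$timestamps[keep], seq$durations[keep], new_bounds)
}

#' Concatenate same-condition segments of one subject
#'
#' Joins multiple recording segments (e.g., the public-speaking and mental
#' arithmetic parts of a stress protocol) into a single labeled sequence.
#' The join positions are recorded as segment boundaries so that downstream
#' sliding windows never mix beats from different segments.
#'
#' @param segments List of [ibi_sequence()] objects sharing `subject_id` and
#'   `condition`.
#' @return A single merged [ibi_sequence()].
#' @export
merge_stress_segments <- function(segments) {
  if (!length(segments) || !all(vapply(segments, inherits, TRUE, "ibi_sequence")))
    stop("segments must be a non-empty list of ibi_sequence objects", call. = FALSE)
  if (length(segments) == 1L) return(segments[[1L]])
  subj <- unique(vapply(segments, `[[`, "", "subject_id"))
  cond <- unique(vapply(segments, `[[`, "", "condition"))
  if (length(subj) != 1L)
    stop("cannot merge segments from different subjects: ",
         paste(subj, collapse = ", "), call. = FALSE)
  if (length(cond) != 1L)
    stop("cannot merge segments with different condition labels: ",
         paste(cond, collapse = ", "), call. = FALSE)
  lens <- vapply(segments, function(s) length(s$durations), 1L)
  # re-base timestamps so the merged vector stays strictly increasing
  ts <- vector("list", length(segments))
  offset <- 0
  for (i in seq_along(segments)) {
    t_i <- segments[[i]]$timestamps
    ts[[i]] <- t_i - t_i[1L] + offset + segments[[i]]$durations[1L]
    offset <- ts[[i]][length(t_i)]
  }
  inner <- lapply(seq_along(segments), function(i) {
    b <- segments[[i]]$boundaries
    if (length(b)) b + sum(lens[seq_len(i - 1L)]) else integer(0)
  })
  boundaries <- sort(unique(c(cumsum(lens[-length(lens)]), unlist(inner))))
  ibi_sequence(subj, cond, unlist(ts),
               unlist(lapply(segments, `[[`, "durations")), boundaries)
}
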