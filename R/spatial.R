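#' Fit an IBI binning scheme
#'
#' Divides the physiologic IBI range into `k` ordered intervals used as the
#' rows of the spatial image. `"quantile"` (the default) places interior
#' edges at empirical quantiles of the supplied durations so each interval
#' captures roughly equal mass; the outer edges are anchored to the
#' configured physiologic range so that a scheme fitted on training subjects
#' still covers every filtered test-subject beat. `"equal_width"` spaces all
#' edges evenly over the range.
#'
#' Degenerate quantile fits (fewer distinct duration values than intervals)
#' fall back to equal-width edges; duplicated quantile edges are deduplicated
#' and the widest remaining gaps split until `k` intervals are restored. Both
#' events are recorded in the scheme's `warnings` field rather than raised.
#'
#' @param durations Numeric vector of filtered beat durations (seconds),
#'   all within `range`.
#' @param k Number of intervals (rows of the image), default 28.
#' @param method `"quantile"` or `"equal_width"`.
#' @param range Physiologic range `c(low, high)` in seconds.
#' @return An object of class `binning_scheme` with fields `edges`
#'   (length `k + 1`, strictly increasing), `k`, `method` (as used),
#'   `range`, `warnings`.
#' @export
fit_bins <- function(durations, k = 28L, method = c("quantile", "equal_width"),
                     range = c(0.6, 1.2)) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (!length(durations)) stop("durations must be non-empty", call. = FALSE)
  if (any(durations < range[1] | durations > range[2]))
    stop("all durations must lie within the configured range; filter first",
         call. = FALSE)
  warn <- character(0)
  if (method == "quantile" && length(unique(durations)) < k) {
    warn <- c(warn, "fewer distinct durations than intervals; fell back to equal-width bins")
    method <- "equal_width"
  }
  if (method == "equal_width") {
    edges <- seq(range[1], range[2], length.out = k + 1L)
  } else {
    edges <- unname(stats::quantile(durations, probs = seq(0, 1, length.out = k + 1L),
                                    type = 7, names = FALSE))
    edges[1L] <- range[1]
    edges[k + 1L] <- range[2]
    if (any(diff(edges) <= 0)) {
      warn <- c(warn, "duplicated quantile edges; deduplicated and widest gaps split")
      ed <- sort(unique(edges))
      while (length(ed) < k + 1L) {
        gaps <- diff(ed)
        i <- which.max(gaps)
        ed <- sort(c(ed, ed[i] + gaps[i] / 2))
      }
      edges <- ed
    }
  }
  structure(list(edges = edges, k = k, method = method,
                 range = as.numeric(range), warnings = warn),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> %d %s intervals over [%.3f, %.3f] s\n",
              x$k, x$method, x$edges[1], x$edges[x$k + 1]))
  if (length(x$warnings)) cat(" note:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Map beat durations to bin (row) indices
#'
#' Interval `i` is `[edges[i], edges[i+1])`; the last interval is closed on
#' the right so the top edge maps to row `k`. Indices are 1-based.
#'
#' @param duration Numeric vector of durations in seconds, all within the
#'   scheme's edge span.
#' @param bins A [fit_bins()] scheme.
#' @return Integer vector of row indices in `1..k`.
#' @export
encode_beat <- function(duration, bins) {
  stopifnot(inherits(bins, "binning_scheme"))
  lo <- bins$edges[1L]
  hi <- bins$edges[bins$k + 1L]
  if (any(duration < lo | duration > hi))
    stop(sprintf("duration outside the binning range [%g, %g]; filter first", lo, hi),
         call. = FALSE)
  idx <- findInterval(duration, bins$edges, rightmost.closed = TRUE)
  as.integer(idx)
}

#' Encode an IBI sequence as 28x28 one-hot spatial images
#'
#' Each beat becomes a one-hot column vector over the `k = 28` duration
#' intervals of `bins`; a sliding window of `window` consecutive beats,
#' advanced by `stride` beats, yields one `k x window` binary image per
#' position (column `j` encodes beat `start_index + j - 1`; row 1 is the
#' shortest-IBI interval). Windows never span a recorded segment boundary.
#' An unbroken segment of `L` beats yields `floor((L - window)/stride) + 1`
#' images when `L >= window`, otherwise none.
#'
#' @param seq A range-filtered [ibi_sequence()].
#' @param bins A [fit_bins()] scheme with `k = window` rows.
#' @param window Window length in beats (default 28).
#' @param stride Window advance in beats (default 1, i.e., move by one
#'   column).
#' @return An object of class `image_set`: list with `pixels` (array
#'   `k x window x n`), `info` (data frame: `subject_id`, `condition`,
#'   `start_index`), `domain = "spatial"`, `bins`, `window`, `stride`.
#' @export
make_images <- function(seq, bins, window = 28L, stride = 1L) {
  stopifnot(inherits(seq, "ibi_sequence"), inherits(bins, "binning_scheme"))
  window <- as.integer(window)
  stride <- as.integer(stride)
  if (window != bins$k)
    stop("window must equal the number of bin rows (square image)", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  idx <- if (length(seq$durations)) encode_beat(seq$durations, bins) else integer(0)
  segs <- segment_table(seq)
  starts <- integer(0)
  for (s in seq_len(nrow(segs))) {
    L <- segs$length[s]
    if (L >= window)
      starts <- c(starts, seq.int(segs$start[s], segs$start[s] + L - window,
                                  by = stride))
  }
  n <- length(starts)
  pixels <- array(0, dim = c(bins$k, window, n))
  if (n) {
    col_j <- rep(seq_len(window), times = n)
    slice <- rep(seq_len(n), each = window)
    beat <- rep(starts, each = window) + col_j - 1L
    pixels[cbind(idx[beat], col_j, slice)] <- 1
  }
  structure(
    list(pixels = pixels,
         info = data.frame(subject_id = rep(seq$subject_id, n),
                           condition = rep(seq$condition, n),
                           start_index = starts,
                           stringsAsFactors = FALSE),
         domain = "spatial", bins = bins,
         window = window, stride = stride),
    class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d %s-domain %dx%d images (%d subject%s)\n",
              n_images(x), x$domain, dim(x$pixels)[1], dim(x$pixels)[2],
              length(unique(x$info$subject_id)),
              if (length(unique(x$info$subject_id)) == 1) "" else "s"))
  invisible(x)
}

#' Number of images in an image set
#' @param x An `image_set`.
#' @return Integer count.
#' @export
n_images <- function(x) {
  stopifnot(inherits(x, "image_set"))
  dim(x$pixels)[3L]
}

#' Combine image sets
#'
#' Concatenates sets that share domain, window, stride and image shape
#' (e.g., the per-sequence outputs of [make_images()] over a cohort encoded
#' with one shared binning scheme).
#'
#' @param sets List of `image_set` objects.
#' @return A single `image_set`.
#' @export
bind_image_sets <- function(sets) {
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "image_set")))
  if (length(sets) == 1L) return(sets[[1L]])
  dom <- unique(vapply(sets, `[[`, "", "domain"))
  if (length(dom) != 1L) stop("cannot bind image sets from different domains",
                              call. = FALSE)
  dims <- vapply(sets, function(s) dim(s$pixels)[1:2], integer(2))
  if (any(dims != dims[, 1L])) stop("image shapes differ", call. = FALSE)
  pixels <- array(unlist(lapply(sets, `[[`, "pixels"), use.names = FALSE),
                  dim = c(dims[, 1L], sum(vapply(sets, n_images, 1L))))
  out <- sets[[1L]]
  out$pixels <- pixels
  out$info <- do.call(rbind, lapply(sets, `[[`, "info"))
  rownames(out$info) <- NULL
  out
}

#' Subset an image set
#' @param x An `image_set`.
#' @param i Integer or logical index over images.
#' @param ... Unused.
#' @return An `image_set` with the selected images.
#' @export
`[.image_set` <- function(x, i, ...) {
  x$pixels <- x$pixels[, , i, drop = FALSE]
  x$info <- x$info[i, , drop = FALSE]
  rownames(x$info) <- NULL
  x
}

#' Mean pixel intensity of an image
#'
#' The intensity of an image is the arithmetic mean of all its pixel values
#' on the rendered grayscale. Internal spatial matrices hold `{0,1}` and are
#' mapped to `{0, rendered_scale}`; frequency-domain images are already on
#' the 0-255 scale and are averaged as stored.
#'
#' @param img A single image matrix, or an `image_set` (then a vector of
#'   per-image intensities is returned).
#' @param rendered_scale Full-scale value for binary spatial images
#'   (default 255).
#' @param domain `"spatial"` or `"frequency"`; inferred for an `image_set`.
#' @return Numeric intensity (or vector thereof).
#' @export
image_intensity <- function(img, rendered_scale = 255, domain = "spatial") {
  if (inherits(img, "image_set")) {
    scale <- if (img$domain == "spatial") rendered_scale else 1
    return(apply(img$pixels, 3L, mean) * scale)
  }
  scale <- if (identical(domain, "spatial")) rendered_scale else 1
  mean(img) * scale
}

#' Quadrant intensities of an image
#'
#' Splits the image into its four half-size corner blocks (lower-left,
#' lower-right, upper-left, upper-right, with row 1 = lowest IBI interval =
#' bottom) and returns each block's mean intensity; the mean of the four
#' equals the whole-image intensity.
#'
#' @inheritParams image_intensity
#' @return Named numeric vector of length 4.
#' @export
quadrant_intensity <- function(img, rendered_scale = 255, domain = "spatial") {
  stopifnot(is.matrix(img))
  h <- nrow(img) %/% 2L
  w <- ncol(img) %/% 2L
  scale <- if (identical(domain, "spatial")) rendered_scale else 1
  c(lower_left  = mean(img[seq_len(h), seq_len(w)]) * scale,
    lower_right = mean(img[seq_len(h), (w + 1L):ncol(img)]) * scale,
    upper_left  = mean(img[(h + 1L):nrow(img), seq_len(w)]) * scale,
    upper_right = mean(img[(h + 1L):nrow(img), (w + 1L):ncol(img)]) * scale)
}

#' Export an image set as grayscale PNG files
#'
#' Display-only convenience; images are vertically flipped at export so the
#' shortest-IBI row appears at the bottom. Requires the `png` package.
#'
#' @param x An `image_set`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
export_png <- function(x, dir) {
  stopifnot(inherits(x, "image_set"))
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- if (x$domain == "spatial") 1 else 1 / 255
  paths <- character(n_images(x))
  for (i in seq_len(n_images(x))) {
    m <- x$pixels[, , i] * scale
    m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # flip for display
    paths[i] <- file.path(dir, sprintf("%s_%s_%05d.png", x$info$subject_id[i],
                                       x$info$condition[i], x$info$start_index[i]))
    png::writePNG(pmin(pmax(m, 0), 1), paths[i])
  }
  invisible(paths)
}
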