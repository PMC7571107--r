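#' Reference 2-D discrete Fourier transform (direct double sum)
#'
#' Evaluates, for every frequency pair `(u, v)`, the normalized double sum
#' `F(u,v) = (1/(M*N)) * sum_x sum_y f(x,y) exp(-2i*pi*(u*x/M + v*y/N))`
#' by direct accumulation. Quadratic per output point and intended purely as
#' an independent oracle for the fast transform used by
#' [to_frequency_images()].
#'
#' @param pixels A square numeric matrix.
#' @return Complex matrix of the same size.
#' @export
dft2_reference <- function(pixels) {
  if (!is.matrix(pixels) || nrow(pixels) != ncol(pixels))
    stop("pixels must be a square matrix", call. = FALSE)
  M <- nrow(pixels)
  N <- ncol(pixels)
  xs <- 0:(M - 1)
  ys <- 0:(N - 1)
  out <- matrix(0 + 0i, M, N)
  for (u in xs) {
    for (v in ys) {
      phase <- outer(xs * u / M, ys * v / N, `+`)
      out[u + 1L, v + 1L] <- sum(pixels * exp(-2i * pi * phase))
    }
  }
  out / (M * N)
}

# move the zero-frequency component to the matrix center: circular shift by
# floor(n/2) along each dimension (even or odd sizes)
fftshift2 <- function(x) {
  n1 <- nrow(x)
  n2 <- ncol(x)
  s1 <- floor(n1 / 2)
  s2 <- floor(n2 / 2)
  x[c(seq.int(n1 - s1 + 1L, n1), seq_len(n1 - s1)),
    c(seq.int(n2 - s2 + 1L, n2), seq_len(n2 - s2)), drop = FALSE]
}

# Core of the spatial -> frequency pipeline for a single matrix; returns the
# normalized matrix plus a flag for a degenerate contrast range. Magnitudes
# below a relative noise floor are treated as exact zero energy: the fast
# transform leaves O(1e-13) rounding residue where the exact spectrum is
# zero, and the base-10 log would otherwise amplify that noise into the
# darkest normalized pixels.
freq_transform_one <- function(m, noise_floor = 1e-12) {
  mag <- Mod(fftshift2(stats::fft(m)))
  mag[mag < max(mag) * noise_floor] <- 0
  l <- log10(mag)
  fin <- is.finite(l)
  if (!any(fin))
    return(list(pixels = matrix(0, nrow(m), ncol(m)), degenerate = TRUE))
  mn <- min(l[fin])
  mx <- max(l[fin])
  out <- matrix(0, nrow(m), ncol(m))
  if (mx == mn) {
    if (all(fin))  # constant spectrum: no contrast to normalize
      return(list(pixels = out, degenerate = TRUE))
    # single finite level over a zero-energy background (e.g. a pure DC
    # image): the finite pixels carry all the energy and render brightest
    out[fin] <- 255
    return(list(pixels = out, degenerate = FALSE))
  }
  out <- (l - mn) / (mx - mn) * 255
  out[!fin] <- 0  # zero spectral energy renders darkest
  list(pixels = out, degenerate = FALSE)
}

#' Transform spatial images to frequency-domain images
#'
#' Applies, per image, the pipeline: 2-D fast Fourier transform, shift of
#' the zero-frequency component to the matrix center, magnitude, base-10
#' logarithm, then an affine min-max rescaling of the finite entries to
#' `[0, 255]`. Pixels with zero spectral magnitude (log = -Inf) are mapped
#' to 0. If the finite range is degenerate (max = min) the image becomes
#' all-zero and a warning record is stored in the result's `warnings`
#' field instead of raising an error.
#'
#' The unnormalized fast transform is used: the `1/(MN)` factor of the
#' textbook transform definition is a constant per image and cancels in the
#' min-max normalization.
#'
#' @param x An `image_set` with `domain = "spatial"`, or a single numeric
#'   matrix (then a plain matrix is returned).
#' @return An `image_set` with `domain = "frequency"` and pixel values in
#'   `[0, 255]` (plus a `warnings` character vector), or a matrix for matrix
#'   input.
#' @export
to_frequency_images <- function(x) {
  if (is.matrix(x)) return(freq_transform_one(x)$pixels)
  stopifnot(inherits(x, "image_set"))
  if (x$domain != "spatial")
    stop("input image_set must be in the spatial domain", call. = FALSE)
  n <- n_images(x)
  out <- x
  warnings <- character(0)
  for (i in seq_len(n)) {
    r <- freq_transform_one(x$pixels[, , i])
    out$pixels[, , i] <- r$pixels
    if (r$degenerate)
      warnings <- c(warnings,
                    sprintf("image %d: degenerate contrast range; emitted all-zero image", i))
  }
  out$domain <- "frequency"
  out$warnings <- warnings
  out
}
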