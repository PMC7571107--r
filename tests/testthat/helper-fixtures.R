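# shared fixture builders; everything is generated in code at test time

make_seq <- function(durations, subject = "S1", condition = "non_stressed",
                     boundaries = integer(0)) {
  ibi_sequence(subject, condition, timestamps = cumsum(durations),
               durations = durations, boundaries = boundaries)
}

# random one-hot spatial images as an image_set (k x k, n slices)
random_onehot_set <- function(n, k = 28L, seed = 1L, condition = "stressed") {
  set.seed(seed)
  pixels <- array(0, dim = c(k, k, n))
  for (i in seq_len(n))
    pixels[cbind(sample.int(k, k, replace = TRUE), seq_len(k), i)] <- 1
  structure(list(pixels = pixels,
                 info = data.frame(subject_id = rep("S1", n),
                                   condition = rep(condition, n),
                                   start_index = seq_len(n),
                                   stringsAsFactors = FALSE),
                 domain = "spatial", bins = NULL, window = k, stride = 1L),
            class = "image_set")
}

# two-class image set with disjoint row-occupancy patterns (linearly separable)
separable_toy_set <- function(n_per_class = 60L, k = 28L, seed = 42L) {
  set.seed(seed)
  pixels <- array(0, dim = c(k, k, 2L * n_per_class))
  cond <- character(2L * n_per_class)
  for (i in seq_len(2L * n_per_class)) {
    stressed <- i <= n_per_class
    rows <- if (stressed) sample.int(k %/% 2L, k, replace = TRUE)
            else sample.int(k %/% 2L, k, replace = TRUE) + k %/% 2L
    pixels[cbind(rows, seq_len(k), i)] <- 1
    cond[i] <- if (stressed) "stressed" else "non_stressed"
  }
  structure(list(pixels = pixels,
                 info = data.frame(subject_id = rep("S1", 2L * n_per_class),
                                   condition = cond,
                                   start_index = seq_len(2L * n_per_class),
                                   stringsAsFactors = FALSE),
                 domain = "spatial", bins = NULL, window = k, stride = 1L),
            class = "image_set")
}

# tiny config for fast training in unit tests
toy_config <- function(epochs = 5L, seed = 1L, ...) {
  cnn_config(epochs = epochs, seed = seed, ...)
}
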