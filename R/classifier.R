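#' Configuration of the stress-image CNN
#'
#' Fixes the classifier topology: 8 convolution layers with 3x3 kernels and
#' size-preserving padding producing 32, 32, 64, 64, 128, 128, 256, 256
#' feature maps, a 2x2 max-pool after every second convolution (4 pools, so
#' the 28x28 input shrinks 28 -> 14 -> 7 -> 3 -> 1), then dense layers of
#' depth 256, 256 and 1 with two dropout layers (rate 0.5) between them and
#' a sigmoid output giving the probability of the stressed class. ReLU is
#' used throughout. Optimization settings (Adam, binary cross-entropy,
#' learning rate 1e-3, batch 32) are exposed here; the layer inventory is
#' validated and enforced.
#'
#' @param conv_channels Integer vector of 8 feature-map counts.
#' @param fc_depths Integer vector of dense depths, last must be 1.
#' @param dropout_rate Dropout rate for the two dense dropout layers.
#' @param epochs Training epochs (default 150, the generic-model setting).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param input_size Side of the square input image.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_channels = c(32L, 32L, 64L, 64L, 128L, 128L, 256L, 256L),
                       fc_depths = c(256L, 256L, 1L),
                       dropout_rate = 0.5, epochs = 150L, batch_size = 32L,
                       learning_rate = 1e-3, input_size = 28L, seed = 1L) {
  conv_channels <- as.integer(conv_channels)
  fc_depths <- as.integer(fc_depths)
  if (length(conv_channels) != 8L)
    stop("the architecture requires exactly 8 convolution layers", call. = FALSE)
  if (any(conv_channels < 1L)) stop("conv_channels must be positive", call. = FALSE)
  if (length(fc_depths) != 3L || fc_depths[3L] != 1L)
    stop("the dense head must have depths (256, 256, 1)-style: three layers ending in 1",
         call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(list(conv_channels = conv_channels, kernel = c(3L, 3L),
                 pool = c(2L, 2L), fc_depths = fc_depths,
                 dropout_rate = dropout_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 input_size = as.integer(input_size), seed = as.integer(seed)),
            class = "cnn_config")
}

# layer-by-layer inventory used for introspection and printing
cnn_architecture <- function(config) {
  layers <- data.frame(type = character(0), detail = character(0),
                       stringsAsFactors = FALSE)
  add <- function(type, detail) rbind(layers, data.frame(type = type, detail = detail,
                                                         stringsAsFactors = FALSE))
  size <- config$input_size
  sizes <- size
  for (l in seq_along(config$conv_channels)) {
    layers <- add("conv", sprintf("3x3, %d maps, ReLU", config$conv_channels[l]))
    if (l %% 2L == 0L) {
      layers <- add("pool", "2x2 max")
      size <- size %/% 2L
    }
    sizes <- c(sizes, size)
  }
  layers <- add("flatten", sprintf("%dx%dx%d -> %d", size, size,
                                   config$conv_channels[length(config$conv_channels)],
                                   size * size * config$conv_channels[8L]))
  for (l in seq_along(config$fc_depths)) {
    act <- if (l < length(config$fc_depths)) "ReLU" else "sigmoid"
    layers <- add("dense", sprintf("%d, %s", config$fc_depths[l], act))
    if (l < length(config$fc_depths))
      layers <- add("dropout", sprintf("rate %.2f", config$dropout_rate))
  }
  list(layers = layers, final_spatial = size,
       final_shape = c(size, size, config$conv_channels[8L]))
}

#' Build an untrained CNN
#'
#' Instantiates the architecture of a [cnn_config()] with seeded
#' He-initialized weights. Two builds from the same config are identical.
#'
#' @param config A [cnn_config()].
#' @return An object of class `cnn_model` with fields `config`, `weights`,
#'   `architecture` (layer inventory data frame), `final_shape`
#'   (pre-flatten feature-map shape), `trained` flag and empty `history`.
#' @export
build_model <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  arch <- cnn_architecture(config)
  if (arch$final_spatial < 1L)
    stop("input_size too small: spatial size collapses below 1 before the dense head",
         call. = FALSE)
  weights <- cnn_init_cpp(config$conv_channels, config$fc_depths,
                          config$input_size, config$seed)
  structure(list(config = config, weights = weights,
                 architecture = arch$layers, final_shape = arch$final_shape,
                 trained = FALSE, history = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  counts <- table(x$architecture$type)
  cat(sprintf("<cnn_model> %s, %d parameters (%d conv, %d pool, %d dropout, %d dense)\n",
              if (x$trained) "trained" else "untrained", n_parameters(x),
              counts[["conv"]], counts[["pool"]], counts[["dropout"]],
              counts[["dense"]]))
  invisible(x)
}

#' Total number of learnable parameters
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  sum(vapply(model$weights, length, 1L))
}

check_images_array <- function(x, input_size) {
  if (inherits(x, "image_set")) x <- x$pixels
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("images must be a k x k x n array or an image_set", call. = FALSE)
  if (dim(x)[1L] != input_size || dim(x)[2L] != input_size)
    stop(sprintf("images must be %dx%d, got %dx%d", input_size, input_size,
                 dim(x)[1L], dim(x)[2L]), call. = FALSE)
  x
}

as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("stressed", "non_stressed"))
    if (length(bad)) stop("unknown condition label(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    return(as.numeric(y == "stressed"))
  }
  as.numeric(y != 0)
}

#' Train the CNN
#'
#' Runs seeded mini-batch Adam on binary cross-entropy for
#' `config$epochs` epochs. Stressed is the positive class. With the same
#' seed and data the run is bit-reproducible (single-threaded compiled
#' kernels). Zero epochs returns the model unchanged apart from an empty
#' history. Frequency-domain image sets are automatically rescaled and
#' centered (see `rescale` and `center`).
#'
#' @param model A [build_model()] result.
#' @param x Training images: `k x k x n` array or `image_set`.
#' @param y Training labels: condition strings, factor, or 0/1 (1 =
#'   stressed). Defaults to the conditions of an `image_set`.
#' @param x_val,y_val Optional validation data, same conventions.
#' @param epochs,batch_size,learning_rate,seed Overrides of the config.
#' @param rescale Divide pixel values by this before training; default 255
#'   for frequency-domain image sets, 1 otherwise.
#' @param center Subtract this after rescaling; default 0.5 for
#'   frequency-domain image sets (their pixels are mostly bright, and
#'   centering removes the large common component that otherwise stalls
#'   early optimization), 0 otherwise.
#' @return The `cnn_model` with trained weights and a `history` data frame
#'   (per-epoch train/validation loss and accuracy).
#' @export
train_cnn <- function(model, x, y = NULL, x_val = NULL, y_val = NULL,
                      epochs = model$config$epochs,
                      batch_size = model$config$batch_size,
                      learning_rate = model$config$learning_rate,
                      seed = model$config$seed,
                      rescale = NULL, center = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.null(y) && inherits(x, "image_set")) y <- x$info$condition
  is_freq <- inherits(x, "image_set") && x$domain == "frequency"
  if (is.null(rescale)) rescale <- if (is_freq) 255 else 1
  if (is.null(center)) center <- if (is_freq) 0.5 else 0
  xs <- check_images_array(x, model$config$input_size) / rescale - center
  y <- as_binary_labels(y)
  if (length(y) != dim(xs)[3L])
    stop("number of labels must match number of images", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training set contains a single class; the loss is degenerate",
         call. = FALSE)
  if (epochs == 0L) {
    model$history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                                train_acc = numeric(0), val_loss = numeric(0),
                                val_acc = numeric(0))
    return(model)
  }
  if (is.null(x_val)) {
    xv <- array(0, dim = c(model$config$input_size, model$config$input_size, 0L))
    yv <- numeric(0)
    warning("training without a validation set", call. = FALSE)
  } else {
    if (is.null(y_val) && inherits(x_val, "image_set")) y_val <- x_val$info$condition
    xv <- check_images_array(x_val, model$config$input_size) / rescale - center
    yv <- as_binary_labels(y_val)
    if (length(yv) != dim(xv)[3L])
      stop("number of validation labels must match validation images", call. = FALSE)
  }
  fit <- cnn_train_cpp(model$weights, xs, y, xv, yv,
                       as.integer(epochs), as.integer(batch_size),
                       learning_rate, model$config$dropout_rate,
                       as.integer(seed))
  model$weights <- fit$weights
  h <- as.data.frame(fit$history)
  h <- cbind(epoch = seq_len(nrow(h)), h)
  model$history <- h
  model$trained <- TRUE
  model$rescale <- rescale
  model$center <- center
  model
}

#' Predict stress probabilities and labels
#'
#' Deterministic forward pass (no dropout). The hard label is
#' `"stressed"` iff the probability is at least 0.5 (ties go to the
#' positive class).
#'
#' @param object A `cnn_model`.
#' @param x Images (`k x k x n` array or `image_set`).
#' @param type `"prob"` for probabilities, `"label"` for hard labels,
#'   `"both"` for a data frame with both.
#' @param rescale,center Pixel divisor and offset; default to the values
#'   used at training time (or 255 and 0.5 for frequency-domain image
#'   sets).
#' @param ... Unused.
#' @return Numeric vector, character vector, or data frame according to
#'   `type`.
#' @export
predict.cnn_model <- function(object, x, type = c("prob", "label", "both"),
                              rescale = NULL, center = NULL, ...) {
  type <- match.arg(type)
  is_freq <- inherits(x, "image_set") && x$domain == "frequency"
  if (is.null(rescale)) {
    rescale <- if (!is.null(object$rescale)) object$rescale
               else if (is_freq) 255 else 1
  }
  if (is.null(center)) {
    center <- if (!is.null(object$center)) object$center
              else if (is_freq) 0.5 else 0
  }
  xs <- check_images_array(x, object$config$input_size) / rescale - center
  prob <- as.numeric(cnn_predict_cpp(object$weights, xs))
  label <- ifelse(prob >= 0.5, "stressed", "non_stressed")
  switch(type,
         prob = prob,
         label = label,
         both = data.frame(prob = prob, label = label, stringsAsFactors = FALSE))
}
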