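#' Configure the CNN-LSTM segment classifier
#'
#' The architecture is a stack of 1-D convolution blocks over the time axis
#' (convolution, optional batch normalization, ReLU, max-pooling, dropout)
#' followed by an LSTM over the pooled time axis and a dense softmax over the
#' two classes. It is trained with Adam on categorical cross-entropy at the
#' stated learning rate and batch size; the layer sizes are configuration,
#' chosen by default for desk-scale trainability on a single CPU.
#'
#' @param conv_filters integer vector of filters per conv block.
#' @param kernel_sizes odd kernel length per block (same length as
#'   `conv_filters`).
#' @param pool_size max-pooling factor applied after each block.
#' @param lstm_units LSTM hidden-state size.
#' @param dropout_rate dropout fraction in (0, 1) applied after each pool.
#' @param use_batchnorm apply batch normalization after each convolution.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 32).
#' @param epochs fixed number of training epochs (no early stopping, so
#'   histories are comparable across augmentation policies).
#' @param seed seed controlling initialization, shuffling, and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(conv_filters = c(32, 64), kernel_sizes = c(5, 5),
                         pool_size = 2, lstm_units = 64, dropout_rate = 0.3,
                         use_batchnorm = TRUE, learning_rate = 0.001,
                         batch_size = 32, epochs = 40, seed = 1L) {
  if (length(conv_filters) != length(kernel_sizes)) {
    stop("conv_filters and kernel_sizes must have the same length",
         call. = FALSE)
  }
  if (any(kernel_sizes %% 2 != 1)) {
    stop("kernel_sizes must be odd (same-padding convolution)", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  if (any(c(conv_filters, pool_size, lstm_units, batch_size, epochs) < 1)) {
    stop("counts in model_config must be at least 1", call. = FALSE)
  }
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(
    list(conv_filters = as.integer(conv_filters),
         kernel_sizes = as.integer(kernel_sizes),
         pool_size = as.integer(pool_size),
         lstm_units = as.integer(lstm_units), dropout_rate = dropout_rate,
         use_batchnorm = isTRUE(use_batchnorm),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), seed = as.integer(seed)),
    class = "model_config")
}

#' Stratified train/validation split of original segments
#'
#' Splits by label so class ratios are preserved (within one segment).
#' Augmentation, channel ranking, and any fitted statistic must be derived
#' from the training side only; validation keeps originals untouched.
#'
#' @param segments list of ORIGINAL [gait_segment()] objects with both
#'   classes present.
#' @param val_fraction fraction held out for validation.
#' @param seed RNG seed for the shuffle.
#' @return List with elements `train` and `validation`.
#' @export
split_dataset <- function(segments, val_fraction = 0.2, seed = 1L) {
  if (any(segment_provenance(segments) != "ORIGINAL")) {
    stop("split_dataset expects ORIGINAL segments only", call. = FALSE)
  }
  labels <- segment_labels(segments)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present before splitting", call. = FALSE)
  }
  val_idx <- integer(0)
  with_seed(seed, {
    for (lab in GAIT_LABELS) {
      idx <- which(labels == lab)
      n_val <- round(length(idx) * val_fraction)
      val_idx <- c(val_idx, sample(idx, n_val))
    }
  })
  train <- segments[setdiff(seq_along(segments), val_idx)]
  validation <- segments[sort(val_idx)]
  for (side in list(train, validation)) {
    if (length(unique(segment_labels(side))) < 2L) {
      stop("a class is absent from one side of the split; adjust ",
           "val_fraction or provide more segments", call. = FALSE)
    }
  }
  list(train = train, validation = validation)
}

#' Train the CNN-LSTM classifier
#'
#' @param train_segments training segments (originals plus any augmented
#'   variants), all sharing one shape.
#' @param val_segments validation segments used only for the per-epoch
#'   monitoring metrics; may be an empty list.
#' @param config a [model_config()].
#' @return List with `model` (class `cnn_lstm_model`) and `history`, a
#'   data frame of per-epoch train/validation loss and accuracy.
#' @export
train_classifier <- function(train_segments, val_segments = list(),
                             config = model_config()) {
  if (length(train_segments) == 0) {
    stop("no training segments", call. = FALSE)
  }
  X <- segments_to_array(train_segments)
  y <- as.integer(segment_labels(train_segments) == "PD")
  if (length(val_segments) > 0) {
    Xv <- segments_to_array(val_segments)
    if (dim(Xv)[1] != dim(X)[1] || dim(Xv)[2] != dim(X)[2]) {
      stop("validation segments must match the training shape", call. = FALSE)
    }
    yv <- as.integer(segment_labels(val_segments) == "PD")
  } else {
    Xv <- array(0, dim = c(dim(X)[1], dim(X)[2], 0))
    yv <- integer(0)
  }
  arch <- list(filters = config$conv_filters, kernels = config$kernel_sizes,
               pool = config$pool_size, lstm_units = config$lstm_units,
               use_bn = config$use_batchnorm)
  opts <- list(dropout = config$dropout_rate,
               learning_rate = config$learning_rate,
               batch_size = config$batch_size, epochs = config$epochs,
               seed = config$seed)
  fit <- cpp_cnnlstm_train(X, y, Xv, yv, arch, opts)
  history <- data.frame(epoch = seq_len(config$epochs),
                        train_loss = fit$history$train_loss,
                        val_loss = fit$history$val_loss,
                        train_accuracy = fit$history$train_accuracy,
                        val_accuracy = fit$history$val_accuracy)
  model <- structure(
    list(params = fit$params, bn = fit$bn, arch = arch, config = config,
         input_len = dim(X)[1], input_channels = dim(X)[2],
         channel_names = colnames(train_segments[[1]]$data),
         classes = GAIT_LABELS),
    class = "cnn_lstm_model")
  list(model = model, history = history)
}

#' Predict class probabilities for segments
#'
#' @param object a trained `cnn_lstm_model`.
#' @param segments list of segments matching the training shape.
#' @param ... unused.
#' @return Numeric matrix, segments x 2, columns `HEALTHY` and `PD`; rows
#'   sum to 1.
#' @export
predict.cnn_lstm_model <- function(object, segments, ...) {
  X <- segments_to_array(segments)
  if (dim(X)[1] != object$input_len || dim(X)[2] != object$input_channels) {
    stop("segment shape ", dim(X)[1], " x ", dim(X)[2],
         " does not match the training shape ", object$input_len, " x ",
         object$input_channels, call. = FALSE)
  }
  P <- cpp_cnnlstm_predict(object$params, object$bn, object$arch, X)
  colnames(P) <- object$classes
  rownames(P) <- segment_ids(segments)
  P
}

#' @export
print.cnn_lstm_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_lstm_model> input %d x %d | conv [%s] | lstm %d | 2-class softmax\n",
    x$input_len, x$input_channels,
    paste(sprintf("%dx%d", x$config$conv_filters, x$config$kernel_sizes),
          collapse = ", "),
    x$config$lstm_units))
  invisible(x)
}
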