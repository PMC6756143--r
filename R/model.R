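#' Declarative layer specification for the 1-D CNN
#'
#' @param kind one of `"conv1d"`, `"maxpool1d"`, `"dropout"`, `"dense"`.
#' @param filters number of filters (conv) or units (dense).
#' @param kernel kernel / pool size in time steps.
#' @param stride stride in time steps.
#' @param pad zero-padding in time steps (0 throughout this architecture).
#' @param rate drop probability for dropout layers (fraction of activations
#'   zeroed during training).
#' @param activation `"relu"`, `"softmax"` or `"none"`.
#' @param name layer name.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind, filters = NULL, kernel = NULL, stride = 1L,
                       pad = 0L, rate = NULL, activation = "none",
                       name = kind) {
  kind <- match.arg(kind, c("conv1d", "maxpool1d", "dropout", "dense"))
  if (kind %in% c("conv1d", "maxpool1d")) {
    if (is.null(kernel) || kernel < 1 || stride < 1) {
      stop_validation("kernel and stride must be >= 1")
    }
  }
  if (kind == "dropout" && (is.null(rate) || rate < 0 || rate >= 1)) {
    stop_validation("dropout rate must be in [0, 1)")
  }
  structure(list(kind = kind, filters = filters, kernel = kernel,
                 stride = stride, pad = pad, rate = rate,
                 activation = activation, name = name),
            class = "layer_spec")
}

#' The compact LeNet-style 1-D CNN architecture for apnea windows
#'
#' The network consumes a 900x2 window (interpolated RR and amplitude
#' channels over the labeled minute plus two minutes of context on each
#' side) and emits a two-class softmax. Layer stack: conv 32 filters,
#' kernel 5, stride 2 -> max-pool 3/3 -> conv 64 filters, kernel 5,
#' stride 2 -> max-pool 3/3 -> dropout (drop probability 0.8) -> dense 32,
#' ReLU -> dense 2, softmax. Output lengths trace
#' 900 -> 448 -> 149 -> 73 -> 24 and the learnable layers carry
#' 352, 10304, 49184 and 66 parameters (59,906 in total).
#'
#' @param input_length window length (default 900).
#' @param input_channels input channels (default 2: RR + amplitude).
#' @param dropout_rate drop probability between the convolutional feature
#'   extractor and the dense classifier head (default 0.8).
#' @return A `model_spec` list with fields `input_length`, `input_channels`,
#'   `layers`.
#' @export
#' @examples
#' spec <- modified_lenet5_spec()
#' count_parameters(spec)$total
modified_lenet5_spec <- function(input_length = 900L, input_channels = 2L,
                                 dropout_rate = 0.8) {
  structure(list(
    input_length = as.integer(input_length),
    input_channels = as.integer(input_channels),
    layers = list(
      layer_spec("conv1d", filters = 32L, kernel = 5L, stride = 2L,
                 activation = "relu", name = "Conv1"),
      layer_spec("maxpool1d", kernel = 3L, stride = 3L, name = "MaxPool2"),
      layer_spec("conv1d", filters = 64L, kernel = 5L, stride = 2L,
                 activation = "relu", name = "Conv3"),
      layer_spec("maxpool1d", kernel = 3L, stride = 3L, name = "MaxPool4"),
      layer_spec("dropout", rate = dropout_rate, name = "Dropout5"),
      layer_spec("dense", filters = 32L, activation = "relu", name = "FC6"),
      layer_spec("dense", filters = 2L, activation = "softmax",
                 name = "Output"))),
    class = "model_spec")
}

#' Output length of a 1-D convolution / pooling layer
#'
#' The standard valid-convolution arithmetic
#' `floor((L_in + 2*pad - kernel) / stride) + 1`; for pooling, `kernel` is
#' the pool size. Equals the number of valid kernel placements.
#'
#' @param l_in input length.
#' @param kernel kernel (or pool) size.
#' @param stride stride.
#' @param pad zero padding per side.
#' @return Integer output length.
#' @export
#' @examples
#' layer_output_length(900, 5, 2)  # 448
layer_output_length <- function(l_in, kernel, stride = 1L, pad = 0L) {
  if (l_in + 2 * pad < kernel) {
    stop_validation(sprintf("input length %d too small for kernel %d",
                            l_in, kernel))
  }
  as.integer(floor((l_in + 2 * pad - kernel) / stride) + 1)
}

#' Trace per-layer output shapes through a model specification
#'
#' @param spec a `model_spec`.
#' @return data.frame with `name`, `length`, `channels` per layer (input
#'   row included).
#' @export
model_shapes <- function(spec) {
  len <- spec$input_length
  ch <- spec$input_channels
  rows <- list(data.frame(name = "Input", length = len, channels = ch))
  flat <- FALSE
  for (ly in spec$layers) {
    if (ly$kind == "conv1d") {
      len <- layer_output_length(len, ly$kernel, ly$stride, ly$pad)
      ch <- ly$filters
    } else if (ly$kind == "maxpool1d") {
      len <- layer_output_length(len, ly$kernel, ly$stride, ly$pad)
    } else if (ly$kind == "dense") {
      if (!flat) {
        len <- len * ch
        flat <- TRUE
      }
      len <- ly$filters
      ch <- 1L
    }
    rows[[length(rows) + 1L]] <-
      data.frame(name = ly$name,
                 length = if (flat) ly$filters %||% len else len,
                 channels = if (flat) 1L else ch)
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count trainable parameters per layer
#'
#' Convolution: `filters * kernel * in_channels + filters`; dense:
#' `units * fan_in + units`; pooling and dropout carry none.
#'
#' @param spec a `model_spec`.
#' @return List with `per_layer` (named integer vector) and `total`.
#' @export
count_parameters <- function(spec) {
  len <- spec$input_length
  ch <- spec$input_channels
  counts <- integer(0)
  flat <- FALSE
  fan_in <- NULL
  for (ly in spec$layers) {
    n <- 0L
    if (ly$kind == "conv1d") {
      n <- ly$filters * (ly$kernel * ch) + ly$filters
      len <- layer_output_length(len, ly$kernel, ly$stride, ly$pad)
      ch <- ly$filters
    } else if (ly$kind == "maxpool1d") {
      len <- layer_output_length(len, ly$kernel, ly$stride, ly$pad)
    } else if (ly$kind == "dense") {
      if (!flat) {
        fan_in <- len * ch
        flat <- TRUE
      }
      n <- ly$filters * fan_in + ly$filters
      fan_in <- ly$filters
    }
    counts[ly$name] <- as.integer(n)
  }
  list(per_layer = counts, total = sum(counts))
}

#' Numerically stable softmax
#'
#' `softmax(z)_k = exp(z_k) / sum_i exp(z_i)`, computed with the row maximum
#' subtracted first so the result is invariant to adding a constant to all
#' scores and never overflows.
#'
#' @param z numeric vector of scores, or a matrix with one score row per
#'   observation.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @export
#' @examples
#' softmax(c(1, 0))
softmax <- function(z) {
  if (is.matrix(z)) {
    m <- apply(z, 1, max)
    e <- exp(z - m)
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Categorical cross-entropy loss
#'
#' `J = -(1/N) * sum_l sum_k y_lk log(yhat_lk)` over `N` observations and
#' `K` classes, with predictions clamped at `eps` to avoid `log(0)`.
#'
#' @param y_true one-hot matrix (rows = observations).
#' @param y_pred predicted probability matrix of the same shape.
#' @param eps clamp floor (default 1e-12).
#' @return Scalar mean loss.
#' @export
#' @examples
#' cross_entropy_loss(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1))  # log(2)
cross_entropy_loss <- function(y_true, y_pred, eps = 1e-12) {
  y_true <- as.matrix(y_true)
  y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred))) {
    stop_validation("y_true and y_pred must have identical shapes")
  }
  mean(-rowSums(y_true * log(pmax(y_pred, eps))))
}

#' Training configuration for the CNN
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement); ignored when `validation_split = 0`.
#' @param validation_split fraction of training windows held out for early
#'   stopping.
#' @param seed RNG seed fixing initialization, shuffling and dropout masks.
#' @param class_weights logical; reweight the loss by inverse class
#'   frequency (off by default).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 128L,
                         epochs = 100L, patience = 10L,
                         validation_split = 0.1, seed = 1L,
                         class_weights = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            validation_split >= 0, validation_split < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 validation_split = validation_split,
                 seed = as.integer(seed),
                 class_weights = isTRUE(class_weights)),
            class = "train_config")
}

#' Export a model's architecture as a framework-independent manifest
#'
#' @param model an `apnea_cnn` (or a bare `model_spec`).
#' @param path optional path to write JSON to.
#' @return The manifest list, invisibly when written.
#' @export
model_manifest <- function(model, path = NULL) {
  spec <- if (inherits(model, "apnea_cnn")) model$spec else model
  pc <- count_parameters(spec)
  manifest <- list(
    input = c(spec$input_length, spec$input_channels),
    layers = lapply(spec$layers, function(ly) {
      ly[!vapply(ly, is.null, logical(1))]
    }),
    parameters = as.list(pc$per_layer),
    total_parameters = pc$total)
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
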