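#' Layer plan of a base architecture
#'
#' The three base classifiers operate on per-minute `240 x 3` feature
#' matrices (RRI, RAMP, EDR columns) and output two-class probabilities:
#'
#' * `wang`: two blocks of \[conv1d(kernel 3, 64 filters, ReLU) ->
#'   batch-norm -> maxpool(2)\], then flatten -> dense(100) -> dense(10) ->
#'   softmax(2). A 1-D adaptation of a 2-D ECG CNN.
#' * `sharan`: three blocks of \[conv1d(kernel 10, ReLU) -> maxpool(2)\]
#'   with 64/128/256 filters, then flatten -> dense(64) -> dense(256) ->
#'   softmax(2).
#' * `almutairi`: each minute is split into 4 consecutive 60-row
#'   sub-windows; a shared stack of three \[conv1d(kernel 3, ReLU) ->
#'   batch-norm -> maxpool(2) -> dropout(0.2)\] blocks with 64/128/16
#'   filters runs per sub-window, the per-window flatten outputs feed an
#'   LSTM(64) across the 4 steps, then dense(64) -> softmax(2).
#'
#' Convolutions use "same" padding; dense hidden layers use ReLU.
#'
#' @param name One of `"wang"`, `"sharan"`, `"almutairi"`.
#' @param k Number of classes (2).
#' @return List of engine layer definitions (see `R/nn.R`).
#' @keywords internal
architecture_layers <- function(name, k = 2) {
  switch(name,
    wang = list(
      layer_conv1d(64, 3), layer_batchnorm(), layer_maxpool(),
      layer_conv1d(64, 3), layer_batchnorm(), layer_maxpool(),
      layer_flatten(),
      layer_dense(100, "relu"), layer_dense(10, "relu"),
      layer_dense(k, "linear")),
    sharan = list(
      layer_conv1d(64, 10), layer_maxpool(),
      layer_conv1d(128, 10), layer_maxpool(),
      layer_conv1d(256, 10), layer_maxpool(),
      layer_flatten(),
      layer_dense(64, "relu"), layer_dense(256, "relu"),
      layer_dense(k, "linear")),
    almutairi = list(
      layer_split_windows(4),
      layer_conv1d(64, 3), layer_batchnorm(), layer_maxpool(), layer_dropout(0.2),
      layer_conv1d(128, 3), layer_batchnorm(), layer_maxpool(), layer_dropout(0.2),
      layer_conv1d(16, 3), layer_batchnorm(), layer_maxpool(), layer_dropout(0.2),
      layer_flatten(), layer_join_windows(4),
      layer_lstm(64),
      layer_dense(64, "relu"), layer_dense(k, "linear")),
    stop("unknown architecture '", name,
         "' (expected 'wang', 'sharan' or 'almutairi')"))
}

#' Build an untrained base classifier
#'
#' @param arch Architecture name: `"wang"`, `"sharan"` or `"almutairi"`.
#' @param input_shape Length-2 integer vector `(grid, channels)`; the
#'   pipeline's native shape is `c(240, 3)`.
#' @param k Number of classes.
#' @return Object of class `apnea_base_model` (untrained: weights are
#'   initialized by [train_base_model()] from its seed).
#' @export
build_model <- function(arch, input_shape = c(240, 3), k = 2) {
  if (!arch %in% c("wang", "sharan", "almutairi")) {
    stop("unknown architecture '", arch,
         "' (expected 'wang', 'sharan' or 'almutairi')")
  }
  if (length(input_shape) != 2 || any(input_shape < 1)) {
    stop("'input_shape' must be (length, channels)")
  }
  if (arch == "almutairi" && input_shape[1] %% 4 != 0) {
    stop("the CNN-LSTM architecture needs a sequence length divisible by 4")
  }
  structure(list(arch = arch, input_shape = as.integer(input_shape), k = k,
                 layers = NULL, history = NULL, trained = FALSE),
            class = "apnea_base_model")
}

#' @export
print.apnea_base_model <- function(x, ...) {
  cat(sprintf("<apnea_base_model '%s'>  input (%d, %d), %s\n", x$arch,
              x$input_shape[1], x$input_shape[2],
              if (x$trained) sprintf("trained (%d params, %d epochs)",
                                     n_parameters(x), nrow(x$history))
              else "untrained"))
  invisible(x)
}

#' Number of trainable parameters of a base model
#'
#' @param model An `apnea_base_model` (weights are materialized if needed).
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "apnea_base_model"))
  layers <- model$layers
  if (is.null(layers)) {
    layers <- with_seed(0, nn_init(architecture_layers(model$arch, model$k),
                                   model$input_shape)$layers)
  }
  as.integer(nn_n_params(layers))
}

check_input_array <- function(model, x) {
  d <- dim(x)
  if (length(d) != 3 || d[2] != model$input_shape[1] ||
      d[3] != model$input_shape[2]) {
    stop(sprintf("input must be an (n, %d, %d) array",
                 model$input_shape[1], model$input_shape[2]))
  }
}

#' Train a base classifier
#'
#' Optimizes softmax cross-entropy (equivalent to binary cross-entropy on
#' two-class one-hot targets) with Adam. The seed drives weight
#' initialization, mini-batch shuffling and dropout, so a fixed seed gives a
#' reproducible fit. `epochs = 0` initializes weights without training
#' (empty history).
#'
#' @param model An `apnea_base_model` from [build_model()].
#' @param x `(n, grid, 3)` feature array.
#' @param y Labels (factor/character, apnea/normal) or integers in `1..k`.
#' @param epochs,batch_size,learning_rate,seed Training contract.
#' @return The trained model; `$history` holds per-epoch training loss and
#'   accuracy.
#' @export
train_base_model <- function(model, x, y, epochs = 100, batch_size = 64,
                             learning_rate = 0.001, seed = 1) {
  stopifnot(inherits(model, "apnea_base_model"))
  check_input_array(model, x)
  y <- encode_labels(y, model$k)
  if (length(y) != dim(x)[1]) stop("x and y lengths differ")
  if (length(unique(y)) < 2) {
    stop("training set must contain at least one sample of every class")
  }
  with_seed(seed, {
    layers <- nn_init(architecture_layers(model$arch, model$k),
                      model$input_shape)$layers
    if (epochs > 0) {
      fit <- nn_fit(layers, x, y, model$k, epochs, batch_size, learning_rate)
      layers <- fit$layers
      model$history <- fit$history
    } else {
      model$history <- data.frame(epoch = integer(0), loss = numeric(0),
                                  accuracy = numeric(0))
    }
    model$layers <- layers
  })
  model$trained <- TRUE
  model
}

encode_labels <- function(y, k) {
  if (is.numeric(y)) {
    y <- as.integer(y)
    if (any(y < 1 | y > k)) stop("integer labels must lie in 1..k")
    y
  } else {
    as.integer(as_apnea_factor(y))
  }
}

#' Class probabilities from a trained base classifier
#'
#' @param model A trained `apnea_base_model`.
#' @param x `(n, grid, 3)` feature array.
#' @return `n x k` matrix of class probabilities (rows sum to 1); for
#'   `k = 2` the columns are named `apnea`, `normal`.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "apnea_base_model"))
  if (!model$trained || is.null(model$layers)) {
    stop("model '", model$arch, "' has not been trained")
  }
  check_input_array(model, x)
  p <- nn_predict_proba(model$layers, x)
  if (model$k == 2) colnames(p) <- apnea_classes()
  p
}
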