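#' Fit the apnea detection ensemble
#'
#' The package's central fitting function: trains the selected base
#' classifiers on per-minute feature arrays and fits the trainable MLP
#' stacker on their training scores. The returned object predicts with all
#' four fusion rules (majority vote, sum rule, Choquet fuzzy fusion, MLP
#' stacker) as well as with each base model alone.
#'
#' @param x `(n, grid, 3)` array of (normalized) feature matrices, as from
#'   [features_to_array()]; or a list of [feature_matrix] objects (labels
#'   are then taken from them and `y` must be missing).
#' @param y Per-sample labels (`apnea`/`normal`).
#' @param archs Base architectures to train (subset of
#'   `c("wang", "sharan", "almutairi")`).
#' @param epochs,batch_size,learning_rate Training contract shared by the
#'   base models and the stacker.
#' @param seed Integer; offsets are derived per model so the fits are
#'   independent but reproducible.
#' @param normalize_densities Passed to [choquet_fuse()] at prediction time.
#' @param stacker_hidden,stacker_epochs MLP stacker width and epochs.
#' @param verbose Print per-model progress.
#' @return Object of class `apnea_ensemble`.
#' @examples
#' sc <- generate_score_matrices(50, seed = 7)   # fusion-only toy example
#' sum_rule(sc$scores)
#' @export
apnea_ensemble <- function(x, y, archs = c("wang", "sharan", "almutairi"),
                           epochs = 100, batch_size = 64,
                           learning_rate = 0.001, seed = 1,
                           normalize_densities = TRUE, stacker_hidden = 16,
                           stacker_epochs = epochs, verbose = FALSE) {
  cl <- match.call()
  if (is.list(x) && !is.array(x)) {
    fa <- features_to_array(x)
    x <- fa$x
    if (missing(y)) y <- fa$y
  }
  y <- as_apnea_factor(y)
  if (dim(x)[1] != length(y)) stop("x and y lengths differ")
  archs <- match.arg(archs, several.ok = TRUE)
  models <- list()
  for (j in seq_along(archs)) {
    if (verbose) message("training base model '", archs[j], "' ...")
    m <- build_model(archs[j], input_shape = dim(x)[2:3])
    models[[archs[j]]] <- train_base_model(
      m, x, y, epochs = epochs, batch_size = batch_size,
      learning_rate = learning_rate, seed = seed + j)
  }
  train_scores <- stack_scores(models, x)
  if (verbose) message("training MLP stacker ...")
  stacker <- fit_stacker(train_scores, y, hidden = stacker_hidden,
                         epochs = stacker_epochs, batch_size = batch_size,
                         learning_rate = learning_rate,
                         seed = seed + length(archs) + 1)
  structure(list(models = models, stacker = stacker, archs = archs,
                 classes = apnea_classes(),
                 normalize_densities = normalize_densities,
                 n_train = length(y), call = cl),
            class = "apnea_ensemble")
}

# (n, l, k) score array from a named list of trained base models
stack_scores <- function(models, x) {
  l <- length(models)
  n <- dim(x)[1]
  scores <- array(0, c(n, l, 2),
                  dimnames = list(NULL, names(models), apnea_classes()))
  for (j in seq_len(l)) scores[, j, ] <- predict_proba(models[[j]], x)
  scores
}

#' Predict from a fitted apnea ensemble
#'
#' @param object An [apnea_ensemble].
#' @param newdata `(n, grid, 3)` feature array or list of [feature_matrix]
#'   objects.
#' @param method `"all"` (default) or one of the base architectures /
#'   fusion rules (`"majority"`, `"sum"`, `"choquet"`, `"mlp"`).
#' @param ... Unused.
#' @return For `method = "all"`: an `apnea_prediction` holding the base
#'   score array and every fusion result. Otherwise the single
#'   `fusion_result` (for a base architecture, its probability matrix).
#' @export
predict.apnea_ensemble <- function(object, newdata, method = "all", ...) {
  if (is.list(newdata) && !is.array(newdata)) {
    newdata <- features_to_array(newdata)$x
  }
  if (method %in% object$archs) {
    return(predict_proba(object$models[[method]], newdata))
  }
  scores <- stack_scores(object$models, newdata)
  if (method == "all") {
    fused <- lapply(stats::setNames(nm = c("majority", "sum", "choquet", "mlp")),
                    function(m) fuse_scores(scores, m,
                                            object$normalize_densities,
                                            object$stacker))
    structure(list(base_scores = scores, fused = fused,
                   classes = object$classes),
              class = "apnea_prediction")
  } else {
    fuse_scores(scores, method, object$normalize_densities, object$stacker)
  }
}

#' @export
print.apnea_prediction <- function(x, ...) {
  n <- dim(x$base_scores)[1]
  cat(sprintf("<apnea_prediction>  %d samples, %d base models, fusion rules: %s\n",
              n, dim(x$base_scores)[2], paste(names(x$fused), collapse = ", ")))
  invisible(x)
}

#' @export
print.apnea_ensemble <- function(x, ...) {
  cat("Apnea detection ensemble\n")
  cat("  base models: ", paste(x$archs, collapse = ", "), "\n", sep = "")
  cat(sprintf("  trained on %d minutes; fusion: majority, sum, choquet (%s densities), mlp (%d hidden)\n",
              x$n_train,
              if (x$normalize_densities) "normalized" else "raw",
              x$stacker$hidden))
  invisible(x)
}

#' @export
summary.apnea_ensemble <- function(object, ...) {
  hist <- lapply(object$models, function(m) m$history)
  final <- t(vapply(hist, function(h) {
    if (nrow(h)) unlist(h[nrow(h), c("loss", "accuracy")])
    else c(loss = NA_real_, accuracy = NA_real_)
  }, numeric(2)))
  out <- list(call = object$call, archs = object$archs,
              n_parameters = vapply(object$models, n_parameters, integer(1)),
              final_train = final, n_train = object$n_train)
  class(out) <- "summary.apnea_ensemble"
  out
}

#' @export
print.summary.apnea_ensemble <- function(x, ...) {
  cat("Apnea detection ensemble (", x$n_train, " training minutes)\n", sep = "")
  df <- data.frame(parameters = x$n_parameters,
                   final_loss = round(x$final_train[, "loss"], 4),
                   final_accuracy = round(x$final_train[, "accuracy"], 4))
  rownames(df) <- x$archs
  print(df)
  invisible(x)
}

#' Plot base-model training histories
#'
#' Draws per-epoch training loss (left axis, solid) for every base model of
#' the ensemble.
#'
#' @param x An [apnea_ensemble].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.apnea_ensemble <- function(x, ...) {
  hs <- lapply(x$models, function(m) m$history)
  if (all(vapply(hs, nrow, integer(1)) == 0)) {
    stop("no training history to plot")
  }
  losses <- do.call(cbind, lapply(hs, function(h) h$loss))
  graphics::matplot(losses, type = "l", lty = 1, xlab = "epoch",
                    ylab = "training loss", ...)
  graphics::legend("topright", legend = names(x$models), lty = 1,
                   col = seq_along(x$models), bty = "n")
  invisible(x)
}
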