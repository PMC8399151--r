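#' Confusion counts with apnea as the positive class
#'
#' @param truth,pred Label vectors (`apnea`/`normal`, `A`/`N` accepted).
#' @return Named integer vector `c(TP, FN, FP, TN)`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as_apnea_factor(truth)
  pred <- as_apnea_factor(pred)
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  c(TP = sum(truth == "apnea" & pred == "apnea"),
    FN = sum(truth == "apnea" & pred == "normal"),
    FP = sum(truth == "normal" & pred == "apnea"),
    TN = sum(truth == "normal" & pred == "normal"))
}

#' The five classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `2PR/(P+R)` and specificity `TN/(TN+FP)`, apnea positive. A
#' zero-denominator metric is reported as `NaN` (an explicit
#' undefined marker, with a note) rather than silently as zero.
#'
#' @param counts Named vector with `TP`, `FN`, `FP`, `TN` (as from
#'   [confusion_counts()]).
#' @param quiet Suppress the note emitted for undefined metrics.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `specificity`.
#' @export
classification_metrics <- function(counts, quiet = FALSE) {
  need <- c("TP", "FN", "FP", "TN")
  if (!all(need %in% names(counts))) stop("counts must name TP, FN, FP, TN")
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  fp <- counts[["FP"]]; tn <- counts[["TN"]]
  total <- tp + fn + fp + tn
  if (total == 0) stop("no samples to evaluate")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  prec <- ratio(tp, tp + fp)
  rec <- ratio(tp, tp + fn)
  f1 <- if (is.nan(prec) || is.nan(rec) || prec + rec == 0) NaN
        else 2 * prec * rec / (prec + rec)
  out <- c(accuracy = (tp + tn) / total, precision = prec, recall = rec,
           f1 = f1, specificity = ratio(tn, tn + fp))
  if (!quiet && anyNA(out)) {
    message("undefined metric(s) (zero denominator): ",
            paste(names(out)[is.nan(out)], collapse = ", "))
  }
  out
}

metric_names <- function() c("accuracy", "precision", "recall", "f1", "specificity")

# Metrics table (7 x 5 for the full grid) for one train/test evaluation.
evaluate_split <- function(x_train, y_train, x_test, y_test, pipeline) {
  if (length(unique(y_train)) < 2 || length(unique(y_test)) < 2) {
    stop("a class is missing from the train or test fold")
  }
  fit <- apnea_ensemble(
    x_train, y_train, archs = pipeline$archs, epochs = pipeline$epochs,
    batch_size = pipeline$batch_size, learning_rate = pipeline$learning_rate,
    seed = pipeline$seed, normalize_densities = pipeline$normalize_densities,
    stacker_hidden = pipeline$stacker_hidden,
    stacker_epochs = pipeline$stacker_epochs, verbose = pipeline$verbose)
  pred <- predict(fit, x_test)
  rows <- c(fit$archs, names(pred$fused))
  tab <- matrix(NA_real_, length(rows), 5,
                dimnames = list(rows, metric_names()))
  for (a in fit$archs) {
    hard <- apnea_classes()[max.col(pred$base_scores[, a, ], ties.method = "first")]
    tab[a, ] <- classification_metrics(confusion_counts(y_test, hard), quiet = TRUE)
  }
  for (m in names(pred$fused)) {
    tab[m, ] <- classification_metrics(confusion_counts(y_test, pred$fused[[m]]$class),
                                       quiet = TRUE)
  }
  tab
}

# Fill pipeline defaults from a config list.
pipeline_spec <- function(config = default_config(), ...) {
  p <- list(archs = config$training$archs, epochs = config$training$epochs,
            batch_size = config$training$batch_size,
            learning_rate = config$training$learning_rate,
            seed = config$training$seed,
            normalize_densities = config$fusion$normalize_densities,
            stacker_hidden = config$fusion$stacker_hidden,
            stacker_epochs = config$fusion$stacker_epochs,
            verbose = FALSE)
  utils::modifyList(p, list(...))
}

cv_result <- function(folds) {
  avg <- Reduce(`+`, folds) / length(folds)
  structure(list(folds = folds, average = avg), class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 4, ...) {
  cat(sprintf("Cross-validation over %d fold(s); averaged metrics:\n",
              length(x$folds)))
  print(round(x$average, digits))
  invisible(x)
}

#' Two-fold swap cross-validation
#'
#' Trains on set A / tests on B, then swaps, and averages the per-fold
#' metric tables (rows: base models then fusion rules; columns: the five
#' metrics).
#'
#' @param x_a,y_a,x_b,y_b Feature arrays and labels of the two sets.
#' @param pipeline Pipeline settings from [pipeline_spec()].
#' @return A `cv_result` with `$folds` (list of 2 metric tables) and
#'   `$average`.
#' @export
two_fold_swap <- function(x_a, y_a, x_b, y_b, pipeline = pipeline_spec()) {
  y_a <- as_apnea_factor(y_a); y_b <- as_apnea_factor(y_b)
  if (length(y_a) == 0 || length(y_b) == 0) stop("both sets must be nonempty")
  cv_result(list(AB = evaluate_split(x_a, y_a, x_b, y_b, pipeline),
                 BA = evaluate_split(x_b, y_b, x_a, y_a, pipeline)))
}

#' k-fold cross-validation
#'
#' Shuffles the data with the pipeline seed, splits it into `folds` parts
#' (unstratified by default), trains on `folds - 1` parts and tests on the
#' held-out part, and averages the metric tables.
#'
#' @param x,y Combined feature array and labels.
#' @param folds Number of folds (default 5).
#' @param stratified Balance class proportions across folds.
#' @param pipeline Pipeline settings from [pipeline_spec()].
#' @return A `cv_result`.
#' @export
k_fold_cv <- function(x, y, folds = 5, stratified = FALSE,
                      pipeline = pipeline_spec()) {
  y <- as_apnea_factor(y)
  n <- length(y)
  if (min(table(y)) < folds) stop("need at least 'folds' samples per class")
  assignment <- with_seed(pipeline$seed, {
    if (stratified) {
      a <- integer(n)
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        a[idx] <- rep_len(seq_len(folds), length(idx))
      }
      a
    } else {
      rep_len(seq_len(folds), n)[sample.int(n)]
    }
  })
  tabs <- lapply(seq_len(folds), function(f) {
    tr <- assignment != f
    evaluate_split(sub_batch(x, which(tr)), y[tr],
                   sub_batch(x, which(!tr)), y[!tr], pipeline)
  })
  names(tabs) <- paste0("fold", seq_len(folds))
  res <- cv_result(tabs)
  res$assignment <- assignment
  res
}

#' Run the end-to-end experiment described by a configuration
#'
#' Generates (or loads) ECG records, preprocesses them into normalized
#' feature matrices, trains the base models and stacker, applies every
#' fusion rule and reports the full metrics grid (rows: base models and
#' fusion rules; columns: the five metrics) under the configured protocol
#' (`"two_fold"`, `"five_fold"` or `"holdout"`).
#'
#' @param config Configuration list (see [default_config()]); with the
#'   default `data$source = "synthetic"` two records (train and test roles)
#'   are generated from the `synthetic` section. For `data$source = "files"`
#'   supply `data$train_paths` / `data$test_paths` and `data$format`.
#' @param out Optional path: the report is additionally written as JSON.
#' @return List with `metrics` (a `cv_result`), `counts` (clear/noise
#'   minutes per set) and `config`.
#' @export
run_experiment <- function(config = default_config(), out = NULL) {
  src <- config$data$source
  if (identical(src, "synthetic")) {
    sp <- config$synthetic
    make <- function(seed_off, id) {
      generate_record(synthetic_spec(
        n_minutes_per_class = sp$n_minutes_per_class, fs = sp$fs,
        base_hr = sp$base_hr, hrv_sd = sp$hrv_sd,
        apnea_cycle_period = sp$apnea_cycle_period,
        apnea_rr_swing = sp$apnea_rr_swing, resp_rate = sp$resp_rate,
        ramp_mod_depth = sp$ramp_mod_depth, noise_sd = sp$noise_sd,
        noisy_minute_rate = sp$noisy_minute_rate, seed = sp$seed + seed_off),
        record_id = id)
    }
    recs_train <- list(make(0, "synth-train"))
    recs_test <- list(make(1, "synth-test"))
  } else if (identical(src, "files")) {
    if (is.null(config$data$train_paths) || is.null(config$data$test_paths)) {
      stop("config$data must supply train_paths and test_paths when source = 'files'")
    }
    recs_train <- lapply(config$data$train_paths, read_record,
                         format = config$data$format)
    recs_test <- lapply(config$data$test_paths, read_record,
                        format = config$data$format)
  } else {
    stop("config$data$source must be 'synthetic' or 'files'")
  }
  feats_train <- unlist(lapply(recs_train, preprocess_record, config = config),
                        recursive = FALSE)
  feats_test <- unlist(lapply(recs_test, preprocess_record, config = config),
                       recursive = FALSE)
  counts <- list(
    train = table(factor(vapply(feats_train, `[[`, "", "quality"),
                         levels = c("clear", "noise"))),
    test = table(factor(vapply(feats_test, `[[`, "", "quality"),
                        levels = c("clear", "noise"))))
  scope <- config$preprocessing$normalization_scope
  if (identical(scope, "global")) {
    zs <- fit_zscore(c(feats_train, feats_test))
    zs_train <- zs_test <- zs
  } else {   # "train" (default) and "per_fold": statistics from the train role
    zs_train <- zs_test <- fit_zscore(feats_train)
  }
  a <- features_to_array(lapply(feats_train, apply_zscore, stats = zs_train))
  b <- features_to_array(lapply(feats_test, apply_zscore, stats = zs_test))
  pipeline <- pipeline_spec(config)
  protocol <- config$evaluation$protocol
  metrics <- switch(protocol,
    two_fold = two_fold_swap(a$x, a$y, b$x, b$y, pipeline),
    five_fold = {
      x_all <- array(0, c(dim(a$x)[1] + dim(b$x)[1], dim(a$x)[2], dim(a$x)[3]))
      x_all[seq_len(dim(a$x)[1]), , ] <- a$x
      x_all[dim(a$x)[1] + seq_len(dim(b$x)[1]), , ] <- b$x
      k_fold_cv(x_all, c(as.character(a$y), as.character(b$y)),
                folds = config$evaluation$folds,
                stratified = config$evaluation$stratified, pipeline = pipeline)
    },
    holdout = cv_result(list(AB = evaluate_split(a$x, a$y, b$x, b$y, pipeline))),
    stop("unknown evaluation protocol '", protocol, "'"))
  report <- list(metrics = metrics, counts = counts, config = config)
  if (!is.null(out)) {
    jsonlite::write_json(
      list(average = as.data.frame(metrics$average),
           folds = lapply(metrics$folds, as.data.frame),
           counts = lapply(counts, as.list)),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
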