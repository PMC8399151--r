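#' Shannon entropy of a probability vector (base 2)
#'
#' `H(p) = -sum(p_i * log2(p_i))` with `0 * log 0 := 0`. For two classes the
#' maximum is exactly 1 (attained at the uniform vector), which is the scale
#' the entropy-derived fuzzy densities rely on.
#'
#' @param p Probability vector (nonnegative, summing to 1).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("probability vector has negative components")
  if (abs(sum(p) - 1) > 1e-6) stop("probability vector must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Entropy-derived fuzzy densities for one sample
#'
#' Each classifier's confidence is `1 - H_j / log2(k)` where `H_j` is the
#' entropy of its probability row (for `k = 2` this is the plain
#' `1 - H_j`, i.e. entropy subtracted from its maximum of 1). With
#' `normalize = TRUE` the confidences are divided by their sum, giving
#' densities that sum to one (and hence an additive measure, lambda = 0);
#' with `normalize = FALSE` the raw confidences are kept and the Sugeno
#' lambda becomes nontrivial. If every row is exactly uniform all densities
#' fall back to `1/l`.
#'
#' @param scores `l x k` matrix: per-classifier class-probability rows.
#' @param normalize Divide densities by their sum (default TRUE).
#' @return Numeric vector of `l` densities in `[0, 1]`.
#' @export
singleton_measures <- function(scores, normalize = TRUE) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  raw <- apply(scores, 1, function(p) 1 - shannon_entropy(p) / log2(k))
  raw <- pmax(raw, 0)   # guard tiny negative rounding
  if (sum(raw) <= 0) return(rep(1 / nrow(scores), nrow(scores)))
  if (normalize) raw / sum(raw) else raw
}

#' Solve for the Sugeno lambda of a density set
#'
#' Finds the unique root of `prod_j(1 + lambda * g_j) = 1 + lambda` on
#' `(-1, Inf)`: zero when the densities sum to one (additive case), positive
#' when they sum to less than one, in `(-1, 0)` when they sum to more. The
#' root is located by bisection to `|f(lambda)| <= 1e-12`.
#'
#' @param g Densities in `[0, 1]`, at least two of them positive unless they
#'   already sum to one.
#' @return The lambda value (> -1).
#' @export
solve_lambda <- function(g) {
  if (any(g < 0 | g > 1)) stop("densities must lie in [0, 1]")
  s <- sum(g)
  if (abs(s - 1) <= 1e-9) return(0)
  if (sum(g > 0) < 2) {
    stop("no Sugeno lambda exists: fewer than two positive densities with sum != 1")
  }
  f <- function(lam) prod(1 + lam * g) - (1 + lam)
  if (s < 1) {            # root in (0, Inf)
    lo <- 0; hi <- 1
    while (f(hi) < 0) hi <- hi * 2
  } else {                # root in (-1, 0)
    lo <- -1 + 1e-12; hi <- 0
    # f(lo) >= 0 since prod(1 - g_j) >= 0; f -> 0^- near 0
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= 1e-12) return(mid)
    pos <- if (s < 1) fm < 0 else fm >= 0
    if (pos) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sugeno lambda-measure over all classifier subsets
#'
#' Builds the measure by folding elements into subsets with
#' `g(A + {m}) = g(A) + g_m + lambda * g(A) * g_m` (order-independent).
#' With the lambda from [solve_lambda()], `g` of the full set is 1 and the
#' measure is monotone.
#'
#' @param g Singleton densities.
#' @param lambda The Sugeno lambda for `g`.
#' @return Numeric vector of length `2^l`; entry `i` is the measure of the
#'   subset whose bitmask is `i - 1` (bit `j` set = classifier `j` in the
#'   subset).
#' @export
sugeno_measure <- function(g, lambda) {
  l <- length(g)
  out <- numeric(2^l)
  for (mask in seq_len(2^l - 1)) {
    j <- trailing_bit(mask)          # fold in the lowest-index member
    rest <- out[mask - 2^(j - 1) + 1]
    out[mask + 1] <- rest + g[j] + lambda * rest * g[j]
  }
  out
}

trailing_bit <- function(mask) {
  j <- 1L
  while (mask %% 2L == 0L) {
    mask <- mask %/% 2L
    j <- j + 1L
  }
  j
}

#' Measure of one classifier subset
#'
#' @param subset Integer indices of the classifiers in the subset.
#' @param g Singleton densities (length `l`).
#' @param lambda The Sugeno lambda for `g`.
#' @return `g(A)`; 0 for the empty subset.
#' @export
measure_of_subset <- function(subset, g, lambda) {
  if (length(subset) == 0) return(0)
  subset <- as.integer(subset)
  if (any(subset < 1 | subset > length(g))) {
    stop("subset contains classifiers outside 1..", length(g))
  }
  if (anyDuplicated(subset)) stop("subset has duplicate elements")
  acc <- 0
  for (j in subset) acc <- acc + g[j] + lambda * acc * g[j]
  acc
}

fusion_result <- function(scores, classes, method) {
  colnames(scores) <- classes
  pred <- factor(classes[max.col(scores, ties.method = "first")],
                 levels = classes)
  structure(list(scores = scores, class = pred, method = method),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  tab <- table(x$class)
  cat(sprintf("<fusion_result '%s'>  %d samples: %s\n", x$method,
              length(x$class),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

score_array_dims <- function(scores) {
  d <- dim(scores)
  if (length(d) != 3) stop("scores must be an (n, l, k) array")
  d
}

score_classes <- function(scores) {
  cls <- dimnames(scores)[[3]]
  if (is.null(cls)) cls <- if (dim(scores)[3] == 2) apnea_classes()
                           else paste0("c", seq_len(dim(scores)[3]))
  cls
}

check_simplex_rows <- function(scores) {
  if (any(!is.finite(scores))) stop("scores contain non-finite values")
  sums <- apply(scores, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("classifier score rows must sum to 1")
  }
}

#' Majority-vote fusion (decision level)
#'
#' Each classifier votes with its argmax class; the class with most votes
#' wins. Vote ties (possible for even classifier counts) are broken by the
#' sum rule on the underlying scores.
#'
#' @param scores `(n, l, k)` array of class probabilities.
#' @return A `fusion_result`; its `scores` field holds the vote counts.
#' @export
majority_vote <- function(scores) {
  d <- score_array_dims(scores)
  if (d[2] < 1) stop("need at least one classifier")
  check_simplex_rows(scores)
  classes <- score_classes(scores)
  n <- d[1]; l <- d[2]; k <- d[3]
  votes <- matrix(0, n, k)
  for (j in seq_len(l)) {
    hard <- max.col(matrix(scores[, j, ], n, k), ties.method = "first")
    votes[cbind(seq_len(n), hard)] <- votes[cbind(seq_len(n), hard)] + 1
  }
  res <- fusion_result(votes, classes, "majority")
  top <- apply(votes, 1, max)
  tied <- rowSums(votes == top) > 1
  if (any(tied)) {
    sums <- apply(scores[tied, , , drop = FALSE], c(1, 3), sum)
    # restrict the sum-rule tie-break to the tied top-vote classes
    sums[votes[tied, , drop = FALSE] != top[tied]] <- -Inf
    res$class[tied] <- factor(classes[max.col(sums, ties.method = "first")],
                              levels = classes)
  }
  res
}

#' Sum-rule fusion (score level)
#'
#' Fused score of class `i` is the sum over classifiers of `p_ij`; the
#' argmax wins, ties broken toward the lower class index.
#'
#' @param scores `(n, l, k)` array of class probabilities.
#' @return A `fusion_result`.
#' @export
sum_rule <- function(scores) {
  score_array_dims(scores)
  check_simplex_rows(scores)
  fusion_result(apply(scores, c(1, 3), sum), score_classes(scores), "sum")
}

#' Choquet-integral fuzzy fusion with entropy-derived Sugeno measures
#'
#' Per sample, fuzzy densities are computed from each classifier's
#' prediction entropy ([singleton_measures()]), the Sugeno lambda is solved,
#' and each class's fused score is the Choquet integral of the classifiers'
#' scores for that class against the lambda-measure: with scores sorted
#' decreasingly (`s_(1) >= s_(2) >= ...`, ties broken by classifier index),
#' `CS = sum_j s_(j) * [g(A_j) - g(A_(j-1))]` where `A_j` is the set of the
#' top `j` classifiers. Confident classifiers therefore carry more weight;
#' with normalized densities the measure is additive and the rule reduces to
#' an entropy-weighted mean.
#'
#' @param scores `(n, l, k)` array of class probabilities.
#' @param normalize_densities Normalize densities to sum to one (the
#'   additive, lambda = 0 path); `FALSE` keeps raw confidences and a
#'   nontrivial lambda.
#' @return A `fusion_result` with the Choquet class scores.
#' @export
choquet_fuse <- function(scores, normalize_densities = TRUE) {
  d <- score_array_dims(scores)
  check_simplex_rows(scores)
  n <- d[1]; l <- d[2]; k <- d[3]
  cs <- matrix(0, n, k)
  for (i in seq_len(n)) {
    S <- matrix(scores[i, , ], l, k)
    g <- singleton_measures(S, normalize = normalize_densities)
    if (sum(g > 0) < 2 && abs(sum(g) - 1) > 1e-9) {
      # degenerate sample (a single informative classifier): no lambda exists
      # for the raw densities, so fall back to the normalized additive measure
      g <- g / sum(g)
    }
    lam <- if (abs(sum(g) - 1) <= 1e-9) 0 else solve_lambda(g)
    meas <- sugeno_measure(g, lam)
    for (cl in seq_len(k)) {
      s <- S[, cl]
      ord <- order(-s, seq_len(l))
      mask <- 0
      prev <- 0
      acc <- 0
      for (j in seq_len(l)) {
        mask <- mask + 2^(ord[j] - 1)
        gj <- meas[mask + 1]
        acc <- acc + s[ord[j]] * (gj - prev)
        prev <- gj
      }
      cs[i, cl] <- acc
    }
  }
  fusion_result(cs, score_classes(scores), "choquet")
}

#' Fit / apply the trainable MLP stacking ensemble
#'
#' Flattens each sample's `l x k` score block into `k*l` features and trains
#' a one-hidden-layer perceptron (16 ReLU units by default, softmax output)
#' with Adam on softmax cross-entropy, mirroring the base training contract.
#'
#' @param scores `(n, l, k)` array of base-classifier probabilities.
#' @param labels True labels (factor/character apnea/normal, or integers
#'   `1..k`).
#' @param hidden Hidden-layer width.
#' @param epochs,batch_size,learning_rate,seed Training contract.
#' @return Object of class `mlp_stacker`.
#' @export
fit_stacker <- function(scores, labels, hidden = 16, epochs = 100,
                        batch_size = 64, learning_rate = 0.001, seed = 1) {
  d <- score_array_dims(scores)
  k <- d[3]
  x <- flatten_scores(scores)
  y <- encode_labels(labels, k)
  if (length(y) != d[1]) stop("scores and labels lengths differ")
  with_seed(seed, {
    layers <- nn_init(list(layer_dense(hidden, "relu"),
                           layer_dense(k, "linear")), c(d[2] * k, 1))$layers
    fit <- nn_fit(layers, x, y, k, epochs, batch_size, learning_rate)
  })
  structure(list(layers = fit$layers, history = fit$history, l = d[2], k = k,
                 classes = score_classes(scores), hidden = hidden),
            class = "mlp_stacker")
}

flatten_scores <- function(scores) {
  d <- dim(scores)
  x <- matrix(0, d[1], d[2] * d[3])
  for (j in seq_len(d[2])) {
    x[, ((j - 1) * d[3] + 1):(j * d[3])] <- scores[, j, ]
  }
  x
}

#' @rdname fit_stacker
#' @param stacker A fitted `mlp_stacker`.
#' @return `predict_stacker`: a `fusion_result` whose scores are the
#'   stacker's class probabilities.
#' @export
predict_stacker <- function(stacker, scores) {
  if (!inherits(stacker, "mlp_stacker")) {
    stop("'stacker' is not a fitted mlp_stacker")
  }
  d <- score_array_dims(scores)
  if (d[2] != stacker$l || d[3] != stacker$k) {
    stop(sprintf("score dimensions (l=%d, k=%d) do not match the stacker (l=%d, k=%d)",
                 d[2], d[3], stacker$l, stacker$k))
  }
  p <- nn_predict_proba(stacker$layers, flatten_scores(scores))
  fusion_result(p, stacker$classes, "mlp")
}

#' Apply a fusion rule by name
#'
#' @param scores `(n, l, k)` array of base-classifier probabilities.
#' @param method `"majority"`, `"sum"`, `"choquet"` or `"mlp"`.
#' @param normalize_densities Passed to [choquet_fuse()].
#' @param stacker Fitted [fit_stacker()] object (required for `"mlp"`).
#' @return A `fusion_result`.
#' @export
fuse_scores <- function(scores, method = c("majority", "sum", "choquet", "mlp"),
                        normalize_densities = TRUE, stacker = NULL) {
  method <- match.arg(method)
  switch(method,
         majority = majority_vote(scores),
         sum = sum_rule(scores),
         choquet = choquet_fuse(scores, normalize_densities),
         mlp = {
           if (is.null(stacker)) stop("method 'mlp' needs a fitted stacker")
           predict_stacker(stacker, scores)
         })
}
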