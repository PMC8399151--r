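test_that("entropy matches its definition at endpoints and interior points", {
  expect_identical(shannon_entropy(c(0.5, 0.5)), 1)
  expect_identical(shannon_entropy(c(1, 0)), 0)
  expect_identical(shannon_entropy(c(0, 1)), 0)
  # frozen from independent evaluation: -(0.9*log2(0.9) + 0.1*log2(0.1))
  expect_equal(shannon_entropy(c(0.9, 0.1)), 0.4689956, tolerance = 1e-4)
  expect_equal(shannon_entropy(c(0.25, 0.25, 0.25, 0.25)), 2)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  # property: entropy of random simplex vectors agrees with the natural-log form
  set.seed(11)
  for (i in 1:50) {
    p <- rgamma(3, 1); p <- p / sum(p)
    expect_equal(shannon_entropy(p), ref_entropy_bits(p), tolerance = 1e-12)
  }
})

test_that("singleton densities follow the confidence rule with normalization", {
  S <- rbind(c(1, 0), c(1, 0), c(0.5, 0.5))
  expect_equal(singleton_measures(S, normalize = FALSE), c(1, 1, 0))
  expect_equal(singleton_measures(S, normalize = TRUE), c(0.5, 0.5, 0))
  # all-uniform rows fall back to equal densities
  U <- matrix(0.5, 3, 2)
  expect_equal(singleton_measures(U), rep(1 / 3, 3))
  # normalized densities always sum to one
  set.seed(12)
  for (i in 1:20) {
    S <- matrix(rgamma(6, 1), 3, 2); S <- S / rowSums(S)
    expect_equal(sum(singleton_measures(S)), 1, tolerance = 1e-12)
  }
})

test_that("the Sugeno lambda solver agrees with closed forms", {
  # closed form for two equal densities g: lambda = (1 - 2g) / g^2
  expect_equal(solve_lambda(c(0.3, 0.3)), 0.4 / 0.09, tolerance = 1e-3)
  expect_equal(solve_lambda(c(0.6, 0.6)), -0.2 / 0.36, tolerance = 1e-3)
  expect_identical(solve_lambda(c(0.5, 0.5)), 0)
  expect_identical(solve_lambda(c(0.2, 0.3, 0.5)), 0)
  expect_error(solve_lambda(c(0.5, 1.2)), "densities")
  # and with the solved lambda the full set always measures 1
  set.seed(13)
  for (i in 1:50) {
    g <- runif(sample(2:4, 1), 0.05, 0.95)
    lam <- solve_lambda(g)
    expect_gt(lam, -1)
    expect_equal(measure_of_subset(seq_along(g), g, lam), 1, tolerance = 1e-8)
  }
})

test_that("the lambda-measure is monotone, bounded and order-independent", {
  expect_identical(measure_of_subset(integer(0), c(0.3, 0.3), 4.4444), 0)
  expect_equal(measure_of_subset(1, c(0.3, 0.4), solve_lambda(c(0.3, 0.4))), 0.3)
  g <- c(0.3, 0.3)
  lam <- solve_lambda(g)
  expect_equal(measure_of_subset(c(1, 2), g, lam), 0.6 + lam * 0.09,
               tolerance = 1e-9)
  expect_equal(measure_of_subset(c(2, 1), g, lam),
               measure_of_subset(c(1, 2), g, lam), tolerance = 1e-12)
  expect_error(measure_of_subset(3, g, lam), "outside")
  # subset-monotonicity by full enumeration for l = 2, 3, 4
  set.seed(14)
  for (l in 2:4) {
    dens <- runif(l, 0.05, 0.6)
    lam <- solve_lambda(dens)
    meas <- sugeno_measure(dens, lam)
    for (mask in 0:(2^l - 1)) {
      for (j in seq_len(l)) {
        if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) == 0L) {
          sup <- mask + 2^(j - 1)
          expect_gte(meas[sup + 1] + 1e-12, meas[mask + 1])
        }
      }
    }
    expect_equal(meas[2^l], 1, tolerance = 1e-8)
    expect_identical(meas[1], 0)
  }
})

test_that("majority vote and sum rule follow their definitions and tie-breaks", {
  arr <- function(rows) array(rows, c(1, nrow(rows), 2))
  # [A, A, N] -> A ; [N, N, N] -> N
  expect_identical(as.character(majority_vote(
    arr(rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))))$class), "apnea")
  expect_identical(as.character(majority_vote(
    arr(rbind(c(0.1, 0.9), c(0.4, 0.6), c(0.2, 0.8))))$class), "normal")
  # l = 4 vote tie resolved by the sum rule over the tied classes
  tie <- arr(rbind(c(0.55, 0.45), c(0.52, 0.48), c(0.1, 0.9), c(0.05, 0.95)))
  expect_identical(as.character(majority_vote(tie)$class), "normal")
  # sum rule: worked example
  s <- arr(rbind(c(0.6, 0.4), c(0.55, 0.45), c(0.2, 0.8)))
  r <- sum_rule(s)
  expect_equal(as.numeric(r$scores), c(1.35, 1.65))
  expect_identical(as.character(r$class), "normal")
  # identical one-hot rows pick that class; all-uniform ties to class 1
  expect_identical(as.character(sum_rule(
    arr(rbind(c(0, 1), c(0, 1), c(0, 1))))$class), "normal")
  expect_identical(as.character(sum_rule(
    arr(rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))))$class), "apnea")
  expect_error(sum_rule(arr(rbind(c(NA, 1), c(0, 1), c(0, 1)))), "finite")
  expect_error(majority_vote(array(0, c(1, 0, 2))), "at least one")
})

test_that("the additive Choquet integral equals the weighted mean example", {
  # lambda = 0 additive case: g = (0.5, 0.3, 0.2), scores (0.9, 0.6, 0.2)
  g <- c(0.5, 0.3, 0.2)
  # 0.9*0.5 + 0.6*0.3 + 0.2*0.2 = 0.67, by the brute-force oracle
  expect_equal(brute_choquet(c(0.9, 0.6, 0.2), g, 0), 0.67, tolerance = 1e-12)
  # and by the package's sorted-increment formula with an additive measure:
  # build a 1-sample score array whose densities normalize to (0.5, 0.3, 0.2)
  S <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8))
  gS <- singleton_measures(S, normalize = TRUE)
  cs <- choquet_fuse(array(S, c(1, 3, 2)), normalize_densities = TRUE)
  expect_equal(unname(cs$scores[1, 1]), sum(gS * S[, 1]), tolerance = 1e-9)
})

test_that("sorted-formula Choquet equals brute-force subset enumeration", {
  set.seed(15)
  ns <- asNamespace("apneafuse")
  for (l in 2:4) {
    for (rep in 1:40) {
      k <- sample(2:3, 1)
      S <- matrix(rgamma(l * k, 1), l, k)
      S <- S / rowSums(S)
      for (normalize in c(TRUE, FALSE)) {
        res <- choquet_fuse(array(S, c(1, l, k)), normalize)
        g <- singleton_measures(S, normalize)
        if (sum(g > 0) < 2 && abs(sum(g) - 1) > 1e-9) g <- g / sum(g)
        lam <- if (abs(sum(g) - 1) <= 1e-9) 0 else solve_lambda(g)
        for (cl in seq_len(k)) {
          expect_equal(unname(res$scores[1, cl]), brute_choquet(S[, cl], g, lam),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("Choquet fusion is idempotent and bounded by the score range", {
  set.seed(16)
  for (rep in 1:20) {
    p <- rgamma(2, 1); p <- p / sum(p)
    S <- rbind(p, p, p)
    res <- choquet_fuse(array(S, c(1, 3, 2)), normalize_densities = FALSE)
    expect_equal(as.numeric(res$scores), p, tolerance = 1e-9)
  }
  for (rep in 1:20) {
    S <- matrix(rgamma(6, 1), 3, 2); S <- S / rowSums(S)
    for (normalize in c(TRUE, FALSE)) {
      res <- choquet_fuse(array(S, c(1, 3, 2)), normalize)
      for (cl in 1:2) {
        expect_gte(res$scores[1, cl], min(S[, cl]) - 1e-9)
        expect_lte(res$scores[1, cl], max(S[, cl]) + 1e-9)
      }
    }
  }
})

test_that("normalized densities make Choquet an entropy-weighted mean", {
  set.seed(17)
  for (rep in 1:30) {
    S <- matrix(rgamma(8, 2), 4, 2); S <- S / rowSums(S)
    res <- choquet_fuse(array(S, c(1, 4, 2)), normalize_densities = TRUE)
    g <- singleton_measures(S, normalize = TRUE)
    expect_equal(as.numeric(res$scores), as.numeric(g %*% S), tolerance = 1e-9)
  }
})

test_that("with equal per-sample entropies Choquet ranks like the sum rule", {
  set.seed(18)
  for (rep in 1:20) {
    p <- runif(1, 0.55, 0.95)
    # all rows are permutations of (p, 1-p): identical entropies
    rows <- t(replicate(3, sample(c(p, 1 - p))))
    arr <- array(rows, c(1, 3, 2))
    ch <- choquet_fuse(arr, normalize_densities = FALSE)
    sr <- sum_rule(arr)
    expect_identical(order(ch$scores[1, ]), order(sr$scores[1, ]))
  }
})

test_that("every fusion rule keeps up with the best synthetic classifier", {
  g <- generate_score_matrices(20000, l = 3, k = 2,
                               accuracies = c(0.75, 0.8, 0.85), seed = 19)
  best <- max(vapply(1:3, function(j) {
    mean(max.col(g$scores[, j, ], ties.method = "first") == g$labels)
  }, numeric(1)))
  idx_tr <- 1:10000
  stk <- fit_stacker(g$scores[idx_tr, , ], g$labels[idx_tr], epochs = 20,
                     seed = 20)
  for (m in c("majority", "sum", "choquet")) {
    r <- fuse_scores(g$scores, m)
    expect_gte(mean(as.integer(r$class) == g$labels), best - 0.01)
  }
  r <- predict_stacker(stk, g$scores[-idx_tr, , ])
  expect_gte(mean(as.integer(r$class) == g$labels[-idx_tr]), best - 0.01)
})

test_that("the MLP stacker recovers a perfect classifier among random ones", {
  set.seed(21)
  n <- 4000
  truth <- sample(1:2, n, replace = TRUE)
  scores <- array(0, c(n, 3, 2))
  conf <- runif(n, 0.6, 0.99)
  scores[cbind(1:n, 1, truth)] <- conf
  scores[cbind(1:n, 1, 3 - truth)] <- 1 - conf
  for (j in 2:3) {
    r <- runif(n)
    scores[, j, 1] <- r
    scores[, j, 2] <- 1 - r
  }
  tr <- 1:2000
  stk <- fit_stacker(scores[tr, , ], truth[tr], epochs = 30, seed = 22)
  pred <- predict_stacker(stk, scores[-tr, , ])
  expect_gte(mean(as.integer(pred$class) == truth[-tr]), 0.95)
})

test_that("the stacker's hidden layer solves an XOR-structured score pattern", {
  set.seed(23)
  n <- 3000
  a <- sample(0:1, n, replace = TRUE)
  b <- sample(0:1, n, replace = TRUE)
  truth <- 1L + xor(a, b)            # class = agreement parity
  scores <- array(0, c(n, 2, 2))
  scores[, 1, 1] <- 0.9 * a + 0.05; scores[, 1, 2] <- 1 - scores[, 1, 1]
  scores[, 2, 1] <- 0.9 * b + 0.05; scores[, 2, 2] <- 1 - scores[, 2, 1]
  tr <- 1:1500
  stk <- fit_stacker(scores[tr, , ], truth[tr], epochs = 60, seed = 24)
  pred <- predict_stacker(stk, scores[-tr, , ])
  expect_gte(mean(as.integer(pred$class) == truth[-tr]), 0.9)
})

test_that("stacker interface rejects mismatched input and unfitted use", {
  g <- generate_score_matrices(50, l = 3, k = 2, seed = 25)
  stk <- fit_stacker(g$scores, g$labels, epochs = 2, seed = 26)
  expect_error(predict_stacker(stk, g$scores[, 1:2, , drop = FALSE]),
               "do not match")
  expect_error(predict_stacker(list(), g$scores), "not a fitted")
  expect_error(fuse_scores(g$scores, "mlp"), "stacker")
})
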