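# Independent oracles used across the suite.

# Brute-force Choquet integral: enumerates all 2^l subsets, computes the
# Sugeno measure for each directly from the closed-form union rule, and
# integrates via the layer-cake definition
#   C(s) = sum_over_levels (s_(j) - s_(j+1)) * g({i : s_i >= s_(j)})
# which never touches the package's sorted-increment formula.
brute_choquet <- function(s, g, lambda) {
  l <- length(s)
  measure <- function(idx) {
    acc <- 0
    for (j in idx) acc <- acc + g[j] + lambda * acc * g[j]
    acc
  }
  lv <- sort(unique(s), decreasing = TRUE)
  lv2 <- c(lv, 0)
  acc <- 0
  for (i in seq_along(lv)) {
    idx <- which(s >= lv[i])
    acc <- acc + (lv[i] - lv2[i + 1]) * measure(idx)
  }
  acc
}

# Reference entropy via high-precision direct evaluation in natural log.
ref_entropy_bits <- function(p) {
  nz <- p[p > 0]
  -sum(nz * log(nz)) / log(2)
}

# Simple RR-variance threshold classifier used for the separability
# monotonicity property: classify a minute as apnea when the sd of its raw
# RRI series exceeds a threshold fitted on the data (midpoint of class means).
rr_sd_per_minute <- function(record) {
  segs <- segment_record(record)
  vapply(segs, function(seg) {
    r <- mteo_detect(seg)
    b <- extract_beat_series(seg, r)
    if (length(b$rri) < 2) return(NA_real_)
    stats::sd(b$rri)
  }, numeric(1))
}

rr_threshold_accuracy <- function(record) {
  sds <- rr_sd_per_minute(record)
  y <- as.character(record$labels[seq_along(sds)])
  ok <- !is.na(sds)
  sds <- sds[ok]; y <- y[ok]
  thr <- mean(c(mean(sds[y == "apnea"]), mean(sds[y == "normal"])))
  mean(ifelse(sds > thr, "apnea", "normal") == y)
}

# Build a small normalized train/test feature-array pair from synthetic
# records (shared by model and evaluation tests).
make_feature_split <- function(n_train_per_class, n_test_per_class,
                               swing = 0.4, seed = 101, noise_sd = 0.02) {
  rec_tr <- generate_record(synthetic_spec(
    n_minutes_per_class = n_train_per_class, apnea_rr_swing = swing,
    noise_sd = noise_sd, seed = seed), record_id = "tr")
  rec_te <- generate_record(synthetic_spec(
    n_minutes_per_class = n_test_per_class, apnea_rr_swing = swing,
    noise_sd = noise_sd, seed = seed + 1), record_id = "te")
  ftr <- preprocess_record(rec_tr)
  fte <- preprocess_record(rec_te)
  zs <- fit_zscore(ftr)
  list(train = features_to_array(lapply(ftr, apply_zscore, stats = zs)),
       test = features_to_array(lapply(fte, apply_zscore, stats = zs)))
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
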