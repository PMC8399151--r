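test_that("segmentation yields 6000-sample minutes and honours indexing", {
  rec <- ecg_record("s", rnorm(2 * 6000 + 123), labels = c("A", "N"))
  segs <- segment_record(rec)
  expect_length(segs, 2)
  expect_length(segs[[1]]$samples, 6000)
  expect_equal(segs[[2]]$samples, rec$samples[6001:12000])
  expect_identical(as.character(segs[[1]]$label), "apnea")
  # no full minute -> empty list
  expect_length(segment_record(ecg_record("s0", rnorm(100), labels = "A")), 0)
  # non-native sampling rate is rejected
  expect_error(segment_record(ecg_record("s2", rnorm(6000), fs = 128,
                                         labels = "A")), "fs = 100")
})

test_that("MTEO handles degenerate inputs", {
  zero <- ecg_segment(rep(0, 6000), "N", "z", 0)
  expect_identical(mteo_detect(zero), integer(0))
  flat <- ecg_segment(rep(2.5, 6000), "N", "f", 0)
  expect_identical(mteo_detect(flat), integer(0))
  impulse <- rep(0, 6000)
  impulse[3000] <- 1   # 0-based index 2999
  one <- mteo_detect(ecg_segment(impulse, "N", "i", 0))
  expect_identical(one, 2999L)
  expect_error(mteo_detect(zero, levels = integer(0)), "levels")
  expect_error(mteo_detect(zero, refractory_s = 0), "refractory")
})

test_that("MTEO localizes noise-free synthetic beats to within 20 ms", {
  rec <- generate_record(synthetic_spec(n_minutes_per_class = 1, hrv_sd = 0,
                                        noise_sd = 0, base_hr = 75, seed = 3))
  seg <- segment_record(rec)[[1]]       # normal minute, RR = 0.8 s
  r <- mteo_detect(seg)
  truth <- rec$beat_times[rec$beat_times < 60] * 100
  expect_length(r, length(truth))
  expect_lt(max(abs(r - truth)), 2 + 1e-9)   # 20 ms at 100 Hz
  rri <- diff(r) / 100
  expect_lt(max(abs(rri - 0.8)), 0.02)
})

test_that("MTEO sensitivity and positive predictivity reach 0.95 at low noise", {
  rec <- generate_record(synthetic_spec(n_minutes_per_class = 10,
                                        noise_sd = 0.05, seed = 17))
  segs <- segment_record(rec)
  tp <- 0; n_det <- 0; n_true <- 0
  for (m in seq_along(segs)) {
    r <- mteo_detect(segs[[m]]) + (m - 1) * 6000
    truth <- rec$beat_times[rec$beat_times >= (m - 1) * 60 &
                            rec$beat_times < m * 60] * 100
    hits <- vapply(truth, function(t) any(abs(r - t) <= 5), logical(1))
    tp <- tp + sum(hits)
    n_true <- n_true + length(truth)
    n_det <- n_det + length(r)
  }
  expect_gt(tp / n_true, 0.95)   # sensitivity
  expect_gt(tp / n_det, 0.95)    # positive predictivity
})

test_that("beat series arithmetic matches its definition", {
  x <- rep(0, 6000)
  x[101] <- 1; x[181] <- 1    # 0-based peaks 100 and 180
  seg <- ecg_segment(x, "N", "b", 0)
  b <- extract_beat_series(seg, c(100L, 180L))
  expect_equal(b$rri, 0.8)
  expect_length(b$ramp, 2)
  expect_false(b$empty)
  # fewer than 2 peaks -> flagged empty
  expect_true(extract_beat_series(seg, 100L)$empty)
  # peak count conservation: beats = length(rri) + 1
  rec <- generate_record(synthetic_spec(n_minutes_per_class = 2, seed = 21))
  for (seg in segment_record(rec)) {
    bs <- extract_beat_series(seg, mteo_detect(seg))
    expect_length(bs$rri, length(bs$r_indices) - 1)
  }
})

test_that("RAMP tracks the respiratory amplitude modulation", {
  rec <- generate_record(synthetic_spec(n_minutes_per_class = 1, hrv_sd = 0,
                                        noise_sd = 0, ramp_mod_depth = 0.2,
                                        seed = 12))
  seg <- segment_record(rec)[[1]]
  b <- extract_beat_series(seg, mteo_detect(seg))
  rel <- (max(b$ramp) - min(b$ramp)) / mean(b$ramp)
  expect_equal(rel, 0.4, tolerance = 0.08)
})

test_that("EDR is constant for a constant-amplitude template train", {
  rec <- generate_record(synthetic_spec(n_minutes_per_class = 1, hrv_sd = 0,
                                        noise_sd = 0, ramp_mod_depth = 0,
                                        seed = 13))
  seg <- segment_record(rec)[[1]]
  b <- extract_beat_series(seg, mteo_detect(seg))
  core <- b$edr[2:(length(b$edr) - 1)]   # boundary beats may clip the window
  expect_lt((max(core) - min(core)) / mean(core), 0.01)
})

test_that("quality classification applies beat-count and RRI bounds", {
  mk <- function(r_idx) {
    x <- rep(0, 6000); x[r_idx + 1] <- 1
    extract_beat_series(ecg_segment(x, "N", "q", 0), r_idx)
  }
  expect_identical(classify_quality(mk(seq(0, 5920, by = 80))), "clear")  # 75 bpm
  expect_identical(classify_quality(mk(c(0, 500, 1000, 1500, 2000))), "noise") # 5 beats
  # a 1.9 s pause stays within the raw RRI bounds -> still clear
  too_slow <- mk(c(seq(0, 2000, by = 80), 2190, 2190 + seq(80, 3000, by = 80)))
  expect_identical(classify_quality(too_slow), "clear")
  with_gap <- mk(c(seq(0, 2000, by = 80), 4500, 4500 + seq(80, 1400, by = 80)))
  expect_identical(classify_quality(with_gap), "noise")   # one RRI of 2.5 s
})

test_that("resampling reproduces constants and lines on the 240-grid", {
  mkbeats <- function(times, rri = NULL, ramp = NULL, edr = NULL) {
    r_idx <- as.integer(round(times * 100))
    x <- rep(0, 6000); x[r_idx + 1] <- 1
    b <- extract_beat_series(ecg_segment(x, "N", "r", 0), r_idx)
    if (!is.null(rri)) b$rri <- rri
    if (!is.null(ramp)) b$ramp <- ramp
    if (!is.null(edr)) b$edr <- edr
    b
  }
  times <- seq(0.2, 59.8, by = 0.8)
  fm <- resample_features(mkbeats(times))
  expect_identical(dim(fm$values), c(240L, 3L))
  expect_identical(fm$quality, "clear")
  expect_equal(fm$values[, "rri"], rep(0.8, 240), tolerance = 1e-9)
  # linear-in-time RRI is reproduced at interior grid points
  b <- mkbeats(times)
  b$rri <- 0.7 + 0.002 * b$times[-1]     # line in anchor time
  fm2 <- resample_features(b, median_width = 1)
  grid <- (0:239) * 0.25
  interior <- grid >= b$times[2] & grid <= b$times[length(b$times) - 1]
  expect_equal(fm2$values[interior, "rri"], 0.7 + 0.002 * grid[interior],
               tolerance = 1e-6)
  # boundary values are held outside the beat range
  expect_equal(fm2$values[1, "rri"], fm2$values[grid == 0.25, "rri"][1])
  # fewer than 4 beats -> reclassified as noise
  few <- mkbeats(c(10, 20, 30))
  expect_identical(resample_features(few)$quality, "noise")
})

test_that("z-score normalization matches its definition and handles sigma = 0", {
  rec <- generate_record(synthetic_spec(n_minutes_per_class = 4, seed = 41))
  fm <- preprocess_record(rec)
  zs <- fit_zscore(fm)
  normed <- lapply(fm, apply_zscore, stats = zs)
  pooled <- do.call(rbind, lapply(normed, function(m) m$values))
  expect_lt(max(abs(colMeans(pooled))), 1e-6)
  expect_lt(max(abs(apply(pooled, 2, sd) - 1)), 1e-6)
  # sigma = 0 column path
  const <- feature_matrix(cbind(rep(5, 240), rnorm(240), rnorm(240)),
                          "N", "clear", "c", 0L)
  expect_warning(zs0 <- fit_zscore(list(const)), "zero-variance")
  out <- apply_zscore(const, zs0)
  expect_identical(out$values[, 1], rep(0, 240))
  expect_error(fit_zscore(list()), "empty fitting set")
  # training stats differ from self-normalization when distributions differ
  shifted <- feature_matrix(const$values + 3, "N", "clear", "c", 1L)
  expect_false(isTRUE(all.equal(apply_zscore(shifted, zs0)$values,
                                suppressWarnings(apply_zscore(shifted, fit_zscore(list(shifted)))$values))))
})

test_that("end-to-end quality flags: clean minutes clear, corrupted flagged", {
  rec <- generate_record(synthetic_spec(n_minutes_per_class = 3, noise_sd = 0,
                                        seed = 55))
  q <- vapply(preprocess_record(rec), `[[`, "", "quality")
  expect_true(all(q == "clear"))
  rec2 <- generate_record(synthetic_spec(n_minutes_per_class = 3,
                                         noisy_minute_rate = 0.5, seed = 56))
  expect_gt(length(rec2$noisy_minutes), 0)
  q2 <- vapply(preprocess_record(rec2), `[[`, "", "quality")
  expect_true(all(q2[rec2$noisy_minutes + 1] == "noise"))
  expect_true(all(q2[-(rec2$noisy_minutes + 1)] == "clear"))
})

test_that("RRI column is invariant to amplitude offsets, RAMP is not", {
  rec <- generate_record(synthetic_spec(n_minutes_per_class = 1, noise_sd = 0,
                                        seed = 60))
  seg <- segment_record(rec)[[1]]
  r <- mteo_detect(seg)
  fm1 <- resample_features(extract_beat_series(seg, r))
  seg2 <- seg
  seg2$samples <- seg$samples * 1.5      # pure amplitude scaling
  fm2 <- resample_features(extract_beat_series(seg2, r))
  expect_equal(fm2$values[, "rri"], fm1$values[, "rri"], tolerance = 1e-12)
  expect_equal(fm2$values[, "ramp"], 1.5 * fm1$values[, "ramp"],
               tolerance = 1e-9)
})
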