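#' Specification for the synthetic ECG generator
#'
#' Defines the study conditions emulated by [generate_record()]: a QRS-like
#' spike train whose RR intervals carry stationary heart-rate variability in
#' normal minutes and, in apnea minutes, an additional cyclic
#' bradycardia–tachycardia oscillation (the cyclical variation of heart rate
#' that ECG-based apnea screening exploits); R amplitudes are modulated at the
#' respiratory rate, and minutes can be replaced by broadband noise to
#' exercise the quality filter.
#'
#' @param n_minutes_per_class Minutes generated per class.
#' @param fs Sampling rate, Hz.
#' @param base_hr Baseline heart rate, beats/min.
#' @param hrv_sd Beat-to-beat RR jitter standard deviation, seconds.
#' @param apnea_cycle_period Period of the apnea RR oscillation, seconds.
#' @param apnea_rr_swing Fractional RR modulation depth in apnea minutes,
#'   in (0, 1).
#' @param resp_rate Respiratory rate driving R-amplitude modulation,
#'   breaths/min.
#' @param ramp_mod_depth Fractional R-amplitude modulation depth.
#' @param noise_sd Additive Gaussian noise standard deviation, mV.
#' @param noisy_minute_rate Probability that a minute is replaced by
#'   high-amplitude broadband noise (it keeps its class label, so the
#'   preprocessing quality filter must catch it).
#' @param seed Integer seed; a fixed seed makes the output bit-identical.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_minutes_per_class = 60, fs = 100, base_hr = 75,
                           hrv_sd = 0.02, apnea_cycle_period = 45,
                           apnea_rr_swing = 0.25, resp_rate = 15,
                           ramp_mod_depth = 0.2, noise_sd = 0.02,
                           noisy_minute_rate = 0, seed = 1) {
  stopifnot_scalar_number(n_minutes_per_class, "n_minutes_per_class", lower = 0)
  stopifnot_scalar_number(fs, "fs", lower = 1e-9)
  stopifnot_scalar_number(base_hr, "base_hr", lower = 1)
  stopifnot_scalar_number(hrv_sd, "hrv_sd", lower = 0)
  stopifnot_scalar_number(apnea_cycle_period, "apnea_cycle_period", lower = 1e-9)
  if (!(apnea_rr_swing > 0 && apnea_rr_swing < 1)) {
    stop("'apnea_rr_swing' must lie in (0, 1)")
  }
  stopifnot_scalar_number(ramp_mod_depth, "ramp_mod_depth", lower = 0, upper = 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(noisy_minute_rate, "noisy_minute_rate",
                          lower = 0, upper = 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# Ricker (Mexican-hat) pulse used as the QRS template: peak amplitude 1,
# width ~0.1 s (support truncated at +/- 0.05 s).
qrs_template <- function(fs, width_s = 0.1, sigma_s = 0.02) {
  half <- round(width_s / 2 * fs)
  t <- (-half:half) / fs
  (1 - (t / sigma_s)^2) * exp(-t^2 / (2 * sigma_s^2))
}

#' Generate a labelled synthetic ECG record
#'
#' Beats are laid down sequentially over the whole record. Each RR interval is
#' `60/base_hr` plus Gaussian jitter; while the current minute is labelled
#' apnea the interval is additionally multiplied by
#' `1 + apnea_rr_swing * sin(2*pi*t/apnea_cycle_period)`. A fixed QRS-like
#' template is placed at each beat time with amplitude
#' `1 + ramp_mod_depth * sin(2*pi*t*resp_rate/60)` mV, Gaussian noise is
#' added, and with probability `noisy_minute_rate` a minute's samples are
#' replaced by high-amplitude broadband noise (label kept, minute recorded in
#' the record's `noisy_minutes` field).
#'
#' Minute labels alternate normal/apnea so both classes see all phases of the
#' respiratory and apnea cycles.
#'
#' @param spec A [synthetic_spec].
#' @param record_id Identifier for the generated record.
#' @return An [ecg_record] with `2 * n_minutes_per_class` labelled minutes.
#' @export
generate_record <- function(spec, record_id = "synth") {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_min <- 2L * as.integer(spec$n_minutes_per_class)
  labels <- rep(c("normal", "apnea"), length.out = n_min)
  fs <- spec$fs
  n_samp <- n_min * 60 * fs
  with_seed(spec$seed, {
    # beat times over the whole record (preallocated upper bound)
    beat_t <- numeric(ceiling(n_min * 60 / 0.2) + 1L)
    nb <- 0L
    t <- 0.05   # first beat shortly after record start
    rr_base <- 60 / spec$base_hr
    while (t < n_min * 60) {
      nb <- nb + 1L
      beat_t[nb] <- t
      rr <- rr_base + stats::rnorm(1, 0, spec$hrv_sd)
      minute <- floor(t / 60)
      if (labels[minute + 1] == "apnea") {
        rr <- rr * (1 + spec$apnea_rr_swing *
                      sin(2 * pi * t / spec$apnea_cycle_period))
      }
      t <- t + max(rr, 0.2)   # physiological floor guards against huge jitter
    }
    beat_t <- beat_t[seq_len(nb)]
    amp <- 1 + spec$ramp_mod_depth * sin(2 * pi * beat_t * spec$resp_rate / 60)
    tmpl <- qrs_template(fs)
    half <- (length(tmpl) - 1L) %/% 2L
    x <- numeric(n_samp)
    centers <- round(beat_t * fs)   # 0-based sample index of each R peak
    for (b in seq_along(centers)) {
      idx <- (centers[b] - half):(centers[b] + half) + 1L
      keep <- idx >= 1L & idx <= n_samp
      x[idx[keep]] <- x[idx[keep]] + amp[b] * tmpl[keep]
    }
    if (spec$noise_sd > 0) x <- x + stats::rnorm(n_samp, 0, spec$noise_sd)
    noisy <- integer(0)
    if (spec$noisy_minute_rate > 0) {
      noisy <- which(stats::runif(n_min) < spec$noisy_minute_rate) - 1L
      for (m in noisy) {
        sl <- (m * 60 * fs + 1):((m + 1) * 60 * fs)
        x[sl] <- stats::rnorm(length(sl), 0, 2)   # broadband, ~2 mV RMS
      }
    }
    rec <- ecg_record(record_id, x, fs = fs, labels = labels,
                      noisy_minutes = noisy)
    rec$beat_times <- beat_t   # ground truth for detector validation
    rec
  })
}

#' Generate synthetic classifier score matrices
#'
#' Simulates the per-sample class-probability outputs of `l` base classifiers
#' with known marginal accuracies, for testing fusion rules in isolation. For
#' each sample and classifier the probability mass concentrates on the true
#' class with the classifier's accuracy, otherwise on a uniformly chosen wrong
#' class; rows are Dirichlet draws with concentration `sharpness` on the
#' chosen class and 1 elsewhere, so `sharpness -> Inf` gives one-hot rows.
#'
#' @param n_samples Number of samples.
#' @param l Number of classifiers.
#' @param k Number of classes.
#' @param accuracies Length-`l` vector of per-classifier accuracies, each in
#'   `(1/k, 1]`.
#' @param sharpness Dirichlet concentration on the chosen class.
#' @param seed Integer seed.
#' @return List with `scores` (an `n x l x k` array) and `labels` (integer
#'   true classes in `1..k`; for `k = 2` class 1 is apnea).
#' @export
generate_score_matrices <- function(n_samples, l = 3, k = 2,
                                    accuracies = rep(0.8, l),
                                    sharpness = 12, seed = 1) {
  if (length(accuracies) != l) stop("'accuracies' must have length l")
  if (any(accuracies <= 1 / k) || any(accuracies > 1)) {
    stop("each accuracy must lie in (1/k, 1]")
  }
  with_seed(seed, {
    truth <- sample.int(k, n_samples, replace = TRUE)
    scores <- array(0, dim = c(n_samples, l, k),
                    dimnames = list(NULL, paste0("m", seq_len(l)),
                                    if (k == 2) apnea_classes() else paste0("c", seq_len(k))))
    for (j in seq_len(l)) {
      correct <- stats::runif(n_samples) <= accuracies[j]
      target <- truth
      wrong_at <- which(!correct)
      if (length(wrong_at)) {
        shift <- sample.int(k - 1, length(wrong_at), replace = TRUE)
        target[wrong_at] <- 1L + (truth[wrong_at] - 1L + shift) %% k
      }
      alpha <- matrix(1, n_samples, k)
      alpha[cbind(seq_len(n_samples), target)] <- sharpness
      if (is.finite(sharpness)) {
        draws <- matrix(stats::rgamma(n_samples * k, shape = alpha), n_samples, k)
        scores[, j, ] <- draws / rowSums(draws)
      } else {
        onehot <- matrix(0, n_samples, k)
        onehot[cbind(seq_len(n_samples), target)] <- 1
        scores[, j, ] <- onehot
      }
    }
    list(scores = scores, labels = truth)
  })
}
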