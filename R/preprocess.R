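#' One-minute ECG segment
#'
#' @param samples Numeric vector of length `60 * fs` (6000 at 100 Hz).
#' @param label Class label (`"apnea"`/`"normal"`).
#' @param record_id,minute_index Provenance (minute index 0-based).
#' @param fs Sampling rate, Hz.
#' @return Object of class `ecg_segment`.
#' @export
ecg_segment <- function(samples, label, record_id, minute_index, fs = 100) {
  if (length(samples) != 60 * fs) {
    stop(sprintf("segment must hold exactly %d samples (got %d)",
                 60 * fs, length(samples)))
  }
  structure(list(samples = as.numeric(samples),
                 label = as_apnea_factor(label)[1],
                 record_id = record_id,
                 minute_index = as.integer(minute_index), fs = fs),
            class = "ecg_segment")
}

#' Split a record into labelled one-minute segments
#'
#' Minute `m` (0-based) maps to samples `[m*60*fs, (m+1)*60*fs)`; a trailing
#' partial minute is dropped, as are labels with no full minute of signal.
#'
#' @param record An [ecg_record]; must be sampled at 100 Hz (resample
#'   upstream otherwise).
#' @return List of [ecg_segment] objects (possibly empty).
#' @export
segment_record <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  if (record$fs != 100) {
    stop("segment_record expects fs = 100 Hz (got ", record$fs,
         "); resample the record first")
  }
  n <- n_full_minutes(record)
  lapply(seq_len(n) - 1L, function(m) {
    ecg_segment(record$samples[(m * 60 * record$fs + 1):((m + 1) * 60 * record$fs)],
                label = record$labels[m + 1], record_id = record$record_id,
                minute_index = m, fs = record$fs)
  })
}

#' Locate R peaks with a multilevel Teager energy operator
#'
#' For each lag `k` the Teager energy `psi_k[n] = x[n]^2 - x[n-k]*x[n+k]`
#' (zero at the boundaries) is smoothed with a Hamming window of length
#' `4k + 1`; the combined energy is the elementwise maximum over lags.
#' Candidate peaks are local maxima of the combined energy exceeding
#' `mean + threshold_c * sd`; a refractory interval keeps the
#' larger-energy peak of any conflicting pair, and each surviving peak is
#' refined to the argmax of `|x|` within `±refine_window_s`.
#'
#' @param segment An [ecg_segment] (or bare numeric vector with `fs`).
#' @param levels Positive integer lags of the multilevel operator.
#' @param threshold_c Threshold in energy standard deviations above the mean.
#' @param refractory_s Minimum peak separation, seconds.
#' @param refine_window_s Amplitude-refinement half-window, seconds.
#' @param fs Sampling rate when `segment` is a bare vector.
#' @return Integer vector of 0-based R-peak sample indices, strictly
#'   increasing; empty for flat or peak-free input.
#' @export
mteo_detect <- function(segment, levels = c(1, 2, 3), threshold_c = 1,
                        refractory_s = 0.25, refine_window_s = 0.05,
                        fs = 100) {
  if (inherits(segment, "ecg_segment")) {
    x <- segment$samples
    fs <- segment$fs
  } else {
    x <- as.numeric(segment)
  }
  if (length(levels) == 0 || any(levels < 1)) {
    stop("'levels' must be a nonempty set of positive integers")
  }
  if (refractory_s <= 0) stop("'refractory_s' must be positive")
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(integer(0))
  energy <- rep(0, n)
  for (k in as.integer(levels)) {
    psi <- rep(0, n)
    core <- (k + 1):(n - k)
    psi[core] <- x[core]^2 - x[core - k] * x[core + k]
    L <- 4 * k + 1
    w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))  # Hamming taper
    sm <- stats::filter(psi, w / sum(w), sides = 2)
    sm[is.na(sm)] <- 0
    energy <- pmax(energy, as.numeric(sm))
  }
  thr <- mean(energy) + threshold_c * stats::sd(energy)
  mid <- 2:(n - 1)
  is_peak <- energy[mid] > energy[mid - 1] & energy[mid] >= energy[mid + 1] &
    energy[mid] > thr
  cand <- mid[is_peak]
  if (length(cand) == 0) return(integer(0))
  # refractory: greedy by descending energy, keep peaks >= refractory apart
  refr <- round(refractory_s * fs)
  cand <- cand[order(energy[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in cand) {
    if (!length(keep) || all(abs(keep - p) >= refr)) keep <- c(keep, p)
  }
  # refine to argmax |x| within +/- refine window
  half <- round(refine_window_s * fs)
  refined <- vapply(keep, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(abs(x[lo:hi])) - 1L)
  }, integer(1))
  sort(unique(refined)) - 1L   # 0-based
}

#' Per-beat feature series derived from R peaks
#'
#' Computes, per beat: `rri` (seconds between consecutive peaks), `ramp`
#' (signal amplitude at the peak after removing the segment mean) and `edr`
#' (an ECG-derived respiration surrogate: the integral of the absolute
#' mean-removed signal over ±50 ms around the peak, which tracks the
#' respiratory modulation of QRS area).
#'
#' @param segment An [ecg_segment].
#' @param r_indices 0-based R-peak sample indices from [mteo_detect()].
#' @param edr_window_s EDR integration half-window, seconds.
#' @return Object of class `beat_series` with fields `r_indices`, `times`
#'   (seconds within the minute), `rri`, `ramp`, `edr`, `fs` and `empty`
#'   (TRUE when fewer than two peaks were available).
#' @export
extract_beat_series <- function(segment, r_indices, edr_window_s = 0.05) {
  stopifnot(inherits(segment, "ecg_segment"))
  x <- segment$samples
  fs <- segment$fs
  r_indices <- sort(as.integer(r_indices))
  if (length(r_indices) < 2) {
    return(structure(list(r_indices = r_indices, times = r_indices / fs,
                          rri = numeric(0), ramp = numeric(0),
                          edr = numeric(0), fs = fs, empty = TRUE,
                          label = segment$label, record_id = segment$record_id,
                          minute_index = segment$minute_index),
                     class = "beat_series"))
  }
  xc <- x - mean(x)
  half <- round(edr_window_s * fs)
  edr <- vapply(r_indices, function(r) {
    lo <- max(0L, r - half); hi <- min(length(x) - 1L, r + half)
    sum(abs(xc[(lo + 1):(hi + 1)])) / fs
  }, numeric(1))
  structure(list(r_indices = r_indices, times = r_indices / fs,
                 rri = diff(r_indices) / fs, ramp = xc[r_indices + 1],
                 edr = edr, fs = fs, empty = FALSE,
                 label = segment$label, record_id = segment$record_id,
                 minute_index = segment$minute_index),
            class = "beat_series")
}

#' Classify a minute as clear or noise from its beat series
#'
#' A minute is `noise` when its beat count falls outside plausibility bounds
#' or any raw RR interval does; otherwise `clear`. The defaults (20–200
#' beats/min, RRI in 0.3–2.0 s) bracket physiologically possible sinus
#' rhythm.
#'
#' @param beats A [beat_series] (from [extract_beat_series()]).
#' @param min_beats,max_beats Per-minute beat-count bounds.
#' @param rri_min_s,rri_max_s Raw RRI bounds, seconds.
#' @return `"clear"` or `"noise"`.
#' @export
classify_quality <- function(beats, min_beats = 20, max_beats = 200,
                             rri_min_s = 0.3, rri_max_s = 2.0) {
  stopifnot(inherits(beats, "beat_series"))
  n_beats <- length(beats$r_indices)
  if (beats$empty || n_beats < min_beats || n_beats > max_beats) return("noise")
  if (any(beats$rri < rri_min_s | beats$rri > rri_max_s)) return("noise")
  "clear"
}

#' Per-minute feature matrix on the uniform grid
#'
#' @param values `grid x 3` numeric matrix (columns `rri`, `ramp`, `edr`);
#'   may be all-NA for noise minutes.
#' @param label,quality,record_id,minute_index Metadata; `quality` is
#'   `"clear"` or `"noise"`.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, label, quality, record_id, minute_index) {
  values <- as.matrix(values)
  if (ncol(values) != 3) stop("feature matrix must have 3 columns")
  if (!quality %in% c("clear", "noise")) stop("quality must be 'clear' or 'noise'")
  if (quality == "clear" && !all(is.finite(values))) {
    stop("clear feature matrix must be finite")
  }
  colnames(values) <- c("rri", "ramp", "edr")
  structure(list(values = values, label = as_apnea_factor(label)[1],
                 quality = quality, record_id = record_id,
                 minute_index = as.integer(minute_index)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix %s/min %d>  %dx3, %s, label=%s\n",
              x$record_id, x$minute_index, nrow(x$values), x$quality,
              as.character(x$label)))
  invisible(x)
}

#' Resample beat-indexed features onto the uniform per-minute grid
#'
#' RRI and RAMP series are median-filtered (ectopic suppression), then
#' cubic-spline interpolated from beat times onto a uniform `grid_size`-point
#' grid over `[0, 60)` seconds; EDR is spline-interpolated without the median
#' filter. Beyond the first/last beat the boundary value is held. An RRI
#' value is anchored at the time of the second peak of its pair.
#'
#' @param beats A [beat_series] of a clear segment.
#' @param grid_size Number of grid points per minute (default 240, i.e. one
#'   per 0.25 s).
#' @param median_width Median filter width in beats (odd; <=1 disables).
#' @return A [feature_matrix]; if fewer than 4 beats survive, the minute is
#'   reclassified as noise (all-NA values).
#' @export
resample_features <- function(beats, grid_size = 240, median_width = 5) {
  stopifnot(inherits(beats, "beat_series"))
  grid <- (seq_len(grid_size) - 1) * 60 / grid_size
  n_beats <- length(beats$r_indices)
  if (beats$empty || n_beats < 4) {
    return(feature_matrix(matrix(NA_real_, grid_size, 3), beats$label,
                          "noise", beats$record_id, beats$minute_index))
  }
  medfilt <- function(v) {
    if (median_width > 1 && length(v) >= median_width) {
      as.numeric(stats::runmed(v, median_width, endrule = "median"))
    } else v
  }
  interp <- function(t, v) {
    f <- stats::splinefun(t, v, method = "fmm")
    g <- pmin(pmax(grid, t[1]), t[length(t)])  # hold boundary values
    f(g)
  }
  rri_t <- beats$times[-1]           # interval anchored at its closing beat
  vals <- cbind(rri = interp(rri_t, medfilt(beats$rri)),
                ramp = interp(beats$times, medfilt(beats$ramp)),
                edr = interp(beats$times, beats$edr))
  feature_matrix(vals, beats$label, "clear", beats$record_id,
                 beats$minute_index)
}

#' Fit / apply per-column z-score normalization
#'
#' `fit_zscore` pools all clear matrices of the fitting set and computes each
#' column's mean and standard deviation; `apply_zscore` maps a matrix to
#' `(X - mu) / sigma` per column. A zero-variance column normalizes to all
#' zeros (with a warning at fit time). Fit on the training split only to
#' avoid leakage into the test data.
#'
#' @param matrices Nonempty list of [feature_matrix] objects (noise matrices
#'   are ignored).
#' @return `fit_zscore`: object of class `zscore_stats` with fields `mean`
#'   and `sd` (length-3 each).
#' @export
fit_zscore <- function(matrices) {
  clear <- Filter(function(m) m$quality == "clear", matrices)
  if (length(clear) == 0) stop("empty fitting set: no clear feature matrices")
  pooled <- do.call(rbind, lapply(clear, function(m) m$values))
  mu <- colMeans(pooled)
  sg <- apply(pooled, 2, stats::sd)
  if (any(sg == 0)) {
    warning("zero-variance feature column(s): ",
            paste(colnames(pooled)[sg == 0], collapse = ", "),
            "; they normalize to 0")
  }
  structure(list(mean = mu, sd = sg), class = "zscore_stats")
}

#' @rdname fit_zscore
#' @param matrix A [feature_matrix].
#' @param stats A `zscore_stats` object from `fit_zscore`.
#' @export
apply_zscore <- function(matrix, stats) {
  stopifnot(inherits(matrix, "feature_matrix"), inherits(stats, "zscore_stats"))
  v <- matrix$values
  for (j in 1:3) {
    v[, j] <- if (stats$sd[j] == 0) 0 else (v[, j] - stats$mean[j]) / stats$sd[j]
  }
  out <- matrix
  out$values <- v
  out
}

#' Full preprocessing of a record into feature matrices
#'
#' Runs segmentation, MTEO R-peak detection, beat-series extraction, the
#' clear/noise quality filter and grid resampling for every labelled full
#' minute. Z-score normalization is applied separately (see [fit_zscore()])
#' so its statistics can come from a designated fitting split.
#'
#' @param record An [ecg_record].
#' @param config Configuration list as from [default_config()] (only the
#'   `preprocessing` section is used).
#' @return List of [feature_matrix] objects, one per labelled full minute.
#' @export
preprocess_record <- function(record, config = default_config()) {
  p <- config$preprocessing
  lapply(segment_record(record), function(seg) {
    r <- mteo_detect(seg, levels = p$mteo_levels, threshold_c = p$threshold_c,
                     refractory_s = p$refractory_s,
                     refine_window_s = p$refine_window_s)
    beats <- extract_beat_series(seg, r)
    if (classify_quality(beats, p$min_beats, p$max_beats,
                         p$rri_min_s, p$rri_max_s) == "noise") {
      feature_matrix(matrix(NA_real_, p$grid_size, 3), seg$label, "noise",
                     seg$record_id, seg$minute_index)
    } else {
      resample_features(beats, grid_size = p$grid_size,
                        median_width = p$median_width)
    }
  })
}

#' Stack clear feature matrices into a model-ready array
#'
#' @param matrices List of [feature_matrix] objects; noise minutes are
#'   dropped.
#' @return List with `x` (`n x grid x 3` array) and `y` (factor of labels,
#'   levels `apnea`, `normal`).
#' @export
features_to_array <- function(matrices) {
  clear <- Filter(function(m) m$quality == "clear", matrices)
  if (length(clear) == 0) {
    return(list(x = array(0, c(0, 240, 3)),
                y = factor(character(), levels = apnea_classes())))
  }
  grid <- nrow(clear[[1]]$values)
  x <- array(0, c(length(clear), grid, 3))
  for (i in seq_along(clear)) x[i, , ] <- clear[[i]]$values
  y <- as_apnea_factor(vapply(clear, function(m) as.character(m$label),
                              character(1)))
  list(x = x, y = y)
}
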