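#' Construct an ECG record
#'
#' Container for a continuous single-lead ECG trace with per-minute apnea
#' annotations. Minute `m` (0-based) covers samples `[m*60*fs, (m+1)*60*fs)`
#' (0-based, half-open). A trailing partial minute is allowed and ignored by
#' downstream segmentation.
#'
#' @param record_id Character identifier.
#' @param samples Numeric vector of amplitudes in millivolts.
#' @param fs Sampling rate in Hz (the pipeline's native rate is 100).
#' @param labels Per-minute labels: factor or character with values
#'   `"apnea"`/`"A"` or `"normal"`/`"N"`.
#' @param noisy_minutes Optional integer vector of 0-based minute indices that
#'   were deliberately corrupted (used by the synthetic generator so tests can
#'   target the quality filter).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, samples, fs = 100, labels = character(),
                       noisy_minutes = integer()) {
  stopifnot_scalar_number(fs, "fs", lower = 1e-9)
  if (!is.numeric(samples)) stop("'samples' must be numeric")
  labels <- as_apnea_factor(labels)
  structure(
    list(record_id = as.character(record_id), samples = as.numeric(samples),
         fs = fs, labels = labels, noisy_minutes = as.integer(noisy_minutes)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'>  %d samples @ %g Hz (%.1f min), %d labelled minutes (%d apnea / %d normal)\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / (60 * x$fs), length(x$labels),
              sum(x$labels == "apnea"), sum(x$labels == "normal")))
  invisible(x)
}

# Number of labelled minutes fully covered by samples.
n_full_minutes <- function(record) {
  min(length(record$labels), floor(length(record$samples) / (60 * record$fs)))
}

#' Read an ECG record with minute annotations
#'
#' Reads either the WFDB layout used by the PhysioNet Apnea-ECG database
#' (header `<record>.hea`, signal `<record>.dat` in format 16 or 212, minute
#' annotations `<record>.apn` in the MIT annotation format with mnemonic
#' `N` = normal, `A` = apnea) or the package's plain-text CSV dialect: a file
#' with header `sample_index,amplitude_mV` plus a sidecar `<record>.labels`
#' holding one character per minute (`A`/`N`, whitespace ignored).
#'
#' @param path For `format = "csv"` the path to the `.csv` file; for
#'   `format = "wfdb"` the record path without extension (as in `wfdb`
#'   tools), i.e. `path.hea`, `path.dat`, `path.apn` must exist.
#' @param format `"csv"` or `"wfdb"`.
#' @param channel 1-based signal channel to extract for multi-signal WFDB
#'   records.
#' @return An [ecg_record].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), channel = 1L) {
  if (length(format) == 1L && !format %in% c("csv", "wfdb")) {
    stop("unknown record format '", format, "'")
  }
  format <- match.arg(format)
  switch(format,
         csv = read_record_csv(path),
         wfdb = read_record_wfdb(path, channel = channel))
}

read_record_csv <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path)
  record_id <- sub("\\.csv$", "", basename(path))
  dat <- utils::read.csv(path)
  need <- c("sample_index", "amplitude_mV")
  if (!all(need %in% names(dat))) {
    stop("CSV record must have columns 'sample_index,amplitude_mV': ", path)
  }
  lab_path <- file.path(dirname(path), paste0(record_id, ".labels"))
  if (!file.exists(lab_path)) {
    stop("missing annotation sidecar for record '", record_id, "': ", lab_path)
  }
  chars <- strsplit(gsub("[[:space:]]", "", paste(readLines(lab_path), collapse = "")), "")[[1]]
  ecg_record(record_id, dat$amplitude_mV, fs = 100, labels = chars)
}

#' Write an ECG record in the package CSV dialect
#'
#' @param record An [ecg_record].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the path of the written `.csv` file.
#' @export
write_record_csv <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(record$record_id, ".csv"))
  utils::write.csv(
    data.frame(sample_index = seq_along(record$samples) - 1L,
               amplitude_mV = record$samples),
    csv, row.names = FALSE, quote = FALSE)
  writeLines(paste(ifelse(record$labels == "apnea", "A", "N"), collapse = ""),
             file.path(dir, paste0(record$record_id, ".labels")))
  invisible(csv)
}

## ---------------------------------------------------------------------------
## Minimal WFDB support (header + signal formats 16 and 212 + MIT annotations)
## ---------------------------------------------------------------------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec <- sub("/.*$", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(nsig)], function(l) {
    tk <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- as.integer(sub("[x:+].*$", "", tk[2]))
    gain_tok <- if (length(tk) >= 3) tk[3] else "200"
    gain_num <- sub("\\(.*$", "", sub("/.*$", "", gain_tok))
    gain <- as.numeric(gain_num)
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_tok)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok))
    } else if (length(tk) >= 5) as.numeric(tk[5]) else 0  # adc zero fallback
    list(file = tk[1], fmt = fmt, gain = gain, baseline = baseline)
  })
  list(record = rec, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_fmt16 <- function(path, nsig, nsamp) {
  n <- file.info(path)$size %/% 2
  raw <- readBin(path, "integer", n = n, size = 2, signed = TRUE, endian = "little")
  matrix(raw, ncol = nsig, byrow = TRUE)[seq_len(nsamp), , drop = FALSE]
}

read_dat_fmt212 <- function(path, nsig, nsamp) {
  bytes <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  npairs <- length(bytes) %/% 3
  b0 <- bytes[3 * seq_len(npairs) - 2]
  b1 <- bytes[3 * seq_len(npairs) - 1]
  b2 <- bytes[3 * seq_len(npairs)]
  s1 <- b0 + 256L * (b1 %% 16L)          # low byte + low nibble of middle
  s2 <- b2 + 256L * (b1 %/% 16L)         # low byte + high nibble of middle
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  matrix(flat[seq_len(nsig * nsamp)], ncol = nsig, byrow = TRUE)
}

# MIT annotation stream -> data.frame(sample, code). Handles SKIP (59),
# NUM/SUB/CHN (60/61/62) and AUX (63) pseudo-annotations.
parse_mit_annotations <- function(path) {
  bytes <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  i <- 1L
  t_now <- 0
  samples <- numeric(0)
  codes <- integer(0)
  while (i + 1L <= length(bytes)) {
    lo <- bytes[i]; hi <- bytes[i + 1L]
    i <- i + 2L
    code <- hi %/% 4L
    interval <- lo + 256L * (hi %% 4L)
    if (code == 0L && interval == 0L) break              # EOF
    if (code == 59L) {                                    # SKIP: 4-byte interval
      if (interval == 0L) {
        hi16 <- bytes[i] + 256L * bytes[i + 1L]
        lo16 <- bytes[i + 2L] + 256L * bytes[i + 3L]
        i <- i + 4L
        long <- hi16 * 65536 + lo16
        if (long >= 2^31) long <- long - 2^32
        t_now <- t_now + long
      }
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN fields: no time advance, ignored
    } else if (code == 63L) {                             # AUX string
      skip <- interval + interval %% 2L
      i <- i + skip
    } else {
      t_now <- t_now + interval
      samples <- c(samples, t_now)
      codes <- c(codes, code)
    }
  }
  data.frame(sample = samples, code = codes)
}

# Annotation codes of the MIT table used by apnea minute annotations.
WFDB_CODE_NORMAL <- 1L   # mnemonic "N"
WFDB_CODE_APNEA  <- 8L   # mnemonic "A"

read_record_wfdb <- function(path, channel = 1L) {
  hea <- paste0(path, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  h <- parse_wfdb_header(hea)
  dat <- file.path(dirname(hea), h$signals[[channel]]$file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat)
  fmt <- h$signals[[channel]]$fmt
  nsamp <- h$nsamp
  if (is.na(nsamp)) {
    bytes <- file.info(dat)$size
    nsamp <- if (fmt == 16) bytes %/% (2 * h$nsig) else (bytes * 2) %/% (3 * h$nsig)
  }
  adc <- switch(as.character(fmt),
                "16" = read_dat_fmt16(dat, h$nsig, nsamp),
                "212" = read_dat_fmt212(dat, h$nsig, nsamp),
                stop("unsupported WFDB signal format ", fmt,
                     " for record '", h$record, "' (formats 16 and 212 are supported)"))
  sig <- h$signals[[channel]]
  mv <- (adc[, channel] - sig$baseline) / sig$gain
  apn <- paste0(path, ".apn")
  if (!file.exists(apn)) {
    stop("missing apnea annotation file for record '", h$record, "': ", apn)
  }
  ann <- parse_mit_annotations(apn)
  ann <- ann[ann$code %in% c(WFDB_CODE_NORMAL, WFDB_CODE_APNEA), , drop = FALSE]
  minute <- round(ann$sample / (60 * h$fs))
  labels <- rep(NA_character_, if (nrow(ann)) max(minute) + 1 else 0)
  labels[minute + 1] <- ifelse(ann$code == WFDB_CODE_APNEA, "apnea", "normal")
  if (anyNA(labels)) stop("annotation stream for record '", h$record,
                          "' does not label every minute")
  ecg_record(basename(path), mv, fs = h$fs, labels = labels)
}

#' Write an ECG record in WFDB layout (format 16 + MIT minute annotations)
#'
#' Counterpart of `read_record(format = "wfdb")`, mainly used to exercise the
#' reader and to export synthetic records in a PhysioNet-style layout.
#' Amplitudes are digitized with the given gain and clipped to 16-bit range.
#'
#' @param record An [ecg_record].
#' @param dir Output directory.
#' @param gain ADC units per millivolt.
#' @return Invisibly, the record path (without extension).
#' @export
write_record_wfdb <- function(record, dir, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, record$record_id)
  adc <- as.integer(pmax(-32768, pmin(32767, round(record$samples * gain))))
  writeBin(adc, paste0(base, ".dat"), size = 2, endian = "little")
  writeLines(c(
    sprintf("%s 1 %g %d", record$record_id, record$fs, length(adc)),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 ECG", record$record_id, gain,
            if (length(adc)) adc[1] else 0)),
    paste0(base, ".hea"))
  # annotation atoms: one per minute at sample m*60*fs
  con <- file(paste0(base, ".apn"), "wb")
  on.exit(close(con))
  t_prev <- 0
  for (m in seq_along(record$labels) - 1L) {
    t_ann <- m * 60 * record$fs
    delta <- t_ann - t_prev
    t_prev <- t_ann
    code <- if (record$labels[m + 1] == "apnea") WFDB_CODE_APNEA else WFDB_CODE_NORMAL
    if (delta > 1023) {  # SKIP atom with 4-byte interval, then zero-interval atom
      writeBin(as.raw(c(0, 59 * 4)), con)
      writeBin(as.raw(c((delta %/% 65536) %% 256, (delta %/% 65536) %/% 256,
                        delta %% 256, (delta %% 65536) %/% 256)), con)
      delta <- 0
    }
    writeBin(as.raw(c(delta %% 256, code * 4 + delta %/% 256)), con)
  }
  writeBin(as.raw(c(0, 0)), con)
  invisible(base)
}

## ---------------------------------------------------------------------------
## Feature-set persistence
## ---------------------------------------------------------------------------

#' Persist a list of per-minute feature matrices
#'
#' Writes a plain-text columnar container: a metadata comment block followed
#' by a CSV table with one row per grid point. The round trip through
#' [read_feature_set()] is lossless (values, labels, quality flags, ids).
#'
#' @param path Output file path.
#' @param matrices List of [feature_matrix] objects sharing one grid size.
#' @return Invisibly, `path`.
#' @seealso [read_feature_set()]
#' @export
write_feature_set <- function(path, matrices) {
  if (length(matrices) > 0) {
    ok <- vapply(matrices, function(m) inherits(m, "feature_matrix"), logical(1))
    if (!all(ok)) stop("all elements must be feature_matrix objects")
    dims <- vapply(matrices, function(m) dim(m$values), integer(2))
    if (length(unique(dims[1, ])) != 1L || any(dims[2, ] != 3L)) {
      stop("all feature matrices must share one grid size and have 3 columns")
    }
    grid <- dims[1, 1]
  } else {
    grid <- 240L
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# apneafuse-features v1",
               sprintf("# n: %d", length(matrices)),
               sprintf("# grid: %d", grid),
               "record_id,minute_index,label,quality,row,rri,ramp,edr"), con)
  for (m in matrices) {
    v <- m$values
    writeLines(sprintf("%s,%d,%s,%s,%d,%s,%s,%s",
                       m$record_id, m$minute_index, as.character(m$label),
                       m$quality, seq_len(nrow(v)) - 1L,
                       format_num(v[, 1]), format_num(v[, 2]), format_num(v[, 3])),
               con)
  }
  invisible(path)
}

format_num <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))

#' Read a persisted feature set
#'
#' @param path Path written by [write_feature_set()].
#' @return List of [feature_matrix] objects.
#' @export
read_feature_set <- function(path) {
  if (!file.exists(path)) stop("feature set not found: ", path)
  hdr <- readLines(path, n = 3)
  if (!identical(hdr[1], "# apneafuse-features v1")) {
    stop("not an apneafuse feature-set file: ", path)
  }
  n_expect <- as.integer(sub("^# n: ", "", hdr[2]))
  grid <- as.integer(sub("^# grid: ", "", hdr[3]))
  dat <- utils::read.csv(path, comment.char = "#",
                         colClasses = c(record_id = "character"))
  if (nrow(dat) == 0) return(list())
  key <- paste(dat$record_id, dat$minute_index, sep = "\r")
  groups <- split(seq_len(nrow(dat)), factor(key, levels = unique(key)))
  out <- lapply(groups, function(idx) {
    g <- dat[idx, ]
    if (nrow(g) != grid) {
      stop(sprintf("feature matrix %s/minute %d has %d rows, expected %d",
                   g$record_id[1], g$minute_index[1], nrow(g), grid))
    }
    if (!identical(g$row, seq_len(nrow(g)) - 1L)) {
      stop("grid rows out of order in feature set: ", path)
    }
    feature_matrix(values = cbind(rri = g$rri, ramp = g$ramp, edr = g$edr),
                   label = g$label[1], quality = g$quality[1],
                   record_id = g$record_id[1], minute_index = g$minute_index[1])
  })
  names(out) <- NULL
  if (!is.na(n_expect) && length(out) != n_expect) {
    stop(sprintf("feature set declares %d matrices but contains %d",
                 n_expect, length(out)))
  }
  out
}

## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

#' Default run configuration
#'
#' Nested list of every tunable in the pipeline, serializable to YAML with
#' [save_config()] / [load_config()]. See the methods vignette for the
#' rationale behind each default.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    preprocessing = list(
      fs = 100,                 # native sampling rate, Hz
      grid_size = 240,          # per-minute feature grid (0.25 s resolution)
      mteo_levels = c(1, 2, 3), # Teager operator lags
      threshold_c = 1,          # peak threshold: mean + c * sd of energy
      refractory_s = 0.25,      # minimum R-R separation enforced, s
      refine_window_s = 0.05,   # |signal| argmax refinement half-window, s
      min_beats = 20, max_beats = 200,     # per-minute plausibility bounds
      rri_min_s = 0.3, rri_max_s = 2.0,    # raw RRI plausibility bounds, s
      median_width = 5,         # ectopic-suppression median filter, beats
      normalization_scope = "train"        # train | per_fold | global
    ),
    synthetic = list(
      n_minutes_per_class = 60, fs = 100, base_hr = 75, hrv_sd = 0.02,
      apnea_cycle_period = 45, apnea_rr_swing = 0.25, resp_rate = 15,
      ramp_mod_depth = 0.2, noise_sd = 0.02, noisy_minute_rate = 0, seed = 1
    ),
    training = list(
      epochs = 100, batch_size = 64, learning_rate = 0.001, seed = 1,
      archs = c("wang", "sharan", "almutairi")
    ),
    fusion = list(
      normalize_densities = TRUE,   # Eq.-style density normalization (=> additive measure)
      stacker_hidden = 16, stacker_epochs = 100
    ),
    evaluation = list(protocol = "two_fold", folds = 5, stratified = FALSE),
    data = list(source = "synthetic", train_paths = NULL, test_paths = NULL,
                format = "csv")
  )
}

#' Load / save a run configuration
#'
#' Reads a YAML file and merges it over [default_config()], so partial
#' configurations are valid; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return `load_config`: the merged configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad)) stop("unknown config key(s) in '", sec, "': ",
                          paste(bad, collapse = ", "))
    vals <- user[[sec]]
    vals <- vals[!vapply(vals, is.null, logical(1))]  # null (~) keeps default
    base[[sec]] <- utils::modifyList(base[[sec]], vals)
  }
  base
}

#' @rdname load_config
#' @param config Configuration list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
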