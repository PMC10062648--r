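# EEG preprocessing and differential-entropy feature extraction.
#
# Preprocessing: zero-phase (forward-backward) Butterworth filtering —
# 0.1 Hz high-pass (order 2) plus 50 Hz low-pass (order 6) for the analysis
# band-pass, and an order-2 band-stop notch at the mains frequency.
# Artifact screening flags 1-second segments by amplitude / robust-z
# thresholds, with a hard cap of 10% of the data removed.
# Features: per 1-second non-overlapping epoch, the differential entropy
# DE = 1/2 ln(2 pi e sigma^2) of each of the five canonical bands, where the
# band variance sigma^2 is the mean-removed periodogram power integrated
# over [low, high) (exact for band-limited signals, unbiased for noise).

#' Canonical EEG frequency bands
#'
#' delta 1-4, theta 4-8, alpha 8-12, beta 13-30, gamma 31-45 Hz.
#'
#' @return data.frame with `name`, `low`, `high`.
#' @export
canonical_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 13, 31), high = c(4, 8, 12, 30, 45),
             stringsAsFactors = FALSE)
}

filtfilt_rows <- function(filt, data) {
  t(apply(data, 1, function(ch) signal::filtfilt(filt, ch)))
}

#' Band-pass filter a recording
#'
#' Zero-phase band-pass implemented as an order-2 Butterworth high-pass at
#' `low` followed by an order-6 Butterworth low-pass at `high`, each applied
#' forward-backward so the passband phase is preserved for epoching.
#'
#' @param rec an [eeg_recording()].
#' @param low,high corner frequencies in Hz; `low < high < fs/2`.
#' @return filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop_field("corners", sprintf("need 0 < low < high < fs/2; got (%g, %g) at fs %g",
               low, high, rec$fs))
  hp <- signal::butter(2, low / (rec$fs / 2), type = "high")
  lp <- signal::butter(6, high / (rec$fs / 2), type = "low")
  rec$data <- filtfilt_rows(lp, filtfilt_rows(hp, rec$data))
  rec
}

#' Notch filter a recording
#'
#' Zero-phase order-2 Butterworth band-stop centred on the mains frequency
#' (default 50 Hz, stop band f0 +/- 2 Hz).
#'
#' @param rec an [eeg_recording()].
#' @param f0 notch centre frequency in Hz; must be below fs/2.
#' @param half_width half the stop-band width in Hz (default 2).
#' @return filtered [eeg_recording()].
#' @export
notch_filter <- function(rec, f0 = 50, half_width = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(f0 > 0 && f0 + half_width < rec$fs / 2))
    stop_field("f0", sprintf("notch at %g Hz invalid for fs %g", f0, rec$fs))
  bs <- signal::butter(2, c(f0 - half_width, f0 + half_width) / (rec$fs / 2),
                       type = "stop")
  rec$data <- filtfilt_rows(bs, rec$data)
  rec
}

trial_segments <- function(rec) {
  # 1-second segments aligned to each trial start; trailing partials dropped
  fs <- rec$fs
  trials <- rec$trials
  if (is.null(trials)) {
    n <- floor(ncol(rec$data) / fs)
    trials <- data.frame(trial = 1L, condition = NA_character_,
                         start_sample = 1L, end_sample = n * fs)
  } else {
    trials$trial <- seq_len(nrow(trials))
  }
  segs <- list()
  for (i in seq_len(nrow(trials))) {
    len <- trials$end_sample[i] - trials$start_sample[i] + 1L
    k <- floor(len / fs)
    if (k < 1L)
      stop_field("trial", sprintf("trial %d shorter than 1 s (%g s)", i, len / fs))
    start <- trials$start_sample[i] + (seq_len(k) - 1L) * fs
    segs[[i]] <- data.frame(trial = trials$trial[i],
                            condition = trials$condition[i],
                            stimulus_id = trials$stimulus_id[i] %||% NA_character_,
                            epoch = seq_len(k),
                            start_sample = start, end_sample = start + fs - 1L,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, segs)
}

#' Screen artifacts in 1-second segments
#'
#' Flags trial-aligned 1-second segments whose peak absolute amplitude
#' exceeds `amp_threshold` microvolts on any channel, or whose per-channel
#' robust z-score (|x - median| / MAD of the channel) exceeds `z_threshold`.
#' Flagged segments are excised: they are recorded on the returned recording
#' and [epoch_signal()] drops them. If flagging would remove more than `cap`
#' of the data, only the most extreme segments up to the cap are removed and
#' the report carries a warning.
#'
#' @param rec an [eeg_recording()] with trials.
#' @param amp_threshold absolute amplitude threshold in microvolts
#'   (default 100).
#' @param z_threshold per-channel robust z threshold (default 5).
#' @param cap maximum fraction of segments removed (default 0.10).
#' @return list with `recording` (the input with removed segments attached)
#'   and `report` (`removed_fraction`, `removed_segments`, `settings`,
#'   `warnings`).
#' @export
remove_artifacts <- function(rec, amp_threshold = 100, z_threshold = 5, cap = 0.10) {
  stopifnot(inherits(rec, "eeg_recording"))
  segs <- trial_segments(rec)
  med <- apply(rec$data, 1, median)
  madv <- apply(rec$data, 1, mad)
  madv[madv == 0] <- Inf
  score <- vapply(seq_len(nrow(segs)), function(i) {
    x <- rec$data[, segs$start_sample[i]:segs$end_sample[i], drop = FALSE]
    peak <- max(abs(x))
    rz <- max(abs(x - med) / madv)
    max(peak / amp_threshold, rz / z_threshold)
  }, numeric(1))
  flagged <- which(score > 1)
  warnings <- character(0)
  max_keep <- floor(cap * nrow(segs))
  if (length(flagged) > max_keep) {
    keep <- flagged[order(score[flagged], decreasing = TRUE)][seq_len(max_keep)]
    warnings <- sprintf(
      "flagging %d of %d segments exceeds the %.0f%% cap; retaining the %d least-extreme flagged segments",
      length(flagged), nrow(segs), 100 * cap, length(flagged) - max_keep)
    flagged <- sort(keep)
  }
  removed <- segs[flagged, c("start_sample", "end_sample"), drop = FALSE]
  rownames(removed) <- NULL
  attr(rec, "removed_segments") <- removed
  report <- list(removed_fraction = length(flagged) / nrow(segs),
                 removed_segments = removed,
                 settings = list(amp_threshold = amp_threshold,
                                 z_threshold = z_threshold, cap = cap),
                 warnings = warnings)
  stopifnot(report$removed_fraction <= cap + 1e-12)
  list(recording = rec, report = report)
}

#' Slice a recording into 1-second epochs
#'
#' Per trial, `floor(duration_s)` non-overlapping epochs of `fs` samples;
#' the trailing partial second is discarded, and epochs flagged by
#' [remove_artifacts()] are dropped. Each epoch inherits its trial's
#' condition label.
#'
#' @param rec an [eeg_recording()] with trials (each at least 1 s long).
#' @return list of epochs, each a list with `data` (channels x fs matrix),
#'   `condition`, `trial`, `stimulus_id`.
#' @export
epoch_signal <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  segs <- trial_segments(rec)
  removed <- attr(rec, "removed_segments")
  if (!is.null(removed) && nrow(removed)) {
    drop <- segs$start_sample %in% removed$start_sample
    segs <- segs[!drop, , drop = FALSE]
  }
  lapply(seq_len(nrow(segs)), function(i) {
    list(data = rec$data[, segs$start_sample[i]:segs$end_sample[i], drop = FALSE],
         condition = segs$condition[i], trial = segs$trial[i],
         stimulus_id = segs$stimulus_id[i])
  })
}

band_variance <- function(x, low, high, fs) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- (f >= low & f < high) | (f > fs - high & f <= fs - low)
  sum(p[sel])
}

#' Differential entropy of one band
#'
#' Band-limits a single-channel segment to \[low, high) by periodogram
#' integration, estimates the variance (mean removed, N denominator) and
#' returns DE = 1/2 ln(2 pi e sigma^2) — for a Gaussian band signal this is
#' its differential entropy, equal up to constants to log band power.
#'
#' @param x numeric vector of at least `fs` samples.
#' @param low,high band edges in Hz, inside (0, fs/2).
#' @param fs sampling rate in Hz.
#' @return DE in nats.
#' @examples
#' fs <- 256
#' de_feature(2 * sin(2 * pi * 10 * (1:fs) / fs), 8, 12, fs)  # ~1.7655
#' @export
de_feature <- function(x, low, high, fs) {
  if (length(x) < fs) stop_field("x", "need at least fs samples")
  if (!(low > 0 && low < high && high <= fs / 2))
    stop_field("band", "band must lie inside (0, fs/2)")
  v <- band_variance(x, low, high, fs)
  if (v <= 0) stop_field("variance", "zero band variance; DE undefined (-Inf)")
  0.5 * log(2 * pi * exp(1) * v)
}

#' Extract the epochs x 70 differential-entropy feature matrix
#'
#' Composes epoching and per-band DE: one row per surviving 1-second epoch,
#' one column per (channel, band) in channel-major order (for each of the 14
#' channels, the five bands delta..gamma).
#'
#' @param rec a preprocessed [eeg_recording()] with trials.
#' @param bands band definition data.frame (default [canonical_bands()]).
#' @return list of class `epoch_features`: `features` (epochs x
#'   channels*bands matrix), `labels` (condition per epoch), `epochs`
#'   (metadata data.frame), `columns` (column -> channel/band map).
#' @export
extract_feature_matrix <- function(rec, bands = canonical_bands()) {
  eps <- epoch_signal(rec)
  nch <- nrow(rec$data)
  cols <- expand.grid(band = bands$name, channel = rec$channel_labels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cols <- cols[, c("channel", "band")]
  feat <- matrix(NA_real_, nrow = length(eps), ncol = nch * nrow(bands),
                 dimnames = list(NULL, paste(cols$channel, cols$band, sep = "_")))
  for (i in seq_along(eps)) {
    x <- eps[[i]]$data
    feat[i, ] <- as.vector(vapply(seq_len(nch), function(ch)
      vapply(seq_len(nrow(bands)), function(b)
        de_feature(x[ch, ], bands$low[b], bands$high[b], rec$fs), numeric(1)),
      numeric(nrow(bands))))
  }
  structure(list(features = feat,
                 labels = vapply(eps, `[[`, character(1), "condition"),
                 epochs = data.frame(
                   trial = vapply(eps, `[[`, numeric(1), "trial"),
                   stimulus_id = vapply(eps, function(e) e$stimulus_id %||% NA_character_,
                                        character(1))),
                 columns = cols),
            class = "epoch_features")
}

#' @export
print.epoch_features <- function(x, ...) {
  cat(sprintf("DE feature matrix: %d epochs x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(names(table(x$labels)), table(x$labels),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
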