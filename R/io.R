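# Rating-table and EEG readers/writers, configuration.

RATING_COLS <- c("participant_id", "gender", "age_band", "stimulus_id",
                 "ee_positive", "ee_neutral", "ee_negative",
                 "sam_valence", "sam_arousal",
                 "sam_dominance", "sam_liking", "sam_familiarity")
RATING_OPTIONAL <- c("sam_dominance", "sam_liking", "sam_familiarity")

#' Read a ratings table
#'
#' Reads a long-format CSV with one row per (participant, stimulus): the
#' three emotional-evaluation state intensities (`ee_positive`, `ee_neutral`,
#' `ee_negative`) and the SAM-style dimensions (`sam_valence`, `sam_arousal`,
#' plus optional `sam_dominance`, `sam_liking`, `sam_familiarity`), all
#' integers on the 1-9 Likert scale, with participant group labels.
#'
#' @param path CSV file with a header row.
#' @return validated data.frame of rating records.
#' @export
read_ratings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_ratings(df)
}

#' Validate a ratings data.frame
#'
#' Enforces the rating-record contract: required columns present, all present
#' ratings integers in 1..9 (the optional SAM dimensions may be NA), group
#' labels valid, and (participant_id, stimulus_id) unique.
#'
#' @param df data.frame in the [read_ratings()] schema.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_ratings <- function(df) {
  required <- setdiff(RATING_COLS, RATING_OPTIONAL)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_field("columns", paste("missing columns:", paste(missing_cols, collapse = ", ")))
  for (col in RATING_OPTIONAL) if (!col %in% names(df)) df[[col]] <- NA_integer_
  bad_gender <- !df$gender %in% names(GENDERS)
  if (any(bad_gender))
    stop_field("gender", sprintf("invalid gender at row %d: '%s'",
               which(bad_gender)[1], df$gender[which(bad_gender)[1]]))
  bad_age <- !df$age_band %in% names(AGE_BANDS)
  if (any(bad_age))
    stop_field("age_band", sprintf("invalid age_band at row %d: '%s'",
               which(bad_age)[1], df$age_band[which(bad_age)[1]]))
  rating_cols <- grep("^(ee|sam)_", RATING_COLS, value = TRUE)
  for (col in rating_cols) {
    v <- df[[col]]
    optional <- col %in% RATING_OPTIONAL
    bad <- if (optional) !is.na(v) & (v %% 1 != 0 | v < 1 | v > 9)
           else is.na(v) | (v %% 1 != 0 | v < 1 | v > 9)
    if (any(bad))
      stop_field(col, sprintf("rating out of 1-9 integer range at row %d (value %s)",
                 which(bad)[1], as.character(v[which(bad)[1]])))
  }
  key <- paste(df$participant_id, df$stimulus_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    stop_field("uniqueness", sprintf("duplicate (participant, stimulus) pair at row %d: (%s, %s)",
               i, df$participant_id[i], df$stimulus_id[i]))
  }
  df[, RATING_COLS]
}

#' Write a ratings table
#'
#' @param df validated ratings data.frame.
#' @param path output CSV path.
#' @export
write_ratings <- function(df, path) {
  df <- validate_ratings(df)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# EEG recordings --------------------------------------------------------------

MONTAGE_14 <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

#' The 14-channel 10-20 montage
#'
#' Canonical channel order of the 14-electrode consumer headset layout used
#' throughout the package.
#'
#' @return character vector of 14 channel labels.
#' @export
montage_14 <- function() MONTAGE_14

#' Construct an EEG recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz (canonical 256).
#' @param channel_labels one label per row of `data`.
#' @param trials optional data.frame with `stimulus_id`, `condition`
#'   (positive/neutral/negative), `start_sample`, `end_sample` (1-based,
#'   inclusive); windows must lie inside the recording and not overlap.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, trials = NULL) {
  data <- as.matrix(data)
  if (length(channel_labels) != nrow(data))
    stop_field("channels", sprintf("%d channel labels for %d data rows",
               length(channel_labels), nrow(data)))
  if (!is.numeric(fs) || fs <= 90)
    stop_field("fs", "sampling rate must exceed twice the highest analysis band edge (45 Hz)")
  if (!is.null(trials)) {
    stopifnot(all(c("condition", "start_sample", "end_sample") %in% names(trials)))
    if (any(trials$start_sample < 1 | trials$end_sample > ncol(data)))
      stop_field("trials", "trial window outside recording")
    if (any(trials$end_sample < trials$start_sample))
      stop_field("trials", "trial end before start")
    o <- order(trials$start_sample)
    if (nrow(trials) > 1 &&
        any(trials$start_sample[o][-1] <= trials$end_sample[o][-nrow(trials)]))
      stop_field("trials", "trial windows overlap")
  }
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 trials = trials),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (!is.null(x$trials)) cat(sprintf("  %d trials\n", nrow(x$trials)))
  invisible(x)
}

#' Read a delimited EEG recording
#'
#' Reads a CSV with a one-line header of channel labels and samples in rows
#' (channels in columns). When the labels are exactly the canonical
#' 14-channel montage (in any order), channels are reordered to the canonical
#' order. Trial/condition labels can be supplied through a sidecar CSV (see
#' [read_trials()]).
#'
#' @param path CSV file.
#' @param fs sampling rate in Hz (the delimited format does not carry it).
#' @param trials optional trials data.frame or path to a sidecar CSV.
#' @return an [eeg_recording()].
#' @export
read_eeg <- function(path, fs = 256, trials = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- t(as.matrix(df))
  if (!is.numeric(mat)) stop_field("data", "non-numeric sample values")
  labels <- colnames(df)
  if (setequal(labels, MONTAGE_14) && length(labels) == 14L) {
    mat <- mat[match(MONTAGE_14, labels), , drop = FALSE]
    labels <- MONTAGE_14
  }
  if (is.character(trials)) trials <- read_trials(trials, fs = fs)
  eeg_recording(mat, fs = fs, channel_labels = labels, trials = trials)
}

#' Write a delimited EEG recording
#'
#' @param rec an [eeg_recording()].
#' @param path output CSV path (samples in rows, channels in columns).
#' @export
write_eeg <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial sidecar table
#'
#' Sidecar CSV columns: `trial_id`, `stimulus_id`, `t_start_s`, `t_end_s`.
#' The condition label is decoded from the stimulus filename grammar.
#'
#' @param path sidecar CSV.
#' @param fs sampling rate used to convert seconds to sample indices.
#' @return data.frame with `stimulus_id`, `condition`, `start_sample`,
#'   `end_sample`.
#' @export
read_trials <- function(path, fs = 256) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "stimulus_id", "t_start_s", "t_end_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_field("columns", paste("missing:", paste(miss, collapse = ", ")))
  df$condition <- vapply(df$stimulus_id, function(s)
    parse_stimulus_filename(paste0(s, ".MP4"))$valence, character(1))
  df$start_sample <- floor(df$t_start_s * fs) + 1L
  df$end_sample <- floor(df$t_end_s * fs)
  df[, c("trial_id", "stimulus_id", "condition", "start_sample", "end_sample")]
}

# Configuration ----------------------------------------------------------------

#' Default analysis configuration
#'
#' Band edges, filter settings, artifact policy, split ratio and seed used by
#' the pipeline. [read_config()] merges a YAML file over these defaults.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    bands = list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
                 beta = c(13, 30), gamma = c(31, 45)),
    bandpass = c(0.1, 50),
    notch = 50,
    artifact = list(amp_threshold_uv = 100, z_threshold = 5, max_removed = 0.10),
    split_ratio = 0.8,
    seed = 1L
  )
}

#' Read a configuration file
#'
#' @param path YAML file; keys override [default_config()] entries.
#' @return merged configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}
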