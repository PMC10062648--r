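# Seed-deterministic generators for both data kinds: Likert rating tables
# with planted age/gender/category effects, and multichannel EEG with
# condition-dependent band power, 1/f background and blink transients.

#' Rating-simulation configuration
#'
#' The default emulates the qualitative pattern of the validated short-video
#' study conditions: eight emotion categories with mid-six valence for the
#' positive ones, low-two valence for the negative ones, near-five neutral
#' valence; arousal around 6.2 for emotional categories and 2.2 for neutral;
#' a small overall female > male shift on both dimensions with a larger
#' female advantage for tenderness; a target/non-target latent gap of 3
#' scale points driving hit rates around 0.85.
#'
#' @param n_per_cell participants per (gender, age band) cell (default 20,
#'   the per-group size of the verification cohort tables).
#' @param categories data.frame with `category`, `valence3` (its collapsed
#'   positive/neutral/negative state), `valence_mean`, `arousal_mean`.
#' @param group_shifts data.frame of planted additive effects with columns
#'   `dv` (`"valence"`, `"arousal"` or `"intensity"`), optional `gender`,
#'   `age_band`, `category` (NA = applies to all) and `shift`.
#' @param intensity_mean latent mean of the target-state rating.
#' @param hit_gap latent target minus non-target gap on the emotional
#'   evaluation scale.
#' @param participant_sd,stimulus_sd,noise_sd standard deviations of the
#'   participant effect, stimulus effect and observation noise (scale
#'   points).
#' @param seed default RNG seed.
#' @return configuration list of class `rating_sim_config`.
#' @export
rating_sim_config <- function(n_per_cell = 20L,
                              categories = default_categories(),
                              group_shifts = default_group_shifts(),
                              intensity_mean = 7.2,
                              hit_gap = 3,
                              participant_sd = 0.5,
                              stimulus_sd = 0.3,
                              noise_sd = 0.8,
                              seed = 1L) {
  stopifnot(n_per_cell >= 2, participant_sd >= 0, stimulus_sd >= 0, noise_sd >= 0,
            hit_gap >= 0, intensity_mean >= 1, intensity_mean <= 9)
  structure(list(n_per_cell = as.integer(n_per_cell), categories = categories,
                 group_shifts = group_shifts, intensity_mean = intensity_mean,
                 hit_gap = hit_gap, participant_sd = participant_sd,
                 stimulus_sd = stimulus_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "rating_sim_config")
}

#' @rdname rating_sim_config
#' @export
default_categories <- function() {
  data.frame(
    category = c("disgust", "anger", "fear", "sadness", "neutrality",
                 "tenderness", "amusement", "joy"),
    valence3 = c("negative", "negative", "negative", "negative", "neutral",
                 "positive", "positive", "positive"),
    valence_mean = c(2.3, 2.7, 2.4, 2.2, 4.9, 6.4, 6.6, 6.5),
    arousal_mean = c(6.4, 6.1, 6.2, 6.1, 2.2, 6.5, 6.2, 6.3),
    stringsAsFactors = FALSE)
}

#' @rdname rating_sim_config
#' @export
default_group_shifts <- function() {
  data.frame(
    dv = c("valence", "arousal", "valence"),
    gender = c("female", "female", "female"),
    age_band = NA_character_,
    category = c(NA, NA, "tenderness"),
    shift = c(0.12, 0.24, 0.22),
    stringsAsFactors = FALSE)
}

shift_for <- function(shifts, dv, gender, age_band, category) {
  if (is.null(shifts) || !nrow(shifts)) return(0)
  sel <- shifts$dv == dv &
    (is.na(shifts$gender) | shifts$gender == gender) &
    (is.na(shifts$age_band) | shifts$age_band == age_band) &
    (is.na(shifts$category) | shifts$category == category)
  sum(shifts$shift[sel])
}

likert <- function(x) pmin(9L, pmax(1L, as.integer(round(x))))

#' Generate a synthetic ratings table
#'
#' Each latent score is grand/category mean + planted group shift +
#' participant effect + stimulus effect + Gaussian noise, clipped to
#' \[1, 9\] and rounded to the integer Likert grid. The emotional-evaluation
#' triple places the target state `hit_gap` latent points above the
#' non-target states, so configured hit rates are recoverable from the hit
#' rule. Identical config and seed give identical output.
#'
#' @param cfg a [rating_sim_config()].
#' @param catalog data.frame with `stimulus_id` and `category` (an entry of
#'   `cfg$categories`); every participant rates every stimulus.
#' @param seed RNG seed (default `cfg$seed`).
#' @return a validated ratings data.frame in the [read_ratings()] schema.
#' @export
gen_ratings <- function(cfg, catalog, seed = cfg$seed) {
  stopifnot(inherits(cfg, "rating_sim_config"),
            all(c("stimulus_id", "category") %in% names(catalog)),
            nrow(catalog) >= 1)
  bad <- setdiff(catalog$category, cfg$categories$category)
  if (length(bad)) stop_field("category", paste("unknown:", paste(bad, collapse = ", ")))
  set.seed(seed)
  gk <- group_keys()
  cats <- cfg$categories
  stim_eff <- stats::setNames(rnorm(nrow(catalog), 0, cfg$stimulus_sd),
                              catalog$stimulus_id)
  rows <- vector("list", nrow(gk) * cfg$n_per_cell)
  ri <- 0L
  for (g in seq_len(nrow(gk))) {
    for (p in seq_len(cfg$n_per_cell)) {
      pid <- sprintf("P%d%s%02d", gk$gender_code[g], gk$age_code[g], p)
      p_eff <- rnorm(1, 0, cfg$participant_sd)
      k <- nrow(catalog)
      ci <- match(catalog$category, cats$category)
      sh <- function(dv) vapply(cats$category[ci], function(cc)
        shift_for(cfg$group_shifts, dv, gk$gender[g], gk$age_band[g], cc), numeric(1))
      val <- cats$valence_mean[ci] + sh("valence") + p_eff + stim_eff +
        rnorm(k, 0, cfg$noise_sd)
      aro <- cats$arousal_mean[ci] + sh("arousal") + p_eff + stim_eff +
        rnorm(k, 0, cfg$noise_sd)
      target <- cats$valence3[ci]
      t_lat <- cfg$intensity_mean + sh("intensity") + p_eff + stim_eff +
        rnorm(k, 0, cfg$noise_sd)
      nt1 <- cfg$intensity_mean - cfg$hit_gap + rnorm(k, 0, cfg$noise_sd)
      nt2 <- cfg$intensity_mean - cfg$hit_gap + rnorm(k, 0, cfg$noise_sd)
      ee <- matrix(NA_integer_, k, 3,
                   dimnames = list(NULL, c("positive", "neutral", "negative")))
      for (j in seq_len(k)) {
        others <- setdiff(colnames(ee), target[j])
        ee[j, target[j]] <- likert(t_lat[j])
        ee[j, others[1]] <- likert(nt1[j])
        ee[j, others[2]] <- likert(nt2[j])
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        participant_id = pid, gender = gk$gender[g], age_band = gk$age_band[g],
        stimulus_id = catalog$stimulus_id,
        ee_positive = ee[, "positive"], ee_neutral = ee[, "neutral"],
        ee_negative = ee[, "negative"],
        sam_valence = likert(val), sam_arousal = likert(aro),
        sam_dominance = likert(rnorm(k, 5, 1)),
        sam_liking = likert(rnorm(k, 5, 1)),
        sam_familiarity = likert(rnorm(k, 4, 1.5)),
        stringsAsFactors = FALSE)
    }
  }
  validate_ratings(do.call(rbind, rows))
}

# EEG generator ----------------------------------------------------------------

#' EEG-simulation configuration
#'
#' Emulates a 14-channel 256 Hz recording: per channel the sum of
#' band-limited Gaussian noise in the five canonical bands (variances in
#' microvolts squared, scaled per condition), a 1/f^chi pink background, and
#' Poisson-timed raised-cosine blink transients on the frontal channels
#' (full amplitude at AF3/AF4, half at F3/F4, absent elsewhere).
#'
#' @param fs sampling rate (default 256).
#' @param band_var named base variances for delta..gamma (microvolts
#'   squared).
#' @param condition_scale data.frame `condition`, `band`, `scale`
#'   multiplying the base band variance per condition; the default plants a
#'   gamma-band power contrast across the three valence conditions.
#' @param background_var variance of the 1/f background (0 disables).
#' @param background_exponent spectral exponent chi of the background.
#' @param blink_rate blinks per minute.
#' @param blink_amplitude blink peak amplitude in microvolts (default 400).
#' @param blink_duration_s blink length in seconds (raised cosine, 0.3).
#' @param seed default RNG seed.
#' @return configuration list of class `eeg_sim_config`.
#' @export
eeg_sim_config <- function(fs = 256,
                           band_var = c(delta = 8, theta = 4, alpha = 4,
                                        beta = 2, gamma = 1),
                           condition_scale = default_condition_scale(),
                           background_var = 2,
                           background_exponent = 1,
                           blink_rate = 6,
                           blink_amplitude = 400,
                           blink_duration_s = 0.3,
                           seed = 1L) {
  stopifnot(fs > 90, all(band_var > 0), background_var >= 0, blink_rate >= 0)
  structure(list(fs = fs, band_var = band_var, condition_scale = condition_scale,
                 background_var = background_var,
                 background_exponent = background_exponent,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 blink_duration_s = blink_duration_s, seed = as.integer(seed)),
            class = "eeg_sim_config")
}

#' @rdname eeg_sim_config
#' @export
default_condition_scale <- function() {
  data.frame(condition = c("positive", "neutral", "negative"),
             band = "gamma", scale = c(2, 1, 1.5), stringsAsFactors = FALSE)
}

band_noise <- function(n, low, high, fs, variance) {
  f <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(f, rnorm(n + 2 * fs))
  x <- x[(fs + 1):(fs + n)]          # trim filter edges
  x * sqrt(variance / mean((x - mean(x))^2))
}

pink_noise <- function(n, exponent, variance) {
  amp <- rep(1, n)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up
  amp <- 1 / pmin(f, n - f + 1)^(exponent / 2)
  amp[1] <- 0
  ph <- runif(n, 0, 2 * pi)
  x <- Re(fft(amp * exp(1i * ph), inverse = TRUE))
  x <- x - mean(x)
  x * sqrt(variance / mean(x^2))
}

#' Generate a synthetic EEG recording
#'
#' @param cfg an [eeg_sim_config()].
#' @param trials data.frame with `stimulus_id` (optional), `condition`
#'   (positive/neutral/negative) and `length_s`; trials are laid out
#'   back-to-back.
#' @param seed RNG seed (default `cfg$seed`).
#' @return an [eeg_recording()] with the 14-channel montage; ground-truth
#'   blink windows are attached as `attr(, "blink_truth")` (one row per
#'   blink: trial, start/end sample).
#' @export
gen_eeg <- function(cfg, trials, seed = cfg$seed) {
  stopifnot(inherits(cfg, "eeg_sim_config"),
            all(c("condition", "length_s") %in% names(trials)),
            all(trials$length_s >= 1))
  set.seed(seed)
  fs <- cfg$fs
  bands <- canonical_bands()
  lens <- as.integer(round(trials$length_s * fs))
  total <- sum(lens)
  data <- matrix(0, 14, total, dimnames = list(MONTAGE_14, NULL))
  offs <- cumsum(c(0L, lens[-length(lens)]))
  blink_gain <- stats::setNames(numeric(14), MONTAGE_14)
  blink_gain[c("AF3", "AF4")] <- 1
  blink_gain[c("F3", "F4")] <- 0.5
  truth <- list()
  for (i in seq_len(nrow(trials))) {
    n <- lens[i]
    idx <- offs[i] + seq_len(n)
    for (ch in seq_len(14)) {
      x <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        v <- cfg$band_var[[bands$name[b]]]
        cs <- cfg$condition_scale
        sel <- cs$condition == trials$condition[i] & cs$band == bands$name[b]
        if (any(sel)) v <- v * prod(cs$scale[sel])
        x <- x + band_noise(n, bands$low[b], bands$high[b], fs, v)
      }
      if (cfg$background_var > 0)
        x <- x + pink_noise(n, cfg$background_exponent, cfg$background_var)
      data[ch, idx] <- x
    }
    n_blink <- rpois(1, cfg$blink_rate * trials$length_s[i] / 60)
    if (n_blink > 0) {
      blen <- round(cfg$blink_duration_s * fs)
      starts <- sort(sample.int(n - blen, n_blink))
      pulse <- cfg$blink_amplitude *
        (1 - cos(2 * pi * seq_len(blen) / blen)) / 2
      for (s in starts) {
        for (ch in which(blink_gain > 0))
          data[ch, offs[i] + s + seq_len(blen) - 1L] <-
            data[ch, offs[i] + s + seq_len(blen) - 1L] + blink_gain[ch] * pulse
        truth[[length(truth) + 1L]] <- data.frame(
          trial = i, start_sample = offs[i] + s,
          end_sample = offs[i] + s + blen - 1L)
      }
    }
  }
  tr <- data.frame(stimulus_id = trials$stimulus_id %||% NA_character_,
                   condition = trials$condition,
                   start_sample = offs + 1L, end_sample = offs + lens,
                   stringsAsFactors = FALSE)
  rec <- eeg_recording(data, fs = fs, channel_labels = MONTAGE_14, trials = tr)
  attr(rec, "blink_truth") <- if (length(truth)) do.call(rbind, truth)
                              else data.frame(trial = integer(0),
                                              start_sample = integer(0),
                                              end_sample = integer(0))
  rec
}
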