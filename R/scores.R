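# Stimulus scoring: intensity, hit rate, success index, top-k selection.

#' Target-emotion intensity of one stimulus
#'
#' The intensity of a stimulus is the mean rating of the target emotional
#' state on the emotional evaluation scale, with the sample (n-1) SD for
#' descriptive reporting.
#'
#' @param records rating records (rows of the [read_ratings()] schema) for a
#'   single stimulus.
#' @param target target valence: `"positive"`, `"neutral"` or `"negative"`.
#' @return list with `mean`, `sd`, `n`.
#' @export
compute_intensity <- function(records, target = c("positive", "neutral", "negative")) {
  target <- match.arg(target)
  col <- paste0("ee_", target)
  if (nrow(records) < 2L) stop_field("records", "need at least 2 records")
  v <- records[[col]]
  if (is.null(v) || anyNA(v)) stop_field(col, "missing target-state ratings")
  list(mean = mean(v), sd = sd(v), n = length(v))
}

#' Hit rate of one stimulus
#'
#' Fraction of participants who rated the target emotional state at least one
#' point higher than every other state; a tie with any non-target state
#' counts as a miss.
#'
#' @inheritParams compute_intensity
#' @return proportion in \[0, 1\].
#' @export
compute_hit_rate <- function(records, target = c("positive", "neutral", "negative")) {
  target <- match.arg(target)
  if (nrow(records) < 1L) stop_field("records", "no records")
  ee <- as.matrix(records[, c("ee_positive", "ee_neutral", "ee_negative")])
  if (anyNA(ee)) stop_field("ee", "incomplete emotional-evaluation triples")
  ti <- match(paste0("ee_", target), colnames(ee))
  hits <- apply(ee, 1, function(r) all(r[ti] >= r[-ti] + 1))
  mean(hits)
}

#' Success index within a scoring pool
#'
#' Scores each stimulus in a pool by summing the z-scores of its hit rate and
#' intensity, where both series are z-scored within the pool using the
#' population (N-denominator) standard deviation. Within a pool, z-scores and
#' hence success indices sum to zero.
#'
#' @param pool data.frame with columns `stimulus_id`, `intensity_m`,
#'   `hit_rate` (at least 2 rows).
#' @return the input with added `z_intensity`, `z_hit`, `success_index`.
#' @examples
#' pool <- data.frame(stimulus_id = c("a", "b", "c"),
#'                    intensity_m = c(5, 6, 7), hit_rate = c(.5, .6, .7))
#' compute_success_index(pool)
#' @export
compute_success_index <- function(pool) {
  stopifnot(all(c("stimulus_id", "intensity_m", "hit_rate") %in% names(pool)))
  if (nrow(pool) < 2L) stop_field("pool", "pool needs at least 2 stimuli")
  z <- function(x, what) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) stop_field(what, "zero pool variance; success index undefined")
    (x - mean(x)) / s
  }
  pool$z_intensity <- z(pool$intensity_m, "intensity")
  pool$z_hit <- z(pool$hit_rate, "hit_rate")
  pool$success_index <- pool$z_intensity + pool$z_hit
  pool
}

#' Score all stimuli in a ratings table
#'
#' Computes per-stimulus intensity and hit rate from each rater group's
#' records and the success index within scoring pools. A pool is one cell of
#' `pool_by`: participant-group columns (`gender`, `age_band`) are taken from
#' the raters, `valence` from the stimulus catalog.
#'
#' @param records validated rating records.
#' @param catalog data.frame with `stimulus_id` and `valence` (the target
#'   emotion of each stimulus), e.g. [stimulus_catalog()]. Defaults to
#'   decoding valence from the stimulus filename grammar.
#' @param pool_by character vector of pooling columns; any of `"gender"`,
#'   `"age_band"` (rater side) and `"valence"` (stimulus side).
#' @return data.frame of stimulus scores: one row per (pool, stimulus) with
#'   `pool_id`, intensity mean/SD/n, hit rate and success index.
#' @export
score_ratings <- function(records, catalog = NULL,
                          pool_by = c("gender", "valence")) {
  records <- validate_ratings(records)
  if (is.null(catalog)) {
    ids <- unique(records$stimulus_id)
    catalog <- data.frame(stimulus_id = ids, valence = vapply(ids, function(s)
      parse_stimulus_filename(paste0(s, ".MP4"))$valence, character(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("stimulus_id", "valence") %in% names(catalog)))
  rater_cols <- intersect(pool_by, c("gender", "age_band"))
  stim_cols <- intersect(pool_by, "valence")
  recs <- merge(records, catalog[, c("stimulus_id", "valence")], by = "stimulus_id")
  cells <- unique(recs[, c(rater_cols, stim_cols), drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(recs))
    for (cn in names(cells)) sel <- sel & recs[[cn]] == cells[[cn]][i]
    sub <- recs[sel, , drop = FALSE]
    ids <- sort(unique(sub$stimulus_id))
    target <- cells$valence[i] %||% NULL
    rows <- lapply(ids, function(id) {
      r <- sub[sub$stimulus_id == id, , drop = FALSE]
      tg <- if (is.null(target)) r$valence[1] else target
      it <- compute_intensity(r, tg)
      data.frame(stimulus_id = id, intensity_m = it$mean, intensity_sd = it$sd,
                 n = it$n, hit_rate = compute_hit_rate(r, tg),
                 stringsAsFactors = FALSE)
    })
    pool <- do.call(rbind, rows)
    pool <- compute_success_index(pool)
    pool$pool_id <- paste(unlist(cells[i, ]), collapse = ".")
    for (cn in names(cells)) pool[[cn]] <- cells[[cn]][i]
    out[[i]] <- pool
  }
  do.call(rbind, out)
}

#' Select the top-k stimuli per cell
#'
#' Within each (gender, age band, valence) cell, keeps the `k` stimuli with
#' the highest success indices. Ties are broken by higher hit rate, then
#' higher intensity mean, then stimulus id. Selected stimuli are assigned
#' canonical filenames following the naming grammar, numbered 1..k by rank.
#'
#' @param scores output of [score_ratings()]; must carry `gender`,
#'   `age_band` and `valence` columns identifying each cell.
#' @param k number to keep per cell (default 3).
#' @return data.frame of selections with the source `stimulus_id`, its cell,
#'   rank and canonical `filename`.
#' @export
select_stimuli <- function(scores, k = 3L) {
  need <- c("gender", "age_band", "valence", "stimulus_id",
            "success_index", "hit_rate", "intensity_m")
  stopifnot(all(need %in% names(scores)))
  cells <- unique(scores[, c("gender", "age_band", "valence")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- scores[scores$gender == cells$gender[i] &
                  scores$age_band == cells$age_band[i] &
                  scores$valence == cells$valence[i], , drop = FALSE]
    if (nrow(sub) < k)
      stop_field("cell", sprintf("cell (%s, %s, %s) has %d candidates; need %d",
                 cells$gender[i], cells$age_band[i], cells$valence[i], nrow(sub), k))
    o <- order(-sub$success_index, -sub$hit_rate, -sub$intensity_m, sub$stimulus_id)
    top <- sub[o[seq_len(k)], , drop = FALSE]
    top$rank <- seq_len(k)
    top$filename <- vapply(seq_len(k), function(j)
      format_stimulus_filename(list(valence = cells$valence[i],
                                    source_kind = "specific_short_video",
                                    gender = cells$gender[i],
                                    age_band = cells$age_band[i],
                                    number = j)), character(1))
    out[[i]] <- top[, c("stimulus_id", "gender", "age_band", "valence",
                        "success_index", "hit_rate", "intensity_m",
                        "rank", "filename")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
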