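# Stimulus naming grammar and participant group coding.
#
# Specific short videos are named  <valence>_<gender>_<age>_<number>.MP4
# with gender 1 = male, 2 = female and age 1 = 20-24, 2 = 25-29, 3 = 30-34.
# Film clips are named             <valence>_film_<number>.MP4
# Numbers run 1..3 within each cell.

VALENCES  <- c("positive", "neutral", "negative")
GENDERS   <- c(male = 1L, female = 2L)
AGE_BANDS <- c("20-24" = 1L, "25-29" = 2L, "30-34" = 3L)

#' Participant group keys
#'
#' The six participant groups: gender (male/female) crossed with age band
#' (20-24, 25-29, 30-34). Codes map to the digits used in stimulus filenames.
#'
#' @return data.frame with columns `gender`, `age_band`, `gender_code`,
#'   `age_code`, one row per group (6 rows).
#' @export
group_keys <- function() {
  g <- expand.grid(gender = names(GENDERS), age_band = names(AGE_BANDS),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$gender_code <- GENDERS[g$gender]
  g$age_code <- AGE_BANDS[g$age_band]
  g[order(g$gender_code, g$age_code), c("gender", "age_band", "gender_code", "age_code")]
}

#' Parse a stimulus filename
#'
#' Decodes the naming grammar into a stimulus descriptor. The valence word is
#' case-sensitive; the `.MP4` extension is accepted in any case.
#'
#' @param name filename, e.g. `"positive_2_3_1.MP4"` or `"neutral_film_2.MP4"`.
#' @return an object of class `stimulus_descriptor`: a list with
#'   `stimulus_id`, `valence`, `source_kind` (`"specific_short_video"` or
#'   `"film_clip"`), `gender`, `age_band` (both `NA` for film clips) and
#'   `number`.
#' @examples
#' parse_stimulus_filename("positive_2_3_1.MP4")
#' parse_stimulus_filename("positive_film_1.MP4")
#' @export
parse_stimulus_filename <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl("\\.mp4$", name, ignore.case = TRUE))
    stop_field("extension", sprintf("'%s' does not end in .MP4", name))
  stem <- sub("\\.mp4$", "", name, ignore.case = TRUE)
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (!length(parts) %in% c(3L, 4L))
    stop_field("tokens", sprintf("'%s' has %d underscore-separated tokens; expected 3 (film) or 4 (specific)", name, length(parts)))
  valence <- parts[1]
  if (!valence %in% VALENCES)
    stop_field("valence", sprintf("unknown valence word '%s' (expected one of %s)", valence, paste(VALENCES, collapse = ", ")))
  if (length(parts) == 3L) {
    if (parts[2] != "film")
      stop_field("tokens", sprintf("'%s': three-token names must have 'film' as second token", name))
    number <- parse_digit(parts[3], "number", 1L, 3L)
    desc <- list(stimulus_id = stem, valence = valence,
                 source_kind = "film_clip", gender = NA_character_,
                 age_band = NA_character_, number = number)
  } else {
    gcode <- parse_digit(parts[2], "gender", 1L, 2L)
    acode <- parse_digit(parts[3], "age", 1L, 3L)
    number <- parse_digit(parts[4], "number", 1L, 3L)
    desc <- list(stimulus_id = stem, valence = valence,
                 source_kind = "specific_short_video",
                 gender = names(GENDERS)[gcode],
                 age_band = names(AGE_BANDS)[acode], number = number)
  }
  structure(desc, class = "stimulus_descriptor")
}

parse_digit <- function(token, field, lo, hi) {
  if (!grepl("^[0-9]+$", token))
    stop_field(field, sprintf("'%s' is not a digit", token))
  v <- as.integer(token)
  if (v < lo || v > hi)
    stop_field(field, sprintf("digit %d out of range [%d, %d]", v, lo, hi))
  v
}

#' Format a stimulus descriptor back to its canonical filename
#'
#' @param desc a `stimulus_descriptor` (or a list with the same fields).
#' @return the canonical filename, ending in `.MP4`.
#' @export
format_stimulus_filename <- function(desc) {
  if (desc$source_kind == "film_clip") {
    sprintf("%s_film_%d.MP4", desc$valence, desc$number)
  } else {
    sprintf("%s_%d_%d_%d.MP4", desc$valence,
            GENDERS[[desc$gender]], AGE_BANDS[[desc$age_band]], desc$number)
  }
}

#' @export
print.stimulus_descriptor <- function(x, ...) {
  cat(format_stimulus_filename(x), "\n")
  if (x$source_kind == "film_clip") {
    cat(sprintf("  film clip, %s, number %d\n", x$valence, x$number))
  } else {
    cat(sprintf("  specific short video, %s, %s aged %s, number %d\n",
                x$valence, x$gender, x$age_band, x$number))
  }
  invisible(x)
}

#' Full stimulus catalog
#'
#' All 54 specific short-video names (6 participant groups x 3 valences x 3
#' numbers) plus the 9 film-clip names, as a data.frame of descriptors.
#'
#' @param films include the 9 film clips (default `TRUE`).
#' @return data.frame with columns `stimulus_id`, `filename`, `valence`,
#'   `source_kind`, `gender`, `age_band`, `number`.
#' @export
stimulus_catalog <- function(films = TRUE) {
  gk <- group_keys()
  rows <- list()
  for (i in seq_len(nrow(gk))) for (v in VALENCES) for (n in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(
      valence = v, source_kind = "specific_short_video",
      gender = gk$gender[i], age_band = gk$age_band[i], number = n,
      stringsAsFactors = FALSE)
  }
  if (films) for (v in VALENCES) for (n in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(
      valence = v, source_kind = "film_clip",
      gender = NA_character_, age_band = NA_character_, number = n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$filename <- vapply(seq_len(nrow(out)), function(i) {
    format_stimulus_filename(as.list(out[i, ]))
  }, character(1))
  out$stimulus_id <- sub("\\.MP4$", "", out$filename)
  out[, c("stimulus_id", "filename", "valence", "source_kind",
          "gender", "age_band", "number")]
}

#' Classify a stimulus source relative to a participant group
#'
#' A specific short video is "specific" for the group it was designed for and
#' "comparison" for any other group; film clips are always "film".
#'
#' @param stimulus_id stimulus id (filename stem) or full filename.
#' @param gender,age_band the viewing participant's group.
#' @return one of `"specific"`, `"comparison"`, `"film"`.
#' @export
classify_source <- function(stimulus_id, gender, age_band) {
  name <- if (grepl("\\.mp4$", stimulus_id, ignore.case = TRUE)) stimulus_id
          else paste0(stimulus_id, ".MP4")
  d <- parse_stimulus_filename(name)
  if (d$source_kind == "film_clip") return("film")
  if (identical(d$gender, gender) && identical(d$age_band, age_band)) "specific" else "comparison"
}
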