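# Published verification-cohort statistics for the male and female groups
# aged 20-24 (n = 20 per group): per stimulus, the target-emotion intensity
# (M, SD) of both groups, the printed t value, hit rates in percent, the
# Yates chi-square of the hit-rate contrast, and both success-index columns.
# Kept verbatim as a regression fixture for the scoring rules.

#' Verification-cohort scoring fixture
#'
#' The published per-stimulus statistics of the two gender groups aged
#' 20-24: 27 stimuli (the two groups' specific short videos plus the nine
#' film clips), each rated by 20 males and 20 females. Success indices were
#' computed within each (group, valence) pool of nine stimuli.
#'
#' @return data.frame with columns `stimulus_id`, `valence`,
#'   `intensity_m_male`, `intensity_sd_male`, `intensity_m_female`,
#'   `intensity_sd_female`, `t_value`, `hit_rate_male`, `hit_rate_female`
#'   (percent), `chi_sq`, `si_male`, `si_female`, plus `n_per_group` (20) as
#'   an attribute.
#' @export
table4_fixture <- function() {
  txt <- "
stimulus_id|im|isdm|imf|isdf|t|hm|hf|chi|sim|sif
positive_1_1_1|7.55|1.20|6.55|1.83|1.99|85|65|1.20|1.34|-2.47
positive_1_1_2|7.80|1.21|6.40|1.11|3.71|80|70|0.13|1.05|-2.32
positive_1_1_3|7.80|1.03|6.70|1.42|2.74|90|85|0.00|2.40|-0.61
positive_2_1_1|6.80|1.96|7.80|0.75|-2.07|80|100|2.50|-0.48|2.43
positive_2_1_2|7.35|1.15|7.75|0.94|-1.17|90|100|0.53|1.72|2.35
positive_2_1_3|6.95|1.53|7.20|1.17|-0.57|80|100|2.50|-0.25|1.43
positive_film_1|5.65|2.22|6.20|1.63|-0.87|75|90|0.96|-2.92|-1.04
positive_film_2|6.65|1.35|6.10|1.64|1.13|85|95|0.28|-0.03|-0.80
positive_film_3|6.60|1.24|7.20|1.63|-1.28|65|95|3.91|-2.82|1.03
neutral_1_1_1|7.90|1.51|7.15|1.62|1.47|95|95|0.00|2.21|0.24
neutral_1_1_2|7.55|1.28|7.25|1.30|0.72|90|95|0.00|1.41|0.44
neutral_1_1_3|8.00|1.10|6.40|2.08|2.96|100|95|0.00|2.70|-1.25
neutral_2_1_1|7.05|1.66|8.05|0.74|-2.40|70|100|4.90|-0.68|2.60
neutral_2_1_2|6.95|1.99|7.25|1.34|-0.55|80|100|2.50|-0.07|1.00
neutral_2_1_3|7.15|1.28|7.25|1.04|-0.26|85|100|1.44|0.55|1.00
neutral_film_1|6.15|2.29|6.30|0.95|-0.26|60|70|0.11|-2.53|-4.21
neutral_film_2|5.30|2.47|6.80|1.57|-2.23|60|90|3.33|-3.58|-1.01
neutral_film_3|6.70|1.71|7.35|1.19|-1.36|85|100|1.44|-0.01|1.20
negative_1_1_1|7.85|0.96|7.65|1.06|0.61|100|95|0.00|1.62|-0.56
negative_1_1_2|8.75|0.54|7.90|0.77|3.96|95|100|0.00|2.07|1.94
negative_1_1_3|7.70|1.10|6.90|1.26|2.08|100|95|0.00|1.48|-2.05
negative_2_1_1|6.85|1.31|8.10|0.94|-3.37|95|100|0.00|0.31|2.34
negative_2_1_2|7.85|1.46|8.25|1.04|-0.97|95|100|0.00|1.24|2.64
negative_2_1_3|7.10|1.14|7.55|0.97|-1.31|90|100|0.53|0.16|1.25
negative_film_1|4.85|2.50|7.20|1.78|-3.34|60|95|5.16|-4.20|-1.46
negative_film_2|6.00|2.07|7.00|1.48|-1.71|70|95|2.77|-2.37|-1.85
negative_film_3|7.00|1.41|6.80|1.17|0.48|85|95|0.28|-0.31|-2.25
"
  df <- read.table(text = txt, sep = "|", header = TRUE, stringsAsFactors = FALSE)
  names(df) <- c("stimulus_id", "intensity_m_male", "intensity_sd_male",
                 "intensity_m_female", "intensity_sd_female", "t_value",
                 "hit_rate_male", "hit_rate_female", "chi_sq",
                 "si_male", "si_female")
  df$valence <- vapply(df$stimulus_id, function(s)
    parse_stimulus_filename(paste0(s, ".MP4"))$valence, character(1))
  attr(df, "n_per_group") <- 20L
  df[, c("stimulus_id", "valence", "intensity_m_male", "intensity_sd_male",
         "intensity_m_female", "intensity_sd_female", "t_value",
         "hit_rate_male", "hit_rate_female", "chi_sq", "si_male", "si_female")]
}

#' Published per-group recognition accuracies
#'
#' The eight participant-group rows of the verification study's recognition
#' accuracy table (percent correct of a Random Forest on differential
#' entropy features, 8:2 split), by stimulus source.
#'
#' @return data.frame in the long format of [aggregate_accuracy_table()]:
#'   `group`, `source` (specific/comparison/film), `accuracy`.
#' @export
published_accuracy_rows <- function() {
  groups <- c("gender: 20-24 male", "gender: 20-24 female",
              "age: 20-24 male", "age: 30-34 male",
              "age_gender: 20-24 male", "age_gender: 30-34 female",
              "specific_random: 25-29 male", "specific_random: 25-29 female")
  specific   <- c(96.12, 87.28, 96.57, 90.24, 95.18, 89.41, 92.18, 84.16)
  comparison <- c(91.22, 83.87, 90.05, 87.32, 89.81, 80.56, 89.79, 78.33)
  film       <- c(84.58, 76.82, 85.43, 81.67, 86.25, 72.34, 81.65, 80.19)
  data.frame(group = rep(groups, 3),
             source = rep(c("specific", "comparison", "film"), each = 8),
             accuracy = c(specific, comparison, film),
             stringsAsFactors = FALSE)
}
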