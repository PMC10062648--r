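# Three-way mixed (split-plot) ANOVA with partial eta squared and
# Bonferroni-corrected simple effects.
#
# Design: two between-subject factors (age band, gender) crossed with one
# within-subject factor (emotion category); subjects are nested in the
# between cells. Between effects are tested against the subjects-within-
# groups error, within effects against the category x subjects-within-groups
# error. No sphericity correction is applied (plain degrees of freedom).

#' Per-participant category means
#'
#' Averages a rating dimension over the stimuli of each emotion category for
#' every participant, the unit of analysis for the mixed ANOVA.
#'
#' @param records validated rating records.
#' @param dv rating column to average (e.g. `"sam_valence"`).
#' @param catalog data.frame mapping `stimulus_id` to `category`; defaults to
#'   decoding the valence from the filename grammar.
#' @return data.frame with `participant_id`, `gender`, `age_band`,
#'   `category`, `value`.
#' @export
category_means <- function(records, dv = "sam_valence", catalog = NULL) {
  if (is.null(catalog)) {
    ids <- unique(records$stimulus_id)
    catalog <- data.frame(stimulus_id = ids, category = vapply(ids, function(s)
      parse_stimulus_filename(paste0(s, ".MP4"))$valence, character(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("stimulus_id", "category") %in% names(catalog)), dv %in% names(records))
  m <- merge(records, catalog, by = "stimulus_id")
  agg <- stats::aggregate(m[[dv]],
    by = list(participant_id = m$participant_id, gender = m$gender,
              age_band = m$age_band, category = m$category), FUN = mean)
  names(agg)[names(agg) == "x"] <- "value"
  agg
}

#' Three-way mixed ANOVA
#'
#' Split-plot decomposition for a design with two between-subject factors and
#' one within-subject factor. Each between effect (and their interaction) is
#' tested against the subjects-within-groups mean square; the within factor
#' and its interactions with the between factors are tested against the
#' within-stratum residual. Effect sizes are partial eta squared,
#' SS_effect / (SS_effect + SS_error-of-that-effect).
#'
#' When all responses are equal every sum of squares is zero; by convention
#' such effects are reported with F = 0 and p = 1.
#'
#' @param data data.frame with one row per participant x within-level (e.g.
#'   [category_means()] output).
#' @param dv name of the response column.
#' @param between names of the two between-subject factor columns.
#' @param within name of the within-subject factor column.
#' @param subject name of the subject identifier column.
#' @return data.frame of class `mixed_anova`: one row per effect with
#'   `effect`, `df_num`, `df_den`, `ss`, `ss_error`, `F`, `p`,
#'   `partial_eta2`, `stratum`.
#' @export
mixed_anova_3way <- function(data, dv = "value",
                             between = c("age_band", "gender"),
                             within = "category",
                             subject = "participant_id") {
  stopifnot(all(c(dv, between, within, subject) %in% names(data)))
  d <- data.frame(y = data[[dv]],
                  A = factor(data[[between[1]]]), B = factor(data[[between[2]]]),
                  W = factor(data[[within]]), S = factor(data[[subject]]))
  # completeness: every subject has every within level exactly once
  tab <- table(d$S, d$W)
  if (any(tab != 1L))
    stop_field("design", "every participant needs exactly one value per within-level")
  cell <- unique(d[, c("S", "A", "B")])
  if (any(table(cell$S) > 1L))
    stop_field("design", "a participant appears in more than one between-cell")
  if (any(table(cell$A, cell$B) < 2L))
    stop_field("design", "each between-cell needs at least 2 participants")

  fit <- aov(y ~ A * B * W + Error(S / W), data = d)
  sm <- summary(fit)
  grab <- function(stratum_name) {
    s <- sm[[stratum_name]][[1]]
    data.frame(term = trimws(rownames(s)), df = s$Df, ss = s$`Sum Sq`,
               stringsAsFactors = FALSE)
  }
  betw <- grab("Error: S")
  with_ <- grab("Error: S:W")
  ss_tol <- 1e-12 * max(1, sum(d$y^2))   # numerically-zero sums of squares
  build <- function(tbl, stratum) {
    err <- tbl[tbl$term == "Residuals", ]
    eff <- tbl[tbl$term != "Residuals", ]
    null_row <- eff$ss < ss_tol & err$ss < ss_tol
    ms_err <- err$ss / err$df
    F <- ifelse(null_row, 0, (eff$ss / eff$df) / ms_err)
    p <- ifelse(null_row, 1, pf(F, eff$df, err$df, lower.tail = FALSE))
    pe2 <- ifelse(eff$ss + err$ss < ss_tol, 0, eff$ss / (eff$ss + err$ss))
    data.frame(effect = eff$term, df_num = eff$df, df_den = err$df,
               ss = eff$ss, ss_error = err$ss, F = F, p = p,
               partial_eta2 = pe2, stratum = stratum, stringsAsFactors = FALSE)
  }
  out <- rbind(build(betw, "between"), build(with_, "within"))
  # restore user-facing factor names
  relabel <- c(A = between[1], B = between[2], W = within)
  out$effect <- vapply(strsplit(out$effect, ":", fixed = TRUE), function(p)
    paste(relabel[p], collapse = ":"), character(1))
  class(out) <- c("mixed_anova", "data.frame")
  attr(out, "aov") <- fit
  attr(out, "factors") <- list(between = between, within = within, subject = subject)
  out
}

#' @export
print.mixed_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$F <- round_half_up(df$F, 2)
  df$partial_eta2 <- round_half_up(df$partial_eta2, 2)
  df$p <- signif(df$p, 3)
  print(df[, c("effect", "df_num", "df_den", "F", "p", "partial_eta2")],
        row.names = FALSE)
  invisible(x)
}

#' Simple and simple-simple effect comparisons
#'
#' After a significant interaction, compares the levels of one factor
#' pairwise within each slice defined by fixed levels of the other
#' factor(s), using the omnibus split-plot error terms: within-factor
#' comparisons use the within-stratum residual; between-factor comparisons
#' at a fixed within-level use the pooled between/within error
#' (SS_between_res + SS_within_res over their summed df). Bonferroni
#' correction is applied within each slice's family of comparisons.
#'
#' @inheritParams mixed_anova_3way
#' @param effect the factor whose levels are compared.
#' @param by character vector of factors fixed to define the slices (one
#'   factor for simple effects, two for simple-simple effects).
#' @return data.frame with the slice levels, `level_a`, `level_b`,
#'   `mean_diff`, `t`, `df`, `p_raw`, `p_adjusted`.
#' @export
simple_effects <- function(data, effect, by, dv = "value",
                           between = c("age_band", "gender"),
                           within = "category",
                           subject = "participant_id") {
  an <- mixed_anova_3way(data, dv, between, within, subject)
  betw_err <- an[an$stratum == "between", ][1, c("ss_error", "df_den")]
  with_err <- an[an$stratum == "within", ][1, c("ss_error", "df_den")]
  if (effect == within) {
    ms <- with_err$ss_error / with_err$df_den
    df_err <- with_err$df_den
  } else if (within %in% by) {
    ms <- (betw_err$ss_error + with_err$ss_error) / (betw_err$df_den + with_err$df_den)
    df_err <- betw_err$df_den + with_err$df_den
  } else {
    ms <- betw_err$ss_error / betw_err$df_den
    df_err <- betw_err$df_den
  }
  slices <- unique(data[, by, drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(slices))) {
    sel <- rep(TRUE, nrow(data))
    for (cn in by) sel <- sel & data[[cn]] == slices[[cn]][i]
    sub <- data[sel, , drop = FALSE]
    levs <- sort(unique(as.character(sub[[effect]])))
    if (length(levs) < 2L)
      stop_field("slice", "slice has fewer than 2 levels of the effect factor")
    prs <- utils::combn(levs, 2, simplify = FALSE)
    rows <- lapply(prs, function(pr) {
      va <- sub[[dv]][sub[[effect]] == pr[1]]
      vb <- sub[[dv]][sub[[effect]] == pr[2]]
      diff <- mean(va) - mean(vb)
      se <- sqrt(ms * (1 / length(va) + 1 / length(vb)))
      tval <- diff / se
      cbind(slices[i, , drop = FALSE],
            data.frame(level_a = pr[1], level_b = pr[2], mean_diff = diff,
                       t = tval, df = df_err,
                       p_raw = 2 * pt(abs(tval), df_err, lower.tail = FALSE),
                       stringsAsFactors = FALSE))
    })
    fam <- do.call(rbind, rows)
    fam$p_adjusted <- bonferroni_adjust(fam$p_raw)
    out[[i]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
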