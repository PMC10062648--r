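anova_as_named <- function(an) {
  key <- c("age_band" = "A", "gender" = "B", "age_band:gender" = "AB",
           "category" = "W", "age_band:category" = "AW",
           "gender:category" = "BW", "age_band:gender:category" = "ABW")
  stats::setNames(an$F, key[an$effect])
}

make_design_df <- function(d) {
  data.frame(participant_id = d$S, age_band = d$A, gender = d$B,
             category = d$W, value = d$y, stringsAsFactors = FALSE)
}

test_that("split-plot F values match the brute-force sums-of-squares oracle", {
  cases <- list(c(nA = 3, nB = 2, nW = 3, r = 4, seed = 1),
                c(nA = 3, nB = 2, nW = 8, r = 10, seed = 2),
                c(nA = 2, nB = 2, nW = 2, r = 2, seed = 3),
                c(nA = 3, nB = 2, nW = 5, r = 3, seed = 4))
  for (cs in cases) {
    d <- random_split_plot(cs["nA"], cs["nB"], cs["nW"], cs["r"], seed = cs["seed"],
                           effects = c(A = 0.4, W = 0.6))
    oracle <- brute_force_split_plot(d)
    an <- mixed_anova_3way(make_design_df(d))
    got <- anova_as_named(an)
    for (eff in names(oracle$F)) {
      expect_equal(got[[eff]], oracle$F[[eff]], tolerance = 1e-8,
                   label = sprintf("F[%s] seed %d", eff, cs["seed"]))
    }
    # partial eta^2 definition against oracle SS
    ss_err_b <- oracle$ss$S_within; ss_err_w <- oracle$ss$W_error
    expect_equal(an$partial_eta2[an$effect == "age_band"],
                 oracle$ss$A / (oracle$ss$A + ss_err_b), tolerance = 1e-8)
    expect_equal(an$partial_eta2[an$effect == "category"],
                 oracle$ss$W / (oracle$ss$W + ss_err_w), tolerance = 1e-8)
    # balanced decomposition is exhaustive
    expect_equal(Reduce(`+`, oracle$ss[c("A", "B", "AB", "S_within", "W",
                                         "AW", "BW", "ABW", "W_error")]),
                 oracle$ss$total, tolerance = 1e-8)
  }
})

test_that("degenerate all-equal data reports F = 0, p = 1 by convention", {
  d <- random_split_plot(3, 2, 3, 2, seed = 5)
  d$y <- 5
  an <- mixed_anova_3way(make_design_df(d))
  expect_true(all(an$F == 0))
  expect_true(all(an$p == 1))
  expect_true(all(an$partial_eta2 == 0))
})

test_that("design preconditions are enforced", {
  d <- random_split_plot(2, 2, 2, 2, seed = 6)
  df <- make_design_df(d)
  expect_error(mixed_anova_3way(df[-1, ]), "within-level")
  one <- df[df$participant_id != "a1.b1.2" | df$category != "w1", ]
  expect_error(mixed_anova_3way(one), "within-level")
  # singleton between-cell
  drop <- df[!(df$participant_id %in% c("a1.b1.1")), ]
  expect_error(mixed_anova_3way(drop), "at least 2 participants")
})

test_that("a planted within-factor effect is detected and null effects are quiet", {
  # category shift Delta = 2 on the latent scale, sigma = 1 noise
  cats <- data.frame(category = c("sadness", "neutrality", "joy"),
                     valence3 = c("negative", "neutral", "positive"),
                     valence_mean = c(4, 5, 6), arousal_mean = c(5, 5, 5))
  cfg <- rating_sim_config(n_per_cell = 10, categories = cats,
                           group_shifts = data.frame(dv = character(0),
                             gender = character(0), age_band = character(0),
                             category = character(0), shift = numeric(0)),
                           participant_sd = 0.5, stimulus_sd = 0, noise_sd = 1)
  catalog <- data.frame(stimulus_id = sprintf("s%d", 1:6),
                        category = rep(cats$category, 2))
  r <- gen_ratings(cfg, catalog, seed = 77)
  cm <- category_means(r, "sam_valence",
                       data.frame(stimulus_id = catalog$stimulus_id,
                                  category = catalog$category))
  an <- mixed_anova_3way(cm)
  expect_lt(an$p[an$effect == "category"], 0.001)
  expect_gt(an$p[an$effect == "gender"], 0.05)
  expect_gt(an$p[an$effect == "age_band"], 0.05)
})

test_that("simple effects find a planted gender-by-category difference", {
  cats <- data.frame(category = c("tenderness", "neutrality"),
                     valence3 = c("positive", "neutral"),
                     valence_mean = c(6.4, 4.9), arousal_mean = c(6.5, 2.2))
  shifts <- data.frame(dv = "valence", gender = "female", age_band = NA,
                       category = "tenderness", shift = 0.5)
  cfg <- rating_sim_config(n_per_cell = 20, categories = cats,
                           group_shifts = shifts, participant_sd = 0.3,
                           stimulus_sd = 0, noise_sd = 0.6)
  catalog <- data.frame(stimulus_id = sprintf("s%d", 1:8),
                        category = rep(cats$category, 4))
  r <- gen_ratings(cfg, catalog, seed = 101)
  cm <- category_means(r, "sam_valence",
                       data.frame(stimulus_id = catalog$stimulus_id,
                                  category = catalog$category))
  se <- simple_effects(cm, effect = "gender", by = "category")
  tender <- se[se$category == "tenderness", ]
  neutral <- se[se$category == "neutrality", ]
  expect_lt(tender$p_adjusted, 0.05)
  expect_gt(neutral$p_adjusted, 0.05)
  # female minus male sign (levels sort female < male, so diff > 0)
  expect_gt(tender$mean_diff * (2 * (tender$level_a == "female") - 1), 0)
})

test_that("Bonferroni family arithmetic inside a slice", {
  d <- random_split_plot(3, 2, 3, 4, seed = 8, effects = c(A = 0.3, W = 0))
  se <- simple_effects(make_design_df(d), effect = "age_band", by = "category")
  one <- se[se$category == "w1", ]
  expect_equal(nrow(one), 3)  # 3 age levels -> 3 pairwise tests
  expect_equal(one$p_adjusted, pmin(1, 3 * one$p_raw))
})
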