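test_that("generators are seed-deterministic", {
  catalog <- data.frame(stimulus_id = c("s1", "s2"),
                        category = c("joy", "sadness"))
  cfg <- rating_sim_config(n_per_cell = 3)
  expect_identical(gen_ratings(cfg, catalog, seed = 4),
                   gen_ratings(cfg, catalog, seed = 4))
  ecfg <- eeg_sim_config()
  tr <- data.frame(condition = "positive", length_s = 5)
  r1 <- gen_eeg(ecfg, tr, seed = 4)
  r2 <- gen_eeg(ecfg, tr, seed = 4)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, gen_eeg(ecfg, tr, seed = 5)$data))
})

test_that("zero effects and zero noise collapse to the rounded grand mean", {
  cats <- data.frame(category = "neutrality", valence3 = "neutral",
                     valence_mean = 4.9, arousal_mean = 2.2)
  cfg <- rating_sim_config(n_per_cell = 2, categories = cats,
                           group_shifts = data.frame(dv = character(0),
                             gender = character(0), age_band = character(0),
                             category = character(0), shift = numeric(0)),
                           participant_sd = 0, stimulus_sd = 0, noise_sd = 0)
  r <- gen_ratings(cfg, data.frame(stimulus_id = c("s1", "s2"),
                                   category = "neutrality"), seed = 1)
  expect_true(all(r$sam_valence == 5L))
  expect_true(all(r$sam_arousal == 2L))
  expect_true(all(r$ee_neutral == 7L))  # rounded intensity mean 7.2
})

test_that("ratings stay on the Likert grid and respect configured means", {
  catalog <- data.frame(stimulus_id = sprintf("s%02d", 1:16),
                        category = rep(default_categories()$category, 2))
  r <- gen_ratings(rating_sim_config(n_per_cell = 12), catalog, seed = 6)
  cols <- grep("^(ee|sam)_", names(r), value = TRUE)
  for (cl in cols) {
    expect_true(all(r[[cl]] %in% 1:9), label = cl)
  }
  # neutral arousal low, emotional arousal high (study-pattern defaults)
  cat_map <- stats::setNames(default_categories()$category,
                             default_categories()$category)
  neutral_ids <- catalog$stimulus_id[catalog$category == "neutrality"]
  expect_lt(mean(r$sam_arousal[r$stimulus_id %in% neutral_ids]), 3.2)
  expect_gt(mean(r$sam_arousal[!r$stimulus_id %in% neutral_ids]), 5.2)
})

test_that("a planted gender shift is recoverable within simulation error", {
  shifts <- data.frame(dv = "valence", gender = "female", age_band = NA,
                       category = "tenderness", shift = 0.5)
  cats <- default_categories()
  cfg <- rating_sim_config(n_per_cell = 60, categories = cats,
                           group_shifts = shifts,
                           participant_sd = 0.4, stimulus_sd = 0, noise_sd = 0.8)
  catalog <- data.frame(stimulus_id = sprintf("t%d", 1:4), category = "tenderness")
  hits <- vapply(1:10, function(s) {
    r <- gen_ratings(cfg, catalog, seed = 200 + s)
    diff <- mean(r$sam_valence[r$gender == "female"]) -
            mean(r$sam_valence[r$gender == "male"])
    abs(diff - 0.5) <= 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the hit-model gap drives hit rates as the normal tail predicts", {
  # gap 3, noise 1: P(target >= nontarget + 1 for both) is ~0.92 before
  # rounding; the realized hit rate should stay comfortably above 0.85
  cfg <- rating_sim_config(n_per_cell = 40, hit_gap = 3,
                           participant_sd = 0, stimulus_sd = 0, noise_sd = 1)
  catalog <- data.frame(stimulus_id = sprintf("j%d", 1:4), category = "joy")
  r <- gen_ratings(cfg, catalog, seed = 33)
  hr <- compute_hit_rate(r, "positive")
  expect_gte(hr, 0.85)
})

test_that("EEG generator plants band power and blinks as configured", {
  # gamma variance ratio 2:1 -> mean gamma DE difference ~ ln(2)/2
  cfg <- eeg_sim_config(blink_rate = 0, background_var = 0,
                        condition_scale = data.frame(
                          condition = "positive", band = "gamma", scale = 2))
  trials <- data.frame(condition = c("positive", "neutral"), length_s = 60)
  fm <- extract_feature_matrix(gen_eeg(cfg, trials, seed = 14))
  g <- grep("_gamma$", colnames(fm$features))
  dd <- mean(fm$features[fm$labels == "positive", g]) -
        mean(fm$features[fm$labels == "neutral", g])
  expect_equal(dd, 0.5 * log(2), tolerance = 0.05)

  # blink_rate 0 -> nothing to remove
  clean <- gen_eeg(cfg, trials, seed = 14)
  expect_equal(remove_artifacts(clean)$report$removed_fraction, 0)
  expect_equal(nrow(attr(clean, "blink_truth")), 0)

  # planted blinks are found by the artifact stage
  bcfg <- eeg_sim_config(blink_rate = 6)
  rec <- gen_eeg(bcfg, data.frame(condition = "neutral", length_s = 100), seed = 15)
  truth <- attr(rec, "blink_truth")
  expect_gt(nrow(truth), 0)
  res <- remove_artifacts(rec)
  # every truth blink lies in a removed segment (up to the cap)
  if (res$report$removed_fraction < 0.10) {
    for (i in seq_len(nrow(truth))) {
      peak <- (truth$start_sample[i] + truth$end_sample[i]) / 2
      expect_true(any(res$report$removed_segments$start_sample <= peak &
                      res$report$removed_segments$end_sample >= peak))
    }
  }
})

test_that("generator configs validate their ranges", {
  expect_error(rating_sim_config(n_per_cell = 1), "n_per_cell")
  expect_error(rating_sim_config(noise_sd = -1), "noise_sd")
  expect_error(eeg_sim_config(band_var = c(delta = -1, theta = 1, alpha = 1,
                                           beta = 1, gamma = 1)), "band_var")
  cfg <- rating_sim_config()
  expect_error(gen_ratings(cfg, data.frame(stimulus_id = "x", category = "bliss")),
               "unknown")
})
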