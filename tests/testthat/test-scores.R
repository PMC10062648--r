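test_that("intensity is the mean target-state rating with sample SD", {
  df <- make_ratings(participants = c("p1", "p2", "p3"),
                     ee = cbind(c(8L, 7L, 9L), 2L, 2L))
  it <- compute_intensity(df, "positive")
  expect_equal(it$mean, 8)
  expect_equal(it$sd, 1)
  expect_equal(it$n, 3)

  const <- make_ratings(participants = sprintf("p%02d", 1:20),
                        ee = cbind(7L, 2L, 2L))
  it <- compute_intensity(const, "positive")
  expect_equal(it$mean, 7)
  expect_equal(it$sd, 0)

  expect_error(compute_intensity(df[0, ], "positive"), "at least 2")
})

test_that("hit rule: target must exceed every other state by at least one point", {
  # enumerated oracle: (8,3,2) hit, (5,5,1) tie -> miss, (6,5,2) hit
  df <- make_ratings(participants = c("p1", "p2", "p3"),
                     ee = cbind(c(8L, 5L, 6L), c(3L, 5L, 5L), c(2L, 1L, 2L)))
  expect_equal(compute_hit_rate(df, "positive"), 2 / 3)
  # boundary: exactly one point higher counts as a hit
  b <- make_ratings(participants = "p1", ee = cbind(6L, 5L, 5L))
  expect_equal(compute_hit_rate(b, "positive"), 1)
  # all hit -> 1
  all_hit <- make_ratings(participants = c("p1", "p2"), ee = cbind(9L, 2L, 3L))
  expect_equal(compute_hit_rate(all_hit, "positive"), 1)
})

test_that("raising a participant's target rating never decreases the hit rate", {
  set.seed(9)
  for (rep in 1:20) {
    ee <- matrix(sample(1:9, 30, replace = TRUE), 10, 3)
    df <- make_ratings(participants = sprintf("p%02d", 1:10), ee = ee)
    h0 <- compute_hit_rate(df, "positive")
    i <- sample(10, 1)
    df$ee_positive[i] <- min(9L, df$ee_positive[i] + sample(1:3, 1))
    expect_gte(compute_hit_rate(df, "positive"), h0)
  }
})

test_that("success index sums population-SD z-scores and is centred", {
  # hand-derived: means 5,6,7 and hits .5,.6,.7 -> z = (-1.2247, 0, 1.2247)
  pool <- data.frame(stimulus_id = c("a", "b", "c"),
                     intensity_m = c(5, 6, 7), hit_rate = c(.5, .6, .7))
  s <- compute_success_index(pool)
  expect_equal(s$success_index, c(-2.449, 0, 2.449), tolerance = 1e-3)
  expect_equal(sum(s$success_index), 0, tolerance = 1e-9)
  expect_equal(sum(s$z_intensity), 0, tolerance = 1e-9)

  # antisymmetry for two swapped stimuli
  two <- data.frame(stimulus_id = c("a", "b"),
                    intensity_m = c(6, 7), hit_rate = c(.9, .6))
  s2 <- compute_success_index(two)
  expect_equal(s2$success_index[1], -s2$success_index[2])

  deg <- data.frame(stimulus_id = c("a", "b"), intensity_m = c(5, 5),
                    hit_rate = c(.5, .6))
  expect_error(compute_success_index(deg), "zero pool variance")
  expect_error(compute_success_index(pool[1, ]), "at least 2")
})

test_that("published success indices reproduce in every scoring pool", {
  f <- table4_fixture()
  for (v in unique(f$valence)) {
    for (side in c("male", "female")) {
      pool <- data.frame(stimulus_id = f$stimulus_id[f$valence == v],
                         intensity_m = f[[paste0("intensity_m_", side)]][f$valence == v],
                         hit_rate = f[[paste0("hit_rate_", side)]][f$valence == v] / 100)
      s <- compute_success_index(pool)
      expect_equal(round_half_up(s$success_index, 2),
                   f[[paste0("si_", side)]][f$valence == v],
                   tolerance = 1e-12)
      expect_lt(abs(sum(s$success_index)), 1e-9)
    }
  }
})

test_that("score_ratings pipelines hit/intensity/index per pool", {
  set.seed(21)
  cats <- data.frame(stimulus_id = c(sprintf("pos%02d", 1:3), sprintf("neg%02d", 1:3)),
                     category = rep(c("joy", "sadness"), each = 3))
  # moderate hit gap and large stimulus spread so pool hit rates vary
  cfg <- rating_sim_config(n_per_cell = 8, stimulus_sd = 1, hit_gap = 1.2,
                           noise_sd = 1)
  records <- gen_ratings(cfg, cats, seed = 3)
  cat3 <- data.frame(stimulus_id = cats$stimulus_id,
                     valence = rep(c("positive", "negative"), each = 3))
  scores <- score_ratings(records, cat3, pool_by = c("gender", "age_band", "valence"))
  # 6 groups x 2 valences x 3 stimuli
  expect_equal(nrow(scores), 36)
  expect_true(all(abs(tapply(scores$success_index, scores$pool_id, sum)) < 1e-9))
  expect_true(all(scores$hit_rate >= 0 & scores$hit_rate <= 1))
})

test_that("selection keeps the top k per cell with the documented tie rules", {
  base <- expand.grid(gender = c("male", "female"),
                      age_band = c("20-24", "25-29", "30-34"),
                      valence = c("positive", "neutral", "negative"),
                      cand = 1:4, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(5)
  base$stimulus_id <- sprintf("cand_%03d", seq_len(nrow(base)))
  base$success_index <- rnorm(nrow(base))
  base$hit_rate <- runif(nrow(base))
  base$intensity_m <- runif(nrow(base), 5, 9)
  sel <- select_stimuli(base, k = 3)
  expect_equal(nrow(sel), 54)
  expect_equal(anyDuplicated(sel$filename), 0L)
  # every selected name follows the grammar
  for (nm in sel$filename) expect_silent(parse_stimulus_filename(nm))

  # exhaustion: a cell with exactly k candidates keeps everything
  cell <- base[base$gender == "male" & base$age_band == "20-24" &
               base$valence == "positive", ][1:3, ]
  cell$success_index <- c(-5, -6, -7)
  one <- select_stimuli(cell, k = 3)
  expect_setequal(one$stimulus_id, cell$stimulus_id)

  # tie on success index broken by the higher hit rate
  tie <- cell
  tie$success_index <- 0
  tie$hit_rate <- c(.2, .9, .5)
  expect_equal(select_stimuli(tie, k = 1)$stimulus_id, tie$stimulus_id[2])

  expect_error(select_stimuli(cell[1:2, ], k = 3), "candidates")
})
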