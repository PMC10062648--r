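# Builders shared across test files; all fixtures are constructed in code.

# minimal well-formed ratings data.frame
make_ratings <- function(participants = c("p1", "p2", "p3"),
                         stimuli = "positive_1_1_1",
                         gender = "male", age_band = "20-24",
                         ee = NULL) {
  grid <- expand.grid(participant_id = participants, stimulus_id = stimuli,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  if (is.null(ee)) ee <- matrix(rep(c(8L, 2L, 2L), each = n), n, 3)
  data.frame(grid["participant_id"], gender = gender, age_band = age_band,
             grid["stimulus_id"],
             ee_positive = ee[, 1], ee_neutral = ee[, 2], ee_negative = ee[, 3],
             sam_valence = 7L, sam_arousal = 6L,
             sam_dominance = 5L, sam_liking = 5L, sam_familiarity = 4L,
             stringsAsFactors = FALSE)
}

# short synthetic recording with known trial layout
make_recording <- function(length_s = c(10, 10, 10), seed = 11,
                           cfg = eeg_sim_config(blink_rate = 0)) {
  trials <- data.frame(
    stimulus_id = c("positive_1_1_1", "neutral_1_1_1", "negative_1_1_1")[seq_along(length_s)],
    condition = c("positive", "neutral", "negative")[seq_along(length_s)],
    length_s = length_s)
  gen_eeg(cfg, trials, seed = seed)
}

# brute-force balanced split-plot sums of squares from cell/marginal means:
# the independent oracle for the mixed ANOVA
brute_force_split_plot <- function(d) {
  # d: data.frame with y, A, B, W, S (balanced, complete)
  gm <- mean(d$y)
  m <- function(...) tapply(d$y, lapply(list(...), function(f) d[[f]]), mean)
  nA <- nlevels(factor(d$A)); nB <- nlevels(factor(d$B))
  nW <- nlevels(factor(d$W))
  r <- length(unique(d$S)) / (nA * nB)          # subjects per between-cell
  mA <- m("A"); mB <- m("B"); mW <- m("W")
  mAB <- m("A", "B"); mAW <- m("A", "W"); mBW <- m("B", "W")
  mABW <- m("A", "B", "W")
  mS <- tapply(d$y, d$S, mean)
  cellOfS <- unique(d[, c("S", "A", "B")])
  mABofS <- mAB[cbind(as.character(cellOfS$A), as.character(cellOfS$B))]
  names(mABofS) <- cellOfS$S
  ss <- list()
  ss$A <- r * nB * nW * sum((mA - gm)^2)
  ss$B <- r * nA * nW * sum((mB - gm)^2)
  ss$AB <- r * nW * sum((mAB - outer(mA, mB, function(a, b) a + b - gm))^2)
  ss$S_within <- nW * sum((mS - mABofS[names(mS)])^2)
  ss$W <- r * nA * nB * sum((mW - gm)^2)
  ss$AW <- r * nB * sum((mAW - outer(mA, mW, function(a, w) a + w - gm))^2)
  ss$BW <- r * nA * sum((mBW - outer(mB, mW, function(b, w) b + w - gm))^2)
  abw <- mABW
  for (a in seq_len(nA)) for (b in seq_len(nB)) for (w in seq_len(nW))
    abw[a, b, w] <- mABW[a, b, w] - mAW[a, w] - mBW[b, w] - mAB[a, b] +
      mA[a] + mB[b] + mW[w] - gm
  ss$ABW <- r * sum(abw^2)
  ss$total <- sum((d$y - gm)^2)
  ss$W_error <- ss$total - ss$A - ss$B - ss$AB - ss$S_within -
    ss$W - ss$AW - ss$BW - ss$ABW
  df <- list(A = nA - 1, B = nB - 1, AB = (nA - 1) * (nB - 1),
             S_within = nA * nB * (r - 1),
             W = nW - 1, AW = (nA - 1) * (nW - 1), BW = (nB - 1) * (nW - 1),
             ABW = (nA - 1) * (nB - 1) * (nW - 1),
             W_error = nA * nB * (r - 1) * (nW - 1))
  F <- list(
    A = (ss$A / df$A) / (ss$S_within / df$S_within),
    B = (ss$B / df$B) / (ss$S_within / df$S_within),
    AB = (ss$AB / df$AB) / (ss$S_within / df$S_within),
    W = (ss$W / df$W) / (ss$W_error / df$W_error),
    AW = (ss$AW / df$AW) / (ss$W_error / df$W_error),
    BW = (ss$BW / df$BW) / (ss$W_error / df$W_error),
    ABW = (ss$ABW / df$ABW) / (ss$W_error / df$W_error))
  list(ss = ss, df = df, F = F)
}

# random balanced split-plot dataset
random_split_plot <- function(nA = 3, nB = 2, nW = 3, r = 4, seed = 1,
                              effects = c(A = 0, W = 0)) {
  set.seed(seed)
  d <- expand.grid(A = paste0("a", 1:nA), B = paste0("b", 1:nB),
                   rep = 1:r, W = paste0("w", 1:nW),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$S <- paste(d$A, d$B, d$rep, sep = ".")
  subj_eff <- stats::setNames(rnorm(length(unique(d$S)), 0, 0.7), unique(d$S))
  d$y <- rnorm(nrow(d)) + subj_eff[d$S] +
    effects["A"] * as.integer(factor(d$A)) +
    effects["W"] * as.integer(factor(d$W))
  d
}
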