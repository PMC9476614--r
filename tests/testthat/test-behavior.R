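test_that("signed asynchronies follow the player1-minus-player2 convention", {
  s <- stream_at(grid_onsets())
  expect_equal(signed_asynchronies(s$p1, s$p2)$asynchrony, rep(0, 14))
  shifted <- stream_at(grid_onsets() + 0.015, grid_onsets())
  expect_equal(signed_asynchronies(shifted$p1, shifted$p2)$asynchrony,
               rep(0.015, 14))
  # hand-built 3-keystroke case
  a <- data.frame(trial = 1, phrase = 1, position = 1:3,
                  onset_s = c(3.00, 3.52, 4.01))
  b <- data.frame(trial = 1, phrase = 1, position = 1:3,
                  onset_s = c(3.01, 3.50, 4.00))
  expect_equal(signed_asynchronies(a, b)$asynchrony,
               c(-0.01, 0.02, 0.01))
  expect_error(signed_asynchronies(a, transform(b, position = 5:7)),
               "common")
})

test_that("normalization subtracts per-cell means and is idempotent", {
  tab <- data.frame(pair = 1, trial = c(1, 2), piece = "A",
                    tempo_condition = "congruent", familiarity = "familiar",
                    phrase = 1, position = 1,
                    asynchrony = c(0.010, -0.004))
  n1 <- normalize_asynchronies(tab)
  expect_equal(n1$normalized, c(0.007, -0.007))
  # idempotence
  n2 <- normalize_asynchronies(transform(n1, asynchrony = normalized))
  expect_equal(n2$normalized, n1$normalized)
  # identical values and single-trial cells map to zero
  same <- transform(tab, asynchrony = 0.02)
  expect_equal(normalize_asynchronies(same)$normalized, c(0, 0))
  single <- tab[1, ]
  expect_equal(normalize_asynchronies(single)$normalized, 0)
  expect_error(normalize_asynchronies(tab[0, ]), "empty")
  # cell means vanish per (pair, piece, phrase, position)
  d <- make_design(2, 4, seed = 2)
  ks <- simulate_keystrokes(d[d$pair_id == 1, ], sim_params(rng_seed = 2))
  nt <- normalize_asynchronies(asynchrony_table(ks, d))
  mu <- aggregate(normalized ~ pair + piece + phrase + position, nt, mean)
  expect_true(all(abs(mu$normalized) < 1e-12))
})

test_that("phrase-half accuracy uses keystrokes 1-3 / 5-7 and omits the
           fourth", {
  base <- expand.grid(trial = 1:2, position = 1:7)
  tab <- data.frame(pair = 1, trial = base$trial, piece = "A",
                    tempo_condition = "congruent",
                    familiarity = "familiar", phrase = 1,
                    position = base$position,
                    asynchrony = 0)
  tab$normalized <- ifelse(tab$position <= 3,
                           0.01 * tab$trial * tab$position, 0.05)
  first <- phrase_half_accuracy(tab, "first")
  # hand arithmetic: mean over positions 1..3 and trials 1..2 of
  # |0.01 * trial * position|
  expect_equal(first$accuracy, mean(c(1:3, 2 * (1:3)) * 0.01))
  # altering position 4 leaves both halves unchanged
  tab2 <- tab; tab2$normalized[tab2$position == 4] <- 99
  expect_equal(phrase_half_accuracy(tab2, "first"), first)
  expect_equal(phrase_half_accuracy(tab2, "second")$accuracy, 0.05)
  expect_error(phrase_half_accuracy(tab, "third"))
  # zero data -> zero accuracy
  tab$normalized <- 0
  expect_equal(phrase_half_accuracy(tab, "second")$accuracy, 0)
})

test_that("lag-0 adaptation equals the Pearson correlation of IKI series", {
  on1 <- c(3, 3.51, 4.02, 4.49, 5.03, 5.52, 6.01)
  s <- stream_at(c(on1, 11 + 0.4 * (0:6)),
                 c(on1 + 0.2, 11.2 + 0.4 * (0:6)))  # IKIs identical
  z <- lag0_adaptation(s$p1, s$p2)
  expect_equal(z, atanh(1 - 1e-10))     # r = 1 at the clamp ceiling
  # hand-built 6-IKI pair against a brute-force Pearson computation
  on2 <- c(3, 3.48, 4.01, 4.53, 5.00, 5.49, 6.02)
  s2 <- stream_at(c(on1, 11 + 0.4 * (0:6)), c(on2, 11 + 0.4 * (0:6)))
  r_oracle <- cor(diff(on1), diff(on2))
  expect_equal(lag0_adaptation(s2$p1, s2$p2), atanh(r_oracle))
  # zero-variance series are flagged, not crashed
  sg <- stream_at(grid_onsets(), c(on2, 11 + 0.4 * (0:6)))
  z0 <- lag0_adaptation(sg$p1, sg$p2)
  expect_true(is.na(z0))
  expect_equal(attr(z0, "flag"), "zero_variance")
})

test_that("independent IKI series give mean Fisher z near zero", {
  set.seed(42)
  zs <- replicate(400, {
    o1 <- cumsum(c(3, 0.5 + rnorm(6, 0, 0.02)))
    o2 <- cumsum(c(3, 0.5 + rnorm(6, 0, 0.02)))
    s <- stream_at(c(o1, 11 + 0.4 * (0:6)), c(o2, 11 + 0.4 * (0:6)))
    lag0_adaptation(s$p1, s$p2)
  })
  # E[z] = 0 under independence; SD(z) ~ 1/sqrt(6-3)
  expect_lt(abs(mean(zs)), 4 / sqrt(3) / sqrt(400))
})

test_that("entry asynchrony and phrase-2 IKI differences match hand
           arithmetic", {
  s <- stream_at(c(3 + 0.5 * (0:6), 11.00 + 0.4 * (0:6)),
                 c(3 + 0.5 * (0:6), 11.08 + 0.4 * (0:6)))
  expect_equal(entry_asynchrony(s$p1, s$p2), 0.08)
  expect_equal(entry_asynchrony(s$p1, s$p1), 0)
  # 150 bpm vs 96 bpm, noise free: |400 - 625| ms = 0.225 s
  s2 <- stream_at(c(3 + 0.5 * (0:6), 11 + 0.400 * (0:6)),
                  c(3 + 0.5 * (0:6), 11 + 0.625 * (0:6)))
  expect_equal(iki_difference_phrase2(s2$p1, s2$p2), 0.225)
  expect_equal(iki_difference_phrase2(s2$p1, s2$p1), 0)
  # missing entry / no common IKI flags
  no2 <- s$p2[s$p2$phrase == 1, ]
  expect_equal(attr(entry_asynchrony(s$p1, no2), "flag"), "missing_entry")
  expect_equal(attr(iki_difference_phrase2(s$p1, no2), "flag"),
               "no_common_ikis")
})

test_that("swapping players negates signed asynchronies and leaves
           absolute measures unchanged", {
  des <- design_with("up", "down")
  ks <- simulate_keystrokes(des, sim_params(rng_seed = 6))
  s <- split_players(ks)
  a12 <- signed_asynchronies(s$p1, s$p2)
  a21 <- signed_asynchronies(s$p2, s$p1)
  expect_equal(a12$asynchrony, -a21$asynchrony)
  expect_equal(entry_asynchrony(s$p1, s$p2), entry_asynchrony(s$p2, s$p1))
  expect_equal(iki_difference_phrase2(s$p1, s$p2),
               iki_difference_phrase2(s$p2, s$p1))
  expect_equal(lag0_adaptation(s$p1, s$p2), lag0_adaptation(s$p2, s$p1))
})

test_that("behavioral trial table feeds the 2x2 rmANOVA report", {
  d <- make_design(2, 3, seed = 8)
  p <- sim_params(rng_seed = 8)
  ks <- do.call(rbind, lapply(split(d, d$pair_id), simulate_keystrokes,
                              params = p))
  tt <- behavior_trial_table(ks, d)
  expect_equal(nrow(tt), nrow(d))
  expect_true(all(tt$valid))
  an <- behavior_anova(tt, "entry_asynchrony")
  expect_equal(an$effect, c("tempo", "familiarity", "interaction"))
  expect_equal(an$df2, rep(1, 3))       # 2 pairs
  expect_true(all(an$F >= 0))
  # incongruent trials enter the pause with opposite drift: entry
  # asynchrony larger than congruent
  agg <- aggregate(entry_asynchrony ~ tempo_condition, tt, mean)
  expect_gt(agg$entry_asynchrony[agg$tempo_condition == "incongruent"],
            agg$entry_asynchrony[agg$tempo_condition == "congruent"])
})
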