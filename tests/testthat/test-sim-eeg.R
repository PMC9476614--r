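test_that("the EEG generator is deterministic and shaped correctly", {
  d <- make_design(2, 1, seed = 2)
  sp <- sim_params(sfreq = 125, rng_seed = 17)
  ep1 <- simulate_dual_eeg(d[d$pair_id == 1, ], sp)
  ep2 <- simulate_dual_eeg(d[d$pair_id == 1, ], sp)
  expect_identical(ep1$p1, ep2$p1)
  expect_identical(ep1$p2, ep2$p2)
  expect_equal(dim(ep1$p1), c(4, 29, 17 * 125 + 1))
  expect_equal(ep1$ch_names, channel_names())
  expect_equal(epoch_times(ep1)[1], -1)
  # unknown topography rejected
  bad <- sp
  bad$kappa_map$roi[1] <- "NOPE"
  expect_error(simulate_dual_eeg(d[d$pair_id == 1, ], bad),
               "unknown topography")
})

test_that("simulated gamma envelopes peak at the beat rate during
           phrase 1", {
  d <- design_with("up", "up")
  d <- do.call(rbind, replicate(6, d, simplify = FALSE))
  d$trial_index <- 1:6
  sp <- sim_params(sfreq = 125, modulation_depth = 0.8, rng_seed = 23)
  ep <- simulate_dual_eeg(d, sp)
  env <- band_envelope(ep, "gamma")
  sf <- ep$sfreq
  filt <- signal::butter(4, c(1, 3) / (sf / 2), "pass")
  tt <- epoch_times(ep)
  sel <- tt >= 3 & tt < 7                       # first phrase
  # average the beat-filtered envelope over trials and channels, then
  # locate its spectral peak
  avg <- 0
  for (tr in 1:6) for (ch in c(14, 16, 20)) {
    avg <- avg + signal::filtfilt(filt, env$p1[tr, ch, ])
  }
  seg <- avg[sel]
  spec <- Mod(fft(seg - mean(seg)))[2:floor(length(seg) / 2)]
  freqs <- (seq_along(spec)) * sf / length(seg)
  expect_equal(freqs[which.max(spec)], 2, tolerance = 0.3)
})

test_that("ground truth round-trips the injected parameters", {
  d <- make_design(2, 1, seed = 5)
  sp <- sim_params(sfreq = 125, anticipation_bias = 1.5,
                   adaptation_gain = 0.3, rng_seed = 3)
  gt <- ground_truth(d, sp)
  expect_equal(gt$timing$anticipation_bias, 1.5)
  expect_equal(gt$timing$adaptation_gain, 0.3)
  expect_equal(gt$modulation_depth, sp$modulation_depth)
  # kappa entries round-trip through the lookup
  k <- gt$kappa
  row <- k[k$band == "gamma" & k$roi == "RP" & k$segment == "pause", ]
  expect_equal(unique(row$kappa[row$tempo_condition == "congruent"]), 8)
  expect_equal(unique(row$kappa[row$tempo_condition == "incongruent"]), 1)
  # per-trial drawn offsets are retrievable from the simulated epochs
  ep <- simulate_dual_eeg(d[d$pair_id == 1, ], sp)
  off <- attr(ep, "ground_truth")$offsets
  expect_equal(nrow(off), 4 * nrow(unique(sp$kappa_map[, c("band", "roi")])))
  expect_true(all(off$offset > -pi & off$offset <= pi))
})

test_that("stronger pause coupling for congruent tempi raises RP gamma
           pause PLV", {
  d <- make_design(2, 4, seed = 9)
  sp <- sim_params(sfreq = 125, rng_seed = 29)
  g <- window_grid(2, 0.25, 6, 12)
  diffs <- sapply(1:2, function(p) {
    ep <- simulate_dual_eeg(d[d$pair_id == p, ], sp)
    ses <- session_plv(epochs_phase_session(list(ep), "gamma"), g, "RP")[[1]]
    pausew <- attr(ses$plv, "centers") >= 8 & attr(ses$plv, "centers") <= 10
    mean(ses$plv[ses$tempo == "congruent", pausew]) -
      mean(ses$plv[ses$tempo == "incongruent", pausew])
  })
  expect_gt(mean(diffs), 0)
})

test_that("uniform coupling produces no systematic condition contrast", {
  flat <- default_kappa_map(base = 4, hi = 4, lo = 4)
  d <- make_design(2, 4, seed = 13)
  sp <- sim_params(sfreq = 125, kappa_map = flat, rng_seed = 31)
  g <- window_grid(2, 0.5, 6, 12)
  eps <- lapply(split(d, d$pair_id), simulate_dual_eeg, params = sp)
  ses <- session_plv(epochs_phase_session(eps, "gamma"), g, "RP")
  out <- pointwise_rmanova(condition_series(ses))
  # with 2 pairs and no effect, F should not be uniformly extreme
  expect_true(all(is.finite(out$F)))
  expect_gt(min(out$p), 1e-4)
})

test_that("von Mises sampler hits its concentration targets", {
  set.seed(77)
  expect_equal(rvonmises(5, 0.3, Inf), rep(0.3, 5))
  u <- rvonmises(4000, 0, 0)
  expect_gt(ks.test(u, "punif", -pi, pi)$p.value, 0.01)
  x <- rvonmises(4000, 0, 8)
  # circular mean near mu, resultant length near besselI ratio
  expect_lt(abs(Arg(mean(exp(1i * x)))), 0.1)
  expect_equal(Mod(mean(exp(1i * x))),
               besselI(8, 1) / besselI(8, 0), tolerance = 0.02)
  expect_error(rvonmises(2, 0, -1))
})
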