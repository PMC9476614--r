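test_that("derangements never map a trial to itself", {
  set.seed(14)
  for (n in c(2, 3, 7, 20)) {
    for (r in 1:20) {
      s <- duetIBS:::.derangement(n)
      expect_true(all(s != seq_len(n)))
      expect_equal(sort(s), seq_len(n))
    }
  }
  expect_error(duetIBS:::.derangement(1))
})

test_that("baseline PLV equals real PLV when all trials are identical", {
  sf <- 50
  S <- 8 * sf
  tt <- (0:(S - 1)) / sf
  th1 <- wrap_angle(2 * pi * 2 * tt)
  th2 <- wrap_angle(2 * pi * 2 * tt + 0.4)
  pp <- list(phase1 = array(rep(th1, each = 4), c(4, 1, S)),
             phase2 = array(rep(th2, each = 4), c(4, 1, S)),
             sfreq = sf, tmin = 0)
  g <- window_grid(2, 0.5, 1, 6)
  bl <- baseline_plv(pp, g, n_rep = 5, seed = 1)
  real <- apply(sliding_plv(pp$phase1, pp$phase2, g, sf, 0), c(2, 3), mean)
  expect_equal(unclass(bl), unclass(real), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(baseline_plv(list(phase1 = pp$phase1[1, , , drop = FALSE],
                                 phase2 = pp$phase2[1, , , drop = FALSE],
                                 sfreq = sf, tmin = 0), g),
               "at least 2")
  # seed-fixed runs are reproducible
  ph <- tiny_phase_session(2, 2, kappa = 8, seed = 3)
  b1 <- baseline_plv(ph[[1]], g, n_rep = 3, seed = 9)
  b2 <- baseline_plv(ph[[1]], g, n_rep = 3, seed = 9)
  expect_identical(b1, b2)
})

test_that("trial-specific coupling makes baseline PLV lower than real
           PLV", {
  g <- window_grid(2, 0.5, 1, 6.9)
  ph <- tiny_phase_session(2, 6, kappa = 16, seed = 21)
  real <- mean(sapply(session_plv(ph, g), function(p) mean(p$plv)))
  bl <- mean(sapply(ph, function(p)
    mean(baseline_plv(p, g, n_rep = 10, seed = 5))))
  expect_gt(real, bl + 0.05)
})

test_that("baseline comparison returns one uncorrected t per window", {
  cond <- matrix(c(0.5, 0.6, 0.7, 0.5, 0.62, 0.71), 3, 2)
  out0 <- compare_to_baseline(cond, cond)
  expect_equal(nrow(out0), 2)
  expect_equal(out0$t, c(0, 0))       # condition = baseline: no circles
  out <- compare_to_baseline(cond * 1.2 + 0.05, cond, centers = c(2, 2.1))
  expect_true(all(out$p < 0.05))
  expect_equal(out$center, c(2, 2.1))
})

test_that("surrogate trial equalization follows the delete/duplicate rule", {
  sf <- 50; S <- 4 * sf
  mk_pair <- function(pair_id, n_by_cell) {
    cells <- c("congruent.familiar", "congruent.unfamiliar",
               "incongruent.familiar", "incongruent.unfamiliar")
    tempo <- fam <- character(0)
    for (i in seq_along(cells)) {
      parts <- strsplit(cells[i], ".", fixed = TRUE)[[1]]
      tempo <- c(tempo, rep(parts[1], n_by_cell[i]))
      fam <- c(fam, rep(parts[2], n_by_cell[i]))
    }
    n <- length(tempo)
    # encode (pair, trial) in the phase values to trace the alignment
    ph <- array(rep(pair_id * 1000 + seq_len(n), times = S),
                c(n, 1, S))
    list(phase1 = ph, phase2 = ph, tempo = tempo, familiarity = fam,
         sfreq = sf, tmin = 0, pair_id = pair_id, ch_names = "ROI")
  }
  # player 1 of pair 1 has 36 trials in cell 1; partner (pair 2) has 33
  phases <- list(mk_pair(1, c(36, 2, 2, 2)), mk_pair(2, c(33, 2, 2, 2)))
  surr <- make_surrogate_dataset(phases, shift = 1)
  s1 <- surr[[1]]
  sel <- s1$tempo == "congruent" & s1$familiarity == "familiar"
  expect_equal(sum(sel), 36)          # counts equal player 1's
  ids <- s1$phase2[sel, 1, 1] - 2000  # traced pair-2 trial numbers
  expect_equal(ids, c(1:33, 1, 2, 3)) # first trials duplicated in order
  # player 2 with spare trials: 40 vs 36 -> trials 37..40 deleted
  phases2 <- list(mk_pair(1, c(36, 2, 2, 2)), mk_pair(2, c(40, 2, 2, 2)))
  ids2 <- make_surrogate_dataset(phases2, shift = 1)[[1]]
  sel2 <- ids2$tempo == "congruent" & ids2$familiarity == "familiar"
  expect_equal(ids2$phase2[sel2, 1, 1] - 2000, 1:36)
  # equal counts -> identity alignment
  phases3 <- list(mk_pair(1, c(3, 2, 2, 2)), mk_pair(2, c(3, 2, 2, 2)))
  s3 <- make_surrogate_dataset(phases3, shift = 1)[[1]]
  expect_equal(s3$phase2[1:3, 1, 1] - 2000, 1:3)
  # no surrogate pair reunites real partners
  expect_error(make_surrogate_dataset(phases, shift = 2), "itself")
  expect_error(make_surrogate_dataset(phases[1]), "at least 2")
  surr_r <- make_surrogate_dataset(c(phases, phases2, phases3), seed = 4)
  expect_equal(length(surr_r), 6)
})

test_that("surrogate pairs lose the dyad-specific condition effect that
           real pairs show", {
  ov <- data.frame(segment = "pause", factor = "tempo_condition",
                   level = c("congruent", "incongruent"),
                   kappa = c(24, 1))
  ph <- simulate_phase_session(6, 6, roi_kappa_map(4, ov), sfreq = 50,
                               tmin = 0.75, tmax = 11.25, seed = 33)
  g <- window_grid(2, 0.25, 6, 11)
  diff_of <- function(session) {
    mean(sapply(session, function(p)
      mean(p$plv[p$tempo == "congruent", ]) -
        mean(p$plv[p$tempo == "incongruent", ])))
  }
  real <- session_plv(ph, g)
  surr <- session_plv(make_surrogate_dataset(ph, shift = 1), g)
  expect_gt(diff_of(real), 0.05)
  expect_lt(abs(diff_of(surr)), 0.02)
})

test_that("power confound check separates amplitude from coupling
           differences", {
  sf <- 125
  d <- make_design(2, 2, seed = 6)
  sp <- sim_params(sfreq = sf, rng_seed = 13)
  eps <- lapply(split(d, d$pair_id), simulate_dual_eeg, params = sp)
  # amplitude-matched conditions: no power effect expected
  out <- power_confound_check(eps, "gamma", c(6.7, 9.3), "RP")
  expect_equal(out$effect, c("tempo_condition", "familiarity"))
  expect_true(all(out$p > 0.01))
  # amplitude-scaled condition: power t becomes significant
  eps2 <- lapply(eps, function(ep) {
    up <- ep$conditions$tempo_condition == "congruent"
    ep$p1[up, , ] <- ep$p1[up, , ] * 2
    ep$p2[up, , ] <- ep$p2[up, , ] * 2
    ep
  })
  out2 <- power_confound_check(eps2, "gamma", c(6.7, 9.3), "RP")
  expect_gt(out2$mean_a[1] / out2$mean_b[1], 2)
  # identical data in both conditions: t = 0 flagged path
  ep0 <- eps[[1]]
  ep0$p1[] <- 1; ep0$p2[] <- 1
  one <- power_confound_check(list(ep0, ep0), "gamma", c(6.7, 9.3), "RP")
  expect_equal(one$t, c(0, 0))
})
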