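test_that("the default window grid reproduces the study arithmetic", {
  g <- window_grid()
  expect_equal(length(g$centers), 113)
  expect_equal(g$centers[1], 2)
  expect_equal(g$centers[113], 13.2)
  expect_equal(max(g$onsets) + g$width, 14.2)   # last window end
  expect_equal(g$onsets[1], 1)                  # starts at metronome onset
  # a run of significant centers [7.7, 8.3] covers data [6.7, 9.3]
  run <- g$centers[g$centers >= 7.7 - 1e-9 & g$centers <= 8.3 + 1e-9]
  expect_equal(c(min(run) - g$width / 2, max(run) + g$width / 2),
               c(6.7, 9.3))
  expect_equal(length(channel_names()), 29)     # homologous pair count
  expect_equal(roi_channels("RP"), c("C4", "CP2", "CP6", "P4", "P8"))
  expect_equal(roi_channels("LP"), c("C3", "CP1", "CP5", "P3", "P7"))
  expect_error(roi_channels("XX"))
})

test_that("PLV identities: identical phases, constant offsets, balanced
           phasors", {
  sf <- 100
  S <- 17 * sf + 1
  g <- window_grid()
  set.seed(3)
  ph <- array(runif(2 * 3 * S, -pi, pi), c(2, 3, S))
  expect_true(all(abs(sliding_plv(ph, ph, g, sf) - 1) < 1e-12))
  expect_true(all(abs(sliding_plv(ph, ph + 1.3, g, sf) - 1) < 1e-9))
  # equally spaced phase differences over 2pi sum to zero
  T_w <- 2 * sf
  g1 <- window_grid(2, 2, 0, 2)
  ramp <- 2 * pi * (0:(S - 1)) / T_w
  p1 <- array(wrap_angle(ramp), c(1, 1, S))
  p0 <- array(0, c(1, 1, S))
  expect_lt(sliding_plv(p1, p0, g1, sf, tmin = 0)[1, 1, 1], 1e-12)
  # grid exceeding the epoch errors
  expect_error(sliding_plv(ph, ph, window_grid(2, 1, 1, 30), sf),
               "exceeds")
})

test_that("windowed PLV equals the brute-force circular resultant", {
  sf <- 100
  S <- 17 * sf + 1
  g <- window_grid(2, 0.5, 1, 14.2)
  set.seed(8)
  p1 <- array(runif(2 * 2 * S, -pi, pi), c(2, 2, S))
  p2 <- array(runif(2 * 2 * S, -pi, pi), c(2, 2, S))
  plv <- sliding_plv(p1, p2, g, sf)
  T_w <- round(g$width * sf)
  i0 <- round((g$onsets + 1) * sf) + 1
  for (tr in 1:2) for (ch in 1:2) for (w in seq_along(i0)) {
    idx <- i0[w] + 0:(T_w - 1)
    bf <- Mod(mean(exp(1i * (p1[tr, ch, idx] - p2[tr, ch, idx]))))
    expect_lt(abs(plv[tr, ch, w] - bf), 1e-12)
  }
  expect_true(all(plv >= 0 & plv <= 1))
  # symmetric under player swap
  expect_equal(sliding_plv(p2, p1, g, sf), plv)
})

test_that("mean PLV of uniform phase differences approaches the Rayleigh
           expectation", {
  sf <- 500
  T_w <- 2 * sf                       # T = 1000 samples per window
  set.seed(5)
  n_win <- 2000
  plv <- replicate(20, {
    z <- matrix(runif(T_w * n_win / 20, -pi, pi), T_w)
    Mod(colMeans(exp(1i * z)))
  })
  expect_equal(mean(plv), sqrt(pi / (4 * T_w)), tolerance = 0.03)
})

test_that("ROI averaging matches hand computation and ordering", {
  ch <- channel_names()
  plv <- array(0, c(2, 29, 3))
  vals <- seq(0.1, by = 0.01, length.out = 29)
  for (w in 1:3) plv[1, , w] <- vals
  plv[2, , ] <- 0.5
  rp <- roi_average(plv, "RP", ch)
  hand <- mean(vals[match(c("C4", "CP2", "CP6", "P4", "P8"), ch)])
  expect_equal(rp[1, 1], hand)
  expect_equal(rp[2, 2], 0.5)
  expect_equal(dim(roi_average(plv, "GLOBAL", ch)), c(2, 3))
  expect_equal(roi_average(plv, "GLOBAL", ch)[1, 1], mean(vals))
  # all-identical channels: ROI mean equals that value
  expect_equal(roi_average(array(0.3, c(1, 29, 2)), "LP", ch)[1, ],
               c(0.3, 0.3))
  expect_error(roi_average(plv, "RP", rep("XX", 29)), "no channels")
})

test_that("condition means and series are assembled in canonical order", {
  plv <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 8, 2)
  tempo <- rep(c("congruent", "incongruent"), each = 4)
  fam <- rep(c("familiar", "familiar", "unfamiliar", "unfamiliar"), 2)
  cm <- cell_means(plv, tempo, fam)
  expect_equal(rownames(cm), c("congruent.familiar", "congruent.unfamiliar",
                               "incongruent.familiar",
                               "incongruent.unfamiliar"))
  expect_equal(unname(cm[, 1]), c(1.5, 3.5, 5.5, 7.5))
  expect_error(cell_means(plv[1:4, ], tempo[1:4], fam[1:4]), "empty")
})

test_that("mean PLV is non-decreasing in the coupling concentration", {
  kappas <- c(0, 2, 8, Inf)
  g <- window_grid(2, 0.5, 1, 6.9)
  means <- sapply(seq_len(30), function(r) {
    sapply(seq_along(kappas), function(ki) {
      ph <- tiny_phase_session(2, 1, kappa = kappas[ki],
                               seed = 1000 * r + ki)
      mean(sapply(session_plv(ph, g), function(p) mean(p$plv)))
    })
  })
  m <- rowMeans(means)
  expect_true(all(diff(m) > 0))
  expect_gt(m[4], 0.999)              # kappa -> Inf: perfect coupling
})
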