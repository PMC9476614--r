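test_that("preprocessing removes line noise and DC and epochs correctly", {
  sf <- 500
  n <- sf * 40
  set.seed(1)
  tt <- (0:(n - 1)) / sf
  line <- sin(2 * pi * 50 * tt)
  ch <- c("CZ", "PZ")
  raw <- list(p1 = rbind(line, line + 2), p2 = rbind(line * 0.5, line),
              sfreq = sf, ch_names = ch, events = c(3 * sf, 20 * sf))
  rownames(raw$p1) <- rownames(raw$p2) <- NULL
  ep <- preprocess_raw(raw, conditions = NULL)
  expect_s3_class(ep, "dyad_epochs")
  expect_equal(dim(ep$p1), c(2, 2, 17 * sf + 1))
  # 50 Hz residual < 1% of the input amplitude (interior samples)
  mid <- 2000:6000
  expect_lt(max(abs(ep$p1[1, 1, mid])), 0.01)
  # DC offset removed by the 0.5 Hz high-pass edge
  expect_lt(abs(mean(ep$p1[1, 2, mid])), 0.02)
  # epoch arithmetic: sample 1 of the epoch is event - sfreq
  imp <- matrix(0, 1, n); imp[1, 3 * sf - sf] <- 1   # impulse at t = -1
  raw2 <- list(p1 = imp, p2 = imp, sfreq = sf, ch_names = "CZ",
               events = 3 * sf)
  ep2 <- preprocess_raw(raw2)
  expect_equal(which.max(abs(ep2$p1[1, 1, ])), 1)
  # error paths
  expect_error(preprocess_raw(list(p1 = imp, p2 = imp, sfreq = 250,
                                   ch_names = "CZ", events = 1000)),
               "sampling-rate mismatch")
  expect_error(preprocess_raw(list(p1 = imp, p2 = imp, sfreq = 500,
                                   ch_names = "CZ", events = numeric(0))),
               "events")
})

test_that("linked-mastoid re-referencing subtracts the mastoid average", {
  sf <- 500
  n <- sf * 25
  sig <- matrix(rnorm(4 * n, sd = 0.1), 4, n)
  sig[3, ] <- sig[3, ] + 1   # M1 offset
  sig[4, ] <- sig[4, ] - 1   # M2 offset
  raw <- list(p1 = sig, p2 = sig, sfreq = sf,
              ch_names = c("CZ", "PZ", "M1", "M2"), events = 5 * sf)
  ep <- preprocess_raw(raw)
  expect_equal(ep$ch_names, c("CZ", "PZ"))
  expect_equal(dim(ep$p1)[2], 2)
})

test_that("band envelopes demodulate tones correctly", {
  sf <- 500
  tt <- seq(-1, 16, by = 1 / sf)
  interior <- tt > 1 & tt < 14
  tone35 <- 0.8 * sin(2 * pi * 35 * tt)
  env <- band_envelope(tone35, "gamma", sf)
  expect_true(all(env >= 0))
  expect_equal(mean(env[interior]), 0.8, tolerance = 0.01)
  # out-of-band rejection
  env10 <- band_envelope(sin(2 * pi * 10 * tt), "gamma", sf)
  expect_lt(mean(env10[interior]), 0.01)
  # AM tone: envelope recovers the 2 Hz modulation within 5%
  am <- (1 + 0.5 * cos(2 * pi * 2 * tt)) * cos(2 * pi * 35 * tt)
  env_am <- band_envelope(am, "gamma", sf)
  mod <- Mod(analytic_signal(
    signal::filtfilt(signal::butter(4, c(1, 3) / (sf / 2), "pass"), env_am)))
  expect_equal(mean(mod[tt > 3 & tt < 10]), 0.5, tolerance = 0.05)
  expect_error(band_envelope(tone35, c(30, 300), sf), "Nyquist")
})

test_that("envelope phase is the analytic phase of the 1-3 Hz component", {
  sf <- 500
  tt <- seq(-1, 16, by = 1 / sf)
  env <- 1 + 0.5 * cos(2 * pi * 2 * tt)
  ph <- envelope_phase(env, sf)
  expect_true(all(ph > -pi & ph <= pi))
  # unwrapped phase advances 2 Hz * 2pi per second
  interior <- tt > 2 & tt < 12
  dph <- diff(ph[interior])
  dph <- dph[abs(dph) < pi]
  expect_equal(mean(dph) * sf / (2 * pi), 2, tolerance = 0.01)
  # identical envelopes -> zero pointwise phase difference
  expect_equal(ph - envelope_phase(env, sf), rep(0, length(ph)))
  # a known phase offset is recovered
  phi <- 0.9
  ph2 <- envelope_phase(1 + 0.5 * cos(2 * pi * 2 * tt - phi), sf)
  dd <- wrap_angle(ph[interior] - ph2[interior])
  expect_equal(mean(dd), phi, tolerance = 0.02)
})

test_that("band power follows the mean-squared-envelope convention", {
  sf <- 250
  tt <- seq(-1, 16, by = 1 / sf)
  S <- length(tt)
  tone <- function(A) A * sin(2 * pi * 35 * tt)
  arr <- function(x) {
    a <- array(0, c(1, 2, S)); a[1, 1, ] <- x; a[1, 2, ] <- x; a
  }
  cond <- data.frame(tempo_condition = "congruent",
                     familiarity = "familiar")
  ep1 <- dyad_epochs(arr(tone(1)), arr(tone(1)), sf, c("CZ", "C3"),
                     conditions = cond)
  ep2 <- dyad_epochs(arr(tone(2)), arr(tone(2)), sf, c("CZ", "C3"),
                     conditions = cond)
  p1 <- band_power(ep1, "gamma", c(3, 7), "GLOBAL")$power
  p2 <- band_power(ep2, "gamma", c(3, 7), "GLOBAL")$power
  expect_equal(p1, 1, tolerance = 0.02)        # envelope A -> power A^2
  expect_equal(p2 / p1, 4, tolerance = 0.01)   # doubling quadruples power
  ep0 <- dyad_epochs(arr(sin(2 * pi * 5 * tt)), arr(sin(2 * pi * 5 * tt)),
                     sf, c("CZ", "C3"), conditions = cond)
  expect_lt(band_power(ep0, "gamma", c(3, 7), "GLOBAL")$power, 1e-4)
})
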