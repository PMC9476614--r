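# Synthetic dual-EEG generator: beat-locked amplitude modulation of
# band-limited noise carriers with condition-dependent between-player
# envelope-phase coupling.
#
# Coupling model. Each latent source (one per band x ROI topography)
# carries an amplitude modulation 1 + d * cos(beat phase - phi_p(t)) per
# player p. The slow modulation-phase wander phi_p is built from a
# dyad-and-trial-specific shared process s(t) and an individual process
# w_p(t), mixed as
#     phi_p = sigma0 * (rho * s + sqrt(1 - rho^2) * w_p),
# with the partner correlation rho = sqrt(kappa / (1 + kappa)) set by the
# segment- and condition-dependent concentration kappa. The stationary
# between-player phase dispersion is then 2 * sigma0^2 / (1 + kappa):
# kappa -> Inf gives identical modulation phases (PLV -> 1), kappa = 0
# independent wander. Player 2 additionally gets a constant per-trial
# von Mises offset (condition-independent), retrievable via the ground
# truth. Because the coupled component s is specific to the dyad and
# trial, surrogate re-pairings destroy the condition contrast — the
# dissociation the control analyses are designed to detect.

.kappa_to_rho <- function(kappa) {
  r <- sqrt(kappa / (1 + kappa))
  r[!is.finite(kappa)] <- 1
  r
}

.segment_of <- function(times, phrase2_end = 16) {
  seg <- character(length(times))
  seg[times < 3] <- "metronome"
  seg[times >= 3 & times < 7] <- "phrase1"
  seg[times >= 7 & times < 11] <- "pause"
  seg[times >= 11] <- "phrase2"
  seg
}

# beat phase 2*pi * integral of f_beat, zero at the metronome onset (1 s);
# f = 2 Hz up to the phrase-2 onset, then the instructed tempo
.beat_phase <- function(times, sfreq, phrase2_bpm) {
  f <- ifelse(times < 11, 2, phrase2_bpm / 60)
  ph <- 2 * pi * cumsum(f) / sfreq
  ph - ph[which.min(abs(times - 1))]
}

#' Simulate epoched dual EEG for one pair
#'
#' Generates the two players' trials x channels x samples arrays on the
#' -1..16 s cue-locked axis. Channels are topography-weighted mixtures of
#' latent beat-modulated sources (one per band x ROI entry of the kappa
#' map) plus 1/f background noise; between-player coupling of the
#' envelope modulation phase is injected per band, segment and condition
#' according to `params$kappa_map`. Deterministic given
#' `params$rng_seed`.
#'
#' @param design Design rows of a single pair (from [make_design()]).
#' @param params [sim_params()] object; `params$kappa_map` must provide a
#'   concentration for every band used downstream.
#' @return `dyad_epochs` with condition labels and a `ground_truth`
#'   attribute (per-trial kappas and drawn phase offsets).
#' @export
simulate_dual_eeg <- function(design, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (length(unique(design$pair_id)) != 1)
    stop("`design` must contain trials of a single pair")
  bad <- setdiff(unique(params$kappa_map$roi), c("GLOBAL", "RP", "LP"))
  if (length(bad))
    stop("unknown topography in kappa map: ", paste(bad, collapse = ", "))
  set.seed(stage_seed(params$rng_seed, paste0("eeg", design$pair_id[1])))
  sf <- params$sfreq
  times <- seq(-1, 16, by = 1 / sf)
  S <- length(times)
  ch <- channel_names()
  n_ch <- length(ch)
  n_tr <- nrow(design)
  sources <- unique(params$kappa_map[, c("band", "roi")])
  bands <- eeg_bands()
  seg <- .segment_of(times)
  d <- params$modulation_depth

  x1 <- array(0, c(n_tr, n_ch, S))
  x2 <- array(0, c(n_tr, n_ch, S))
  gt_kappa <- list(); gt_off <- list()

  for (i in seq_len(n_tr)) {
    tr <- design[i, ]
    bp1 <- .beat_phase(times, sf, tr$phrase2_bpm_p1)
    bp2 <- .beat_phase(times, sf, tr$phrase2_bpm_p2)
    mod_on1 <- times >= 1 & times < 11 + 8 * 60 / tr$phrase2_bpm_p1
    mod_on2 <- times >= 1 & times < 11 + 8 * 60 / tr$phrase2_bpm_p2
    ch1 <- matrix(0, n_ch, S); ch2 <- matrix(0, n_ch, S)
    for (sidx in seq_len(nrow(sources))) {
      band <- sources$band[sidx]; roi <- sources$roi[sidx]
      kk <- vapply(c("metronome", "phrase1", "pause", "phrase2"),
                   function(sg) kappa_for_trial(params$kappa_map, band,
                                                roi, sg, tr),
                   numeric(1))
      rho <- .kappa_to_rho(kk)[seg]
      gp <- smooth_gp(S, 3, sf, params$wander_fc)
      phi1 <- params$sigma0 * (rho * gp[, 1] +
                                 sqrt(pmax(1 - rho^2, 0)) * gp[, 2])
      delta <- rvonmises(1, 0, params$offset_kappa)
      phi2 <- params$sigma0 * (rho * gp[, 1] +
                                 sqrt(pmax(1 - rho^2, 0)) * gp[, 3]) + delta
      carr <- band_noise(S, 2, sf, bands[[band]])
      m1 <- ifelse(mod_on1, 1 + d * cos(bp1 - phi1), 1)
      m2 <- ifelse(mod_on2, 1 + d * cos(bp2 - phi2), 1)
      w <- as.numeric(ch %in% roi_channels(roi))
      ch1 <- ch1 + w %o% (carr[, 1] * m1)
      ch2 <- ch2 + w %o% (carr[, 2] * m2)
      gt_kappa[[length(gt_kappa) + 1L]] <-
        data.frame(pair_id = tr$pair_id, trial_index = tr$trial_index,
                   band = band, roi = roi,
                   segment = names(kk), kappa = unname(kk),
                   stringsAsFactors = FALSE)
      gt_off[[length(gt_off) + 1L]] <-
        data.frame(pair_id = tr$pair_id, trial_index = tr$trial_index,
                   band = band, roi = roi, offset = delta,
                   stringsAsFactors = FALSE)
    }
    x1[i, , ] <- ch1 + t(pink_noise(S, n_ch, sf, params$noise_exponent))
    x2[i, , ] <- ch2 + t(pink_noise(S, n_ch, sf, params$noise_exponent))
  }
  cond <- design
  names(cond)[names(cond) == "pair_id"] <- "pair"
  ep <- dyad_epochs(x1, x2, sfreq = sf, ch_names = ch, tmin = -1,
                    conditions = design, pair_id = design$pair_id[1])
  attr(ep, "ground_truth") <- list(
    kappa = do.call(rbind, gt_kappa),
    offsets = do.call(rbind, gt_off),
    modulation_depth = d, sigma0 = params$sigma0,
    anticipation_bias = params$anticipation_bias,
    adaptation_gain = params$adaptation_gain)
  ep
}

#' Ground-truth table of the injected effects
#'
#' Pure bookkeeping: resolves, for every trial of the design and every
#' latent source of the kappa map, the coupling concentration the
#' simulators use, alongside the timing-model parameters. Per-trial drawn
#' phase offsets live in `attr(simulate_dual_eeg(...), "ground_truth")`.
#'
#' @param design Design table (any number of pairs).
#' @param params [sim_params()] object.
#' @return List with `kappa` (per trial x band x roi x segment) and
#'   `timing` (the keystroke-model parameters).
#' @export
ground_truth <- function(design, params = sim_params()) {
  sources <- unique(params$kappa_map[, c("band", "roi")])
  segs <- c("metronome", "phrase1", "pause", "phrase2")
  rows <- list()
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    for (sidx in seq_len(nrow(sources))) {
      kk <- vapply(segs, function(sg)
        kappa_for_trial(params$kappa_map, sources$band[sidx],
                        sources$roi[sidx], sg, tr), numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(pair_id = tr$pair_id, trial_index = tr$trial_index,
                   tempo_condition = tr$tempo_condition,
                   familiarity = tr$familiarity,
                   band = sources$band[sidx], roi = sources$roi[sidx],
                   segment = segs, kappa = unname(kk),
                   stringsAsFactors = FALSE)
    }
  }
  list(kappa = do.call(rbind, rows),
       timing = data.frame(anticipation_bias = params$anticipation_bias,
                           adaptation_gain = params$adaptation_gain,
                           motor_noise_sigma = params$motor_noise_sigma),
       modulation_depth = params$modulation_depth)
}
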