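# Lightweight ROI-level session generator. Instead of synthesizing full
# 29-channel EEG and running the envelope pipeline, it draws the
# envelope-phase series of one ROI-level source directly (the quantity
# whose between-player coupling the PLV measures), using the same
# coupling model as simulate_dual_eeg(). This makes large calibration
# studies of the cluster-permutation statistics (hundreds of sessions)
# tractable while exercising the identical PLV, rmANOVA, clustering,
# permutation and surrogate machinery.

#' ROI-level coupling concentration map
#'
#' Simplified kappa map for [simulate_phase_session()]: one source
#' ("ROI"), concentrations per trial segment, optionally split by a
#' condition factor.
#'
#' @param base Condition-independent concentration for all segments.
#' @param overrides Optional data.frame with `segment`, `factor`,
#'   `level`, `kappa` rows replacing the base entry of that segment.
#' @return kappa map data.frame usable by [kappa_for_trial()].
#' @examples
#' # congruent tempo plans more strongly coupled during the pause:
#' roi_kappa_map(4, data.frame(segment = "pause",
#'                             factor = "tempo_condition",
#'                             level = c("congruent", "incongruent"),
#'                             kappa = c(16, 1)))
#' @export
roi_kappa_map <- function(base = 4, overrides = NULL) {
  segs <- c("metronome", "phrase1", "pause", "phrase2")
  m <- data.frame(band = "env", roi = "ROI", segment = segs,
                  factor = NA_character_, level = NA_character_,
                  kappa = base, stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    for (sg in unique(overrides$segment)) {
      m <- m[m$segment != sg, , drop = FALSE]
      o <- overrides[overrides$segment == sg, , drop = FALSE]
      m <- rbind(m, data.frame(band = "env", roi = "ROI", segment = sg,
                               factor = o$factor, level = o$level,
                               kappa = o$kappa, stringsAsFactors = FALSE))
    }
  }
  rownames(m) <- NULL
  m
}

#' Simulate a session of ROI-level envelope-phase data
#'
#' Draws, for every trial of every pair, the two players' envelope phase
#' series theta_p(t) = beat phase + slow wander, with between-player
#' wander coupling set by the segment/condition kappa map (see
#' [simulate_dual_eeg()] for the coupling model). Condition labels come
#' from [make_design()]. The common beat is modelled at the shared task
#' tempo (2 Hz); the condition manipulation enters only through the
#' dyad-specific coupling, so surrogate re-pairings are condition-null by
#' construction.
#'
#' @param n_pairs,trials_per_cell Design size (e.g. 14 pairs, 36 kept
#'   trials per cell as in the cleaned study data).
#' @param kappa_map ROI-level map from [roi_kappa_map()].
#' @param sfreq Sampling frequency of the phase series (Hz); the PLV is
#'   scale-free in time, so a reduced rate only coarsens the within-window
#'   average.
#' @param tmin,tmax Time span to generate (s, cue-locked).
#' @param sigma0 Stationary wander SD (radians).
#' @param wander_fc Wander low-pass corner (Hz).
#' @param offset_kappa Concentration of the constant per-trial offset.
#' @param seed Integer seed (full determinism).
#' @return Phase session (list per pair with `phase1`, `phase2`,
#'   `tempo`, `familiarity`, `sfreq`, `tmin`, `pair_id`, `ch_names`),
#'   with the design in `attr(, "design")`.
#' @export
simulate_phase_session <- function(n_pairs = 14, trials_per_cell = 36,
                                   kappa_map = roi_kappa_map(),
                                   sfreq = 100, tmin = 0.75, tmax = 7.25,
                                   sigma0 = 1.5, wander_fc = 0.4,
                                   offset_kappa = 4, seed = 1) {
  design <- make_design(n_pairs, trials_per_cell,
                        seed = stage_seed(seed, "design"))
  times <- seq(tmin, tmax, by = 1 / sfreq)
  S <- length(times)
  seg <- .segment_of(times)
  segs <- c("metronome", "phrase1", "pause", "phrase2")
  seg_idx <- match(seg, segs)
  beat <- 2 * pi * 2 * (times - 1)
  set.seed(stage_seed(seed, "phase_session"))
  out <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    dp <- design[design$pair_id == p, , drop = FALSE]
    n_tr <- nrow(dp)
    # per-trial, per-segment kappa -> samples x trials rho matrix
    kk <- vapply(segs, function(sg) {
      k <- kappa_map[kappa_map$segment == sg, , drop = FALSE]
      if (all(is.na(k$factor))) rep(k$kappa[1], n_tr)
      else k$kappa[match(dp[[k$factor[1]]], k$level)]
    }, numeric(n_tr))
    kk <- matrix(kk, n_tr, length(segs))
    rho <- .kappa_to_rho(t(kk)[seg_idx, , drop = FALSE])  # S x trials
    gp <- smooth_gp(S, 3 * n_tr, sfreq, wander_fc)
    gp_s <- gp[, seq_len(n_tr), drop = FALSE]
    gp_1 <- gp[, n_tr + seq_len(n_tr), drop = FALSE]
    gp_2 <- gp[, 2 * n_tr + seq_len(n_tr), drop = FALSE]
    mix <- sqrt(pmax(1 - rho^2, 0))
    phi1 <- sigma0 * (rho * gp_s + mix * gp_1)
    delta <- rvonmises(n_tr, 0, offset_kappa)
    phi2 <- sweep(sigma0 * (rho * gp_s + mix * gp_2), 2, delta, "+")
    th1 <- beat + phi1                           # S x trials
    th2 <- beat + phi2
    a1 <- array(t(th1), c(n_tr, 1, S))
    a2 <- array(t(th2), c(n_tr, 1, S))
    out[[p]] <- list(phase1 = a1, phase2 = a2,
                     tempo = dp$tempo_condition,
                     familiarity = dp$familiarity,
                     sfreq = sfreq, tmin = tmin, pair_id = p,
                     ch_names = "ROI", offsets = delta)
  }
  structure(out, design = design, kappa_map = kappa_map)
}
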