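#' Build the 2 x 2 trial schedule for a set of dyads
#'
#' Generates the full factorial TEMPO (congruent / incongruent) x
#' FAMILIARITY (familiar / unfamiliar) trial schedule. Each pair performs
#' `trials_per_cell` trials in every cell (the full study used 48, i.e.
#' 192 trials per pair). Piece-to-familiarity assignment is counterbalanced:
#' the first half of the pairs learns pieces A and B bimanually (familiar)
#' and C and D unimanually (unfamiliar), the second half the opposite.
#' Tempo instructions within the congruent cells alternate between up-up
#' and down-down, within the incongruent cells between up-down and down-up,
#' so that instruction combinations are balanced. Trial order is randomized
#' independently per pair.
#'
#' @param n_pairs Number of dyads; must be even when `counterbalance = TRUE`.
#' @param trials_per_cell Trials in each of the four design cells per pair.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param counterbalance Counterbalance piece sets across pairs (default).
#' @return data.frame with one row per trial: `pair_id`, `trial_index`,
#'   `piece_id`, `familiarity`, `instruction_p1`, `instruction_p2`,
#'   `tempo_condition`, `phrase2_bpm_p1`, `phrase2_bpm_p2`.
#' @examples
#' d <- make_design(2, 1, seed = 1)
#' table(d$tempo_condition, d$familiarity)
#' @export
make_design <- function(n_pairs, trials_per_cell, seed = 1,
                        counterbalance = TRUE) {
  stopifnot(n_pairs >= 1, trials_per_cell >= 1)
  if (counterbalance && n_pairs %% 2 != 0)
    stop("`n_pairs` must be even: piece-to-familiarity assignment is ",
         "counterbalanced across pairs (half of the pairs learn pieces ",
         "A and B bimanually, half C and D). Use an even number of pairs ",
         "or set counterbalance = FALSE.")
  set.seed(as.integer(seed))
  bpm_of <- c(up = 150, down = 96)
  out <- vector("list", n_pairs)
  for (p in seq_len(n_pairs)) {
    bimanual <- if (!counterbalance || p <= n_pairs / 2) c("A", "B") else c("C", "D")
    unimanual <- setdiff(c("A", "B", "C", "D"), bimanual)
    rows <- list()
    for (fam in c("familiar", "unfamiliar")) {
      pieces <- rep_len(if (fam == "familiar") bimanual else unimanual,
                        trials_per_cell)
      for (tc in c("congruent", "incongruent")) {
        if (tc == "congruent") {
          i1 <- rep_len(c("up", "down"), trials_per_cell)
          i2 <- i1
        } else {
          i1 <- rep_len(c("up", "down"), trials_per_cell)
          i2 <- ifelse(i1 == "up", "down", "up")
        }
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = p, piece_id = pieces, familiarity = fam,
          instruction_p1 = i1, instruction_p2 = i2,
          tempo_condition = tc, stringsAsFactors = FALSE)
      }
    }
    d <- do.call(rbind, rows)
    d <- d[sample.int(nrow(d)), , drop = FALSE]
    d$trial_index <- seq_len(nrow(d))
    out[[p]] <- d
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d$phrase2_bpm_p1 <- unname(bpm_of[d$instruction_p1])
  d$phrase2_bpm_p2 <- unname(bpm_of[d$instruction_p2])
  d[, c("pair_id", "trial_index", "piece_id", "familiarity",
        "instruction_p1", "instruction_p2", "tempo_condition",
        "phrase2_bpm_p1", "phrase2_bpm_p2")]
}

#' Simulation parameters for the synthetic dyad generator
#'
#' Collects and validates all tunable parameters of the synthetic data
#' generator. Defaults emulate the duet paradigm: 14 pairs, 48 trials per
#' design cell, 500 Hz sampling, beat-locked envelope modulation of depth
#' 0.5, pink (1/f) background noise, 10 ms motor timing noise, a 0.5 ms/beat
#' anticipatory tempo bias, and first-order mutual phase correction with
#' gain 0.25.
#'
#' @param n_pairs,trials_per_cell Design size.
#' @param sfreq EEG sampling frequency (Hz); must exceed twice the highest
#'   band edge (40 Hz).
#' @param modulation_depth Depth `d` in `[0, 1]` of the beat-locked
#'   amplitude modulation `1 + d * cos(beat phase - wander)`.
#' @param kappa_map Coupling concentration table, see [default_kappa_map()].
#' @param noise_exponent Spectral slope of the 1/f background.
#' @param motor_noise_sigma Keystroke timing noise SD in ms.
#' @param anticipation_bias Anticipatory tempo drift toward the instructed
#'   second-phrase tempo, in ms per beat during phrase 1 and pause.
#' @param adaptation_gain First-order phase-correction gain in `[0, 1)`
#'   applied to the heard partner asynchrony during phrase 1.
#' @param sigma0 Stationary SD (radians) of each player's slow envelope
#'   phase wander; together with kappa it sets the between-player phase
#'   dispersion `2 * sigma0^2 / (1 + kappa)`.
#' @param wander_fc Low-pass corner (Hz) of the slow phase wander.
#' @param offset_kappa Concentration of the condition-independent constant
#'   per-trial von Mises offset between the players' modulation phases.
#' @param rng_seed Master seed for all randomness in the generator.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 14, trials_per_cell = 48, sfreq = 500,
                       modulation_depth = 0.5,
                       kappa_map = default_kappa_map(),
                       noise_exponent = 1, motor_noise_sigma = 10,
                       anticipation_bias = 0.5, adaptation_gain = 0.25,
                       sigma0 = 1.5, wander_fc = 0.4, offset_kappa = 4,
                       rng_seed = 1) {
  if (adaptation_gain < 0 || adaptation_gain >= 1)
    stop("`adaptation_gain` must lie in [0, 1): values >= 1 make the ",
         "mutual phase-correction loop unstable")
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("`modulation_depth` must lie in [0, 1]")
  if (any(kappa_map$kappa < 0, na.rm = TRUE))
    stop("all coupling concentrations must be >= 0")
  top <- max(vapply(eeg_bands(), max, numeric(1)))
  if (sfreq <= 2 * top)
    stop("`sfreq` must exceed twice the highest band edge (", 2 * top, " Hz)")
  structure(list(n_pairs = n_pairs, trials_per_cell = trials_per_cell,
                 sfreq = sfreq, modulation_depth = modulation_depth,
                 kappa_map = kappa_map, noise_exponent = noise_exponent,
                 motor_noise_sigma = motor_noise_sigma,
                 anticipation_bias = anticipation_bias,
                 adaptation_gain = adaptation_gain, sigma0 = sigma0,
                 wander_fc = wander_fc, offset_kappa = offset_kappa,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_params")
}

#' Default envelope-coupling concentration map
#'
#' One latent modulated source per ROI topography and band. Each row maps
#' (band, source topography, trial segment, condition factor level) to a
#' von Mises-style concentration `kappa` of the between-player envelope
#' phase coupling. The defaults inject the qualitative effect pattern of
#' the duet study: gamma coupling over all electrodes higher for unfamiliar
#' pieces during the first phrase, right-posterior gamma coupling higher
#' for congruent tempo plans during the pause, and delta/theta coupling
#' higher for incongruent tempi during the first phrase. All remaining
#' band/segment combinations share a condition-independent base
#' concentration (task-structure coupling common to all trials).
#'
#' @param base Condition-independent base concentration.
#' @param hi,lo Concentrations of the favored / unfavored condition level
#'   in the segments carrying injected effects.
#' @return data.frame with columns `band`, `roi`, `segment`, `factor`,
#'   `level`, `kappa`. `factor = NA` rows apply to both levels.
#' @export
default_kappa_map <- function(base = 2, hi = 8, lo = 1) {
  segs <- c("metronome", "phrase1", "pause", "phrase2")
  rows <- expand.grid(band = names(eeg_bands()), roi = "GLOBAL",
                      segment = segs, stringsAsFactors = FALSE)
  m <- data.frame(rows, factor = NA_character_, level = NA_character_,
                  kappa = base, stringsAsFactors = FALSE)
  override <- function(m, band, roi, segment, factor, levels, kappas) {
    drop <- m$band == band & m$roi == roi & m$segment == segment
    m <- m[!drop, , drop = FALSE]
    rbind(m, data.frame(band = band, roi = roi, segment = segment,
                        factor = factor, level = levels, kappa = kappas,
                        stringsAsFactors = FALSE))
  }
  m <- override(m, "gamma", "GLOBAL", "phrase1", "familiarity",
                c("familiar", "unfamiliar"), c(lo, hi))
  m <- override(m, "theta", "GLOBAL", "phrase1", "tempo_condition",
                c("congruent", "incongruent"), c(lo, hi))
  m <- override(m, "delta", "GLOBAL", "phrase1", "tempo_condition",
                c("congruent", "incongruent"), c(lo, hi))
  # right-posterior source only carries gamma; coupled during the pause
  m <- rbind(m, data.frame(band = "gamma", roi = "RP",
                           segment = segs[segs != "pause"],
                           factor = NA_character_, level = NA_character_,
                           kappa = base, stringsAsFactors = FALSE))
  m <- override(m, "gamma", "RP", "pause", "tempo_condition",
                c("congruent", "incongruent"), c(hi, lo))
  rownames(m) <- NULL
  m
}

#' Look up the coupling concentration for one trial
#'
#' @param kappa_map Table from [default_kappa_map()].
#' @param band,roi,segment Source coordinates.
#' @param trial One-row design data.frame (as from [make_design()]).
#' @return Scalar concentration; `NA` when the (band, roi, segment) source
#'   is absent from the map.
#' @export
kappa_for_trial <- function(kappa_map, band, roi, segment, trial) {
  k <- kappa_map[kappa_map$band == band & kappa_map$roi == roi &
                   kappa_map$segment == segment, , drop = FALSE]
  if (nrow(k) == 0) return(NA_real_)
  if (all(is.na(k$factor))) return(k$kappa[1])
  lev <- as.character(trial[[k$factor[1]]])
  kk <- k$kappa[match(lev, k$level)]
  if (is.na(kk)) stop("no kappa entry for level '", lev, "'")
  kk
}
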