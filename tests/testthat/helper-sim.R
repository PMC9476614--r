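# Shared fixtures, built in code at test time.

# noise-free, bias-free parameters: both players sit exactly on the
# 120 bpm grid
quiet_params <- function(...) {
  args <- utils::modifyList(list(motor_noise_sigma = 0,
                                 anticipation_bias = 0,
                                 adaptation_gain = 0), list(...))
  do.call(sim_params, args)
}

# one-pair design with a chosen instruction combination
design_with <- function(i1, i2, fam = "familiar", piece = "A") {
  data.frame(pair_id = 1L, trial_index = 1L, piece_id = piece,
             familiarity = fam, instruction_p1 = i1, instruction_p2 = i2,
             tempo_condition = if (i1 == i2) "congruent" else "incongruent",
             phrase2_bpm_p1 = if (i1 == "up") 150 else 96,
             phrase2_bpm_p2 = if (i2 == "up") 150 else 96,
             stringsAsFactors = FALSE)
}

split_players <- function(ks) {
  list(p1 = ks[ks$player == 1, ], p2 = ks[ks$player == 2, ])
}

# hand-built keystroke stream at given onsets
stream_at <- function(onsets_p1, onsets_p2 = onsets_p1, piece = "A",
                      trial = 1L) {
  mk <- function(on, player) {
    voice <- player_voice(player, piece)
    pit <- piece_pitches(piece)[[voice]]
    data.frame(pair = 1L, trial = trial, player = player, piece = piece,
               familiarity = "familiar", instruction_self = "up",
               instruction_other = "up",
               phrase = rep(1:2, each = 7), position = rep(1:7, 2),
               onset_s = on, pitch = pit, stringsAsFactors = FALSE)
  }
  list(p1 = mk(onsets_p1, 1), p2 = mk(onsets_p2, 2))
}

grid_onsets <- function(phrase2_period = 0.4) {
  c(3 + 0.5 * (0:6), 11 + phrase2_period * (0:6))
}

# tiny ROI-level phase session (fast): n_pairs pairs, tpc trials per cell
tiny_phase_session <- function(n_pairs = 2, tpc = 2, kappa = 4,
                               seed = 1, tmax = 7.25, sfreq = 50,
                               overrides = NULL) {
  simulate_phase_session(n_pairs, tpc,
                         roi_kappa_map(kappa, overrides),
                         sfreq = sfreq, tmin = 0.75, tmax = tmax,
                         seed = seed)
}
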