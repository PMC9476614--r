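#' Nominal pitch sequences of the four duet pieces
#'
#' Each piece has a melody (right hand) and a bassline (left hand), two
#' phrases of seven crotchets each. The sequences are fixed constants used
#' both by the simulator and by trial validation (key-error detection).
#' Player 1 plays the melody in pieces A and C and the bassline in B and D;
#' player 2 the complement, so melody/bassline assignment is balanced
#' across pieces.
#'
#' @param piece One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return List with numeric MIDI vectors `melody` and `bassline`, each of
#'   length 14 (phrase 1 positions 1-7, then phrase 2 positions 1-7).
#' @export
piece_pitches <- function(piece) {
  tabs <- list(
    A = list(melody = c(72, 74, 76, 72, 69, 71, 72, 74, 76, 77, 76, 74, 72, 71),
             bassline = c(48, 50, 52, 48, 45, 47, 48, 50, 52, 53, 52, 50, 48, 47)),
    B = list(melody = c(76, 74, 72, 71, 69, 71, 72, 71, 72, 74, 76, 74, 72, 72),
             bassline = c(52, 50, 48, 47, 45, 47, 48, 47, 48, 50, 52, 50, 48, 48)),
    C = list(melody = c(67, 69, 71, 72, 74, 72, 71, 69, 71, 72, 74, 76, 74, 72),
             bassline = c(43, 45, 47, 48, 50, 48, 47, 45, 47, 48, 50, 52, 50, 48)),
    D = list(melody = c(74, 72, 71, 69, 67, 69, 71, 72, 74, 72, 71, 69, 67, 67),
             bassline = c(50, 48, 47, 45, 43, 45, 47, 48, 50, 48, 47, 45, 43, 43)))
  piece <- match.arg(piece, names(tabs))
  tabs[[piece]]
}

#' Voice played by a given player in a given piece
#'
#' @param player 1 or 2.
#' @param piece Piece id.
#' @return `"melody"` or `"bassline"`.
#' @export
player_voice <- function(player, piece) {
  stopifnot(player %in% c(1, 2))
  mel1 <- piece %in% c("A", "C")
  if ((player == 1) == mel1) "melody" else "bassline"
}

#' Simulate duet keystroke streams for one or more trials
#'
#' Generates the two players' keystroke onsets with a first-order mutual
#' phase-correction timing model. Each player tracks an internal beat
#' whose period starts at 500 ms (120 bpm) and drifts toward the
#' instructed second-phrase period by `anticipation_bias` ms per beat
#' during the first phrase and the pause (capped at the target period).
#' During the first phrase, when players can hear each other, the next
#' onset is additionally corrected by `adaptation_gain` times the last
#' heard asynchrony; the pause and the (muted) second phrase are timed
#' without feedback. Gaussian motor noise of SD `motor_noise_sigma` ms is
#' added to every produced onset. Each phrase yields keystrokes at
#' positions 1-7 (the eighth beat is a crotchet rest).
#'
#' @param design Design rows for one pair (from [make_design()]).
#' @param params [sim_params()] object.
#' @return data.frame with columns `pair`, `trial`, `player`, `piece`,
#'   `familiarity`, `instruction_self`, `instruction_other`, `phrase`,
#'   `position`, `onset_s`, `pitch`, in the keystroke CSV schema.
#' @export
simulate_keystrokes <- function(design, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (length(unique(design$pair_id)) != 1)
    stop("`design` must contain trials of a single pair")
  set.seed(stage_seed(params$rng_seed,
                      paste0("keystrokes", design$pair_id[1])))
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    tr <- design[i, ]
    tt <- .simulate_trial_onsets(tr$phrase2_bpm_p1, tr$phrase2_bpm_p2, params)
    out[[i]] <- rbind(
      .emit_keystrokes(tr, 1, tt$t1),
      .emit_keystrokes(tr, 2, tt$t2))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Joint internal-beat recursion over beats 1..28 for one trial
# (beat 1 = first metronome beat at 1.0 s; beats 1..4 metronome,
#  5..11 phrase-1 keystrokes, 12 crotchet rest, 13..20 pause,
#  21..27 phrase-2 keystrokes, 28 final rest).
# next onset = previous onset + own period
#              + adaptation_gain * (partner - own onset at the last
#                audible keystroke beat)                    [phrase 1 only]
#              + N(0, motor_noise_sigma);
# own period drifts from 500 ms toward the instructed phrase-2 period by
# anticipation_bias per beat (capped at the target) until the second
# phrase, where the instructed period is used.
.simulate_trial_onsets <- function(bpm1, bpm2, params) {
  tgt <- 60 / c(bpm1, bpm2)
  sgn <- sign(tgt - 0.5)
  beta <- params$anticipation_bias / 1000
  a <- params$adaptation_gain
  sig <- params$motor_noise_sigma / 1000
  t <- matrix(0, 2, 28)
  t[, 1:4] <- rep(1 + 0.5 * (0:3), each = 2)    # entrained to the metronome
  for (b in 5:28) {
    # intervals up to the phrase-2 entry (beat 21 at nominal 11 s) run at
    # the drifting 120 bpm pulse; from the entry on, the instructed tempo
    per <- if (b >= 22) tgt else
      0.5 + sgn * pmin(beta * (b - 4), abs(tgt - 0.5))
    corr <- if (b - 1 >= 5 && b - 1 <= 11)      # partner audible at b-1
      a * (t[2:1, b - 1] - t[, b - 1]) else c(0, 0)
    t[, b] <- t[, b - 1] + per + corr + rnorm(2, 0, sig)
  }
  list(t1 = t[1, ], t2 = t[2, ])
}

.emit_keystrokes <- function(tr, player, t) {
  beats <- c(5:11, 21:27)
  phrase <- rep(c(1L, 2L), each = 7)
  position <- rep(1:7, 2)
  voice <- player_voice(player, tr$piece_id)
  pit <- piece_pitches(tr$piece_id)[[voice]]
  instr_self <- if (player == 1) tr$instruction_p1 else tr$instruction_p2
  instr_other <- if (player == 1) tr$instruction_p2 else tr$instruction_p1
  data.frame(pair = tr$pair_id, trial = tr$trial_index, player = player,
             piece = tr$piece_id, familiarity = tr$familiarity,
             instruction_self = instr_self, instruction_other = instr_other,
             phrase = phrase, position = position, onset_s = t[beats],
             pitch = pit, stringsAsFactors = FALSE)
}

#' Write / read keystroke event tables
#'
#' Plain CSV in the schema produced by [simulate_keystrokes()].
#'
#' @param keystrokes data.frame of keystroke events.
#' @param path CSV file path.
#' @export
write_keystrokes <- function(keystrokes, path) {
  utils::write.csv(keystrokes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_keystrokes
#' @export
read_keystrokes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
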