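# Behavioral synchrony and adaptation measures from duet keystroke streams.
#
# Keystroke streams are data.frames in the CSV schema of
# simulate_keystrokes(): one row per keystroke with `player`, `trial`,
# `phrase`, `position` (1-7), `onset_s`, `pitch`, `piece`. Keystrokes of
# the two players are matched by score position ("complementary"
# keystrokes), never by nearest onset. The sign convention throughout is
# player 1 minus player 2.

.one_trial_stream <- function(ks) {
  stopifnot(all(c("phrase", "position", "onset_s") %in% names(ks)))
  if (length(unique(ks$trial)) > 1)
    stop("stream contains more than one trial")
  ks[order(ks$phrase, ks$position), , drop = FALSE]
}

#' Validate one duet trial
#'
#' A trial is valid when both players produced exactly the seven
#' correct-pitch keystrokes of each phrase and executed the instructed
#' tempo change: the mean second-phrase inter-keystroke interval (IKI)
#' must move from 500 ms toward the instructed target IKI (400 ms for
#' "up", 625 ms for "down") in the right direction by at least a fraction
#' `tol` of the full distance.
#'
#' @param stream1,stream2 Single-trial keystroke streams of players 1, 2.
#' @param design Matching one-row design data.frame.
#' @param tol Minimum fraction of the 500 ms-to-target distance that the
#'   mean phrase-2 IKI must cover (default 0.5).
#' @return `TRUE` or `FALSE`.
#' @export
validate_trial <- function(stream1, stream2, design, tol = 0.5) {
  s1 <- .one_trial_stream(stream1); s2 <- .one_trial_stream(stream2)
  if (s1$trial[1] != s2$trial[1])
    stop("streams belong to different trials (",
         s1$trial[1], " vs ", s2$trial[1], ")")
  ok_player <- function(s, player, instruction) {
    voice <- player_voice(player, design$piece_id)
    expected <- piece_pitches(design$piece_id)[[voice]]
    for (ph in 1:2) {
      sp <- s[s$phrase == ph, ]
      if (nrow(sp) != 7 || !identical(sort(sp$position), 1:7)) return(FALSE)
      if (!all(sp$pitch[order(sp$position)] ==
                 expected[(ph - 1) * 7 + 1:7])) return(FALSE)
    }
    s2p <- s[s$phrase == 2, ]
    iki <- mean(diff(s2p$onset_s[order(s2p$position)]))
    target <- if (instruction == "up") 0.4 else 0.625
    moved <- (iki - 0.5) / (target - 0.5)      # signed fraction covered
    moved >= tol
  }
  ok_player(s1, 1, design$instruction_p1) &&
    ok_player(s2, 2, design$instruction_p2)
}

#' Signed keystroke asynchronies of one trial
#'
#' Onset-time differences between complementary keystrokes (same phrase
#' and score position), signed as player 1 minus player 2.
#'
#' @param stream1,stream2 Single-trial keystroke streams.
#' @return data.frame with `phrase`, `position`, `asynchrony` (seconds).
#' @export
signed_asynchronies <- function(stream1, stream2) {
  s1 <- .one_trial_stream(stream1); s2 <- .one_trial_stream(stream2)
  m <- merge(s1[, c("phrase", "position", "onset_s")],
             s2[, c("phrase", "position", "onset_s")],
             by = c("phrase", "position"), suffixes = c("_1", "_2"))
  if (nrow(m) == 0)
    stop("no common score positions between the two streams")
  m <- m[order(m$phrase, m$position), ]
  data.frame(phrase = m$phrase, position = m$position,
             asynchrony = m$onset_s_1 - m$onset_s_2)
}

#' Asynchrony table for a whole session
#'
#' Applies [signed_asynchronies()] to every trial of a keystroke table and
#' attaches the condition labels of the design.
#'
#' @param keystrokes Keystroke table (both players, many trials).
#' @param design Design table of the same pair(s).
#' @return data.frame with one row per (pair, trial, phrase, position).
#' @export
asynchrony_table <- function(keystrokes, design) {
  key <- interaction(keystrokes$pair, keystrokes$trial, drop = TRUE)
  out <- lapply(split(keystrokes, key), function(ks) {
    a <- signed_asynchronies(ks[ks$player == 1, ], ks[ks$player == 2, ])
    tr <- design[design$pair_id == ks$pair[1] &
                   design$trial_index == ks$trial[1], ]
    data.frame(pair = ks$pair[1], trial = ks$trial[1],
               piece = tr$piece_id, tempo_condition = tr$tempo_condition,
               familiarity = tr$familiarity,
               instruction_p1 = tr$instruction_p1,
               instruction_p2 = tr$instruction_p2,
               a, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize signed asynchronies
#'
#' Subtracts, within each pair, the across-trial mean signed asynchrony
#' separately for each keystroke position (phrase x position) and piece,
#' removing metric-position and key-distance offsets. The across-trial
#' mean of the normalized asynchrony is zero in every
#' (pair, piece, phrase, position) cell; the operation is idempotent.
#'
#' @param tab Asynchrony table from [asynchrony_table()].
#' @return The table with a `normalized` column (replaced if present).
#' @export
normalize_asynchronies <- function(tab) {
  if (nrow(tab) == 0) stop("empty asynchrony table")
  cell <- interaction(tab$pair, tab$piece, tab$phrase, tab$position,
                      drop = TRUE)
  tab$normalized <- tab$asynchrony -
    ave(tab$asynchrony, cell, FUN = mean)
  tab
}

#' Synchronization accuracy per phrase half
#'
#' Mean absolute normalized asynchrony over keystrokes 1-3 (`"first"`
#' half) or 5-7 (`"second"` half) of the first phrase — the fourth
#' keystroke is omitted — averaged over trials, per pair and design cell.
#'
#' @param tab Normalized asynchrony table.
#' @param half `"first"` or `"second"`.
#' @return data.frame with `pair`, `tempo_condition`, `familiarity`,
#'   `half`, `accuracy` (seconds; larger = less synchronous).
#' @export
phrase_half_accuracy <- function(tab, half = c("first", "second")) {
  half <- match.arg(half)
  if (is.null(tab$normalized))
    stop("normalize the table first (see `normalize_asynchronies`)")
  pos <- if (half == "first") 1:3 else 5:7
  sub <- tab[tab$phrase == 1 & tab$position %in% pos, ]
  agg <- aggregate(list(accuracy = abs(sub$normalized)),
                   by = list(pair = sub$pair,
                             tempo_condition = sub$tempo_condition,
                             familiarity = sub$familiarity),
                   FUN = mean)
  agg$half <- half
  agg[order(agg$pair, agg$tempo_condition, agg$familiarity), ]
}

.phrase_ikis <- function(stream, phrase) {
  s <- stream[stream$phrase == phrase, ]
  s <- s[order(s$position), ]
  if (nrow(s) < 2) return(numeric(0))
  ik <- diff(s$onset_s)
  names(ik) <- paste(s$position[-nrow(s)], s$position[-1], sep = "-")
  ik[diff(s$position) == 1]           # only intervals of adjacent positions
}

#' Lag-0 adaptation coefficient of one trial
#'
#' Pearson correlation at lag zero between the two players' first-phrase
#' inter-keystroke-interval series (6 IKIs from 7 keystrokes), Fisher-z
#' transformed. More negative values indicate stronger mutual
#' (compensatory) adaptation. The correlation is clamped to
#' `+/-(1 - 1e-10)` before `atanh` so downstream averages stay finite.
#' Zero-variance IKI series yield `NA` flagged with
#' `attr(, "flag") = "zero_variance"` (to be excluded from averaging).
#'
#' @param stream1,stream2 Single-trial keystroke streams.
#' @return Fisher-z transformed lag-0 correlation (scalar).
#' @export
lag0_adaptation <- function(stream1, stream2) {
  i1 <- .phrase_ikis(.one_trial_stream(stream1), 1)
  i2 <- .phrase_ikis(.one_trial_stream(stream2), 1)
  common <- intersect(names(i1), names(i2))
  if (length(common) < 3)
    stop("need at least 3 common first-phrase IKIs")
  i1 <- i1[common]; i2 <- i2[common]
  if (sd(i1) == 0 || sd(i2) == 0)
    return(structure(NA_real_, flag = "zero_variance"))
  r <- cor(i1, i2)
  r <- pmin(pmax(r, -(1 - 1e-10)), 1 - 1e-10)
  atanh(r)
}

#' Entry asynchrony after the pause
#'
#' Absolute onset difference of the first keystroke of the second phrase.
#'
#' @param stream1,stream2 Single-trial keystroke streams.
#' @return Seconds; `NA` flagged `"missing_entry"` when either player
#'   lacks the entry keystroke.
#' @export
entry_asynchrony <- function(stream1, stream2) {
  e1 <- stream1$onset_s[stream1$phrase == 2 & stream1$position == 1]
  e2 <- stream2$onset_s[stream2$phrase == 2 & stream2$position == 1]
  if (length(e1) != 1 || length(e2) != 1)
    return(structure(NA_real_, flag = "missing_entry"))
  abs(e1 - e2)
}

#' Tempo matching in the second phrase
#'
#' Mean absolute difference between the two players' second-phrase IKIs,
#' computed over intervals available in both streams.
#'
#' @param stream1,stream2 Single-trial keystroke streams.
#' @return Seconds; `NA` flagged `"no_common_ikis"` when no interval is
#'   shared.
#' @export
iki_difference_phrase2 <- function(stream1, stream2) {
  i1 <- .phrase_ikis(.one_trial_stream(stream1), 2)
  i2 <- .phrase_ikis(.one_trial_stream(stream2), 2)
  common <- intersect(names(i1), names(i2))
  if (length(common) == 0)
    return(structure(NA_real_, flag = "no_common_ikis"))
  mean(abs(i1[common] - i2[common]))
}

#' Trial-level behavioral outcome table
#'
#' Computes, per kept trial, the outcomes entering the brain-behavior
#' models: lag-0 adaptation z, early-phrase synchronization accuracy
#' (mean |normalized asynchrony| of keystrokes 1-3), entry asynchrony and
#' second-phrase IKI difference, together with condition labels and a
#' validity flag.
#'
#' @param keystrokes Keystroke table (both players, many trials).
#' @param design Matching design table.
#' @param tol Tempo-validity tolerance, see [validate_trial()].
#' @return data.frame, one row per trial.
#' @export
behavior_trial_table <- function(keystrokes, design, tol = 0.5) {
  norm <- normalize_asynchronies(asynchrony_table(keystrokes, design))
  key <- interaction(keystrokes$pair, keystrokes$trial, drop = TRUE)
  rows <- lapply(split(keystrokes, key), function(ks) {
    s1 <- ks[ks$player == 1, ]; s2 <- ks[ks$player == 2, ]
    tr <- design[design$pair_id == ks$pair[1] &
                   design$trial_index == ks$trial[1], ]
    sub <- norm[norm$pair == ks$pair[1] & norm$trial == ks$trial[1] &
                  norm$phrase == 1 & norm$position %in% 1:3, ]
    data.frame(pair = ks$pair[1], trial = ks$trial[1],
               tempo_condition = tr$tempo_condition,
               familiarity = tr$familiarity,
               valid = validate_trial(s1, s2, tr, tol),
               adaptation_z = as.numeric(lag0_adaptation(s1, s2)),
               early_asynchrony = mean(abs(sub$normalized)),
               entry_asynchrony = as.numeric(entry_asynchrony(s1, s2)),
               iki_difference = as.numeric(iki_difference_phrase2(s1, s2)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$pair, res$trial), ]
}

#' Repeated-measures ANOVA report for a behavioral measure
#'
#' Aggregates a per-trial measure to pair x design-cell means and runs the
#' fully within-pairs 2 x 2 TEMPO x FAMILIARITY ANOVA of
#' [rmanova_2x2()].
#'
#' @param trial_table Output of [behavior_trial_table()] (or any data.frame
#'   with `pair`, `tempo_condition`, `familiarity` and the measure).
#' @param measure Column name of the measure.
#' @param keep_only_valid Drop trials with `valid == FALSE` when present.
#' @return data.frame of F statistics per effect.
#' @export
behavior_anova <- function(trial_table, measure, keep_only_valid = TRUE) {
  tt <- trial_table
  if (keep_only_valid && !is.null(tt$valid)) tt <- tt[tt$valid, ]
  tt <- tt[is.finite(tt[[measure]]), ]
  agg <- aggregate(tt[[measure]],
                   by = list(pair = tt$pair, tempo = tt$tempo_condition,
                             fam = tt$familiarity), FUN = mean)
  cells <- .cells_matrix(agg$pair, agg$tempo, agg$fam, agg$x)
  rmanova_2x2(cells)
}

# pair x 4 cell-mean matrix in the canonical column order
# congruent.familiar, congruent.unfamiliar,
# incongruent.familiar, incongruent.unfamiliar
.cells_matrix <- function(pair, tempo, fam, value) {
  lev <- paste(rep(c("congruent", "incongruent"), each = 2),
               rep(c("familiar", "unfamiliar"), 2), sep = ".")
  key <- paste(tempo, fam, sep = ".")
  pairs <- sort(unique(pair))
  m <- matrix(NA_real_, length(pairs), 4,
              dimnames = list(pairs, lev))
  m[cbind(match(pair, pairs), match(key, lev))] <- value
  m
}
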