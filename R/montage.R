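#' Standard 29-channel montage
#'
#' Channel labels of the 29-electrode extended 10-20 montage used throughout
#' the package. Inter-brain PLV is computed between homologous electrodes of
#' the two players (C3-C3, C4-C4, ...), so the montage also defines the 29
#' homologous channel pairs.
#'
#' @return Character vector of 29 channel labels.
#' @export
channel_names <- function() {
  c("FP1", "FPZ", "FP2", "F7", "F3", "FZ", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "CZ", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "PZ", "P4", "P8",
    "O1", "OZ", "O2")
}

#' Region-of-interest channel sets
#'
#' `GLOBAL` covers all 29 electrodes, `RP` is the right-posterior ROI
#' (C4, CP2, CP6, P4, P8) and `LP` its left-hemispheric homolog
#' (C3, CP1, CP5, P3, P7).
#'
#' @param roi One of `"GLOBAL"`, `"RP"`, `"LP"`.
#' @return Character vector of channel labels belonging to the ROI.
#' @export
roi_channels <- function(roi) {
  switch(match.arg(roi, c("GLOBAL", "RP", "LP")),
         GLOBAL = channel_names(),
         RP = c("C4", "CP2", "CP6", "P4", "P8"),
         LP = c("C3", "CP1", "CP5", "P3", "P7"))
}

#' EEG frequency bands
#'
#' Band edges (Hz) of the five analysis bands: delta 1-3, theta 4-7,
#' alpha 8-12, beta 13-30, gamma 30-40 Hz.
#'
#' @return Named list of two-element numeric vectors.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 12),
       beta = c(13, 30), gamma = c(30, 40))
}

#' Convert a musical tempo to a modulation frequency
#'
#' @param bpm Beats per minute, positive.
#' @return Frequency in Hz (`bpm / 60`).
#' @examples
#' bpm_to_hz(120) # 2 Hz
#' @export
bpm_to_hz <- function(bpm) {
  if (any(!is.finite(bpm)) || any(bpm <= 0))
    stop("`bpm` must be positive and finite")
  bpm / 60
}

#' Trial timeline
#'
#' Event onsets (seconds relative to the visual cue) of one duet trial:
#' cue at 0 s, metronome (4 beats at 120 bpm) at 1 s, first phrase
#' (7 crotchets + crotchet rest, 120 bpm) at 3 s, silent pause (8 beats,
#' internally timed at 120 bpm) at 7 s, and second phrase (8 beats at the
#' instructed tempo) at 11 s, ending at 14.2 s (150 bpm) or 16 s (96 bpm).
#'
#' @param phrase2_bpm Instructed tempo of the second phrase (150 or 96 in
#'   the standard design; any positive tempo is accepted).
#' @return List with `cue_onset`, `metronome_onset`, `phrase1_onset`,
#'   `pause_onset`, `phrase2_onset`, `phrase2_end` and `beat_period`
#'   (of the 120 bpm sections).
#' @export
timeline <- function(phrase2_bpm = 150) {
  stopifnot(is.numeric(phrase2_bpm), phrase2_bpm > 0)
  list(cue_onset = 0, metronome_onset = 1, phrase1_onset = 3,
       pause_onset = 7, phrase2_onset = 11,
       phrase2_end = 11 + 8 * 60 / phrase2_bpm,
       beat_period = 60 / 120)
}

#' Segment boundaries of a trial
#'
#' @param phrase2_bpm Instructed second-phrase tempo.
#' @return data.frame with columns `segment`, `start`, `end` (seconds) for
#'   the metronome, first phrase, pause and second phrase.
#' @export
trial_segments <- function(phrase2_bpm = 150) {
  tl <- timeline(phrase2_bpm)
  data.frame(
    segment = c("metronome", "phrase1", "pause", "phrase2"),
    start = c(tl$metronome_onset, tl$phrase1_onset, tl$pause_onset,
              tl$phrase2_onset),
    end = c(tl$phrase1_onset, tl$pause_onset, tl$phrase2_onset,
            tl$phrase2_end),
    stringsAsFactors = FALSE)
}
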