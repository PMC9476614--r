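# Sliding-window phase-locking values between homologous channels.

#' Sliding window grid
#'
#' Window layout for the PLV time course: windows of `width` seconds,
#' moving in steps of `step`, the first window starting at `tstart`
#' (metronome onset, 1 s) and the last one ending at `tend` (14.2 s, where
#' fast trials finish). Windows are half-open `[t0, t0 + width)` and are
#' indexed by their center time, so the default grid has 113 windows with
#' centers 2.0, 2.1, ..., 13.2 s, and a run of significant centers
#' `[a, b]` covers the data from `a - width/2` to `b + width/2`.
#'
#' @param width,step Window width and step (s).
#' @param tstart Left edge of the first window (s).
#' @param tend Right edge of the last window (s).
#' @return List of class `window_grid` with `onsets`, `centers`, `width`,
#'   `step`.
#' @export
window_grid <- function(width = 2, step = 0.1, tstart = 1, tend = 14.2) {
  stopifnot(width > 0, step > 0, tend - tstart >= width)
  onsets <- seq(tstart, tend - width + 1e-9, by = step)
  structure(list(onsets = onsets, centers = onsets + width / 2,
                 width = width, step = step),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat("<window_grid>", length(x$onsets), "windows of", x$width,
      "s, step", x$step, "s, centers", x$centers[1], "...",
      x$centers[length(x$centers)], "s\n")
  invisible(x)
}

#' Windowed phase-locking value between two phase series
#'
#' For every window, trial and homologous channel pair, the PLV is the
#' modulus of the time-averaged unit phasor of the phase difference:
#' `PLV = |mean over t of exp(i * (theta1 - theta2))|`. Values lie in
#' `[0, 1]`; 1 means a constant phase offset within the window, 0 a
#' balanced dispersion over the circle.
#'
#' @param phase1,phase2 Phase arrays (trials x channels x samples; a
#'   matrix is treated as trials x samples with one channel).
#' @param grid [window_grid()] object.
#' @param sfreq Sampling frequency (Hz).
#' @param tmin Time of the first sample (s).
#' @return trials x channels x windows array with window centers in
#'   `attr(, "centers")`.
#' @export
sliding_plv <- function(phase1, phase2, grid = window_grid(), sfreq,
                        tmin = -1) {
  if (is.matrix(phase1)) dim(phase1) <- c(nrow(phase1), 1, ncol(phase1))
  if (is.matrix(phase2)) dim(phase2) <- c(nrow(phase2), 1, ncol(phase2))
  stopifnot(identical(dim(phase1), dim(phase2)))
  d <- dim(phase1)
  n_s <- d[3]
  T_w <- round(grid$width * sfreq)
  i0 <- round((grid$onsets - tmin) * sfreq) + 1
  if (any(i0 < 1) || any(i0 + T_w - 1 > n_s))
    stop("window grid exceeds the epoch (samples ", min(i0), "..",
         max(i0 + T_w - 1), " of ", n_s, ")")
  z <- exp(1i * (phase1 - phase2))
  dim(z) <- c(d[1] * d[2], n_s)
  cs <- t(apply(z, 1, cumsum))
  if (d[1] * d[2] == 1) cs <- matrix(cs, 1, n_s)
  lower <- matrix(0i, nrow(cs), length(i0))
  has_prev <- i0 > 1
  lower[, has_prev] <- cs[, i0[has_prev] - 1, drop = FALSE]
  sums <- cs[, i0 + T_w - 1, drop = FALSE] - lower
  plv <- Mod(sums) / T_w
  out <- array(plv, c(d[1], d[2], length(i0)))
  attr(out, "centers") <- grid$centers
  out
}

#' Average PLVs over a region of interest
#'
#' Averages a trials x channels x windows PLV array over the homologous
#' channel pairs of an ROI (first step of the two-step averaging: within
#' ROI, then across trials per condition).
#'
#' @param plv PLV array from [sliding_plv()].
#' @param roi ROI name (see [roi_channels()]).
#' @param ch_names Channel labels of the PLV array's channel dimension.
#' @return trials x windows matrix with window centers preserved.
#' @export
roi_average <- function(plv, roi = "GLOBAL", ch_names = channel_names()) {
  sel <- which(ch_names %in% roi_channels(roi))
  if (length(sel) == 0) {
    if (roi == "GLOBAL") sel <- seq_len(dim(plv)[2])
    else stop("no channels of ROI '", roi, "' present")
  }
  out <- if (length(sel) == 1) {
    matrix(plv[, sel, ], dim(plv)[1], dim(plv)[3])
  } else {
    apply(plv[, sel, , drop = FALSE], c(1, 3), mean)
  }
  attr(out, "centers") <- attr(plv, "centers")
  out
}

#' Condition-mean PLV time courses
#'
#' Averages trial-level ROI PLVs across trials per design cell — the
#' second averaging step, yielding the pair's four condition time
#' courses.
#'
#' @param plv_roi trials x windows matrix from [roi_average()].
#' @param tempo,familiarity Per-trial condition labels.
#' @return 4 x windows matrix, rows in the canonical cell order
#'   (congruent.familiar, congruent.unfamiliar, incongruent.familiar,
#'   incongruent.unfamiliar).
#' @export
cell_means <- function(plv_roi, tempo, familiarity) {
  lev <- paste(rep(c("congruent", "incongruent"), each = 2),
               rep(c("familiar", "unfamiliar"), 2), sep = ".")
  key <- factor(paste(tempo, familiarity, sep = "."), levels = lev)
  if (any(is.na(key))) stop("unknown condition labels")
  g <- rowsum(plv_roi, key)
  cnt <- as.vector(table(key))
  if (any(cnt == 0)) stop("empty design cell")
  out <- g / cnt
  rownames(out) <- lev
  attr(out, "centers") <- attr(plv_roi, "centers")
  out
}

#' Assemble an IBS session from per-pair phase data
#'
#' Computes trial-level ROI-averaged PLV time courses for every pair of a
#' phase session — the input of [permutation_test()] and the controls.
#'
#' @param phases Phase session: list with one element per pair, each a
#'   list with `phase1`, `phase2` (trials x channels x samples), `tempo`,
#'   `familiarity`, `sfreq`, `tmin`, `pair_id`, `ch_names`.
#' @param grid [window_grid()] object.
#' @param roi ROI name.
#' @return List of class `ibs_session`: per pair `plv` (trials x windows),
#'   `tempo`, `familiarity`, `pair_id`; window centers in
#'   `attr(, "centers")`.
#' @export
session_plv <- function(phases, grid = window_grid(), roi = "GLOBAL") {
  out <- lapply(phases, function(p) {
    plv <- sliding_plv(p$phase1, p$phase2, grid, p$sfreq, p$tmin)
    ch <- if (!is.null(p$ch_names)) p$ch_names else
      rep("ROI", dim(plv)[2])
    list(plv = roi_average(plv, roi, ch), tempo = p$tempo,
         familiarity = p$familiarity, pair_id = p$pair_id,
         trial_index = p$trial_index)
  })
  structure(out, centers = grid$centers, class = "ibs_session")
}

#' Per-pair condition series of an IBS session
#'
#' @param session `ibs_session` object.
#' @return pairs x 4 cells x windows array (canonical cell order).
#' @export
condition_series <- function(session) {
  cm <- lapply(session, function(p) cell_means(p$plv, p$tempo,
                                               p$familiarity))
  out <- array(0, c(length(cm), 4, ncol(cm[[1]])),
               dimnames = list(NULL, rownames(cm[[1]]), NULL))
  for (i in seq_along(cm)) out[i, , ] <- cm[[i]]
  attr(out, "centers") <- attr(session, "centers")
  out
}

#' Phase session of a band from epoched dual EEG
#'
#' Runs the envelope pipeline (band-pass, Hilbert envelope, 1-3 Hz
#' envelope filter, Hilbert phase) on every pair's kept trials.
#'
#' @param epoch_list List of `dyad_epochs` objects (one per pair).
#' @param band Band name or edges (Hz).
#' @return Phase session consumable by [session_plv()],
#'   [baseline_plv()] and [make_surrogate_dataset()].
#' @export
epochs_phase_session <- function(epoch_list, band) {
  lapply(epoch_list, function(ep) {
    stopifnot(inherits(ep, "dyad_epochs"))
    keep <- which(ep$keep)
    ph <- envelope_phase(band_envelope(ep, band))
    list(phase1 = ph$p1[keep, , , drop = FALSE],
         phase2 = ph$p2[keep, , , drop = FALSE],
         tempo = ep$conditions$tempo_condition[keep],
         familiarity = ep$conditions$familiarity[keep],
         sfreq = ep$sfreq, tmin = ep$tmin, pair_id = ep$pair_id,
         ch_names = ep$ch_names,
         trial_index = ep$conditions$trial_index[keep])
  })
}
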