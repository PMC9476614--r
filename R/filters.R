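# Preprocessing and envelope extraction. All filters are zero-phase
# (two-pass) Butterworth filters; transforms run over the whole -1..16 s
# epoch so the pre-cue second and the tail absorb filter transients.

#' Preprocess a continuous dual recording into epochs
#'
#' Applies the standard preprocessing chain: 0.5-95 Hz band-pass and
#' 45-55 Hz band-stop (both zero-phase Butterworth, order 3 per pass),
#' linked-mastoid re-referencing when both mastoid channels are present
#' (skipped otherwise, e.g. for synthetic reference-free data), and
#' epoching from -1 to 16 s around each cue event.
#'
#' @param raw List with `p1`, `p2` (channels x samples matrices), `sfreq`,
#'   `ch_names`, and `events` (cue onsets, 1-based sample indices).
#' @param mastoids Labels of the two mastoid channels.
#' @param expect_sfreq If non-`NULL`, error when `raw$sfreq` differs.
#' @param tmin,tmax Epoch limits (s) relative to the cue.
#' @param conditions,pair_id Passed to [dyad_epochs()].
#' @return `dyad_epochs` object (mastoid channels dropped if used).
#' @export
preprocess_raw <- function(raw, mastoids = c("M1", "M2"),
                           expect_sfreq = 500, tmin = -1, tmax = 16,
                           conditions = NULL, pair_id = 1L) {
  stopifnot(is.list(raw), !is.null(raw$p1), !is.null(raw$p2))
  sf <- raw$sfreq
  if (!is.null(expect_sfreq) && sf != expect_sfreq)
    stop("sampling-rate mismatch: got ", sf, " Hz, expected ",
         expect_sfreq, " Hz")
  if (is.null(raw$events) || length(raw$events) == 0)
    stop("no cue events in the recording")
  nyq <- sf / 2
  bp <- signal::butter(3, c(0.5, 95) / nyq, type = "pass")
  bs <- signal::butter(3, c(45, 55) / nyq, type = "stop")
  ch <- raw$ch_names
  filt_one <- function(x) {
    x <- t(apply(x, 1, function(v) signal::filtfilt(bp, v)))
    x <- t(apply(x, 1, function(v) signal::filtfilt(bs, v)))
    if (all(mastoids %in% ch)) {
      ref <- colMeans(x[match(mastoids, ch), , drop = FALSE])
      x <- sweep(x, 2, ref)
      x <- x[-match(mastoids, ch), , drop = FALSE]
    }
    x
  }
  x1 <- filt_one(raw$p1); x2 <- filt_one(raw$p2)
  ch_out <- if (all(mastoids %in% ch)) setdiff(ch, mastoids) else ch
  n_ep <- round((tmax - tmin) * sf) + 1
  i0 <- round(raw$events + tmin * sf)           # epoch sample 1 (t = tmin)
  if (any(i0 < 1) || any(i0 + n_ep - 1 > ncol(x1)))
    stop("epoch window exceeds the recording for at least one event")
  n_tr <- length(raw$events)
  ep <- function(x) {
    a <- array(0, c(n_tr, nrow(x), n_ep))
    for (k in seq_len(n_tr)) a[k, , ] <- x[, i0[k] + seq_len(n_ep) - 1]
    a
  }
  dyad_epochs(ep(x1), ep(x2), sfreq = sf, ch_names = ch_out, tmin = tmin,
              conditions = conditions, pair_id = pair_id)
}

.band_edges <- function(band) {
  if (is.character(band)) {
    bands <- eeg_bands()
    if (!band %in% names(bands)) stop("unknown band '", band, "'")
    bands[[band]]
  } else {
    stopifnot(is.numeric(band), length(band) == 2, band[1] < band[2])
    band
  }
}

#' Band-limited amplitude envelope
#'
#' Band-pass filters the signal (zero-phase Butterworth, order 4 per
#' pass) and takes the modulus of the analytic signal — the amplitude
#' envelope of that frequency band.
#'
#' @param x Numeric array (trials x channels x samples), matrix
#'   (rows = series) or vector; time runs along the last dimension. A
#'   `dyad_epochs` object is also accepted, in which case both players are
#'   processed and a list `p1`/`p2` of envelope arrays is returned.
#' @param band Band name (see [eeg_bands()]) or `c(low, high)` in Hz.
#' @param sfreq Sampling frequency; taken from the container when `x` is a
#'   `dyad_epochs` object.
#' @return Non-negative envelope, same shape as the input.
#' @export
band_envelope <- function(x, band, sfreq = NULL) {
  edges <- .band_edges(band)
  if (inherits(x, "dyad_epochs")) {
    return(list(p1 = band_envelope(x$p1, edges, x$sfreq),
                p2 = band_envelope(x$p2, edges, x$sfreq),
                band = if (is.character(band)) band else paste(edges, collapse = "-"),
                sfreq = x$sfreq, tmin = x$tmin))
  }
  if (is.null(sfreq)) stop("`sfreq` is required for plain arrays")
  if (edges[2] >= sfreq / 2)
    stop("band edge ", edges[2], " Hz is at or above Nyquist (",
         sfreq / 2, " Hz)")
  filt <- signal::butter(4, edges / (sfreq / 2), type = "pass")
  y <- .filt_array(x, filt)
  .map_series(y, function(v) Mod(analytic_signal(v)))
}

#' Phase of the beat-filtered amplitude envelope
#'
#' Band-pass filters an amplitude envelope in the musical tempo range
#' (1-3 Hz, zero-phase Butterworth, order 4 per pass) and extracts the
#' instantaneous phase of its analytic signal — the quantity entering the
#' envelope PLV.
#'
#' @param env Envelope array/matrix/vector, or the list returned by
#'   [band_envelope()] on a `dyad_epochs` object.
#' @param sfreq Sampling frequency (taken from the list input if present).
#' @param tempo_band Envelope filter band in Hz (default `c(1, 3)`, the
#'   range of the task tempi 96-150 bpm = 1.6-2.5 Hz).
#' @return Phase in `(-pi, pi]`, same shape as the input.
#' @export
envelope_phase <- function(env, sfreq = NULL, tempo_band = c(1, 3)) {
  if (is.list(env) && !is.null(env$p1)) {
    return(list(p1 = envelope_phase(env$p1, env$sfreq, tempo_band),
                p2 = envelope_phase(env$p2, env$sfreq, tempo_band),
                band = env$band, sfreq = env$sfreq, tmin = env$tmin))
  }
  if (is.null(sfreq)) stop("`sfreq` is required for plain arrays")
  filt <- signal::butter(4, tempo_band / (sfreq / 2), type = "pass")
  y <- .filt_array(env, filt)
  .map_series(y, function(v) Arg(analytic_signal(v)))
}

# apply a vector function along the time dimension, preserving shape
.map_series <- function(x, fun) {
  if (is.null(dim(x))) return(fun(x))
  d <- dim(x)
  if (length(d) == 2) {
    out <- t(apply(x, 1, fun))
    dim(out) <- d
    return(out)
  }
  out <- x
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out[i, j, ] <- fun(x[i, j, ])
  out
}

#' Band power in a time window and ROI
#'
#' Mean squared amplitude envelope over the window samples, ROI channels
#' and kept trials — the power control accompanying PLV effects. Returned
#' per design cell and player, plus the player average.
#'
#' @param epochs `dyad_epochs` object with condition labels.
#' @param band Band name or edges (Hz).
#' @param window `c(start, end)` in seconds (data window, cue-locked).
#' @param roi ROI name, see [roi_channels()].
#' @return data.frame with `tempo_condition`, `familiarity`, `power_p1`,
#'   `power_p2`, `power` (mean of the two players).
#' @export
band_power <- function(epochs, band, window, roi = "GLOBAL") {
  stopifnot(inherits(epochs, "dyad_epochs"))
  env <- band_envelope(epochs, band)
  tt <- epoch_times(epochs)
  sel <- tt >= window[1] & tt < window[2]
  if (!any(sel)) stop("window lies outside the epoch")
  chi <- which(epochs$ch_names %in% roi_channels(roi))
  if (length(chi) == 0) chi <- seq_along(epochs$ch_names)
  keep <- which(epochs$keep)
  cond <- epochs$conditions[keep, , drop = FALSE]
  pw <- function(a) {
    v <- apply(a[keep, chi, sel, drop = FALSE]^2, 1, mean)
    aggregate(list(power = v),
              by = list(tempo_condition = cond$tempo_condition,
                        familiarity = cond$familiarity), FUN = mean)
  }
  a1 <- pw(env$p1); a2 <- pw(env$p2)
  out <- merge(a1, a2, by = c("tempo_condition", "familiarity"),
               suffixes = c("_p1", "_p2"))
  out$power <- (out$power_p1 + out$power_p2) / 2
  out[order(out$tempo_condition, out$familiarity), ]
}
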