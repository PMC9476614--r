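# Control analyses: baseline PLV (within-dyad trial re-pairing),
# surrogate pairs (cross-dyad re-pairing with condition matching), and the
# power-confound check.

# random derangement (permutation without fixed points)
.derangement <- function(n) {
  if (n < 2) stop("need at least 2 trials for a derangement")
  repeat {
    s <- sample.int(n)
    if (!any(s == seq_len(n))) return(s)
  }
}

#' Baseline PLV from within-dyad trial re-pairing
#'
#' Estimates the PLV driven by the temporal structure common to all
#' trials (shared tempo, cue timing) rather than by trial-specific
#' interaction: player 1's trial i is paired with player 2's trial
#' sigma(i) for a random derangement sigma, the PLV pipeline is re-run,
#' and the result averaged over trials and `n_rep` derangements.
#'
#' @param pair_phase One pair's phase data: list with `phase1`, `phase2`
#'   (trials x channels x samples), `sfreq`, `tmin`.
#' @param grid [window_grid()] object.
#' @param n_rep Number of derangements averaged (stabilizes the curve).
#' @param seed Seed for the derangement stream.
#' @return channels x windows matrix of baseline PLV, window centers in
#'   `attr(, "centers")`.
#' @export
baseline_plv <- function(pair_phase, grid = window_grid(), n_rep = 20,
                         seed = 1) {
  n_tr <- dim(pair_phase$phase1)[1]
  if (n_tr < 2) stop("baseline PLV needs at least 2 kept trials")
  set.seed(seed)
  acc <- 0
  for (r in seq_len(n_rep)) {
    s <- .derangement(n_tr)
    plv <- sliding_plv(pair_phase$phase1,
                       pair_phase$phase2[s, , , drop = FALSE],
                       grid, pair_phase$sfreq, pair_phase$tmin)
    acc <- acc + apply(plv, c(2, 3), mean)
  }
  out <- acc / n_rep
  attr(out, "centers") <- grid$centers
  out
}

#' Pointwise comparison of condition PLV against baseline PLV
#'
#' Uncorrected paired t-tests across pairs, one per window (the "small
#' circles" comparison accompanying the PLV time courses).
#'
#' @param condition_plv,baseline Matrices pairs x windows.
#' @param centers Optional window centers for the report.
#' @return data.frame with `window`, `center`, `t`, `df`, `p`,
#'   `mean_diff`.
#' @export
compare_to_baseline <- function(condition_plv, baseline, centers = NULL) {
  stopifnot(identical(dim(condition_plv), dim(baseline)))
  W <- ncol(condition_plv)
  rows <- lapply(seq_len(W), function(w) {
    r <- paired_t(condition_plv[, w], baseline[, w])
    data.frame(window = w,
               center = if (is.null(centers)) NA_real_ else centers[w],
               t = r$t, df = r$df, p = r$p, mean_diff = r$mean_diff)
  })
  do.call(rbind, rows)
}

#' Build a surrogate-pair dataset
#'
#' Re-pairs players across dyads (player 1 of pair k with player 2 of
#' pair k', k' != k) while matching trials of the same experimental
#' condition, so no surrogate pair reunites two real partners. Within
#' every design cell trial counts are equalized to player 1's count:
#' spare player-2 trials are deleted, missing ones filled by duplicating
#' player 2's first trials of that cell in order. The surrogate analyses
#' therefore run at exactly the statistical power of the real analyses.
#'
#' @param phases Phase session (list per pair, see [session_plv()]).
#' @param shift Cyclic shift used for the deterministic default pairing
#'   (pair k gets player 2 of pair k + shift).
#' @param seed If non-`NULL`, draw a random fixed-point-free pair
#'   permutation instead of the cyclic shift.
#' @return Phase session of surrogate pairs (condition labels follow
#'   player 1).
#' @export
make_surrogate_dataset <- function(phases, shift = 1, seed = NULL) {
  n <- length(phases)
  if (n < 2) stop("surrogate pairing needs at least 2 real pairs")
  if (is.null(seed)) {
    perm <- ((seq_len(n) - 1 + shift) %% n) + 1
    if (any(perm == seq_len(n)))
      stop("`shift` must not map any pair to itself")
  } else {
    set.seed(seed)
    perm <- .derangement(n)
  }
  out <- vector("list", n)
  for (k in seq_len(n)) {
    A <- phases[[k]]; B <- phases[[perm[k]]]
    cells_a <- paste(A$tempo, A$familiarity, sep = ".")
    cells_b <- paste(B$tempo, B$familiarity, sep = ".")
    ia_all <- integer(0); ib_all <- integer(0)
    for (cl in unique(cells_a)) {
      ia <- which(cells_a == cl)
      ib <- which(cells_b == cl)
      n1 <- length(ia); n2 <- length(ib)
      if (n2 == 0)
        stop("surrogate partner lacks condition cell '", cl, "'")
      ib_use <- if (n2 >= n1) ib[seq_len(n1)]      # delete spare trials
      else ib[c(seq_len(n2), rep_len(seq_len(n2), n1 - n2))]  # duplicate
      ia_all <- c(ia_all, ia)
      ib_all <- c(ib_all, ib_use)
    }
    out[[k]] <- list(phase1 = A$phase1[ia_all, , , drop = FALSE],
                     phase2 = B$phase2[ib_all, , , drop = FALSE],
                     tempo = A$tempo[ia_all],
                     familiarity = A$familiarity[ia_all],
                     sfreq = A$sfreq, tmin = A$tmin,
                     pair_id = paste0(A$pair_id, "x", B$pair_id),
                     ch_names = A$ch_names)
  }
  out
}

#' Cluster analysis of surrogate pairs
#'
#' Runs the identical PLV + cluster-permutation pipeline on a surrogate
#' re-pairing of the session, probing whether condition effects require
#' the real interaction.
#'
#' @param phases Phase session of the real pairs.
#' @param grid,roi,config As in [session_plv()] / [permutation_test()].
#' @param shift,seed Surrogate pairing control, see
#'   [make_surrogate_dataset()].
#' @return `ibs_cluster_test` with `attr(, "analysis") = "surrogate"`.
#' @export
surrogate_cluster_analysis <- function(phases, grid = window_grid(),
                                       roi = "GLOBAL",
                                       config = perm_config(),
                                       shift = 1, seed = NULL) {
  surr <- make_surrogate_dataset(phases, shift = shift, seed = seed)
  res <- permutation_test(session_plv(surr, grid, roi), config)
  attr(res, "analysis") <- "surrogate"
  res
}

#' Power-confound check for a PLV effect
#'
#' Tests whether band power differs between conditions in the ROI and
#' time window of an observed PLV effect: per pair the envelope power is
#' averaged per condition and the marginal means compared across pairs by
#' paired t-tests (one per design factor).
#'
#' @param epoch_list List of `dyad_epochs`, one per pair.
#' @param band Band name or edges (Hz).
#' @param window `c(start, end)` data window in seconds (for a cluster
#'   with centers `[a, b]` this is `[a - 1, b + 1]`).
#' @param roi ROI name.
#' @return data.frame with one row per effect (`tempo`, `familiarity`):
#'   `t`, `df`, `p`, `mean_diff`, and the per-level means.
#' @export
power_confound_check <- function(epoch_list, band, window,
                                 roi = "GLOBAL") {
  per_pair <- lapply(epoch_list, band_power, band = band, window = window,
                     roi = roi)
  lvl_mean <- function(bp, fac, lev)
    mean(bp$power[bp[[fac]] == lev])
  res <- lapply(list(c("tempo_condition", "congruent", "incongruent"),
                     c("familiarity", "familiar", "unfamiliar")),
                function(spec) {
    a <- vapply(per_pair, lvl_mean, numeric(1), fac = spec[1],
                lev = spec[2])
    b <- vapply(per_pair, lvl_mean, numeric(1), fac = spec[1],
                lev = spec[3])
    r <- paired_t(a, b)
    data.frame(effect = spec[1], level_a = spec[2], level_b = spec[3],
               mean_a = mean(a), mean_b = mean(b), t = r$t, df = r$df,
               p = r$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
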