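# Pointwise repeated-measures ANOVA over the PLV time axis with
# cluster-mass permutation correction, plus generic paired tests.

#' Permutation test configuration
#'
#' @param n_perm Number of label permutations (study value 1000).
#' @param cluster_alpha Cluster-forming pointwise alpha (0.01, chosen to
#'   control for the five frequency bands).
#' @param min_run Minimum cluster length in consecutive windows (2).
#' @param cluster_p Cluster-level significance threshold (0.05).
#' @param seed Seed for the permutation stream.
#' @return List of class `perm_config`.
#' @export
perm_config <- function(n_perm = 1000, cluster_alpha = 0.01, min_run = 2,
                        cluster_p = 0.05, seed = 1) {
  stopifnot(n_perm >= 1, cluster_alpha > 0, cluster_alpha < 1,
            cluster_p > 0, cluster_p < 1, min_run >= 1)
  structure(list(n_perm = as.integer(n_perm),
                 cluster_alpha = cluster_alpha, min_run = as.integer(min_run),
                 cluster_p = cluster_p, seed = as.integer(seed)),
            class = "perm_config")
}

# Within-subject F for a 2-level contrast: with difference scores d_i the
# effect F equals n * mean(d)^2 / var(d) = t^2 on df (1, n - 1).
.contrast_F <- function(d) {
  n <- length(d)
  v <- var(d)
  m <- mean(d)
  if (!is.finite(v) || v <= 0) {
    f <- if (abs(m) < 1e-12) 0 else Inf
  } else {
    f <- n * m^2 / v
  }
  c(F = f, p = pf(f, 1, n - 1, lower.tail = FALSE))
}

.effect_contrasts <- function() {
  # columns in canonical cell order: congruent.familiar,
  # congruent.unfamiliar, incongruent.familiar, incongruent.unfamiliar
  list(tempo = c(1, 1, -1, -1) / 2,
       familiarity = c(1, -1, 1, -1) / 2,
       interaction = c(1, -1, -1, 1) / 2)
}

#' Fully within-pairs 2 x 2 repeated-measures ANOVA
#'
#' Main effects and interaction of the TEMPO x FAMILIARITY design with
#' one observation (cell mean) per pair and cell. Every effect has
#' 2 levels, so its F statistic on df (1, n - 1) equals the squared
#' paired t on the corresponding marginal differences; no sphericity
#' correction is needed.
#'
#' @param cells n_pairs x 4 matrix of cell means, columns in the canonical
#'   order congruent.familiar, congruent.unfamiliar, incongruent.familiar,
#'   incongruent.unfamiliar.
#' @return data.frame with `effect`, `F`, `df1`, `df2`, `p`.
#' @export
rmanova_2x2 <- function(cells) {
  cells <- as.matrix(cells)
  if (ncol(cells) != 4) stop("`cells` must have 4 columns (design cells)")
  if (anyNA(cells)) stop("incomplete cells: every pair needs all 4 cell means")
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 pairs")
  ct <- .effect_contrasts()
  res <- t(vapply(ct, function(cv) .contrast_F(drop(cells %*% cv)),
                  numeric(2)))
  data.frame(effect = names(ct), F = res[, "F"], df1 = 1, df2 = n - 1,
             p = res[, "p"], row.names = NULL)
}

#' Pointwise repeated-measures ANOVA along the window axis
#'
#' One [rmanova_2x2()] per window, vectorized over windows.
#'
#' @param series pairs x 4 cells x windows array (see
#'   [condition_series()]).
#' @return List with `F` and `p`, each a 3 x windows matrix with rows
#'   `tempo`, `familiarity`, `interaction`, and the window `centers`.
#' @export
pointwise_rmanova <- function(series) {
  stopifnot(length(dim(series)) == 3, dim(series)[2] == 4)
  n <- dim(series)[1]
  if (n < 2) stop("need at least 2 pairs")
  if (anyNA(series)) stop("incomplete cells")
  ct <- .effect_contrasts()
  W <- dim(series)[3]
  Fm <- pm <- matrix(NA_real_, length(ct), W,
                     dimnames = list(names(ct), NULL))
  for (e in seq_along(ct)) {
    cv <- ct[[e]]
    D <- series[, 1, ] * cv[1] + series[, 2, ] * cv[2] +
      series[, 3, ] * cv[3] + series[, 4, ] * cv[4]
    D <- matrix(D, n, W)
    mu <- colMeans(D)
    v <- (colSums(D^2) - n * mu^2) / (n - 1)
    f <- ifelse(v > 0, n * mu^2 / v, ifelse(abs(mu) < 1e-12, 0, Inf))
    Fm[e, ] <- f
    pm[e, ] <- pf(f, 1, n - 1, lower.tail = FALSE)
  }
  list(F = Fm, p = pm, centers = attr(series, "centers"))
}

#' Form temporal clusters from pointwise p- and F-series
#'
#' Maximal runs of at least `min_run` consecutive windows with
#' `p < cluster_alpha`; the cluster mass is the sum of the F values over
#' the run.
#'
#' @param p_series,F_series Aligned numeric vectors.
#' @param config [perm_config()] object.
#' @return data.frame with `start`, `end` (window indices) and `mass`;
#'   zero rows when no cluster forms.
#' @export
form_clusters <- function(p_series, F_series, config = perm_config()) {
  stopifnot(length(p_series) == length(F_series))
  below <- p_series < config$cluster_alpha
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= config$min_run
  if (!any(keep))
    return(data.frame(start = integer(0), end = integer(0),
                      mass = numeric(0)))
  s <- starts[keep]; e <- ends[keep]
  data.frame(start = s, end = e,
             mass = vapply(seq_along(s),
                           function(i) sum(F_series[s[i]:e[i]]),
                           numeric(1)))
}

# stack an ibs_session into one trial matrix with pair / cell indices
.stack_session <- function(session) {
  lev <- paste(rep(c("congruent", "incongruent"), each = 2),
               rep(c("familiar", "unfamiliar"), 2), sep = ".")
  X <- do.call(rbind, lapply(session, function(p) p$plv))
  pair <- rep(seq_along(session),
              vapply(session, function(p) nrow(p$plv), integer(1)))
  cell <- unlist(lapply(session, function(p) {
    k <- match(paste(p$tempo, p$familiarity, sep = "."), lev)
    if (anyNA(k)) stop("unknown condition labels in session")
    k
  }))
  cnt <- table(factor(pair), factor(cell, levels = 1:4))
  if (any(cnt == 0))
    stop("fewer trials than design cells: every pair needs >= 1 trial ",
         "per cell")
  list(X = X, pair = pair, cell = cell, n_pairs = length(session),
       counts = as.vector(t(cnt)))
}

# cell-mean array (pairs x 4 x windows) for given cell labels
.cell_mean_array <- function(st, cell) {
  grp <- (st$pair - 1L) * 4L + cell
  g <- rowsum(st$X, factor(grp, levels = seq_len(st$n_pairs * 4L)))
  g <- g / st$counts
  array(aperm(array(g, c(4, st$n_pairs, ncol(st$X))), c(2, 1, 3)),
        c(st$n_pairs, 4, ncol(st$X)))
}

#' Cluster-based permutation test of the PLV time course
#'
#' Runs the pointwise TEMPO x FAMILIARITY rmANOVA over the window axis,
#' forms clusters of at least `min_run` consecutive windows with
#' `p < cluster_alpha`, and assesses each cluster's summed-F mass against
#' a permutation null: in every permutation the assignment of trials to
#' the four conditions is re-shuffled within each pair (preserving cell
#' counts), the cell means and F series recomputed, and the largest
#' cluster mass recorded per effect (0 when no cluster forms).
#' Cluster p-values use the add-one convention
#' `(b + 1) / (n_perm + 1)`.
#'
#' @param session `ibs_session` (trial-level ROI-averaged PLVs with
#'   condition labels per pair, see [session_plv()]).
#' @param config [perm_config()] object.
#' @return Object of class `ibs_cluster_test`: `clusters` data.frame
#'   (`effect`, `start`, `end`, `start_s`, `end_s`, `mass`, `p_cluster`,
#'   `significant`), observed `F`/`p` series, `null_mass` matrix
#'   (permutations x effects), `centers`, `config`.
#' @export
permutation_test <- function(session, config = perm_config()) {
  st <- .stack_session(session)
  centers <- attr(session, "centers")
  obs <- pointwise_rmanova(structure(.cell_mean_array(st, st$cell),
                                     centers = centers))
  effects <- rownames(obs$F)
  obs_clusters <- lapply(effects, function(e)
    form_clusters(obs$p[e, ], obs$F[e, ], config))
  names(obs_clusters) <- effects

  set.seed(config$seed)
  pair_idx <- split(seq_along(st$cell), st$pair)
  null_mass <- matrix(0, config$n_perm, length(effects),
                      dimnames = list(NULL, effects))
  cell_perm <- st$cell
  for (r in seq_len(config$n_perm)) {
    for (ix in pair_idx) cell_perm[ix] <- st$cell[ix][sample.int(length(ix))]
    pr <- pointwise_rmanova(.cell_mean_array(st, cell_perm))
    for (e in seq_along(effects)) {
      cl <- form_clusters(pr$p[e, ], pr$F[e, ], config)
      null_mass[r, e] <- if (nrow(cl)) max(cl$mass) else 0
    }
  }

  rows <- lapply(effects, function(e) {
    cl <- obs_clusters[[e]]
    if (nrow(cl) == 0) return(NULL)
    cl$effect <- e
    cl$p_cluster <- vapply(cl$mass, function(m)
      (sum(null_mass[, e] >= m) + 1) / (config$n_perm + 1), numeric(1))
    cl
  })
  clusters <- do.call(rbind, rows)
  if (is.null(clusters))
    clusters <- data.frame(start = integer(0), end = integer(0),
                           mass = numeric(0), effect = character(0),
                           p_cluster = numeric(0))
  if (!is.null(centers) && nrow(clusters)) {
    clusters$start_s <- centers[clusters$start]
    clusters$end_s <- centers[clusters$end]
  }
  clusters$significant <- clusters$p_cluster < config$cluster_p
  ord <- c("effect", "start", "end",
           intersect(c("start_s", "end_s"), names(clusters)),
           "mass", "p_cluster", "significant")
  structure(list(clusters = clusters[, ord, drop = FALSE],
                 F = obs$F, p = obs$p, null_mass = null_mass,
                 centers = centers, config = config),
            class = "ibs_cluster_test")
}

#' @export
print.ibs_cluster_test <- function(x, ...) {
  cat("<ibs_cluster_test>", ncol(x$F), "windows,", x$config$n_perm,
      "permutations, cluster-forming alpha", x$config$cluster_alpha, "\n")
  if (nrow(x$clusters) == 0) cat("no clusters formed\n")
  else print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Two-sided paired t-test across pairs
#'
#' Thin wrapper around [stats::t.test()] returning a flat record; a
#' zero-variance difference series is flagged rather than raising.
#'
#' @param a,b Paired value vectors (one entry per pair).
#' @return List with `t`, `df`, `p`, `mean_diff`, `flag`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    return(list(t = if (mean(d) == 0) 0 else NA_real_,
                df = length(d) - 1,
                p = if (mean(d) == 0) 1 else NA_real_,
                mean_diff = mean(d), flag = "zero_variance"))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), flag = "ok")
}
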