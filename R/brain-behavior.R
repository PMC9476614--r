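# Trial-level brain-behavior models: behavioral synchrony predicted from
# windowed PLV with a pair-level random intercept, assessed against an
# intercept-only null with the same random structure.

.skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x); s <- sd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

# |skewness| > 1 selects a variance-stabilizing transform: log for
# strictly positive data, square root for non-negative data.
.auto_transform <- function(x) {
  sk <- .skewness(x)
  if (is.na(sk) || abs(sk) <= 1) return(list(fun = identity, name = "none"))
  if (all(x > 0, na.rm = TRUE)) return(list(fun = log, name = "log"))
  if (all(x >= 0, na.rm = TRUE)) return(list(fun = sqrt, name = "sqrt"))
  list(fun = identity, name = "none")
}

.bb_frame <- function(table, outcome, predictor, group) {
  stopifnot(all(c(outcome, predictor, group) %in% names(table)))
  df <- data.frame(y = table[[outcome]], x = table[[predictor]],
                   g = factor(table[[group]]))
  df <- df[is.finite(df$y) & is.finite(df$x), ]
  if (nrow(df) < 10) stop("need at least 10 finite trials")
  df
}

#' Linear mixed model: behavior ~ PLV + (1 | pair)
#'
#' Fits the PLV slope with a pair random intercept (ML), reports the
#' fixed-effect estimate with Wald statistics, and assesses the model by
#' a likelihood-ratio test against the intercept-only null with the same
#' random structure. Outcomes with |skewness| > 1 are log- (strictly
#' positive data) or square-root-transformed first; the choice is
#' recorded in the output. With a single group the model degenerates to
#' ordinary regression (with a warning); singular random-effect fits are
#' flagged, not dropped.
#'
#' @param table Trial table (e.g. [behavior_trial_table()] joined with a
#'   PLV predictor column).
#' @param outcome,predictor,group Column names.
#' @param transform `"auto"` (default), `"none"`, `"log"` or `"sqrt"`.
#' @return List with `estimate`, `se`, `t`, `p_wald`, `chisq`, `df`,
#'   `p_lr`, `transform`, `singular`, `n_trials`, `n_groups`, `model`.
#' @export
fit_linear_mixed <- function(table, outcome, predictor = "plv",
                             group = "pair", transform = "auto") {
  df <- .bb_frame(table, outcome, predictor, group)
  tr <- if (identical(transform, "auto")) .auto_transform(df$y)
  else list(fun = switch(transform, none = identity, log = log,
                         sqrt = sqrt),
            name = transform)
  df$y <- tr$fun(df$y)
  if (nlevels(df$g) < 2) {
    warning("single pair: fitting ordinary least squares instead of a ",
            "mixed model")
    full <- lm(y ~ x, df)
    null <- lm(y ~ 1, df)
    co <- unname(summary(full)$coefficients["x", ])
    chisq <- as.numeric(2 * (logLik(full) - logLik(null)))
    return(list(estimate = co[1], se = co[2], t = co[3],
                p_wald = co[4], chisq = chisq, df = 1,
                p_lr = pchisq(chisq, 1, lower.tail = FALSE),
                transform = tr$name, singular = NA, n_trials = nrow(df),
                n_groups = 1, model = full))
  }
  full <- lme4::lmer(y ~ x + (1 | g), data = df, REML = FALSE)
  null <- lme4::lmer(y ~ 1 + (1 | g), data = df, REML = FALSE)
  co <- summary(full)$coefficients["x", ]
  lr <- anova(null, full)
  list(estimate = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       t = unname(co["t value"]),
       p_wald = 2 * pnorm(-abs(unname(co["t value"]))),
       chisq = lr$Chisq[2], df = lr$Df[2], p_lr = lr$`Pr(>Chisq)`[2],
       transform = tr$name, singular = lme4::isSingular(full),
       n_trials = nrow(df), n_groups = nlevels(df$g), model = full)
}

#' Logistic mixed model on a median-split outcome
#'
#' Bins a bimodal outcome into two categories by median split (ties go to
#' the lower bin) and fits a binomial generalized mixed model
#' `category ~ PLV + (1 | pair)`, with the same likelihood-ratio
#' null-model comparison as [fit_linear_mixed()].
#'
#' @inheritParams fit_linear_mixed
#' @return List as in [fit_linear_mixed()] (estimates on the logit
#'   scale) plus `median` and `converged`.
#' @export
fit_logistic_mixed <- function(table, outcome, predictor = "plv",
                               group = "pair") {
  df <- .bb_frame(table, outcome, predictor, group)
  med <- median(df$y)
  df$bin <- as.integer(df$y > med)        # ties assigned to the lower bin
  if (length(unique(df$bin)) < 2)
    stop("median split yields a single category")
  conv_msgs <- character(0)
  fit_g <- function(fm) withCallingHandlers(
    lme4::glmer(fm, data = df, family = binomial),
    warning = function(w) {
      conv_msgs <<- c(conv_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  full <- fit_g(bin ~ x + (1 | g))
  null <- fit_g(bin ~ 1 + (1 | g))
  co <- summary(full)$coefficients["x", ]
  lr <- anova(null, full)
  list(estimate = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       t = unname(co["z value"]), p_wald = unname(co["Pr(>|z|)"]),
       chisq = lr$Chisq[2], df = lr$Df[2], p_lr = lr$`Pr(>Chisq)`[2],
       transform = "median_split", singular = lme4::isSingular(full),
       median = med, converged = length(conv_msgs) == 0,
       n_trials = nrow(df), n_groups = nlevels(df$g), model = full)
}
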