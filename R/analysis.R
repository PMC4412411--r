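#' Classify stimulus events as one-shot or incremental
#'
#' One-shot learning events (OS) are stimulus presentations whose
#' model-assigned learning rate is strictly greater than the chosen empirical
#' percentile of all rates (default the 90th); the remaining events are
#' incremental (IC). The threshold uses the linear-interpolation percentile
#' convention (`stats::quantile()` type 7); events tied with the threshold
#' are IC because OS is defined by strict exceedance.
#'
#' @param rates Numeric vector of event learning rates (or a
#'   `model_trajectory`, whose `events$rate` column is used).
#' @param percentile Percentile in (0, 100).
#' @return Object of class `event_classification`: list with `labels`
#'   (factor, `"OS"`/`"IC"`), `threshold`, `percentile`.
#' @export
classify_events <- function(rates, percentile = 90) {
  if (inherits(rates, "model_trajectory")) rates <- rates$events$rate
  if (length(rates) == 0L) stop("no learning rates to classify")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be inside (0, 100)")
  threshold <- unname(stats::quantile(rates, percentile / 100, type = 7))
  labels <- factor(ifelse(rates > threshold, "OS", "IC"),
                   levels = c("IC", "OS"))
  structure(list(labels = labels, threshold = threshold,
                 percentile = percentile),
            class = "event_classification")
}

#' @export
print.event_classification <- function(x, ...) {
  cat("Event classification at the ", x$percentile, "th percentile ",
      "(threshold ", format(x$threshold, digits = 4), "): ",
      sum(x$labels == "OS"), " OS / ", sum(x$labels == "IC"), " IC events\n",
      sep = "")
  invisible(x)
}

#' Classify rounds by predicted occurrence of one-shot learning
#'
#' A round is an OS round if it contains at least one one-shot event and an
#' IC round otherwise. OS rounds are sub-labelled `OS_novel` when an OS event
#' falls on the novel stimulus (stimulus 3) and `OS_familiar` when all its OS
#' events fall on non-novel stimuli.
#'
#' @param events A `model_trajectory` (or its `events` data.frame with
#'   columns `round`, `stimulus`, `rate`).
#' @param classification An [classify_events()] result for those events.
#' @return Data.frame with one row per round: `round`, `label`
#'   (`"OS_round"`/`"IC_round"`), `sublabel` (`"OS_novel"`, `"OS_familiar"`
#'   or `NA`), `n_os_events`.
#' @export
classify_rounds <- function(events, classification = NULL) {
  if (is.null(classification)) classification <- classify_events(
    if (inherits(events, "model_trajectory")) events$events$rate
    else events$rate)
  if (inherits(events, "model_trajectory")) events <- events$events
  os <- classification$labels == "OS"
  out <- do.call(rbind, lapply(split(seq_len(nrow(events)), events$round),
    function(idx) {
      any_os <- any(os[idx])
      on_novel <- any(os[idx] & events$stimulus[idx] == 3L)
      data.frame(round = events$round[idx[1]],
                 label = if (any_os) "OS_round" else "IC_round",
                 sublabel = if (!any_os) NA_character_
                            else if (on_novel) "OS_novel" else "OS_familiar",
                 n_os_events = sum(os[idx]))
    }))
  rownames(out) <- NULL
  out
}

#' One-shot effect index of a round
#'
#' The causal rating for the novel cue minus the mean causal rating of the
#' non-novel cues. Positive values indicate that the novel stimulus is judged
#' the most probable cause of the novel outcome.
#'
#' @param ratings Numeric vector of per-stimulus ratings for one round
#'   (novel stimulus last), or an `os_ratings` data.frame, in which case the
#'   index is computed per round.
#' @param novel_stimulus Index of the novel stimulus (default 3).
#' @return Scalar (vector input) or named per-round vector.
#' @export
one_shot_effect_index <- function(ratings, novel_stimulus = 3L) {
  if (is.data.frame(ratings)) {
    df <- ratings[ratings$outcome_type == "novel", ]
    return(vapply(split(df, df$round), function(d) {
      r <- d$rating[order(d$stimulus)]
      if (length(r) < novel_stimulus || anyNA(r))
        stop("alignment error: missing stimulus rating in a round")
      r[novel_stimulus] - mean(r[-novel_stimulus])
    }, numeric(1)))
  }
  if (anyNA(ratings) || length(ratings) < novel_stimulus)
    stop("alignment error: missing stimulus rating")
  ratings[novel_stimulus] - mean(ratings[-novel_stimulus])
}

#' Validate the one-shot threshold with a Gaussian mixture
#'
#' Fits a two-component univariate Gaussian mixture to a learning-rate
#' distribution and locates the decision boundary between the slow and the
#' rapid component: the point between the component means where the two
#' posterior responsibilities are equal. When the fitted mixture is
#' effectively unimodal (a vanishing weight or merged means), the boundary is
#' flagged as unreliable. Comparing the boundary with the empirical 90th
#' percentile checks that the percentile cut-off separates incremental from
#' one-shot learning.
#'
#' @param rates Numeric vector of learning rates (>= 50 values).
#' @param percentile Reference percentile to report (default 90).
#' @return List with `boundary`, `percentile_value`, `means`, `sds`,
#'   `weights`, `unimodal` flag, and the mclust fit in `fit`.
#' @export
gmm_threshold_check <- function(rates, percentile = 90) {
  if (length(rates) < 50L) stop("need at least 50 rates for a mixture fit")
  fit <- mclust::Mclust(rates, G = 1:2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  out <- list(boundary = NA_real_,
              percentile_value = unname(stats::quantile(rates,
                                                        percentile / 100)),
              unimodal = TRUE, fit = fit)
  if (fit$G < 2L) return(out)   # BIC prefers a single component
  mu <- fit$parameters$mean
  sd <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sd) == 1L) sd <- rep(sd, 2L)
  w <- fit$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; sd <- sd[ord]; w <- w[ord]
  out$means <- mu; out$sds <- sd; out$weights <- w
  ## the two-component solution only separates slow from rapid learning if
  ## the fitted density actually dips between the component means
  grid <- seq(mu[1], mu[2], length.out = 201)
  dens <- w[1] * stats::dnorm(grid, mu[1], sd[1]) +
    w[2] * stats::dnorm(grid, mu[2], sd[2])
  has_dip <- min(dens[-c(1, 201)]) < min(dens[1], dens[201]) * (1 - 1e-8)
  if (min(w) < 0.02 || !has_dip) return(out)
  f <- function(x) log(w[1]) + stats::dnorm(x, mu[1], sd[1], log = TRUE) -
    log(w[2]) - stats::dnorm(x, mu[2], sd[2], log = TRUE)
  ## posterior responsibilities cross between the means of separated modes
  if (f(mu[1]) > 0 && f(mu[2]) < 0) {
    out$boundary <- stats::uniroot(f, c(mu[1], mu[2]))$root
    out$unimodal <- FALSE
  }
  out
}

#' Does learning-rate dispersion forecast uncertainty reduction?
#'
#' Granger-causality check that the variance of learning rates across stimuli
#' (Var L) carries information about the subsequent change in total causal
#' uncertainty (Delta U). For a single pair of series an OLS F-test at the
#' requested lag is used; the Pearson correlation between `Var L` at trial t
#' and `Delta U` at t+1 is reported alongside.
#'
#' @param var_rates Numeric series of per-trial learning-rate variances.
#' @param delta_u Numeric series (same length) of changes in total causal
#'   uncertainty, `U(t+1) - U(t)` aligned so that element t follows
#'   `var_rates[t]`.
#' @param max_lag Lag order of the test (default 1).
#' @return List with `F`, `p`, `correlation`, `lag`.
#' @export
granger_uncertainty_test <- function(var_rates, delta_u, max_lag = 1L) {
  if (length(var_rates) != length(delta_u))
    stop("series must have equal length")
  if (length(var_rates) <= 3L * max_lag)
    stop("series too short for the requested lag")
  if (stats::sd(var_rates) == 0 || stats::sd(delta_u) == 0)
    stop("degenerate (constant) series")
  gt <- lmtest::grangertest(delta_u ~ var_rates, order = max_lag)
  list(F = gt$F[2], p = gt$`Pr(>F)`[2],
       correlation = stats::cor(var_rates, delta_u),
       lag = max_lag)
}

## pooled (panel) lag-1 Granger F-test across many short repetitions:
## rows (one per rep and usable trial) y_t ~ y_{t-1} [+ x_{t-1}], F-test for
## the lagged x term by model comparison. The reported correlation is the
## contemporaneous one between Var(L) at trial t and the uncertainty change
## Delta U produced during trial t (while those rates were in effect).
granger_pooled <- function(var_list, du_list) {
  rows <- do.call(rbind, Map(function(v, d) {
    ## d[t] = U(t+1)-U(t), the change produced during trial t
    t_idx <- 2:length(d)
    data.frame(y = d[t_idx], y1 = d[t_idx - 1L], x1 = v[t_idx - 1L],
               x0 = v[t_idx])
  }, var_list, du_list))
  m0 <- stats::lm(y ~ y1, data = rows)
  m1 <- stats::lm(y ~ y1 + x1, data = rows)
  a <- stats::anova(m0, m1)
  list(F = a$F[2], p = a$`Pr(>F)`[2],
       correlation = stats::cor(rows$x0, rows$y),
       n = nrow(rows))
}

#' Matthews correlation coefficient
#'
#' Agreement between two binary labelings in `[-1, 1]`; returns 0 when either
#' labeling is constant (undefined marginals).
#'
#' @param a,b Binary label vectors of equal length (logical, 0/1, or
#'   two-level factors).
#' @return Scalar MCC.
#' @export
mcc <- function(a, b) {
  if (length(a) != length(b)) stop("alignment error: label lengths differ")
  a <- as.integer(as.factor(a)) - 1L
  b <- as.integer(as.factor(b)) - 1L
  tp <- sum(a == 1 & b == 1); tn <- sum(a == 0 & b == 0)
  fp <- sum(a == 0 & b == 1); fn <- sum(a == 1 & b == 0)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' Build novelty and causal-uncertainty event regressors
#'
#' For every stimulus presentation, records (i) the familiarity/novelty
#' value -- the number of prior encounters of that stimulus within the round
#' (0 at first presentation) -- and (ii) the presented stimulus's causal
#' uncertainty under the model at that event. Their correlation measures how
#' confounded novelty and uncertainty are in a design.
#'
#' @param trajectory A `model_trajectory` from [run_bayes_family()].
#' @return Object of class `regressor_set`: the per-event data.frame
#'   (`novelty`, `uncertainty`, plus event identifiers) and
#'   `cross_correlation`.
#' @export
build_regressors <- function(trajectory) {
  ev <- trajectory$events
  structure(list(events = ev[, c("round", "trial", "position", "stimulus",
                                 "novelty", "uncertainty")],
                 cross_correlation = stats::cor(ev$novelty, ev$uncertainty)),
            class = "regressor_set")
}

#' @export
print.regressor_set <- function(x, ...) {
  cat("Regressor set:", nrow(x$events), "stimulus events;",
      "novelty-uncertainty correlation",
      format(x$cross_correlation, digits = 3), "\n")
  invisible(x)
}
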