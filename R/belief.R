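#' Dirichlet belief over candidate causes
#'
#' A belief about which stimulus causes a given outcome type is a Dirichlet
#' distribution over the candidate causes, parameterised by a nonnegative
#' concentration vector `alpha`. Its mean is the causal strength (probability
#' that each stimulus is the cause) and its variance the causal uncertainty.
#'
#' @param prior Nonnegative concentration vector, one entry per candidate
#'   cause. The default of 1 per stimulus is the uniform prior consistent with
#'   the worked two-cue example in which nine observations of the first cue
#'   and one of the second yield a posterior mean of 0.83 for the first.
#' @return An object of class `dirichlet_belief`.
#' @export
dirichlet_belief <- function(prior = c(1, 1, 1)) {
  if (any(prior < 0)) stop("concentrations must be nonnegative")
  structure(list(alpha = as.numeric(prior), prior = as.numeric(prior)),
            class = "dirichlet_belief")
}

#' Posterior mean and variance of a Dirichlet belief
#'
#' For concentrations `alpha` with total `a0 = sum(alpha)`, the causal
#' strength of stimulus i is `alpha_i / a0` and the causal uncertainty is
#' `alpha_i (a0 - alpha_i) / (a0^2 (a0 + 1))`. The shared normaliser `a0`
#' produces latent inhibition: growth in one stimulus's concentration
#' suppresses the causal strength of the others.
#'
#' @param belief A `dirichlet_belief`, or a bare concentration vector.
#' @return List with components `mean` (sums to 1) and `variance`.
#' @export
posterior_stats <- function(belief) {
  alpha <- if (inherits(belief, "dirichlet_belief")) belief$alpha else belief
  a0 <- sum(alpha)
  if (a0 <= 0) stop("degenerate belief: all concentrations are zero")
  list(mean = alpha / a0,
       variance = alpha * (a0 - alpha) / (a0^2 * (a0 + 1)))
}

#' Softmax allocation of learning rates
#'
#' Converts per-stimulus causal uncertainties (or any modulating signal) into
#' learning rates via a softmax with inverse temperature `tau`:
#' `w_i = exp(tau v_i) / sum_j exp(tau v_j)`. The effective rate is
#' `gamma_i = gamma0 * n * w_i`, so that when all inputs are equal every
#' stimulus learns at exactly the baseline rate `gamma0`, and the baseline
#' model (constant rate) is nested at `tau = 0`. Stabilised by max
#' subtraction, so weights are invariant to adding a constant to all inputs
#' and never overflow.
#'
#' @param variances Numeric vector of modulating values (finite).
#' @param tau Inverse temperature (>= 0); 0 gives uniform weights.
#' @param gamma0 Baseline learning rate (>= 0).
#' @return List with `weights` (sum to 1) and `rates` (`gamma0 * n * weights`).
#' @export
softmax_learning_rates <- function(variances, tau, gamma0 = 1) {
  if (tau < 0 || gamma0 < 0) stop("tau and gamma0 must be nonnegative")
  z <- tau * variances
  z <- z - max(z)
  w <- exp(z)
  w <- w / sum(w)
  list(weights = w, rates = gamma0 * length(w) * w)
}

#' Update a Dirichlet belief from one trial
#'
#' Applies the trial-end update `delta_i = gamma_i * (x_i + dp*[first event is
#' S_i] + dr*[last event is S_i])`, added to the belief when the trial's
#' outcome matches the belief's outcome type (`congruent = TRUE`) and
#' subtracted otherwise. Salience `x_i` is the within-trial presentation count
#' (additive subtype) or a presence indicator (sole subtype). Concentrations
#' are floored at zero: a stimulus whose concentration reaches zero stays
#' there until it receives a positive update, i.e. the model stops learning
#' once no causal uncertainty remains.
#'
#' @param belief A `dirichlet_belief`.
#' @param trial_events Integer vector of the stimuli presented in the trial,
#'   in presentation order.
#' @param congruent Does the delivered outcome match this belief's outcome
#'   type?
#' @param rates Per-stimulus learning-rate vector (nonnegative), computed from
#'   the belief state at the end of the previous trial.
#' @param subtype `"additive"` or `"sole"`.
#' @param delta_p,delta_r Primacy and recency weights: extra update credit for
#'   the first and last stimulus of the trial.
#' @return The updated `dirichlet_belief`.
#' @export
dirichlet_update <- function(belief, trial_events, congruent, rates,
                             subtype = c("additive", "sole"),
                             delta_p = 0, delta_r = 0) {
  subtype <- match.arg(subtype)
  if (any(rates < 0)) stop("learning rates must be nonnegative")
  k <- length(belief$alpha)
  x <- tabulate(trial_events, nbins = k)
  if (subtype == "sole") x <- as.numeric(x > 0)
  bonus <- numeric(k)
  bonus[trial_events[1L]] <- bonus[trial_events[1L]] + delta_p
  n_ev <- length(trial_events)
  bonus[trial_events[n_ev]] <- bonus[trial_events[n_ev]] + delta_r
  delta <- rates * (x + bonus)
  sign <- if (isTRUE(congruent)) 1 else -1
  belief$alpha <- pmax(belief$alpha + sign * delta, 0)
  belief
}
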