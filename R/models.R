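#' Run a Dirichlet causal-inference learner over a task
#'
#' The learner maintains one Dirichlet belief per outcome type over the three
#' candidate-cause stimuli (prior concentration 1 each). At every stimulus
#' presentation it reads out a learning rate from the belief state at the end
#' of the previous trial; at every trial outcome it updates both beliefs with
#' the same rates: the belief for the delivered outcome type receives a
#' positive update, the other a negative one, both floored at zero.
#' Variants differ only in how rates are allocated:
#' \describe{
#'   \item{Bayes}{constant rate `gamma0` for every stimulus;}
#'   \item{BayesM}{softmax over causal strength (posterior mean);}
#'   \item{BayesU}{softmax over causal uncertainty (posterior variance) --
#'     the causal-uncertainty model: the stimulus whose causal status is
#'     least resolved learns fastest, producing one-shot learning.}
#' }
#' Rates, predicted ratings and uncertainty traces are read from the belief
#' about the *novel* outcome, the association the task asks for.
#'
#' @param task An `os_task` (or a single `os_round`).
#' @param variant `"Bayes"`, `"BayesM"` or `"BayesU"`.
#' @param params Named vector with `gamma0`, `tau` (ignored for Bayes),
#'   `delta_p`, `delta_r`; see [proto_params()].
#' @param subtype `"additive"` or `"sole"` within-trial salience.
#' @param prior Prior concentration vector (default 1 per stimulus).
#' @return An object of class `model_trajectory`: a list with
#'   \describe{
#'     \item{events}{data.frame, one row per stimulus presentation: `round`,
#'       `trial`, `position`, `stimulus`, `rate` (learning rate in effect),
#'       `uncertainty` (the presented stimulus's causal uncertainty),
#'       `novelty` (count of prior encounters of that stimulus in the round);}
#'     \item{trial_rates}{list per round of trials x stimuli rate matrices;}
#'     \item{post_mean, post_var}{list per round of trials x stimuli
#'       post-update posterior statistics (novel-outcome belief);}
#'     \item{total_uncertainty}{rounds x (trials+1) matrix of summed causal
#'       uncertainty, column 1 being the prior state;}
#'     \item{strengths}{rounds x stimuli matrix of final causal strengths.}
#'   }
#' @export
run_bayes_family <- function(task, variant = c("BayesU", "BayesM", "Bayes"),
                             params = proto_params(), subtype = "additive",
                             prior = c(1, 1, 1)) {
  variant <- match.arg(variant)
  if (inherits(task, "os_round"))
    task <- structure(list(rounds = list(task), config = task_config()),
                      class = "os_task")
  sums <- task_summaries(task)
  n_rounds <- length(sums)
  k <- length(prior)
  gamma0 <- params[["gamma0"]]
  tau <- if (variant == "Bayes") 0 else params[["tau"]]
  dp <- params[["delta_p"]]
  dr <- params[["delta_r"]]

  ev_list <- vector("list", n_rounds)
  trial_rates <- post_mean <- post_var <- vector("list", n_rounds)
  total_u <- NULL
  strengths <- matrix(NA_real_, n_rounds, k)

  for (r in seq_len(n_rounds)) {
    s <- sums[[r]]
    nt <- nrow(s$counts)
    if (is.null(total_u)) total_u <- matrix(NA_real_, n_rounds, nt + 1L)
    bel_nov <- dirichlet_belief(prior)   # causes of the novel outcome
    bel_non <- dirichlet_belief(prior)   # causes of the non-novel outcome
    rates_m <- mean_m <- var_m <- matrix(NA_real_, nt, k)
    total_u[r, 1L] <- sum(belief_var(bel_nov))
    seen <- integer(k)
    ev <- data.frame(round = r, trial = s$trial,
                     position = seq_along(s$stimulus),
                     stimulus = s$stimulus, rate = NA_real_,
                     uncertainty = NA_real_, novelty = NA_real_)
    for (tr in seq_len(nt)) {
      v <- belief_var(bel_nov)
      mu <- belief_mean(bel_nov)
      rates <- switch(variant,
        Bayes  = rep(gamma0, k),
        BayesM = softmax_learning_rates(mu, tau, gamma0)$rates,
        BayesU = softmax_learning_rates(v, tau, gamma0)$rates)
      rates_m[tr, ] <- rates
      idx <- which(s$trial == tr)
      stim <- s$stimulus[idx]
      ev$rate[idx] <- rates[stim]
      ev$uncertainty[idx] <- v[stim]
      for (j in seq_along(idx)) {
        ev$novelty[idx[j]] <- seen[stim[j]]
        seen[stim[j]] <- seen[stim[j]] + 1L
      }
      congruent_nov <- s$novel[tr]
      bel_nov <- dirichlet_update(bel_nov, stim, congruent_nov, rates,
                                  subtype, dp, dr)
      bel_non <- dirichlet_update(bel_non, stim, !congruent_nov, rates,
                                  subtype, dp, dr)
      mean_m[tr, ] <- belief_mean(bel_nov)
      var_m[tr, ] <- belief_var(bel_nov)
      total_u[r, tr + 1L] <- sum(var_m[tr, ])
    }
    ev_list[[r]] <- ev
    trial_rates[[r]] <- rates_m
    post_mean[[r]] <- mean_m
    post_var[[r]] <- var_m
    strengths[r, ] <- mean_m[nt, ]
  }
  structure(list(events = do.call(rbind, ev_list),
                 trial_rates = trial_rates,
                 post_mean = post_mean, post_var = post_var,
                 total_uncertainty = total_u,
                 strengths = strengths,
                 variant = variant, params = params, subtype = subtype),
            class = "model_trajectory")
}

## degenerate-safe readouts used inside trajectories: an all-zero belief has
## nothing left to learn -- strength and uncertainty are reported as zero
belief_mean <- function(b) {
  a0 <- sum(b$alpha)
  if (a0 <= 0) numeric(length(b$alpha)) else b$alpha / a0
}
belief_var <- function(b) {
  a0 <- sum(b$alpha)
  if (a0 <= 0) return(numeric(length(b$alpha)))
  b$alpha * (a0 - b$alpha) / (a0^2 * (a0 + 1))
}

#' @export
print.model_trajectory <- function(x, ...) {
  cat("Trajectory of", x$variant, "(", x$subtype, "):",
      nrow(x$strengths), "rounds,", nrow(x$events), "stimulus events\n")
  cat("params:", paste(names(x$params), signif(unlist(x$params), 3),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Rescorla-Wagner associative model
#'
#' Delta-rule learner: `V(t+1) = V(t) + salience * gamma0 * (lambda -
#' V_total(t))` for every stimulus presented in the trial, where `lambda` is
#' the delivered outcome's magnitude normalised by the largest magnitude in
#' the round (so the novel -50 outcome gives `lambda = 1` and the +10
#' non-novel outcome `lambda = 0.2`, and learning rates live in `[0, 1]`),
#' and `V_total` the summed pre-trial associative strength of the presented
#' stimuli. The learning rate is constant; salience grows with repeated
#' presentation, `min(1, sal_c * cumulative count)`. Predicted causal ratings
#' are `V` clipped to `[0, 1]`: stimuli whose associative strength tracks the
#' large novel outcome are rated its probable cause.
#'
#' @param rsum A round summary (internal) or `os_round`.
#' @param params Named vector `gamma0`, `sal_c`, `delta_p`, `delta_r`.
#' @param subtype `"additive"` or `"sole"`.
#' @return List with `V` (final strengths) and `V_by_trial`.
#' @keywords internal
rw_round <- function(rsum, params, subtype = "additive") {
  assoc_round(rsum, params, subtype, model = "RW")
}

#' @keywords internal
ph_round <- function(rsum, params, subtype = "additive") {
  assoc_round(rsum, params, subtype, model = "PH")
}

## shared associative machinery for RW and PH; lambda is the delivered
## outcome's |magnitude| normalised by the round's largest magnitude, so V
## and the Pearce-Hall surprise rate |lambda - V_total| live on [0, 1]
assoc_round <- function(rsum, params, subtype, model) {
  if (inherits(rsum, "os_round")) rsum <- round_summary(rsum)
  nt <- nrow(rsum$counts)
  k <- ncol(rsum$counts)
  gamma0 <- params[["gamma0"]]
  sal_c <- params[["sal_c"]]
  dp <- if ("delta_p" %in% names(params)) params[["delta_p"]] else 0
  dr <- if ("delta_r" %in% names(params)) params[["delta_r"]] else 0
  V <- numeric(k)
  V_by_trial <- matrix(NA_real_, nt, k)
  cum <- numeric(k)
  gamma_ph <- 1                       # Pearce-Hall: initial surprise maximal
  for (tr in seq_len(nt)) {
    x <- rsum$counts[tr, ]
    u <- if (subtype == "sole") as.numeric(x > 0) else as.numeric(x)
    u[rsum$first[tr]] <- u[rsum$first[tr]] + dp
    u[rsum$last[tr]] <- u[rsum$last[tr]] + dr
    pres <- x > 0
    lambda <- rsum$lambda[tr]
    Vtot <- sum(V[pres])
    cum <- cum + x
    sal <- pmin(1, sal_c * cum)
    if (model == "RW") {
      V <- V + pres * sal * u * gamma0 * (lambda - Vtot)
    } else {                          # PH: rate from the last trial's surprise
      V <- V + pres * sal * u * gamma0 * gamma_ph * lambda
      gamma_ph <- min(abs(lambda - Vtot), 1)  # prediction held at that trial
    }
    V_by_trial[tr, ] <- V
  }
  list(V = V, V_by_trial = V_by_trial)
}

#' Probabilistic contrast estimate for one round
#'
#' Computes `deltaP_i = P(E | C_i) - P(E | not C_i)` across the trials of a
#' round, where E is delivery of the novel outcome and C_i presence of
#' stimulus i (additive subtype weights trials by within-trial presentation
#' count). Conditionals with an empty conditioning set contribute 0.
#'
#' @param rsum A round summary or `os_round`.
#' @param subtype `"additive"` or `"sole"`.
#' @return Numeric vector of per-stimulus contrasts in `[-1, 1]`.
#' @export
pcm_estimate <- function(rsum, subtype = "additive") {
  if (inherits(rsum, "os_round")) rsum <- round_summary(rsum)
  k <- ncol(rsum$counts)
  w <- if (subtype == "sole") (rsum$counts > 0) * 1 else rsum$counts
  out <- numeric(k)
  for (i in seq_len(k)) {
    with_i <- w[, i]
    without_i <- as.numeric(with_i == 0)
    p_with <- if (sum(with_i) > 0) sum(with_i * rsum$novel) / sum(with_i) else 0
    p_without <- if (sum(without_i) > 0)
      sum(without_i * rsum$novel) / sum(without_i) else 0
    out[i] <- p_with - p_without
  }
  out
}

#' Heuristic causal-judgment ratings
#'
#' The post-hoc heuristic rater: in a type2 round (novel cue paired with the
#' novel outcome) the novel stimulus is rated from DiscreteUniform{6..10} and
#' non-novel stimuli from DiscreteUniform{0..5}; in a type1 round every
#' stimulus is rated from DiscreteUniform{0..10}.
#'
#' @param round An `os_round` (or its summary).
#' @param seed Optional integer seed.
#' @return Integer rating vector (one per stimulus, 0-10 scale).
#' @export
heuristic_ratings <- function(round, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rt <- if (inherits(round, "os_round")) round$round_type else round$round_type
  if (rt == "type2") {
    c(sample(0:5, 2L, replace = TRUE), sample(6:10, 1L))
  } else {
    sample(0:10, 3L, replace = TRUE)
  }
}

## deterministic expectation of the heuristic rater, on the [0,1] scale
heuristic_expectation <- function(round_type) {
  if (round_type == "type2") c(2.5, 2.5, 8) / 10 else rep(5, 3) / 10
}

#' Prototype parameters for the causal-uncertainty learner
#'
#' Default parameter set used by the simulation suite and as a synthetic
#' generating model: baseline learning rate 0.2, inverse temperature 20,
#' primacy and recency weights 0.35. These are package defaults chosen to
#' produce clear learning-rate modulation on the default task, not estimates
#' from any subject cohort.
#'
#' @param gamma0,tau,delta_p,delta_r Override individual values.
#' @return Named numeric vector.
#' @export
proto_params <- function(gamma0 = 0.2, tau = 20, delta_p = 0.35,
                         delta_r = 0.35) {
  c(gamma0 = gamma0, tau = tau, delta_p = delta_p, delta_r = delta_r)
}

#' The model registry
#'
#' Central catalogue of the nine models compared by the package. Each entry
#' records the free parameters (with the positivity constraints enforced
#' during fitting by a log transform and the boxes from which multi-start
#' initial values are drawn) and whether predictions are stochastic.
#'
#' @return Named list of model descriptors.
#' @export
model_registry <- function() {
  box_pos <- function(lo, hi) list(type = "loguniform", lo = lo, hi = hi)
  box_lin <- function(lo, hi) list(type = "uniform", lo = lo, hi = hi)
  delta_boxes <- list(delta_p = box_lin(-1, 2), delta_r = box_lin(-1, 2))
  list(
    Random = list(par_names = character(0), stochastic = TRUE),
    Heuristic = list(par_names = character(0), stochastic = TRUE),
    BayesStruct = list(par_names = character(0), stochastic = FALSE),
    RW = list(par_names = c("gamma0", "sal_c", "delta_p", "delta_r"),
              positive = c("gamma0", "sal_c"),
              boxes = c(list(gamma0 = box_pos(0.01, 2),
                             sal_c = box_pos(0.01, 2)), delta_boxes),
              stochastic = FALSE),
    PCM = list(par_names = "gamma0", positive = "gamma0",
               boxes = list(gamma0 = box_pos(0.05, 5)), stochastic = FALSE),
    PH = list(par_names = c("gamma0", "sal_c", "delta_p", "delta_r"),
              positive = c("gamma0", "sal_c"),
              boxes = c(list(gamma0 = box_pos(0.01, 2),
                             sal_c = box_pos(0.01, 2)), delta_boxes),
              stochastic = FALSE),
    Bayes = list(par_names = c("gamma0", "delta_p", "delta_r"),
                 positive = "gamma0",
                 boxes = c(list(gamma0 = box_pos(0.01, 2)), delta_boxes),
                 stochastic = FALSE),
    BayesM = list(par_names = c("gamma0", "tau", "delta_p", "delta_r"),
                  positive = c("gamma0", "tau"),
                  boxes = c(list(gamma0 = box_pos(0.01, 2),
                                 tau = box_pos(0.1, 100)), delta_boxes),
                  stochastic = FALSE),
    BayesU = list(par_names = c("gamma0", "tau", "delta_p", "delta_r"),
                  positive = c("gamma0", "tau"),
                  boxes = c(list(gamma0 = box_pos(0.01, 2),
                                 tau = box_pos(0.1, 100)), delta_boxes),
                  stochastic = FALSE)
  )
}

#' Predicted causal strengths for any registered model
#'
#' Returns the model's predicted causal-strength vector (scale `[0, 1]`,
#' comparable to ratings divided by 10) for every round of a task.
#' Stochastic models (Random, Heuristic) draw from the session RNG.
#'
#' @param model Model name; one of `names(model_registry())`.
#' @param task An `os_task`.
#' @param params Named parameter vector (parametric models).
#' @param subtype `"additive"` or `"sole"`.
#' @return Numeric matrix, rounds x stimuli.
#' @export
predict_model <- function(model, task, params = proto_params(),
                          subtype = "additive") {
  reg <- model_registry()
  if (!model %in% names(reg))
    stop("unknown model '", model, "'; registered models: ",
         paste(names(reg), collapse = ", "))
  predict_sums(model, task_summaries(task), params, subtype, task = task)
}

## workhorse behind predict_model, operating on precomputed round summaries.
## expected = TRUE replaces stochastic raters by their expected predictions
## (used for deterministic model evaluation; Random has no meaningful
## expectation-based prediction and is handled analytically in model_sse)
predict_sums <- function(model, sums, params, subtype, expected = FALSE,
                         task = NULL) {
  n <- length(sums)
  k <- ncol(sums[[1]]$counts)
  switch(model,
    Random = matrix(stats::runif(n * k), n, k),
    Heuristic = if (expected) {
      t(vapply(sums, function(s) heuristic_expectation(s$round_type),
               numeric(k)))
    } else {
      t(vapply(sums, function(s) {
        if (s$round_type == "type2")
          c(sample(0:5, 2L, replace = TRUE), sample(6:10, 1L)) / 10
        else sample(0:10, k, replace = TRUE) / 10
      }, numeric(k)))
    },
    BayesStruct = {
      if (is.null(task)) stop("BayesStruct predictions need the task rounds")
      structure_strengths(task)
    },
    RW = ,
    PH = assoc_strengths(sums, model, params, subtype),
    PCM = t(vapply(sums, function(s)
      pmin(pmax(params[["gamma0"]] * pcm_estimate(s, subtype), 0), 1),
      numeric(k))),
    Bayes = ,
    BayesM = ,
    BayesU = bayes_strengths(sums, model, params, subtype))
}

## stack per-round summaries into the flat matrices the compiled loops take
pack_sums <- function(sums) {
  list(counts = do.call(rbind, lapply(sums, `[[`, "counts")),
       firsts = unlist(lapply(sums, `[[`, "first")),
       lasts = unlist(lapply(sums, `[[`, "last")),
       novel = unlist(lapply(sums, `[[`, "novel")),
       lambda = unlist(lapply(sums, `[[`, "lambda")),
       n_rounds = length(sums),
       nt = nrow(sums[[1]]$counts))
}

## fast path for the Dirichlet family: compiled round loop
bayes_strengths <- function(sums, variant, params, subtype,
                            prior = c(1, 1, 1), pk = pack_sums(sums)) {
  bayes_strengths_cpp(pk$counts, pk$firsts, pk$lasts, pk$novel, pk$n_rounds,
                      pk$nt, match(variant, c("Bayes", "BayesM", "BayesU")),
                      params[["gamma0"]],
                      if (variant == "Bayes") 0 else params[["tau"]],
                      params[["delta_p"]], params[["delta_r"]],
                      subtype == "sole", prior)
}

## fast path for the associative pair: compiled round loop, clipped to [0,1]
assoc_strengths <- function(sums, model, params, subtype,
                            pk = pack_sums(sums)) {
  V <- assoc_strengths_cpp(pk$counts, pk$firsts, pk$lasts, pk$lambda,
                           pk$n_rounds, pk$nt, match(model, c("RW", "PH")),
                           params[["gamma0"]], params[["sal_c"]],
                           params[["delta_p"]], params[["delta_r"]],
                           subtype == "sole")
  pmin(pmax(V, 0), 1)
}
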