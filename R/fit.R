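#' Sum-of-squares objective for a causal model
#'
#' The fitting criterion: the sum over rounds and stimulus-outcome pairs of
#' squared differences between the model's causal strengths and the
#' normalized (0-1) ratings. Reaches zero exactly when predictions equal the
#' normalized ratings everywhere, and is invariant to round order.
#'
#' @param model Model name (see [model_registry()]).
#' @param params Named parameter vector.
#' @param task An `os_task`.
#' @param ratings An `os_ratings` data.frame (0-10 integer scale).
#' @param subtype `"additive"` or `"sole"`.
#' @return Nonnegative scalar SSE.
#' @export
objective_sse <- function(model, params, task, ratings,
                          subtype = "additive") {
  R <- ratings_matrix(ratings, length(task$rounds)) / 10
  pred <- predict_model(model, task, params, subtype)
  sum((pred - R)^2)
}

## ratings table -> rounds x stimuli matrix, with alignment checks
ratings_matrix <- function(ratings, n_rounds) {
  df <- as.data.frame(ratings)
  df <- df[df$outcome_type == "novel", ]
  if (!setequal(unique(df$round), seq_len(n_rounds)))
    stop("alignment error: ratings rounds do not match the task's rounds")
  k <- max(df$stimulus)
  m <- matrix(NA_real_, n_rounds, k)
  m[cbind(df$round, df$stimulus)] <- df$rating
  if (anyNA(m))
    stop("alignment error: missing rating for some stimulus-round pair")
  m
}

## deterministic SSE of a model evaluated on a subset of rounds.
## Random is scored by its exact expected SSE under Uniform(0,1) draws;
## Heuristic by its expected ratings; parametric models by their predictions.
model_sse <- function(model, params, sums, R, subtype, struct_pred = NULL) {
  if (model == "Random")
    return(sum(1 / 12 + (0.5 - R)^2))
  pred <- if (model == "BayesStruct") struct_pred
          else predict_sums(model, sums, params, subtype, expected = TRUE)
  sum((pred - R)^2)
}

## closure computing the SSE objective with per-task quantities precomputed
## once (packed round matrices; PCM's parameter-independent contrasts)
make_sse <- function(model, sums, R, subtype, struct_pred = NULL) {
  k <- ncol(R)
  switch(model,
    Random = local({ v <- sum(1 / 12 + (0.5 - R)^2); function(params) v }),
    Heuristic = local({
      pred <- t(vapply(sums, function(s) heuristic_expectation(s$round_type),
                       numeric(k)))
      v <- sum((pred - R)^2)
      function(params) v
    }),
    BayesStruct = local({ v <- sum((struct_pred - R)^2); function(params) v }),
    PCM = local({
      dP <- t(vapply(sums, pcm_estimate, numeric(k), subtype = subtype))
      function(params)
        sum((pmin(pmax(params[["gamma0"]] * dP, 0), 1) - R)^2)
    }),
    RW = ,
    PH = local({
      pk <- pack_sums(sums)
      function(params)
        sum((assoc_strengths(sums, model, params, subtype, pk = pk) - R)^2)
    }),
    Bayes = ,
    BayesM = ,
    BayesU = local({
      pk <- pack_sums(sums)
      function(params)
        sum((bayes_strengths(sums, model, params, subtype, pk = pk) - R)^2)
    }))
}

## natural <-> unconstrained transforms for the optimizer (positivity by log)
to_unconstrained <- function(par, positive) {
  par[positive] <- log(par[positive])
  par
}
to_natural <- function(par, positive) {
  par[positive] <- exp(par[positive])
  par
}

## draw one restart start point from a model's registry boxes
draw_start <- function(entry) {
  vapply(entry$par_names, function(p) {
    b <- entry$boxes[[p]]
    if (b$type == "loguniform") exp(stats::runif(1, log(b$lo), log(b$hi)))
    else stats::runif(1, b$lo, b$hi)
  }, numeric(1))
}

#' Fit a causal learning model to rating data
#'
#' Estimates a model's free parameters by minimising the sum of squared
#' differences between its causal strengths and a subject's normalized causal
#' ratings, using multi-start Nelder-Mead. Positivity constraints (baseline
#' learning rate, inverse temperature, salience constant) are enforced by a
#' log transform; start points are drawn from the registry's loguniform /
#' uniform boxes. Non-parametric models (Random, Heuristic, BayesStruct) have
#' nothing to fit and are simply evaluated.
#'
#' @param model Model name; one of `names(model_registry())`.
#' @param task An `os_task`.
#' @param ratings An `os_ratings` data.frame for one subject.
#' @param subtype `"additive"` or `"sole"` salience subtype.
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Optional integer seed for restart draws.
#' @param extra_starts Optional list of named parameter vectors used as
#'   additional start points (e.g. a previous fit's parameters).
#' @param control Passed to [stats::optim()]; defaults to simplex termination
#'   at `reltol = 1e-6` and at most 2000 iterations per restart.
#' @return An object of class `causal_fit` with components `model`,
#'   `subtype`, `par` (natural scale), `value` (training SSE), `n_obs`,
#'   `restart_values`, `best_restart`, `eval_trace` (objective evaluations of
#'   the winning restart), `task`, `ratings`.
#' @seealso [loocv()], [compare_causal_models()], [predict.causal_fit()]
#' @export
fit_causal_model <- function(model, task, ratings, subtype = "additive",
                             n_restarts = 100L, seed = NULL,
                             extra_starts = NULL,
                             control = list(maxit = 2000, reltol = 1e-6)) {
  reg <- model_registry()
  if (!model %in% names(reg))
    stop("unknown model '", model, "'; registered models: ",
         paste(names(reg), collapse = ", "))
  entry <- reg[[model]]
  sums <- task_summaries(task)
  R <- ratings_matrix(ratings, length(sums)) / 10
  struct_pred <- if (model == "BayesStruct") structure_strengths(task)
  out <- list(model = model, subtype = subtype,
              n_obs = length(R), task = task, ratings = ratings,
              call = match.call())

  if (length(entry$par_names) == 0L) {
    out$par <- NULL
    out$value <- model_sse(model, NULL, sums, R, subtype, struct_pred)
    out$n_restarts <- 0L
    class(out) <- "causal_fit"
    return(out)
  }

  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  positive <- entry$positive
  sse <- make_sse(model, sums, R, subtype)
  trace_env <- new.env(parent = emptyenv())
  fn <- function(u) {
    v <- sse(to_natural(u, positive))
    trace_env$evals <- c(trace_env$evals, v)
    v
  }
  starts <- c(lapply(seq_len(n_restarts), function(i) draw_start(entry)),
              lapply(extra_starts, function(p) p[entry$par_names]))
  best <- NULL
  restart_values <- numeric(length(starts))
  for (i in seq_along(starts)) {
    trace_env$evals <- numeric(0)
    u0 <- to_unconstrained(starts[[i]], positive)
    opt <- suppressWarnings(
      stats::optim(u0, fn, method = "Nelder-Mead", control = control))
    restart_values[i] <- opt$value
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      best$restart <- i
      best$evals <- trace_env$evals
    }
  }
  if (is.null(best)) stop("fit error: all restarts failed")
  out$par <- to_natural(best$par, positive)
  out$value <- best$value
  out$n_restarts <- length(starts)
  out$restart_values <- restart_values
  out$best_restart <- best$restart
  out$eval_trace <- best$evals
  out$convergence <- best$convergence
  class(out) <- "causal_fit"
  out
}

#' @export
print.causal_fit <- function(x, digits = 4, ...) {
  cat("Causal learning model fit:", x$model, "(", x$subtype, ")\n")
  if (!is.null(x$par)) {
    cat("parameters:\n")
    print(round(x$par, digits))
  } else cat("non-parametric model (no fitted parameters)\n")
  cat("training SSE:", format(x$value, digits = digits),
      "over", x$n_obs, "ratings\n")
  invisible(x)
}

#' @export
coef.causal_fit <- function(object, ...) object$par

#' @export
summary.causal_fit <- function(object, ...) {
  pred <- predict(object, type = "strength")
  R <- ratings_matrix(object$ratings, length(object$task$rounds)) / 10
  per_round <- rowSums((pred - R)^2)
  structure(list(fit = object, per_round_sse = per_round,
                 rmse = sqrt(mean((pred - R)^2))),
            class = "summary.causal_fit")
}

#' @export
print.summary.causal_fit <- function(x, ...) {
  print(x$fit)
  cat("RMSE (normalized ratings):", format(x$rmse, digits = 4), "\n")
  cat("per-round SSE quartiles:\n")
  print(stats::quantile(x$per_round_sse))
  invisible(x)
}

#' Predictions from a fitted causal model
#'
#' @param object A `causal_fit`.
#' @param newdata Optional `os_task` (defaults to the training task).
#' @param type `"strength"` for causal strengths in `[0, 1]` or `"rating"`
#'   for the 0-10 scale.
#' @param ... Unused.
#' @return Numeric matrix, rounds x stimuli.
#' @export
predict.causal_fit <- function(object, newdata = NULL,
                               type = c("strength", "rating"), ...) {
  type <- match.arg(type)
  task <- if (is.null(newdata)) object$task else newdata
  sums <- task_summaries(task)
  pred <- if (object$model == "BayesStruct") structure_strengths(task)
          else predict_sums(object$model, sums, object$par, object$subtype,
                            expected = TRUE)
  if (type == "rating") pred <- 10 * pred
  pred
}

#' @export
residuals.causal_fit <- function(object, ...) {
  R <- ratings_matrix(object$ratings, length(object$task$rounds)) / 10
  R - predict(object, type = "strength")
}

#' Simulate rating tables from a fitted model
#'
#' @param object A `causal_fit` (parametric models only).
#' @param nsim Number of rating tables.
#' @param seed Optional integer seed.
#' @param noise_sd Rating-scale Gaussian noise added before rounding.
#' @param ... Unused.
#' @return A list of `os_ratings` data.frames.
#' @export
simulate.causal_fit <- function(object, nsim = 1, seed = NULL,
                                noise_sd = 0.5, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i)
    simulate_ratings(object$task, object$model, object$par,
                     noise_sd = noise_sd, subtype = object$subtype,
                     subject = i))
}

#' @export
plot.causal_fit <- function(x, ...) {
  R <- ratings_matrix(x$ratings, length(x$task$rounds)) / 10
  pred <- predict(x, type = "strength")
  graphics::plot(as.vector(pred), as.vector(R),
                 xlab = "model causal strength",
                 ylab = "normalized causal rating",
                 main = paste("Fit of", x$model), xlim = c(0, 1),
                 ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Leave-one-out cross-validation of a causal model
#'
#' Generalization error with the round as the held-out unit: for each round,
#' the model is refitted on the remaining rounds and its SSE evaluated on the
#' held-out round's rating vector. The previous full-data estimate is always
#' included among the restart start points. Set `unit = "rating"` to hold out
#' single stimulus ratings instead of whole rounds.
#'
#' @param object A `causal_fit`.
#' @param n_restarts Random restarts per fold (in addition to the full-data
#'   parameter start).
#' @param unit Held-out unit: `"round"` (default) or `"rating"`.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return An object of class `causal_loocv`: list with per-fold errors
#'   (`fold_errors`), their mean (`mean_error`), and fold parameters.
#' @export
loocv <- function(object, ...) UseMethod("loocv")

#' @rdname loocv
#' @export
loocv.causal_fit <- function(object, n_restarts = 5L,
                             unit = c("round", "rating"), seed = NULL, ...) {
  unit <- match.arg(unit)
  if (!is.null(seed)) set.seed(seed)
  model <- object$model
  entry <- model_registry()[[model]]
  task <- object$task
  sums <- task_summaries(task)
  n_rounds <- length(sums)
  if (n_rounds < 2L) stop("leave-one-out needs at least 2 rounds")
  R <- ratings_matrix(object$ratings, n_rounds) / 10
  struct_pred <- if (model == "BayesStruct") structure_strengths(task)
  parametric <- length(entry$par_names) > 0L

  fold_fit <- function(train_idx) {
    if (!parametric) return(NULL)
    sse <- make_sse(model, sums[train_idx], R[train_idx, , drop = FALSE],
                    object$subtype)
    fn <- function(u) sse(to_natural(u, entry$positive))
    starts <- c(list(object$par),
                lapply(seq_len(n_restarts), function(i) draw_start(entry)))
    best <- NULL
    for (s in starts) {
      opt <- suppressWarnings(
        stats::optim(to_unconstrained(s, entry$positive), fn,
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-6)))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    to_natural(best$par, entry$positive)
  }

  if (unit == "round") {
    folds <- seq_len(n_rounds)
    fold_errors <- numeric(n_rounds)
    fold_par <- vector("list", n_rounds)
    for (r in folds) {
      par <- fold_fit(setdiff(folds, r))
      fold_par[[r]] <- par
      fold_errors[r] <- model_sse(model, par, sums[r],
                                  R[r, , drop = FALSE], object$subtype,
                                  if (!is.null(struct_pred))
                                    struct_pred[r, , drop = FALSE])
    }
  } else {
    obs <- which(!is.na(R), arr.ind = TRUE)
    fold_errors <- numeric(nrow(obs))
    fold_par <- vector("list", nrow(obs))
    for (j in seq_len(nrow(obs))) {
      Rtrain <- R
      Rtrain[obs[j, 1], obs[j, 2]] <- NA
      ## ratings folds: mask one rating; objective skips missing entries
      fn_par <- if (parametric) {
        fn <- function(u) {
          par <- to_natural(u, entry$positive)
          pred <- if (model == "BayesStruct") struct_pred
                  else predict_sums(model, sums, par, object$subtype,
                                    expected = TRUE)
          sum((pred - Rtrain)^2, na.rm = TRUE)
        }
        starts <- c(list(object$par),
                    lapply(seq_len(n_restarts), function(i) draw_start(entry)))
        best <- NULL
        for (s in starts) {
          opt <- suppressWarnings(
            stats::optim(to_unconstrained(s, entry$positive), fn,
                         method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-6)))
          if (is.null(best) || opt$value < best$value) best <- opt
        }
        to_natural(best$par, entry$positive)
      } else NULL
      fold_par[[j]] <- fn_par
      pred <- if (model == "BayesStruct") struct_pred
              else if (parametric)
                predict_sums(model, sums, fn_par, object$subtype,
                             expected = TRUE)
              else predict_sums(model, sums, NULL, object$subtype,
                                expected = TRUE)
      fold_errors[j] <- if (model == "Random")
        1 / 12 + (0.5 - R[obs[j, 1], obs[j, 2]])^2
      else (pred[obs[j, 1], obs[j, 2]] - R[obs[j, 1], obs[j, 2]])^2
    }
  }
  structure(list(model = model, subtype = object$subtype, unit = unit,
                 fold_errors = fold_errors,
                 mean_error = mean(fold_errors),
                 fold_par = fold_par),
            class = "causal_loocv")
}

#' @export
print.causal_loocv <- function(x, ...) {
  cat("Leave-one-out CV of", x$model, "(", x$subtype, "), unit =", x$unit,
      "\n")
  cat(length(x$fold_errors), "folds; mean held-out SSE:",
      format(x$mean_error, digits = 4), "\n")
  invisible(x)
}

#' Compare causal learning models across synthetic subjects
#'
#' Fits every requested model to every subject's ratings, picks the winning
#' salience subtype (additive vs sole) per subject by training fit, evaluates
#' generalization by round-wise leave-one-out cross-validation, and tests
#' every model pair with a paired two-sided t-test on per-subject mean
#' held-out errors.
#'
#' @param task An `os_task` shared by the subjects.
#' @param rating_sets List of `os_ratings`, one per subject.
#' @param models Character vector of model names.
#' @param subtypes Subtypes to consider for parametric models.
#' @param n_restarts Restarts for the full-data fits.
#' @param cv_restarts Restarts per cross-validation fold.
#' @param seed Optional integer seed.
#' @return Object of class `causal_model_comparison`: `errors`
#'   (subjects x models mean LOOCV error), `winner_subtype`, `pairwise`
#'   (data.frame of paired t-tests), `mean_errors`.
#' @export
compare_causal_models <- function(task, rating_sets,
                                  models = names(model_registry()),
                                  subtypes = c("additive", "sole"),
                                  n_restarts = 10L, cv_restarts = 3L,
                                  seed = NULL) {
  if (length(models) < 2L) stop("need at least two models to compare")
  if (!is.null(seed)) set.seed(seed)
  reg <- model_registry()
  unknown <- setdiff(models, names(reg))
  if (length(unknown)) stop("unknown model(s): ", paste(unknown, collapse = ", "))
  n_sub <- length(rating_sets)
  errors <- matrix(NA_real_, n_sub, length(models),
                   dimnames = list(NULL, models))
  winner <- matrix(NA_character_, n_sub, length(models),
                   dimnames = list(NULL, models))
  for (s in seq_len(n_sub)) {
    for (m in models) {
      parametric <- length(reg[[m]]$par_names) > 0L
      cand <- if (parametric) subtypes else subtypes[1]
      fits <- lapply(cand, function(st)
        fit_causal_model(m, task, rating_sets[[s]], subtype = st,
                         n_restarts = if (parametric) n_restarts else 1L))
      best <- which.min(vapply(fits, `[[`, numeric(1), "value"))
      winner[s, m] <- cand[best]
      errors[s, m] <- loocv(fits[[best]], n_restarts = cv_restarts)$mean_error
    }
  }
  pairs <- utils::combn(models, 2L)
  pairwise <- data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
                         t = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    d <- errors[, pairs[1, i]] - errors[, pairs[2, i]]
    if (stats::sd(d) == 0) {
      pairwise$t[i] <- 0
      pairwise$p[i] <- 1
    } else {
      tt <- stats::t.test(errors[, pairs[1, i]], errors[, pairs[2, i]],
                          paired = TRUE)
      pairwise$t[i] <- unname(tt$statistic)
      pairwise$p[i] <- tt$p.value
    }
  }
  structure(list(errors = errors, winner_subtype = winner,
                 mean_errors = colMeans(errors), pairwise = pairwise),
            class = "causal_model_comparison")
}

#' @export
print.causal_model_comparison <- function(x, ...) {
  cat("Model comparison over", nrow(x$errors), "subjects (mean LOOCV error)\n")
  m <- sort(x$mean_errors)
  print(round(m, 4))
  cat("best model:", names(m)[1], "\n")
  invisible(x)
}

#' @export
plot.causal_model_comparison <- function(x, ...) {
  m <- x$mean_errors
  sem <- apply(x$errors, 2, stats::sd) / sqrt(nrow(x$errors))
  bp <- graphics::barplot(m, ylab = "mean LOOCV error", las = 2,
                          ylim = c(0, max(m + sem) * 1.1), ...)
  graphics::arrows(bp, m - sem, bp, m + sem, angle = 90, code = 3,
                   length = 0.04)
  invisible(x)
}
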