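test_that("the SSE objective matches its definition and symmetries", {
  task <- generate_task(4, seed = 6)
  p <- proto_params()
  pred <- predict_model("BayesU", task, p)
  rs <- ratings_from_matrix(pred)
  expect_equal(objective_sse("BayesU", p, task, rs), 0)

  # constant-1/3 predictions (Bayes at gamma0 = 0) against all-10 ratings
  task1 <- generate_task(2, seed = 1)
  all10 <- ratings_from_matrix(matrix(1, 2, 3))
  p0 <- c(gamma0 = 0, delta_p = 0, delta_r = 0)
  expect_equal(objective_sse("Bayes", p0, task1, all10), 2 * 3 * (2 / 3)^2)

  # invariance to round order
  perm <- c(3, 1, 4, 2)
  task_p <- task
  task_p$rounds <- task$rounds[perm]
  rs_p <- rs
  rs_p$round <- match(rs$round, perm)
  expect_equal(objective_sse("BayesU", p, task_p, rs_p),
               objective_sse("BayesU", p, task, rs))

  # misaligned ratings are rejected
  bad <- rs[rs$round != 2, ]
  expect_error(objective_sse("BayesU", p, task, bad), "alignment")
})

test_that("multi-start fitting recovers a noise-free generating model", {
  task <- generate_task(10, seed = 13)
  truth <- proto_params(gamma0 = 0.25, tau = 30)
  rs <- ratings_from_matrix(predict_model("BayesU", task, truth))
  fit <- fit_causal_model("BayesU", task, rs, n_restarts = 10, seed = 99)
  expect_lt(fit$value, 1e-3)
  expect_s3_class(fit, "causal_fit")

  # more restarts can only improve the best objective (same first start)
  f1 <- fit_causal_model("BayesU", task, rs, n_restarts = 1, seed = 7)
  f3 <- fit_causal_model("BayesU", task, rs, n_restarts = 3, seed = 7)
  expect_lte(f3$value, f1$value)

  # the winning restart's evaluation trace reaches the reported optimum
  expect_equal(min(fit$eval_trace), fit$value)
  expect_true(all(diff(cummin(fit$eval_trace)) <= 0))
})

test_that("fitted-model methods expose the standard modelling interface", {
  task <- generate_task(6, seed = 17)
  rs <- simulate_ratings(task, "BayesU", cohort_params(), noise_sd = 0.5,
                         seed = 3)
  fit <- fit_causal_model("BayesU", task, rs, n_restarts = 5, seed = 5)

  expect_named(coef(fit), c("gamma0", "tau", "delta_p", "delta_r"))
  pred <- predict(fit)
  expect_equal(dim(pred), c(6L, 3L))
  expect_true(all(pred >= 0 & pred <= 1))
  expect_equal(predict(fit, type = "rating"), 10 * pred)
  res <- residuals(fit)
  expect_equal(sum(res^2), fit$value, tolerance = 1e-10)
  sm <- summary(fit)
  expect_length(sm$per_round_sse, 6L)
  expect_output(print(fit), "BayesU")
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2L)
  expect_s3_class(sim[[1]], "os_ratings")
})

test_that("round-wise cross-validation counts folds and never sees the
           held-out round", {
  task <- generate_task(6, seed = 23)
  task$rounds <- task$rounds[1:5]              # a 5-round task: 5 folds
  rs <- simulate_ratings(task, "BayesU", cohort_params(), noise_sd = 0.5,
                         seed = 4)
  fit <- fit_causal_model("BayesU", task, rs, n_restarts = 3, seed = 2)
  cv <- loocv(fit, n_restarts = 1, seed = 31)
  expect_length(cv$fold_errors, 5L)
  expect_true(all(cv$fold_errors >= 0))

  # data-flow check: corrupt only the held-out round's ratings; with the same
  # start point, the fold trained without that round refits identically
  rs2 <- rs
  rs2$rating[rs2$round == 3 & rs2$outcome_type == "novel"] <- c(10, 0, 10)
  fit2 <- fit_causal_model("BayesU", task, rs2, n_restarts = 3, seed = 2)
  fit2$par <- fit$par                       # common warm start for all folds
  cv_a <- loocv(fit, n_restarts = 0, seed = 31)
  cv_b <- loocv(fit2, n_restarts = 0, seed = 31)
  expect_equal(cv_b$fold_par[[3]], cv_a$fold_par[[3]])

  # fewer than two rounds cannot be cross-validated
  one_round <- structure(list(rounds = task$rounds[1], config = task$config),
                         class = "os_task")
  rs1 <- rs[rs$round == 1, ]
  f1 <- fit_causal_model("Heuristic", one_round, rs1)
  expect_error(loocv(f1), "at least 2")
})

test_that("constant models have equal training and cross-validated error", {
  task <- generate_task(6, seed = 29)
  rs <- simulate_ratings(task, "BayesU", cohort_params(), noise_sd = 0.5,
                         seed = 6)
  for (m in c("Heuristic", "Random")) {
    fit <- fit_causal_model(m, task, rs)
    cv <- loocv(fit)
    expect_equal(sum(cv$fold_errors), fit$value, tolerance = 1e-12)
  }
})

test_that("model comparison aligns subjects and degenerate pairs score zero", {
  task <- generate_task(4, seed = 37)
  rsets <- lapply(1:3, function(s)
    simulate_ratings(task, "BayesU", cohort_params(), noise_sd = 0.5,
                     subject = s, seed = s))
  cmp <- compare_causal_models(task, rsets,
                               models = c("Heuristic", "Heuristic"),
                               seed = 1)
  expect_equal(cmp$pairwise$t, 0)
  expect_equal(cmp$pairwise$p, 1)
  expect_error(compare_causal_models(task, rsets, models = "BayesU"),
               "at least two")
  expect_error(compare_causal_models(task, rsets, models = c("BayesU", "Zed")),
               "unknown")
})
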