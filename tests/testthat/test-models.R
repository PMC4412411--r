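test_that("reference and compiled Dirichlet-family paths agree exactly", {
  set.seed(11)
  task <- generate_task(8)
  for (variant in c("Bayes", "BayesM", "BayesU")) {
    for (subtype in c("additive", "sole")) {
      p <- c(gamma0 = stats::runif(1, 0.05, 0.5),
             tau = stats::runif(1, 1, 60),
             delta_p = stats::runif(1, -0.5, 1),
             delta_r = stats::runif(1, -0.5, 1))
      traj <- run_bayes_family(task, variant, p, subtype)
      fast <- predict_model(variant, task, p, subtype)
      expect_equal(traj$strengths, fast, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("reference and compiled associative paths agree exactly", {
  set.seed(12)
  task <- generate_task(6)
  sums <- oneshot:::task_summaries(task)
  for (model in c("RW", "PH")) {
    for (subtype in c("additive", "sole")) {
      p <- c(gamma0 = stats::runif(1, 0.05, 0.8),
             sal_c = stats::runif(1, 0.05, 1),
             delta_p = stats::runif(1, -0.5, 1),
             delta_r = stats::runif(1, -0.5, 1))
      ref <- t(vapply(sums, function(s)
        pmin(pmax(oneshot:::assoc_round(s, p, subtype, model)$V, 0), 1),
        numeric(3)))
      expect_equal(predict_model(model, task, p, subtype), ref,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("the plain Bayes learner keeps a constant learning rate and is
           nested in BayesU at tau = 0 without sequence effects", {
  task <- generate_task(4, seed = 2)
  p <- proto_params(gamma0 = 0.17)
  traj <- run_bayes_family(task, "Bayes", p)
  expect_true(all(traj$events$rate == 0.17))

  p0 <- proto_params(gamma0 = 0.17, tau = 0, delta_p = 0, delta_r = 0)
  pb <- proto_params(gamma0 = 0.17, delta_p = 0, delta_r = 0)
  tu <- run_bayes_family(task, "BayesU", p0)
  tb <- run_bayes_family(task, "Bayes", pb)
  expect_equal(tu$strengths, tb$strengths)
  expect_equal(tu$events$rate, tb$events$rate)
})

test_that("learning rate is monotone in a stimulus's own causal uncertainty", {
  set.seed(33)
  for (i in 1:50) {
    v <- stats::runif(3, 0, 0.2)
    tau <- stats::runif(1, 0, 60)
    r1 <- softmax_learning_rates(v, tau)$rates[1]
    v2 <- v
    v2[1] <- v[1] + stats::runif(1, 0, 0.2)
    r2 <- softmax_learning_rates(v2, tau)$rates[1]
    expect_gte(r2, r1)
  }
})

test_that("trajectories record rates from the pre-trial belief and causal
           strength stays on the simplex", {
  task <- generate_task(6, seed = 8)
  traj <- run_bayes_family(task, "BayesU", proto_params())
  # trial-1 events always see the uniform prior: equal rates at baseline
  t1 <- traj$events[traj$events$trial == 1, ]
  expect_true(all(t1$rate == t1$rate[1]))
  for (r in seq_along(traj$post_mean)) {
    sums <- rowSums(traj$post_mean[[r]])
    expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
    expect_true(all(traj$post_var[[r]] >= 0))
  }
})

test_that("Rescorla-Wagner updates implement the delta rule", {
  p <- c(gamma0 = 0.1, sal_c = 100, delta_p = 0, delta_r = 0)  # salience 1
  # one trial, S1 shown once (sole), novel outcome: V1 = 0.1 * (1 - 0)
  rd <- make_round(list(c(1L, 1L)), "novel")
  out <- oneshot:::assoc_round(oneshot:::round_summary(rd), p, "sole", "RW")
  expect_equal(out$V[1], 0.1)

  # two stimuli sharing a trial update against the same pre-trial V_total
  rd2 <- make_round(list(c(1L, 2L, 2L)), "novel")
  out2 <- oneshot:::assoc_round(oneshot:::round_summary(rd2), p, "additive",
                                "RW")
  expect_equal(out2$V[2] / out2$V[1], 2)  # salience-count proportional

  # lambda = V_total: the error term vanishes, no stimulus changes
  # (drive V1 to lambda over many novel trials, then verify a fixed point)
  p3 <- c(gamma0 = 1, sal_c = 100, delta_p = 0, delta_r = 0)
  rd3 <- make_round(list(1L, 1L), c("novel", "novel"))
  out3 <- oneshot:::assoc_round(oneshot:::round_summary(rd3), p3, "sole", "RW")
  expect_equal(out3$V_by_trial[1, 1], 1)  # reaches lambda after one trial
  expect_equal(out3$V_by_trial[2, 1], 1)  # and stays: zero error term
})

test_that("Pearce-Hall surprise controls the next trial's learning rate", {
  p <- c(gamma0 = 1, sal_c = 100, delta_p = 0, delta_r = 0)
  # trial 1 (novel, lambda 1, initial gamma 1): V1 = 1; the surprise carried
  # into trial 2 is still |1 - 0| = 1 (prediction held at trial 1), so trial
  # 2 learns again; by trial 3 the outcome is fully predicted and gamma = 0
  rd <- make_round(list(1L, 1L, 1L), c("novel", "novel", "novel"))
  out <- oneshot:::assoc_round(oneshot:::round_summary(rd), p, "sole", "PH")
  expect_equal(out$V_by_trial[1, 1], 1)
  expect_equal(out$V_by_trial[2, 1], 2)
  expect_equal(out$V_by_trial[3, 1], 2)  # |lambda - V_total| = 0: no update

  # fully unpredicted outcome keeps the rate maximal: |lambda - 0| = 1
  rd2 <- make_round(list(1L, 2L), c("novel", "novel"))
  out2 <- oneshot:::assoc_round(oneshot:::round_summary(rd2), p, "sole", "PH")
  expect_equal(out2$V_by_trial[1, 1], 1)  # gamma was 1 at trial 1
  expect_equal(out2$V_by_trial[2, 2], 1)  # S2 unseen before, gamma still 1
})

test_that("probabilistic contrasts match their defining conditionals", {
  # S1 present exactly when the novel outcome occurs: deltaP = 1
  rd <- make_round(list(c(1L, 2L), 2L, c(1L, 2L), 2L, 2L),
                   c("novel", "non_novel", "novel", "non_novel", "non_novel"))
  dp <- pcm_estimate(rd, subtype = "sole")
  expect_equal(dp[1], 1)
  # S2 present in every trial: no trials without it, contribution 0
  expect_equal(dp[2], 2 / 5)
  # never-presented stimulus: anticorrelated with the outcome base rate
  expect_equal(dp[3], -2 / 5)

  # outcome independent of the stimulus
  rd2 <- make_round(list(c(1L, 2L), 2L, c(1L, 2L), 2L),
                    c("novel", "novel", "non_novel", "non_novel"))
  expect_equal(pcm_estimate(rd2, subtype = "sole")[1], 0)

  # additive weighting: counts, not presence, enter the conditionals
  rd3 <- make_round(list(c(1L, 1L), 1L), c("novel", "non_novel"))
  expect_equal(pcm_estimate(rd3, subtype = "additive")[1], 2 / 3)
  expect_equal(pcm_estimate(rd3, subtype = "sole")[1], 1 / 2)
})

test_that("heuristic causal judgments respect the round-type ranges", {
  set.seed(5)
  t2 <- make_round(list(1L), "novel", round_type = "type2")
  draws <- t(replicate(2000, heuristic_ratings(t2)))
  expect_true(all(draws[, 3] >= 6 & draws[, 3] <= 10))
  expect_true(all(draws[, 1:2] >= 0 & draws[, 1:2] <= 5))
  expect_equal(mean(draws[, 1:2]), 2.5, tolerance = 0.05)

  t1 <- make_round(list(1L), "novel", round_type = "type1")
  draws1 <- t(replicate(500, heuristic_ratings(t1)))
  expect_true(all(draws1 >= 0 & draws1 <= 10))
})

test_that("the registry rejects unknown models everywhere", {
  task <- generate_task(2, seed = 1)
  expect_error(predict_model("NotAModel", task), "unknown model")
  expect_error(fit_causal_model("NotAModel", task,
                                simulate_ratings(task, seed = 1)),
               "unknown model")
  expect_error(simulate_ratings(task, "NotAModel"), "unknown model")
})
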