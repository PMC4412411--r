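test_that("event classification matches a sorting oracle for the percentile
           threshold", {
  cls <- classify_events(1:20)
  expect_equal(cls$threshold, 18.1)          # linear interpolation
  expect_identical(sum(cls$labels == "OS"), 2L)

  expect_identical(sum(classify_events(rep(3, 50))$labels == "OS"), 0L)
  expect_error(classify_events(numeric(0)), "no learning rates")
  expect_error(classify_events(1:10, percentile = 100), "inside")

  # brute-force oracle: threshold from sorted order statistics
  oracle_threshold <- function(x, p) {
    s <- sort(x)
    h <- (length(x) - 1) * p / 100 + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
  }
  set.seed(101)
  for (i in 1:1000) {
    x <- stats::runif(sample(5:60, 1), 0, sample(c(1, 10, 100), 1))
    p <- stats::runif(1, 5, 95)
    cls <- classify_events(x, p)
    thr <- oracle_threshold(x, p)
    expect_equal(cls$threshold, thr)
    expect_identical(cls$labels == "OS", x > thr)
  }
})

test_that("round classification aggregates one-shot events", {
  ev <- data.frame(round = rep(1:3, each = 3), trial = 1,
                   position = 1:9,
                   stimulus = c(1, 2, 3, 1, 2, 3, 1, 2, 3),
                   rate = c(1, 1, 1,  1, 1, 9,  9, 1, 1))
  cls <- list(labels = factor(ifelse(ev$rate > 5, "OS", "IC"),
                              levels = c("IC", "OS")),
              threshold = 5, percentile = 90)
  rc <- classify_rounds(ev, cls)
  expect_identical(rc$label, c("IC_round", "OS_round", "OS_round"))
  expect_identical(rc$sublabel, c(NA, "OS_novel", "OS_familiar"))
  expect_identical(rc$n_os_events, c(0L, 1L, 1L))
})

test_that("both round types contain OS and IC rounds on simulated cohorts", {
  set.seed(55)
  counts <- matrix(0, 2, 2,
                   dimnames = list(c("type1", "type2"), c("IC", "OS")))
  for (s in 1:6) {
    task <- generate_task(40)
    traj <- run_bayes_family(task, "BayesU", cohort_params())
    rc <- classify_rounds(traj)
    types <- vapply(task$rounds, `[[`, "", "round_type")
    counts <- counts + table(factor(types, c("type1", "type2")),
                             factor(ifelse(rc$label == "OS_round",
                                           "OS", "IC"), c("IC", "OS")))
  }
  expect_true(all(counts > 0))

  # the OS/IC and novel/non-novel partitions are distinct
  task <- generate_task(40, seed = 9)
  traj <- run_bayes_family(task, "BayesU", cohort_params())
  cls <- classify_events(traj)
  novel_event <- traj$events$stimulus == 3L
  expect_lt(mcc(cls$labels == "OS", novel_event), 1)
})

test_that("one-shot effect index is the novel-vs-familiar rating contrast", {
  expect_equal(one_shot_effect_index(c(2, 4, 8)), 5)
  expect_equal(one_shot_effect_index(c(7, 7, 7)), 0)
  expect_error(one_shot_effect_index(c(2, NA, 5)), "alignment")

  df <- data.frame(subject = 1, round = rep(1:2, each = 3),
                   stimulus = rep(1:3, 2), outcome_type = "novel",
                   rating = c(2, 4, 8, 5, 5, 5))
  expect_equal(unname(one_shot_effect_index(df)), c(5, 0))
})

test_that("the mixture boundary validates the percentile threshold", {
  set.seed(71)
  x <- c(stats::rnorm(900, 0.2, 0.05), stats::rnorm(100, 0.8, 0.05))
  chk <- gmm_threshold_check(x)
  expect_false(chk$unimodal)
  expect_gt(chk$boundary, 0.35)
  expect_lt(chk$boundary, 0.65)
  # population values: responsibility crossing at 0.509, 90th percentile at
  # 0.42, a gap of 0.09; allow for the sampling error of both estimates
  expect_lt(abs(chk$boundary - chk$percentile_value), 0.15)

  # affine rescaling moves the boundary with the data
  chk2 <- gmm_threshold_check(3 * x + 2)
  expect_equal(chk2$boundary, 3 * chk$boundary + 2, tolerance = 0.02)

  # a single Gaussian is flagged rather than split
  y <- stats::rnorm(500, 0.4, 0.1)
  expect_true(gmm_threshold_check(y)$unimodal)

  expect_error(gmm_threshold_check(stats::rnorm(20)), "at least 50")
})

test_that("the Granger check detects lagged dependence and keeps the null", {
  set.seed(91)
  x <- as.numeric(stats::arima.sim(list(ar = 0.8), 200))
  y <- c(0, -x[-200]) + stats::rnorm(200, sd = 0.1)
  out <- granger_uncertainty_test(x, y)
  expect_lt(out$p, 1e-4)
  expect_lt(out$correlation, 0)

  null_p <- replicate(100, {
    granger_uncertainty_test(stats::rnorm(100), stats::rnorm(100))$p
  })
  expect_gte(mean(null_p > 0.01), 0.95)

  expect_error(granger_uncertainty_test(rep(1, 50), stats::rnorm(50)),
               "degenerate")
  expect_error(granger_uncertainty_test(1:3, 1:4), "equal length")
})

test_that("Matthews correlation behaves at its reference points", {
  a <- c(1, 0, 1, 1, 0, 0)
  expect_equal(mcc(a, a), 1)
  expect_equal(mcc(a, 1 - a), -1)
  expect_equal(mcc(rep(1, 6), a), 0)
  set.seed(13)
  expect_lt(abs(mcc(sample(0:1, 1e4, TRUE), sample(0:1, 1e4, TRUE))), 0.05)
  expect_error(mcc(a, a[-1]), "alignment")
})

test_that("novelty and uncertainty regressors are built per event", {
  task <- generate_task(4, seed = 3)
  traj <- run_bayes_family(task, "BayesU", proto_params())
  reg <- build_regressors(traj)
  ev <- reg$events
  # first presentation of each stimulus in a round has novelty 0
  for (r in unique(ev$round)) for (s in 1:3) {
    rows <- ev[ev$round == r & ev$stimulus == s, ]
    if (nrow(rows)) expect_equal(rows$novelty[1], 0)
  }
  # the 16th presentation of stimulus 1 has seen 15 prior ones
  s1 <- ev[ev$round == 1 & ev$stimulus == 1, ]
  expect_equal(s1$novelty, 0:15)
  expect_true(is.finite(reg$cross_correlation))

  # with the cohort prototype parameters, novelty and uncertainty carry
  # separable information (the design decorrelates them)
  set.seed(19)
  cors <- replicate(5, {
    tk <- generate_task(40)
    abs(build_regressors(run_bayes_family(tk, "BayesU",
                                          cohort_params()))$cross_correlation)
  })
  # the two regressors share roughly a quarter of their variance here --
  # informative but far from collinear (observed mean |r| near 0.50)
  expect_lt(mean(cors), 0.6)
  expect_gt(mean(cors), 0.1)
})
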