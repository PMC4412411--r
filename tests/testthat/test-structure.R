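# small binary fixtures built in code
coupled_data <- function(n = 20) {
  a <- rep(c(0L, 1L), length.out = n)
  cbind(A = a, B = a)                      # B perfectly tracks A
}

independent_data <- function(n = 20, seed = 1) {
  set.seed(seed)
  cbind(A = sample(0:1, n, TRUE), B = sample(0:1, n, TRUE))
}

test_that("BDeu scoring prefers the data-generating structure", {
  d <- independent_data(20)
  empty <- graph_marginal_likelihood(matrix(character(0), 0, 2), d)
  edge <- graph_marginal_likelihood(cbind("A", "B"), d)
  expect_gt(empty, edge)

  dc <- coupled_data(20)
  post <- exact_structure_posterior(dc, allowed = NULL)
  linked <- vapply(post$graphs, function(e) nrow(e) > 0, logical(1))
  expect_gt(sum(post$prob[linked]), 0.9)

  # a single-node graph scores as the bare Dirichlet-multinomial of counts
  d1 <- cbind(A = c(1L, 1L, 0L, 1L))
  expect_equal(graph_marginal_likelihood(matrix(character(0), 0, 2), d1),
               oneshot:::bdeu_family_score(d1, "A", character(0)))

  cyc <- cbind(c("A", "B"), c("B", "A"))
  expect_error(graph_marginal_likelihood(cyc, d), "acyclic")
})

test_that("exact enumeration produces a normalized posterior with the true
           edge dominant", {
  set.seed(8)
  n <- 30
  a <- sample(0:1, n, TRUE)
  b <- ifelse(stats::runif(n) < 0.9, a, 1L - a)   # A -> B, strong
  c_ <- sample(0:1, n, TRUE)
  d <- cbind(A = a, B = b, C = c_)
  post <- exact_structure_posterior(d, allowed = NULL)
  expect_length(post$prob, 25L)                    # all 3-node DAGs
  expect_equal(sum(post$prob), 1, tolerance = 1e-12)
  marg <- post$edge_marginals
  ab <- max(marg["A", "B"], marg["B", "A"])        # direction not identifiable
  expect_true(ab >= max(marg[cbind(c("A","A","B","C","C"),
                                   c("C","C","C","A","B"))]))

  d1 <- cbind(A = c(0L, 1L, 1L))
  p1 <- exact_structure_posterior(d1, allowed = NULL)
  expect_equal(p1$prob, 1)
})

test_that("MCMC structure sampling converges to the exact posterior", {
  set.seed(8)
  n <- 30
  a <- sample(0:1, n, TRUE)
  b <- ifelse(stats::runif(n) < 0.9, a, 1L - a)
  d <- cbind(A = a, B = b, C = sample(0:1, n, TRUE))
  exact <- exact_structure_posterior(d, allowed = NULL)
  mc <- mcmc_structure_posterior(d, burn_in = 2000, n_samples = 1e5,
                                 allowed = NULL, seed = 1)
  expect_lt(structure_tv_distance(exact, mc), 0.05)

  mc2 <- mcmc_structure_posterior(d, burn_in = 2000, n_samples = 1e5,
                                  allowed = NULL, seed = 2)
  expect_lt(max(abs(mc$edge_marginals - mc2$edge_marginals)), 0.03)

  d1 <- cbind(A = c(0L, 1L, 1L))
  m1 <- mcmc_structure_posterior(d1, burn_in = 10, n_samples = 100,
                                 allowed = NULL, seed = 3)
  expect_equal(unname(m1$prob), 1)   # only the empty graph exists

  expect_error(mcmc_structure_posterior(d, burn_in = 0, n_samples = 10),
               "positive")
})

test_that("structure ratings rescale edge marginals onto the rating scale", {
  task <- generate_task(2, seed = 4)
  d <- round_trial_data(task$rounds[[1]])
  expect_identical(colnames(d), c("S1", "S2", "S3", "O_non", "O_nov"))
  post <- exact_structure_posterior(d)
  r <- structure_ratings(post)
  expect_true(all(r >= 0 & r <= 10))

  # perfectly coupled pair dominates the ratings
  dc <- cbind(S1 = c(1L,0L,1L,0L,1L,0L,1L,0L), S2 = rep(1L, 8),
              O_nov = c(1L,0L,1L,0L,1L,0L,1L,0L))
  pc <- exact_structure_posterior(dc)
  rc <- structure_ratings(pc, outcome = "O_nov")
  expect_gt(rc["S1"], rc["S2"])
})

test_that("the regularity spectrum separates repeated from random structure", {
  same <- matrix(rep(c(0.9, 0.1, 0.5, 0.2, 0.8, 0.3), each = 40), nrow = 40)
  expect_equal(regularity_analysis(same)$top1, 1)

  set.seed(14)
  rand <- matrix(stats::runif(240), 40, 6)
  expect_lt(regularity_analysis(rand)$top1, 0.35)

  base <- outer(stats::runif(40), stats::runif(6))
  noisy <- base + matrix(stats::rnorm(240, sd = 0.01), 40)
  expect_gt(regularity_analysis(noisy)$top1, 0.9)

  expect_error(regularity_analysis(rand[1:2, ]), "3 rounds")
})

test_that("graphs and posteriors serialize to edge-list JSON and CSV", {
  g <- cbind(from = c("S1", "O_non"), to = c("O_nov", "O_nov"))
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, path)
  expect_equal(read_graph_json(path), g, ignore_attr = TRUE)

  empty <- matrix(character(0), 0, 2)
  write_graph_json(empty, path)
  expect_identical(nrow(read_graph_json(path)), 0L)

  d <- coupled_data(10)
  post <- exact_structure_posterior(d, allowed = NULL)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_posterior_csv(post, cpath)
  back <- utils::read.csv(cpath)
  expect_equal(back$probability, post$prob, tolerance = 1e-12)
})
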