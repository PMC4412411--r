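# shared fixtures for the test suite; everything is generated in code

# generating parameters used for synthetic cohorts in the event-level and
# model-comparison experiments (see the methods vignette for the calibration
# of tau against the reported round-composition statistics)
cohort_params <- function() proto_params(gamma0 = 0.2, tau = 50,
                                         delta_p = 0.35, delta_r = 0.35)

# Dirichlet sampler built from gammas; the Monte-Carlo oracle for posterior
# moments, independent of the closed-form path under test
rdirichlet_oracle <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g / rowSums(g)
}

# hand-built round: stimuli per trial (list of integer vectors) and outcome
# labels, bypassing the task generator so degenerate designs can be tested
make_round <- function(stimuli, outcomes,
                       magnitudes = c(non_novel = 10, novel = -50),
                       round_type = "type1") {
  structure(list(stimulus = unlist(stimuli),
                 trial = rep(seq_along(stimuli), lengths(stimuli)),
                 outcome = outcomes,
                 magnitudes = magnitudes,
                 round_type = round_type),
            class = "os_round")
}

# ratings data.frame from a strengths matrix (possibly non-integer), used
# where exact prediction-rating identities are needed
ratings_from_matrix <- function(m, subject = 1L) {
  df <- data.frame(subject = subject,
                   round = rep(seq_len(nrow(m)), ncol(m)),
                   stimulus = rep(seq_len(ncol(m)), each = nrow(m)),
                   outcome_type = "novel",
                   rating = as.vector(m) * 10)
  class(df) <- c("os_ratings", "data.frame")
  df
}
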