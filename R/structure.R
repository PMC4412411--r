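#' Trial-level binary data for structure learning
#'
#' Encodes a round as a trials x nodes binary matrix over five nodes: presence
#' of each stimulus in the trial and indicators for delivery of the non-novel
#' and the novel outcome.
#'
#' @param round An `os_round`.
#' @return Integer matrix with columns `S1`, `S2`, `S3`, `O_non`, `O_nov`.
#' @export
round_trial_data <- function(round) {
  s <- round_summary(round)
  m <- cbind(s$presence * 1L,
             O_non = as.integer(!s$novel),
             O_nov = as.integer(s$novel))
  colnames(m) <- c("S1", "S2", "S3", "O_non", "O_nov")
  m
}

#' Default admissible edges for causal-structure learning
#'
#' Stimuli may cause outcomes, and outcomes may cause each other; edges into
#' stimuli are excluded (stimuli are experimenter-controlled roots).
#'
#' @param nodes Character vector of node names (`S*` stimuli, `O*` outcomes).
#' @return Two-column character matrix of (from, to) pairs.
#' @export
default_edge_set <- function(nodes = c("S1", "S2", "S3", "O_non", "O_nov")) {
  is_outcome <- grepl("^O", nodes)
  from <- rep(nodes, times = length(nodes))
  to <- rep(nodes, each = length(nodes))
  keep <- from != to & is_outcome[match(to, nodes)]
  cbind(from = from[keep], to = to[keep])
}

## ---- BDeu scoring --------------------------------------------------------

## log marginal likelihood of one binary node given a parent set
## (Dirichlet-multinomial, equivalent sample size spread uniformly over the
## parent-configuration x state table)
bdeu_family_score <- function(data, node, parents, ess = 1) {
  n <- nrow(data)
  if (length(parents) == 0L) {
    config <- rep(1L, n)
    q <- 1L
  } else {
    pm <- data[, parents, drop = FALSE]
    config <- as.integer(pm %*% 2^(seq_along(parents) - 1L)) + 1L
    q <- 2L^length(parents)
  }
  a_pc <- ess / q
  a_pcs <- ess / (2 * q)
  score <- 0
  x <- data[, node]
  for (c in unique(config)) {
    idx <- config == c
    n1 <- sum(x[idx])
    n0 <- sum(idx) - n1
    score <- score + lgamma(a_pc) - lgamma(a_pc + n0 + n1) +
      lgamma(a_pcs + n1) - lgamma(a_pcs) +
      lgamma(a_pcs + n0) - lgamma(a_pcs)
  }
  ## parent configurations never observed contribute 0
  score
}

#' BDeu marginal likelihood of a causal graph
#'
#' Dirichlet-multinomial (BDeu) log marginal likelihood of a trial table
#' under a directed acyclic graph, decomposed over node families.
#'
#' @param graph Adjacency matrix (rows = from, cols = to) over the columns of
#'   `data`, or a two-column (from, to) edge matrix of node names.
#' @param data Binary trials x nodes matrix, as from [round_trial_data()].
#' @param ess Equivalent sample size of the BDeu prior.
#' @return Log marginal likelihood (scalar).
#' @export
graph_marginal_likelihood <- function(graph, data, ess = 1) {
  adj <- as_adjacency(graph, colnames(data))
  if (has_cycle(adj)) stop("graph must be acyclic")
  nodes <- colnames(data)
  sum(vapply(seq_along(nodes), function(j) {
    bdeu_family_score(data, nodes[j], nodes[adj[, j] == 1L], ess)
  }, numeric(1)))
}

as_adjacency <- function(graph, nodes) {
  n <- length(nodes)
  if (is.matrix(graph) && nrow(graph) == n && ncol(graph) == n &&
      !is.character(graph))
    return(graph != 0)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (length(graph)) {
    graph <- matrix(graph, ncol = 2L)
    adj[cbind(match(graph[, 1], nodes), match(graph[, 2], nodes))] <- TRUE
  }
  adj
}

has_cycle <- function(adj) {
  ## reachability by repeated squaring on a <=5 node matrix
  n <- nrow(adj)
  reach <- adj
  for (i in seq_len(n)) reach <- reach | (reach %*% adj) > 0
  any(diag(reach))
}

## enumerate all acyclic subsets of an allowed edge list by branching on each
## edge and pruning branches that would close a cycle (supersets of a cyclic
## edge set are cyclic, so pruning is exact)
enumerate_dags <- function(nodes, allowed = NULL) {
  n <- length(nodes)
  if (is.null(allowed)) {
    from <- rep(seq_len(n), times = n)
    to <- rep(seq_len(n), each = n)
    keep <- from != to
    allowed <- cbind(from[keep], to[keep])
  } else {
    allowed <- cbind(match(allowed[, 1], nodes), match(allowed[, 2], nodes))
  }
  m <- nrow(allowed)
  out <- vector("list", 0L)
  recurse <- function(i, reach, edges) {
    if (i > m) {
      out[[length(out) + 1L]] <<- edges
      return(invisible(NULL))
    }
    recurse(i + 1L, reach, edges)                     # edge absent
    u <- allowed[i, 1L]; v <- allowed[i, 2L]
    if (!reach[v, u]) {                               # adding u->v keeps DAG
      r2 <- reach
      ## new reachabilities: anything reaching u now reaches all v reaches
      src <- which(r2[, u] | seq_len(n) == u)
      dst <- which(r2[v, ] | seq_len(n) == v)
      r2[src, dst] <- TRUE
      recurse(i + 1L, r2, rbind(edges, allowed[i, ]))
    }
  }
  recurse(1L, matrix(FALSE, n, n), matrix(integer(0), 0L, 2L))
  out
}

#' Exact posterior over causal graph structures
#'
#' Enumerates every directed acyclic graph over the admissible edge set,
#' scores each with the BDeu marginal likelihood under a uniform structure
#' prior, and normalises. Family scores are cached per (node, parent set), so
#' enumeration over the default restricted edge space is immediate. Serves as
#' the ground-truth oracle for the MCMC sampler.
#'
#' @param data Binary trials x nodes matrix ([round_trial_data()]).
#' @param allowed Two-column (from, to) matrix of admissible edges; `NULL`
#'   allows every edge. Defaults to [default_edge_set()] when the column names
#'   follow the task's S/O convention.
#' @param ess BDeu equivalent sample size.
#' @return Object of class `structure_posterior`: list with `graphs` (edge
#'   lists), `log_score`, `prob`, `edge_marginals` (nodes x nodes matrix) and
#'   `nodes`.
#' @export
exact_structure_posterior <- function(data, allowed = NULL, ess = 1) {
  nodes <- colnames(data)
  if (length(nodes) > 5L) stop("exact enumeration supports at most 5 nodes")
  if (is.null(allowed) && all(grepl("^[SO]", nodes)) && any(grepl("^O", nodes)))
    allowed <- default_edge_set(nodes)
  dags <- enumerate_dags(nodes, allowed)
  ## family-score cache: node x parent-set
  fam <- new.env(parent = emptyenv())
  family_score <- function(node, parents) {
    key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
    val <- fam[[key]]
    if (is.null(val)) {
      val <- bdeu_family_score(data, node, parents, ess)
      fam[[key]] <- val
    }
    val
  }
  log_scores <- vapply(dags, function(edges) {
    sum(vapply(seq_along(nodes), function(j) {
      pa <- if (nrow(edges)) nodes[edges[edges[, 2] == j, 1]] else character(0)
      family_score(nodes[j], pa)
    }, numeric(1)))
  }, numeric(1))
  lw <- log_scores - max(log_scores)
  prob <- exp(lw) / sum(exp(lw))
  marg <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (g in seq_along(dags)) {
    e <- dags[[g]]
    if (nrow(e)) marg[e] <- marg[e] + prob[g]
  }
  structure(list(graphs = dags, log_score = log_scores, prob = prob,
                 edge_marginals = marg, nodes = nodes, method = "exact"),
            class = "structure_posterior")
}

#' @export
print.structure_posterior <- function(x, ...) {
  cat("Posterior over", length(x$prob), "causal structures (", x$method,
      ")\n")
  cat("edge marginals:\n")
  print(round(x$edge_marginals, 3))
  invisible(x)
}

#' MCMC posterior over causal graph structures
#'
#' Metropolis-Hastings sampler over the admissible DAG space using symmetric
#' single-edge moves: toggling a uniformly chosen admissible edge (add if the
#' result stays acyclic, otherwise delete/reject) and, one proposal in three,
#' reversing a uniformly chosen existing edge. Edge marginals and graph
#' frequencies converge to [exact_structure_posterior()].
#'
#' @inheritParams exact_structure_posterior
#' @param burn_in Number of warm-up sweeps discarded.
#' @param n_samples Number of retained samples.
#' @param seed Optional integer seed.
#' @return A `structure_posterior` with sample frequencies in `prob` and
#'   sampled-graph keys in `graph_keys`.
#' @export
mcmc_structure_posterior <- function(data, burn_in = 1000L,
                                     n_samples = 10000L, allowed = NULL,
                                     ess = 1, seed = NULL) {
  if (burn_in <= 0L || n_samples <= 0L)
    stop("burn_in and n_samples must be positive")
  if (!is.null(seed)) set.seed(seed)
  nodes <- colnames(data)
  n <- length(nodes)
  if (is.null(allowed) && all(grepl("^[SO]", nodes)) && any(grepl("^O", nodes)))
    allowed <- default_edge_set(nodes)
  if (is.null(allowed)) {
    from <- rep(seq_len(n), times = n); to <- rep(seq_len(n), each = n)
    keep <- from != to
    aidx <- cbind(from[keep], to[keep])
  } else {
    aidx <- cbind(match(allowed[, 1], nodes), match(allowed[, 2], nodes))
  }
  allowed_set <- paste(aidx[, 1], aidx[, 2])
  fam <- new.env(parent = emptyenv())
  family_score <- function(j, pa_idx) {
    key <- paste(j, paste(sort(pa_idx), collapse = ","), sep = "|")
    val <- fam[[key]]
    if (is.null(val)) {
      val <- bdeu_family_score(data, nodes[j], nodes[pa_idx], ess)
      fam[[key]] <- val
    }
    val
  }
  adj <- matrix(FALSE, n, n)
  score_node <- function(j) family_score(j, which(adj[, j]))
  node_scores <- vapply(seq_len(n), score_node, numeric(1))
  marg <- matrix(0, n, n, dimnames = list(nodes, nodes))
  keys <- character(n_samples)
  accept <- 0L
  total <- burn_in + n_samples
  for (it in seq_len(total)) {
    if (nrow(aidx) == 0L) {             # no admissible edges: empty graph only
      if (it > burn_in) keys[it - burn_in] <- ""
      next
    }
    move_rev <- stats::runif(1) < 1 / 3
    if (move_rev) {
      existing <- which(adj)
      if (length(existing) == 0L) { prop <- NULL } else {
        e <- existing[sample.int(length(existing), 1L)]
        u <- (e - 1L) %% n + 1L
        v <- (e - 1L) %/% n + 1L
        ok <- paste(v, u) %in% allowed_set
        if (ok) {
          adj2 <- adj
          adj2[u, v] <- FALSE
          adj2[v, u] <- TRUE
          prop <- if (!has_cycle(adj2)) list(adj2 = adj2, touched = c(u, v))
                  else NULL
        } else prop <- NULL
      }
    } else {
      e <- sample.int(nrow(aidx), 1L)
      u <- aidx[e, 1L]; v <- aidx[e, 2L]
      adj2 <- adj
      adj2[u, v] <- !adj2[u, v]
      prop <- if (adj2[u, v] && has_cycle(adj2)) NULL
              else list(adj2 = adj2, touched = v)
    }
    if (!is.null(prop)) {
      old <- sum(node_scores[prop$touched])
      new_scores <- vapply(prop$touched, function(j)
        family_score(j, which(prop$adj2[, j])), numeric(1))
      if (log(stats::runif(1)) < sum(new_scores) - old) {
        adj <- prop$adj2
        node_scores[prop$touched] <- new_scores
        accept <- accept + 1L
      }
    }
    if (it > burn_in) {
      s <- it - burn_in
      marg <- marg + adj
      keys[s] <- paste(which(adj), collapse = ",")
    }
  }
  structure(list(edge_marginals = marg / n_samples,
                 graph_keys = keys,
                 prob = as.vector(table(keys)) / n_samples,
                 acceptance_rate = accept / total,
                 nodes = nodes, method = "mcmc"),
            class = "structure_posterior")
}

#' Causal ratings from a structure posterior
#'
#' The causal rating for a stimulus-outcome pair is the posterior probability
#' of the corresponding directed edge, rescaled to the 0-10 rating scale.
#'
#' @param posterior A `structure_posterior`.
#' @param outcome Outcome node name (default the novel outcome).
#' @return Numeric vector of ratings (0-10), one per stimulus node.
#' @export
structure_ratings <- function(posterior, outcome = "O_nov") {
  stim <- grep("^S", posterior$nodes, value = TRUE)
  10 * posterior$edge_marginals[stim, outcome]
}

## per-round predicted strengths for the model zoo: edge marginal S_i -> O_nov
structure_strengths <- function(task, ess = 1) {
  t(vapply(task$rounds, function(rd) {
    post <- exact_structure_posterior(round_trial_data(rd), ess = ess)
    unname(post$edge_marginals[grep("^S", post$nodes), "O_nov"])
  }, numeric(3)))
}

#' Total-variation distance between two structure posteriors
#'
#' Compares the probability mass over graph keys (exact) with sample
#' frequencies (MCMC).
#'
#' @param exact,mcmc `structure_posterior` objects from
#'   [exact_structure_posterior()] and [mcmc_structure_posterior()].
#' @return Total-variation distance in `[0, 1]`.
#' @export
structure_tv_distance <- function(exact, mcmc) {
  exact_keys <- vapply(exact$graphs, function(e) {
    n <- length(exact$nodes)
    adj <- matrix(FALSE, n, n)
    if (nrow(e)) adj[e] <- TRUE
    paste(which(adj), collapse = ",")
  }, character(1))
  freq <- table(mcmc$graph_keys) / length(mcmc$graph_keys)
  all_keys <- union(exact_keys, names(freq))
  p <- numeric(length(all_keys)); names(p) <- all_keys
  q <- p
  p[exact_keys] <- exact$prob
  q[names(freq)] <- freq
  sum(abs(p - q)) / 2
}

#' Principal-component regularity analysis of causal associations
#'
#' Measures how much structure recurs across rounds: given one association
#' vector per round (for example, the fitted edge marginals or strengths),
#' computes the eigen-spectrum of the rounds x features matrix and reports the
#' normalised variance explained by the leading components. Dominant leading
#' components indicate a recurring cross-round causal structure; a flat
#' spectrum indicates none.
#'
#' @param assoc Numeric matrix, rounds x features (>= 3 rounds).
#' @return List with `explained` (normalised eigenvalues), `top1` and `top3`
#'   cumulative explained-variance proportions.
#' @export
regularity_analysis <- function(assoc) {
  assoc <- as.matrix(assoc)
  if (nrow(assoc) < 3L) stop("need at least 3 rounds for a spectrum")
  pc <- stats::prcomp(assoc, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) < 1e-12) {
    ## every round carries the same association vector: perfectly regular
    explained <- c(1, numeric(length(ev) - 1L))
  } else {
    explained <- ev / sum(ev)
  }
  list(explained = explained,
       top1 = explained[1],
       top3 = sum(explained[seq_len(min(3L, length(explained)))]))
}

#' Serialize graphs and posteriors
#'
#' `write_graph_json()` stores a graph as an edge-list JSON file;
#' `read_graph_json()` restores the (from, to) edge matrix.
#' `write_posterior_csv()` stores a structure posterior as CSV
#' (graph id, log score, probability).
#'
#' @param graph Two-column (from, to) edge matrix.
#' @param path File path.
#' @export
write_graph_json <- function(graph, path) {
  edges <- if (length(graph)) {
    graph <- matrix(graph, ncol = 2L)
    lapply(seq_len(nrow(graph)),
           function(i) list(from = graph[i, 1], to = graph[i, 2]))
  } else list()
  jsonlite::write_json(edges, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  edges <- jsonlite::read_json(path)
  if (!length(edges)) return(matrix(character(0), 0L, 2L,
                                    dimnames = list(NULL, c("from", "to"))))
  m <- t(vapply(edges, function(e) c(e$from, e$to), character(2)))
  colnames(m) <- c("from", "to")
  m
}

#' @rdname write_graph_json
#' @param posterior A `structure_posterior` from
#'   [exact_structure_posterior()].
#' @export
write_posterior_csv <- function(posterior, path) {
  df <- data.frame(graph_id = seq_along(posterior$prob),
                   log_score = if (!is.null(posterior$log_score))
                     posterior$log_score else NA_real_,
                   probability = posterior$prob)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
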