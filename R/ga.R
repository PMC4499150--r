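#' Genetic-algorithm configuration
#'
#' Defaults are the scaled configuration used throughout the package's
#' tests and examples (population 32, up to 500 generations, 10 independent
#' runs).  The full-scale search — 128 candidates per run, up to 20 000
#' generations and 1000 suboptimal networks — is obtained by setting the
#' corresponding fields.
#'
#' @param population_size number of chromosomes (candidate networks), >= 4
#' @param max_generations generation cap
#' @param mutation_rate_per_group expected number of edge mutations per
#'   chromosome per generation, one rate per fitness quartile group
#'   (group 1 = fittest; rates increase towards the least-fit group)
#' @param poisson_init_rate Poisson rate of random extra links per regulator
#'   when initialising chromosomes
#' @param plateau_window,plateau_tol stop when the best fitness improves by
#'   less than `plateau_tol` (relative) over `plateau_window` consecutive
#'   generations
#' @param n_runs number of independent GA(+MCMC) runs combined by consensus
#' @param consensus_min_support minimum run support for a consensus edge;
#'   NULL means half the runs (rounded up)
#' @param crossover_enabled disable to copy parents unchanged (degenerate
#'   GA useful for diagnostics)
#' @return list of class `ga_config`
#' @export
ga_config <- function(population_size = 32, max_generations = 500,
                      mutation_rate_per_group = c(0.5, 1, 2, 4),
                      poisson_init_rate = 1,
                      plateau_window = 200, plateau_tol = 1e-6,
                      n_runs = 10, consensus_min_support = NULL,
                      crossover_enabled = TRUE) {
  stopifnot(population_size >= 4, max_generations >= 1,
            length(mutation_rate_per_group) == 4,
            all(mutation_rate_per_group >= 0), poisson_init_rate >= 0)
  structure(list(population_size = population_size,
                 max_generations = max_generations,
                 mutation_rate_per_group = mutation_rate_per_group,
                 poisson_init_rate = poisson_init_rate,
                 plateau_window = plateau_window, plateau_tol = plateau_tol,
                 n_runs = n_runs,
                 consensus_min_support = consensus_min_support,
                 crossover_enabled = crossover_enabled),
            class = "ga_config")
}

# add edge u->v (indices) if acyclic and within the parent cap; NULL if not
try_add_edge <- function(adj, u, v, max_parents) {
  if (u == v || adj[u, v]) return(NULL)
  if (sum(adj[, v]) >= max_parents) return(NULL)
  if (adj_creates_cycle(adj, u, v)) return(NULL)
  adj[u, v] <- TRUE
  adj
}

init_adj <- function(prior_idx, prior_prob, nodes, regulators_idx, rate,
                     max_parents) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(prior_idx)) {
    take <- which(stats::runif(nrow(prior_idx)) < prior_prob)
    for (i in resample(take, length(take))) {
      res <- try_add_edge(adj, prior_idx[i, 1], prior_idx[i, 2], max_parents)
      if (!is.null(res)) adj <- res
    }
  }
  if (rate > 0 && length(regulators_idx)) {
    for (r in regulators_idx) {
      d <- stats::rpois(1, rate)
      if (d == 0) next
      for (v in sample.int(n, min(d, n - 1))) {
        res <- try_add_edge(adj, r, v, max_parents)
        if (!is.null(res)) adj <- res
      }
    }
  }
  adj
}

#' Initialise a GA population from a prior table
#'
#' Each chromosome includes every prior pair with probability equal to its
#' prior probability, then adds per-regulator random extra links with a
#' Poisson(`poisson_init_rate`) count.  Edges that would close a cycle (or
#' exceed the parent cap) are rejected in random insertion order.
#'
#' @param prior a `prior_table`
#' @param config a [ga_config()]
#' @param nodes gene universe; defaults to the prior's genes
#' @param regulators candidate edge sources for the random extras; defaults
#'   to the prior's regulators, or all nodes for an empty prior
#' @param seed integer seed, or NULL to use the current RNG state
#' @param score a [score_config()] (only `max_parents` is used)
#' @return list of `gene_network` chromosomes
#' @export
init_population <- function(prior, config = ga_config(), nodes = NULL,
                            regulators = NULL, seed = NULL,
                            score = score_config()) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nodes)) nodes <- sort(unique(c(prior$regulator, prior$target)))
  if (!length(nodes)) stop("empty gene universe")
  if (is.null(regulators))
    regulators <- if (nrow(prior)) unique(prior$regulator) else nodes
  pidx <- cbind(match(prior$regulator, nodes), match(prior$target, nodes))
  keep <- !is.na(pidx[, 1]) & !is.na(pidx[, 2])
  pidx <- pidx[keep, , drop = FALSE]
  pprob <- prior$probability[keep]
  ridx <- match(intersect(regulators, nodes), nodes)
  lapply(seq_len(config$population_size), function(i) {
    adj <- init_adj(pidx, pprob, nodes, ridx, config$poisson_init_rate,
                    score$max_parents)
    gene_network(edges_from_adj(adj), nodes = nodes)
  })
}

# marshal a prior table to 0-based index vectors over `nodes`
prior_indices <- function(prior, nodes) {
  i <- match(prior$regulator, nodes)
  j <- match(prior$target, nodes)
  ok <- !is.na(i) & !is.na(j)
  list(u = i[ok] - 1L, v = j[ok] - 1L, p = prior$probability[ok])
}

prior_log_matrix <- function(prior, nodes, kappa) {
  n <- length(nodes)
  logL <- matrix(log(kappa), n, n, dimnames = list(nodes, nodes))
  if (!is.null(prior) && nrow(prior)) {
    pi <- prior_indices(prior, nodes)
    logL[cbind(pi$u + 1L, pi$v + 1L)] <- log(pi$p)
  }
  logL
}

#' Evolve a GA population of candidate networks
#'
#' Each generation scores all chromosomes under the BDeu-plus-prior score,
#' splits them into four fitness quartile groups, breeds the next
#' generation by group-identity crossover (top x top, top x second, second
#' x third; the bottom quarter is replaced by fresh prior-sampled
#' chromosomes) and mutates with the group-specific rates using
#' cycle-rejecting add/delete/reverse edge moves.  Elitism carries the best
#' chromosome over unchanged, so the best fitness is non-decreasing.  The
#' loop stops at `max_generations` or when the best fitness plateaus.
#'
#' @param population list of `gene_network` chromosomes
#'   (see [init_population()])
#' @param data discretized (or continuous) expression matrix
#' @param prior a `prior_table`
#' @param config a [ga_config()]
#' @param seed integer seed, or NULL to use the current RNG state
#' @param score a [score_config()]
#' @param regulators candidate sources for mutation-added edges (default:
#'   all nodes)
#' @return list with `best` (a `gene_network` with attribute `"fitness"`),
#'   `trace` (data frame per generation: best fitness, prior edges
#'   recovered by the best chromosome, total edges) and `fitness` (final
#'   population fitness values)
#' @export
evolve <- function(population, data, prior, config = ga_config(),
                   seed = NULL, score = score_config(), regulators = NULL) {
  if (!length(population)) stop("population is empty")
  if (!is.null(seed)) set.seed(seed)
  data <- ensure_discrete(data)
  k <- attr(data, "k")
  nodes <- population[[1]]$nodes
  data <- data[nodes, , drop = FALSE]
  pi <- prior_indices(prior, nodes)
  logL <- prior_log_matrix(prior, nodes, score$kappa)
  msrc <- if (is.null(regulators)) seq_along(nodes) - 1L else
    match(intersect(regulators, nodes), nodes) - 1L
  isrc <- if (length(pi$u)) unique(pi$u) else seq_along(nodes) - 1L
  pop0 <- lapply(population, function(net)
    adj_from_edges(net$edges, nodes))
  res <- cpp_evolve(data, k, pop0, pi$u, pi$v, pi$p, logL, score$ess,
                    score$max_parents, config$max_generations,
                    config$mutation_rate_per_group,
                    config$poisson_init_rate, config$plateau_window,
                    config$plateau_tol, msrc, isrc,
                    config$crossover_enabled)
  badj <- res$best
  dimnames(badj) <- list(nodes, nodes)
  best <- gene_network(edges_from_adj(badj), nodes = nodes)
  attr(best, "fitness") <- res$best_fitness
  trace <- as.data.frame(res$trace)
  names(trace) <- c("generation", "fitness", "prior_edges", "total_edges")
  list(best = best, trace = trace, fitness = res$fitness)
}

resample <- function(x, size) x[sample.int(length(x), size)]
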