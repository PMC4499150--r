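#' MCMC configuration
#'
#' @param n_steps number of Metropolis--Hastings steps
#' @param temperature sampling temperature; 1 targets the posterior
#'   `exp(score)`, values below 1 sharpen it
#' @param burn_in fraction of steps discarded before edge frequencies are
#'   accumulated
#' @return list of class `mcmc_config`
#' @export
mcmc_config <- function(n_steps = 2000, temperature = 1, burn_in = 0.25) {
  stopifnot(n_steps >= 1, temperature > 0, burn_in >= 0, burn_in < 1)
  structure(list(n_steps = n_steps, temperature = temperature,
                 burn_in = burn_in),
            class = "mcmc_config")
}

#' Refine a network by structure MCMC
#'
#' Metropolis--Hastings over single-edge moves.  A uniformly drawn ordered
#' pair proposes an addition when the edge is absent, and a deletion or a
#' reversal (equal probability) when present; the acceptance probability is
#' `min(1, exp(delta score / T) x proposal correction)`, where the
#' correction is 1/2 for additions, 2 for deletions and 1 for reversals.
#' Proposals that would create a cycle or exceed the parent cap are
#' rejected, so every visited state is a DAG.
#'
#' @param seed_network acyclic `gene_network` used as the starting state
#'   (typically the best GA chromosome)
#' @param data discretized (or continuous) expression matrix
#' @param prior a `prior_table` or NULL
#' @param config an [mcmc_config()]
#' @param seed integer seed, or NULL to use the current RNG state
#' @param score a [score_config()]
#' @return list with `freq` (per-edge visit frequency matrix after
#'   burn-in), `best` (best-scoring `gene_network` visited, with attribute
#'   `"score"`) and `accept_rate`
#' @export
mcmc_refine <- function(seed_network, data, prior = NULL,
                        config = mcmc_config(), seed = NULL,
                        score = score_config()) {
  stopifnot(inherits(seed_network, "gene_network"))
  if (!is_acyclic(seed_network)) stop("seed network is cyclic")
  if (!is.null(seed)) set.seed(seed)
  data <- ensure_discrete(data)
  k <- attr(data, "k")
  nodes <- seed_network$nodes
  data <- data[nodes, , drop = FALSE]
  logL <- prior_log_matrix(prior, nodes, score$kappa)
  adj <- adj_from_edges(seed_network$edges, nodes)
  res <- cpp_mcmc(data, k, adj, logL, score$ess,
                  score$max_parents, config$n_steps, config$temperature,
                  config$burn_in)
  freq <- res$freq
  dimnames(freq) <- list(nodes, nodes)
  badj <- res$best
  dimnames(badj) <- list(nodes, nodes)
  best <- gene_network(edges_from_adj(badj), nodes = nodes)
  attr(best, "score") <- res$best_score
  list(freq = freq, best = best, accept_rate = res$accept_rate)
}
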