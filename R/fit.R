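#' Fit a global causal transcription network
#'
#' The hybrid structure-learning pipeline: `n_runs` independent genetic
#' algorithm searches are seeded from the prior table, each run's best
#' chromosome is refined by structure MCMC, and the refined networks are
#' combined by keeping the edges supported by at least `min_support` runs.
#' The score being maximised is the BDeu marginal likelihood of the
#' discretized expression plus an edge-wise log structure prior (see
#' [score_config()]).
#'
#' With `n_runs = 1` the result reduces to a single [evolve()] +
#' [mcmc_refine()] pass.  Runs are mutually independent: `threads` only
#' partitions them and has no effect on the result.
#'
#' @param expr expression matrix (genes x samples).  A continuous matrix is
#'   discretized with [discretize_expression()] into `k` levels; an integer
#'   matrix with attribute `"k"` is used as is.
#' @param prior a `prior_table`
#' @param k number of discretization levels
#' @param nodes gene universe; default: the rows of `expr`
#' @param regulators candidate edge sources for random GA moves; default
#'   all nodes
#' @param ga a [ga_config()]
#' @param mcmc an [mcmc_config()]
#' @param score a [score_config()]
#' @param min_support consensus support threshold; default half the runs
#' @param seed integer seed driving all runs
#' @param threads accepted for interface compatibility; runs are executed
#'   identically regardless of its value
#' @return an object of class `loopnet`; see [summary.loopnet()].  The
#'   consensus network is in `$network` (a `gene_network` with `support`
#'   and `posterior_frequency` edge columns), per-run GA traces in
#'   `$traces`, refined per-run networks in `$runs`.
#' @seealso [evolve()], [mcmc_refine()], [consensus_network()]
#' @export
loopnet <- function(expr, prior, k = 3, nodes = NULL, regulators = NULL,
                    ga = ga_config(), mcmc = mcmc_config(),
                    score = score_config(), min_support = NULL,
                    seed = 1, threads = 1) {
  stopifnot(is.matrix(expr))
  if (threads < 1) stop("threads must be >= 1")
  data <- if (is.null(attr(expr, "k")) && !is.integer(expr))
    discretize_expression(expr, k = k) else ensure_discrete(expr)
  if (is.null(nodes)) nodes <- rownames(data)
  klev <- attr(data, "k")
  data <- data[nodes, , drop = FALSE]
  attr(data, "k") <- klev
  n_runs <- ga$n_runs
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  runs <- vector("list", n_runs)
  traces <- vector("list", n_runs)
  freq_sum <- matrix(0, length(nodes), length(nodes),
                     dimnames = list(nodes, nodes))
  for (i in seq_len(n_runs)) {
    set.seed(run_seeds[i])
    pop <- init_population(prior, ga, nodes = nodes, score = score)
    ev <- evolve(pop, data, prior, ga, score = score,
                 regulators = regulators)
    mc <- mcmc_refine(ev$best, data, prior, mcmc, score = score)
    runs[[i]] <- mc$best
    traces[[i]] <- ev$trace
    freq_sum <- freq_sum + mc$freq
  }
  if (is.null(min_support))
    min_support <- if (!is.null(ga$consensus_min_support))
      ga$consensus_min_support else ceiling(n_runs / 2)
  net <- consensus_network(runs, min_support)
  net <- gene_network(net$edges, nodes = nodes)
  attr(net, "cyclic") <- !is_acyclic(net)
  if (nrow(net$edges)) {
    freq <- freq_sum / n_runs
    net$edges$posterior_frequency <-
      freq[cbind(net$edges$regulator, net$edges$target)]
  } else {
    net$edges$posterior_frequency <- numeric()
  }
  structure(list(network = net, runs = runs, traces = traces,
                 posterior_frequency = freq_sum / n_runs,
                 min_support = min_support, n_runs = n_runs,
                 configs = list(ga = ga, mcmc = mcmc, score = score),
                 seed = seed, nodes = nodes, call = match.call()),
            class = "loopnet")
}

#' @export
print.loopnet <- function(x, ...) {
  cat("Global causal transcription network (GA-seeded MCMC consensus)\n")
  cat("  runs:", x$n_runs, " consensus support >=", x$min_support, "\n")
  cat("  nodes:", length(x$nodes), " consensus edges:",
      nrow(x$network$edges))
  cat(if (isTRUE(attr(x$network, "cyclic"))) "  (consensus contains cycles)\n"
      else "  (acyclic)\n")
  invisible(x)
}

#' Summarise a fitted network
#'
#' @param object a `loopnet` fit
#' @param ... unused
#' @return invisibly, a list with the support table and final GA fitness
#'   per run
#' @export
summary.loopnet <- function(object, ...) {
  print(object)
  sup <- table(object$network$edges$support)
  if (length(sup)) {
    cat("  edge support distribution:\n")
    print(sup)
  }
  fits <- vapply(object$traces, function(tr) tr$fitness[nrow(tr)], 0)
  cat("  final GA fitness per run: ",
      paste(format(fits, digits = 6), collapse = ", "), "\n")
  invisible(list(support = sup, fitness = fits))
}

#' Extract the consensus edge table from a fit
#' @param x a `loopnet` fit
#' @return data frame: regulator, target, support, posterior_frequency
#' @export
edges <- function(x) UseMethod("edges")

#' @export
edges.loopnet <- function(x) x$network$edges

#' @export
edges.gene_network <- function(x) x$edges

#' Plot GA convergence traces of a fit
#'
#' One line per run: best fitness against generation.
#'
#' @param x a `loopnet` fit
#' @param ... passed to [graphics::matplot()]
#' @export
plot.loopnet <- function(x, ...) {
  gmax <- max(vapply(x$traces, nrow, 0L))
  m <- sapply(x$traces, function(tr) {
    c(tr$fitness, rep(tr$fitness[nrow(tr)], gmax - nrow(tr)))
  })
  graphics::matplot(seq_len(gmax), m, type = "l", lty = 1,
                    xlab = "GA generation", ylab = "best fitness", ...)
  invisible(x)
}
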