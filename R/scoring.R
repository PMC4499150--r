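#' Scoring configuration for network learning
#'
#' The network score is the BDeu marginal likelihood of the discretized
#' expression data (equivalent sample size `ess`) plus an edge-wise
#' structure prior: `log(p)` for an edge present in the prior table with
#' probability `p`, and `log(kappa)` for an edge absent from it.  A small
#' `kappa` penalises edges with no physical or genetic support and keeps
#' learned networks sparse.  The score is decomposable: changing one node's
#' parent set changes only that node's family term plus the prior terms of
#' the toggled edges.
#'
#' @param ess equivalent sample size of the BDeu score
#' @param kappa baseline prior probability for non-prior edges, in (0, 1)
#' @param max_parents cap on the number of parents per node
#' @return list of class `score_config`
#' @export
score_config <- function(ess = 1, kappa = 0.01, max_parents = 5) {
  stopifnot(ess > 0, kappa > 0, kappa < 1, max_parents >= 1)
  structure(list(ess = ess, kappa = kappa, max_parents = max_parents),
            class = "score_config")
}

# Build a closure-based scorer over a fixed discretized data matrix.
# Returns functions sharing one memo of per-family BDeu terms, so that
# populations of similar networks are scored incrementally.
make_scorer <- function(data_int, prior = NULL, config = score_config()) {
  stopifnot(is.matrix(data_int))
  k <- attr(data_int, "k")
  if (is.null(k)) k <- max(data_int)
  k <- as.integer(k)
  nodes <- rownames(data_int)
  n <- length(nodes)
  ns <- ncol(data_int)
  storage.mode(data_int) <- "integer"
  logL <- matrix(log(config$kappa), n, n, dimnames = list(nodes, nodes))
  if (!is.null(prior) && nrow(prior)) {
    i <- match(prior$regulator, nodes)
    j <- match(prior$target, nodes)
    ok <- !is.na(i) & !is.na(j)
    logL[cbind(i[ok], j[ok])] <- log(prior$probability[ok])
  }
  memo <- new.env(parent = emptyenv(), size = 4096L)
  ess <- config$ess

  family <- function(node, parents) {
    key <- paste(node, paste(parents, collapse = ","), sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    x <- data_int[node, ]
    np <- length(parents)
    if (np == 0L) {
      q <- 1L
      cell <- x
    } else {
      cfg <- integer(ns)
      mult <- 1L
      for (p in parents) {
        cfg <- cfg + (data_int[p, ] - 1L) * mult
        mult <- mult * k
      }
      q <- mult
      cell <- cfg * k + x
    }
    cnt <- tabulate(cell, q * k)
    Nj <- .colSums(cnt, k, q)          # counts per parent config
    aj <- ess / q
    ajk <- ess / (q * k)
    obs_j <- Nj > 0
    obs_c <- cnt > 0
    # unobserved parent configs / cells contribute exactly zero
    val <- sum(obs_j) * lgamma(aj) - sum(lgamma(aj + Nj[obs_j])) +
      sum(lgamma(ajk + cnt[obs_c])) - sum(obs_c) * lgamma(ajk)
    memo[[key]] <- val
    val
  }

  family_scores <- function(adj) {
    vapply(seq_len(n), function(j) family(j, which(adj[, j])), 0)
  }
  prior_sum <- function(adj) sum(logL[adj])
  net_score <- function(adj) sum(family_scores(adj)) + prior_sum(adj)

  list(nodes = nodes, n = n, k = k, logL = logL, family = family,
       family_scores = family_scores, prior_sum = prior_sum,
       net_score = net_score, max_parents = config$max_parents)
}

#' Score a network against discretized expression and a prior table
#'
#' Log posterior score: BDeu marginal likelihood plus the edge-wise log
#' structure prior (see [score_config()]).
#'
#' @param network an acyclic `gene_network`
#' @param data discretized integer matrix (genes x samples, levels `1..k`
#'   with attribute `"k"`), or a continuous matrix which is discretized
#'   with [discretize_expression()] defaults
#' @param prior a `prior_table` or NULL
#' @param config a [score_config()]
#' @return the log score (numeric scalar)
#' @export
score_network <- function(network, data, prior = NULL,
                          config = score_config()) {
  stopifnot(inherits(network, "gene_network"))
  if (!is_acyclic(network)) stop("network is cyclic")
  missing <- setdiff(network$nodes, rownames(data))
  if (length(missing))
    stop("node(s) missing from data: ", paste(missing, collapse = ", "))
  data <- ensure_discrete(data)
  klev <- attr(data, "k")
  data <- data[network$nodes, , drop = FALSE]
  attr(data, "k") <- klev
  sc <- make_scorer(data, prior, config)
  adj <- adj_from_edges(network$edges, network$nodes)
  if (any(colSums(adj) > config$max_parents))
    stop("a node exceeds max_parents = ", config$max_parents)
  sc$net_score(adj)
}

ensure_discrete <- function(data) {
  if (!is.null(attr(data, "k"))) return(data)
  if (is.integer(data)) {
    attr(data, "k") <- max(data)
    return(data)
  }
  discretize_expression(data)
}
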