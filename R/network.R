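#' Directed gene network
#'
#' Light-weight container for a directed network over gene symbols: an edge
#' table (`regulator`, `target`, plus optional metadata columns such as
#' `support`, `sign` or `probability`) together with the node universe the
#' network is defined over.  The node universe matters for enrichment
#' statistics, whose denominators are all ordered gene pairs.
#'
#' @param edges data frame with character columns `regulator` and `target`;
#'   additional columns are kept as edge metadata.
#' @param nodes character vector of gene identifiers; defaults to the genes
#'   occurring in `edges`.  Must cover all edge endpoints.
#' @param allow_self_loops keep regulator == target rows?  Defaults to FALSE
#'   (such rows are an error, as in all learning and prior inputs).
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(edges = NULL, nodes = NULL, allow_self_loops = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(regulator = character(), target = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("regulator", "target") %in% names(edges)))
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (!allow_self_loops && any(edges$regulator == edges$target)) {
    bad <- edges$regulator[edges$regulator == edges$target]
    stop("self-loop edge(s) not allowed: ", paste(unique(bad), collapse = ", "))
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$regulator, edges$target)))
  nodes <- as.character(nodes)
  missing <- setdiff(c(edges$regulator, edges$target), nodes)
  if (length(missing))
    stop("edge endpoints outside node universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  key <- paste(edges$regulator, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges")
  if (!is.null(attr(x, "cyclic"))) cat(";", if (attr(x, "cyclic")) "cyclic" else "acyclic")
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

edge_keys <- function(net) {
  if (inherits(net, "gene_network")) net <- net$edges
  paste(net$regulator, net$target, sep = "\r")
}

#' @export
as.data.frame.gene_network <- function(x, ...) x$edges

#' Convert a gene network to an igraph graph
#' @param net a `gene_network`
#' @return directed `igraph` graph over the full node universe
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  igraph::graph_from_data_frame(net$edges[, c("regulator", "target")],
                                directed = TRUE, vertices = net$nodes)
}

#' Test a network for acyclicity
#' @param net a `gene_network`
#' @return TRUE if the directed graph has no cycle
#' @export
is_acyclic <- function(net) {
  if (nrow(net$edges) == 0) return(TRUE)
  igraph::is_dag(as_igraph(net))
}

## ---- internal adjacency-matrix helpers used by the learners -------------

adj_from_edges <- function(edges, nodes) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    adj[cbind(match(edges$regulator, nodes), match(edges$target, nodes))] <- TRUE
  }
  adj
}

edges_from_adj <- function(adj) {
  idx <- which(adj, arr.ind = TRUE)
  nodes <- rownames(adj)
  data.frame(regulator = nodes[idx[, 1]], target = nodes[idx[, 2]],
             stringsAsFactors = FALSE)
}

# TRUE if `to` is reachable from `from` following directed edges in adj.
adj_reachable <- function(adj, from, to) {
  if (from == to) return(TRUE)
  n <- nrow(adj)
  visited <- logical(n)
  frontier <- from
  visited[from] <- TRUE
  while (length(frontier)) {
    nxt <- which(adj[frontier[1], ] & !visited)
    frontier <- frontier[-1]
    if (length(nxt)) {
      if (any(nxt == to)) return(TRUE)
      visited[nxt] <- TRUE
      frontier <- c(frontier, nxt)
    }
  }
  FALSE
}

# Would adding u -> v close a cycle?  Yes iff u is reachable from v.
adj_creates_cycle <- function(adj, u, v) adj_reachable(adj, v, u)

adj_is_acyclic <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  active <- rep(TRUE, n)
  queue <- which(indeg == 0)
  seen <- 0L
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    active[u] <- FALSE
    seen <- seen + 1L
    ch <- which(adj[u, ] & active)
    if (length(ch)) {
      indeg[ch] <- indeg[ch] - 1L
      queue <- c(queue, ch[indeg[ch] == 0])
    }
  }
  seen == n
}

#' Consensus network over repeated structure-learning runs
#'
#' Keeps the edges that appear in at least `min_support` of the supplied
#' networks.  The consensus summarises independently learned suboptimal
#' networks and is not itself constrained to be acyclic; whether it contains
#' a cycle is flagged in the `"cyclic"` attribute.
#'
#' @param networks list of `gene_network` objects over a common node universe
#' @param min_support minimum number of networks an edge must occur in
#' @return `gene_network` with a `support` edge column and a `"cyclic"`
#'   attribute.
#' @export
consensus_network <- function(networks, min_support) {
  if (!length(networks)) stop("empty network list")
  stopifnot(min_support >= 1, min_support <= length(networks))
  nodes <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
  keys <- unlist(lapply(networks, edge_keys))
  if (!length(keys)) {
    out <- gene_network(nodes = nodes)
    out$edges$support <- integer()
    attr(out, "cyclic") <- FALSE
    return(out)
  }
  tab <- table(keys)
  keep <- names(tab)[tab >= min_support]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  edges <- data.frame(regulator = vapply(parts, `[`, "", 1),
                      target = vapply(parts, `[`, "", 2),
                      support = as.integer(tab[keep]),
                      stringsAsFactors = FALSE)
  out <- gene_network(edges, nodes = nodes)
  attr(out, "cyclic") <- !is_acyclic(out)
  out
}

#' Edge-set consistency between two networks
#'
#' Jaccard index of the two edge sets: shared edges divided by the union.
#' Two empty networks are defined to be fully consistent (1.0).
#'
#' @param a,b `gene_network` objects over the same gene universe
#' @return a number in `[0, 1]`
#' @export
network_consistency <- function(a, b) {
  ka <- edge_keys(a); kb <- edge_keys(b)
  un <- union(ka, kb)
  if (!length(un)) return(1.0)
  length(intersect(ka, kb)) / length(un)
}
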