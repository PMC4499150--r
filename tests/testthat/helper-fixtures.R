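# Shared fixtures and independent oracles used across the test files.

# hand-construct a true_network without the random generator, for cases
# where exact edges/signs/effects matter
make_truth <- function(nodes, regulators, edges, order = nodes) {
  if (is.null(edges$sign)) edges$sign <- rep(1, nrow(edges))
  if (is.null(edges$effect)) edges$effect <- rep(1, nrow(edges))
  structure(list(nodes = nodes, regulators = regulators, order = order,
                 edges = edges),
            class = "true_network")
}

edge_set <- function(x) {
  e <- if (inherits(x, "gene_network")) x$edges else x
  paste(e$regulator, e$target)
}

# F1 between an estimated edge set and a reference edge set
edge_set_f1 <- function(est, truth) {
  est <- unique(est); truth <- unique(truth)
  tp <- length(intersect(est, truth))
  if (length(est) + length(truth) == 0) return(NA_real_)
  2 * tp / (length(est) + length(truth))
}

# exhaustive enumeration of all labelled DAGs on a small node set
# (independent oracle for the structure learners)
all_dags <- function(nodes) {
  pairs <- expand.grid(regulator = nodes, target = nodes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$regulator != pairs$target, ]
  m <- nrow(pairs)
  out <- list()
  for (code in 0:(2^m - 1)) {
    sel <- bitwAnd(code, 2^(seq_len(m) - 1)) > 0
    net <- gene_network(pairs[sel, , drop = FALSE], nodes = nodes)
    if (is_acyclic(net)) out[[length(out) + 1L]] <- net
  }
  out
}

# independent BDeu implementation (direct formula, no memoisation) used to
# cross-check the package's scorer on tiny cases
oracle_bdeu <- function(net, data_int, k, ess = 1, kappa = 0.01,
                        prior = NULL) {
  nodes <- net$nodes
  total <- 0
  for (v in nodes) {
    parents <- net$edges$regulator[net$edges$target == v]
    np <- length(parents)
    q <- k^np
    cfg <- rep(1, ncol(data_int))
    if (np) {
      mult <- 1
      for (p in parents) {
        cfg <- cfg + (data_int[p, ] - 1) * mult
        mult <- mult * k
      }
    }
    for (j in unique(cfg)) {
      xs <- data_int[v, cfg == j]
      nj <- length(xs)
      aj <- ess / q
      ajk <- ess / (q * k)
      total <- total + lgamma(aj) - lgamma(aj + nj)
      for (c in seq_len(k)) {
        njk <- sum(xs == c)
        if (njk > 0) total <- total + lgamma(ajk + njk) - lgamma(ajk)
      }
    }
  }
  pk <- if (!is.null(prior)) paste(prior$regulator, prior$target) else
    character()
  for (i in seq_len(nrow(net$edges))) {
    key <- paste(net$edges$regulator[i], net$edges$target[i])
    total <- total + if (key %in% pk)
      log(prior$probability[match(key, pk)]) else log(kappa)
  }
  total
}

# small hand-made cohort with full control over expression values
make_cohort <- function(expr, subclass, genotypes = NULL,
                        risk_links = NULL) {
  patients <- unique(sub("_[TN]$", "", colnames(expr)))
  structure(list(
    expression = expr,
    samples = data.frame(sample = colnames(expr),
                         patient = sub("_[TN]$", "", colnames(expr)),
                         tissue = ifelse(grepl("_T$", colnames(expr)),
                                         "tumor", "normal")),
    subclass = data.frame(patient = patients, subclass = subclass),
    coding_mutations = data.frame(patient = character(), gene = character()),
    noncoding_mutations = data.frame(),
    genotypes = genotypes %||%
      data.frame(patient = character(), snp = character(),
                 dosage = integer()),
    risk_links = risk_links),
    class = "cohort_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
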