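## Edge-sign annotation and the evaluation statistics: per-node F1 against a
## reference catalog, global precision, prior-recovery enrichment odds
## ratios and DRE-PRE loop geometry summaries.

#' Annotate edge signs from expression correlation
#'
#' Pearson correlation of regulator and target expression per edge, on the
#' continuous (pre-discretization) matrix.  An edge is called activation
#' when r is strictly greater than `threshold`, inhibition when r is
#' strictly below `-threshold`, and left unsigned otherwise (so
#' `|r| = threshold` exactly is unsigned).  Zero-variance genes yield
#' unsigned edges with a warning.
#'
#' @param network a `gene_network`
#' @param expr numeric matrix genes x samples containing all edge endpoints
#' @param threshold absolute-correlation threshold (default 0.1)
#' @return the network with edge columns `r` and `sign` (one of
#'   `activation`, `inhibition`, `unsigned`) and attribute
#'   `"activation_inhibition_ratio"`
#' @export
infer_edge_signs <- function(network, expr, threshold = 0.1) {
  stopifnot(inherits(network, "gene_network"))
  e <- network$edges
  missing <- setdiff(unique(c(e$regulator, e$target)), rownames(expr))
  if (length(missing))
    stop("edge endpoint(s) missing from expression: ",
         paste(missing, collapse = ", "))
  sds <- apply(expr, 1, stats::sd)
  r <- rep(NA_real_, nrow(e))
  for (i in seq_len(nrow(e))) {
    if (sds[e$regulator[i]] == 0 || sds[e$target[i]] == 0) next
    r[i] <- stats::cor(expr[e$regulator[i], ], expr[e$target[i], ])
  }
  if (anyNA(r) && nrow(e))
    warning("zero-variance gene(s); affected edges left unsigned")
  sign <- rep("unsigned", nrow(e))
  sign[!is.na(r) & r > threshold] <- "activation"
  sign[!is.na(r) & r < -threshold] <- "inhibition"
  e$r <- r
  e$sign <- sign
  network$edges <- e
  n_act <- sum(sign == "activation")
  n_inh <- sum(sign == "inhibition")
  attr(network, "activation_inhibition_ratio") <-
    if (n_inh > 0) n_act / n_inh else NA_real_
  network
}

# reference catalog -> set of keys; undirected catalogs match either order
reference_keys <- function(reference, directed) {
  if (inherits(reference, "gene_network")) reference <- reference$edges
  a <- as.character(reference[[1]])
  b <- as.character(reference[[2]])
  if (directed) paste(a, b, sep = "\r")
  else unique(c(paste(a, b, sep = "\r"), paste(b, a, sep = "\r")))
}

#' Per-node F1 of outgoing links against a reference catalog
#'
#' For each node: TP = outgoing network links present in the reference,
#' FP = outgoing links absent from it, FN = reference links from the node
#' missing in the network; F1 = 2 TP / (2 TP + FP + FN).  Reference
#' catalogs are treated as undirected by default (functional-interaction
#' style); set `directed = TRUE` for TF-target catalogs.  Nodes with no
#' outgoing links and no reference links are excluded.
#'
#' @param network a `gene_network`
#' @param reference two-column data frame (or `gene_network`) of reference
#'   pairs
#' @param directed compare pairs as ordered?
#' @return data frame: node, tp, fp, fn, f1
#' @export
node_f1 <- function(network, reference, directed = FALSE) {
  if ((is.data.frame(reference) && nrow(reference) == 0) ||
      (inherits(reference, "gene_network") && nrow(reference$edges) == 0)) {
    warning("empty reference; F1 undefined for all nodes")
    return(data.frame(node = character(), tp = integer(), fp = integer(),
                      fn = integer(), f1 = numeric()))
  }
  refk <- reference_keys(reference, directed)
  ref_src <- sub("\r.*", "", refk)
  e <- network$edges
  net_keys <- edge_keys(network)
  # in undirected mode a reference pair counts as recovered when the
  # network contains it in either orientation
  net_any <- if (directed) net_keys else
    unique(c(net_keys, paste(e$target, e$regulator, sep = "\r")))
  out <- lapply(network$nodes, function(v) {
    tgt <- e$target[e$regulator == v]
    ek <- if (length(tgt)) paste(v, tgt, sep = "\r") else character(0)
    rk <- refk[ref_src == v]
    tp <- sum(ek %in% rk)
    fp <- length(ek) - tp
    fn <- sum(!(rk %in% net_any))
    if (tp + fp + fn == 0) return(NULL)
    f1 <- 2 * tp / (2 * tp + fp + fn)
    data.frame(node = v, tp = tp, fp = fp, fn = fn, f1 = f1,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(node = character(), tp = integer(), fp = integer(),
                      fn = integer(), f1 = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Global network precision against a reference catalog
#'
#' TP / (TP + FP) over all edges.  Preferred over F1 for large networks
#' interrogated against small catalogs, where false negatives are
#' disproportionately inflated.
#'
#' @inheritParams node_f1
#' @return precision in `[0, 1]`, or `NA` (with a warning) for an edgeless
#'   network
#' @export
network_precision <- function(network, reference, directed = FALSE) {
  e <- network$edges
  if (!nrow(e)) {
    warning("network has no edges; precision undefined")
    return(NA_real_)
  }
  refk <- reference_keys(reference, directed)
  mean(edge_keys(network) %in% refk)
}

#' Prior-recovery enrichment odds ratios
#'
#' For each class of prior relationships (prior-probability bin, topology,
#' or evidence type) the recovered fraction is the share of the class's
#' pairs present in the functional network as an edge (regardless of sign
#' or direction of recovery is ordered — pairs are compared as ordered
#' pairs).  The expected fraction is the functional network's density over
#' all ordered gene pairs, and the odds ratio is their quotient.
#'
#' @param prior a `prior_table`
#' @param functional a `gene_network` (its `nodes` provide the all-pairs
#'   denominator)
#' @param by classify priors by probability `bin`, by `topology`, or by
#'   `evidence`
#' @param bins probability bin edges (left-closed, right-open except the
#'   last)
#' @return data frame: class, n_prior, n_recovered, recovered_fraction,
#'   expected_fraction, odds_ratio.  Empty classes are omitted.
#' @export
prior_recovery_enrichment <- function(prior, functional,
                                      by = c("bin", "topology", "evidence"),
                                      bins = c(0, 0.25, 0.5, 0.75, 1)) {
  by <- match.arg(by)
  n <- length(functional$nodes)
  stopifnot(n >= 2)
  expected <- nrow(functional$edges) / (n * (n - 1))
  df <- as.data.frame(prior)
  cls <- switch(by,
    bin = {
      lab <- paste0("[", utils::head(bins, -1), ",", utils::tail(bins, -1),
                    ")")
      lab[length(lab)] <- sub("\\)$", "]", lab[length(lab)])
      lab[findInterval(df$probability, bins, rightmost.closed = TRUE)]
    },
    topology = ifelse(is.na(df$topology), df$evidence, df$topology),
    evidence = df$evidence)
  fk <- edge_keys(functional)
  pk <- paste(df$regulator, df$target, sep = "\r")
  rec <- pk %in% fk
  out <- lapply(split(seq_len(nrow(df)), cls), function(idx) {
    frac <- mean(rec[idx])
    data.frame(class = cls[idx[1]], n_prior = length(idx),
               n_recovered = sum(rec[idx]), recovered_fraction = frac,
               expected_fraction = expected,
               odds_ratio = if (expected > 0) frac / expected else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' DRE-PRE loop geometry summary
#'
#' Classifies each DRE--PRE chromatin loop by positioning — intragenic (the
#' DRE overlaps the linked gene's body), intergenic by distance band, or
#' inter-chromosomal — and tabulates the prior (physical) against the
#' posterior (functional) interactions.  A loop is counted as prior /
#' functional when some TF bound at its DRE regulates the looped PRE's gene
#' in the respective pair set.  Distance is measured between element
#' midpoints; bands are half-open (`[0,100kb)`, `[100,200kb)`, ...).
#'
#' @param landscape a `regulatory_landscape`
#' @param prior_pairs data frame (regulator, target) of prior pairs, e.g. a
#'   `prior_table`
#' @param functional_pairs data frame (regulator, target) of functional
#'   network edges
#' @param band_width distance band width in bp
#' @param max_band upper distance for banding; longer spans share the last
#'   band label
#' @return list with `positioning` (data frame: category, prior count,
#'   posterior count) and `distances` (list of numeric vectors `prior`,
#'   `posterior`)
#' @export
dre_pre_geometry_summary <- function(landscape, prior_pairs,
                                     functional_pairs,
                                     band_width = 1e5, max_band = 1e6) {
  el <- landscape$elements
  kind <- stats::setNames(el$kind, el$element)
  loops <- landscape$loops
  is_dp <- (kind[loops$anchor1] == "DRE" & kind[loops$anchor2] == "PRE") |
    (kind[loops$anchor1] == "PRE" & kind[loops$anchor2] == "DRE")
  loops <- loops[is_dp, , drop = FALSE]
  pk <- paste(prior_pairs$regulator, prior_pairs$target, sep = "\r")
  fk <- paste(functional_pairs$regulator, functional_pairs$target, sep = "\r")
  bind <- landscape$binding
  rows <- list()
  for (i in seq_len(nrow(loops))) {
    dre <- if (kind[loops$anchor1[i]] == "DRE") loops$anchor1[i] else
      loops$anchor2[i]
    pre <- setdiff(c(loops$anchor1[i], loops$anchor2[i]), dre)
    ed <- el[match(dre, el$element), ]
    ep <- el[match(pre, el$element), ]
    g <- ep$gene
    tfs <- unique(bind$tf[bind$element == dre])
    if (!length(tfs)) next
    keys <- paste(tfs, g, sep = "\r")
    in_prior <- any(keys %in% pk)
    in_post <- any(keys %in% fk)
    if (!in_prior && !in_post) next
    gr <- landscape$genes[match(g, landscape$genes$gene), ]
    if (ed$chrom != ep$chrom) {
      cat_ <- "inter_chromosomal"
      dist <- NA_real_
    } else {
      dist <- abs((ed$start + ed$end) / 2 - (ep$start + ep$end) / 2)
      if (ed$start < gr$end && ed$end > gr$start) {
        cat_ <- "intragenic"
      } else {
        lo <- min(floor(dist / band_width), max_band / band_width - 1)
        cat_ <- sprintf("intergenic_%g-%gkb", lo * band_width / 1e3,
                        (lo + 1) * band_width / 1e3)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(category = cat_, dist = dist,
                                            prior = in_prior,
                                            posterior = in_post,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(list(positioning = data.frame(category = character(),
                                         prior = integer(),
                                         posterior = integer()),
                distances = list(prior = numeric(), posterior = numeric())))
  }
  d <- do.call(rbind, rows)
  cats <- sort(unique(d$category))
  positioning <- data.frame(
    category = cats,
    prior = vapply(cats, function(cc) sum(d$prior[d$category == cc]), 0L),
    posterior = vapply(cats, function(cc) sum(d$posterior[d$category == cc]),
                       0L),
    stringsAsFactors = FALSE)
  rownames(positioning) <- NULL
  list(positioning = positioning,
       distances = list(prior = d$dist[d$prior & !is.na(d$dist)],
                        posterior = d$dist[d$posterior & !is.na(d$dist)]))
}
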