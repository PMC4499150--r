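## Prior model: physical TF binding routed through chromatin loops, plus
## cis/trans genetic association, turned into a regulator->target prior table.

TOPOLOGIES <- c("PRE_direct", "DRE_loop_PRE", "PRE_loop_PRE",
                "DRE_loop_PRE_loop_PRE")

#' Construct/validate a prior table
#'
#' A prior table is a data frame of regulator->target entries with a
#' probability in (0, 1] and a class label (`evidence`, `cell_context`,
#' `topology`); eQTL-derived entries carry `evidence = "eqtl"`.  At most one
#' entry per ordered pair; no self-loops.
#'
#' @param entries data frame with columns `regulator`, `target`,
#'   `probability` and optionally `evidence`, `cell_context`, `topology`
#' @return the validated data frame with class `prior_table`
#' @export
prior_table <- function(entries = NULL) {
  if (is.null(entries))
    entries <- data.frame(regulator = character(), target = character(),
                          probability = numeric(), evidence = character(),
                          cell_context = character(), topology = character(),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("regulator", "target", "probability") %in% names(entries)))
  for (col in c("evidence", "cell_context", "topology"))
    if (is.null(entries[[col]])) entries[[col]] <- NA_character_
  if (any(entries$regulator == entries$target))
    stop("prior table contains self-loops")
  if (any(entries$probability <= 0 | entries$probability > 1))
    stop("prior probabilities must lie in (0, 1]")
  if (anyDuplicated(paste(entries$regulator, entries$target, sep = "\r")))
    stop("duplicate (regulator, target) pairs; use merge_priors()")
  entries <- entries[order(entries$regulator, entries$target),
                     c("regulator", "target", "probability", "evidence",
                       "cell_context", "topology")]
  rownames(entries) <- NULL
  class(entries) <- c("prior_table", "data.frame")
  entries
}

#' Default prior probability assignment over binding classes
#'
#' Completes the 2 (evidence) x 2 (cell context) x 4 (topology) class grid.
#' The ordering encodes the evidence hierarchy: same-cell > cross-cell
#' observation, ChIP peak > motif-in-DHS, and shorter tethering topologies >
#' longer ones; the strongest classes sit above 0.75 so that high-confidence
#' priors fall in the top probability bin.  All values are configurable.
#'
#' @param chip_same probabilities for the four topologies under ChIP evidence
#'   observed in the same cell type
#' @param cross_penalty subtracted for cross-cell-type evidence
#' @param motif_penalty subtracted for motif (vs ChIP) evidence
#' @param floor minimum probability
#' @return data frame (`evidence`, `cell_context`, `topology`,
#'   `probability`) covering all 16 classes
#' @export
default_probability_assignment <- function(chip_same = c(0.9, 0.8, 0.6, 0.5),
                                           cross_penalty = 0.15,
                                           motif_penalty = 0.25,
                                           floor = 0.05) {
  grid <- expand.grid(topology = TOPOLOGIES,
                      cell_context = c("same_cell", "cross_cell"),
                      evidence = c("chip", "motif"),
                      stringsAsFactors = FALSE)[, 3:1]
  base <- chip_same[match(grid$topology, TOPOLOGIES)]
  p <- base - ifelse(grid$cell_context == "cross_cell", cross_penalty, 0) -
    ifelse(grid$evidence == "motif", motif_penalty, 0)
  grid$probability <- pmax(floor, p)
  grid
}

#' Classify binding events by regulatory topology
#'
#' For every TF binding event, enumerates the target genes reachable under
#' the four topologies: the bound element is the target's PRE (direct); a
#' DRE looped to the target's PRE; another gene's PRE looped to the target's
#' PRE; or a DRE looped to a PRE that is itself looped to the target's PRE.
#' Loop traversal depth is at most two anchors.  Events on elements with no
#' reachable PRE yield no rows.
#'
#' @param landscape a `regulatory_landscape`
#' @return data frame: `tf`, `element`, `evidence`, `cell_context`,
#'   `accessible`, `target`, `topology`
#' @export
classify_topologies <- function(landscape) {
  el <- landscape$elements
  kind <- stats::setNames(el$kind, el$element)
  egene <- stats::setNames(el$gene, el$element)
  if (nrow(landscape$loops)) {
    nb <- split(c(landscape$loops$anchor2, landscape$loops$anchor1),
                c(landscape$loops$anchor1, landscape$loops$anchor2))
  } else nb <- list()
  out <- vector("list", nrow(landscape$binding))
  for (i in seq_len(nrow(landscape$binding))) {
    b <- landscape$binding[i, ]
    e <- b$element
    if (is.na(kind[e]))
      stop("binding event references unknown element: ", e)
    hits <- list()
    if (kind[e] == "PRE") {
      hits[[length(hits) + 1L]] <- c(egene[[e]], "PRE_direct")
      for (n1 in nb[[e]])
        if (!is.na(kind[n1]) && kind[n1] == "PRE" && egene[[n1]] != egene[[e]])
          hits[[length(hits) + 1L]] <- c(egene[[n1]], "PRE_loop_PRE")
    } else { # DRE
      for (n1 in nb[[e]]) {
        if (is.na(kind[n1]) || kind[n1] != "PRE") next
        hits[[length(hits) + 1L]] <- c(egene[[n1]], "DRE_loop_PRE")
        for (n2 in nb[[n1]])
          if (n2 != e && !is.na(kind[n2]) && kind[n2] == "PRE" &&
              egene[[n2]] != egene[[n1]])
            hits[[length(hits) + 1L]] <- c(egene[[n2]],
                                           "DRE_loop_PRE_loop_PRE")
      }
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    out[[i]] <- data.frame(tf = b$tf, element = e, evidence = b$evidence,
                           cell_context = b$cell_context,
                           accessible = b$accessible,
                           target = h[, 1], topology = h[, 2],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(tf = character(), element = character(),
                      evidence = character(), cell_context = character(),
                      accessible = logical(), target = character(),
                      topology = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# class rank used to break ties when several classes share the maximum
# probability: chip > motif, same > cross, shorter topology first.
class_rank <- function(evidence, cell_context, topology) {
  ev <- match(evidence, c("chip", "motif", "eqtl", "null"))
  cc <- match(cell_context, c("same_cell", "cross_cell"))
  cc[is.na(cc)] <- 1L
  tp <- match(topology, TOPOLOGIES)
  tp[is.na(tp)] <- 1L
  (ev - 1L) * 8L + (cc - 1L) * 4L + tp
}

#' Build the TF prior table from a regulatory landscape
#'
#' Classifies every binding event by topology, drops cross-cell-type
#' evidence that does not fall in accessible chromatin, looks up the class
#' probability in `assignment`, and keeps the maximum probability per
#' (regulator, target) pair.  Self-pairs are discarded.
#'
#' @param landscape a `regulatory_landscape`
#' @param assignment probability assignment data frame, as produced by
#'   [default_probability_assignment()]
#' @return a `prior_table`
#' @export
build_tf_priors <- function(landscape,
                            assignment = default_probability_assignment()) {
  cls <- classify_topologies(landscape)
  cls <- cls[cls$cell_context != "cross_cell" | cls$accessible, , drop = FALSE]
  cls <- cls[cls$tf != cls$target, , drop = FALSE]
  if (!nrow(cls)) return(prior_table())
  akey <- paste(assignment$evidence, assignment$cell_context,
                assignment$topology)
  ckey <- paste(cls$evidence, cls$cell_context, cls$topology)
  idx <- match(ckey, akey)
  if (anyNA(idx))
    stop("probability assignment missing class: ",
         paste(unique(ckey[is.na(idx)]), collapse = "; "))
  cls$probability <- assignment$probability[idx]
  names(cls)[names(cls) == "tf"] <- "regulator"
  take_max_per_pair(cls)
}

# keep the max-probability row per ordered pair; ties broken by class rank
take_max_per_pair <- function(df) {
  df <- df[order(df$regulator, df$target, -df$probability,
                 class_rank(df$evidence, df$cell_context, df$topology)), ]
  df <- df[!duplicated(paste(df$regulator, df$target, sep = "\r")), ]
  prior_table(df[, c("regulator", "target", "probability", "evidence",
                     "cell_context", "topology")])
}

#' Merge prior tables by the maximum-probability rule
#'
#' The merged entry set is the union of pairs; a pair present in both tables
#' takes the maximum probability and the class label of the maximum
#' contributor (ties broken by the fixed class order).  The operation is
#' commutative, associative and idempotent.
#'
#' @param a,b `prior_table` objects
#' @return a `prior_table`
#' @export
merge_priors <- function(a, b) {
  df <- rbind(as.data.frame(a)[, c("regulator", "target", "probability",
                                   "evidence", "cell_context", "topology")],
              as.data.frame(b)[, c("regulator", "target", "probability",
                                   "evidence", "cell_context", "topology")])
  if (!nrow(df)) return(prior_table())
  take_max_per_pair(df)
}

#' Build eQTL priors from genotypes and expression
#'
#' For each SNP, dosage-expression correlations are tested against all
#' genes.  A SNP associated in cis (within `cis_window` of a gene's TSS on
#' the same chromosome) with gene A and in trans with gene B yields a causal
#' prior A -> B.  The prior probability is a monotone map of the trans
#' association strength: within the emitted set, |r| ranks are scaled into
#' `[0.05, 0.95]`.
#'
#' @param genotypes long data frame (`patient`, `snp`, `dosage`)
#' @param snps data frame (`snp`, `chrom`, `pos`)
#' @param expression numeric matrix genes x samples with patient ids as
#'   column names
#' @param genes data frame (`gene`, `chrom`, `tss`)
#' @param cis_window cis window around the TSS in bp
#' @param p_threshold nominal correlation-test p-value threshold for both
#'   the cis and the trans association
#' @return a `prior_table` with `evidence = "eqtl"`
#' @export
build_eqtl_priors <- function(genotypes, snps, expression, genes,
                              cis_window = 1e6, p_threshold = 1e-3) {
  shared <- intersect(unique(genotypes$patient), colnames(expression))
  if (!length(shared)) stop("no overlap between genotyped and expression samples")
  expr <- expression[, shared, drop = FALSE]
  out <- list()
  for (s in unique(genotypes$snp)) {
    gsub_ <- genotypes[genotypes$snp == s, ]
    dos <- gsub_$dosage[match(shared, gsub_$patient)]
    if (sum(!is.na(dos)) < 3 || stats::sd(dos, na.rm = TRUE) == 0) next
    sp <- snps[match(s, snps$snp), ]
    if (is.na(sp$chrom)) stop("SNP absent from snp table: ", s)
    r <- suppressWarnings(apply(expr, 1, function(x) stats::cor(dos, x)))
    r[is.na(r)] <- 0
    nn <- sum(!is.na(dos))
    tval <- abs(r) * sqrt(pmax(nn - 2, 1)) / sqrt(pmax(1 - r^2, 1e-12))
    pval <- 2 * stats::pt(tval, df = nn - 2, lower.tail = FALSE)
    gidx <- match(rownames(expr), genes$gene)
    is_cis <- !is.na(gidx) & genes$chrom[gidx] == sp$chrom &
      abs(genes$tss[gidx] - sp$pos) <= cis_window
    cis_hit <- which(is_cis & pval < p_threshold)
    if (!length(cis_hit)) next
    a <- rownames(expr)[cis_hit[which.min(pval[cis_hit])]]
    trans_hit <- which(!is_cis & pval < p_threshold)
    for (j in trans_hit) {
      b <- rownames(expr)[j]
      if (b == a) next
      out[[length(out) + 1L]] <- data.frame(regulator = a, target = b,
                                            strength = abs(r[j]),
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(prior_table())
  df <- do.call(rbind, out)
  m <- nrow(df)
  df$probability <- 0.05 + 0.9 * rank(df$strength, ties.method = "average") / m
  df$evidence <- "eqtl"
  df$cell_context <- NA_character_
  df$topology <- NA_character_
  take_max_per_pair(df)
}

#' Subset a prior table, or draw a Poisson null prior
#'
#' Modes mirror the four prior sets used for evaluation: `complete_tf`
#' (all physical-binding entries, proximal and distal), `proximal_tf`
#' (direct PRE binding only), `eqtl` (genetic-association entries), and
#' `null_poisson` (random pairs ignoring the input entries, with
#' Poisson-distributed out-degree per regulator at `null_rate`; null entry
#' probabilities are resampled from the input table's probabilities so the
#' marginal prior mass is comparable).
#'
#' @param table a `prior_table`
#' @param mode one of `complete_tf`, `proximal_tf`, `eqtl`, `null_poisson`
#' @param null_rate Poisson out-degree rate for the null mode
#' @param seed integer seed (null mode only)
#' @param regulators,genes universe for the null mode; default: the table's
#' @return a `prior_table`
#' @export
subset_priors <- function(table, mode = c("complete_tf", "proximal_tf",
                                          "eqtl", "null_poisson"),
                          null_rate = 3, seed = 1,
                          regulators = NULL, genes = NULL) {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  if (mode == "complete_tf") {
    keep <- df[df$evidence %in% c("chip", "motif"), , drop = FALSE]
    return(prior_table(keep))
  }
  if (mode == "proximal_tf") {
    keep <- df[df$evidence %in% c("chip", "motif") &
                 !is.na(df$topology) & df$topology == "PRE_direct", ,
               drop = FALSE]
    return(prior_table(keep))
  }
  if (mode == "eqtl") {
    return(prior_table(df[!is.na(df$evidence) & df$evidence == "eqtl", ,
                          drop = FALSE]))
  }
  # null_poisson
  set.seed(seed)
  if (is.null(regulators)) regulators <- unique(df$regulator)
  if (is.null(genes)) genes <- unique(c(df$regulator, df$target))
  probs <- df$probability
  out <- list()
  for (r in regulators) {
    pool <- setdiff(genes, r)
    d <- min(stats::rpois(1, null_rate), length(pool))
    if (d == 0) next
    tgt <- sample(pool, d)
    p <- if (length(probs)) sample(probs, d, replace = TRUE) else
      stats::runif(d, 0.05, 0.95)
    out[[r]] <- data.frame(regulator = r, target = tgt, probability = p,
                           evidence = "null", cell_context = NA_character_,
                           topology = NA_character_, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(prior_table())
  prior_table(do.call(rbind, out))
}
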