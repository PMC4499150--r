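## Network-interpretation statistics: tumor-subclass gene programs, drug-TF
## connectivity, expression perturbation, regulatory-driver discovery by
## mutation randomisation, driver/risk permutation tests and risk-allele
## susceptibility.  Expression matrices are assumed log-scale, so a k-fold
## change corresponds to an absolute difference of log2(k) between matched
## tumor and normal values.

tumor_cols <- function(cohort, patients) paste0(patients, "_T")
normal_cols <- function(cohort, patients) paste0(patients, "_N")

#' Patient-wise differential-expression vector for one gene
#'
#' Codes each matched tumor/normal patient as +1 (up-regulated), -1
#' (down-regulated) or 0 (unchanged) at a fold-change threshold (default
#' 2-fold, i.e. |tumor - normal| >= log2(2) on the log scale).
#'
#' @param cohort a `cohort_data`
#' @param gene gene identifier
#' @param fold fold-change threshold
#' @param patients subset of patients; default all
#' @return named integer vector in `{-1, 0, 1}` per patient
#' @export
diff_expression_vector <- function(cohort, gene, fold = 2, patients = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!gene %in% rownames(cohort$expression)) stop("unknown gene: ", gene)
  if (is.null(patients)) patients <- cohort$subclass$patient
  d <- cohort$expression[gene, tumor_cols(cohort, patients)] -
    cohort$expression[gene, normal_cols(cohort, patients)]
  v <- ifelse(abs(d) >= log2(fold), sign(d), 0L)
  stats::setNames(as.integer(v), patients)
}

#' Subclass-specific gene sets
#'
#' A gene is specific to a tumor subclass when it is differentially
#' expressed between tumor and matched normal by at least `fold` (either
#' direction) in strictly more than `patient_fraction` of that subclass's
#' patients.
#'
#' @param cohort a `cohort_data`
#' @param fold fold-change threshold (default 2)
#' @param patient_fraction patient fraction threshold, strict (default 0.20)
#' @return named list of gene vectors, one per subclass
#' @export
subclass_specific_genes <- function(cohort, fold = 2, patient_fraction = 0.20) {
  stopifnot(inherits(cohort, "cohort_data"))
  lab <- cohort$subclass
  out <- list()
  for (s in sort(unique(lab$subclass))) {
    pats <- lab$patient[lab$subclass == s]
    if (!length(pats)) {
      warning("subclass with no patients: ", s)
      out[[s]] <- character()
      next
    }
    dmat <- cohort$expression[, tumor_cols(cohort, pats), drop = FALSE] -
      cohort$expression[, normal_cols(cohort, pats), drop = FALSE]
    frac <- rowMeans(abs(dmat) >= log2(fold))
    out[[s]] <- rownames(cohort$expression)[frac > patient_fraction]
  }
  out
}

#' Fraction of a gene set reachable from a regulator
#'
#' Share of `gene_set` members lying downstream of `regulator` by directed
#' paths; genes absent from the network count as unreachable.
#'
#' @param network a `gene_network`
#' @param regulator gene id present in the network
#' @param gene_set character vector
#' @return fraction in `[0, 1]`
#' @export
descendant_pathway_fraction <- function(network, regulator, gene_set) {
  if (!regulator %in% network$nodes) stop("regulator not in network: ",
                                          regulator)
  if (!length(gene_set)) return(NaN)
  g <- as_igraph(network)
  desc <- setdiff(names(igraph::subcomponent(g, regulator, mode = "out")),
                  regulator)
  mean(gene_set %in% desc)
}

#' Network distance as intervening-node counts
#'
#' Shortest directed path length from `source` to each target, minus one
#' (the number of intervening nodes); a direct edge gives 0 and
#' unreachable targets give `Inf`.
#'
#' @param network a `gene_network`
#' @param source gene id present in the network
#' @param targets character vector of targets
#' @return named numeric vector of intervening-node counts
#' @export
network_distance <- function(network, source, targets) {
  if (!source %in% network$nodes) stop("source not in network: ", source)
  g <- as_igraph(network)
  tin <- intersect(targets, network$nodes)
  d <- rep(Inf, length(targets))
  names(d) <- targets
  if (length(tin)) {
    dd <- igraph::distances(g, v = source, to = tin, mode = "out")
    d[tin] <- dd[1, tin] - 1
  }
  d[targets == source] <- Inf
  d
}

#' Drug-TF connectivity matrix
#'
#' For each drug the `top_n` genes with the largest absolute expression
#' changes are selected; each responsive gene is attributed to its closest
#' upstream TF (minimum intervening-node directed distance; ties split the
#' gene's weight equally).  The raw connectivity score of a TF for a drug
#' is the fraction of the drug's responsive genes attributed to it, so raw
#' scores per drug sum to at most 1.  The matrix is then z-normalised
#' column-wise and row-wise (in that order), TFs whose normalised score
#' lies within (-0.2, 0.2) for every drug are removed, and the filtered
#' matrix is clustered two-way by complete linkage on Spearman-correlation
#' distance.
#'
#' @param network a `gene_network`
#' @param responses a `drug_response_set`, or a genes x drugs matrix of
#'   absolute change magnitudes
#' @param top_n responsive genes per drug (drugs with fewer measured genes
#'   use all, with a warning)
#' @param tfs TF universe; default: all regulators with outgoing edges
#' @param mode `"path"` attributes genes to TFs over directed paths (the
#'   default, consistent with the pathway-descendant analyses); `"direct"`
#'   counts direct targets only
#' @param filter_cutoff normalised-score filter half-width
#' @return object of class `connectivity_matrix`: `raw`, `normalized`,
#'   `filtered` matrices plus `row_hclust`/`col_hclust` (or NULL when the
#'   filtered matrix is too small to cluster)
#' @export
drug_connectivity <- function(network, responses, top_n = 200, tfs = NULL,
                              mode = c("path", "direct"),
                              filter_cutoff = 0.2) {
  mode <- match.arg(mode)
  changes <- if (inherits(responses, "drug_response_set")) responses$changes
             else responses
  stopifnot(is.matrix(changes))
  if (is.null(tfs)) tfs <- unique(network$edges$regulator)
  if (!length(tfs)) stop("no TFs with outgoing edges")
  g <- as_igraph(network)
  genes <- intersect(rownames(changes), network$nodes)
  D <- igraph::distances(g, v = tfs, to = genes, mode = "out")
  if (mode == "direct") D[D > 1] <- Inf
  D[D < 1] <- Inf  # a gene is not its own upstream TF
  raw <- matrix(0, length(tfs), ncol(changes),
                dimnames = list(tfs, colnames(changes)))
  for (j in seq_len(ncol(changes))) {
    v <- changes[, j]
    v <- v[names(v) %in% genes]
    if (length(v) < top_n)
      warning("drug ", colnames(changes)[j], ": only ", length(v),
              " measured genes; using all")
    top <- names(sort(-abs(v)))[seq_len(min(top_n, length(v)))]
    for (gx in top) {
      dg <- D[, gx]
      m <- min(dg)
      if (!is.finite(m)) next
      hit <- which(dg == m)
      raw[hit, j] <- raw[hit, j] + 1 / length(hit)
    }
    raw[, j] <- raw[, j] / length(top)
  }
  zcol <- scale(raw)
  zcol[is.nan(zcol)] <- 0
  norm <- t(scale(t(zcol)))
  norm[is.nan(norm)] <- 0
  keep <- apply(abs(norm) >= filter_cutoff, 1, any)
  filtered <- norm[keep, , drop = FALSE]
  row_h <- col_h <- NULL
  if (nrow(filtered) >= 3 && ncol(filtered) >= 3) {
    row_h <- tryCatch(stats::hclust(stats::as.dist(
      1 - stats::cor(t(filtered), method = "spearman")), method = "complete"),
      error = function(e) NULL)
    col_h <- tryCatch(stats::hclust(stats::as.dist(
      1 - stats::cor(filtered, method = "spearman")), method = "complete"),
      error = function(e) NULL)
  }
  structure(list(raw = raw, normalized = norm, filtered = filtered,
                 row_hclust = row_h, col_hclust = col_h),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("connectivity_matrix:", nrow(x$raw), "TFs x", ncol(x$raw), "drugs;",
      nrow(x$filtered), "TFs pass the normalised-score filter\n")
  invisible(x)
}

#' Group-wise expression perturbation
#'
#' For each gene, the expected level E is the mean across all samples of
#' `expr`; each group's perturbation score is the mean absolute deviation
#' from E within the group, `sum(|X_i - E|) / n`.  The summary fraction is
#' the share of `gene_set` genes whose group-1 score exceeds the group-2
#' score.
#'
#' @param expr numeric matrix genes x samples
#' @param gene_set genes to summarise (rows of `expr`)
#' @param group1,group2 disjoint character vectors of column names
#' @return list with `scores` (data frame: gene, group1, group2) and
#'   `fraction` (share of genes with group1 > group2)
#' @export
expression_perturbation <- function(expr, gene_set, group1, group2) {
  stopifnot(length(group1) >= 1, length(group2) >= 1)
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  gene_set <- intersect(gene_set, rownames(expr))
  e_all <- rowMeans(expr)
  s1 <- rowMeans(abs(expr[gene_set, group1, drop = FALSE] - e_all[gene_set]))
  s2 <- rowMeans(abs(expr[gene_set, group2, drop = FALSE] - e_all[gene_set]))
  list(scores = data.frame(gene = gene_set, group1 = s1, group2 = s2,
                           row.names = NULL, stringsAsFactors = FALSE),
       fraction = mean(s1 > s2))
}

#' Misregulation concordance of two differential-expression vectors
#'
#' Absolute Pearson correlation between two patient-wise -1/0/+1
#' differential-expression vectors (regulator and target), with the
#' two-sided correlation-test p-value.  Constant vectors are degenerate:
#' the result is flagged and both values are NA.
#'
#' @param reg,tgt integer vectors in `{-1,0,1}` over the same patients
#'   (length >= 3)
#' @return list: `r_abs`, `p`, `degenerate`
#' @export
misregulation_concordance <- function(reg, tgt) {
  if (length(reg) != length(tgt)) stop("vectors differ in length")
  if (length(reg) < 3) stop("need at least 3 patients")
  if (stats::sd(reg) == 0 || stats::sd(tgt) == 0) {
    return(list(r_abs = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(reg, tgt))
  list(r_abs = abs(unname(ct$estimate)), p = ct$p.value, degenerate = FALSE)
}

#' Combine coding and regulatory driver factors
#'
#' The transcriptional cancer driver set is the union of the coding driver
#' factors and the regulatory driver factors (TFs whose binding sites carry
#' recurrent non-coding mutations); factors in both lists are counted once.
#'
#' @param coding character vector of coding driver factors
#' @param regulatory character vector of regulatory driver factors
#' @return sorted character vector of drivers with attributes `n_coding`,
#'   `n_regulatory`, `n_overlap`, `n_total`
#' @export
transcriptional_drivers <- function(coding, regulatory) {
  u <- sort(union(coding, regulatory))
  structure(u, n_coding = length(unique(coding)),
            n_regulatory = length(unique(regulatory)),
            n_overlap = length(intersect(coding, regulatory)),
            n_total = length(u))
}

# driver statistic: per TF, the number of its target genes mutated in at
# least `recurrence_min` distinct patients
driver_statistic <- function(patient, tf, gene, recurrence_min = 2) {
  key <- paste(tf, gene, sep = "\r")
  npat <- tapply(patient, key, function(p) length(unique(p)))
  rec <- names(npat)[npat >= recurrence_min]
  tf_of <- sub("\r.*", "", rec)
  table(factor(tf_of, levels = unique(tf)))
}

#' Identify regulatory driver factors by mutation randomisation
#'
#' The observed statistic for each TF is the number of its target genes
#' recurrently hit by non-coding binding-site mutations (>= `recurrence_min`
#' distinct patients).  The null distribution reassigns each mutation to a
#' random binding site from the supplied pool — `clinical` mode resamples
#' within the same chromosome, which preserves the per-chromosome and
#' per-patient mutation counts; `insilico` mode samples sites uniformly with
#' the same per-patient counts.  Empirical p-values use the add-one
#' estimator `(1 + #{null >= obs}) / (n_sim + 1)`; drivers are TFs with
#' p below `alpha`.
#'
#' @param mutations data frame of observed mutations: `patient`, `chrom`,
#'   `site` (index/id into `sites`)
#' @param sites pool of mutable binding sites: `site`, `chrom`, `tf`,
#'   `gene` (the TF whose site it is, and the regulated target gene)
#' @param n_sim number of randomisations (>= 19 so p < 0.05 is reachable)
#' @param mode `clinical` or `insilico`
#' @param recurrence_min distinct patients required for recurrence
#' @param alpha significance threshold
#' @param seed integer seed
#' @return data frame: tf, observed, p, driver
#' @export
identify_regulatory_drivers <- function(mutations, sites, n_sim = 999,
                                        mode = c("clinical", "insilico"),
                                        recurrence_min = 2, alpha = 0.05,
                                        seed = 1) {
  mode <- match.arg(mode)
  if (n_sim < 19) stop("n_sim < 19 cannot reach p < 0.05")
  set.seed(seed)
  idx <- match(mutations$site, sites$site)
  if (anyNA(idx)) stop("mutation references unknown site")
  tfs <- unique(sites$tf)
  obs <- driver_statistic(mutations$patient, sites$tf[idx], sites$gene[idx],
                          recurrence_min)
  obs <- as.integer(obs[tfs]); obs[is.na(obs)] <- 0L
  names(obs) <- tfs
  m <- nrow(mutations)
  by_chrom <- split(seq_len(nrow(sites)), sites$chrom)
  ge <- matrix(0L, length(tfs), 1)
  count_ge <- stats::setNames(integer(length(tfs)), tfs)
  for (s in seq_len(n_sim)) {
    if (mode == "clinical") {
      pick <- integer(m)
      for (ch in unique(mutations$chrom)) {
        rows <- which(mutations$chrom == ch)
        pool <- by_chrom[[ch]]
        if (is.null(pool)) stop("no sites on chromosome ", ch)
        pick[rows] <- pool[sample.int(length(pool), length(rows),
                                      replace = TRUE)]
      }
    } else {
      pick <- sample.int(nrow(sites), m, replace = TRUE)
    }
    st <- driver_statistic(mutations$patient, sites$tf[pick],
                           sites$gene[pick], recurrence_min)
    st <- as.integer(st[tfs]); st[is.na(st)] <- 0L
    count_ge <- count_ge + (st >= obs)
  }
  p <- (1 + count_ge) / (n_sim + 1)
  data.frame(tf = tfs, observed = obs, p = p, driver = p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation test of driver-to-risk-gene connectivity
#'
#' Observed statistics: (i) the number of directed driver-to-risk edges,
#' (ii) the percentage of risk genes with at least one incoming driver
#' link — reported both for direct edges (the headline statistic) and for
#' directed paths — and the reverse-direction counterparts.  The null
#' resamples gene sets of the same size as the risk set from the network
#' nodes minus the drivers; empirical p-values use the add-one estimator.
#'
#' @param network a `gene_network`
#' @param drivers,risk_genes disjoint gene sets within the network nodes
#' @param n_perm number of random samplings
#' @param seed integer seed
#' @return object of class `driver_risk_test`: `observed` and `p` (named
#'   lists over the five statistics), `n_perm`, set sizes
#' @export
driver_risk_connectivity_test <- function(network, drivers, risk_genes,
                                          n_perm = 1000, seed = 1) {
  set.seed(seed)
  nodes <- network$nodes
  drivers <- intersect(drivers, nodes)
  universe <- setdiff(nodes, drivers)
  risk_genes <- intersect(risk_genes, universe)
  if (length(risk_genes) > length(universe))
    stop("risk set larger than sampling universe")
  if (!length(risk_genes)) stop("empty risk set")
  e <- network$edges
  from_driver <- e[e$regulator %in% drivers, ]
  in_deg_driver <- table(factor(from_driver$target, levels = nodes))
  g <- as_igraph(network)
  desc <- unique(unlist(lapply(drivers, function(d)
    names(igraph::subcomponent(g, d, mode = "out")))))
  desc <- setdiff(desc, drivers)
  to_driver <- e[e$target %in% drivers, ]
  out_to_driver <- table(factor(to_driver$regulator, levels = nodes))
  driver_parents <- lapply(drivers, function(d) e$regulator[e$target == d])

  stat_fun <- function(set) {
    c(links_direct = sum(in_deg_driver[set]),
      pct_incoming_direct = 100 * mean(in_deg_driver[set] > 0),
      pct_incoming_path = 100 * mean(set %in% desc),
      reverse_links_direct = sum(out_to_driver[set]),
      reverse_pct_incoming_direct =
        100 * mean(vapply(driver_parents,
                          function(par) any(par %in% set), TRUE)))
  }
  obs <- stat_fun(risk_genes)
  ge <- numeric(length(obs))
  for (i in seq_len(n_perm)) {
    s <- sample(universe, length(risk_genes))
    ge <- ge + (stat_fun(s) >= obs)
  }
  p <- (1 + ge) / (n_perm + 1)
  names(p) <- names(obs)
  structure(list(observed = obs, p = p, n_perm = n_perm,
                 n_drivers = length(drivers), n_risk = length(risk_genes)),
            class = "driver_risk_test")
}

#' @export
print.driver_risk_test <- function(x, ...) {
  cat("driver-risk connectivity permutation test (", x$n_perm,
      " samplings)\n", sep = "")
  df <- data.frame(statistic = names(x$observed),
                   observed = round(unname(x$observed), 3),
                   p = unname(x$p))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Risk-allele susceptibility of driver-risk gene pairs
#'
#' Patients are split by the linked SNP into a risk group (dosage >= 1;
#' heterozygotes count as risk carriers) and a non-risk group.  A pair is
#' evaluated only when both groups have strictly more than `min_group`
#' patients.  Misregulation concordance between the driver and the risk
#' gene is computed within each group; "identified cases" are pairs whose
#' concordance is significant (p < `p_threshold`) in either group.  The
#' summary is the fraction of identified cases in which the risk group's
#' |r| exceeds the non-risk group's.
#'
#' @param cohort a `cohort_data` with genotypes
#' @param pairs data frame: `driver`, `gene`, `snp`
#' @param min_group strict minimum group size
#' @param p_threshold concordance significance threshold
#' @param fold fold-change threshold for the differential vectors
#' @return list with `pairs` (per-pair table: group sizes, |r| and p per
#'   group, identified flag) and `fraction` (risk > non-risk among
#'   identified cases; NaN when none)
#' @export
risk_allele_susceptibility <- function(cohort, pairs, min_group = 10,
                                       p_threshold = 0.01, fold = 2) {
  stopifnot(inherits(cohort, "cohort_data"))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    snp <- pairs$snp[i]
    gt <- cohort$genotypes[cohort$genotypes$snp == snp, ]
    if (!nrow(gt)) stop("SNP absent from genotypes: ", snp)
    risk_p <- gt$patient[gt$dosage >= 1]
    nonrisk_p <- gt$patient[gt$dosage == 0]
    rec <- data.frame(driver = pairs$driver[i], gene = pairs$gene[i],
                      snp = snp, n_risk = length(risk_p),
                      n_nonrisk = length(nonrisk_p),
                      r_risk = NA_real_, p_risk = NA_real_,
                      r_nonrisk = NA_real_, p_nonrisk = NA_real_,
                      evaluated = FALSE, identified = FALSE,
                      stringsAsFactors = FALSE)
    if (length(risk_p) > min_group && length(nonrisk_p) > min_group) {
      cr <- misregulation_concordance(
        diff_expression_vector(cohort, pairs$driver[i], fold, risk_p),
        diff_expression_vector(cohort, pairs$gene[i], fold, risk_p))
      cn <- misregulation_concordance(
        diff_expression_vector(cohort, pairs$driver[i], fold, nonrisk_p),
        diff_expression_vector(cohort, pairs$gene[i], fold, nonrisk_p))
      rec$evaluated <- TRUE
      rec$r_risk <- cr$r_abs; rec$p_risk <- cr$p
      rec$r_nonrisk <- cn$r_abs; rec$p_nonrisk <- cn$p
      rec$identified <- isTRUE(cr$p < p_threshold) ||
        isTRUE(cn$p < p_threshold)
    }
    out[[i]] <- rec
  }
  tab <- do.call(rbind, out)
  idf <- tab[tab$identified & !is.na(tab$r_risk) & !is.na(tab$r_nonrisk), ]
  list(pairs = tab,
       fraction = if (nrow(idf)) mean(idf$r_risk > idf$r_nonrisk) else NaN)
}
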