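#' Generate a ground-truth regulatory network
#'
#' Samples a random directed acyclic network in which only a designated set
#' of regulator nodes (transcription factors) have outgoing edges.  Edges are
#' drawn forward along a random topological order, which guarantees
#' acyclicity by construction.  Each edge carries a sign (+1 activation, -1
#' inhibition) and a linear effect size used by [simulate_expression()].
#'
#' @param n_genes total number of genes (>= 2)
#' @param n_regulators number of regulator (TF) nodes, <= `n_genes`
#' @param mean_out_degree expected number of targets per regulator
#'   (Poisson-distributed, truncated by the number of downstream nodes)
#' @param seed integer seed; identical seeds give identical networks
#' @param effect_range range of absolute per-edge linear effects
#' @return object of class `true_network` with elements `nodes`,
#'   `regulators`, `order` (the topological order used) and `edges`
#'   (data frame: regulator, target, sign, effect).
#' @export
generate_true_network <- function(n_genes, n_regulators, mean_out_degree,
                                  seed = 1, effect_range = c(0.8, 1.2)) {
  if (n_genes < 2) stop("n_genes must be >= 2")
  if (n_regulators < 1 || n_regulators > n_genes)
    stop("n_regulators must be in [1, n_genes]")
  if (mean_out_degree <= 0) stop("mean_out_degree must be > 0")
  set.seed(seed)
  regulators <- sprintf("TF%02d", seq_len(n_regulators))
  others <- if (n_genes > n_regulators)
    sprintf("G%03d", seq_len(n_genes - n_regulators)) else character()
  nodes <- c(regulators, others)
  ord <- sample(nodes)
  pos <- match(nodes, ord)
  edges <- list()
  for (r in regulators) {
    downstream <- ord[seq_along(ord) > pos[match(r, nodes)]]
    if (!length(downstream)) next
    d <- min(stats::rpois(1, mean_out_degree), length(downstream))
    if (d == 0) next
    tgt <- sample(downstream, d)
    edges[[r]] <- data.frame(regulator = r, target = tgt,
                             stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(regulator = character(), target = character())
  if (nrow(edges)) {
    edges$sign <- sample(c(1, -1), nrow(edges), replace = TRUE)
    edges$effect <- stats::runif(nrow(edges), effect_range[1], effect_range[2])
    edges <- edges[order(edges$regulator, edges$target), ]
    rownames(edges) <- NULL
  } else {
    edges$sign <- numeric(); edges$effect <- numeric()
  }
  structure(list(nodes = nodes, regulators = regulators, order = ord,
                 edges = edges),
            class = "true_network")
}

#' @export
print.true_network <- function(x, ...) {
  cat("true_network:", length(x$nodes), "genes (",
      length(x$regulators), "regulators ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Ground-truth edges as a gene_network
#' @param truth a `true_network`
#' @return `gene_network` over the truth's node universe
#' @export
truth_network <- function(truth) {
  stopifnot(inherits(truth, "true_network"))
  gene_network(truth$edges, nodes = truth$nodes)
}

#' Generate a synthetic regulatory landscape for a known network
#'
#' Builds genes with TSS coordinates, promoter-proximal elements (PREs),
#' distal elements (DREs), chromatin loops and TF binding events such that
#' every true edge is physically supported by one of the four binding
#' topologies: direct PRE binding, DRE looped to a PRE, binding at another
#' gene's PRE looped to the target's PRE, or a DRE--PRE--PRE chain.  Tethered
#' topologies route through a companion true target of the same regulator on
#' dedicated secondary PREs, so that with `decoy_binding_rate = 0` the
#' implied regulator-target pair set equals the truth edge set exactly.
#' Decoy binding events (pairs that are not true edges) are added at the
#' requested rate.
#'
#' Coordinates are 0-based half-open (BED convention).  DRE--PRE loop spans
#' are drawn from a log-normal distribution (default median 100 kb) capped
#' at 1 Mb, intra-chromosomal.
#'
#' @param truth a `true_network`
#' @param decoy_binding_rate decoy events per true-edge event, in `[0, 1]`
#' @param loop_distance list with `meanlog`, `sdlog`, `cap` describing the
#'   DRE--PRE span distribution in bp
#' @param pre_halfwidth half-width of the PRE window around the TSS, bp
#' @param seed integer seed
#' @return object of class `regulatory_landscape`: `genes`, `elements`,
#'   `loops`, `binding` data frames.
#' @export
generate_landscape <- function(truth, decoy_binding_rate = 0.2,
                               loop_distance = list(meanlog = log(1e5),
                                                    sdlog = 0.8, cap = 1e6),
                               pre_halfwidth = 2500, seed = 1) {
  stopifnot(inherits(truth, "true_network"))
  if (decoy_binding_rate < 0 || decoy_binding_rate > 1)
    stop("decoy_binding_rate must be in [0, 1]")
  set.seed(seed)
  nodes <- truth$nodes
  n <- length(nodes)
  n_chrom <- max(1L, ceiling(n / 15))
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% n_chrom) + 1L)
  idx_on_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  tss <- 2e6 * idx_on_chrom + sample.int(1e4, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  glen <- round(stats::runif(n, 2e4, 2e5))
  genes <- data.frame(gene = nodes, chrom = chrom, strand = strand,
                      tss = tss,
                      start = ifelse(strand == "+", tss, tss - glen),
                      end = ifelse(strand == "+", tss + glen, tss),
                      stringsAsFactors = FALSE)
  hw <- pre_halfwidth
  elements <- data.frame(element = paste0("PRE_", nodes),
                         kind = "PRE", chrom = chrom,
                         start = pmax(0, tss - hw), end = tss + hw,
                         gene = nodes, stringsAsFactors = FALSE)
  loops <- data.frame(anchor1 = character(), anchor2 = character())
  binding <- data.frame(tf = character(), element = character(),
                        evidence = character(), cell_context = character(),
                        accessible = logical())

  draw_span <- function() {
    min(loop_distance$cap,
        round(stats::rlnorm(1, loop_distance$meanlog, loop_distance$sdlog)))
  }
  gene_row <- function(g) genes[match(g, genes$gene), ]
  new_elements <- list(); new_loops <- list(); new_binding <- list()
  dre_i <- 0L; sec_count <- new.env(parent = emptyenv())

  add_dre <- function(near_gene) {
    # a fresh DRE near `near_gene`'s TSS at a loop-span distance
    dre_i <<- dre_i + 1L
    gr <- gene_row(near_gene)
    d <- draw_span()
    pos <- max(0, gr$tss + sample(c(-1, 1), 1) * d)
    id <- sprintf("DRE%04d", dre_i)
    new_elements[[id]] <<- data.frame(element = id, kind = "DRE",
                                      chrom = gr$chrom, start = pos,
                                      end = pos + 600, gene = NA_character_,
                                      stringsAsFactors = FALSE)
    id
  }
  add_secondary_pre <- function(g) {
    ct <- (sec_count[[g]] %||% 0L) + 1L
    sec_count[[g]] <- ct
    gr <- gene_row(g)
    id <- sprintf("PRE_%s_s%03d", g, ct)
    off <- hw * 2 + 500 * ct
    new_elements[[id]] <<- data.frame(element = id, kind = "PRE",
                                      chrom = gr$chrom,
                                      start = gr$tss + off,
                                      end = gr$tss + off + hw,
                                      gene = g, stringsAsFactors = FALSE)
    id
  }
  add_loop <- function(a, b) new_loops[[length(new_loops) + 1L]] <<-
    data.frame(anchor1 = a, anchor2 = b, stringsAsFactors = FALSE)
  add_event <- function(tf, el, accessible = TRUE) {
    ev <- sample(c("chip", "motif"), 1, prob = c(0.65, 0.35))
    cc <- sample(c("same_cell", "cross_cell"), 1, prob = c(0.7, 0.3))
    new_binding[[length(new_binding) + 1L]] <<-
      data.frame(tf = tf, element = el, evidence = ev, cell_context = cc,
                 accessible = accessible, stringsAsFactors = FALSE)
  }

  for (r in unique(truth$edges$regulator)) {
    targets <- truth$edges$target[truth$edges$regulator == r]
    for (t in targets) {
      topo_pool <- c("direct", "dre_loop")
      if (length(targets) >= 2) topo_pool <- c(topo_pool, "pre_loop", "chain")
      topo <- sample(topo_pool, 1,
                     prob = c(0.35, 0.35, 0.15, 0.15)[seq_along(topo_pool)])
      if (topo == "direct") {
        add_event(r, paste0("PRE_", t))
      } else if (topo == "dre_loop") {
        dre <- add_dre(t)
        add_loop(dre, paste0("PRE_", t))
        add_event(r, dre)
      } else {
        comp <- sample(setdiff(targets, t), 1)
        sec_t <- add_secondary_pre(t)
        sec_c <- add_secondary_pre(comp)
        if (topo == "pre_loop") {
          add_loop(sec_c, sec_t)
          add_event(r, sec_c)
        } else { # chain: DRE -- PRE(companion) -- PRE(target)
          dre <- add_dre(comp)
          add_loop(dre, sec_c)
          add_loop(sec_c, sec_t)
          add_event(r, dre)
        }
      }
    }
  }

  n_true_events <- length(new_binding)
  n_decoy <- round(decoy_binding_rate * n_true_events)
  truth_keys <- paste(truth$edges$regulator, truth$edges$target, sep = "\r")
  if (n_decoy > 0 && length(truth$regulators)) {
    made <- 0L; guard <- 0L
    while (made < n_decoy && guard < 50 * n_decoy) {
      guard <- guard + 1L
      tf <- sample(truth$regulators, 1)
      g <- sample(nodes, 1)
      if (g == tf || paste(tf, g, sep = "\r") %in% truth_keys) next
      if (stats::runif(1) < 0.7) {
        el <- paste0("PRE_", g)
      } else {
        el <- add_dre(g)
        add_loop(el, paste0("PRE_", g))
      }
      add_event(tf, el, accessible = stats::runif(1) < 0.8)
      made <- made + 1L
    }
  }

  if (length(new_elements))
    elements <- rbind(elements, do.call(rbind, new_elements))
  if (length(new_loops)) loops <- do.call(rbind, new_loops)
  if (length(new_binding)) binding <- do.call(rbind, new_binding)
  rownames(elements) <- rownames(loops) <- rownames(binding) <- NULL
  structure(list(genes = genes, elements = elements, loops = loops,
                 binding = binding),
            class = "regulatory_landscape")
}

#' @export
print.regulatory_landscape <- function(x, ...) {
  cat("regulatory_landscape:", nrow(x$genes), "genes,",
      sum(x$elements$kind == "PRE"), "PREs,",
      sum(x$elements$kind == "DRE"), "DREs,",
      nrow(x$loops), "loops,", nrow(x$binding), "binding events\n")
  invisible(x)
}

#' Simulate continuous expression from a true network
#'
#' Linear-Gaussian model evaluated in topological order: root genes are
#' standard normal; every other gene is the signed, effect-weighted sum of
#' its parents plus Gaussian noise.  The returned matrix emulates a
#' normalised (log-scale) expression matrix; discretisation for network
#' scoring is done separately by [discretize_expression()].
#'
#' @param truth a `true_network`
#' @param n_samples number of samples (columns)
#' @param noise_sd Gaussian noise standard deviation (> 0)
#' @param seed integer seed
#' @return numeric matrix genes x samples
#' @export
simulate_expression <- function(truth, n_samples, noise_sd = 0.5, seed = 1) {
  stopifnot(inherits(truth, "true_network"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  set.seed(seed)
  sim_expression_matrix(truth, n_samples, noise_sd)
}

# internal: one expression draw per column; optional per-gene additive shift
# and per-gene multiplier on incoming-edge effects (used by simulate_cohort).
sim_expression_matrix <- function(truth, n_samples, noise_sd,
                                  shift = NULL, amp = NULL) {
  nodes <- truth$nodes
  x <- matrix(0, length(nodes), n_samples,
              dimnames = list(nodes, sprintf("S%03d", seq_len(n_samples))))
  e <- truth$edges
  parents <- split(seq_len(nrow(e)), e$target)
  for (g in truth$order) {
    p <- parents[[g]]
    if (is.null(p)) {
      x[g, ] <- stats::rnorm(n_samples)
    } else {
      w <- e$sign[p] * e$effect[p]
      if (!is.null(amp) && g %in% names(amp)) w <- w * amp[[g]]
      contrib <- drop(crossprod(x[e$regulator[p], , drop = FALSE], w))
      x[g, ] <- contrib + stats::rnorm(n_samples, sd = noise_sd)
    }
    if (!is.null(shift) && g %in% names(shift)) x[g, ] <- x[g, ] + shift[[g]]
  }
  x
}

#' Discretize an expression matrix for network scoring
#'
#' Per-gene z-scores cut into `k` levels; with the default three levels the
#' cut points are at z = -1 and z = +1.
#'
#' @param x numeric matrix genes x samples
#' @param k number of levels
#' @param cuts cut points on the z scale (length `k - 1`)
#' @return integer matrix with values in `1..k` and attribute `"k"`
#' @export
discretize_expression <- function(x, k = 3, cuts = c(-1, 1)) {
  stopifnot(is.matrix(x), length(cuts) == k - 1)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (x - mu) / sdv
  d <- matrix(findInterval(z, cuts) + 1L, nrow(x), ncol(x),
              dimnames = dimnames(x))
  attr(d, "k") <- as.integer(k)
  d
}

#' Default effect configuration for cohort simulation
#'
#' @param driver_shift additive shift (in noise-SD units of the expression
#'   scale) applied to a mutated driver gene in tumor tissue
#' @param driver_freq per-driver probability that a patient carries the
#'   mutation
#' @param risk_amplification multiplier on the incoming-edge effects of a
#'   risk gene in risk-allele carriers (both tissues; the genotype is
#'   constitutive)
#' @param risk_maf risk-allele frequency used to draw genotype dosages
#' @param subclass_shift additive tumor shift for subclass-specific gene
#'   sets (0 disables subclass effects)
#' @param subclass_gene_fraction fraction of genes made specific per subclass
#' @param noise_sd expression noise standard deviation
#' @return named list of class `cohort_effects`
#' @export
cohort_effects <- function(driver_shift = 3, driver_freq = 0.35,
                           risk_amplification = 2.5, risk_maf = 0.35,
                           subclass_shift = 0, subclass_gene_fraction = 0.1,
                           noise_sd = 0.5) {
  structure(list(driver_shift = driver_shift, driver_freq = driver_freq,
                 risk_amplification = risk_amplification,
                 risk_maf = risk_maf, subclass_shift = subclass_shift,
                 subclass_gene_fraction = subclass_gene_fraction,
                 noise_sd = noise_sd),
            class = "cohort_effects")
}

#' Simulate a paired tumor/normal cohort
#'
#' Every patient contributes a matched tumor and normal expression sample
#' drawn from the linear-Gaussian model of `truth`.  Patients carrying a
#' driver mutation have that driver shifted in tumor tissue (the shift
#' propagates to downstream genes through the network).  Carriers of a risk
#' allele (dosage >= 1; heterozygotes count as carriers) have the incoming
#' regulatory effects of the linked risk gene amplified in both tissues,
#' which raises that gene's transcriptional responsiveness to its upstream
#' regulators.
#'
#' @param truth a `true_network`
#' @param n_patients number of patients
#' @param driver_genes genes mutated in a fraction of patients (must exist
#'   in `truth`)
#' @param risk_links data frame (`snp`, `gene`) linking risk SNPs to genes
#' @param effect_config a [cohort_effects()] list
#' @param seed integer seed
#' @return object of class `cohort_data` with `expression` (genes x samples,
#'   columns `<patient>_T` / `<patient>_N`), `samples`, `subclass`,
#'   `coding_mutations`, `noncoding_mutations`, `genotypes`, `risk_links`.
#' @export
simulate_cohort <- function(truth, n_patients, driver_genes = character(),
                            risk_links = NULL,
                            effect_config = cohort_effects(), seed = 1) {
  stopifnot(inherits(truth, "true_network"))
  if (n_patients < 1) stop("n_patients must be >= 1")
  unknown <- setdiff(c(driver_genes,
                       if (!is.null(risk_links)) risk_links$gene), truth$nodes)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  cfg <- effect_config
  set.seed(seed)
  patients <- sprintf("P%03d", seq_len(n_patients))
  subclasses <- c("luminalA", "luminalB", "HER2", "basal")
  subclass <- data.frame(patient = patients,
                         subclass = sample(subclasses, n_patients,
                                           replace = TRUE,
                                           prob = c(0.35, 0.2, 0.15, 0.3)),
                         stringsAsFactors = FALSE)
  # subclass-specific gene programs (fixed gene sets per subclass)
  sub_sets <- list()
  if (cfg$subclass_shift != 0) {
    n_sub <- max(1L, round(cfg$subclass_gene_fraction * length(truth$nodes)))
    for (s in subclasses) sub_sets[[s]] <- sample(truth$nodes, n_sub)
  }
  coding <- data.frame(patient = character(), gene = character())
  for (d in driver_genes) {
    carriers <- patients[stats::runif(n_patients) < cfg$driver_freq]
    if (length(carriers))
      coding <- rbind(coding, data.frame(patient = carriers, gene = d,
                                         stringsAsFactors = FALSE))
  }
  genotypes <- data.frame(patient = character(), snp = character(),
                          dosage = integer())
  if (!is.null(risk_links) && nrow(risk_links)) {
    for (s in unique(risk_links$snp)) {
      genotypes <- rbind(genotypes,
                         data.frame(patient = patients, snp = s,
                                    dosage = stats::rbinom(n_patients, 2,
                                                           cfg$risk_maf),
                                    stringsAsFactors = FALSE))
    }
  }
  nodes <- truth$nodes
  expr <- matrix(0, length(nodes), 2 * n_patients, dimnames = list(
    nodes, as.vector(rbind(paste0(patients, "_T"), paste0(patients, "_N")))))
  for (i in seq_len(n_patients)) {
    p <- patients[i]
    amp <- NULL
    if (nrow(genotypes)) {
      g_p <- genotypes[genotypes$patient == p & genotypes$dosage >= 1, ]
      if (nrow(g_p)) {
        risk_g <- unique(risk_links$gene[risk_links$snp %in% g_p$snp])
        if (length(risk_g))
          amp <- stats::setNames(rep(cfg$risk_amplification, length(risk_g)),
                                 risk_g)
      }
    }
    shift_t <- numeric(0)
    mut_p <- coding$gene[coding$patient == p]
    if (length(mut_p))
      shift_t <- stats::setNames(rep(cfg$driver_shift, length(mut_p)), mut_p)
    if (length(sub_sets)) {
      sg <- sub_sets[[subclass$subclass[i]]]
      add <- stats::setNames(rep(cfg$subclass_shift, length(sg)), sg)
      shift_t <- c(shift_t, add[setdiff(names(add), names(shift_t))])
    }
    expr[, 2 * i - 1] <- sim_expression_matrix(truth, 1, cfg$noise_sd,
                                               shift = if (length(shift_t)) shift_t,
                                               amp = amp)
    expr[, 2 * i] <- sim_expression_matrix(truth, 1, cfg$noise_sd, amp = amp)
  }
  samples <- data.frame(sample = colnames(expr),
                        patient = rep(patients, each = 2),
                        tissue = rep(c("tumor", "normal"), n_patients),
                        stringsAsFactors = FALSE)
  # non-coding mutation records (plumbing for driver-discovery inputs)
  noncoding <- list()
  regs_with_targets <- intersect(truth$regulators, truth$edges$regulator)
  if (length(regs_with_targets)) {
    for (p in patients) {
      m <- stats::rpois(1, 1)
      if (m == 0) next
      tf <- sample(regs_with_targets, m, replace = TRUE)
      tgt <- vapply(tf, function(f)
        sample(truth$edges$target[truth$edges$regulator == f], 1), "")
      noncoding[[p]] <- data.frame(
        patient = p, chrom = paste0("chr", sample.int(23, m, replace = TRUE)),
        position = sample.int(1e8, m), broken_tf = tf, target_gene = tgt,
        stringsAsFactors = FALSE)
    }
  }
  noncoding <- if (length(noncoding)) do.call(rbind, noncoding) else
    data.frame(patient = character(), chrom = character(),
               position = integer(), broken_tf = character(),
               target_gene = character())
  rownames(noncoding) <- NULL
  structure(list(expression = expr, samples = samples, subclass = subclass,
                 coding_mutations = coding, noncoding_mutations = noncoding,
                 genotypes = genotypes, risk_links = risk_links,
                 driver_genes = driver_genes),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", nrow(x$subclass), "patients (matched tumor/normal),",
      nrow(x$expression), "genes\n")
  invisible(x)
}

#' Simulate drug-response expression changes
#'
#' Each drug is assigned one or more true target TFs; genes downstream of
#' those TFs in the truth network receive large absolute expression changes
#' while all other genes receive small noise.  The annotation records the
#' true TFs per drug so that connectivity analyses can be validated.
#'
#' @param truth a `true_network`
#' @param n_drugs number of drugs (>= 1)
#' @param targets_per_drug TFs targeted by each drug (>= 1)
#' @param seed integer seed
#' @param effect mean absolute change of downstream genes
#' @param noise_sd scale of the background changes
#' @return object of class `drug_response_set`: `changes` (genes x drugs
#'   matrix of absolute change magnitudes) and `targets` (list drug -> TFs).
#' @export
simulate_drug_responses <- function(truth, n_drugs, targets_per_drug = 1,
                                    seed = 1, effect = 3, noise_sd = 0.3) {
  stopifnot(inherits(truth, "true_network"))
  if (n_drugs < 1) stop("n_drugs must be >= 1")
  if (targets_per_drug < 1) stop("targets_per_drug must be >= 1")
  set.seed(seed)
  g <- as_igraph(truth_network(truth))
  drugs <- sprintf("drug%03d", seq_len(n_drugs))
  changes <- matrix(abs(stats::rnorm(length(truth$nodes) * n_drugs,
                                     sd = noise_sd)),
                    length(truth$nodes), n_drugs,
                    dimnames = list(truth$nodes, drugs))
  targets <- list()
  regs <- intersect(truth$regulators, truth$edges$regulator)
  for (d in drugs) {
    tfs <- sample(regs, min(targets_per_drug, length(regs)))
    targets[[d]] <- tfs
    down <- unique(unlist(lapply(tfs, function(f)
      names(igraph::subcomponent(g, f, mode = "out")))))
    down <- setdiff(down, tfs)
    if (length(down))
      changes[down, d] <- abs(stats::rnorm(length(down), mean = effect))
  }
  structure(list(changes = changes, targets = targets),
            class = "drug_response_set")
}

#' @export
print.drug_response_set <- function(x, ...) {
  cat("drug_response_set:", ncol(x$changes), "drugs x", nrow(x$changes),
      "genes\n")
  invisible(x)
}
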