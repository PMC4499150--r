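# cohort with hand-set tumor/normal values (log scale)
fixed_cohort <- function() {
  # 5 patients, 3 genes; gene UP is 3-fold up in all basal patients,
  # gene EDGE is 2-fold up in exactly 1 of 5 (= 20%), gene FLAT constant
  patients <- paste0("P", 1:5)
  expr <- matrix(0, 3, 10,
                 dimnames = list(c("UP", "EDGE", "FLAT"),
                                 as.vector(rbind(paste0(patients, "_T"),
                                                 paste0(patients, "_N")))))
  expr["UP", paste0(patients, "_T")] <- log2(3)
  expr["EDGE", "P1_T"] <- 1
  make_cohort(expr, subclass = rep("basal", 5))
}

test_that("subclass-specific genes require a strict patient fraction", {
  co <- fixed_cohort()
  sets <- subclass_specific_genes(co)
  expect_true("UP" %in% sets$basal)
  expect_false("EDGE" %in% sets$basal)   # exactly 20% is excluded
  expect_false("FLAT" %in% sets$basal)
})

test_that("differential-expression vectors code the 2-fold threshold", {
  co <- fixed_cohort()
  expect_equal(unname(diff_expression_vector(co, "UP")), rep(1L, 5))
  expect_equal(unname(diff_expression_vector(co, "EDGE")),
               c(1L, 0L, 0L, 0L, 0L))
  expect_error(diff_expression_vector(co, "NOPE"), "unknown")
})

test_that("descendant fractions and network distances follow reachability", {
  star <- gene_network(data.frame(regulator = "hub",
                                  target = paste0("g", 1:5)))
  expect_equal(descendant_pathway_fraction(star, "hub", paste0("g", 2:4)), 1)
  chain <- gene_network(data.frame(regulator = c("a", "b"),
                                   target = c("b", "c")),
                        nodes = c("a", "b", "c", "d"))
  expect_equal(descendant_pathway_fraction(chain, "a", c("b", "c", "d")),
               2 / 3)
  expect_equal(descendant_pathway_fraction(chain, "c", c("a", "b")), 0)
  expect_error(descendant_pathway_fraction(chain, "zzz", "a"), "not in")

  d <- network_distance(chain, "a", c("b", "c", "d"))
  expect_equal(unname(d), c(0, 1, Inf))
})

test_that("drug connectivity attributes responsive genes to upstream TFs", {
  net <- gene_network(data.frame(regulator = "TF1",
                                 target = paste0("g", 1:6)),
                      nodes = c("TF1", "TF2", paste0("g", 1:8)))
  changes <- matrix(0.1, 10, 1,
                    dimnames = list(c("TF1", "TF2", paste0("g", 1:8)),
                                    "drugA"))
  changes[paste0("g", 1:4), 1] <- 5
  suppressWarnings(cm <- drug_connectivity(net, changes, top_n = 4,
                                           tfs = c("TF1", "TF2")))
  expect_equal(cm$raw["TF1", "drugA"], 1)   # all top genes are TF1 targets
  expect_equal(cm$raw["TF2", "drugA"], 0)
  expect_true(all(colSums(cm$raw) <= 1 + 1e-12))
})

test_that("synthetic drugs score highest for their true target TF", {
  # flat TF layer with balanced out-degrees: with TF-on-TF edges the
  # closest upstream regulator of a changed gene would legitimately be an
  # intermediate TF rather than the drug target
  tfs <- paste0("TF", 1:6)
  tgts <- paste0("g", 1:36)
  edges <- data.frame(regulator = rep(tfs, each = 6), target = tgts,
                      sign = 1, effect = 1)
  truth <- make_truth(c(tfs, tgts), tfs, edges, order = c(tfs, tgts))
  net <- truth_network(truth)
  dr <- simulate_drug_responses(truth, 8, seed = 3)
  suppressWarnings(cm <- drug_connectivity(net, dr, top_n = 6))
  hits <- 0
  for (d in colnames(cm$raw)) {
    tf <- dr$targets[[d]]
    if (!tf %in% rownames(cm$raw)) next
    if (cm$raw[tf, d] == max(cm$raw[, d])) hits <- hits + 1
  }
  expect_gte(hits / ncol(cm$raw), 0.75)

  # permuting gene labels destroys the matched drug-TF structure
  perm <- dr$changes
  set.seed(5)
  rownames(perm) <- sample(rownames(perm))
  suppressWarnings(cmp <- drug_connectivity(net, perm, top_n = 6))
  matched <- vapply(colnames(cm$raw), function(d)
    cm$raw[dr$targets[[d]], d], 0)
  matched_perm <- vapply(colnames(cmp$raw), function(d)
    cmp$raw[dr$targets[[d]], d], 0)
  expect_gt(mean(matched), mean(matched_perm))
})

test_that("expression perturbation is a mean absolute deviation from E", {
  expr <- matrix(c(1, 3, 1, 3), 1, 4,
                 dimnames = list("g", paste0("s", 1:4)))
  res <- expression_perturbation(expr, "g", c("s1", "s2"), c("s3", "s4"))
  expect_equal(res$scores$group1, 1.0)  # E = 2; (|1-2| + |3-2|)/2
  expect_error(expression_perturbation(expr, "g", "s1", "s1"), "disjoint")

  # translation invariance and linear scaling
  set.seed(6)
  m <- matrix(rnorm(60), 3, 20,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:20)))
  g1 <- paste0("s", 1:8); g2 <- paste0("s", 9:20)
  base <- expression_perturbation(m, rownames(m), g1, g2)
  shifted <- expression_perturbation(m + 5, rownames(m), g1, g2)
  expect_equal(base$scores$group1, shifted$scores$group1)
  scaled <- expression_perturbation(m * 3, rownames(m), g1, g2)
  expect_equal(scaled$scores$group1, 3 * base$scores$group1)
})

test_that("exchangeable groups split the perturbation fraction evenly", {
  set.seed(7)
  fracs <- replicate(40, {
    m <- matrix(rnorm(50 * 30), 50, 30,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:30)))
    expression_perturbation(m, rownames(m), paste0("s", 1:15),
                            paste0("s", 16:30))$fraction
  })
  expect_lt(abs(mean(fracs) - 0.5), 0.05)
})

test_that("misregulation concordance matches hand arithmetic", {
  r <- misregulation_concordance(c(1, 1, 0, -1), c(1, 0, 0, -1))
  # direct computation of the Pearson formula
  x <- c(1, 1, 0, -1); y <- c(1, 0, 0, -1)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r_abs, abs(num / den))

  expect_equal(misregulation_concordance(c(1, 0, -1, 1),
                                         c(1, 0, -1, 1))$r_abs, 1)
  expect_equal(misregulation_concordance(c(1, 1, -1, -1),
                                         c(1, -1, 1, -1))$r_abs, 0)
  # symmetry and joint sign-flip invariance
  a <- c(1, 0, 1, -1, 0); b <- c(0, 1, 1, -1, -1)
  expect_equal(misregulation_concordance(a, b)$r_abs,
               misregulation_concordance(b, a)$r_abs)
  expect_equal(misregulation_concordance(-a, -b)$r_abs,
               misregulation_concordance(a, b)$r_abs)
  # degenerate and error cases
  deg <- misregulation_concordance(c(0, 0, 0), c(1, 0, -1))
  expect_true(deg$degenerate)
  expect_error(misregulation_concordance(c(1, 0), c(0, 1)), "3 patients")
})

test_that("driver union counts overlapping factors once", {
  coding <- paste0("C", 1:10)
  regulatory <- c("C1", "C2", paste0("R", 1:5))
  u <- transcriptional_drivers(coding, regulatory)
  expect_length(u, 15)
  expect_equal(attr(u, "n_overlap"), 2)
  expect_equal(attr(u, "n_total"),
               attr(u, "n_coding") + attr(u, "n_regulatory") -
                 attr(u, "n_overlap"))
})

driver_sites <- function(n_tf = 5, genes_per_tf = 8, chroms = 3) {
  sites <- expand.grid(tf = paste0("TF", seq_len(n_tf)),
                       gene = paste0("g", seq_len(genes_per_tf)),
                       stringsAsFactors = FALSE)
  sites$gene <- paste0(sites$tf, "_", sites$gene)
  sites$site <- paste0("site", seq_len(nrow(sites)))
  sites$chrom <- paste0("chr", (seq_len(nrow(sites)) %% chroms) + 1)
  sites
}

test_that("a concentrated mutation burden reaches the minimum p-value", {
  sites <- driver_sites()
  tf1_sites <- sites$site[sites$tf == "TF1"]
  # every TF1 target gene hit in 3 distinct patients
  mutations <- do.call(rbind, lapply(tf1_sites, function(s)
    data.frame(patient = paste0("P", 1:3), site = s)))
  mutations$chrom <- sites$chrom[match(mutations$site, sites$site)]
  res <- identify_regulatory_drivers(mutations, sites, n_sim = 99,
                                     mode = "insilico", seed = 1)
  expect_equal(res$p[res$tf == "TF1"], 1 / 100)
  expect_true(res$driver[res$tf == "TF1"])
  expect_error(identify_regulatory_drivers(mutations, sites, n_sim = 10),
               "n_sim")
})

test_that("recurrence requires at least two distinct patients", {
  sites <- driver_sites()
  # many mutations, all in one patient: nothing is recurrent
  mutations <- data.frame(patient = "P1", site = sites$site)
  mutations$chrom <- sites$chrom
  res <- identify_regulatory_drivers(mutations, sites, n_sim = 19,
                                     mode = "clinical", seed = 2)
  expect_true(all(res$observed == 0))
  expect_true(all(res$p == 1))
})

test_that("driver-risk permutation statistics behave at the extremes", {
  set.seed(11)
  truth <- generate_true_network(40, 5, 4, seed = 23)
  net <- truth_network(truth)
  drivers <- truth$regulators
  out_nb <- unique(net$edges$target[net$edges$regulator %in% drivers])
  out_nb <- setdiff(out_nb, drivers)
  res <- driver_risk_connectivity_test(net, drivers, out_nb,
                                       n_perm = 99, seed = 3)
  expect_equal(unname(res$observed["pct_incoming_direct"]), 100)
  expect_equal(unname(res$p["links_direct"]), 1 / 100)
  expect_true(all(res$p >= 1 / (res$n_perm + 1)))
  expect_error(driver_risk_connectivity_test(net, drivers, character(),
                                             n_perm = 9), "empty risk")
})

test_that("risk-allele susceptibility applies the group-size rule", {
  truth <- make_truth(c("TF1", "R1"), "TF1",
                      data.frame(regulator = "TF1", target = "R1",
                                 sign = 1, effect = 0.7),
                      order = c("TF1", "R1"))
  links <- data.frame(snp = "rs1", gene = "R1")
  co <- simulate_cohort(truth, 80, risk_links = links,
                        effect_config = cohort_effects(
                          risk_amplification = 3, risk_maf = 0.45), seed = 4)
  pairs <- data.frame(driver = "TF1", gene = "R1", snp = "rs1")
  res <- risk_allele_susceptibility(co, pairs, min_group = 10)
  expect_true(res$pairs$evaluated)

  # all patients homozygous non-risk: pair skipped
  co0 <- co
  co0$genotypes$dosage <- 0L
  res0 <- risk_allele_susceptibility(co0, pairs)
  expect_false(res0$pairs$evaluated)
  expect_true(is.nan(res0$fraction))
  expect_error(risk_allele_susceptibility(
    co, data.frame(driver = "TF1", gene = "R1", snp = "rsX")), "absent")
})

test_that("amplified risk pairs are called susceptible more often than not", {
  truth <- make_truth(c("TF1", "R1"), "TF1",
                      data.frame(regulator = "TF1", target = "R1",
                                 sign = 1, effect = 0.7),
                      order = c("TF1", "R1"))
  links <- data.frame(snp = "rs1", gene = "R1")
  wins <- vapply(1:12, function(s) {
    co <- simulate_cohort(truth, 100, risk_links = links,
                          effect_config = cohort_effects(
                            risk_amplification = 3, risk_maf = 0.4),
                          seed = 40 + s)
    res <- risk_allele_susceptibility(
      co, data.frame(driver = "TF1", gene = "R1", snp = "rs1"),
      p_threshold = 0.05)
    isTRUE(res$pairs$r_risk > res$pairs$r_nonrisk)
  }, TRUE)
  expect_gt(mean(wins), 0.5)
})
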