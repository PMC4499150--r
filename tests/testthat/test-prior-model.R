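# hand-built mini landscape: DRE looped to PRE(g1), PRE(g1) looped to PRE(g2)
chain_landscape <- function() {
  structure(list(
    genes = data.frame(gene = c("g1", "g2"), chrom = "chr1", strand = "+",
                       tss = c(1e5, 3e5), start = c(1e5, 3e5),
                       end = c(1.5e5, 3.5e5)),
    elements = data.frame(element = c("D1", "P1", "P2"),
                          kind = c("DRE", "PRE", "PRE"),
                          chrom = "chr1",
                          start = c(1e4, 97500, 297500),
                          end = c(1.06e4, 102500, 302500),
                          gene = c(NA, "g1", "g2")),
    loops = data.frame(anchor1 = c("D1", "P1"), anchor2 = c("P1", "P2")),
    binding = data.frame(tf = "TFX", element = "D1", evidence = "chip",
                         cell_context = "same_cell", accessible = TRUE)),
    class = "regulatory_landscape")
}

test_that("topology classification enumerates loop paths up to two anchors", {
  land <- chain_landscape()
  cls <- classify_topologies(land)
  expect_setequal(paste(cls$target, cls$topology),
                  c("g1 DRE_loop_PRE", "g2 DRE_loop_PRE_loop_PRE"))

  # direct PRE binding yields exactly one pair
  land$binding <- data.frame(tf = "TFX", element = "P1", evidence = "chip",
                             cell_context = "same_cell", accessible = TRUE)
  cls <- classify_topologies(land)
  expect_equal(paste(cls$target, cls$topology),
               c("g1 PRE_direct", "g2 PRE_loop_PRE"))

  # DRE looped to two distinct PREs fans out to both genes
  land$loops <- data.frame(anchor1 = c("D1", "D1"), anchor2 = c("P1", "P2"))
  land$binding <- data.frame(tf = "TFX", element = "D1", evidence = "chip",
                             cell_context = "same_cell", accessible = TRUE)
  cls <- classify_topologies(land)
  expect_setequal(paste(cls$target, cls$topology),
                  c("g1 DRE_loop_PRE", "g2 DRE_loop_PRE"))
})

test_that("TF priors take class probabilities with the max rule", {
  land <- chain_landscape()
  assign <- default_probability_assignment()
  # single chip/same-cell event on g1's PRE
  land$loops <- land$loops[0, ]
  land$binding <- data.frame(tf = "TFX", element = "P1", evidence = "chip",
                             cell_context = "same_cell", accessible = TRUE)
  pri <- build_tf_priors(land, assign)
  expect_equal(nrow(pri), 1)
  expect_equal(pri$probability,
               assign$probability[assign$evidence == "chip" &
                                    assign$cell_context == "same_cell" &
                                    assign$topology == "PRE_direct"])

  # same pair supported twice -> the larger probability wins
  land2 <- chain_landscape()
  land2$binding <- rbind(
    data.frame(tf = "TFX", element = "P1", evidence = "chip",
               cell_context = "same_cell", accessible = TRUE),
    data.frame(tf = "TFX", element = "D1", evidence = "motif",
               cell_context = "cross_cell", accessible = TRUE))
  pri2 <- build_tf_priors(land2, assign)
  g1row <- pri2[pri2$target == "g1", ]
  expect_equal(g1row$probability, 0.9)
  expect_equal(g1row$topology, "PRE_direct")

  # cross-cell evidence outside accessible chromatin is dropped
  land3 <- chain_landscape()
  land3$binding$cell_context <- "cross_cell"
  land3$binding$accessible <- FALSE
  expect_equal(nrow(build_tf_priors(land3, assign)), 0)
})

test_that("default probability assignment preserves the class ordering", {
  a <- default_probability_assignment()
  expect_equal(nrow(a), 16)
  expect_true(all(a$probability > 0 & a$probability <= 1))
  get <- function(ev, cc, tp)
    a$probability[a$evidence == ev & a$cell_context == cc & a$topology == tp]
  for (tp in unique(a$topology)) {
    expect_gte(get("chip", "same_cell", tp), get("chip", "cross_cell", tp))
    expect_gte(get("chip", "same_cell", tp), get("motif", "same_cell", tp))
  }
  # shorter tether beats longer at equal evidence
  expect_gt(get("chip", "same_cell", "PRE_direct"),
            get("chip", "same_cell", "DRE_loop_PRE_loop_PRE"))
})

random_prior <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  pairs <- expand.grid(regulator = paste0("R", 1:4),
                       target = paste0("T", 1:6), stringsAsFactors = FALSE)
  pairs <- pairs[sample(nrow(pairs), n), ]
  pairs$probability <- runif(n, 0.05, 1)
  pairs$evidence <- sample(c("chip", "motif"), n, replace = TRUE)
  pairs$cell_context <- sample(c("same_cell", "cross_cell"), n, TRUE)
  pairs$topology <- sample(c("PRE_direct", "DRE_loop_PRE"), n, TRUE)
  prior_table(pairs[!duplicated(paste(pairs$regulator, pairs$target)), ])
}

test_that("merge_priors is a commutative, associative, idempotent max-merge", {
  t1 <- random_prior(1)
  expect_identical(merge_priors(t1, prior_table()), t1)
  expect_identical(merge_priors(t1, t1), t1)

  a <- prior_table(data.frame(regulator = "R", target = "T",
                              probability = 0.5, evidence = "chip",
                              cell_context = "same_cell",
                              topology = "PRE_direct"))
  b <- prior_table(data.frame(regulator = "R", target = "T",
                              probability = 0.8, evidence = "motif",
                              cell_context = "same_cell",
                              topology = "DRE_loop_PRE"))
  m <- merge_priors(a, b)
  expect_equal(m$probability, 0.8)
  expect_equal(m$evidence, "motif")

  for (s in 1:30) {
    x <- random_prior(3 * s); y <- random_prior(3 * s + 1)
    z <- random_prior(3 * s + 2)
    expect_identical(merge_priors(merge_priors(x, y), z),
                     merge_priors(x, merge_priors(y, z)))
    expect_identical(merge_priors(x, y), merge_priors(y, x))
  }
})

eqtl_fixture <- function(seed, n = 300, mediated = TRUE) {
  set.seed(seed)
  dos <- rbinom(n, 2, 0.4)
  a <- dos + rnorm(n, sd = 0.5)
  b <- if (mediated) a * 0.9 + rnorm(n, sd = 0.5) else rnorm(n)
  c_ <- rnorm(n)
  expr <- rbind(A = a, B = b, C = c_)
  colnames(expr) <- paste0("P", seq_len(n))
  genotypes <- data.frame(patient = colnames(expr), snp = "rs1",
                          dosage = dos)
  snps <- data.frame(snp = "rs1", chrom = "chr1", pos = 5e5)
  genes <- data.frame(gene = c("A", "B", "C"),
                      chrom = c("chr1", "chr2", "chr3"),
                      tss = c(6e5, 1e6, 1e6))
  list(genotypes = genotypes, snps = snps, expr = expr, genes = genes)
}

test_that("eQTL priors recover cis-trans mediation as a causal pair", {
  fx <- eqtl_fixture(1)
  pri <- build_eqtl_priors(fx$genotypes, fx$snps, fx$expr, fx$genes)
  expect_true("A B" %in% edge_set(pri))
  expect_true(all(pri$evidence == "eqtl"))

  # cis-only association yields no entry
  fx0 <- eqtl_fixture(2, mediated = FALSE)
  pri0 <- build_eqtl_priors(fx0$genotypes, fx0$snps, fx0$expr, fx0$genes)
  expect_false("A B" %in% edge_set(pri0))

  # no sample overlap is an input error
  bad <- fx$genotypes; bad$patient <- paste0("X", seq_len(nrow(bad)))
  expect_error(build_eqtl_priors(bad, fx$snps, fx$expr, fx$genes),
               "overlap")
})

test_that("mediation chains are recovered in at least 90% of seeds", {
  hits <- vapply(1:50, function(s) {
    fx <- eqtl_fixture(100 + s, n = 500)
    "A B" %in% edge_set(build_eqtl_priors(fx$genotypes, fx$snps, fx$expr,
                                          fx$genes))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("prior subsets follow the four evaluation modes", {
  df <- data.frame(
    regulator = c("R1", "R1", "R2", "R2"),
    target = c("T1", "T2", "T1", "T3"),
    probability = c(0.9, 0.6, 0.8, 0.5),
    evidence = c("chip", "chip", "motif", "eqtl"),
    cell_context = c("same_cell", "same_cell", "cross_cell", NA),
    topology = c("PRE_direct", "DRE_loop_PRE", "PRE_direct", NA))
  tab <- prior_table(df)
  expect_setequal(edge_set(subset_priors(tab, "proximal_tf")),
                  c("R1 T1", "R2 T1"))
  expect_setequal(edge_set(subset_priors(tab, "eqtl")), "R2 T3")
  cmp <- subset_priors(tab, "complete_tf")
  expect_true(all(edge_set(subset_priors(tab, "proximal_tf")) %in%
                    edge_set(cmp)))

  dre_only <- prior_table(df[df$topology %in% "DRE_loop_PRE", ])
  expect_equal(nrow(subset_priors(dre_only, "proximal_tf")), 0)
  expect_error(subset_priors(tab, "bogus"))
})

test_that("the Poisson null prior has the requested mean out-degree", {
  tab <- random_prior(9)
  regs <- paste0("R", 1:100)
  genes <- paste0("G", 1:200)
  degs <- vapply(1:10, function(s) {
    nul <- subset_priors(tab, "null_poisson", null_rate = 3, seed = s,
                         regulators = regs, genes = genes)
    nrow(nul) / length(regs)
  }, 0)
  expect_lt(abs(mean(degs) - 3), 0.5)
})

test_that("removing all loops collapses complete priors to proximal ones", {
  truth <- generate_true_network(25, 5, 3, seed = 11)
  land <- generate_landscape(truth, decoy_binding_rate = 0.3, seed = 2)
  land$loops <- land$loops[0, ]
  pri <- build_tf_priors(land)
  expect_identical(edge_set(subset_priors(pri, "complete_tf")),
                   edge_set(subset_priors(pri, "proximal_tf")))
  expect_true(all(pri$topology == "PRE_direct"))
})

test_that("prior tables reject self-loops and bad probabilities", {
  expect_error(prior_table(data.frame(regulator = "A", target = "A",
                                      probability = 0.5)), "self-loop")
  expect_error(prior_table(data.frame(regulator = "A", target = "B",
                                      probability = 0)), "probabilities")
  expect_error(prior_table(data.frame(regulator = c("A", "A"),
                                      target = c("B", "B"),
                                      probability = c(0.5, 0.7))),
               "duplicate")
})
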