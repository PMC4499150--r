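test_that("generate_true_network returns a reproducible regulator-rooted DAG", {
  tiny <- generate_true_network(2, 1, 1, seed = 1)
  expect_length(tiny$nodes, 2)
  expect_true(all(tiny$edges$regulator %in% tiny$regulators))

  t1 <- generate_true_network(30, 5, 3, seed = 7)
  expect_true(is_acyclic(truth_network(t1)))
  expect_true(all(t1$edges$regulator %in% t1$regulators))
  expect_true(all(t1$edges$sign %in% c(-1, 1)))

  t2 <- generate_true_network(30, 5, 3, seed = 7)
  expect_identical(t1$edges, t2$edges)

  expect_error(generate_true_network(1, 1, 1), "n_genes")
  expect_error(generate_true_network(10, 11, 1), "n_regulators")
  expect_error(generate_true_network(10, 2, 0), "mean_out_degree")
})

test_that("landscape with no decoys implies exactly the truth pair set", {
  truth <- generate_true_network(25, 5, 3, seed = 11)
  land <- generate_landscape(truth, decoy_binding_rate = 0, seed = 2)
  prior <- build_tf_priors(land)
  expect_setequal(edge_set(prior), edge_set(truth$edges))
})

test_that("decoy binding keeps full recall but lowers precision", {
  truth <- generate_true_network(25, 5, 3, seed = 11)
  land <- generate_landscape(truth, decoy_binding_rate = 0.5, seed = 2)
  prior <- build_tf_priors(land)
  tk <- edge_set(truth$edges)
  pk <- edge_set(prior)
  expect_equal(mean(tk %in% pk), 1)
  expect_lt(mean(pk %in% tk), 1)
})

test_that("landscape generation is byte-identical under a fixed seed", {
  truth <- generate_true_network(20, 4, 3, seed = 5)
  l1 <- generate_landscape(truth, 0.3, seed = 9)
  l2 <- generate_landscape(truth, 0.3, seed = 9)
  expect_identical(l1, l2)
  expect_error(generate_landscape(truth, 1.5), "decoy_binding_rate")
})

test_that("DRE-PRE loop spans reproduce the configured median distance", {
  truth <- generate_true_network(400, 80, 5, seed = 3)
  land <- generate_landscape(truth, decoy_binding_rate = 0, seed = 4)
  el <- land$elements
  kind <- setNames(el$kind, el$element)
  gene_tss <- setNames(land$genes$tss, land$genes$gene)
  spans <- c()
  for (i in seq_len(nrow(land$loops))) {
    a <- land$loops$anchor1[i]; b <- land$loops$anchor2[i]
    dre <- if (kind[a] == "DRE") a else if (kind[b] == "DRE") b else NA
    if (is.na(dre)) next
    pre <- setdiff(c(a, b), dre)
    g <- el$gene[match(pre, el$element)]
    spans <- c(spans, abs(el$start[match(dre, el$element)] - gene_tss[g]))
  }
  expect_gt(length(spans), 100)
  expect_gt(median(spans), 5e4)
  expect_lt(median(spans), 2e5)
})

test_that("expression follows the linear-Gaussian model along edges", {
  truth <- make_truth(c("A", "B"), "A",
                      data.frame(regulator = "A", target = "B",
                                 sign = 1, effect = 1))
  x <- simulate_expression(truth, 500, noise_sd = 0.1, seed = 1)
  # analytic correlation effect/sqrt(effect^2 + noise^2) = 0.995
  expect_gt(cor(x["A", ], x["B", ]), 0.9)

  neg <- make_truth(c("A", "B"), "A",
                    data.frame(regulator = "A", target = "B",
                               sign = -1, effect = 1))
  xn <- simulate_expression(neg, 500, noise_sd = 0.1, seed = 1)
  expect_lt(cor(xn["A", ], xn["B", ]), 0)

  null <- make_truth(c("A", "B", "C"), "A",
                     data.frame(regulator = character(),
                                target = character(),
                                sign = numeric(), effect = numeric()))
  x0 <- simulate_expression(null, 500, noise_sd = 1, seed = 2)
  cors <- cor(t(x0))
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.2))

  expect_error(simulate_expression(truth, 0), "n_samples")
  expect_error(simulate_expression(truth, 10, noise_sd = 0), "noise_sd")
})

test_that("marginal variances match the linear-Gaussian closed form", {
  # chain A -> B -> C with known effects
  truth <- make_truth(c("A", "B", "C"), c("A", "B"),
                      data.frame(regulator = c("A", "B"),
                                 target = c("B", "C"),
                                 sign = c(1, -1), effect = c(1.2, 0.8)),
                      order = c("A", "B", "C"))
  sd_n <- 0.5
  x <- simulate_expression(truth, 2000, noise_sd = sd_n, seed = 3)
  v_b <- 1.2^2 * 1 + sd_n^2
  v_c <- 0.8^2 * v_b + sd_n^2
  expect_equal(var(x["A", ]), 1, tolerance = 0.1)
  expect_equal(var(x["B", ]), v_b, tolerance = 0.1)
  expect_equal(var(x["C", ]), v_c, tolerance = 0.1)
})

test_that("a null-effect cohort has indistinguishable tumor and normal", {
  truth <- generate_true_network(20, 4, 3, seed = 21)
  co <- simulate_cohort(truth, 40,
                        effect_config = cohort_effects(driver_shift = 0,
                                                       risk_amplification = 1),
                        seed = 1)
  pvals <- sapply(rownames(co$expression), function(g) {
    tum <- co$expression[g, grepl("_T$", colnames(co$expression))]
    nor <- co$expression[g, grepl("_N$", colnames(co$expression))]
    t.test(tum, nor)$p.value
  })
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("driver mutations perturb downstream genes in carriers", {
  truth <- generate_true_network(20, 3, 4, seed = 8)
  driver <- truth$edges$regulator[which.max(
    table(truth$edges$regulator)[truth$edges$regulator])]
  co <- simulate_cohort(truth, 60, driver_genes = driver,
                        effect_config = cohort_effects(driver_shift = 3),
                        seed = 2)
  carriers <- co$coding_mutations$patient[co$coding_mutations$gene == driver]
  noncar <- setdiff(co$subclass$patient, carriers)
  expect_gt(length(carriers), 5)
  g <- igraph::subcomponent(as_igraph(truth_network(truth)), driver,
                            mode = "out")
  down <- setdiff(names(g), driver)
  res <- expression_perturbation(co$expression, down,
                                 paste0(carriers, "_T"),
                                 paste0(noncar, "_T"))
  expect_gt(res$fraction, 0.5)
})

test_that("risk amplification raises concordance in the risk group", {
  truth <- make_truth(c("TF1", "R1"), "TF1",
                      data.frame(regulator = "TF1", target = "R1",
                                 sign = 1, effect = 0.6),
                      order = c("TF1", "R1"))
  links <- data.frame(snp = "rs1", gene = "R1")
  co <- simulate_cohort(truth, 120, risk_links = links,
                        effect_config = cohort_effects(
                          risk_amplification = 3, risk_maf = 0.4), seed = 6)
  risk <- co$genotypes$patient[co$genotypes$dosage >= 1]
  nonrisk <- setdiff(co$subclass$patient, risk)
  cr <- misregulation_concordance(
    diff_expression_vector(co, "TF1", patients = risk),
    diff_expression_vector(co, "R1", patients = risk))
  cn <- misregulation_concordance(
    diff_expression_vector(co, "TF1", patients = nonrisk),
    diff_expression_vector(co, "R1", patients = nonrisk))
  expect_gt(cr$r_abs, cn$r_abs)
})

test_that("cohort simulation rejects unknown genes", {
  truth <- generate_true_network(10, 2, 2, seed = 1)
  expect_error(simulate_cohort(truth, 5, driver_genes = "NOPE"), "unknown")
})

test_that("drug responses concentrate on genes downstream of the target TF", {
  truth <- generate_true_network(40, 6, 4, seed = 13)
  dr <- simulate_drug_responses(truth, 6, targets_per_drug = 1, seed = 2)
  g <- as_igraph(truth_network(truth))
  for (d in colnames(dr$changes)) {
    tf <- dr$targets[[d]]
    down <- setdiff(names(igraph::subcomponent(g, tf, mode = "out")), tf)
    if (length(down) < 3) next
    top <- names(sort(-dr$changes[, d]))[seq_len(min(20, length(down)))]
    frac_top <- mean(top %in% down)
    frac_all <- length(down) / length(truth$nodes)
    expect_gt(frac_top, frac_all)
  }
  # drugs sharing a target TF have correlated change profiles
  tfs <- vapply(dr$targets, `[`, "", 1)
  shared <- which(duplicated(tfs) | duplicated(tfs, fromLast = TRUE))
  if (length(shared) >= 2) {
    i <- shared[1]; j <- shared[tfs[shared] == tfs[shared[1]]][2]
    expect_gt(cor(dr$changes[, i], dr$changes[, j]), 0)
  }
  expect_error(simulate_drug_responses(truth, 0), "n_drugs")
})

test_that("discretization cuts per-gene z-scores at the requested levels", {
  x <- matrix(rnorm(200), 4, 50, dimnames = list(paste0("g", 1:4), NULL))
  d <- discretize_expression(x)
  expect_true(all(d %in% 1:3))
  expect_identical(attr(d, "k"), 3L)
  z <- (x[1, ] - mean(x[1, ])) / sd(x[1, ])
  expect_identical(unname(d[1, z < -1]), rep(1L, sum(z < -1)))
  expect_identical(unname(d[1, z >= 1]), rep(3L, sum(z >= 1)))
})
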