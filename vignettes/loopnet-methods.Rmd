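---
title: "Methods: loop-aware priors and GA-seeded MCMC network learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop-aware priors and GA-seeded MCMC network learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`loopnet` infers a directed causal network over genes by combining two
sources of information: a *physical/genetic prior* over regulator–target
pairs, and the *statistical signal* in a gene-by-sample expression matrix.
This vignette documents the model, its assumptions, the tunable parameters,
and the design choices made where several reasonable constructions exist.

## The prior model

A binding event is a tuple (TF, element, evidence, cell context,
accessibility flag), where elements are promoter-proximal (PRE, assigned to
exactly one gene) or distal (DRE).  `classify_topologies()` routes each
event to candidate targets through chromatin loops under four topologies,
traversing at most two loop anchors:

* `PRE_direct` — the element is the target's PRE;
* `DRE_loop_PRE` — a DRE looped to the target's PRE;
* `PRE_loop_PRE` — another gene's PRE looped to the target's PRE;
* `DRE_loop_PRE_loop_PRE` — a DRE–PRE–PRE chain.

Each (evidence, cell context, topology) class maps to a probability via a
`ProbabilityAssignment` table.  The default
(`default_probability_assignment()`) encodes three monotone orderings that
the class structure implies — ChIP peak > motif-in-DHS evidence, same-cell
observation > cross-cell observation in accessible chromatin, and shorter
tether > longer tether — with ChIP/same-cell values (0.9, 0.8, 0.6, 0.5)
over the four topologies, a 0.15 penalty for cross-cell context, a 0.25
penalty for motif evidence, and a floor of 0.05.  These constants are a
package default, deliberately configurable: the orderings are the
substantive assumption, the exact values are not.  Cross-cell evidence
contributes only when the element lies in accessible chromatin.  A pair
supported by several classes takes the maximum probability; ties keep the
class that ranks first under (chip > motif, same > cross, shorter topology
first), which makes `merge_priors()` commutative, associative and
idempotent.

The eQTL prior emits A→B when a SNP associates in cis with A (within 1 Mb
of A's TSS by default) and in trans with B, both at a nominal
correlation-test threshold.  The association strength is mapped to a
probability monotonically by scaling |r| ranks into [0.05, 0.95]; any
monotone map would serve, since downstream use is through the log-prior
ordering.

## The score

Candidate networks are scored on discretized expression by the BDeu
marginal likelihood (equivalent sample size 1) plus an edge-wise structure
prior: `log p` for a prior pair with probability `p`, `log kappa` otherwise
(`kappa = 0.01`).  The score is decomposable — a single-edge change
re-evaluates one node's family plus one prior term — which both search
algorithms exploit.  A maximum of 5 parents per node bounds the
contingency tables; unobserved parent configurations contribute exactly
zero.  Discretization is per-gene z-scoring cut at ±1 into three levels;
both the cut points and the level count are configurable.  The fitness
function is a reconstruction: prior-informed Bayesian scoring with BDeu is
the standard decomposable instantiation of the approach, and `kappa`
controls network density in the same way that the Poisson-seeded
initialisation implies sparse candidates.

## Search

**Genetic algorithm** (`evolve()`).  Chromosomes are edge sets, initialised
by including each prior pair with probability equal to its prior
probability and adding Poisson(1) random extra links per regulator; edges
are inserted in random order and any insertion that would close a cycle or
exceed the parent cap is rejected.  Each generation sorts chromosomes into
four fitness-quartile groups.  Offspring are produced by uniform edge
crossover with parent pools (top × top), (top × second), (second × third);
the bottom quarter is replaced by fresh prior-sampled chromosomes.
Mutation applies Poisson-many add/delete/reverse edge moves with
group-specific rates (0.5, 1, 2, 4 by default, increasing towards the
least-fit group).  Elitism carries the best chromosome over unchanged, so
the best fitness is non-decreasing.  The loop stops when the best fitness
improves by less than 1e-6 (relative) over 200 consecutive generations, or
at the generation cap.  The group-identity crossover operator is likewise a
reconstruction that preserves the stated selective pressure: fitter groups
breed together, less fit groups mutate more aggressively and are refreshed
from the prior.

**Structure MCMC** (`mcmc_refine()`).  Metropolis–Hastings over single-edge
moves: a uniformly drawn ordered pair proposes an addition when absent and
a deletion or reversal (equal probability) when present.  The Hastings
correction is 1/2 for additions and 2 for deletions (the two halves of the
asymmetric pairing), 1 for reversals; cycle- or cap-violating proposals are
rejected in place, which preserves detailed balance on the DAG space.  On
three-node instances the post-burn-in edge frequencies reproduce the
exhaustively enumerated Boltzmann distribution over all 25 DAGs to within
sampling error, and on four-node instances (543 DAGs) both the GA and the
chain locate the enumerated optimum; these checks run in the test suite.

**Consensus** (`loopnet()`).  Independent GA runs are each refined by MCMC
and the refined best networks are combined by keeping edges supported by at
least half the runs.  Each run is refined *before* the consensus; the
alternative (consensus first, one refinement after) discards the
run-to-run variability that the consensus support is meant to summarise.
The consensus is a summary, not a scored DAG, so it may in principle
contain cycles; this is flagged rather than repaired.  Scaled defaults —
population 32, 500 generations, 10 runs, 2000 MCMC steps — keep a 30-gene
problem under a few seconds; the full-scale settings (128 candidates,
20 000 generations, 1000 runs) are plain configuration values.  Runs are
mutually independent, so a thread count can only partition them and never
changes results.  All randomness flows from explicit integer seeds.

## The synthetic-data generators

The generators exist so that every statistic in the package can be tested
against a known truth.  `generate_true_network()` samples a DAG whose edges
leave a designated regulator subset, forward along a random topological
order.  Expression is linear-Gaussian in that order — root genes standard
normal, children the signed effect-weighted sum of parents plus
Gaussian noise.  This is the simplest generative model consistent with
fitting discretized data; the real method makes no such assumption, so
passing recovery tests demonstrates correctness of the machinery, not that
tumor expression is linear-Gaussian.

`generate_landscape()` realises every true edge through one of the four
binding topologies.  Tethered topologies route through a *companion* true
target of the same regulator on dedicated secondary PREs, so that with no
decoys the implied pair set equals the truth edge set exactly — a sharp
oracle for the prior builder.  Decoy binding events (not corresponding to
true edges) are added at a configurable rate.  Coordinates are 0-based
half-open; PREs are ±2.5 kb windows around the TSS; DRE–PRE spans are
log-normal with median 100 kb, capped at 1 Mb, intra-chromosomal.  These
are simulation defaults chosen to be realistic for enhancer–promoter
contact distances, not estimates of anything.

`simulate_cohort()` draws matched tumor/normal pairs; driver mutations
shift the driver's tumor expression (propagating downstream through the
network), and risk alleles (dosage ≥ 1, heterozygotes included) multiply
the incoming-edge effects of the linked gene in both tissues, raising its
responsiveness to upstream regulators.  Expression values are treated as
log-scale throughout the downstream statistics, so a 2-fold change is an
absolute difference of log2(2); this avoids ratio pathologies at zero and
matches how normalised expression data are usually handled.  What the
cohort generator does *not* emulate: batch structure, subtype-specific
copy-number effects, measurement noise heterogeneity, or linkage
disequilibrium between SNPs.

## Downstream statistics: conventions and tie rules

* *Edge signs*: Pearson correlation on the continuous (pre-discretization)
  matrix, activation strictly above the threshold (default 0.1),
  inhibition strictly below its negative; |r| exactly at the threshold is
  unsigned, zero-variance genes are unsigned with a warning.
* *Reference catalogs* are undirected by default (functional-interaction
  style); a directed mode serves TF–target catalogs.  In undirected mode a
  pair recovered in either orientation is not charged as a false negative
  at the opposite endpoint.
* *Closest upstream TF* for drug connectivity: minimal intervening-node
  directed distance among TF nodes; ties split the gene's weight equally.
  "Connected" means reachable by a directed path by default (a
  direct-edge-only mode exists).  The connectivity matrix is z-normalised
  column-wise then row-wise; TFs whose normalised scores all fall in
  (−0.2, 0.2) are removed; clustering is complete linkage on
  Spearman-correlation distance.
* *Driver→risk connectivity*: both the direct-edge and the directed-path
  variant of "incoming links" are computed; direct edges are the headline
  statistic.  The sampling universe excludes the drivers.
* *Regulatory drivers*: a target gene is recurrent at ≥ 2 distinct
  patients; the clinical null resamples sites within chromosomes
  (preserving per-chromosome and per-patient counts), the in-silico null
  resamples sites uniformly.  Empirical p-values use the add-one estimator
  (1 + k)/(N + 1), which is never zero and never below 1/(N + 1).
* *Risk-allele susceptibility*: groups split at dosage ≥ 1; a pair is
  evaluated only when both groups exceed 10 patients strictly; "identified
  cases" have concordance p < 0.01 in either group.

## Numerical and testing notes

Determinism is absolute: identical seeds and configurations give
byte-identical consensus networks and analysis tables (the compiled cores
draw from R's RNG).  The test suite checks the scorer against an
independent direct-formula BDeu implementation, checks incremental against
from-scratch rescoring over random move sequences at 1e-6, and runs the
enumeration oracles described above.  Calibration of the permutation tests
is checked on simulated nulls at desk scale; because the link-count
statistic is integer-valued, its null support must be reasonably
fine-grained for the nominal level to be meaningful, so the calibration
fixture uses a comparatively dense network (250 genes, 25 regulators) —
at full scale the statistic is effectively continuous and the issue does
not arise.  Parameter-recovery tests use a 30-gene, 5-regulator truth with
300 samples and a 0.3 decoy rate; prior-subset comparisons (complete vs
proximal vs null) use the same data over five seeds.

## Known limitations

* The linear-Gaussian generator cannot represent saturating or
  combinatorial (XOR-like) regulation; BDeu can, so recovery rates here
  may be optimistic for strongly nonlinear systems.
* The consensus can contain cycles and is deliberately not repaired.
* eQTL priors use marginal correlations, not a mediation model; with
  strong trans effects and weak cis effects the emitted direction can be
  wrong.
* The drug-connectivity "closest upstream TF" attribution is ambiguous in
  TF cascades: an intermediate TF legitimately outranks the perturbed one.
* Prior probability constants are package defaults; analyses that depend
  on their absolute values (rather than their ordering) should treat them
  as tunable.
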