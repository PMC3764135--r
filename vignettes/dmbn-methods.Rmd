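---
title: "Models and methods behind dmbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dmbn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmbn)
```

# The inference problem

The data are a genes × mutants matrix of discrete differential-expression
calls: +1 (significant up-regulation), −1 (significant down-regulation),
0 (no significant change) for each gene in each deletion-mutant strain
relative to wild type. Each mutant column is treated as one random
variable; the N genes are the observations. The goal is a directed
network over the *mutants* — which regulators influence which — learned
by score-based Bayesian-network structure search, then summarized as a
partially directed graph separating compelled (causal) from
non-compelled (reversible) edges.

The central modelling premise is that a regulator's deletion profile is
predictable from the deletion profiles of its upstream regulators:
perturbing an upstream gene propagates through the regulatory cascade and
reproduces, in attenuated form, the transcriptional consequences of
perturbing its targets. Everything in the package — the kernel, the
score, the template, the simulator — operationalizes that premise for
data that are overwhelmingly zero.

# The deletion-mutant kernel and its feature space

Sparse call vectors defeat naive discrete similarity: two mutants that
each perturb 2% of the genome agree on ~96% of genes by shared zeros
alone. The deletion-mutant kernel therefore scores a pair of calls 1 only
when both are +1 or both are −1, and 0 otherwise — co-silence carries no
information, only co-regulation does.

This kernel is the inner product of the indicator map
φ(x) = (1{x = +1}, 1{x = −1}), which cannot have both coordinates equal
to 1. All production computations use the centered N × 2 feature blocks
(`feature_block()`); the N × N Gram matrix (`centered_gram()`) exists for
inspection and as the independent oracle formulation in the test suite,
where the identity det(I + AᵀA) = det(I + AAᵀ) lifts the feature-space
determinants to Gram space. This turns an O(N³) kernel computation into
O(N·m² + m³) for m variables, which is what makes search over thousands
of genes interactive.

# Kernel Generalized Variance and its regularization

Dependence among a variable set S is measured by the Gaussian
multi-information of the regularized feature correlation structure:

$$\hat J(S) = -\tfrac12 \log\frac{\det(C_S + \Lambda_S)}{\prod_{i\in S}\det(C_{ii} + \lambda_i I_2)},$$

with feature covariances $C_{ij} = \tilde\Phi_i^\top \tilde\Phi_j / N$
and a **per-variable relative ridge** $\lambda_i = \kappa\,\bar v_i$,
$\bar v_i = \mathrm{tr}(C_{ii})/2$. Two properties motivated the relative
(rather than absolute) ridge:

* *Uniform shrinkage.* Every canonical correlation is shrunk by the same
  factor 1/(1+κ) regardless of how sparse a profile is. An absolute
  ridge shrinks sparse variables (tiny feature variances) far more than
  dense ones, and the uneven shrinkage leaks large spurious partial
  correlations into conditional score differences — enough, at realistic
  signal strengths, to outweigh any plausible complexity penalty.
* *Scale freedom.* κ means the same thing for a panel with 1% DEG rates
  and one with 20%.

Zero-variance variables (mutants with no differentially expressed genes)
are dropped from the determinants; this is exact, since their rows and
columns cancel in the ratio. Ĵ of a single variable is identically 0,
and tiny negative round-off (beyond −10⁻⁹ it would warn) is clamped to
zero. Natural logarithms are used throughout so the data term and the
BIC penalty live on the same scale. The default κ = 0.01 keeps the
shrinkage at 1%, well below the sampling noise of correlations at the
gene counts the package targets; it is exposed in
`search_config(kappa = )`.

Because every Ĵ(S) is the multi-information of one fixed covariance
matrix (C + Λ) restricted to S, the Gaussian chain rule holds exactly
across subsets, and the resulting network score is *score-equivalent*:
Markov-equivalent DAGs receive identical totals. That property is what
licenses the Meek-rule interpretation of the final graph.

# The structure score

The local score of child x with parent set pa is

$$\mathrm{score}(x \mid pa) = N\left(\hat J(\{x\}\cup pa) - \hat J(pa)\right) - \omega\,\frac{d}{2}\,\log N,\qquad d = 4\,|pa|.$$

The data term is N times the estimated conditional dependence of x on
its parents. The penalty charges the true dimension of the model each
parent adds: in the rank-2 feature space a parent contributes
2 × 2 = 4 Gaussian regression coefficients, so twice the data term of a
null parent is approximately χ² with 4 degrees of freedom (mean 4,
routinely 8–11). A penalty that charged less than the dimension — for
example, a nominal half-parameter per parent — would admit noise edges
at *any* sample size; charging d = 4|pa| makes ω = 1 the consistent BIC
baseline and ω the interpretable sparsity multiplier. The default ω = 2
prunes at roughly twice the BIC rate; the sweep 1.5–9 maps out the
precision/recall trade-off. An empty parent set scores exactly 0, so the
empty graph is the natural origin of the search.

# The template

Per-mutant target lists (the signed nonzero entries of each column)
induce a binary R × R template over the mutants:

1. mutual membership — each regulator's gene responds to the other's
   deletion: both directions allowed (the dominant direction is unknown);
2. one-way membership — only B responds to deleting A: A→B allowed, B→A
   forbidden;
3. target overlap — neither responds to the other but they share at
   least one target gene (signs ignored): both directions allowed;
4. otherwise: forbidden.

Rules are applied with exactly that precedence. Membership matching
strips dataset tags (`GENE@dataset`) and, for double-deletion mutants
(`GENE1+GENE2`), accepts either constituent — a permissive choice that
only ever *licenses* additional edges, which the score can still reject.
The template's asymmetric (one-way) pairs also serve as background
causal knowledge for edge orientation. Mutually-allowed pairs are
symmetric and contribute no background orientation. `--template none`
(or `permissive_template()`) disables all constraints, the mode used to
ask whether orientation accuracy survives without prior knowledge.

# Search

`tabu_search()` starts from the empty graph and repeatedly applies the
best-gain legal move among edge additions (template-licensed), deletions,
and reversals (licensed in the opposite direction), rejecting moves that
would create a directed cycle. Cycle queries are answered incrementally
by a maintained ancestor relation (`acyclicity_guard()`): adding a→b is
cyclic iff b already reaches a; reversing a→b is cyclic iff a second
a→…→b path exists. Additions update the closure in O(R²); deletions and
reversals recompute it, the rarer case in greedy ascent.

Both an applied move and its inverse are tabu for `tabu_tenure`
iterations (default 10) unless a move would beat the best score seen
(aspiration). Keying only the inverse is insufficient: a three-move
add/reverse/delete cycle returns to the starting state without ever
touching an inverse key. The search accepts the best move even when
negative, stops after `patience` (default 20) non-improving moves, and
returns the best graph visited.

Greedy ascent with a one-move horizon has a characteristic failure mode
on this score: an early edge oriented against the data-generating
direction can create a spurious collider whose cost only materializes
through the extra edges it later attracts, and escaping requires a
coordinated multi-edge rearrangement in which every single step loses
heavily. Two deterministic deepening sweeps address this after
convergence — force-reversing each incumbent edge, and "lifting" each
node (deleting all its incident edges at once) before re-climbing —
followed by `restarts` (default 8) seeded iterated-local-search rounds
that perturb the incumbent with `perturb_moves` (default 4) random legal
moves. All randomness derives from `search_config(seed = )`; ties among
equal-gain moves break lexicographically (add < delete < reverse, then
parent, then child), so runs are exactly reproducible.

Zero-variance mutants remain in the node set but are excluded from move
generation (with a warning): under this kernel they can justify no edge.

# Causal interpretation

`to_pdag()` converts the learned DAG into compelled and non-compelled
edges: start from the undirected skeleton, orient the DAG's v-structures,
orient the background (template one-way) pairs, and close under Meek's
rules R1–R4. Background pairs whose edge the search did not select are
ignored with a warning — the template licenses edges, it does not mandate
them — while a background pair opposing a v-structure orientation raises
an error rather than silently flipping, since the search already enforced
template consistency and such a conflict indicates corrupted inputs. By
soundness of the rules, every compelled edge carries the orientation the
learned DAG itself had; the implementation asserts this. The test suite
verifies the closure against brute-force Markov-equivalence-class
enumeration for every DAG on up to five nodes, and against
consistent-extension enumeration under random background sets.

# Evaluation statistics

A regulator profiled in two datasets keeps two columns
(`GENE@d1`, `GENE@d2`); `collapse_duplicates()` merges the copies for
evaluation, counting parallel edges once — directed if all copies agree,
undirected on any disagreement — and dropping self-pairs.
`precision_recall()` matches edges as unordered pairs; the recall
denominator counts only reference pairs whose both endpoints are network
nodes. A network with no predicted edges has *undefined* (NA) precision,
never 0, so precision/recall curves carry no spurious points.

`orientation_precision()` restricts to compelled edges whose gene pair
occurs in a directed reference (in either direction) and reports the
fraction oriented consistently, with the exact one-sided binomial tail
P(X ≥ k), X ~ Bin(n, ½), as the test against coin-flip orientation. The
tail is an exact `choose()` sum — the coefficients are integers below
2⁵³ at these n — and the suite cross-checks it against `pbinom` for all
n ≤ 40. The regulator-DEG reference itself comes from the input matrix:
A→B is a reference pair iff regulator gene B is differentially expressed
in A's deletion column.

`jaccard_index()`/`jaccard_network()` provide the similarity baseline
(intersection over union of target sets, signs ignored; empty sets score
0), and `hypergeom_tail()`/`enrich_targets()` the functional-enrichment
test P(X ≥ m) for drawing n query genes from a universe of G with S in
the category, with Benjamini–Hochberg adjustment reported alongside raw
p-values. The universe defaults to all genes responsive in at least one
mutant.

# The synthetic model

`simulate_planted_model()` generates the scenario the learner assumes,
so that structure recovery can be measured against a known truth:

* a planted DAG over R regulators (random topological order, independent
  edge inclusion with probability `edge_probability`);
* per-regulator signed direct-target sets over the non-regulator genes
  (Poisson-distributed sizes, uniform gene choice, down-regulation with
  probability `sign_mix`);
* **ancestral sampling of columns in planted order**: a regulator's
  column inherits each nonzero target-gene entry of each parent's
  observed column independently with probability `propagation_decay`,
  signs unchanged, with its own direct targets written on top. Retention
  composes along edges (a depth-k ancestor's influence arrives with
  probability ≈ decay^k), and conditioning on the parents screens off
  deeper ancestors exactly — the column ensemble is Markov, and
  faithful, with respect to the planted DAG. This is the literal form of
  the premise that a deletion profile is predictable from its
  regulators' profiles;
* regulator-row marks: deleting r always marks its own gene row −1 and
  marks each planted descendant's row −1 with probability decay^dist —
  the evidence from which the template derives its one-way constraints
  and the orientation reference its directed pairs;
* entry-wise corruption: with probability `noise_flip` an entry is
  replaced by a uniform draw from {−1, 0, 1}, applied to each column
  *before* its children sample from it, so noise propagates through the
  cascade rather than sitting on top of it. Overlaying noise at the end
  would make every observed parent a noisy proxy of a latent effect set
  and re-introduce residual dependence between non-adjacent columns that
  no consistent score could prune.

Defaults — R = 10, N = 2000, edge probability 0.2 (≈9 planted edges, a
sparse regulatory backbone), 40 direct targets per regulator (a 2% DEG
rate), decay 0.8, noise 0.02, balanced signs — describe a small, strongly
powered panel of the kind the learner targets. The generator does *not*
emulate real microarray noise structure (correlated probes, intensity
dependence), double-deletion epistasis, context-specific regulation, or
post-transcriptional effects; recovery results on it demonstrate the
correctness and calibration of the machinery under the model's own
assumptions, not performance on any particular experimental compendium.

# Numerical and testing choices

* Determinants are computed via `determinant(log = TRUE)`; KGV values are
  clamped at 0 with a warning beyond −10⁻⁹.
* KGV results are cached per sorted variable subset inside
  `kgv_scorer()`; cache hits are bit-identical to recomputation.
* Score ties break lexicographically; all stochastic components consume
  a single configured seed; simulations restore the caller's RNG state.
* Test problem sizes: the feature/Gram equivalence oracle runs 100
  random instances (m ≤ 4, N ≤ 200, tolerance 10⁻⁸); the Meek oracle
  enumerates all 29,281 DAGs (8,782 equivalence classes) on five nodes;
  the acyclicity guard is checked against a fresh DFS over 1,000 random
  moves on 20-node graphs; exhaustive search optimality is verified over
  all 25 three-node DAGs on 20 random datasets; planted-model recovery
  uses ten seeds at the default conditions, where mean skeleton
  precision and recall and orientation precision are required to reach
  0.8 / 0.6 / 0.7.

# Known limitations

* The KGV is a Gaussian surrogate: it measures linear dependence in the
  indicator feature space and can under-detect purely higher-order
  (e.g., XOR-type) combinatorial regulation.
* TABU search with deepening is still a local method; on adversarial
  landscapes it can return a local optimum, and no optimality guarantee
  is made beyond the exhaustively verified three-node case.
* The template is built from single calls; a single corrupted call can
  license a wrong orientation or withhold a right one. The search can
  reject licensed edges but cannot recover forbidden ones.
* Orientation evaluation against regulator-DEG references treats those
  references as ground truth; they are themselves derived from the same
  matrix and are permissive by construction.
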