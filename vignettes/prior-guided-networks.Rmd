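---
title: "Prior-guided network inference at trans-QTL hotspots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-guided network inference at trans-QTL hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A trans-QTL hotspot is a genetic locus associated with many distal
molecular traits — gene expression or CpG methylation on other
chromosomes. A plausible mechanism is a short regulatory cascade: the SNP
perturbs a nearby (cis) gene, whose product — often via intermediate
signalling proteins and a transcription factor — reaches the distal
targets. `priorgraph` reconstructs such cascades as undirected Gaussian
graphical models (GGMs) over a small, role-tagged node universe (the
*locus set*) and, crucially, lets external biological evidence enter the
estimation as per-edge prior probabilities.

Inference at a hotspot faces an $N \ll P$ problem only after it is cut
down to a locus set; even then, samples are scarce relative to the number
of node pairs, and generic sparsity assumptions ignore everything known
about the locus. The package's premise is that edge-wise priors built
from reference resources (eQTL catalogues, co-expression panels,
chromatin-state maps, TF binding sites, protein-protein interactions)
measurably improve recovery, and that this improvement can be quantified
by simulation.

# Locus sets

For each hotspot (a sentinel SNP with at least five distinct trans
targets; redundant SNPs collapsed by an upstream LD clustering, keeping
the SNP with the highest MAF, then the largest trans count), the locus
set collects:

* **cis genes** — genes whose annotated interval intersects the 1 Mbp
  window centred on the SNP (closed window; interval intersection, so a
  gene body touching the boundary is in). Hotspots with no *expressed*
  cis gene are flagged invalid and discarded: without a cis anchor the
  cascade hypothesis cannot be represented.
* **trans entities** — the associated genes or CpGs themselves.
* **CpG genes** (meQTL only) — the previous, next and overlapping gene
  around each trans CpG.
* **TFs** — factors with a binding site within 50 bp of a trans CpG, or
  inside a promoter window of a trans gene (2000 bp upstream to 1000 bp
  downstream of the TSS, strand-aware). Binding-site collections are
  first filtered to blood-related cell types by case-insensitive
  substring matching on 19 cell-label terms.
* **shortest-path genes** — interior genes on minimum-cost PPI paths
  between trans entities and cis genes (below).

Coordinates are held 0-based half-open internally (BED native); 1-based
TSV inputs are converted at the I/O boundary and positions round-trip
losslessly.

## Propagation and shortest paths

The PPI network (restricted to expressed genes, CpGs attached to their
binding TFs) is scored by a random walk with restart: restart probability
0.5, uniform restart mass on the seeds (trans entities and cis genes),
dangling-node mass returned to the seeds, power iteration to an L1
tolerance of 1e-10. The walk parameters are deliberately plain — restart
0.5 balances local and global structure and is exposed as an argument.

High-scoring nodes should be *cheap* to route through. Since standard
shortest-path algorithms require nonnegative weights, node scores $PS$
are mapped to costs $W(v) = \max(PS) - PS(v)$, which is order-equivalent
to weighting by $-PS$ but Dijkstra-safe. Path cost is the sum over
*interior* nodes only, so a trans entity directly adjacent to a cis gene
costs zero and contributes no interior genes. One minimum-cost path is
extracted per (trans, cis) pair; cost ties are broken by the
lexicographically smallest node-name sequence, making the output
deterministic. Disconnected pairs are skipped. A property test checks the
implementation against exhaustive path enumeration on all graphs with up
to 8 nodes.

# Edge priors

Every unordered node pair carries exactly one prior class:

* **SNP–cis gene**: $1 - \mathrm{lFDR}$ of the pair's reference eQTL
  p-value.
* **gene–gene** (PPI-connected pairs among cis genes, TFs, and — for
  eQTL hotspots — trans genes): $1 - \mathrm{lFDR}$ of the Pearson
  correlation p-value in a reference expression panel. The panel is
  preprocessed by log2, per-sample quantile normalization, per-gene
  rank-based inverse-normal transform, and removal of the first 10
  principal components (a standard guard against broad confounders).
  The lFDR is fitted once over all scored pairs, not per locus.
* **CpG–gene** (meQTL, gene within 200 bp of the CpG): the proportion of
  reference cell lines whose chromatin state at the CpG's 200 bp window
  is TSS-related (`TssA`, `TssAFlnk`, `TssBiv`, `BivFlnk`), optionally
  weighted by blood cell-type proportions; cell lines without a weight
  receive the mean weight. A CpG on a window boundary belongs to the
  half-open window containing it.
* **TF–target**: a fixed 0.99 wherever the binding-site windows above
  are met — ChIP-seq-grade evidence is treated as near-certain.
* **pseudo**: all remaining pairs get the floor $10^{-7}$, and assembled
  values are clipped to $[10^{-7}, 0.999999]$ so that Bernoulli sampling
  and prior odds stay well defined.

## The lFDR estimator

The local false discovery rate is fitted on the p-value scale with a
two-component model $\mathrm{lfdr}(p) = \eta_0 f_0(p)/f(p)$, uniform null
$f_0 = 1$. The mixture density $f$ is the Grenander estimator — the
monotone-decreasing density given by the left derivative of the least
concave majorant of the empirical CDF, computed by weighted
pool-adjacent-violators. $\eta_0$ is the plateau estimate
$(1 - F_{\mathrm{LCM}}(0.8))/0.2$, capped at 1; simulations in the test
suite show recovery within $\pm 0.1$ for $\eta_0 \in \{0.5, 0.8, 1\}$ at
$n = 5000$. Estimates are clipped to $[0, 1]$ and a final isotonic pass
enforces monotonicity in $p$. At least 200 p-values are required by
default; the partial-correlation engine relaxes this to 50 because a
20–25-node network yields only 190–300 edge p-values.

# The simulation benchmark

The benchmark asks: *if the priors were the truth generator, how much do
they help, and how quickly does the benefit die as they become wrong?*

1. **Ground truth**: sample $G_T$ from the prior matrix — edge $(i,j)$
   iff $p_{ij} > 10^{-7}$ and $u_{ij} \le p_{ij}$.
2. **Prior error**: rewire a fraction $F \in \{0.1, \dots, 1\}$ of
   $G_T$'s edges by double-edge swaps, preserving the degree sequence
   exactly; every introduced edge must lie outside the prior support, so
   comparing the priors with $G_N^F$ realizes an error of $F$. A swap can
   remove two original edges at once; swaps overshooting the target are
   avoided whenever possible (realized count within one of
   $\lceil F|E|\rceil$). Because the constrained swap walk can never step
   back onto prior-supported slots, an unlucky sequence can dead-end on a
   feasible instance; the implementation therefore restarts the sequence
   (20 attempts within the overall proposal budget) before declaring the
   constraint infeasible. Genuinely infeasible instances exist — a
   4-cycle cannot be rewired to an edge-disjoint graph on the same four
   nodes — and raise an explicit error.
3. **Data**: draw $n = 612$ i.i.d. Gaussian samples with covariance
   structured by the graph. The precision matrix takes off-diagonal
   entries uniform in $\pm[0.4, 0.8]$ on edges, diagonal
   $|\lambda_{\min}| + 0.1$ (diagonal dominance), and the covariance is
   standardized to unit variances — the same support semantics as
   G-Wishart simulators, in a closed, reproducible form.
4. **SNP column**: the first node is discretized to dosages by cutting at
   the empirical type-1 (order-statistic) quantiles of the cumulative
   Hardy–Weinberg dosage frequencies of the configured MAF. Type 1 makes
   the cut points exactly reproducible.
5. Each configured engine infers a network from each dataset and is
   scored against the matching ground truth by MCC; scenario blocks
   repeat the no-error condition under sub-sampled data (50–600), thinned
   priors (keep 10–90%), and a scalar density prior
   $p_{rbinom} = \max\left(\tfrac{1}{N_S}\sum_G |E_G| / |E_T|,\ 10^{-7}\right)$.

Benchmark hotspot priors are generated by `random_prior_matrix()`:
25 nodes, an informative prior on 10% of pairs with strengths uniform in
$[0.7, 0.95]$ — a locus-set-sized universe whose candidate set is a few
times larger than the expected graph, resembling the real prior classes
(strong but not certain evidence on a minority of pairs).

# Inference engines

All engines consume the same rank-based inverse-normal transformed
(`gaussianize()`) and standardized data, so dosage columns enter as
copula-style normal scores and results are comparable across engines.

**Per-edge-penalty graphical lasso** (`penalized_mle`, `penalized_cv`).
Block coordinate descent maximizes
$\log\det\Theta - \mathrm{tr}(S\Theta) - \sum_{i\ne j}\Lambda_{ij}|\Theta_{ij}|$
with the diagonal unpenalized; priors enter as
$\Lambda = (1-\mathcal{P})\,\omega$. Every fit is verified against the
KKT stationarity conditions to $10^{-6}$. The global weight $\omega$ is
screened over $\{0.01, 0.015, \dots, 1\}$ by 5-fold cross-validation:
each candidate's *support* is rescored by the training-fold MLE refitted
to that support and the held-out
$\mathrm{BIC} = -2\ell(\hat\Theta; S_{\mathrm{test}}, n_{\mathrm{test}})
+ |E|\log n_{\mathrm{test}}$ is averaged over folds. The refit step is a
deliberate numerical choice: scoring the shrunken lasso estimate itself
biases selection toward the densest fit (lasso bias inflates the
likelihood gap between small and large $\omega$), which empirically
selects the smallest $\omega$ on every input; the debiased refit restores
the intended model-selection behaviour (near-empty networks on null
data, clean recovery of strong structures).

**Bayesian structure search** (`mcmc_structure_search`). A
Metropolis–Hastings chain over graphs with single-edge toggle proposals;
acceptance $\exp(-\Delta\mathrm{BIC}/2)$ times the Bernoulli prior odds
of the toggled edge, where a graph's BIC uses the support-constrained
Gaussian MLE (zero penalty on allowed edges, effectively infinite
elsewhere). The chain starts from the prior incidence (entries $> 0.5$),
runs 10 000 iterations with 5 000 burn-in by default, and reports
posterior inclusion frequencies; edges with posterior $\ge 0.9$ form the
network. This is a deliberate desk-scale surrogate for birth–death
G-Wishart samplers: it preserves their functional role (edge priors,
posterior cutoff, prior start graph) and is exact to enumerate on three
nodes, where the test suite checks agreement within $\pm 0.05$ at 50 000
iterations. BIC values are cached per visited graph and the
support-constrained fits are warm-started from the chain's current
state. One consequence of the surrogate, visible in the acceptance
suite, is that at the benchmark's scaled-down size (25 nodes,
$n = 600$) the BIC search is strong enough to saturate: with and
without priors it recovers the truth almost perfectly at zero prior
error, so the *strict* prior benefit shows only in the penalized engine
at these conditions, and the Bayesian benefit appears under prior error
(hostile priors drag its recovery below the no-error level).

**Shrinkage partial correlations** (`shrinkage_pcor_network`). The
correlation matrix is shrunk toward the identity with the closed-form
analytic intensity (clamped to $[0,1]$), inverted to partial
correlations, p-values from a t approximation with $n - p$ degrees of
freedom, and edges kept at $\mathrm{lfdr} \le 0.2$ (posterior edge
probability $\ge 0.8$). No prior information enters; this is the
prior-free reference method.

**Tree-ensemble link ranking** (`tree_ensemble_links`,
`scale_free_cutoff`). Per target, a random-forest regression on all other
columns (impurity importance, normalized per target, symmetrized by the
maximum of the two directions, single-threaded with per-target seeds for
determinism). The weight cutoff is chosen by scale-free topology fit: up
to 200 weight quantiles are screened; for each candidate network the
$R^2$ of $\log_{10}$ frequency on $\log_{10}$ degree over 10
logarithmically spaced degree bins (zero bins dropped) is computed;
candidates occupying fewer than 3 bins get no fit (a star's two-point
degree distribution would score a meaningless $R^2 = 1$). Among
candidates with $R^2 > 0.8$ the one with most edges wins; otherwise the
highest-$R^2$ candidate; if no candidate has enough bins, the largest
candidate with a warning.

The prior-weighted random forest of the original method family (custom
per-split candidate sampling) is not implemented; the benchmark harness
accepts any engine as a function `(data, prior, seed) -> adjacency`.

# Evaluation, prioritization, merging

Networks are compared over the union of node sets (a node absent from one
network contributes only non-edges) by confusion counts over unordered
pairs and
$\mathrm{MCC} = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}$,
with any zero factor giving 0 — needed for empty predictions on sparse
truths. Cross-cohort replication is the MCC between networks inferred on
the two cohorts.

The graph score restricts the network to the connected component
containing the SNP and computes
$S_G = -\log_{10}(D_G)\left[\frac{|G_S|-|\bar G_S|}{|\mathcal{G}_C|} +
\frac{|G_T|-|\bar G_T|}{|\mathcal{T}|}\right]$, rewarding SNP–cis
adjacency and trans entities reached through cis genes while penalizing
density ($D_G$ over the cluster's node count). "Directly connected to
another cis gene" is read as 1-hop adjacency, not transitive chains;
trans reachability is computed with the SNP and the other trans entities
deleted. The score is 0 when the SNP is absent or no cis gene shares its
cluster. Consensus networks across cohorts keep only edges present in
both networks and drop isolated nodes; ranking is by score (descending),
then edges and nodes (ascending, smaller is better), then hotspot id.

TF activities are per-sample ridge least-squares solutions of
$e \approx C a$ on standardized expression (ridge $10^{-3}$), a
closed-form stand-in for latent-activity estimators; the partial-least-
squares variant used elsewhere would add an unspecified rank parameter.
Activities can replace TF expression columns before inference.

# What the synthetic fixtures emulate — and what they do not

`make_locus_fixture()` writes a miniature genome in the real external
formats (annotation TSV/GTF, TFBS BED, chromHMM BED, PPI TSV, QTL TSV)
and reads it back through the package readers, so every test exercises
the I/O layer. Planted structure is recovered by construction: cis genes
inside the window plus one decoy outside, TFBS within the 50 bp windows,
a PPI chain with known interior genes. `make_prior_reference()`
constructs reference data whose assembled priors support exactly a
configurable fraction of the true edges — signal rows in the eQTL table,
correlated column pairs in the reference expression (with PC removal
disabled there, since its planted per-pair factors are exactly what PC
removal strips from 200-gene panels), TSS states at covered CpGs, and
binding sites for covered TF edges. `make_cohort_pair()` draws two
independent cohorts from one truth.

The fixtures do *not* emulate: LD structure (clusters are consumed as
input), methylation beta distributions (continuous Gaussian stands in, as
in the benchmark design), array artefacts or probe-level missingness
beyond simple NA injection, and cell-type heterogeneity. Passing tests
therefore demonstrate correctness of the machinery and the qualitative
prior-benefit findings at desk scale, not cohort-level effect sizes.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run the benchmark at 10–20
hotspots of 25 nodes, $n = 600$, the full $\omega$ grid, and MCMC at its
default 10 000 iterations; these sizes give stable medians while keeping
a complete run in the minutes range on one CPU. Key numerical constants:
convergence tolerances $10^{-9}$ (final penalized fits; KKT residuals
$< 10^{-6}$), $10^{-7}$ (cross-validation path), power iteration
$10^{-10}$; adjacency threshold $|\Theta_{ij}| > 10^{-8}$; prior floor
$10^{-7}$ and cap $0.999999$; quantile conventions: type 1 for dosage
cuts and scale-free cutoffs (exact reproducibility), type 7 for the
predicted-TFBS width percentile. Degenerate inputs fail loudly: constant
columns in `gaussianize()`, seeds missing from the propagation graph,
conflicting prior classes, infeasible rewiring.

# Known limitations

* The Bayesian engine approximates the marginal likelihood by BIC; at
  desk scale it saturates where a G-Wishart sampler would not, so
  between-engine comparisons should be read per engine, against its own
  prior-free twin and its own error ladder.
* The lFDR estimator assumes a uniform null on well-behaved p-values;
  heavily discretized p-values would need pre-smoothing.
* Cell-type weighting of chromatin-state priors assumes a user-provided
  mapping from reference cell lines to weighted types; unmapped lines
  get the mean weight.
* The graph score's 1-hop reading of cis-gene connectivity is one of two
  defensible readings of the definition; chains of cis genes only count
  through their directly connected members.
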