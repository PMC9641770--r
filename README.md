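# priorgraph

Reconstruction of the regulatory networks underlying *trans*-acting QTL
hotspots, with biological prior knowledge wired into the network
inference itself.

## The problem

A *trans*-QTL hotspot is a genetic locus associated with many distal
molecular traits — expression of genes, or methylation of CpGs, on other
chromosomes (here, at least five). The mechanistic hypothesis is a short
cascade: the SNP perturbs a nearby **cis gene**, whose product reaches
the distal **trans** targets through signalling intermediates and a
**transcription factor**. `priorgraph` turns this hypothesis into a
statistical object: an undirected Gaussian graphical model (GGM) over a
role-tagged node universe (the *locus set*) built around each hotspot,
estimated from cohort multi-omics data (genotype dosages, expression,
methylation) with **per-edge prior probabilities** derived from public
reference resources.

For node pair $(i,j)$ the prior $p_{ij}$ comes from exactly one evidence
class — reference eQTL local false discovery rates
($p = 1 - \mathrm{lFDR}$), reference co-expression of PPI-connected gene
pairs, promoter-like chromatin states at CpGs, or TF binding sites
(fixed $p = 0.99$) — and everything else gets a pseudo-prior of
$10^{-7}$. Priors enter inference two ways:

* **graphical lasso with per-edge penalties**: $\Lambda = (1 -
  \mathcal{P})\,\omega$, the global weight $\omega$ screened over
  $\{0.01, 0.015, \dots, 1\}$ by 5-fold cross-validation with a
  test-fold BIC;
* **Bayesian structure search**: Metropolis sampling over graphs with
  acceptance $\exp(-\Delta\mathrm{BIC}/2)$ times the Bernoulli prior
  odds of the toggled edge, posterior edge cutoff 0.9.

Prior-free engines (shrinkage partial correlations, tree-ensemble link
ranking with a scale-free cutoff) serve as references. Networks are
scored against ground truth or across cohorts with the Matthews
correlation coefficient

$$\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
{\sqrt{(TP{+}FP)(TP{+}FN)(TN{+}FP)(TN{+}FN)}},$$

prioritized with the graph score
$S_G = -\log_{10}(D_G)\,[(|G_S|-|\bar G_S|)/|\mathcal{G}_C| +
(|G_T|-|\bar G_T|)/|\mathcal{T}|]$, filtered by GWAS-catalog membership,
and merged across cohorts into consensus networks. A built-in simulation
benchmark measures how inference degrades with prior error (degree-
preserving rewiring), sample size, and prior completeness. A synthetic
fixture generator emulates every input format, so the whole pipeline
runs and is tested without any download.

## Worked example

```r
library(priorgraph)

# a complete synthetic hotspot: annotation, TFBS, PPI and QTL tables are
# written in their native formats and read back through the package readers
spec <- fixture_spec(seed = 11)           # 3 cis genes, 5 trans CpGs, 2 TFs
fx   <- make_locus_fixture(spec)
fx$locus_set
#> Locus set for rs1 (meqtl)
#>   cis genes:      3
#>   trans entities: 5
#>   CpG genes:      5
#>   TFs:            2
#>   SP genes:       4
#>   nodes total:    18

# reference-derived per-edge priors (eQTL lFDR, co-expression, chromHMM, TFBS)
pr <- make_prior_reference(fx, spec)
ed <- network_edges(fx$truth)
mean(pr$prior[cbind(ed$a, ed$b)] > pseudo_prior())
#> [1] 1                                  # prior support covers the truth

# two cohorts sharing the true network; prior-guided inference on each
set.seed(1)
pair  <- make_cohort_pair(fx$locus_set, fx$truth, spec)
net_a <- penalized_cv(pair$A, pr$prior)$network
net_b <- penalized_cv(pair$B, pr$prior)$network
mcc(confusion(net_a, fx$truth))
#> [1] 1                                  # recovery vs ground truth
cross_cohort_mcc(net_a, net_b)
#> [1] 1                                  # replication across cohorts

consensus <- merge_networks(net_a, net_b) # high-confidence edges only
graph_score(consensus, fx$locus_set)
#> graph score 1.9085 (density 0.111; |G_S| 3, |G_S bar| 0, |G_T| 5, |G_T bar| 0)
```

With full prior coverage and 200 samples the prior-guided graphical
lasso recovers the planted 17-edge cascade exactly in both cohorts (MCC
1 against the truth, cross-cohort MCC 1); the benchmark in
`scripts/acceptance.R` probes the harder regimes where priors are
partially or completely wrong. The graph score rewards the consensus
network for connecting the SNP through cis genes to all five trans CpGs
without direct SNP-trans shortcuts, scaled by its sparsity
($-\log_{10}(0.111) \times (3/3 + 5/5) \approx 1.91$).

A thin command-line front end over the same functions ships in
`inst/cli/priorgraph.R` (subcommands `hotspots`, `locusset`, `infer`,
`evaluate`, `score`, `merge`, `tfa`, `fixtures`).

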