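# scCloneTree

Bayesian reconstruction of tumor clonal trees by integrating bulk DNA-seq
variant read counts (with clonal copy numbers) and sparse single-cell
RNA-seq variant read counts.

## The problem

Bulk sequencing measures, per somatic SNV, a variant allele frequency
that constrains only the *cellular prevalence* of the clone carrying the
SNV — many trees explain the same bulk data, so clonal-tree
reconstruction from bulk alone is unidentifiable (a cherry and a chain
can fit identical VAFs). Reads at the same SNV loci in single-cell
RNA-seq reveal which variants co-occur in the same cells, which is
exactly the information that separates sibling clones from nested ones.
scCloneTree scores both data sources under one generative model:

* a tree-structured stick-breaking (TSSB) prior over the clonal tree
  `T` and the SNV-to-clone assignment `z` (root = healthy cells with a
  single child, the cancer progenitor);
* cellular prevalences `phi` per clone and region, with clone fractions
  `eta_v = phi_v − sum(children's phi)` carrying a flat Dirichlet prior;
* bulk variant reads `b_n ~ Binomial(d_n, theta(g, phi, eps))` with the
  genotype `g` marginalized uniformly over the set compatible with the
  clonal major/minor copy numbers `(M_n, m_n)`;
* single-cell variant reads at mutated loci following a Beta-Binomial
  mixture of bursty mono-allelic expression (`Beta(0.01, 0.01)`) and
  locus-specific bi-allelic expression (`Beta(alpha_n, beta_n)`), with
  the cell-to-clone membership marginalized under a uniform prior over
  clones — cost `O(C·|V|)` per likelihood evaluation.

Inference is MCMC: slice sampling of SNV assignments through the
stick-breaking representation (with exact trans-dimensional prior
accounting, validated by a Geweke test), conjugate Gibbs updates of the
sticks, and adaptive Metropolis–Hastings on the clone fractions. The
output is a posterior sample trace, a MAP tree with prevalences and SNV
assignments, and posterior cell-to-clone assignments.

## Worked example

```r
library(scCloneTree)

# simulate a cherry-shaped tumor: progenitor with two sibling subclones,
# 100 SNVs, 20 Smart-Seq-like cells, no copy-number evolution
sim <- simulateCloneData(simulationConfig(
  topology = "cherry", nSnvs = 100, nCells = 20,
  etaFixed = c(0.10, 0.05, 0.50, 0.35), seed = 1))

fit <- runCloneMCMC(sim$bulk, sim$sc, scHyper = sim$scHyper,
                    config = samplerConfig(nIterations = 600, burnIn = 300,
                                           seed = 11),
                    nChains = 2)
fit
#> CloneTreeFit: MAP log-joint -873.22 with 6 nodes; 300 retained samples

mapTree(fit)
#> ClonalTree with 6 nodes (max depth 4)
#>   healthy root: 0; progenitor clone: 0.1
#>   0
#>     0.1
#>       0.1.1
#>       0.1.2
#>         0.1.2.1
#>           0.1.2.1.1

evaluateFit(fit, sim$truth)
#> $vMeasure           [1] 0.9804812
#> $adjustedRandIndex  [1] 0.9871665
#> $adjustedMutualInfo [1] 0.9799112
#> $ancestralError     [1] 0.003838384

cells <- assignCells(fit, sim$sc, sim$scHyper)
table(mapClone(cells))
#>         0     0.1.1     0.1.2 0.1.2.1.1
#>         1         5        13         1
```

The MAP tree recovers the branching structure — the two subclones are
siblings, not nested, which bulk data alone cannot decide — with two
extra one-SNV micro-clones hanging below the larger subclone (a known
behavior of the exact posterior at few cells; they disappear from the
clustering metrics almost entirely: V-measure 0.98, and the ancestral
error counts the fraction of ordered SNV pairs whose ancestry relation
is wrong). `prevalence(fit)` returns the per-clone, per-region cellular
prevalences (here 0.90 for the progenitor and 0.35/0.50 for the
subclones, close to the simulated 0.90/0.35/0.50).

A command-line interface with `simulate`, `preprocess`, `run`,
`evaluate` and `score` subcommands is installed under `exec/`
(`scclonetree simulate --out sim_dir --seed 7`, then
`scclonetree run --bulk sim_dir/bulk.tsv --sc sim_dir/sc.tsv --out run_dir`).

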