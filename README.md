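# rwrhnet

Disease-gene and disease-disease prioritization by **random walk with
restart on a heterogeneous network** (RWRH).

## The problem

Given a disease of interest, which genes in a protein-interaction network
are likely associated with it, and which other diseases is it most related
to? `rwrhnet` answers both by propagating probability mass over a
*heterogeneous* network built from three layers:

* a weighted, undirected **gene/protein interaction network** (adjacency
  `W_G`),
* a **phenotypic disease-similarity network** (`W_D`), sparsified so each
  disease keeps only its `k` strongest similarities (top-k filter, default
  `k = 5`),
* a **bipartite layer of known disease-gene associations** (`W_GD`)
  connecting the two.

## The method

A walker starts from the disease of interest `d1` and its known associated
genes `S`, and at every step either moves along an edge or restarts at the
seeds with back-probability γ:

    P(t+1) = (1 − γ) W′ᵀ P(t) + γ P⁰

`W′` is the row-stochastic block transition matrix

    W′ = | W′_G   W′_GD |
         | W′_DG  W′_D  |

where a node with bipartite links crosses to the other layer with jumping
probability λ (mass split proportionally to association weights) and stays
inside its own layer with probability 1 − λ; nodes without bipartite links
keep all their mass inside their layer. The initial vector `P⁰` puts weight
η on the seed disease(s) and 1 − η spread equally over the seed genes
(η = 0.7, λ = 0.6, γ = 0.5 by default). Candidate genes and diseases are
ranked by the steady state `P∞`, a contraction fixed point reached by power
iteration. Shared-annotation evidence (genes, pathways, protein complexes,
disease ontology terms) can then be collected for the top-ranked
candidate diseases, and the whole pipeline is benchmarked by leave-one-out
cross-validation with a rank-based AUC.

## Worked example

Everything runs on seeded synthetic networks with planted disease modules,
so no external data is needed:

```r
library(rwrhnet)

syn <- generate_hetnet(synthetic_spec())   # 200 genes, 30 diseases, seed 42
syn$net
#> <hetnet> 200 genes (761 interactions), 30 diseases (84 similarities), 120 associations

fit <- rwrh_rank(syn$net, diseases = "d01")
fit
#> <rwrh_result> disease(s): d01 | 4 seed genes | converged in 27 iterations
#> top candidate genes:
#>    id type       score rank
#>  g012 gene 0.013092503    1
#>  g009 gene 0.008221902    2
#>  g016 gene 0.007771961    3
#>  g005 gene 0.007188132    4
#>  g015 gene 0.005036614    5

res <- leave_one_out(syn$net, rwrh_params())
res
#> <loo_result> 120 trials over 30 diseases | AUC = 0.9540
```

The top-ranked candidates are genes from the disease's planted module that
were *not* revealed to the walk, and the leave-one-out AUC of 0.954 says
held-out causal genes are ranked far above the candidate background (an
AUC of 0.5 is chance). `tidy()`, `glance()` and `autoplot()` methods give
per-node score tables, one-row summaries and ranking/ROC plots; a thin
command-line dispatcher (`inst/cli/rwrhnet.R`) exposes the same pipeline
as `simulate`, `rank`, `evaluate` and `evidence` subcommands.

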