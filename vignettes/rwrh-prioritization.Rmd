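---
title: "Prioritizing disease genes and diseases by random walk with restart on a heterogeneous network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes and diseases by random walk with restart on a heterogeneous network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrhnet)
```

## The model

`rwrhnet` scores every gene and disease in a heterogeneous network by its
proximity to a seed set — a disease of interest $d_1$ (or a disease class
$D$) together with its known associated genes $S$. The network
$G(V, E)$ has $N = n_G + n_D$ nodes: a weighted gene/protein interaction
network ($W_G$), a phenotypic disease-similarity network ($W_D$), and a
bipartite layer of known disease-gene associations ($W_{GD}$) joining
them. A random walker repeatedly either moves to a neighbour or restarts
at the seeds:

$$P^{t+1} = (1-\gamma)\, W'^{\mathsf T} P^t + \gamma P^0,$$

with back-probability $\gamma \in (0,1)$. Nodes are ranked by the steady
state $P^\infty$.

The transition matrix is assembled blockwise. With jumping probability
$\lambda$, a gene $g_i$ that has bipartite links sends mass $\lambda$ into
the disease layer, split proportionally to association weights, and mass
$1-\lambda$ along its interactions; a gene with no bipartite links keeps
all its mass in the gene layer. Diseases behave symmetrically on $W_D$ and
the columns of $W_{GD}$. Two conventions are worth making explicit:

* **Transpose in the update.** $W'$ is stored row-stochastic
  ($M_{ij} = P(i \to j)$), so the propagation multiplies by
  $W'^{\mathsf T}$: this is the column-stochastic action that conserves
  total probability. Writing the update without the transpose would leak
  mass at every step on any network with asymmetric degrees.
* **Degenerate rows.** The block formulas leave a node whose *only* links
  are bipartite with outgoing mass $\lambda < 1$. Such a row's bipartite
  block is renormalized to sum to 1 — the walker has nowhere else to go —
  which keeps every row stochastic. Rows that would be entirely zero
  cannot occur: assembly rejects any node with total degree 0 across the
  three layers (full single-component connectivity is *not* required,
  because the restart term makes the walk well defined on any
  degree-positive graph; mass simply concentrates in the seed
  component).

The initial vector places $\eta$ on the seed disease(s) — $\eta/|D|$ each
for a class — and $1-\eta$ split equally over the seed genes. When a
disease has no known genes, all mass goes to the disease side, so
prioritization still works for diseases without a known molecular basis.
When $S \neq \emptyset$ the normalizing reading is used: seed genes share
exactly $1-\eta$ and the disease(s) exactly $\eta$, so $\sum_i P^0_i = 1$;
any reading that also counted $d_1$ inside $S$ would break normalization.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $\gamma$ | restart probability per step | 0.5 | contraction factor of the iteration is $1-\gamma$ |
| $\lambda$ | probability of jumping between layers | 0.6 | only applies to nodes with bipartite links |
| $\eta$ | initial mass on the disease side | 0.7 | $\eta \to 1$ favours disease-similarity signal |
| `k_top` | similarities kept per disease | 5 | ties broken lexicographically by neighbour id |
| `tol` | L1 convergence threshold | $10^{-10}$ | iteration stops when $\lVert P^{t+1}-P^t\rVert_1 <$ `tol` |
| `max_iter` | iteration cap | 1000 | exceeding it raises a condition carrying the last iterate |

The propagation defaults (0.5, 0.6, 0.7) are standard operating settings
for this family of methods. The convergence threshold and cap are this
package's choices: with $\gamma = 0.5$ the L1 error contracts by half per
step, so $10^{-10}$ is reached in roughly 35 iterations and the cap is
never a binding constraint in practice.

## Numerical choices and degenerate inputs

* The steady state is computed by sparse power iteration; because the map
  is a $(1-\gamma)$-contraction in L1, the fixed point is unique and the
  starting vector is irrelevant (the test suite verifies agreement with
  the direct linear solve $\gamma (I - (1-\gamma) W'^{\mathsf T})^{-1} P^0$
  to $10^{-8}$, and independence of the start to $10\times$ `tol`).
* Duplicate edges keep the maximum weight and self-loops are dropped on
  read, so file order never matters. An asymmetric similarity matrix is
  symmetrized by averaging *before* the top-k filter, since phenotypic
  similarity is symmetric by construction.
* The top-k filter selects each disease's `k_top` strongest similarities
  (ties broken lexicographically by neighbour id for reproducibility) and
  keeps the union: an edge survives if either endpoint chose it, with its
  continuous similarity as weight. Continuous weights are kept rather
  than binarized because they feed the row normalization. The
  union-symmetrized filter is idempotent, which is what makes the written
  edge-list files round-trip exactly.
* Ranking ties share a score but are ordered lexicographically by id, so
  ranks are deterministic across runs; inside the cross-validation AUC,
  tied scores contribute their average rank, which makes the AUC
  order-independent.

## Leave-one-out evaluation

For every disease with at least two known genes, each association
$(d, g)$ is removed in turn, the walk is re-seeded with $d$ and its
remaining known genes, and the rank of $g$ is recorded among the
candidate universe of all genes outside the remaining seed set (the same
"all remaining genes" universe used for ordinary prioritization; a
k-random-controls variant can be had by passing an explicit candidate
set). Each trial contributes $(n - r)/(n - 1)$, the fraction of candidate
negatives ranked below the held-out gene, and the AUC is the mean over
trials — identical to trapezoidal integration of the pooled ROC curve
with one positive versus $n-1$ negatives per trial (verified to $10^{-9}$
against explicit ROC integration). Pooling is per-trial, not
per-disease, so diseases with more known genes carry proportionally more
weight.

## What the synthetic generator emulates

Real inputs of this pipeline — a protein-interaction network, a
text-mining-derived disease-similarity matrix, curated disease-gene
associations — are external data. The generator replaces them with a
network whose ground truth is known:

* genes follow a planted-partition model (`n_modules` modules, edge
  probability `p_in` within and `p_out` between; defaults 200 genes, 10
  modules, 0.3/0.01), emulating the functional modules that make network
  propagation informative;
* each disease draws `genes_per_disease` causal genes from one module
  (default 8), and disease similarity is the Jaccard index of causal gene
  sets plus uniform noise in $[0, 0.05]$ — encoding the premise that
  phenotypically similar diseases share genes, with the noise preventing
  degenerate ties in the top-k filter;
* the bipartite layer reveals a per-disease `known_fraction` of the truth
  (default 0.5, i.e. 4 of 8 genes), so held-out causal genes exist by
  construction;
* isolated genes are re-wired with one uniform edge rather than deleted,
  keeping `n_genes` exact for test arithmetic. All randomness flows from
  one seed; equal specs give bit-identical networks.

At these defaults the leave-one-out AUC is about 0.95, and a
degree-preserving shuffle of the bipartite layer drops it to about 0.5 —
the appropriate chance model, since the shuffle destroys exactly the
disease-gene pairing the method exploits. Setting `p_in = p_out` instead
removes only the gene-module structure and leaves the AUC well above
chance, because the similarity layer still links diseases with
overlapping causal sets; it is therefore a *weaker* null, and the tests
only assert that it loses most of the recovery margin.

The generator does **not** mimic the heavy-tailed degree distribution of
real protein-interaction networks, literature bias in curated
associations, or the similarity statistics of text-mining pipelines.
Passing tests demonstrate that the machinery is correct and that planted
signal of realistic strength is recovered — not that any particular AUC
will be attained on real human data, where published applications of this
method report substantially higher values on large curated networks.

## Evidence semantics

For a candidate disease and the disease of interest, the package counts
shared known genes, shared disease ontology terms (set intersections),
and shared pathways/protein complexes. The latter two use *dual
membership*: a term counts as shared when it contains at least one gene
of each disease. This is the only definition available when pathways and
complexes annotate genes rather than diseases, and it reproduces the
qualitative pattern seen in practice — diseases can share pathway-level
evidence while sharing no gene, and phenotypically similar diseases can
rank highly while sharing no annotation at all.

## Problem sizes used in the checks

The automated checks run the transition-builder oracle on 100 random
networks of up to ~16 nodes, the linear-solve oracle on 100 networks of
up to ~50 nodes, the AUC oracle on 1000 random trial sets, and the full
leave-one-out evaluation (120 trials) on the default 200-gene/30-disease
synthetic network plus its shuffled null — sizes at which the dense
oracles are exact and the whole suite completes in well under a minute on
one core.

## Known limitations

* The evaluation rebuilds the transition matrix per trial; at
  genome scale (tens of thousands of genes) an incremental update of the
  two affected rows would be the natural optimization.
* No identifier mapping between gene naming systems is attempted; ids
  are opaque strings and the gene and disease namespaces must not
  collide.
* Remote evidence retrieval (literature databases, curated web services)
  is out of scope; annotation files are supplied locally.
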