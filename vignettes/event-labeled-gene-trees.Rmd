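---
title: "Species trees from event-labeled gene trees: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species trees from event-labeled gene trees: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trispec)
```

## The model

A gene family evolves inside a species phylogeny through speciations,
duplications, and losses. When orthology analysis supplies, for every
interior vertex of a gene tree, whether it represents a speciation or a
duplication, the gene tree becomes a triple $(T, t, \sigma)$: a rooted
phylogenetic tree $T$ on a set $L$ of genes, an event labeling $t$ mapping
each interior vertex to $\{\bullet$ (speciation), $\square$
(duplication)$\}$ (leaves are extant genes, $\odot$), and an assignment
$\sigma: L \to B$ of each gene to the species it resides in. `trispec`
answers two questions about such data:

1. **Existence.** Is there any species tree on $B$ with which $(T,t,\sigma)$
   can be reconciled, and if so, which constraints does the gene tree place
   on it?
2. **Reconstruction of the map.** Given a compatible species tree $S$, how
   do the gene-tree vertices embed into $S$?

Throughout, phylogenetic trees are rooted, may contain polytomies, and have
no vertices with in- and outdegree one. The one sanctioned exception is the
species tree's root: $S$ carries an extra vertex $\rho_S$ and an extra edge
above the last common ancestor of $B$, so that duplications predating the
first speciation have an image. Compatibility between $t$ and $\sigma$ is
the condition enforced at construction of every `gene_tree`: below any two
distinct children of a speciation vertex, the species sets are disjoint.
The converse is deliberately not assumed — disjointness does not force a
speciation.

## Informative triples and the BUILD decision

A rooted triple $((x,y),z)$ is displayed by $T$ when the lca of $x,y$ lies
strictly below the lca of all three. Not every displayed triple says
anything about the species tree: when the triple's root is a duplication,
the two paralogous lineages may have separated long before the species
did, and the induced species triple can outright contradict the true
species tree (`test-reconcile.R` carries a regression fixture of exactly
this shape). The informative set is

$$\mathbb{G}(T,t,\sigma) = \{ r \in \mathcal{R}(T) :
  t(\mathrm{lca}_T(L(r))) = \bullet,\;
  \sigma \text{ injective on } L(r) \},$$

and its image under $\sigma$, written $\mathbb{S}(T,t,\sigma)$
(`species_triples()`), is the constraint set over species labels. Two
results drive everything the package does:

* every species tree for $(T,t,\sigma)$ displays all of
  $\mathbb{S}(T,t,\sigma)$; and
* a species tree exists **iff** $\mathbb{S}(T,t,\sigma)$ is consistent,
  decidable in polynomial time with the BUILD (Aho) algorithm.

`informative_gene_triples()` implements the definition literally
(enumerate displayed triples, filter). `species_triples()` uses an
equivalent per-speciation-vertex construction — for children $c_1 \neq
c_2$ of a speciation, all $((A,B),C)$ with $A \neq B$ species below $c_1$
and $C$ a species below $c_2$ — which avoids materializing the cubic gene
triple set; the equality of the two routes is a standing property test.

There is no free lunch in the other direction: any triple set over
species, consistent or not, is realized exactly by some event-labeled gene
tree, and `gene_tree_from_triples()` builds the canonical witness (one
speciation-rooted triple subtree per constraint under a duplication root).
When the set has a single element the duplication root is omitted — the
literal construction would give it outdegree one, which the tree axioms
forbid.

BUILD itself (`build_tree()`) recursively partitions the current label set
by the connected components of the graph with one edge $\{x,y\}$ per
active triple $((x,y),z)$; a connected component covering two or more
labels with no split certifies inconsistency and is returned as the
certificate. Because the output depends on recursion order in general,
components and children are canonically ordered (by smallest label), so
results are deterministic and tree equality is decidable by comparing
canonical Newick strings. The output tree is minor-minimal but not
necessarily unique nor vertex-minimal; the package returns the canonical
one and makes no uniqueness claim. Components use a plain union-find;
asymptotically optimal BUILD variants are out of scope at the problem
sizes targeted here.

## The reconciliation map

For a species tree $S = (W,H)$ displaying all of $\mathbb{S}$, the
canonical map constructed by `construct_reconciliation()` is

* $\mu(x) = \sigma(x)$ for leaves,
* $\mu(x) = \mathrm{lca}_S(\sigma(L(x)))$ for speciations,
* $\mu(x) = $ the edge above $\mathrm{lca}_S(\sigma(L(x)))$ for
  duplications,

computed with one bottom-up pass over $T$ for the species sets and one lca
evaluation per vertex. Leaf and speciation images admit no freedom at all;
duplications may slide rootward, and
`enumerate_duplication_placements()` walks the admissible edges (up to the
extra root edge) and returns every assignment that validates, in
deterministic order.

`validate_reconciliation()` checks the defining conditions — leaf
anchoring, speciations to interior vertices, duplications to edges,
ancestor-order preservation (non-strict between consecutive duplications,
strict otherwise), and the lca condition on speciations — plus two derived
properties that are theorems for any valid map and therefore flag
implementation bugs rather than borderline inputs: the lca bounds on
images, and $\mathrm{lca}_S(\mu(x),\mu(y)) \preceq_S \mu(\mathrm{lca}_T(x,y))$
over all vertex pairs. Order comparisons involving edges use the edge
extension of the ancestor relation: a vertex $v$ lies below edge $[u,w]$
iff $v \preceq w$, an edge $[u,w]$ lies below vertex $v$ iff $u \preceq
v$, and edges compare through their child endpoints. Under this extension
two nested duplications with identical species sets may legitimately share
an edge, and the validator accepts that. All violations are reported with
clause tags, not just the first.

## The simulator

`sim_species_tree(n)` draws an age-model species tree: a ranked topology
from successive uniformly random merges of lineages, interior vertex ages
as sorted uniforms on $(0,1)$, root age 1, leaves at age 0. This
realization reproduces the two properties that matter downstream —
ultrametry with unit root-to-leaf depth, and balance in expectation — and
is documented here as this package's own stand-in for the age model's full
original definition. The extra root edge needs a length for event
sampling; it defaults to the mean edge length of the tree, a convention
chosen once so that pre-divergence duplications occur at a plausible rate.

`sim_gene_tree(s, dup_rate, loss_rate)` evolves a single ancestral gene
down the species tree. Per species-tree edge of length $\ell$, each
entering gene lineage draws $\mathrm{Poisson}(r\,\ell)$ duplication and
loss counts with i.i.d. uniform positions, and events apply in temporal
order; a duplication forks the lineage and the new copy receives no
further events until the next edge (the interleaving semantics had to be
fixed somewhere; this choice is simple and reproducible). At every
speciation vertex all live lineages fork into all daughter edges.

Retention of at least one gene copy per species ($\sigma(L) = B$) is
enforced by a per-edge guard: a loss event is discarded whenever its
lineage is the only one alive on the current species edge. A
rejection-sampling alternative (resample whole scenarios until all species
survive) preserves the unconditional Poisson law more transparently, but
its acceptance probability collapses roughly like
$e^{-r_{loss}\cdot\mathrm{depth}\cdot n}$ in the low-duplication,
high-loss regime — about $10^{-6}$ already at $n = 10$, $r_{loss} = 1$ —
so the guard is used instead; it is also the natural per-edge reading of
"retain at least one copy in each species", since an interior species
edge stripped of all copies could never repopulate its descendants. A
consequence worth knowing: with a duplication rate of zero the guard
suppresses *every* loss, and the observable gene tree mirrors the species
tree exactly.

The simulator records the full truth: the complete gene tree including
loss leaves, all event labels, and the true map $\hat\mu$ (vertices for
speciations and extant genes; edge-plus-time for duplications and
losses). `observable_gene_tree()` restricts to extant genes, suppressing
exactly those vertices with fewer than two surviving child lineages, and
returns a validated `gene_tree` with the restricted true map attached —
the simulator is the package's own fixture generator, and every observable
tree must pass the compatibility checks by construction.

## Split recovery and the experiment

The recovery score (`split_recovery()`) is defined here as the cluster
intersection ratio
$100\cdot|\mathcal{C}(\text{inferred}) \cap \mathcal{C}(\text{true})| /
|\mathcal{C}(\text{true})|$, clusters taken over interior vertices
including the root and excluding $\rho_S$. In the regime observed in all
simulations — the inferred tree is a homomorphic contraction of the true
one — this coincides with the interior-vertex-count ratio, and the
interior-vertex difference (there equal to the split metric) is reported
as a diagnostic. The contraction property itself is *not* mathematically
guaranteed, so the experiment records it per replicate and the test suite
asserts it only on its fixed seeds rather than treating it as a theorem.

`run_experiment()` chains simulator, observable restriction, triple
extraction, BUILD, and scoring, one row per replicate;
`run_rate_grid()` aggregates cell means over a rate grid for heat maps.
Default problem sizes are desk-scale by design: the headline high-loss run
uses 20 species trees with 10–30 species, duplication rate uniform on
$[0,1]$ and loss rate uniform on $[0.8,1]$ ("very high loss" is
operationalized as the top fifth of the sampled range); the theorem suites
in the tests run over 200 scenarios with 5–15 species and both rates
uniform on $[0,1]$.

## Numerical and degenerate-input choices

* Tree equivalence is decided via canonical serialization (children
  sorted by smallest descendant leaf); lca uses root-path walking, $O(d)$
  per query — no sparse-table preprocessing at these sizes.
* Gene trees require $|L| \ge 3$; smaller inputs are rejected at
  `gene_tree()` construction, while the plain tree utilities degrade
  gracefully.
* $|B| = 1$ is permitted: the species "tree" is then the single species
  under $\rho_S$ (`species_tree_single`), its triple set is necessarily
  empty, and no uniqueness is claimed.
* Edge lengths are optional everywhere except in the simulator, which
  needs them for Poisson sampling.
* Seeds: all stochastic entry points either accept a `seed` argument or
  document reliance on R's global RNG; identical seeds give byte-identical
  scenario serializations.

## Limitations

The simulator emulates duplication–loss evolution only: no horizontal
transfer, no incomplete lineage sorting, no sequence evolution, and
perfect event labels. Passing tests therefore say nothing about how the
method copes with misannotated events or estimated gene trees; with real
data, an inconsistent triple set is the expected outcome and only the
verdict-with-certificate is provided — maximum consistent subset repair
is deliberately out of scope, as are the enumeration of all minor-minimal
trees and loss-minimizing or duplication-clustering reconciliation
objectives.
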