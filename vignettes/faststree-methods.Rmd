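---
title: "Methods: species-tree estimation from gene trees and its simulation-based evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-tree estimation from gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faststree)
```

## The problem

A species phylogeny is usually estimated indirectly, through phylogenetic
analyses of many individual genes. The true gene trees can disagree with the
species tree — most prominently because of incomplete lineage sorting (ILS),
the population-level failure of gene lineages to coalesce within the branch
where their species diverged — and estimated gene trees disagree further
because of estimation error. `faststree` implements the family of *fast*
species-tree methods that combine single estimated gene trees (consensus
methods, distance methods, and reconciliation-criterion searches), along with
everything needed to evaluate them by simulation: a multispecies-coalescent
(MSC) gene-tree simulator, an indel-aware sequence evolver that tracks true
alignment homology, desk-scale gene-tree estimation, error scoring, and
paired statistical comparisons.

## Error measure

Estimated species trees may be partially resolved, and the Robinson–Foulds
(RF) distance is biased in favor of unresolved trees. Accuracy is therefore
scored with the **missing-branch (false negative, FN) rate**: the proportion
of the true tree's internal bipartitions absent from the estimate, computed
by `missing_branch_rate()`. The denominator is the internal-edge count of the
*true* tree, so partially resolved reference trees are handled; for a binary
reference on $n$ leaves it equals $n-3$, and for two binary trees FN rate
$= \mathrm{RF}/(2(n-3))$. `rf_distance()` is provided for completeness.

All bipartition machinery ignores the root: a rooted tree is unrooted before
splits are enumerated. Bipartitions are keyed canonically by the side *not*
containing the lexicographically smallest leaf, which gives set-equality
semantics for free.

## Species-tree methods

**Majority consensus** (`majority_consensus()`) keeps exactly the splits
occurring in strictly more than half of the gene trees ("more than half" is
strict: a split in exactly half the trees is dropped). **Greedy (extended
majority) consensus** (`greedy_consensus()`) then walks the remaining
observed splits in decreasing frequency, adding each one compatible with the
set accumulated so far. Where the frequency order is not unique the walk is
made deterministic: ties are ordered by smaller-side size and then
lexicographically by the smaller side's label tuple. This choice is ours —
any fixed rule would do — and it makes outputs reproducible.

**GLASS** (`glass_tree()`) takes per-gene distance matrices, forms the
element-wise minimum across genes, and single-linkage-clusters the result.
Under a molecular clock the minimum coalescence time across many genes
converges from above to the species divergence time, which is why the method
is statistically consistent given correct gene trees. The returned tree is
rooted by the final merge and its node depths equal the merge heights (so a
leaf-to-leaf path length is twice the clustered distance). Distances can come
from alignments (`logdet_distance()`) or from gene trees
(`tree_path_distances()`).

**Reconciliation criteria.** For a rooted species tree $S$ and rooted gene
tree $G$ on the same leaf set:

* *Deep coalescences* (`mdc_score()`): for each cluster $C$ of $S$ (one per
  internal edge), let $k_C$ be the number of maximal clades of $G$ whose leaf
  sets lie inside $C$; the branch above $C$ carries $k_C - 1$ extra lineages
  and the score is $\sum_C (k_C - 1)$.
* *Duplications and losses* (`dup_loss_score()`): with the LCA mapping $M$
  (`lca_mapping()`), a gene node $v$ is a duplication when $M(v) = M(u)$ for
  one of its children $u$; losses accumulate as
  $\sum_i d(M(u_i), M(v)) - 2\,[v\ \text{speciation}]$ with $d$ the
  edge-count distance in $S$. For a shared leaf set the identity
  *extra lineages = losses − 2·duplications* holds and is exercised in the
  tests.

These counting formulas are the standard ones from the reconciliation
literature. The test suite does not take them on faith: an independent
brute-force oracle enumerates every valid reconciliation map on small
instances, computes each cost from first principles, and minimizes over maps;
implementation and oracle agree on all rooted binary pairs with up to 5 taxa
and on random 6-taxon instances.

**Constrained MDC** (`mdc_score_unrooted()`): an estimated gene tree is
unrooted and possibly unresolved, and is treated as a *constraint* on the
true gene tree. The score is the minimum over all rooted binary trees whose
unrooted topology displays the estimate's splits. This is computed by
explicit enumeration — the unrooted topology is refined at a leaf-anchored
rooting and every refinement is rooted on each of its edges. Refinement
counts grow as the double factorial of polytomy degree, so enumeration is
guarded (`refinement_limit`, default 20000 ≈ polytomies up to degree 8);
larger polytomies raise an error rather than silently approximating. The
exact polynomial-time algorithm for this problem is out of scope here;
correctness is defined against brute force on small instances, which is the
regime the package targets.

**Search** (`search_species_tree()`): hill climbing over rooted binary
species trees minimizing the chosen criterion summed over genes. Moves are
rooted NNI (default) or rooted SPR (a superset); reconciliation criteria
have large score plateaus, so the climber may take up to 10 consecutive
equal-score moves to unvisited topologies before giving up, which in
practice escapes the flat regions. The first start is the greedy consensus
randomly refined to binary; `random_restarts` (default 2) adds random
topologies; the whole procedure is deterministic given `seed`. Under MDC,
unrooted/unresolved genes are scored with the constrained criterion; under
dup/dup-loss, unrooted binary genes are scored at their best rooting and
unresolved genes are rejected (point estimates fed to these criteria must be
resolved).

## The simulator

`generate_dataset()` reproduces two protocols.

**ILS mode.** A birth–death species tree (via `ape::rphylo`, conditioned on
the leaf count, ultrametric) is uniformly scaled by `branch_scale` (default
0.05) and its branch lengths are then read in *coalescent units* (2N
generations): within a branch carrying $k$ lineages, coalescences occur at
rate $k(k-1)/2$, truncated at the branch end, and surviving lineages coalesce
freely above the root (`simulate_msc_gene_tree()`). The choice of 2N units
(pair rate 1) is recorded here; a 4N convention would halve all times. Note
that the ILS intensity produced by `branch_scale` depends on the time scale
of the birth–death tree: the examples and the acceptance script use a small
birth rate (deep trees) so that the 0.05 scaling leaves internal branches of
a few tenths of a coalescent unit — substantial but not saturating ILS.

**No-ILS mode.** All gene trees share the species topology; half keep its
branch lengths verbatim and half have each length multiplied by an
independent positive mean-1 draw and are then rescaled to the original total
tree length (`perturb_branch_lengths()`). The multiplier family is lognormal
with $\mu = -\sigma^2/2$ (mean exactly 1), $\sigma$ = `perturbation_sd`
(default 0.3): positive support and pluggable spread.

**Sequences** (`simulate_sequences()`) evolve from a root sequence of length
`root_length` (default 1000) drawn from the stationary frequencies. The
substitution model is GTR (+ continuous Gamma rates per site, mean 1, plus an
optional invariant proportion), normalized to one expected substitution per
unit branch length; transition matrices come from the eigendecomposition of
the symmetrized rate matrix. A Jukes–Cantor preset is available. Indels are
Poisson processes per branch (`indel_model()`, default 0.01
events/site/substitution for each of insertion and deletion) with truncated
geometric lengths ($p = 0.3$, max 10); insertions fall uniformly between
sites with fresh residues, deletions clip at sequence ends, and event counts
use the branch's starting length. Homology is tracked exactly through a
global column order, so the true alignment (gaps as `-`) is emitted alongside
the unaligned sequences, and no all-gap column can appear. The default model
parameters are explicit configuration defaults — generic, plausible values —
not estimates of any particular biological dataset. `subst_scale` (default 1)
converts gene-tree (coalescent-unit) lengths to expected substitutions.

The simulator intentionally does *not* emulate: alignment estimation error
from real aligners (true alignments are available directly), migration,
population-size variation, multiple alleles per species, HGT, or gene
duplication/loss. Passing tests therefore demonstrate correctness of the
coalescent/substitution machinery and relative method behavior under ILS and
branch-length noise, not performance on data with those additional
processes.

## Gene-tree estimation

The package deliberately does not reimplement ML or Bayesian tree inference.
Externally produced trees can be read with `read_newick_lines()` (supports as
internal node labels, 0–1 or percentage scale, auto-detected). The
self-contained estimation path is distance-based: `logdet_distance()`
implements the logdet/paralinear distance
$d = -\tfrac14\left(\ln\det(F/n) - \tfrac12 \sum_i \ln(f_i g_i)\right)$
with pairwise deletion of gapped/ambiguous sites; saturated pairs (singular
divergence matrix) are capped at a large configurable distance with a
warning. `nj_tree()` wraps neighbor joining with negative branch lengths
clamped to zero, and `bootstrap_support()` resamples alignment columns,
re-estimates, and attaches to each internal edge of the point tree the
fraction of replicates displaying its bipartition. `contract_low_support()`
collapses edges with support strictly below the threshold — an edge at
exactly 0.75 survives a 75% threshold — and returns a topology (branch
lengths are dropped, as every downstream consumer of contracted trees is
topology-only). `point_estimates()` summarizes a tree sample by majority
consensus or by its modal topology (ties by first occurrence).

## Statistics

`wilcoxon_signed_rank()` is the paired two-sided test used for method
comparisons. Zero differences are dropped before ranking (the common
convention; the choice is recorded here because alternatives exist). With 12
or fewer non-zero differences the null is enumerated exactly over all $2^n$
sign patterns (midranks make this correct under ties); beyond that a normal
approximation with tie and continuity corrections is used. Two-sided
p-values were chosen because the direction of a method difference is not
known in advance. `bonferroni()` multiplies by the number of comparisons
performed in the invoked report (`compare_methods()` uses the number of
requested pairs) and caps at 1.

## Orchestration

`run_experiment()` maps (dataset × method) to FN-rate records and returns a
tidy tibble; a method that cannot run on a dataset (e.g. dup-loss on an
unresolved point estimate) produces a row with `NA` and a note rather than
aborting the sweep. Dataset $i$ uses seed `config$seed + i - 1`, and method
runs derive their seeds from it, so a table is byte-reproducible from its
configuration. `compare_methods()` and the plot helpers (`plot_fn_rates()`,
`plot_fn_by_genes()`) operate on the table; `tidy()`/`glance()` summarize
search fits.

## Numerical and design choices, in one place

* Support scale auto-detection: any support value > 1 switches the whole
  tree to the percentage interpretation.
* "Below threshold" contraction is strict (<); equality survives.
* Missing branch lengths are never treated as zero — operations that need
  lengths raise errors.
* Saturated logdet pairs are capped (default 10) with a warning, not NA.
* Greedy-consensus and search tie-breaks are deterministic (lexicographic /
  first-found).
* All stochastic entry points accept a seed and are reproducible from it;
  internal derived seeds stay below $2^{31}$.
* Degenerate inputs: star trees are legal everywhere except as the FN-rate
  reference (undefined denominator) and as dup/dup-loss gene trees.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes: exhaustive oracle checks on all tree pairs
with ≤ 5 taxa plus random 6-taxon instances; search optimality on 5-taxon,
3-gene instances against the enumerated 105-tree space; coalescent and
Jukes–Cantor closed-form checks at $10^4$ draws and several $10^5$ sites;
and end-to-end experiments with 8–10 taxa and 4–25 genes. These sizes are
the package's choices for its own verification; the methods themselves scale
well beyond (consensus and GLASS are polynomial; the search cost is driven
by the neighborhood size and the constrained-MDC enumeration guard).

## Known limitations

* Constrained MDC is exact but enumerative: gene trees with polytomies of
  degree ≳ 9 exceed the refinement guard.
* The hill-climbing search is a heuristic; optimality is verified only at
  small scale, as with the tools it emulates.
* One allele per species; all genes on all taxa.
* The lognormal perturbation family and the default GTR/indel parameters are
  generic choices, not fitted to a biological dataset.
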