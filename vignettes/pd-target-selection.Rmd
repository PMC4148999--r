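---
title: "Phylogenetic diversity scoring and sequencing-target selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic diversity scoring and sequencing-target selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdselect)
```

## The problem

Microbial genome-sequencing programs in the GEBA/KMG mold pick their
targets to maximize *phylogenetic diversity* (PD): given a reference 16S
rRNA tree of all cultured type strains, a fixed sequencing budget of $k$
genomes should capture as much of the tree's total branch length as
possible. Strains whose genomes are already sequenced (or registered as
ongoing projects in GOLD) contribute covered diversity but consume no
budget; strains that cannot be grown to sufficient cell mass are not
candidates at all. `pdselect` implements this selection end to end: PD
arithmetic on newick trees, greedy target selection with an exhaustive
small-instance oracle, the per-phylum bookkeeping tables used to plan such
projects, and a seeded simulator so every stage is testable at full scale
without external data.

## The PD model

For a rooted tree $T$ with branch lengths and a leaf subset $S$, the
package computes

* **rooted PD**: the sum of branch lengths over the union of root-to-leaf
  paths for all members of $S$ (Faith's PD with the root retained), and
* **unrooted PD**: the total branch length of the minimal connected
  subgraph of $T$ spanning $S$ (zero when $|S| \le 1$).

Both appear in the literature as "the overall distance on the tree".
Rooted PD is the package default: the first greedy pick is then
well-defined (every unrooted singleton has PD 0) and cumulative coverage
curves start meaningfully. For $|S| \ge 2$ the two differ only by the
length of the path from the root down to the crown ancestor of $S$, so
conclusions about large selections are insensitive to the choice. The
`pd_mode` switch exists because which convention a published 16S analysis
used is generally not recoverable from the text.

A taxon's **score** can be taken as either its leave-one-out *unique
contribution* (`unique_contribution()`, `pd_contributions()`) or its
*sequential greedy gain* (`greedy_select()`). The two orderings agree on
the first pick and diverge afterwards; the pipeline uses the greedy gain
because a target list assembled stepwise is exactly what a greedy run
produces, and on trees greedy selection is provably optimal at every step
(see below). This is a design choice of this package, not a claim about
what any particular historical list used.

## Greedy selection and its oracle

`greedy_select(tree, k, preselected, excluded, mode)` repeatedly adds the
eligible leaf with the largest marginal PD gain, breaking ties
lexicographically so runs are bit-reproducible across platforms. The
implementation keeps the covered subtree as node marks and re-evaluates
cached gains lazily: PD is submodular, so a stale cached gain is an upper
bound and only the current maximum ever needs recomputation. This makes a
1,685-target selection on an 8,029-leaf tree take on the order of a second.

Correctness is anchored by `brute_force_select()`, an exhaustive
enumerator (refusing pools over 20 leaves) that the test suite compares
against greedy cumulative PD at *every* step on hundreds of seeded random
trees. For rooted PD, plain greedy from any preselected set is optimal.
For unrooted PD a greedy run started from an empty set must be seeded: all
singletons have PD 0, so `greedy_select()` takes as its first pick an
endpoint of a maximum-distance leaf pair (found by the standard two-sweep
argument restricted to eligible leaves), after which stepwise greedy is
again optimal for every $k \ge 2$. The first unrooted step is recorded
with its true gain of 0; consequently the non-increasing-gains property
holds from the second step onward in that one case, and unconditionally
whenever the run starts from a nonempty preselected or rooted state.

Preselected (already-sequenced) taxa are *not* pruned from the tree: their
PD is counted as covered, exactly as a coverage plot of existing projects
would draw it, and pruning would distort the marginal gains of everything
nearby. Leaves with no matching record stay in the tree too — they
contribute to the total-PD denominator of every coverage fraction — but
are never eligible.

## Taxonomy ledger

`summarize_by_phylum()` rolls a strain/nomenclature record table into the
planning table used for such projects: per phylum, distinct type strains,
distinct species/subspecies names, percent synonyms, type and non-type
genome sequences, coverage, and proposed targets.

Two derived columns deserve comment:

* **Percent synonyms** is computed as
  $100\,(n_\text{species} - n_\text{type strains})/n_\text{species}$ —
  every validly published name beyond one per type strain reflects a
  recorded homotypic synonymy, new combination or coordinate-status event.
  This single formula reproduces every checkable cell of the published
  mid-2011 census (`kmg_census()`).
* **Coverage** divides type-strain genome sequences by type strains. For
  the totals row two conventions circulate: type genomes only
  (1,316/9,786 = 13.4%) and including non-type genomes
  ((1,316+74)/9,786 = 14.2%). Published totals have used the latter while
  per-phylum rows use the former, so `summarize_by_phylum()` emits both,
  labeled, and prefers neither. Similarly, the totals row percent synonyms
  recomputed from the summed counts is 16.9 after half-up rounding; a
  printed value of 16.8 can only arise from unrounded intermediate
  bookkeeping not recoverable from the counts, so the package always
  recomputes from the counts.

All percentages are carried at full precision; half-up rounding to one
decimal and comma grouping happen only in `format_phylum_summary()`.
`expand_census_records()` reverses the roll-up: it builds a synthetic
record table (synthetic strain names, real counts) whose summary
reproduces a census exactly, which is how the arithmetic is tested without
any nomenclature database export.

## The simulator

`simulate_yule_tree()` grows a rooted binary tree under a pure-birth
(Yule) process: starting from two lineages at the root, each of $m$
extant lineages splits at rate $\lambda$ (so waits are
$\mathrm{Exp}(m\lambda)$), growth stops at `n_leaves` lineages, and one
final $\mathrm{Exp}(n\lambda)$ interval is appended so the last cherry
does not have systematically zero pendant edges. Total branch length then
has expectation $(n-1)/\lambda$ and variance $(n-1)/\lambda^2$, which the
test suite checks against 50 seeded replicates at three standard errors.
A Yule tree was chosen over a coalescent because the analysis consumes
only topology and lengths and the Yule total length is analytically
checkable; no coalescent option is provided.

`assign_records()` makes the taxonomy: the tree is cut into `n_phyla`
monophyletic clades by repeatedly splitting the largest group, so
per-phylum PD summaries remain interpretable, and genome status /
growability flags are drawn independently per leaf. Default parameters
describe the study conditions the package targets: trees of 8,029 type
strains (the size of the September 2010 Living Tree Project release), 13%
of strains with a registered genome project (7% with sequence data, 6%
ongoing — the documented mid-2011 split), 33 phyla, and a 5% growth-screen
failure rate (the screening outcome is not published; 5% is a modest,
fixed choice and none of the package's conclusions are sensitive to it).
Every draw flows from the single integer `seed` through one generator
whose state is saved and restored, so simulations never perturb the
caller's RNG; record draws use a sub-seed derived from the tree seed by a
fixed affine map so the two stages are decorrelated but jointly
reproducible.

What the simulator does *not* emulate: real 16S trees have strongly
imbalanced, rate-heterogeneous shapes, zero-length edges from identical
sequences, and taxonomically clustered (not independent) sequencing
status. Passing tests on Yule data therefore demonstrate algorithmic
correctness and scalability, not that any particular coverage percentage
will be attained on a real reference tree.

## Numerical choices

* Branch lengths must be present, finite and non-negative; zero is allowed
  (identical 16S sequences produce it). Trees without lengths are rejected
  outright — defaulting to 1.0 would silently corrupt every score.
* Out-degree-1 internal nodes are collapsed on read, summing edge lengths,
  which preserves all path lengths and hence all PD values.
* Ties in greedy gains, brute-force optima, and leaf orderings resolve
  lexicographically (byte order), making every output deterministic.
* Oracle comparisons use an absolute tolerance of 1e-9 in PD units;
  outputs are serialized at 15 significant digits so re-parsing
  round-trips exactly.
* The exhaustive oracle refuses pools above 20 leaves ($\binom{20}{10}
  \approx 1.8 \times 10^5$ subsets is the practical ceiling for a test
  suite).

## Problem sizes used in the shipped checks

The test suite verifies greedy-vs-oracle equality at every step on 200+
seeded Yule trees of 5–12 leaves with random preselected sets, and runs
the full pipeline (1,000 primary targets, ~13% preselected) on twenty
8,029-leaf simulated trees, where greedy selection beat matched random
selection in every replicate observed and covered PD roughly doubles —
the qualitative behavior claimed for PD-driven target selection. The
quantitative headline of the original selection (the specific coverage
fraction of a specific proposed list on the real LTP tree) requires that
tree and that list, neither of which is redistributable here; the scaled
simulation is the substitute, and is labeled as such.

## Limitations

* No per-phylum quotas: backups are the global greedy continuation.
* No weighted or attribute-augmented PD variants, no phylogenetic entropy.
* Growability is a boolean input; actual culture-condition screening is
  manual and out of scope.
* Taxon joining is exact string matching after whitespace trimming — no
  fuzzy nomenclature reconciliation.
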