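---
title: "Exhaustive pathway enumeration in bipartite metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive pathway enumeration in bipartite metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metenum)
```

## The model

A metabolic network is represented as a directed bipartite graph $G(M, R, E)$:
metabolite nodes $M$, reaction nodes $R$, and directed edges from each
reactant metabolite into its reaction node and from the reaction node out to
each product metabolite. The bipartite form matters: a reaction fires only
when *all* of its substrates are available, which substrate graphs (where
metabolites connect directly to metabolites) cannot express — they allow
notorious artefacts such as a two-step glucose-to-pyruvate "pathway" running
through a shared cofactor. Reversible reactions become two reaction nodes
(the reverse half gets the `_rev` suffix and swapped sides), so each node has
a single direction.

Three inputs drive everything: a *seed set* $S$ of metabolites assumed freely
and inexhaustibly available (the source molecules plus cofactors, coenzymes
and currency metabolites — high-degree currency species are handled by
seeding them, not by deleting nodes); a set of *target* metabolites; and a
size cut-off $\beta$.

A *pathway* (or sub-network) producing $m$ is a set $R'$ of reactions such
that $m$ is an output of at least one member and every input of every member
is producible from $S$; its *size* is $|R'|$. A pathway is *cyclic* when a
metabolite it produces participates, through member reactions, in its own
production. The goal is to enumerate, exhaustively, every such set of size at
most $\beta$.

The method is purely topological: stoichiometric coefficients, flux bounds
and thermodynamics are read past. This is a deliberate trade — it makes the
method applicable to draft reconstructions that constraint-based analyses
cannot use, at the price of admitting pathways that a stoichiometric or
thermodynamic filter would reject (see Limitations).

## Phase 1: guided breadth-first scope

`guided_bfs()` computes the *scope* $M_s \supseteq S$: every metabolite
producible from the seeds. The traversal is a BFS guided by precursor
availability — a reaction is enqueued only once all of its inputs are in
scope. A reaction examined while still missing a precursor is marked *stuck*;
each metabolite keeps the list of reactions waiting on it and decrements
their missing-precursor counters as it enters scope, so a stuck reaction is
triggered automatically the moment its last precursor appears, and total work
is $O(|E|)$. At the fixpoint no reaction outside the visited set $R_v$ has
all inputs in scope (the naive "fire everything fireable until nothing
changes" loop provably computes the same sets, and the test suite asserts
exactly that equality).

Step counts are shortest distances in graph *edges* from the seed frontier:
seeds sit at 0, a reaction fires at $1 + \max$ of its input levels (so
reaction levels are odd), a non-seed metabolite at $1 + \min$ over its
visited producers. Firing reactions in level order makes the counts
deterministic and independent of adjacency ordering. These counts are *not*
reaction counts; they are used only to prune the enumeration (below).

## Phase 2: dynamic programme over integer partitions

`enumerate_pathways()` fills a table with one row per scoped metabolite and
one column per size: `Table[m][k]` is the set of all complete pathways of
size exactly $k$ producing $m$, with an explicit bottom sentinel for "no
such pathway". Column 0 holds the empty pathway for seeds only; column 1 the
single reactions whose inputs are all seeds.

For columns $k \ge 2$, every visited reaction $r$ with inputs
$m_1, \dots, m_n$ is combined over ordered integer partitions
$(p_1, \dots, p_n)$: $p_i$ is the size of the sub-pathway chosen for input
$i$, drawn only from columns where `Table[m_i][p_i]` is non-bottom
(partition feasibility is the main combinatorial control), with
$p_i \le k - 1$ and $k - 1 \le \sum p_i \le n(k - 1)$. The upper sum range
is not an optimisation but a correctness requirement: merging is *set
union*, so sub-pathways that share reactions collapse — the classic case is
a single reaction $r'$ producing both inputs of $r$, where the $(1, 1)$
partition yields $\{r', r\}$ of size 2, not 3. Each merged set is stored at
the column equal to its actual cardinality; every cell deduplicates by the
sorted reaction-id tuple, which is also why cyclic pathways are reported
exactly once.

### Sweep schedule and cyclic closure

Writes can land in columns above the current $k$ (up to $n(k-1)+1$); those
overflow cells are retained in the object but excluded from queries beyond
the requested $\beta$. Writes can also land *below* $k$ when a union
collapses, and — the subtle case — a cyclic pathway's sub-derivation can be
recorded only after the plain column sweep has passed the column that needs
it. A concrete three-reaction example: `r1: A→B`, `r2: B→A`, `r3: C→A` with
seed `C`. The set `{r1, r2, r3}` produces `B` with three reactions, but its
derivation unfolds `B ← A ← B ← A ← C`, so the sub-pathway of `A` needed at
column 3 has size 3 itself and only exists after column 3 has been swept.
The implementation therefore sweeps $k = 2 \dots \beta + 1$ and repeats the
sweep until no new entry appears at any column $\le \beta$. This closure is
exhaustive: a sub-pathway of a size-$s$ pathway is a subset of it, hence
never larger than $\beta$, so partition values up to $\beta$ (available at
$k = \beta + 1$) suffice, and the repeated sweep is a monotone iteration on
a finite lattice. Repeat passes are cheap in practice — cells deduplicate,
so a pass that discovers nothing new does no writes and terminates the loop.

### The independent reference enumerator

`derive_pathways()` re-derives the same objects with none of this machinery:
it applies the derivation rule ("a derivation of $m$ is $\varnothing$ if $m$
is a seed, or the union of one derivation per input of a producing reaction
$r$, plus $r$") bottom-up to all metabolites until the family of derivable
sets stops growing, discarding intermediate sets larger than $\beta$.
Iterating to the fixpoint rather than recursing to a fixed depth is
essential for exactly the cyclic case above: unfolding a size-$s$ cyclic
pathway can revisit a reaction, so its derivation depth can exceed $s$. The
test suite asserts set-for-set equality between the dynamic programme and
this reference on hundreds of random networks; that equivalence, not any
property of the sweep schedule, is the package's correctness surface.

## Tunable parameters

* `beta` (integer, no default): the pathway size cut-off, in reactions.
  Governs everything; enumeration cost is worst-case exponential in it.
  Values of 10–30 are typical for genome-scale work (compartmentalised
  models need the higher end because transport steps inflate sizes).
* `prune` (default `TRUE`): skip reaction $r$ at column $k$ when
  $\lceil \ell_r / 2 \rceil > k$, i.e. when the minimum number of reaction
  layers needed to fire $r$ exceeds the size budget — a pathway containing
  $r$ must contain a distinct reaction per firing layer, so none of size
  $\le k$ exists. Output-neutral by construction and by test (tables with
  pruning on and off are compared cell by cell).
* `max_pathways` (default $10^7$): hard cap on stored pathway entries.
  Exhaustive enumeration can explode; the package fails loudly, naming the
  offending cell, rather than thrash.
* `exchange_prefix` (default `"EX_"`) and `extracellular_suffix` (default
  `"_e$"`): model conventions for recognising exchange reactions and
  extracellular species. Model collections differ here and no standard
  exists, so both are explicit arguments rather than hard-coded.

## Community graphs

`build_community_graph()` joins two or more organism models through a common
extracellular medium: every non-shared node id is prefixed with its organism
label (`org1:`…), and an extracellular metabolite occurring in the exchange
reactions of at least two organisms is merged into a single shared, untagged
node. Exchange metabolites unique to one organism stay attached only to that
organism's boundary. Organism prefixes are what keep two copies of the same
strain (the typical knockout-pair design) from colliding in one namespace.
Non-extracellular compartments (periplasm included) are deliberately kept
per-organism: merging rules for them are not standardised, and sharing only
the extracellular space is the conservative reading of how community models
are usually assembled.

`find_exchanges()` then scans enumerated pathways that span at least two
organism tags for shared extracellular metabolites produced by one
organism's reactions and consumed by another's. The optional
`check_load_bearing` flag re-runs the completeness check on the recipient's
portion of each witnessing pathway with and without the exchanged metabolite
seeded, keeping only exchanges the recipient genuinely depends on; it is off
by default because it costs one scope computation per report.

## Pathway analytics

Similarity between pathways is the Jaccard index of their reaction sets,
with $J(\varnothing, \varnothing) = 1$. `similarity_spectrum()` scores all
$\binom{N}{2}$ unordered pairs, streaming blocks of a sparse
pathway-by-reaction incidence matrix so no $N \times N$ matrix is ever
materialised. Default bins are closed-open $[lo, hi)$ with the final bin
closed; `closed = "both"` gives endpoint-inclusive bins for reproducing
published interval counts, whose convention is typically unstated.
`most_different_pair()` minimises the Jaccard index with deterministic
tie-breaking (smallest combined size, then lexicographic ids).

## Numerical and determinism choices

* Pathway identity is the sorted tuple of reaction ids; cells are keyed on
  it, so set-union semantics and $O(1)$ dedup come for free.
* All node iteration is in lexicographic id order and every query output is
  sorted (size, then id tuple). Tests assert that permuting model row order
  and adjacency-list order changes no result byte.
* Both halves of a reversible pair may co-occur in one pathway — they are
  distinct nodes, and excluding them would silently change counts. Such
  pathways carry a `contains_reversible_pair` flag so users can filter.
* A degenerate reaction with no inputs (a pure boundary inflow) fires
  unconditionally and can only ever form the singleton pathway of size 1.
* Knockouts evaluate the GPR rule with the listed genes false and all
  others true; metabolites orphaned by a knockout stay in the graph as
  inert nodes, keeping table indexing stable.

## The toy-network generator

`toy_network()` produces the fixtures the test suite runs on: structured
kinds (chain, parallel routes, branched join, cycle, cross-feeding pair)
whose exact pathway inventories are known by construction, and a `random`
kind built connected-by-construction — each new reaction consumes an
already-producible metabolite with probability 0.7, otherwise a fresh
orphan precursor, so both the visited and the stuck/triggered branches of
the guided BFS are exercised. Random ground truth comes from the reference
enumerator, which is why that kind is capped at 12 reactions. Generation is
a pure function of its arguments.

What the generator emulates is network *topology* at small scale: branching,
convergence, cycles, reversibility, orphan precursors, cross-feeding through
a shared extracellular node. What it does not emulate: realistic degree
distributions (genome-scale networks have heavy-tailed metabolite degrees),
stoichiometry, compartment structure beyond one extracellular space, or
model-curation artefacts (duplicate transporters, lumped reactions). Passing
tests therefore certify the algorithms' correctness on the combinatorial
structures that make enumeration hard, not the biological plausibility of
any particular genome-scale result — on real models the output is only as
good as the reconstruction.

The suite's problem sizes — random networks up to 10–12 reactions, $\beta
\le 6$, a few hundred seeded instances for the oracle-equivalence and
monotonicity properties — were chosen so the naive reference enumerator
(exponential by design) stays comfortably tractable while still covering
cycles, reversible pairs and stuck-reaction triggering.

## Limitations

* Output size is the real constraint: the number of pathways grows
  exponentially with $\beta$ on genome-scale models, and the memory guard
  exists because no algorithmic cleverness changes what "exhaustive" means.
* Topology-only semantics admit pathways that are stoichiometrically or
  thermodynamically infeasible; results are hypotheses to be filtered by
  elementary-mode or constraint-based follow-up, not predictions.
* Predicted community exchanges inherit every artefact of the member
  reconstructions; gap-filled or promiscuous exchange reactions produce
  spurious cross-feeding candidates.
* The SBML reader covers species/reactions/reversibility/compartments and
  fbc gene-product associations — the subset a topological method needs.
  Legacy note-embedded gene associations are not parsed.
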