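---
title: "Parsimony, stratigraphic congruence, and ancestral areas: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony, stratigraphic congruence, and ancestral areas: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the models and procedures, the assumptions they carry, the numerical and
design choices that were genuinely open, and what the test suite does and
does not establish.

## 1. The data model

A `morph_matrix` holds taxa scored for unordered discrete characters with
states 0–9. Each cell is one of three things: an observed state set (a
singleton for ordinary scorings; the polymorphism {0,1}, written `a` in the
file formats, is the only multi-state observation the published matrices
use), a missing entry (`?`), or an inapplicable entry (`-`). Missing and
inapplicable cells are kept distinct — they round-trip through the TNT and
NEXUS writers unchanged — but both behave as "any state" in parsimony
scoring. We deliberately do not implement reductive or hierarchical coding
for inapplicable characters: the matrices this package targets were scored
and analysed under the plain "any state" convention, and silently changing
the optimality criterion would change every downstream number.

Only `a` = {0,1} is accepted as a polymorphism code. Any other letter in a
matrix is a parse error naming the symbol and its position, on the view
that guessing an undocumented code is worse than failing loudly.

## 2. Parsimony scoring

Tree length is the minimum number of state changes, summed over characters,
under equal (unit) costs — Fitch counting, generalised to arbitrary
multifurcations as uniform-cost dynamic programming. For each node the cost
vector over states satisfies

    cost_v(s) = sum over children c of min( cost_c(s), min_t cost_c(t) + 1 )

which is the Sankoff recursion specialised to unit costs; it costs O(k) per
child rather than O(k^2). Two implementation facts matter:

* **A common state space is exact.** Under unit costs an optimal labelling
  never uses a state absent from the character's observed cells (replacing
  any maximal region of an unobserved state with a neighbouring region's
  state strictly reduces the change count). All characters therefore share
  one k = 10 state space in the compiled scorer, which keeps the inner loop
  branch-free; most-parsimonious-reconstruction (MPR) sets automatically
  exclude unobserved states.
* **The scorer is compiled.** The per-tree scorer (`src/sankoff.cpp`) takes
  an edge list with arbitrary node ids, roots itself anywhere (the score is
  root-invariant), and is the only performance-critical code; everything
  above it — MPR sets, uppass costs, collapse decisions — is vectorised R,
  because those paths run once per reported tree, not once per candidate
  neighbour.

Per-character step floors and ceilings feed the ensemble indices. The
ceiling is the star-tree length (scorable cells minus the largest count any
single state can reach, with polymorphic cells free to join the majority).
The floor is the number of states the character is *forced* to exhibit
minus one: a state present only in {0,1} polymorphic cells adds nothing,
since such cells may side with an existing state. (The naive "observed
states minus one" floor can exceed the true minimum and would break the
invariant `min <= length` that the index algebra relies on.) Because
published CI/RI values sometimes exclude parsimony-uninformative
characters and sometimes do not, `fitch_length()` reports both variants;
a character is uninformative exactly when its floor equals its ceiling.

## 3. Tree search

Search operates on unrooted binary trees held as plain edge matrices; trees
are reported rooted on a designated outgroup (by default the first matrix
taxon, by the convention that matrices list the most distant outgroup
first).

* **Starting trees** come from random stepwise addition: each taxon, in
  seeded random order, is inserted at the placement minimising total length,
  ties broken uniformly at random.
* **Branch swapping** is full TBR: every branch is bisected; the clipped
  fragment is rerooted along each of its branches and reattached along each
  branch of the other fragment. Strictly shorter neighbours are accepted
  immediately; equal-length, topologically distinct trees are collected up
  to a cap; the climb ends when every saved tree has had its whole
  neighbourhood examined. At four taxa the neighbourhood plus the tree
  itself covers all three topologies, and on every random matrix with seven
  or fewer taxa the suite verifies the heuristic's optimum against
  exhaustive enumeration.
* **Collapsing** contracts each internal branch whose minimum length over
  all most-parsimonious reconstructions is zero (computed per character
  from downpass/uppass costs, verified against brute-force enumeration of
  optimal labellings). One subtlety is inherent to this rule: branches are
  individually collapsible under *different* reconstructions, so the
  multifurcating tree obtained by contracting them all can rescore longer
  than its binary source. Length bookkeeping therefore always refers to the
  binary trees; the collapsed trees define topological distinctness.
* **Constraints** (enforce or forbid the monophyly of a taxon set) restrict
  both stepwise addition and swapping; Bremer supports are computed by
  forbid-searches started from the optimal trees pushed off each consensus
  clade, and equal exhaustive decay indices on every small random instance
  tested.
* **Bootstrap** resamples characters with replacement as integer weights
  (the scorer takes a weight vector, so no matrix is materialised), runs a
  reduced search per pseudoreplicate, and reports each clade's frequency
  among pseudoreplicate strict consensus trees. A clade supported by a
  single character cannot exceed ~63% expected support (the character is
  absent from a bootstrap sample with probability (1-1/n)^n); the "perfect
  matrix" test therefore replicates each clade's character eight-fold.
* **Determinism.** Every stochastic choice flows from the config seed
  through one RNG stream (plus derived child seeds for bootstrap
  pseudoreplicates), so identical configs give byte-identical results; the
  suite asserts this.

Default problem sizes: the `"desk"` preset (50 replicates, hold 500) is for
interactive use and testing; the `"paper"` preset (10,000 replicates,
10,000 trees held) matches the published protocol and is only sensible on
the real 65 x 255 matrix.

## 4. Time calibration and stratigraphic congruence

Calibration is minimum-age: each leaf takes an endpoint of its
first-appearance interval, each node the maximum of its children's ages, so
every implied gap is as short as the topology allows; branch "ghosts" are
the age differences along branches and MIG is their sum. No positive
padding is added between nodes — zero-length ghosts are legitimate (a taxon
as old as its divergence).

GER and MSM\* need the extremal MIG over all rooted binary topologies on
the same ages. We derived closed forms and certified them against
exhaustive enumeration (a subset dynamic programme that minimises and
maximises over all (2n-3)!! topologies exactly, available as
`g_bounds(method = "exhaustive")` up to n = 8):

* `Gmin = oldest - youngest`: attained by the pectinate tree with taxa
  nested oldest-first, where every gap telescopes along a single root path;
  no tree can do better because the youngest taxon's root path alone
  accumulates that much gap.
* `Gmax = sum(oldest - age_i)`: attained by a pectinate tree carrying the
  oldest taxon at its innermost position, so every other taxon hangs from a
  root-age node; no tree can do worse because summing gaps over root-to-leaf
  paths counts every branch at least once.

One consequence worth stating: a *perfectly congruent* tree still has
MIG = Gmin, not zero, whenever ages differ — congruence shows up as
GER = MSM\* = 1, never as a vanishing MIG.

Uncertainty is reported as ranges, not point values. Polytomies: every
binary resolution is enumerated when the count (product of (2d-3)!! over
polytomies) is at most a cap, otherwise uniform seeded samples are drawn
(by random leaf insertion, which is exactly uniform) and the result is
flagged as sampling-based. Age intervals: endpoint combinations are
enumerated exhaustively up to 12 uncertain taxa, otherwise a seeded
coordinate search (flip one taxon's endpoint while it improves, several
restarts) bounds each metric; the enumerated trichotomy test pins the
implementation to the exact three-resolution range. Because metric
evaluation sits inside this cross product, each resolution's traversal is
precompiled into a closure that evaluates one age assignment in
microseconds.

## 5. Ancestral areas

The geographic character has one state per taxon from a six-continent
universe (no Antarctic taxa). Three analyses share one fixed topology, the
strict consensus, with its polytomies analysed as hard multifurcations —
resolving them would manufacture resolution the character data did not
support:

* **PB** (parsimony): each node's vector is uniform over its MPR state set,
  the convention behind equivocal pie-chart nodes.
* **LEB** (likelihood, every branch length 1) and **LFR** (likelihood,
  branch length = ghost duration in myr, zeros replaced by 1): the
  single-rate symmetric Mk model, i.e. Mesquite's one-parameter default,
  with transition probability `1/k + (k-1)/k exp(-k a t)` on the diagonal.
  The rate is estimated by bounded 1-D maximisation on a log scale
  (tolerance 1e-10, bracket 1e-8 to 1e3) and re-optimised per
  branch-length scheme, since the two schemes define different time
  scales. Node supports are marginal posteriors via the inside–outside
  pass, equal to brute-force conditional sums at 1e-10 in the suite.
* **Root prior:** flat (1/k). Mesquite's alternative conventions exist, but
  flat is both its shipped default and the only choice that keeps the
  label-equivariance property the suite asserts (permuting area labels
  permutes reconstructions exactly). `marginal_areas()` accepts any prior
  through its `model` argument, so the sensitivity is one line to check.

## 6. The simulator: what it emulates, and what it does not

`simulate_dataset()` generates everything the pipeline consumes with known
truth: a Yule tree (pure birth; the process stops at `n_taxa` lineages plus
a memoryless grace period, so waiting times are exactly exponential — the
suite checks the distributional identity), Mk-evolved characters with
cell-wise missing/inapplicable/{0,1}-polymorphic degradation, true first
appearances drawn uniformly along terminal branches with symmetric interval
noise truncated at zero, and an Mk-evolved geographic character.

Defaults mirror the published study's scale: 65 taxa, 255 characters, up to
4 states, ~30% missing cells, 1% polymorphic, 2% inapplicable, a birth rate
of 0.025 per lineage per myr (root on the order of 170 Ma for 65 taxa,
matching a Triassic origin), character rate 0.002 per myr, area rate 0.001
per myr (dispersal is rare), and ±2.5 myr age uncertainty (stage-level
precision). Tests and the acceptance script run scaled-down versions of
these conditions — 8–16 taxa, 25–100 characters, 3–5 search replicates, 10
recovery seeds, 100–200 Mk fit replicates — chosen so the whole suite runs
in minutes on one core; the vignette states these sizes as the package's
own test design.

What the simulator does **not** emulate: block-structured missingness
(whole anatomical regions absent per taxon — real matrices are worse than
cell-wise i.i.d. missingness), correlated character evolution,
ascertainment bias (real matrices contain only variable characters),
extinction (a birth–death fossil record), and polymorphism that reflects
true intraspecific variation rather than scoring uncertainty. Passing
recovery tests therefore demonstrates correctness of the machinery under a
clean generative model, not expected performance on real matrices.

Two recovery facts established while fixing the test design, recorded here
because they bound what the package can promise:

* **Topology recovery has a statistical ceiling.** At the "strong signal"
  setting (rate x depth = 0.3 per character, 100 characters, 16 taxa,
  no degradation), mean recovery of true splits by the strict consensus is
  about 0.75–0.87, not higher. The cause is not the search — on every
  small instance the heuristic matches exhaustive enumeration, and on
  these simulations it routinely finds trees at or below the true tree's
  length — but the data: a Yule tree always contains some internal
  branches short enough that the expected number of character changes on
  them is far below one, and no method can recover a split that no
  character records. More characters, not more search effort, is the only
  remedy.
* **Rate recovery depends on the time scale.** Estimating the Mk rate
  0.05 within 25% median error on a 64-leaf tree holds under unit branch
  lengths (~31 expected events per tree); on strongly rescaled trees the
  Fisher information collapses or the process saturates. The acceptance
  experiment states the unit-length condition explicitly.

## 7. Degenerate inputs and numerical conventions

* GER is undefined (NA, not NaN-by-accident) when all ages are equal;
  MSM\* when MIG = 0. Both cases are tested.
* Characters that are entirely missing/inapplicable, or constant,
  contribute zeros to lengths and both bounds and are never dropped, so
  CI/RI denominators stay well defined across matrices.
* Monomorphic area data make the Mk rate unidentifiable; `fit_mk()` refuses
  with a pointer to parsimony rather than returning a boundary estimate.
* Branch lengths for likelihood must be strictly positive; the ghost
  scheme's zero-to-one replacement guarantees this by construction.
* Ages are Ma before present (larger = older), ghosts in myr, reported to
  0.1 myr; area supports are percentages to 0.1.
* Tie-breaking anywhere (equal-length insertions, equal TBR neighbours,
  duplicate filtering order) is by seeded uniform choice; no ordering
  depends on hash or address.

## 8. Known limitations

Ordered, Dollo, or weighted characters and implied weighting are out of
scope (the target analyses run all characters unordered and unweighted), as
are ratchet/sectorial "new technology" searches, GER\*, maximum-agreement
subtrees, and model-based biogeography (DEC, stochastic mapping). The
published study's own numbers (tree length 868, CI 0.37, the 50.7%/81.1%
node supports, the +7/+9 constraint costs) are reproducible only with its
supplementary data files, which cannot ship with the package; the
acceptance tests encode those checks and fail cleanly at the data-loading
step until the files are installed (see `?study_data_paths`).
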