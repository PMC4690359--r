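# stratphylo

Maximum-parsimony phylogenetics, stratigraphic congruence, and ancestral-area
reconstruction for discrete morphological matrices of fossil taxa — the
complete workflow used in modern analyses of ornithischian dinosaur
relationships, as one reproducible R pipeline.

## Who this is for

Palaeontologists and systematists who score fossil taxa for discrete
morphological characters and want, from a single matrix plus two small
tables (first-appearance ages and geographic areas):

1. **Tree inference** — heuristic maximum-parsimony search: random stepwise
   addition, tree-bisection-reconnection (TBR) branch swapping, collapsing of
   branches whose minimum length is zero, strict and majority-rule consensus,
   Bremer (decay) and nonparametric bootstrap supports, constrained searches
   for hypothesis tests, and the list of unambiguously optimised character
   changes.
2. **Stratigraphic congruence** — minimum-age time calibration with ghost
   lineages, and the congruence metrics MIG, GER, and MSM\* reported as
   ranges over all binary resolutions of consensus polytomies and over the
   endpoints of each taxon's first-appearance age interval.
3. **Historical biogeography** — ancestral-area reconstruction on the fixed
   consensus under parsimony (PB), and under a single-rate symmetric Mk
   likelihood model with unit branch lengths (LEB) or ghost-lineage branch
   lengths (LFR).

## The core quantities

For a character with observed length `s_i` on the tree, minimum conceivable
steps `m_i`, and star-tree (maximum) steps `g_i`, the ensemble indices are

    CI  = sum(m_i) / sum(s_i)
    RI  = (sum(g_i) - sum(s_i)) / (sum(g_i) - sum(m_i))
    RCI = CI * RI

With leaf ages fixed at first appearances and every node dated by its oldest
descendant, each branch's ghost lineage is the age difference between its
ends; summing over branches gives the minimum implied gap (MIG, in myr).
With `Gmin` and `Gmax` the extremal MIG over all rooted binary topologies on
the same ages,

    GER  = (Gmax - MIG) / (Gmax - Gmin)        MSM* = Gmin / MIG

The Mk model used for likelihood area tracing is the symmetric k-state
Markov process with transition probabilities
`P(i -> i, t) = 1/k + (k-1)/k exp(-k a t)` and
`P(i -> j, t) = (1 - exp(-k a t))/k`, with the single rate `a` estimated by
maximum likelihood and a flat root prior; node supports are marginal
posteriors computed by the inside–outside two-pass.

## Worked example

The package ships a simulator that generates matrices, trees, ages, and
areas with known ground truth, so the full pipeline runs without any data
files:

```r
library(stratphylo)

cfg <- sim_config(n_taxa = 12, n_characters = 60, alpha_char = 0.004,
                  alpha_area = 0.02, missing_frac = 0.2, seed = 2026)
sim <- simulate_dataset(cfg)
print(sim$matrix)
#> Morphological character matrix: 12 taxa x 60 characters
#>   missing 20.0%, inapplicable 1.9%, polymorphic 1.0%

res <- run_full_analysis(sim$matrix, sim$ages, sim$areas,
                         search_config(replicates = 5, seed = 1))
print(res$search)
#> Parsimony search result
#>   best length: 137
#>   most parsimonious trees (collapsed, distinct): 4
#>   replicates: 5  seed: 1

print(res$strat)
#> Stratigraphic congruence metrics (sampling-based bounds)
#>   resolutions considered: 100  uncertain-age taxa: 12
#>    metric      lo      hi
#>       mig  36.126 119.650
#>     g_min  19.873  27.546
#>     g_max 170.545 268.097
#>       ger   0.552   0.938
#>  msm_star   0.226   0.663

print(res$leb)
#> Ancestral-state reconstruction (LEB) over 6 areas
#>        South America Africa Asia North America Europe Australia   best
#> node13           5.6   21.3 40.4           5.6   17.7       9.4   Asia
#> node14           3.5    6.4 47.4           3.5    6.0      33.3   Asia
#> ...
```

Reading: the search found trees of 137 steps; four distinct topologies
survive collapsing, and their strict consensus implies between 36 and 120
myr of missing fossil record depending on how its polytomies are resolved
and which end of each age interval is used; GER between 0.55 and 0.94 says
the consensus is substantially more congruent with the fossil record than a
random topology on the same ages. The LEB table gives each internal node's
percentage support per area; the root's best area here is Asia at 40.4%.

To run the same pipeline on real data, parse a TNT or NEXUS matrix with
`parse_morph_matrix()`, the age and area tables with `read_age_table()` /
`read_area_table()`, and call `run_full_analysis()`. Reproducing the
published 65-taxon ornithischian analysis additionally requires the study's
supplementary data files, which are not redistributable with the package;
see `?study_data_paths` for where to place them.

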