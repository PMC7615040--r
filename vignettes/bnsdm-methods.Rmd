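---
title: "Ensemble SDMs with Bayesian-network biotic interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SDMs with Bayesian-network biotic interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnsdm)
```

## The problem

Correlative species distribution models (SDMs) relate occurrence records to
climate and project habitat suitability over a grid, but they ignore biotic
interactions: a herbivorous insect cannot persist where its food plants are
absent, however suitable the climate, and predator pressure depresses its
occurrence probability. `bnsdm` implements a pipeline in which the SDM
output of a focal species is treated as a *prior* per-cell occurrence
probability and modified by a Bayesian network of signed interactions with
other modelled species, before thresholding and landscape summary. The
motivating application is a savanna insect whose range is tied to a single
dominant food tree, is preyed upon by many bird species, and competes
indirectly with a large herbivore for that tree — but every stage is generic
and accepts user rasters and occurrence tables in plain formats (ESRI ASCII
grids, CSV).

## Pipeline overview

1. **Occurrence preparation** — basis-of-record whitelist (human
   observation, living specimen, machine observation), coordinate-error
   cleaning, rarefaction to one record per grid cell, and a minimum of 20
   records per species.
2. **SDM fitting** — three contrasting algorithms per species: a BIOCLIM
   style climate envelope, a logistic regression with quadratic terms, and
   a random forest; 4-fold cross-validated AUC; projection onto present and
   future climate; AUC-weighted ensemble.
3. **Network resolution** — per-cell condensation of same-role interactor
   rasters to their top-k suitabilities, sub-network chaining for indirect
   interactions, and the OR/AND three-state posterior update; per-algorithm
   posteriors are re-cross-validated and ensembled with the new weights.
4. **Landscape summary** — TSS or prevalence thresholding estimated on the
   present period, binary maps for every scenario, spherical habitat areas,
   queen-adjacency patch counts and densities, and integer percent changes
   by scenario and region.

A synthetic virtual-ecosystem module generates every input at desk scale so
each stage is testable against known truth.

## The resolution model

Per cell, let $p$ be the focal prior and $q_j \in [0,1]$ the occurrence
probabilities of its parents, split into positive and negative interactors.
Each direction fires with trigger probability

$$T_{OR} = 1 - \prod_j (1 - q_j), \qquad T_{AND} = \prod_j q_j,$$

and a direction with no parents never fires. The posterior has exactly
three states — increased, decreased, unchanged:

$$\text{post} = T^{+}(1-T^{-})\,p^{+} + (1-T^{+})T^{-}\,p^{-} +
  \left[T^{+}T^{-} + (1-T^{+})(1-T^{-})\right] p,$$

with $p^{+} = p + \alpha(1-p)$ and $p^{-} = p(1-\alpha)$. Simultaneous
positive and negative triggers cancel to "no change"; we chose this because
a three-state posterior admits no principled dominance rule between
directions, and cancellation is the only symmetric option. The product form
is the exact closed form of the $2^n$ enumeration over parent
presence/absence outcomes (`enumerate_posterior()` is kept as an
independent oracle and the equivalence is tested to $10^{-12}$), so
resolution is linear in the parent count — the naive enumeration becomes
impractical beyond roughly a dozen dependencies, which is precisely why
functional-group condensation and sub-network chaining exist.

Design choices that were genuinely open:

* **Interaction strength $\alpha$.** The magnitude of a triggered push is
  not identifiable from binary interaction signs, so it is a configuration
  parameter, default $\alpha = 0.5$ (a triggered positive effect moves the
  prior halfway to 1; a negative one halves it). The linear push keeps the
  posterior in $[0,1]$, is monotone in every $q_j$, and reduces to the
  identity at $\alpha = 0$ — all three properties are tested.
* **Empty-direction AND.** A vacuous product would make an absent direction
  "always fire"; we define $T = 0$ instead, so a species with no negative
  interactors is never pushed down by the empty set.
* **Parents are continuous ensembles.** Parent rasters enter unthresholded;
  thresholding first would discard the probabilistic information the
  trigger formulas consume. Sub-network focals (e.g. the food tree) are
  resolved per algorithm, so each algorithm's posterior chain is internally
  consistent; pure parents use their ensembled rasters.
* **Network cross-validation.** When re-scoring the resolved model, parent
  rasters are held fixed at their full-data values and only the focal SDM
  is refitted per fold, with the same fold assignment as the no-network
  branch. Refitting all parents per fold would convolve parent sampling
  noise into the comparison; holding data fixed isolates the effect of the
  network itself, and makes "edgeless network = no-network branch" an exact
  identity that the test suite asserts cell-wise.

## SDM algorithms

* **Climate envelope.** For each variable the training values at presence
  cells are stored; a cell scores $2\min(F, 1-F)$ per variable, where $F$
  is the mid-rank fraction $(\#\{<x\} + \tfrac12\#\{=x\})/n$, and the cell
  score is the minimum over variables (values outside the training range
  score 0). This ranks cells by niche centrality; it needs no background
  and is the weakest but most transparent member of the ensemble.
* **Logistic regression.** Presence vs background on the six variables,
  standardised to training mean/sd, with linear *and quadratic* terms so
  unimodal climate responses are expressible. On non-convergence or
  exploding coefficients (separation) the model is refitted with a small
  ridge penalty and a warning.
* **Random forest.** 500 trees, $\lfloor\sqrt{6}\rfloor = 2$ split
  candidates per node, seeded; suitability is the fraction of trees voting
  presence.

Background points are drawn uniformly without replacement over non-masked
cells, excluding presence cells, with count
$\min(10\,000,\ 10 \times n_{\text{presences}},\ n_{\text{available}})$ —
a common presence-background convention; the scheme is configurable because
no single choice is canonical. AUC is the rank-based (Mann–Whitney)
statistic, ties counted one half, so it is invariant under monotone
transforms of the scores. Cross-validation partitions presences and
background independently (stratified by class) into $k = 4$ seeded folds.

## Thresholding and landscape metrics

The maximum-TSS threshold (sensitivity + specificity − 1, scanned over all
unique evaluation scores, ties to the smallest candidate) converts
suitability to presence/absence; a prevalence-matching threshold is
computed alongside to display threshold uncertainty. Both are estimated on
the present-period model and reused unchanged for future projections —
re-estimating on a future scenario would require future occurrences, which
do not exist. Whether the prevalence rule is more or less restrictive than
TSS depends on the presence:background ratio of the evaluation points; with
the 1:10 ratio used here it can fall on either side, so the nesting of the
two binary maps is asserted only conditionally on the threshold order.

Cell areas use the exact spherical quadrangle formula
$R^2\,\Delta\lambda\,(\sin\varphi_t - \sin\varphi_b)$ with $R = 6371$ km (a
2-arcmin cell on the equator is ≈ 13.74 km²); habitat area is the sum over
present cells in thousands of km². Patches are connected components under
queen (8-neighbour) adjacency — the landscape-ecology default, configurable
to rook — computed via the adjacency graph's components and verified
against a brute-force flood fill. Patch density divides the patch count by
the *suitable-habitat* area per 1000 km² (the study-area denominator is
available in config). Percent change is
$100(\text{after}-\text{before})/\text{before}$ rounded half away from zero
to a signed integer, matching the reporting convention of habitat-change
tables.

## The virtual ecosystem

The generator replaces real climatologies and aggregator occurrence
downloads with closed-form stand-ins:

* **Climate** — seeded white noise smoothed by a separable Gaussian kernel
  (range in cells), rescaled to plausible savanna values (mean annual
  temperature ~22 °C ± 4, annual rainfall ~450 mm ± 250, truncated at 0).
  The temperature ordering (max warmest ≥ annual mean ≥ min coldest) is
  enforced constructively — the extremes are the mean plus/minus strictly
  positive offsets — so the invariant holds by construction rather than by
  rejection. Wettest-month and driest-month rainfall are non-overlapping
  shares of the annual total. Future grids shift temperatures additively
  and scale rainfall multiplicatively.
* **Species** — axis-aligned Gaussian niches
  $s(x) = p_{\max}\exp(-\tfrac12\sum_v ((x_v-\mu_v)/\sigma_v)^2)$, chosen
  for closed-form truth: parameter-recovery tests compare envelope training
  quantiles against the known niche.
* **Occurrences** — presence cells drawn with probability proportional to
  true suitability (with replacement, so rarefaction has duplicates to
  remove), jittered uniformly within the cell to mimic coordinate
  imprecision. A contamination spec injects exact counts of each error
  class: plain zeros, equal lon/lat (drawn off-grid, as with real
  transposed coordinates), points within 1° of a gazetteer institution,
  and at-sea points from the land mask.

What the generator does **not** emulate: spatial sampling bias, taxonomic
misidentification, temporal turnover, dispersal limitation, occurrence
clustering beyond the niche, and real covariance structure between
bioclimatic variables. Passing tests therefore demonstrate correctness of
the machinery and calibration under idealised sampling, not predictive
skill on real data.

## The bundled demonstration

`demo_config()` defines a 20 × 20 grid of 0.25° cells (a 5° × 5° window —
large enough that a 1° institution buffer removes some records without
swallowing the study region), five species (focal insect, food tree,
competitor, two predators condensed to top-2 groups), two future scenarios
(+1.8 °C / −10 % rain and +3.7 °C / −20 % rain, moderate and severe
warming), niche optima ~1 °C below the present temperature mean so warming
contracts habitat, and 150–180 occurrence draws per species so every
species clears the 20-record minimum after cleaning and rarefaction. The
interaction network is

```
elephant   -(-)-> food_tree      (sub-network, resolved first)
food_tree  -(+)-> focal_moth
pred_group_1/2 -(-)-> focal_moth (per-cell top-2 of the predator ensembles)
```

These sizes keep a full pipeline run under ten seconds on one CPU while
exercising every stage, including the sub-network chain and the
functional-group condensation; the test suite and the acceptance script
both run the same configuration.

```{r, eval = FALSE}
art <- run_all(demo_config(), seed = 1, out_dir = "results/run")
art$landscape$network$report
```

## Numerical conventions

* Every generator and fitter is a pure function of (seed, parameters);
  sub-seeds are derived per stage and species from one master seed, and
  RNG state is saved and restored so library calls never perturb the
  caller's stream.
* Exact-match cleaning tests (capitals, zeros, equal lon/lat) compare at
  full stored precision, no tolerance; the institution buffer is a plain
  Euclidean test in degree space, matching the "one degree around"
  convention of coordinate-cleaning tools.
* Rarefaction keeps the first record per cell in input order — a
  deterministic tie-break with no hidden randomness.
* The ≥20-record rule is applied *after* cleaning and rarefaction, because
  model fitting consumes cleaned, rarefied data; applying it before would
  admit species whose effective sample is smaller than the minimum.
* Threshold scans break ties toward the smallest candidate threshold
  (the least restrictive map among the optima).
* Ensemble weights are the raw mean fold AUCs, not rescaled above 0.5; a
  no-skill algorithm still enters with weight ≈ 0.5, which slightly
  shrinks the ensemble toward the mean — rescaling is a one-line config
  change if sharper weighting is wanted.

## Known limitations

* Interaction strength is a single global $\alpha$; per-edge strengths
  would need data that binary interaction signs cannot provide.
* The SUM-style multi-state resolution (stronger effect with more
  co-occurring dependencies) is not implemented; the three-state model
  cancels opposing triggers instead of weighing them.
* Cross-validation is random, not spatially blocked, so AUC is optimistic
  under strong spatial autocorrelation.
* The envelope algorithm scores niche centrality, which caps its CV AUC on
  suitability-proportional samples: held-out edge presences score like
  background by construction.
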