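---
title: "Decomposing gene-tree discordance: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing gene-tree discordance: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodiscord)
```

## The problem

Across a species tree, individual loci often support conflicting
genealogies. Three processes dominate that heterogeneity: incomplete
lineage sorting (ILS, the retention of ancestral polymorphism through
short internal branches), gene-tree estimation error, and introgression
(gene flow between non-sister lineages). `phylodiscord` simulates
multilocus data in which the contribution of each process is known, and
provides the per-branch statistics used to tell them apart in waterfowl
and other radiations: gene concordance factors (gCF), quartet
frequencies, coalescent-unit branch lengths, the theta ratio, a
simulate-and-reestimate error measure (BP), ABBA-BABA D with a block
jackknife, a reticulation index, a windowed V0--V3 genealogy scan, and
an LMG relative-importance regression that partitions per-node
discordance among the three factors.

## The simulation model

The generator is the multispecies coalescent on a rooted, binary,
ultrametric species tree whose branch lengths are **coalescent units**
(time divided by 2N generations, increasing root-ward). Within a branch,
`k` gene lineages coalesce at rate `k(k-1)/2` per unit; uncoalesced
lineages enter the parent branch; the root branch is unbounded.
Introgression is a **pulse**: at one time point, each lineage on the
recipient branch independently relocates to the donor branch with
probability `gamma`. This matches the discrete-event framing of
ABBA-BABA and hidden-Markov genealogy analyses; continuous migration is
out of scope.

Mutation-unit lengths are obtained by multiplying coalescent durations by
a **scale** `s` (substitutions/site per coalescent unit; `s = 2N u` up to
constants, a population-mutation-rate proxy). The default `s = 0.01`
gives, e.g., about 4% sister-pair divergence at a 2-coalescent-unit
depth, a realistic magnitude for the bird genomes this emulates. Scales
may vary per branch, emulating lineage-specific effective population
sizes; the lineage-path integral of the scale is accumulated during
simulation, so theta varies across nodes exactly as Ne does.

Sequences evolve along the simulated gene trees under JC69 (default, for
speed), HKY, or GTR, with the rate matrix normalized so branch lengths
are expected substitutions per site. The simulator draws the root state
from the equilibrium frequencies and applies exact transition
probabilities per branch; an independent simulator (`phangorn::simSeq`)
serves as a cross-check oracle in the test suite.

Key closed forms used throughout:

* concordance probability on an internal branch of length `t`:
  `f1 = 1 - (2/3) exp(-t)`; each discordant topology has probability
  `(1/3) exp(-t)`;
* its inverse, used for coalescent-unit branch length estimation:
  `t = -log(3 (1 - f1) / 2)`;
* with one pulse of proportion `gamma` from P3 into a sister-pair
  lineage at time `tau`, the moved lineage pairs with P3 unless it
  escapes the shared branch (probability `E = exp(-(t_anc - tau))`),
  giving expected discordant fractions
  `gamma (1 - 2E/3) + (1 - gamma)(1/3) exp(-t)` for the introgressed
  pairing and `gamma E/3 + (1 - gamma)(1/3) exp(-t)` for the other.

## Presets

`waterfowl_preset()` ships four 4-taxon networks emulating the focal
waterfowl quartets, plus a 25-leaf backbone (24 waterfowl + chicken
outgroup). For each quartet the internal branch length (and, where the
preset carries gene flow, `gamma`) was solved from the closed forms
above so that the expected discordant share V2+V3 matches the
genome-wide ILS level the preset emulates:

| preset | t (coal. units) | gamma | design ILS% | V2/V3 asymmetry |
|---|---|---|---|---|
| screamer_magpie | 0.952 | 0.458 (P3 -> P1) | 56.8 | V2 >> V3 |
| shelduck_perching | 0.766 | 0 | 31 | none |
| steamer_shoveler | 0.03 | 0.245 (P3 -> P1) | 69.4 | V2 > V3 |
| mallard_complex | 0.146 | 0.05 (P3 -> P2) | 59 | V3 > V2 |

Two remarks. The 69.4% target exceeds the pure-ILS maximum of 2/3, so
that preset *requires* introgression on top of a near-zero internal
branch. And the effective-population and scaling assumptions behind
these presets (sister split at 1 coalescent unit, outgroup at 5,
pulse at 0.3, `s = 0.01`) are assumptions of this package, chosen once
for realism — no external study states them.

The backbone (`full24`) assigns per-branch scales so that mutation-unit
branch durations are comparable (lognormal around 0.004 subs/site) while
coalescent-unit durations vary. This makes theta vary across nodes and
track each branch's ILS propensity — the situation the theta statistic
is designed for. With a single global scale, theta is constant by
construction and carries no signal; real genomes are not like that.

## Per-branch statistics

**gCF and quartet frequencies.** For each internal branch of the
(unrooted) reference tree the four adjacent clades are reduced to one
representative each — the lexicographically smallest leaf present in the
gene tree. This deliberate simplification of the gCF reference
definition removes the paraphyletic category, leaving exactly
concordant/alt1/alt2/non-decisive, and is deterministic and testable.
`gCF = 100 f1` over decisive trees only; branches with no decisive tree
propagate as missing, never as zero.

**Coalescent lengths and theta.** `t = -log(3(1-f1)/2)`, with `f1 <= 1/3`
mapped to 0 (low-signal flag) and `f1 = 1` capped at 10 units
(saturation flag). Theta divides the OLS mutation-unit branch length
(fitted on the reference topology from average patristic distances, or
from sequence distances) by the coalescent-unit length; undefined values
(zero coalescent length) are reported missing and excluded from the
regression with a logged count. Theta is computed for internal branches
only; terminal branches have no quartet-based coalescent length.

**BP.** Estimation error is measured by the simulate-and-reestimate
protocol: alignments are simulated along the fixed reference tree (no
coalescent variation, isolating estimation error; default 200 replicates
of 1,500 sites), trees are re-inferred with the pipeline's own estimator
(JC distances + neighbor joining), and BP is the percentage of
replicates recovering each bipartition. Using NJ on both sides mirrors
the matched-estimator logic of the protocol; it trades the likelihood
machinery of large-scale tools for a deterministic, desk-scale
estimator, and the `estimate_trees` pipeline option lets the same error
process contaminate the concordance stage.

**D statistic.** Site patterns are counted on fixed-role (P1, P2, P3, O)
windows: biallelic columns where the outgroup carries the ancestral
state, ABBA = (A,B,B,A), BABA = (B,A,B,A). `D = (ABBA-BABA)/(ABBA+BABA)`
with a delete-one block jackknife for the standard error and `Z = D/SE`;
Bonferroni correction is applied across the arrangements tested in one
call. Because every simulated window carries a single genealogy,
informative sites are strongly clustered; jackknife blocks should
therefore span several genealogy windows. The packaged design uses 1-Mb
datasets of 500 independent 2-kb windows pooled into 100 10-kb blocks
— under the null this yields an essentially standard-normal Z (the test
suite verifies |Z| < 3 in at least 99% of 200 null datasets), while one
genealogy per block produces heavy-tailed Z scores and an
anti-conservative test.
Real recombining 10-kb blocks also contain several gene trees, so the
pooled design is the more faithful emulation.

**Reticulation index.** Under pure ILS the two discordant counts are
symmetric; `RI = |c2 - c3| / (c2 + c3)` measures the excess, with an
exact two-sided binomial test against 0.5. The cited reticulation-index
implementation is not restated in any source available to us; this
normalized asymmetry with a binomial symmetry test is this package's
explicit definition of the same signal. Similarly,
`ils_share = 2 min(f2, f3)` and `ih_share = |f2 - f3|` split total
discordance into its symmetric (ILS) and asymmetric (introgression)
parts; the two always sum to `f2 + f3` exactly.

## The windowed genealogy scan

Whole-genome alignments are emulated as ordered windows (0-based,
half-open coordinates), each an independent MSC draw — free
recombination between windows, none within. Windows are classified into
V0 (species topology, sister coalescence below the ancestral
speciation), V1 (species topology, deep coalescence), V2 (P1 with P3),
V3 (P2 with P3) from the three ingroup JC distances: the sister pair is
the argmin, and V0/V1 are separated by a threshold `tau` estimated as
the 0.05 quantile of `min(d13, d23)` across windows (distances to P3
cannot predate the ancestral speciation, so their lower envelope tracks
it). Exact ties are resolved deterministically (priority V0 > V2 > V3),
flagged, and excluded from fraction denominators by default.
`ILS% = 100 (V2 + V3)` follows the field's reporting convention even
though V1 is also deep coalescence; V1 is reported separately.

Window-level classification with an optional 4-state HMM
(self-transition `rho = 0.9`, emission error `eps = 0.1`,
forward-backward posteriors) replaces site-level hidden-Markov decoding:
the window is the unit at which such scans are reported, and this keeps
the artifact desk-scale while preserving the V0--V3 semantics. This is
the package's central simplification. Note the smoothing prior assumes
autocorrelated states; on the package's own independent-window
simulations it is a no-op at best, and the class fractions are always
computed from the raw per-window states. The z-standardized ILS
posterior track (`z_ils`) feeds horizon-style plots via `autoplot()`.

Simulation presets use 10-kb windows as a scaled stand-in for the 100-kb
windows of genome-scale practice; at `s = 0.01` a 10-kb window carries
roughly the same number of informative sites per coalescent unit as a
100-kb window would at genome-typical divergence, and per-window
classification accuracy against simulation truth exceeds 90% at `t = 1`.

## The LMG decomposition

Per-node discordance `y = 100 - gCF` is regressed on standardized
theta (ILS), `100 - BP` (estimation error) and RI (introgression).
The LMG share of a predictor is its sequential R² increment averaged
over all `p!` predictor orderings, computed exactly by subset
enumeration with the closed-form weights `|S|!(p-|S|-1)!/p!`; shares are
nonnegative, order-invariant, and sum to R². The `first` (marginal) and
`last` (added-last) increments are reported alongside; the `pratt`
variant is omitted (it can be negative). Rows with any undefined entry
are dropped with a logged count; constant predictors are dropped with a
warning and reported as zero share. The response and standardization
choices are this package's own (the protocol it follows does not state
them); standardization makes shares scale-free.

One pitfall deserves its own paragraph. The raw reticulation index never
averages to zero on finite data: under symmetric ILS,
`E|c2 - c3| / (c2 + c3)` is approximately `sqrt(2 / (pi (c2 + c3)))`, so
branches with few discordant trees — exactly the high-gCF branches —
score systematically higher. Fed into the regression, this noise floor
correlates with the response through the back door and can hand the
introgression factor a large, wildly seed-dependent share on data
simulated *without* gene flow. The pipeline therefore supplies the
regression a noise-corrected asymmetry,
`sqrt(max(0, (c2 - c3)^2 - (c2 + c3))) / (c2 + c3)`, which subtracts the
binomial expectation of the squared asymmetry; it is near zero (and
zero-inflated) under pure ILS and converges to the raw index when a real
signal dominates. `reticulation_index()` still reports the conventional
index with its exact binomial test; per-node tables carry both columns,
and `assemble_node_matrix()` uses the corrected one when present.

## Numerical choices and degenerate inputs

* JC distances use pairwise (not listwise) deletion; pairs at or beyond
  the JC saturation point `p >= 0.75` are capped at 5 subs/site and
  flagged. A pair with no comparable sites is an error naming the pair.
* Negative NJ and OLS branch lengths are clipped to zero (flagged).
* `SE = 0` in the jackknife yields `Z = 0` when `D = 0` (identical
  blocks) and an undefined flag otherwise.
* All randomness flows from one master seed; per-locus and per-window
  streams are derived by index, so locus `i` is identical whether 100 or
  10,000 loci are requested, and every pipeline output is reproducible
  from config + seed.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
each check completes in minutes on one core while keeping Monte-Carlo
error well inside the asserted tolerances: 10,000 loci for simulator
calibration and branch-length recovery; 200 datasets of 1 Mb each per
arm of the D-statistic calibration; 600--2,000 windows of 10 kb for the
scan checks; 1,500--2,000 loci and 100--150 error replicates for the
backbone decomposition. These sizes are package choices, not statements
about the scales the statistics support.

## What passing tests do and do not show

The generator reproduces the statistical structure the analyses assume:
MSC topology frequencies, pulse-introgression asymmetries, windowed
alignments with recorded truth, and Ne-driven theta variation. It omits,
by design: intra-window recombination, continuous migration, substitution
rate heterogeneity across sites and lineages beyond the per-branch
scale, indels and alignment error, gene duplication/loss, and
population-level sampling (one haploid genome per species). Passing
checks therefore validate the statistics' behavior under the model they
assume, not their robustness to real-data violations of it — most
importantly alignment error and within-window recombination, which real
whole-genome analyses must confront.

## A worked backbone run

```{r backbone, eval = FALSE}
nw <- waterfowl_preset("full24")
rep <- run_pipeline(pipeline_config(network = nw, n_loci = 1500,
                                    n_reps = 150, seed = 1))
rep$decomposition
tidy(rep$decomposition)
autoplot(rep$decomposition)
```

Adding one strong pulse raises the introgression share, the package's
end-to-end contrast:

```{r contrast, eval = FALSE}
nw_flow <- add_introgression_event(nw, "Dendrocygna_arborea",
                                   "Oxyura_jamaicensis", 0.1, 0.3)
rep_flow <- run_pipeline(pipeline_config(network = nw_flow,
                                         n_loci = 1500, n_reps = 150,
                                         seed = 1))
rep_flow$decomposition$percent["ri"] - rep$decomposition$percent["ri"]
```
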