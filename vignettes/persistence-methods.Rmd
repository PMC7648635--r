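---
title: "Weighted residence time and trait-based persistence analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted residence time and trait-based persistence analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegpersist)
```

## The problem

Permanent-plot resurvey programmes record which herb-layer species occur in
which small quadrats at a series of revisits, together with their percent
cover. Two questions drive the analyses this package implements: *how
persistent is each species at a fine spatial grain*, and *which functional
traits are associated with that persistence* in a given ecological context?
Around those two questions sit the standard supporting analyses of
trait-based community ecology: compositional comparison between sites
(PERMANOVA on Bray–Curtis dissimilarities) and the comparison of functional
with phylogenetic diversity at the quadrat level.

## The weighted residence time index

For one species in one sampling unit, let `Z` be the number of surveys,
`P` the number of surveys at which the species was present, and `T` the
number of maximal runs of consecutive presences (the pattern `1,1,0,0,1,0,1,0`
has `P = 4`, `T = 3`). The presence/absence index is

```
WRT_pa = 100 * (P / T) / Z
```

`P / T` is the mean length of a residence episode, so `WRT_pa` is the mean
residence time expressed as a percentage of the whole series: 100 for a
species present throughout (`P = Z`, `T = 1`), `100 / Z` for a species that
never survives from one survey to the next (`P = T`), and 0 by convention
for an all-absent pattern, where the ratio `0/0` is undefined. Runs are
counted on the ordered survey sequence; irregular calendar gaps between
revisits are deliberately ignored, so "consecutive" means consecutive
*observations*.

The abundance-weighted variant multiplies by the species' mean relative
cover in the unit:

```
WRT_abu = WRT_pa * Rel.cov,    Rel.cov in [0, 1]
```

`Rel.cov` is the species' share of the summed cover of all species in the
unit, averaged over time. Two averaging conventions are supported because
the definition is genuinely ambiguous. The default, `presence_only`,
averages the share over the surveys at which the species was present;
absence is then penalised once (through `WRT_pa`) rather than twice. The
alternative `all_surveys` averages over all `Z` surveys with absences
contributing zero. Both are exposed via the `mode` argument of
`rel_cover()` and `wrt_table()`.

Reported tables round the indices to one decimal with halves rounded up
(`wrt_report()`); all internal computation is unrounded.

## Compositional and trait-composition PERMANOVA

Between-site compositional differences at the first survey are tested with
a one-way permutational MANOVA computed directly from the Bray–Curtis
distance matrix, using the distance-based sum-of-squares partition

```
SS_total  = (1/N) * sum_{i<j} d_ij^2
SS_within = sum_g (1/n_g) * sum_{i<j in g} d_ij^2
pseudo-F  = (SS_between / (k-1)) / (SS_within / (N-k))
```

with significance by unrestricted permutation of site labels. When the
number of distinct label assignments is small (at most 10,000) the
permutation distribution is enumerated exactly; otherwise a seeded
Monte-Carlo sample is drawn and the p-value uses the add-one rule
`(b + 1) / (n_perm + 1)`, so p is never reported as zero. The default 999
permutations match common practice for this design.

The *trait-abundance composition* of a unit is not a standard object, and
we document our construction explicitly: for each binary or categorical
trait attribute, the summed cover of species bearing the attribute; for
each quantitative trait, the cover-weighted mean (zero in an empty unit).
Columns are range-standardised to `[0, 1]` (`range_standardise()`) before
Bray–Curtis, since summed covers and CWMs live on incommensurate scales.
Species pairs of all-zero units have an undefined Bray–Curtis distance; we
define it as 0 with a warning so empty quadrats remain comparable rather
than aborting the analysis.

## Functional and phylogenetic diversity

Functional diversity of a quadrat is the mean pairwise Gower distance among
the species present; phylogenetic diversity is the mean pairwise patristic
distance on a species tree. Both are undefined (NA) with fewer than two
species. Gower components are the classical ones — range-normalised
absolute differences for quantitative traits, 0/1 mismatches for binary and
categorical traits — with pairwise deletion of missing traits and weight
renormalisation; computation is delegated to `cluster::daisy()`, which
implements exactly these conventions, behind a validating wrapper.
Quantitative ranges are taken over the species pool actually supplied, so
passing each site's trait subset yields site-level ranges (the default in
`run_pipeline()`); this is configurable simply by passing the global table
instead.

Trees are handled as `ape` `phylo` objects. `neighbor_joining()` wraps the
classic Saitou–Nei agglomeration (`ape::nj`) and post-processes negative
branch-length estimates — which arise only on non-additive inputs — by
clamping them to zero and transferring the deficit to a sister branch.
Trees without branch lengths fall back to nodal (edge-count) patristic
distances with a message. Species absent from the tree can be mapped to
congeneric stand-ins only through an explicit alias map; nothing is matched
silently by genus.

The per-site association between FD and PD across quadrats uses Spearman's
rank correlation with mid-rank ties (exact p for n <= 9 without ties,
t-approximation otherwise), on all units with both scores defined at the
first survey.

## Conditional inference trees

The trait–persistence relationship is modelled by recursive binary
partitioning in which every split must first pass a test of independence,
so the tree stops growing exactly when no predictor shows a significant
association — there is no pruning step. We implement the framework with
rank-based permutation tests rather than the quadratic-form machinery of
the full conditional-inference framework; this is a deliberate
simplification that preserves the three defining behaviours: permutation-
based significance, strongest-association variable selection, and stopping
on non-rejection.

* **Association test** (`association_test()`): for an ordered predictor the
  statistic is the absolute Spearman-type rank correlation; for a
  categorical predictor a Kruskal–Wallis-type between-group statistic on
  response ranks. p-values come from seeded Monte-Carlo permutation of the
  response with the add-one rule.
* **Variable selection** (`select_split_variable()`): Bonferroni adjustment
  over the testable predictors; the smallest adjusted p wins if it is below
  `alpha`. Because Monte-Carlo p-values saturate at the floor
  `1/(n_perm + 1)`, two strongly associated predictors frequently tie at
  the floor; ties are therefore broken by smaller raw p, then by the larger
  permutation-standardised statistic `(obs - mean(perm)) / sd(perm)` (which
  is comparable across predictor kinds because it is standardised against
  each test's own permutation distribution), and only then by declared
  predictor order. Identical predictors still resolve by declared order.
* **Splitting** (`best_split()`): for ordered predictors the cutpoint
  maximising the standardised two-sample rank statistic, reported as the
  largest observed value of the left group; for categorical predictors an
  exhaustive search over binary level subsets (feasible up to 10 observed
  levels). Both children must hold at least `min_leaf` observations.
* **Missing values**: casewise deletion within each association test; an
  observation missing the chosen split variable follows the majority child.

Defaults (`cit_control()`): `alpha = 0.05`, `n_perm = 9999`,
`min_node = 20`, `min_leaf = 7`, `max_depth = 4`. Per-node test seeds are
derived deterministically from the control seed, so a fitted tree is fully
reproducible. The observation unit is one row per (species, sampling unit)
with at least one occurrence, the response being that row's WRT (either
variant) and the predictors the species' fixed trait values; species-level
mean responses can be analysed instead by aggregating before fitting.

## The synthetic study generator

Because long-term monitoring data of this kind are rarely redistributable,
every stage is exercised against a synthetic generator
(`simulate_study()`) whose defaults describe the study design the package
targets: 4 sites, 100 quadrats per site, 8 surveys labelled
1999–2011, species pools of about 33 per site drawn from a global pool with
overlap such that roughly 60% of species are confined to a single site
(global pool ≈ 90 species). Occupancy follows a first-order Markov chain
per (species, unit): initial presence `p_init = 0.15`, per-survey
persistence `baseline_persist = 0.7` on the logit scale plus optional
trait effects, colonisation `baseline_colonize = 0.03`. Cover when present
is log-normal (`meanlog = log(3)`, `sdlog = 0.8`, i.e. a median cover of
3%) perturbed by ±20% between surveys. These values were chosen once as
plausible for temperate forest herb layers (sparse quadrat occupancy,
strongly right-skewed cover) and are not tuned to any test outcome.

Trait marginals are calibrated to magnitudes a field ecologist would
recognise: log-normal seed mass with median ≈ 2 mg and a tail into tens of
mg; SLA normal (25, 8) mm²·mg⁻¹ truncated above 5; a 60% prevalence of a
perennial belowground bud bank; vegetative mobility none/slow/fast at
(0.2, 0.4, 0.4); four leaf-anatomy types. Trees are Yule topologies with
exponential branch lengths.

The generator is a first-order Markov model: it produces exactly the
run-structured occupancy patterns WRT measures, but it has no spatial
autocorrelation between quadrats, no year effects or climate forcing, no
observer error, and no interspecific interactions. Tests passing on it
therefore validate the *estimators and algorithms*, not the ecological
realism of any particular dataset.

## Numerical choices and degenerate inputs

* All-absent occupancy patterns: `WRT = 0`; `T = 0` only in that case.
* `rel_cover()` errors if a unit's total cover is zero at a survey where
  the focal species has positive cover (inconsistent input), and treats a
  zero-total survey as share 0.
* Bray–Curtis of two all-zero rows: 0 with a warning.
* Exactly tied split statistics resolve to the smaller cutpoint (ordered)
  or the earlier-enumerated level subset (categorical).
* Monte-Carlo p-values never equal 0 (add-one rule); exhaustive PERMANOVA
  p-values are exact fractions that include the observed assignment.
* NJ negative branch lengths: clamped, deficit moved to a sister edge,
  with a message; additive inputs are reproduced to ~1e-14.
* Survey CSVs write covers at full double precision (`%.17g`) so a
  write/read round trip is bit-exact.

## Problem sizes used in the tests

The shipped test-suite exercises: all 2^8 occupancy patterns exhaustively;
PERMANOVA against exact enumeration on 6 objects (20 assignments) and
against an independent reference implementation on random tables;
neighbor joining on 50 random additive trees of 5–20 leaves; Gower metric
axioms on 100 random trait tables; association-test calibration on 1000
null replicates (n = 30, 199 permutations); planted-effect recovery on 100
replicates of n = 400 with a 35-point effect against 15-point noise; and
three full 4-site studies for the end-to-end north–south contrast. These
sizes keep the whole suite under a minute of compute while leaving every
Monte-Carlo margin wide relative to its standard error.

## Known limitations

* Aboveground persistence only: a species may survey as absent while
  persisting below ground; the index cannot distinguish these.
* The index treats survey gaps of one and three years identically.
* The CIT framework is a rank-based approximation; its p-values are valid
  permutation p-values, but they are not numerically identical to those of
  the full conditional-inference framework, and no surrogate splits are
  implemented.
* The trait-abundance composition fed to PERMANOVA is one defensible
  construction among several; alternative constructions can be supplied by
  building the matrix manually and calling `permanova()` directly.
* Intraspecific trait variation is not modelled: traits are fixed per
  species by design.
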