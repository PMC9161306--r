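---
title: "Concordance-index networks: model, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concordance-index networks: model, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordr)
```

# The problem

Metabolite concentrations and phosphopeptide LFQ intensities measured in the
same plants across four tissue-by-time conditions — end-of-day root (DR),
end-of-day shoot (DS), end-of-night root (NR), end-of-night shoot (NS) —
carry joint regulatory information, but with only four condition means per
molecule the usual co-expression tools behave badly. A rank correlation over
~16–24 replicate measurements is dominated by within-condition noise when
the condition effects are small; conversely, when measurements form two
tight clusters (e.g. a pure shoot/root difference), correlations are
near ±1 regardless of whether the two molecules' *patterns* actually agree
in any detail. Euclidean distance on z-scored patterns fails in the other
direction: standardization maps a flat, uninformative profile onto the unit
sphere where it can sit arbitrarily close to a strongly regulated one.

The concordance index I_C addresses this by scoring, pair by pair of
conditions, whether two molecules deviate *in the same direction and by a
substantial amount relative to their own replicate spread*, and by rewarding
the weaker of the two signals only.

# The model

For one molecule with per-condition means `x̄_i` and sample standard
deviations `sd(x)_i` (denominator n−1), every ordered condition pair
(j | i) contributes a condition deviation

d_k = (x̄_j − x̄_i) / sd(x)_i,  k = 1…12,

in units of the reference condition's standard deviation. The enumeration
order of the 12 ordered pairs is fixed (DS|DR, NR|DR, NS|DR, DR|DS, NR|DS,
NS|DS, DR|NR, DS|NR, NS|NR, DR|NS, DS|NS, NR|NS) so that serialized outputs
are bit-stable.

For a metabolite M and phosphopeptide P the combined condition deviation is

z_k(M, P) = sign(d_k(M)) · sign(d_k(P)) · min(|d_k(M)|, |d_k(P)|).

It is positive when both molecules deviate the same way between conditions
i and j, negative otherwise, and its magnitude is capped by the *weaker*
partner — a pair only scores where both molecules carry signal. Each z_k is
discretized into a component z̃_k by magnitude class,

| |z| | [0,1) | [1,2) | [2,3) | [3,5) | [5,10) | [10,∞) |
|-----|------|-------|-------|-------|--------|--------|
| z̃  | 0    | 0.25  | 1     | 1.5   | 1.75   | 2      |

with the sign of z_k carried over. Negative and positive components are
summed separately into I_C(−) and I_C(+), and

I_C = I_C(−) + I_C(+) ∈ [−24, 24].

The discretization makes the index robust against single extreme deviations
(everything at |z| ≥ 10 counts the same) while the jump from 0.25 to 1 at
|z| = 2 sharply separates noise-level from substantial deviations. Because
every component is an exact quarter-multiple, I_C is stored as an exact
quarter-integer and threshold comparisons such as `ic >= 7` are exact, never
subject to floating-point slack.

Assumptions worth stating: measurements are on the log2 scale; replicates
within a condition are exchangeable; the sample standard deviation of 4–6
replicates is an acceptable (noisy) scale estimate — the discretization is
what keeps that noise from propagating linearly into the score.

## Co-filters

Two filters complement the index when declaring "connections":

* **Spearman rank correlation** on replicate-paired values, two-sided
  t-approximation, significant at α = 0.05. Observations are paired by
  (condition, replicate index), truncated per condition to the smaller
  replicate count. Pairing by index is a design decision: replicates are
  shared biological samples, and index pairing keeps n ≈ 16–24, where the
  t-approximation is reliable. Pairs with fewer than 4 paired points get
  p = 1 (the filter then always removes them).
* **Flatness**: a Kruskal–Wallis rank test across the condition groups;
  molecules with p > 0.05 are "flat" and cannot form connections. Flat
  patterns are exactly the ones standardization would inflate.

## Null model and calibration

To estimate how many pairs pass any threshold by chance, the package
simulates datasets matched to the experimental moments. Per molecule, a
three-parameter Gamma (location, shape, scale) is fitted to its condition
means by the method of moments; a Gamma is preferred over a normal because
phosphopeptide condition-mean distributions are strongly asymmetric. For
each simulated molecule one mean per condition is drawn from that fit, then
replicate values are drawn from a normal centred on the *drawn* mean with
the molecule's *experimental* per-condition standard deviation, with
matching replicate counts. Centring on the drawn mean is the only reading
under which the Gamma draw has any consequence. Three modes randomize the
metabolites, the phosphopeptides, or both; the share of pairs at each
threshold in experimental vs simulated data gives the calibration curve
(quarter-integer grid on [−24, 24] for I_C, 100 classes on [−1, 1] for ρ).

Numerical choices in the fit: with four points a maximum-likelihood
three-parameter fit is ill-posed, so moments are used; when the sample
skewness is ≤ 0.05 the fit is applied to the reflected values ("mirrored");
and |skewness| is floored at 0.05 before solving shape = (2/g)², because a
near-zero skewness would otherwise demand an absurdly large shape — the
floor yields a well-conditioned, effectively normal fit. Zero-variance
molecules get a degenerate fit that reproduces their constant.

One subtlety: the simulation reproduces the experimental *variance*
faithfully, so the average simulated sample *standard deviation* sits below
the experimental one by the usual c4 small-sample factor (≈ 0.92–0.95 at
n = 4–6). The package's tests therefore compare spreads on the variance
scale, where the sample statistic is unbiased.

## Clustering and the between-genotype distance

Standardized condition-mean patterns (z-scores over the four means,
population standardization — the z-scores only serve clustering geometry)
are clustered per genotype and across genotypes, with flat molecules
assigned to the dedicated cluster "Z". k-means uses hand-written k-means++
seeding (100 restarts, ≤ 300 iterations, Euclidean); hierarchical
clustering uses Euclidean distance with Ward linkage — the linkage is a
package choice, made to match the k-means geometry, and is exposed through
the method argument. The default k = 13 for metabolites reflects the scale
at which both methods stabilize on this kind of data; a silhouette scan
(`select_k_silhouette()`) is provided for choosing k on new data.

The between-genotype distance of a molecule combines, with equal weights
(configurable),

* the fraction of (clustering configuration × genotype pair) combinations
  in which the molecule's labels differ, over the default ensemble
  {k-means, hierarchical} × {k−2, k, k+2} of genotype-overlapping
  clusterings, and
* the summed pairwise Euclidean distance between its z-patterns across
  genotypes, normalized by the dataset maximum.

Both components lie in [0, 1], hence d_GT ∈ [0, 1]; the equal weighting and
max-normalization are package choices (the combination rule is inherently
conventional), so d_GT should be read as a ranking device, not an absolute
scale. Molecules flat in all genotypes get NA; a flip into or out of
flatness counts as a label change.

## Over-representation profiles

Enrichment of an entity (a functional bin, or a metabolite) along a ranked
list is profiled with a one-sided Fisher exact test at every position
n = 1…⌊f·N⌋ of the top fraction f (0.10 for interaction lists, 0.25 for
molecule lists), Bonferroni-corrected by the number of profile positions.
One-sided is the right sidedness because the procedure scans for
over-representation only; the Bonferroni family is the per-entity profile
(positions), a deliberate choice where the alternative (entities ×
positions) would conflate the question "is this entity enriched somewhere
early" with the number of entities tested. Profiles are collapsed into
x_k = Σ w_i·(−log10 p_i) with descending weights w = (n, n−1, …, 1), so
enrichment at the very top dominates; per genotype, entities are ranked by
x_k (ties broken lexicographically, deterministic) and the rank is mapped
to the open interval (0, 1) as rank/(count+1) — the alternative
(rank−1)/(count−1) hits the endpoints and is rejected. Entities are
reported by ascending mean scaled rank across genotypes.

## Networks

Connections (I_C ≥ 7 by default for networks, 6 for screening; both
thresholds inclusive) are grouped by (metabolite, bin, genotype); each edge
carries the arithmetic mean I_C and the connection count, a phosphopeptide
mapped to several bins contributes to each, and unannotated ones fall into
bin "unknown". The result is a bipartite igraph multigraph with parallel
per-genotype edges, exported as GraphML/GML/TSV with edge weights so an
external tool can lay it out; discordant edges (I_C ≤ −threshold) are
computed behind a flag but excluded from the default network.

# The synthetic-data generator

`generate_dataset()` emulates the study dimensions: 42 metabolites and
3,330 phosphopeptides per genotype, 3 genotypes, 4–6 replicates per
condition, additive Gaussian noise on the log2 scale. Each molecule draws a
pattern archetype — tissue-dominant (−1,+1,−1,+1), time-dominant
(+1,+1,−1,−1), interaction (+1,−1,−1,+1) or flat (0,0,0,0) over
(DR, DS, NR, NS) — a polarity, and a baseline ~ N(10, 1.5²); replicate
values are baseline + polarity·pattern·effect_size + N(0, noise_sd²).
Ground truth labels every metabolite–phosphopeptide pair concordant (shared
non-flat archetype, equal polarity), discordant (opposite polarity) or
independent.

Defaults, chosen once: `effect_size = 2` log2 units and `noise_sd = 0.5`
(ratio 4 — recoverable but not trivial, in the range of the strongly
significant pairs such a design produces); archetype mixture 0.25 / 0.25 /
0.20 / 0.30 (a substantial flat class, matching how often real molecules
fail the Kruskal–Wallis screen); replicate counts drawn per (genotype,
condition) and shared across molecules, because replicates are shared
biological samples; `polarity_prob` controls the concordant/discordant
balance among planted pairs.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: mass-spectrometry missingness mechanisms and
intensity-dependent noise; correlated noise between molecules measured in
the same run; the continuum of intermediate, non-archetypal patterns; and
genotype-specific pattern rewiring (molecules keep their archetype across
genotypes unless the user constructs otherwise). One consequence worth
knowing: because every non-flat synthetic molecule carries a *strong*
archetype, null datasets simulated from such molecules show heavier I_C
tails than nulls built from real, mostly weakly structured molecules — the
calibration ratio (experimental/simulated share) is therefore demonstrated
on constructions with a large flat class, and the study-scale calibration
thresholds are only checked on the study's own tables.

# Degenerate inputs and numerical conventions

* `sd_i = 0` with differing means: the deviation becomes a signed infinity
  sentinel and lands in the outermost class (component ±2) — a genuine mean
  difference with zero spread counts maximally rather than crashing. Both
  means equal gives d_k = 0.
* Absent conditions (fewer than 2 unmasked replicates) invalidate their
  pairs; invalid components contribute 0 (neutral) and the count of valid
  components is recorded so users can filter. Molecules with fewer than 2
  usable conditions are excluded with a message.
* Outlier flagging (modified z-score, threshold 5, conservative for 4–6
  replicates) is applied per molecule per condition group, on the log2
  values — per-condition grouping prevents condition effects from
  masquerading as outliers. When the MAD is 0 the score falls back to the
  mean absolute deviation scaled by 1.2533; when that is also 0 nothing is
  flagged. Flagging is invariant under positive affine transforms.
* All-equal replicate groups: Kruskal–Wallis is degenerate, the molecule is
  reported flat (p = 1) with variance ratio 0 and NA z-scores.
* Ties: Spearman uses midranks; ranked lists break ties by molecule ids;
  scaled ranks break score ties lexicographically. All outputs are written
  with `%.17g` so that TSVs round-trip bit-exactly.

# Problem sizes used by the tests

The shipped test-suite exercises the full 42 × 3,330 = 139,860-pair universe
once (cardinality and ranked-list sizes), and otherwise uses reduced
universes (12–42 metabolites × 80–300 phosphopeptides, 1–2 genotypes, one
simulated dataset per mode) for the stochastic checks: planted-pair
recovery (recall ≥ 0.8 at effect = 4 × noise), null shares below 5% at
I_C ≥ 6, and the ≥ 2× experimental/simulated calibration ratio. These sizes
were chosen as the smallest at which the Monte-Carlo properties are stable
across seeds.

# Limitations

* I_C is a *pattern similarity* score, not a causal statement; no direction
  is inferred, and no mutual-information style dependence measure is
  attempted.
* The null model randomizes molecules independently; it has no analytical
  form and no permutation variant, so calibration inherits Monte-Carlo
  error from the number of simulated datasets (1 per mode by default in
  tests; increase `simulation_reps` for reports).
* With 4 condition means, the Gamma fit is inevitably coarse; it matches
  the first two moments exactly and the third only through the clamped
  skewness.
* d_GT values are comparable within a dataset, not across datasets, because
  of the max-normalization of the Euclidean component.
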