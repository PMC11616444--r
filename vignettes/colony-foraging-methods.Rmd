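---
title: "Methods: segmenting, modelling and comparing colony foraging trips"
author: "batforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting, modelling and comparing colony foraging trips}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batforage)
```

## The problem

Greater spear-nosed bats (*Phyllostomus hastatus*) roosting in island caves
leave every evening, commute tens of kilometres in nearly straight flight to
a foraging area, forage there in short tortuous movements, and return before
dawn. `batforage` turns raw nightly GPS fixes into answers to three
questions: where does each behavioural phase begin and end, how far and in
which direction does each colony forage, and how much of the landscape that
was *available* did each colony actually use?

The pipeline is: track cleaning and regularization, a two-state hidden
Markov model (HMM) over step lengths and turning angles, foraging metrics,
a landscape-constrained null-track simulation, a hierarchical Bayesian model
of foraging distance and bearing, and rasterized foraging-density overlap.
A synthetic-data generator with known ground truth exercises every stage.

## Coordinates, angles, units

All modelling happens on a local transverse-Mercator grid (default UTM 17N,
implemented in-package from the standard ellipsoidal series; round-trip
error is far below GPS noise). Distances are kilometres, step lengths
metres per sampling interval.

Bearings use a **south-zero, clockwise-positive** convention in
$(-\pi, \pi]$: 0 rad is due south, $\pi/2$ due west. Compass degrees are
`rad * 180/pi + 180`. This convention is fixed so that radian and degree
summaries of the same posterior agree to within rounding, and it is applied
uniformly by `angle_distance_to_roost()`, the generator and the reports.
Turning angles are counterclockwise-positive in $(-\pi, \pi]$.

## Preprocessing

`remove_outliers()` applies two rules: a *sequential* speed filter — a fix
is dropped when the speed implied from the previous retained fix exceeds
15 m/s, beyond this species' flight capability — and an over-water range
rule that drops fixes over water farther than 60 km from the roost. The
sequential formulation means one bad fix never condemns its neighbours, and
the filter is idempotent. The 60 km default is a deliberate over-bound
(beyond any plausible commute in this system) because the rule is meant to
catch satellite glitches, not behaviour; it is exposed as an argument.

`downsample()` aligns tracks on a common interval (default 120 s, matching
the coarsest duty cycle in multi-year deployments) by keeping the nearest
fix within half an interval of each grid time. `regularize()` then builds
the complete grid, inserting missing slots so the HMM sees a proper time
series, and computes steps and turning angles where three consecutive
locations exist. `classify_night()` calls a night *complete* when the first
and last fixes lie within 500 m of the roost and the bat actually left that
radius; 500 m operationalizes "returned to the roost" at GPS accuracy and
is configurable.

## Behavioural segmentation

The HMM has one gamma step-length distribution and one wrapped Cauchy
turning-angle distribution per state, a shared transition matrix, and the
stationary distribution as the initial law. Two states are the default:
*foraging* (short steps, low directional persistence, including rest) and
*commuting* (long, straight). Three-state models typically score lower AIC
by splitting slow behaviours, but the split is not interpretable at 2-min
resolution; `n_states` accepts any value so the comparison can be made
explicitly.

Fitting is by direct numerical maximization of the pooled forward
log-likelihood across series (Nelder-Mead on log/logit-transformed
parameters with a BFGS polish and random restarts), the common approach in
movement HMMs and simpler to pool than EM. Starting values come from a
k-means split of log step lengths with moment matching per cluster — in
testing this was the difference between reliable convergence and a local
optimum that flattens the foraging-state angle concentration. Missing
observations contribute emission probability one (transition-only steps);
zero steps are shifted to half the smallest positive step because the gamma
density is singular at zero for shape < 1. States are relabelled after
fitting by increasing mean step so "state 1 = foraging" is deterministic
even though the likelihood is permutation-invariant. Decoding returns both
the Viterbi path and forward-backward smoothing probabilities; slots without
observations take the Viterbi bridge state and are flagged imputed.

## Foraging metrics

A *foraging bout* is a maximal run of foraging-state slots; bouts of length
one are discarded as decoding noise, and each retained bout contributes its
first located slot as a *foraging location* with distance and bearing to the
roost and a home-island flag. The *outbound commute* is the maximal
commuting-state run between the first departure from the roost radius and
the first foraging bout (inbound mirrored); its straightness index is net
displacement over path length. A `full_path` flag measures the whole
roost-to-first-bout path instead, since published analyses rarely state
which segment they used.

On/off-island foraging time is aggregated per night into binomial counts
and modelled with `stats::glm` (logit link) — aggregation gives the same
likelihood as per-slot Bernoulli rows with a far smaller design matrix.
"Off-island" is decided purely by the land-polygon test, not a distance
threshold. The balsa energetics utility converts a colony size and a
bats-fed-per-tree range into the implied number of simultaneously flowering
trees via `ceiling(colony/max)` and `floor(colony/min)`.

## Null-track simulation

The null model asks where bats *could* have foraged, ignorant of resources:
a generative run of the fitted HMM kernel from the roost, with (a)
transitions into foraging rejected over water (the chain stays commuting),
(b) headings evolving by wrapped Cauchy turns, initial heading uniform,
(c) commuting headings re-centred on the roost bearing after half the night
so trips end near home, and (d) bounding-box escapes handled by heading
resampling then reflection. Null foraging locations pass through the *same*
`extract_foraging_locations()` code path as observed data, and locations
over water are dropped with the drop rate logged.

This module is a *reconstruction*: the original study describes its
simulation only in supplementary material that is not available, so every
choice here (return-onset fraction, rejection rules, box handling) is an
explicit argument that can be swapped. The comparisons it supports are
therefore qualitative — the angular spread of available space versus used
space — not numeric reproductions.

## Hierarchical model of distance and bearing

For one colony × season × provenance group with individuals $i$ and
foraging locations $j$:

$$d_{ij} \sim \mathrm{Normal}(\mu_d + b_i,\ \sigma_d), \qquad
  b_i \sim \mathrm{Normal}(0, \tau_d)$$
$$\theta_{ij} \sim \mathrm{vonMises}(\mu_\theta + a_i,\ \kappa), \qquad
  a_i \sim \mathrm{Normal}(0, \tau_\theta)$$

with weakly regularizing priors $\mu_d \sim N(20, 20)$ km,
$\sigma_d, \tau_d \sim \mathrm{HalfNormal}(10)$ km,
$\mu_\theta \sim N(0, 2)$ rad, $\kappa \sim \mathrm{HalfNormal}(10)$,
$\tau_\theta \sim \mathrm{HalfNormal}(1)$ rad. A prior-predictive check
(in the test suite) confirms these keep distances mostly inside 0-80 km
without pinning them. Fits are restricted to off-island locations: they are
the bulk of foraging, and a Gaussian on km is a reasonable likelihood there
(truncation at zero is immaterial 15-25 km out). The two components are
conditionally independent given the individual index; the original
"multivariate" structure is unknown, and no cross-correlation parameter is
introduced. The von Mises likelihood is the standard tractable choice for
concentrated circular data; a wrapped-Cauchy variant would change tail
weight only.

Sampling is an adaptive Metropolis-within-Gibbs scheme written for this
model: random effects in non-centred form, conjugate Gibbs updates for
$\mu_d$ and the distance effects, vectorized componentwise Metropolis for
the angle effects, and two likelihood-neutral moves — a *shift* (slide the
population mean against the effects) and a *rescale* ($\tau \to \tau e^e$,
effects $\to$ effects $e^{-e}$, with its Jacobian) — that break the
mean-effect and funnel couplings. These two moves raised the effective
sample size of $\mu_d$ about five-fold at fixed cost. Convergence is
checked with split-$\hat R$ on every parameter; hyperparameter
$\hat R > 1.05$ triggers one rerun at doubled length, then an error (or a
warning where the caller expects weak identification — a null cohort with
near-uniform bearings genuinely has no mean direction).

Reported quantities per group: population means ($\mu_d$; $\mu_\theta$
wrapped, summarized circularly, plus compass degrees), *effective SD* — the
spread of the observation-level predictive, $\sqrt{\sigma_d^2+\tau_d^2}$
for distance and for angle the circular SD
$\sqrt{\tau_\theta^2 - 2\log(I_1(\kappa)/I_0(\kappa))}$, whose Monte-Carlo
counterpart `effective_circular_sd()` agrees with the Bessel closed form —
and *individual-level variability* $\tau$. Contrasts are draw-wise
differences with angular differences wrapped; at matched draw counts the
identity contrast is exactly zero.

## Foraging-density maps and overlap

`pdf_map()` evaluates, at each raster cell, the product of the posterior
marginal predictive densities of distance and bearing to the roost — the
plain product, not the polar-Jacobian-corrected density, following the
"scaled product" construction (a `jacobian` flag provides the corrected
variant). `contour_mask()` takes the highest-density 95% set by ranking
cells (ties broken by index, so masks are deterministic), computed before
land clipping; land clipping is applied at the overlap step, and both
orders are available. `overlap_percentage()` reports the asymmetric pair
$100\,|A \cap B|/|A|$ and $100\,|A \cap B|/|B|$ on land cells. Cells are
equal-area, so counts are areas; 500 m cells resolve the fitted densities
(total mass is stable to well under 2% when the cell size is doubled).

## The synthetic generator

`simulate_dataset()` draws per-individual mean bearings and distances from
colony-level distributions, then builds each night as: outbound biased
correlated walk (bias 0.8 toward the individual target, wrapped Cauchy
heading noise truncated at 60° — directed flight has no hairpin turns) to
an anchor that must lie on land off the island, a two-state Markov
foraging/relocation phase leashed to the anchor, a straight return, an
optional on-island foraging bout near the roost, and roosting until 06:00.
Default conditions mirror the study system: 18:00-06:00 nights at 120 s
fixes, 15-25 km colony-specific commute distances, night-level angular
spread 0.15 rad in the dry season and doubled in the wet, between-individual
spreads 0.12/0.25 rad, and ~30% of foraging time on the home island.
Corruptions (dropout, speed spikes, over-water strays) are off by default
and injected with recorded ground truth when testing the filters.

What the generator does *not* emulate: resource depletion, wind, social
interaction between bats, tag-specific fix-quality covariates, and
multi-modal within-night trips. Passing tests therefore demonstrate that
the pipeline recovers the structure this generator encodes, not that real
data meet its assumptions. Two further honest caveats: the realized
on-island foraging share runs a few percentage points above the allocation
parameter because end-of-night rest at the roost counts as on-island
foraging in the two-state scheme, and truth labels the within-area
relocation steps "commuting", so decode accuracy against full-night truth
plateaus around 90% even when the emission parameters are recovered almost
exactly (on data simulated from the kernel itself it is ~100%).

All synthetic randomness flows from one seed through deterministic
per-(colony, individual, night) substreams, so datasets are reproducible
and insensitive to evaluation order.

## Problem sizes and determinism

The shipped tests and the acceptance script use desk-scale sizes chosen to
exercise every code path with stable statistics: ten 360-slot nights for
HMM recovery, 50 replicates of 20 individuals × 8 locations for
hierarchical coverage, 20 replicates for the null-spread property, and a
three-colony study of 4 bats × 3 nights for the end-to-end run. Posterior
sampling uses 2 chains × 600-1000 draws after equal warmup, which yields
effective sample sizes in the hundreds for the population means. Every
stochastic entry point takes an explicit seed.

## Known limitations

* The null-track procedure is a documented reconstruction, not a
  reproduction of the original simulation.
* One bat-night per HMM fit is supported, but the pipeline pools per
  colony × season; per-night fits are noisier at 2-min resolution.
* The hierarchical model omits distance-bearing correlation and covariates
  beyond the grouping.
* Landscape polygons have no holes, and "land" is a binary predicate —
  habitat quality is out of scope.
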