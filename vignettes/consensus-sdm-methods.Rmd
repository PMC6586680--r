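---
title: "Consensus species distribution modelling under climate change: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus species distribution modelling under climate change: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleSDM)
```

# The problem

Perennial tropical crops such as Arabica coffee and cocoa, and the shade
trees planted with them in agroforestry systems, occupy climatic niches that
are expected to shift substantially by mid-century. A standard way to
quantify this exposure is correlative species distribution modelling (SDM):
relate presence records to bioclimatic predictors, project the fitted
suitability surface onto downscaled future climates from many general
circulation models (GCMs), and summarise where suitability is retained,
lost, or newly gained — including derived questions such as whether a
vulnerable crop can be replaced by another crop in the same cells, and how
many candidate agroforestry tree species remain available per location.

`ensembleSDM` implements that pipeline as composable, seeded stages, and —
because real occurrence archives and climate grids are heavy, noisy and
unversioned — pairs it with a *virtual ecologist* harness: synthetic
climate landscapes and virtual species whose true suitability surface is
known, so that every stage can be validated by parameter recovery rather
than by visual plausibility.

# The consensus model

For one species with presence/pseudo-absence training rows, the pipeline
is:

1. **Cleaning.** Records with missing or impossible coordinates, records
   off the study grid or on masked (no-data/ocean) cells, and records dated
   1959 or earlier (predating a ~1960–1990 climate baseline) are removed;
   records with a missing year are retained, since collection year is
   frequently absent in aggregated archives and absence of a date is not
   evidence of age.
2. **Systematic thinning.** A grid of 2.5 arc-min cells (the working
   resolution) is overlaid, anchored at the study-grid origin, and one
   presence is kept per occupied cell, chosen uniformly at random under the
   stage seed. This reduces sampling bias and spatial pseudo-replication at
   the cost of sample size.
3. **Pseudo-absences.** 1,000 cells are drawn uniformly without
   replacement from the valid study area. By default cells containing
   presences are excluded — the original method description is silent on
   this; we exclude them to avoid label contamination, and
   `exclude_presence_cells = FALSE` restores the literal behaviour.
4. **Predictor screening.** Stepwise variance-inflation-factor removal:
   `VIF_j = 1/(1 - R²_j)` with `R²_j` from the least-squares regression of
   layer *j* on all other layers; while the largest VIF exceeds 10, that
   layer is dropped. Ties are broken lexicographically. VIFs are computed
   on a seeded subsample of at most 10,000 valid cells; whether the
   original analysis used the full grid or a sample is unstated, and the
   subsample is our documented default (`sample_n = Inf` gives the full
   grid).
5. **Cross-validation.** Rows are assigned to `k = 4` stratified folds
   (per-class sizes differ by at most one). Each learner is calibrated on
   three folds and scored on the fourth; performance is the rank-based AUC
   (Mann–Whitney, ties one half).
6. **AUC weighting.** Per-learner AUCs are averaged over folds — the
   source method computes fold-wise AUCs but does not state the aggregate;
   the mean is the natural choice and is fixed here — then divided by their
   total to give raw weights summing to one. Learners with raw weight
   > 0.05 (at least 5% contribution to consensus predictivity) are
   selected and their weights renormalised.
7. **Refit and consensus.** Selected learners are refitted on all training
   rows (calibration used only three quarters of the data per fit;
   refitting maximises data use for projection). Consensus suitability is
   the weighted average of the member probabilities, hence bounded by the
   member predictions cell-wise.
8. **Binarisation.** The presence threshold maximises sensitivity +
   specificity over the candidate set of unique observed consensus scores
   on the full training set, with rule *presence iff score ≥ t*. When
   several thresholds tie, the smallest is used, which maximises mapped
   presence area; the tie rule is asserted by test.
9. **Projection and agreement voting.** The fitted consensus and the
   *baseline* threshold are applied unchanged to each GCM's future stack.
   The per-GCM binary maps are integrated by a likelihood-scale rule: a
   cell keeps presence (or absence) only if at least `ceil(0.66 · g)`
   GCMs agree — 12 of 17 at the defaults. Cells where neither class
   reaches agreement are set to absence in the integrated map
   (conservative: we never claim suitability on disagreement) but flagged
   in a separate uncertainty raster so the information survives; how the
   original analysis handled such cells is not described, and we make no
   claim that this matches it.

Downstream, `classify_change()` partitions cells into remain / loss
("vulnerable") / gain / never; `area_change_percent()` expresses areas as
percentages of the baseline range; `replacement_analysis()` intersects one
crop's losses with another crop's future range; `portfolio_richness()`
counts projected-suitable tree species per crop cell, in total and per use
group (fruit, N-fixing, timber), classifying cells as high-option
(> 30 species in total and ≥ 10 per group) or low-option (≤ 3 species).

# The learner registry

The original consensus platforms average over a dozen or more named SDM
algorithms; which algorithms is an implementation detail of those
platforms, not part of the method. Here any object honouring the
`learner_spec()` contract (`fit(x, y, seed)`, `predict(state, x)` in
[0, 1]) can join the ensemble, and six distinct families ship by default:
logistic GLM and ridge-regularised logistic regression on a linear +
quadratic design, a discriminant-analysis posterior on the same design, a
binomial GAM with thin-plate smooths, a k-nearest-neighbour presence
frequency on standardised predictors, and a Gaussian climate-envelope
scorer around the presence centroid. The quadratic design for the
parametric learners is deliberate: species' responses to climate are
typically unimodal, and a purely linear logistic model predicts
monotonically *increasing* suitability past the niche optimum, which
degrades spatial agreement with the true surface even when discrimination
(AUC) stays high. A learner that errors during cross-validation receives
AUC 0.5 — which the weight cutoff then usually eliminates — rather than
aborting the species; failures are logged in the calibration object.

# The synthetic world

`generate_predictor_stack()` builds each layer as a deterministic
large-scale gradient plus moving-average-smoothed white noise (5-cell box
filter; any kernel would do — determinism is the contract). Temperature-like
layers (bioclim 1–11) live on a °C-like scale and, with
`elevation_coupling`, decrease with elevation at 6.5 °C km⁻¹, the standard
environmental lapse rate; precipitation-like layers live on a mm-like
scale truncated at zero. The lowest tenth of the elevation field becomes
the ocean mask. Pseudo-GCM futures add the scenario's per-layer mean shift
plus a per-GCM, per-layer *spatially constant* deviation: GCMs are treated
as alternative plausible futures, not as spatial error fields, which is
all the ≥ 66% voting rule needs to be exercised. The default scenarios
shift temperature-like layers by +1.4 °C (`rcp45-like`) and +2.0 °C
(`rcp85-like`) — the mid-century mean warming of the intermediate and
high-emission pathways — with a 0.3 °C per-GCM spread, and dry
precipitation-like layers by 10 mm with a 10 mm spread.

Virtual species define true suitability as a product of independent
Gaussian responses, `s(x) = Π_j exp(−0.5 ((v_j(x) − μ_j)/σ_j)²)`, the
standard virtual-species construction. `random_virtual_species()` centres
the niche on a randomly chosen cell's predictor values and then rescales
all widths by a common factor so that the landscape-mean suitability
equals `prevalence_target` (default 0.1). The calibration is exact and
cheap: scaling every σ by *c* maps *s* to *s^(1/c²)*, so the target
reduces to a monotone one-dimensional root find. Without it, a niche
centred on a rare predictor combination can occupy a vanishing fraction
of the landscape — not a species anyone would model. Occurrences are
sampled with replacement across cells with probability proportional to
suitability times an optional effort-bias surface, and reported at cell
centres (sub-cell jitter is omitted; thinning operates at cell
granularity anyway).

What the generator does **not** emulate: realistic covariance among
bioclim variables, spatially structured GCM disagreement, land-cover or
soil constraints, dispersal limitation, or taxonomically messy occurrence
archives. A green parameter-recovery test therefore establishes that the
pipeline's statistics do what they claim on a well-posed landscape — not
that any particular real-world projection is right.

# Numerical choices and edge cases

* Perfect collinearity is reported as `VIF = ∞` (triggered when
  `1 − R² < 1e-12`); a zero-variance layer is an error naming the layer.
* AUC uses midranks, so ties count one half exactly; the implementation is
  checked against brute-force pair counting to 1e-12 on random instances.
* `integrate_gcm_votes()` requires `agreement ∈ (0.5, 1]`; at 0.5 or below
  both classes could "win" a cell.
* Pseudo-absence sampling is without replacement **at cell level**; one
  point per cell, at the cell centre.
* Empty-baseline species yield `NA` percent change and are excluded from
  winner/loser counts (and listed in an attribute), not silently dropped.
* Every stochastic stage derives a child seed from the global seed by a
  stable string hash of the stage name (`stage_seed()`), so stages are
  decoupled: inserting a draw in one stage cannot silently shift every
  later stage's randomness. All child seeds stay below 2³¹.
* Cell membership uses half-open intervals on both axes; rows run north to
  south. Area percentages use cell counts by default; a cos(latitude)
  weighting is available, and percentages of baseline area are nearly
  invariant to the choice on small extents.

# Held-out evaluation of the recovery tests

The acceptance-level recovery check fits the full ensemble on 300 sampled
presences and 1,000 pseudo-absences of a 100 × 100 landscape and evaluates
(i) the cell-wise Pearson correlation between consensus and true
suitability and (ii) the AUC of the consensus on a *fresh* draw of 200
presences and 500 background cells never seen in training. At the default
prevalence of 0.1 this presence-versus-background design has an intrinsic
ceiling: scoring the held-out points with the *true* suitability itself
yields a median AUC of about 0.856 across the test seeds, because
moderately suitable background cells are genuinely hard negatives. The
consensus reaches a median of about 0.850 — effectively at the ceiling —
while correlating with the true surface at r ≈ 0.93.

# Known limitations

Pseudo-absences are drawn once per species, not redrawn per fold (the
original description does not say which; redrawing would leak no data
either way). The thinning grid is anchored at the stack origin; a shifted
anchor changes which duplicates are removed, though not the one-per-cell
guarantee. The elevation bands reported alongside profiles (0–300,
400–700, > 1800 m) intentionally leave 300–400 m unassigned, mirroring
common reporting practice; band edges are configurable and nothing is
interpolated into the gap. The package models climate suitability only —
no pest pressure, soils, management, markets, or dispersal.
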