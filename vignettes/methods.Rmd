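---
title: "Models and methods: small-area snakebite risk and treatment accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: small-area snakebite risk and treatment accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its science: the models and
procedures, the parameters that matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations.

## 1. The disease-mapping model

District counts are modelled as

$$Y_i \sim \mathrm{Poisson}\!\left(E_i\, e^{\beta_0 + X_i\beta + u_i}\right),$$

where $E_i$ is the *offset* — the cases district $i$ would receive if all
cases were distributed evenly over the population,
$E_i = Y_{\mathrm{tot}} \cdot \mathrm{pop}_i / \mathrm{pop}_{\mathrm{tot}}$,
so $\sum_i E_i = \sum_i Y_i$ identically (`compute_offsets()`). $X_i$ holds
five district covariates: urban population fraction and forest-proximity
fraction on their natural $[0,1]$ scale (coefficients are reported per
+100 percentage points), and elevation, annual precipitation and number of
dry months standardised to mean 0, SD 1. We use the population-SD
convention (divide by $n$, not $n-1$): it makes the two-point example
$\{0,2\} \mapsto \{-1,1\}$ exact, and the convention is recorded in the
scaling record that travels with every fit.

$u$ is an intrinsic conditional autoregressive (Besag) field on the queen
adjacency graph (districts sharing a border *or a corner* are neighbours):
each $u_i$ is conditionally normal around the mean of its neighbours with
variance $\sigma_u^2/d_i$. The intrinsic prior is improper; identifiability
comes from re-imposing the sum-to-zero constraint every sweep, transferring
the current mean of $u$ into the intercept (which leaves the likelihood
unchanged because the shift cancels).

**Priors.** Fixed effects get $N(0, \text{precision } 10^{-4})$; the
intercept an improper flat prior. The CAR scale was described in the source
material only as "a non-informative gamma prior" on the variance, with no
hyperparameters; we follow the conventional disease-mapping choice of a
Gamma(shape 0.5, rate 0.0005) prior on the *precision*
$\tau = 1/\sigma_u^2$, which is conjugate given $u$
($\tau \mid u \sim \Gamma(0.5 + (n-1)/2,\; 0.0005 + \tfrac12 u^\top Q u)$,
with $u^\top Q u = \sum_{i \sim j}(u_i - u_j)^2$ over edges and $n-1$ the
rank of $Q$ on a connected graph). Both hyperparameters are configurable
(`model_priors()`); sensitivity can be probed through the config rather
than baked in.

**Sampler.** WinBUGS-equivalent behaviour without an external probabilistic
language: Metropolis-within-Gibbs in C++.

* Normal random-walk updates for $\beta_0$ and each $\beta_j$, with
  per-parameter Robbins–Monro adaptation of the proposal scale towards 0.44
  acceptance during burn-in.
* Because the covariates are deliberately collinear (see §4), single-site
  updates alone crawl along the posterior ridge. An adaptive-Metropolis
  block update of $(\beta_0, \beta)$ is therefore run three times per sweep:
  the proposal is $2.38/\sqrt{d}$ times the Cholesky factor of the running
  empirical covariance of $(\beta_0,\beta)$, accumulated over the later
  three quarters of burn-in (the initial transient would inflate it) and
  frozen afterwards. This raised effective sample sizes several-fold in our
  measurements without changing the stationary distribution.
* Single-site random-walk updates for each $u_i$ against its Poisson term
  and CAR full conditional, adaptively scaled; then centring; then the
  conjugate $\tau$ draw.

All randomness flows through R's RNG, so results are exactly reproducible
under `set.seed()`; chain $k$ of a fit runs under `seed + 1000k`. Default
run sizes are desk-scale (2,000 burn-in + 2,000 kept); `paper_scale = TRUE`
selects the original 50,000 + 50,000. Convergence can be checked with
`rhat()`, a pooled-versus-within variance ratio: with several chains it
compares chains directly (identical chains give exactly 1); a single chain
is split into halves first.

**Outputs.** `posterior_incidence()` converts each draw to an annual rate
per 100,000, $10^5 E_i e^{\eta_i}/(\mathrm{pop}_i\, \mathrm{years})$;
`exceedance_probability()` is the fraction of draws strictly above the
threshold (strict ">", matching "exceeded"; ties have probability zero);
`incidence_ratio_summary()` reports $e^{\beta_j}$ as posterior medians with
2.5/97.5 percentile intervals per natural unit.

## 2. Evaluating the smoothing (method comparison)

The methodological question: does model-based smoothing predict *future*
high-incidence districts better than raw rates? Training scores are
computed on one-year (1994, 1998, 2002) or five-year (1990–1994, 1994–1998,
1998–2002) windows; each is paired with a five-year test window (1995–1999,
1999–2003, 2003–2007; consecutive five-year windows intentionally share a
boundary year). A district is a positive if its test-window annual
incidence strictly exceeds 30 per 100,000 — twice the long-run national
average of ~15, and the package default threshold.

Three scores are compared: raw incidence; method A, the posterior
exceedance probability from the CAR model; and method B, a stand-in for the
undocumented "local smoothing, neighbourhood = adjacency" tool used in the
original comparison — we adopt Marshall's (1991) local empirical Bayes,
the canonical smoother matching that description, with the focal district
included in its own neighbourhood. Ranking quality is the Mann–Whitney AUC
(ties count one half) with the Hanley–McNeil standard error, and the
mean over the three period pairs carries an empirical 95% CI obtained by
simulating each pair's AUC from a normal truncated to $[0,1]$ (10,000
simulations by default — the source only said "simulating plausible AUC
values", so the distribution is our choice).

`calibrate_cutoff()` finds, per period pair, the largest exceedance-
probability cutoff that still captures the target fraction (default 90%)
of true positives, and averages over pairs — the procedure that motivates
the 10% flagging cutoff used downstream.

## 3. Habitat, overlay, and travel time

**Cleaning.** Records identical on (age, sex, month of bite, district of
residence) are collapsed to the first occurrence; records missing a key
field go to a rejected-records report rather than being silently dropped.
Cloud-masked forest coverage is mean-imputed from the observed districts.

**Habitat rule.** The focal pit viper occupies humid lowlands: a location
is suitable iff elevation is *strictly* below 1,200 m and the biotic unit
is Moist, Wet or Pluvial (vocabulary fixed to these plus Dry and Other).
Rural census units on suitable habitat are high-risk regardless of their
district's incidence flag; urban units are only flagged through their
district (probability $\ge$ 0.10, inclusive — the calibrated level is the
flagging level). Populated areas are proxied by 2 km Euclidean buffers
around census centroids, judged at cell centres for resolution-consistency.
The final populated-risk mask buffers the *high-risk* units; the generic
populated-area proxy buffers all units (the source is ambiguous here; both
are exposed).

**Cost surface.** The per-cell traversal time is

$$t_{r,\alpha} = \frac{c/\cos\alpha}{v} + \beta_r\,\alpha^2,$$

with $c$ the cell size (30 m), $\alpha$ the slope in degrees from the
gradient magnitude (central differences, one-sided at edges — isotropic
slope, since a single slope raster implies direction-independence), $v$
the speed, and $\beta_r$ 0.001 (road) or 0.02 (off-road) seconds per
squared degree. The first term is the slope-lengthened hypotenuse at flat
speed; the second adds time proportional to squared slope and creates
barriers on extreme terrain (at 10° an off-road cell costs ≈ 20.28 s
versus 18 s flat). The exact printed form of the original equation is not
recoverable from the source text (it was typeset as images); this
reconstruction matches both verbal descriptions and produces plausible
magnitudes — it is the module's defining assumption. Units of $\beta_r$
(s/deg²) are likewise our adoption.

Speeds: primary 60, secondary/urban 40, tertiary/local 20 km/h; off-road
open 6 km/h, forest 3 (50% slower), water 1.2 (one fifth of open) — but
cells carrying a road keep the road speed, so bridges work. The off-road
base speed stays 6 km/h in the cost raster: the effective 3 km/h emerges
from summing the two accumulated rasters, because the walk from the road
to the victim is covered twice (ambulance out, ambulance back).

**Accumulation.** `accumulate_time()` runs multi-source Dijkstra on the
8-connected grid; a move between adjacent cells costs the mean of the two
cell times, times $\sqrt2$ on diagonals (knight's moves, which some GIS
engines add, are not used — 8-connectivity is standard and
oracle-testable). Station and facility accumulations are summed and
converted to hours; means over each unit's 2 km buffer are categorised
half-open: $[0,2)$, $[2,3)$, $[3,\infty)$ hours.

## 4. The synthetic world

The generator's job is to produce a world *from the model the pipeline
assumes*, at the conditions the source study states, so that green tests
mean "the implementation recovers what it should", not "the data were easy".

* **Districts**: a 10 × 15 lattice (150 districts) tiling the raster
  extent. Lattice cells, not realistic polygons — adjacency and CAR
  structure are what matter for every consumer.
* **Covariates**: elevation is a smooth field (sum of seeded Gaussian
  bumps) scaled to 0–2,000 m; precipitation decreases with elevation plus
  noise; dry months discretise inverse precipitation; urban and forest
  fractions are Beta(1.5, 3) and Beta(2, 2). This reproduces the
  humid-lowland collinearity (elevation–precipitation correlation ≈ −0.9)
  without claiming realism — deliberately, since that collinearity is what
  stresses the sampler.
* **True effects**: `beta_true` is defined per +1 SD of every covariate and
  defaults to the published multivariate incidence ratios (elevation 0.60,
  dry months 0.66, precipitation 1.45 per SD; forest 1.53 and urban 0.39
  per +100%-units, converted to per-SD via the Beta SDs 0.224 and 0.201).
  The fitting module reports fractions per +100%-units as in the published
  table; `standardized_coefficients()` converts fitted draws to the per-SD
  scale for recovery comparisons.
* **Rates**: the generative offset is
  $E_i = \lambda_0 \cdot \mathrm{pop}_i \cdot \mathrm{years} / 10^5$ with
  `baseline_rate` $\lambda_0 = 15$ per 100,000 person-years (the stated
  national incidence; the spec's world configuration needed such a field
  to make generative offsets well defined before any counts exist). The
  linear predictor is centred population-weighted so that the *realized*
  mean incidence equals $\lambda_0$ — without this, Jensen's inequality
  inflates the mean rate of a log-linear field by a factor
  $e^{\mathrm{var}(\eta)/2}$ (over 2× here), silently doubling the
  caseload relative to the stated world. Centring shifts only the
  intercept, never the coefficients, so parameter recovery is unaffected.
* **CAR field**: drawn exactly by eigen-decomposition of the Besag
  precision $Q = D - W$ (null space removed, scaled by $\sigma_u$,
  centred); no burn-in, and $\sigma_u = 0$ gives exactly zero. Default
  $\sigma_u = 0.3$.
* **Case records**: 72% male; age bands below 15 / 15–30 / 30–45 / above
  45 with the published percentages 27/32/21/22 — which sum to 102%, an
  inconsistency in the source we resolve by proportional normalisation;
  months uniform (no seasonality is modelled); a seeded binomial fraction
  (default 1.3%, the source's duplicate share) of records is duplicated
  exactly on the four key fields to exercise the cleaning rule. Because
  the key space (age × sex × month × district) is finite, *accidental*
  collisions also occur and are removed by the rule, exactly as the rule
  would on real data.
* **Raster world**: elevation bumps scaled to 0–1,600 m; a meandering
  river provides water; a forest class from a second smooth field; the
  road network is the rasterised minimum spanning tree over facilities,
  stations and town nodes — connected by construction and touching every
  facility and station — with trunk edges primary, station edges
  secondary/urban, the rest tertiary. Census units sit mostly on or near
  roads, are urban within 1.5 km of a facility, and carry log-normal
  populations. Biotic units follow a moisture field.

**What the generator does not emulate** — and hence what a green test does
*not* establish: temporal drift in risk (true risk is constant across the
18 simulated years, so the value of longer training windows is smaller
than with real, non-stationary data); model misspecification (the world is
drawn exactly from the fitted model family, so the model-based method is
near its performance ceiling with minimal data — see the decisions notes on
the one acceptance clause this makes unattainable); reporting artefacts
other than exact-duplicate records; real geography, real road topology, or
realistic facility placement.

## 5. Numerical choices, degenerate inputs, tie-breaks

* Offsets error on zero total population or zero total cases; constant
  covariates are refused by name in standardisation.
* Disconnected adjacency graphs are refused with the component count; an
  island district (no neighbours) is an error naming it — the intrinsic
  CAR prior is undefined there.
* Exceedance uses strict ">"; district flagging uses inclusive "≥" at the
  cutoff; habitat elevation is strict "<" (all stated conventions, all
  configurable).
* AUC ties get half credit; the cutoff calibration returns the k-th
  largest positive score with $k = \lceil \text{target} \cdot
  n_{\mathrm{pos}}\rceil$, and the maximum score when the target is 0.
* Cell costs reject slopes outside $[0, 90)$ degrees and non-positive
  speeds; `NA` cost cells are impassable; a source on an impassable cell
  reaches nothing; unreachable cells are `NA`, and units whose buffer
  holds no finite time are reported unreachable rather than averaged.
* ESRI ASCII grids store the north-west-origin convention used throughout
  (`row 1 = north`); nodata round-trips as `NA`.
* The pipeline derives all stage seeds from one global seed; manifests
  carry MD5 checksums of every output, and re-running a stage from prior
  stage outputs reproduces its files byte-for-byte.

## 6. Known limitations

* Method B approximates an undocumented tool; only its published
  description ("local smoothing, neighbourhood defined as adjacency") is
  honoured.
* The travel-time model ignores dispatch queueing, ambulance availability,
  traffic and time of day, as the original analysis also cautioned; the
  cost equation itself is a reconstruction.
* Significance tests between AUCs (the original quoted p-values without a
  stated test) are not reconstructed; the comparison reports CIs only.
* Single-site + block MCMC is adequate at the package's scales but is not
  a general-purpose sampler; very large lattices would warrant sparse
  linear algebra in the CAR updates.
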