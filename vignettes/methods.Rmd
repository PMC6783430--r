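---
title: "Methods: mapping ocean methane disequilibrium and estimating air-sea fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping ocean methane disequilibrium and estimating air-sea fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The estimation problem

Dissolved methane in the surface ocean is sampled only along ship tracks, yet
the quantity of interest — the global air–sea CH~4~ flux — is an integral over
the whole ocean surface at daily resolution. `oceanch4` implements the full
estimation chain for this problem:

1. **Disequilibrium.** Each shipboard measurement of dissolved methane
   `[CH4]` (nM) is converted to the methane disequilibrium
   $$\Delta\mathrm{CH_4} = [\mathrm{CH_4}] - S_{\mathrm{CH_4}}(T,S)\,
   p_{\mathrm{CH_4}}^{\mathrm{moist}},$$
   where $S_{\mathrm{CH_4}}$ is the atmospheric-equilibrium solubility as a
   function of temperature and salinity (`ch4_solubility()`, a
   Wiesenburg–Guinasso-form coefficient set returning nM per ppb) and
   $p^{\mathrm{moist}}$ is the dry-air partial pressure, kriged from a
   station network to the sample's position and year-month and reduced by the
   saturation water-vapor pressure over seawater (`moist_pch4()`).
   Positive $\Delta$CH~4~ is supersaturation driving outgassing; negative
   values (polar undersaturation) drive uptake.
2. **Climatology.** Mixed-layer records are binned by calendar month
   (regardless of year) onto a regular grid and averaged per cell
   (`bin_climatology()`), which suppresses the over-weighting of a few
   high-resolution cruise tracks.
3. **Mapping.** Ensembles of two model families — single-hidden-layer neural
   networks and regression forests — are trained to predict the
   IHS-transformed cell means from environmental predictor climatologies,
   and then evaluated over the full grid to produce continuous monthly
   $\Delta$CH~4~ maps (`generate_ensemble()`).
4. **Diffusive flux.** Each map enters the gas-transfer model
   $$F_{\mathrm{diff}} = (1 - \varepsilon_{\mathrm{ice}} f_{\mathrm{ice}})\,
   k(U_{10}, Sc)\, \Delta\mathrm{CH_4}$$
   at daily resolution, and a Monte-Carlo procedure propagates the spread
   among five wind products, three sea-ice products, four published
   wind-speed parameterizations of $k$, and an ice gas-exchange blocking
   efficiency $\varepsilon_{\mathrm{ice}} \in [0.9, 1]$
   (`monte_carlo_flux()`).
5. **Ebullition.** Bubble-mediated transfer from seafloor seeps is bounded by
   $$\Sigma F_{\mathrm{eb}} = \bar{\varepsilon}_{\mathrm{tr}}\,
   \Sigma F_{\mathrm{sf}},$$
   with the transfer efficiency $\varepsilon_{\mathrm{tr}}(d_0, z_0)$
   computed by a two-gas bubble dissolution model (`bubble_rise()`),
   integrated over a bubble size spectrum and over the hypsometry of the
   seep depth interval (`depth_averaged_efficiency()`).
6. **Attribution.** The mapped field is analysed for its drivers: a coastal
   power law of seafloor depth, an open-ocean linear relation to net primary
   production (NPP), an NPP + PO~4~ multiple regression, and
   latitudinal-band averages (`attribution_report()`).

The package ships a synthetic-world generator (`make_world()`,
`sample_observations()`) whose outputs have the statistical structure of the
real observing system, so the entire chain is testable end to end with a
known truth.

# The synthetic world

The world is a closed rectangular basin (default 40° of longitude by 140° of
latitude at 0.5° resolution; all knobs in `synth_config()`). Its four walls
play the role of coastlines. Design choices, in the order they matter:

**Bathymetry.** Depth increases monotonically (on average) with distance
from the nearest wall. The depth profile is the inverse of a target
hypsometric curve, so the four bathymetric region classes occupy prescribed
area fractions — near-shore (0–50 m) 3%, outer shelf (50–200 m) 4%,
continental slope (200–2000 m) 8%, open ocean 85% — the approximate area
structure of the real ocean. The minimum cell depth is 2 m: very shallow
near-shore cells carry a disproportionate share of bubble-mediated transfer,
and removing them would bias the depth-averaged transfer efficiency low.

**Truth field.** The $\Delta$CH~4~ truth is a deterministic skeleton —
$69\,z^{-0.8}$ nM in coastal waters, $(0.3\,\mathrm{NPP} + 14)/10^3$ nM in
the open ocean, blended smoothly over 1500–2500 m, with a small negative
patch south of 50°S — multiplied by mean-one lognormal heterogeneity. The
heterogeneity is the load-bearing part of the design: the real field
scatters by orders of magnitude around its depth/NPP relationships, and that
scatter is what makes statistical mapping both necessary and uncertain. Its
log-standard-deviation is 1.25 in coastal waters and 0.6 in the open ocean,
chosen so that depth alone explains ~55% of coastal log-log variance and NPP
~30% of open-ocean variance, while binned-mean fits of the two relationships
reach R² ≈ 0.9–0.97 — the statistical signature of the real database. Half
of the coastal heterogeneity log-variance (15% in the open ocean, where
secondary predictors add little explanatory power) is carried by latent
smooth surfaces that also appear as the anomaly texture of the PO~4~, O~2~
and SSS predictor fields, so a multi-predictor model can learn it; the rest
is a short-scale stationary field (white noise smoothed with a one-cell
Gaussian kernel on a padded grid) that no predictor explains.

Two numerical subtleties are worth recording. First, the free heterogeneity
field must have spatially uniform local variance: because it enters through
an exponential, any systematic variance structure (the spatially varying
local variance of a truncated Fourier series, or edge-variance inflation
from reflect-padding a smoothing kernel at the basin walls) converts into a
systematic multiplicative bias exactly along the coastline and corrupts the
depth power law. Second, the combined heterogeneity is residualized against
log-depth (linearly — the coastal relation is a log-log line) and against a
cubic in NPP (the open-ocean relation is fitted on linearly binned means, so
low-order curvature in the realized field would masquerade as slope) before
use; without this, predictor fields that are themselves depth- or
latitude-structured tilt the generating relationships.

**Observations.** Cruise tracks are persistent random walks entering the
basin near a random wall, with the calendar month advancing every 100
records (long cruises span seasons). The default is 8 tracks of 300 records:
the real database's size scaled by the ratio of grid cells between this
basin and a global 0.25° grid. This sparsity matters — with an order of
magnitude more synthetic data, ensemble members become nearly
interchangeable and mapping uncertainty collapses below gas-transfer
uncertainty, inverting the realistic uncertainty budget. Measurement noise
is mean-preserving multiplicative lognormal with sdlog 0.3 (the scale of
reported interlaboratory discrepancies, 25–50%). Configured fractions of
records fall below the mixed layer, outside the 1980–2016 station window, or
lack temperature/salinity, to exercise the filters.

**Atmosphere, winds, ice, bubbles.** Station dry pCH~4~ rises linearly from
~1650 to ~1850 ppb over 1980–2016 with a small meridional gradient and a
hemisphere-antiphased seasonal cycle. Five wind products share one base
field (westerly maxima, weak seasonality, a shared synoptic AR(1) daily
component) and differ by smooth multiplicative perturbations of scale 8%;
three ice products are clamped perturbations of a seasonal ice field
poleward of 60°. The bubble spectrum is a discrete lognormal volume-weight
distribution on 1–10 mm with ≥99% of volume between 2 and 8 mm and a
volume-weighted mean diameter of ~4 mm.

What the generator does **not** emulate: real coastline geometry, ocean
circulation and seasonality of the truth field, autocorrelated measurement
drift between laboratories, and the real products' shared large-scale biases.
Consequently, passing tests demonstrate that the estimation chain is
correct and well-calibrated *for data with this statistical structure*; they
do not validate the upstream data products themselves.

# Mapping models

Both families are trained per member on a random 70% row subset, with skill
evaluated on the held-out 30% in IHS space. The IHS transform
$\sinh^{-1}(x) = \ln(x + \sqrt{x^2 + 1})$ behaves like a log for large
arguments but is defined for negative disequilibrium.

* **ANN**: `nnet` with one hidden layer of 20 sigmoid units and a linear
  output. The regularized objective uses an L2 weight penalty (default
  `decay = 1e-2`; `select_decay()` grid-searches it on a validation split).
  A full evidence-maximizing Bayesian regularization is out of scope: the
  contract is regularized fitting at the stated topology.
* **RRF**: a bagged ensemble of CART regression trees (`randomForest` with
  `mtry = p`, i.e. no feature subsampling), each tree grown on an
  independent 70% subsample without replacement and capped at 101 terminal
  nodes — 100 splits per binary tree. We read the "maximum of 100 decision
  splits" as a per-tree bound.

Months enter as a cyclic sin/cos pair (a configuration switch, default on)
and seafloor depth is log10-transformed (its power-law role motivates this;
also a switch). Members whose held-out correlation does not exceed the
retention bar `skill_floor = 0.75` are discarded, counted, and replaced (up
to a 2× attempt budget); under the default conditions 0–3 of 16 members are
typically discarded. Overfitting behaviour is guarded by a test: growing the
hidden layer 5 → 20 → 80 units must keep improving training skill while
held-out skill plateaus.

Ordinary least-squares baselines (per-predictor simple regressions and a
full multiple regression) run under the same split protocol for comparison
only; on this world the nonlinear families beat them clearly, as they must
for a power-law-dominated field.

# Flux computation

Monthly fields are interpolated to days linearly between month centers with
wrap-around at the year boundary. Because the annual sum
$\sum_d k_d (1 - \varepsilon f_d) \Delta_d$ is linear in the monthly
$\Delta$CH~4~ map and in $\varepsilon$, the package precomputes per
(wind, ice, k-algorithm) permutation the two annual transfer fields
$A = \sum_d W_{dm} k_d$ and $B = \sum_d W_{dm} k_d f_d$
(`transfer_terms()`), after which every Monte-Carlo draw costs
O(cells × 12). This reformulation is exact — equality with the direct
365-day loop is unit-tested to 10⁻¹⁰ — and is what makes 1000-draw ensembles
interactive.

The four k algorithms are the published quadratic (0.251 u², 0.31 u²),
hybrid (0.222 u² + 0.333 u) and cubic (0.0283 u³) wind-speed relations, each
in cm hr⁻¹ at Sc = 660, normalized by (Sc/660)^(−1/2) with the CH~4~
Schmidt-number polynomial, and converted centrally to m day⁻¹. Their spread
exceeds 20% of their mean at 5–10 m s⁻¹ winds, which is the dominant
gas-transfer uncertainty. Unit conventions: $\Delta$CH~4~ in nM equals
µmol m⁻³, so k (m day⁻¹) × $\Delta$ (nM) × 10⁻³ gives mmol m⁻² day⁻¹;
annual regional integrals convert to Tg yr⁻¹ with a molar mass of
16.043 g mol⁻¹. $\varepsilon_{\mathrm{ice}}$ is drawn once per Monte-Carlo
member (not per cell), uniformly in [0.9, 1].

The variance partition follows the two-ensemble construction: all 60
wind × ice × k permutations applied to the ensemble-mean map (transfer
uncertainty), versus the permutation-mean transfer applied to each member
map (mapping uncertainty). Under the default conditions mapping uncertainty
dominates, and the near-shore class contributes both the largest share of
the mean flux and the largest share of its spread.

# Bubble model

`bubble_rise()` integrates a minimal two-gas bubble in depth: CH~4~ plus a
lumped N~2~/O~2~ "air" gas, in a constant-temperature (10 °C) water column
that is air-saturated and CH~4~-free. Gas exchange across the bubble wall
uses penetration-theory mass-transfer coefficients
$k_L = \tfrac{2}{\sqrt{\pi}}\sqrt{D w / d}$; rise velocity follows the
standard contaminated-bubble parameterization (Stokes-like below 1.4 mm
diameter, a 0.23 m s⁻¹ plateau across the mm range, a weak power law above
~10 mm); the bubble expands hydrostatically via the ideal gas law. Henry
constants carry van't Hoff temperature corrections. Integration uses
`deSolve::lsodar` with relative tolerance 10⁻⁸, a 0.5 m step cap, and a root
function that terminates when the bubble shrinks below 0.02 mm (fully
dissolved → zero transfer, not an error). A cumulative-dissolution state
variable makes mass conservation checkable to 10⁻⁶ relative.

This model is a re-implementation in spirit, not a bit-exact copy, of the
published seep-bubble models; the contract is a monotone,
mass-conserving efficiency surface with the right printed bounds. It
reproduces the key anchors: an 8 mm bubble released at 100 m loses >99% of
its CH~4~ (we compute 99.75%), and depth-averaging the spectrum-integrated
efficiency over the synthetic hypsometry gives ~13% for seeps uniform over
0–100 m and ~8% over 0–200 m — within a few percentage points of the 17%
and 11% reference values, with the correct ordering. The residual gap
traces to the synthetic basin's hypsometry within the shelf band, not to
the bubble physics. "Transfer to the atmosphere" is counted at the surface:
CH~4~ still in the bubble when it surfaces is assumed emitted.

The ebullition upscaling is interval arithmetic: efficiencies 11–17% on a seafloor flux of
35 Tg yr⁻¹ give 3.85–5.95 (≈4–6) Tg yr⁻¹; on 18–48 Tg yr⁻¹ they give
1.98–8.16 (≈2–8) Tg yr⁻¹, with uniform probability within the interval when
combined with the diffusive distribution (`total_emissions()`).

# Attribution

`powerlaw_fit()` bins observations into 12 log-spaced depth bins over
10–2000 m and fits log10(mean $\Delta$CH~4~) against log10(depth) by OLS;
`npp_fit()` does the linear analogue over NPP bins. Binned arithmetic means
carry a small within-bin discretization (Jensen) term, so even noiseless
power-law input is recovered only to ~10⁻³ in the exponent — the tests
document this rather than pretending exactness. Non-positive $\Delta$CH~4~
values are excluded from log fits and counted. The NPP+PO~4~ multiple
regression runs unbinned on open-ocean cells and flags |r| > 0.99
collinearity. Latitudinal bands use fixed cuts at 23°, 45° and 60°. The DMS
predictor is an independent noise field by construction, so its expected
correlation with $\Delta$CH~4~ is nil — a deliberate negative control.

# Kriging and other numerical choices

* Ordinary kriging of station pCH~4~ uses an exponential covariance with a
  3000 km range and zero nugget (atmospheric CH~4~ is smooth at monthly
  scale; exactness at stations is the binding contract), great-circle
  distances, and a degenerate-case rule that a single reporting station
  yields a constant field. The mixed-layer-depth interpolation is in space
  and month.
* Grid edges are half-open [lo, hi); longitudes live in [−180, 180); cell
  areas are exact spherical-zone areas.
* Cell means are arithmetic means of raw $\Delta$CH~4~; the IHS transform is
  applied only for training.
* Taylor statistics use population moments throughout so the identity
  cRMSD² = s_p² + s_o² − 2 s_p s_o R holds exactly.
* Per-stage seeds derive from the master seed by hashing stage names, so no
  stage's draw count can perturb another's stream; everything is
  reproducible from one integer.
* Atmospheric pressure is fixed at 1 atm in the moist correction (no
  sea-level-pressure field); records without temperature are rejected unless
  their source is on an explicit allow-list, in which case temperature is
  filled from the SST climatology and flagged.

# Problem sizes and runtime

The default configuration (0.5° grid, 22 400 cells, 2400 observations,
~2000 gridded cell-months) trains a member in under a second; 100 members
per family plus 1000 Monte-Carlo draws complete in a few minutes on one CPU,
with the transfer-term precomputation (~1 minute) amortized across all
draws. The test suite runs reduced configurations (2° grid, handfuls of
members) and completes in about two minutes.

# Known limitations

* The synthetic world's heterogeneity is stationary and seasonal-free; real
  $\Delta$CH~4~ has seasonally varying sources the monthly climatology only
  partially captures.
* The bubble model's environment is idealized (constant temperature, zero
  ambient CH~4~, clean-bubble mass transfer with dirty-bubble rise
  velocity); site-specific seep dynamics, hydrate skins and water-column
  oxidation are out of scope.
* The depth-averaged transfer efficiencies depend on the hypsometry supplied;
  the synthetic basin's shelf hypsometry is stylized, and real-world use
  should pass an observed area-depth table to
  `depth_averaged_efficiency()`.
* Attribution stops at correlation; the package makes no causal claims about
  methane production pathways.
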