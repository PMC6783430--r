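# oceanch4

Estimating oceanic methane emissions from sparse shipboard observations.

The ocean is one of the most uncertain terms in the natural atmospheric
CH₄ budget, because dissolved methane is measured only along scattered
cruise tracks while the emission is an integral over the whole ocean
surface. `oceanch4` implements the complete estimation chain for this
problem and a synthetic observing system to validate it against a known
truth.

## What the package computes

**Methane disequilibrium.** Each measurement of dissolved methane is
converted to the air–sea disequilibrium

&nbsp;&nbsp;&nbsp;&nbsp;ΔCH₄ = [CH₄] − S(T, S) · p<sub>CH₄</sub><sup>moist</sup>,

with the solubility S from the Wiesenburg–Guinasso atmospheric-equilibrium
form and dry-air pCH₄ kriged from a monitoring-station network and corrected
for water vapor. Records are filtered to the mixed layer and binned into a
monthly gridded climatology.

**Ensemble mapping.** Two model families — single-hidden-layer neural
networks (20 sigmoid units, L2-regularized) and regression forests (bagged
CART trees, ≤100 splits each) — are trained on the inverse-hyperbolic-sine
transformed climatology against environmental predictors (seafloor depth,
SST, SSS, NPP, POC export, PO₄, subsurface O₂, hydrate inventory), each
member on its own random 70/30 split. The ensemble of back-transformed
monthly maps carries the mapping uncertainty.

**Diffusive flux with uncertainty propagation.** Each map enters

&nbsp;&nbsp;&nbsp;&nbsp;F<sub>diff</sub> = (1 − ε<sub>ice</sub> f<sub>ice</sub>) · k(U₁₀, Sc) · ΔCH₄

at daily resolution. A Monte-Carlo procedure draws among five wind products,
three sea-ice products, four published k(U₁₀) algorithms (which diverge by
>20% at 5–10 m s⁻¹) and ε<sub>ice</sub> ∈ [0.9, 1], integrating annual
emissions over four bathymetric regions (near-shore, shelf, slope, open
ocean) and globally, in Tg CH₄ yr⁻¹.

**Ebullition.** A two-gas bubble dissolution model gives the fraction of
seafloor bubble CH₄ surviving to the surface as a function of diameter and
release depth; integrated over a 2–8 mm bubble spectrum and the shelf
hypsometry, it bounds atmospheric ebullitive emissions through
ΣF<sub>eb</sub> = ε̄<sub>tr</sub> · ΣF<sub>sf</sub>, and combines them with
the diffusive distribution for total emissions.

**Attribution.** The mapped field is analysed for its drivers: a coastal
power law of seafloor depth (ΔCH₄ = A·z<sup>b</sup>), an open-ocean linear
relation to net primary production, an NPP + PO₄ multiple regression, and
latitudinal-band averages.

## Worked example

The synthetic world is a closed basin whose truth field follows the coastal
power law 69·z⁻⁰·⁸ nM and the open-ocean relation (0.3·NPP + 14)/10³ nM,
wrapped in realistic order-of-magnitude heterogeneity, and observed by
sparse cruise tracks:

```r
library(oceanch4)
cfg <- synth_config(resolution_deg = 1, seed = 7)
res <- run_pipeline(cfg, n_members = 20, n_draws = 500)
print(res)
```

```
och4_pipeline run
Diffusive CH4 emissions (Tg yr^-1), pooled ensemble:
  nearshore   0.138 +/- 0.060  (10-90%: 0.077 to 0.225)
  shelf       0.044 +/- 0.018  (10-90%: 0.024 to 0.071)
  slope       0.020 +/- 0.006  (10-90%: 0.013 to 0.029)
  open        0.108 +/- 0.022  (10-90%: 0.076 to 0.133)
  global      0.309 +/- 0.092  (10-90%: 0.192 to 0.436)
Ebullitive transfer efficiency range: 8.2% to 13.1%
Ebullitive emissions interval: 2.88 to 4.60 Tg yr^-1
Total emissions: mean 4.05, 10-90%: 3.36 to 4.74 Tg yr^-1
Coastal power law: dCH4 = 76.8 depth^-0.792 (R2 = 0.97)
Open-ocean NPP fit: dCH4 = (0.272 NPP + 31.7)/10^3 (R2 = 0.95)
```

Reading the output: the near-shore class (3% of the basin's area) emits as
much as the open ocean (85% of it) and carries the widest spread — the
hallmark of a coastally dominated, mapping-limited flux estimate. The
attribution fits recover the embedded power-law exponent (−0.79 vs the
generating −0.8) and NPP slope (0.27 vs 0.3) from the noisy mapped field.
The 10–90th percentile interval of an ensemble is its "likely range"
throughout. Absolute magnitudes scale with the basin's area, which is a few
percent of the real ocean's.

A thin command-line wrapper is installed with the package
(`inst/scripts/och4`) with subcommands `synthgen`, `climatology`, `train`,
`flux`, `ebullition`, `attribute` and `run`:

```sh
Rscript inst/scripts/och4 run --seed 42 --outdir out/
```

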