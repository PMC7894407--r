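---
title: "Methods: leaf-to-global exchange of isoprene oxidation products"
author: "ovocflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf-to-global exchange of isoprene oxidation products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovocflux)
```

## The problem

Isoprene, the dominant biogenic volatile organic compound, is oxidised in
the atmosphere within hours. Under low-NOx conditions the main product is
the hydroperoxide 1,2-ISOPOOH; under high-NOx conditions, the carbonyls
MVK and MACR. Both 1,2-ISOPOOH and MVK deposit rapidly into leaves, where
1,2-ISOPOOH decomposes to the cytotoxic MVK (plus HCHO) and MVK is
enzymatically reduced by the NADPH-dependent alkenal/one oxidoreductase
(AOR) to the far less toxic MEK, which — being only weakly soluble — is
re-emitted. `ovocflux` implements every quantitative stage of that chain:

1. **Enclosure mass balance** — exchange fluxes, deposition velocities
   ($v_d = -\Phi/c$) and molar conversion yields from
   inlet/background/plant outlet mixing-ratio series.
2. **Enzyme kinetics** — two-substrate Michaelis–Menten forward model and
   initial-slope fitting of A340 assay traces.
3. **Leaf box model** — a mechanistic chamber-gas + apoplast-liquid model
   of uptake, conversion and re-emission, calibrated to the measured
   exchange quantities.
4. **Dry deposition** — a Wesely-type resistance-in-series calculator
   with $H^*$/$f_0$ scaling and the measured land day/night constants.
5. **Eddy covariance** — despiking, lag determination and block-averaged
   covariance fluxes from 10-Hz series, with emission-ratio summaries.
6. **Global budget** — molar closure converting deposited MVK and
   1,2-ISOPOOH masses to an MEK source and an isoprene-recycling
   fraction.
7. **Synthetic data** — generators with prescribed ground truth for each
   stage, so the whole pipeline is testable end to end without any
   external data.

## Enclosure mass balance

The enclosure is treated as a single well-mixed compartment,
$$V \frac{dc}{dt} = Q (c_{in} - c) - (k_{bg} + v_d A)\, c,$$
with through-flow $Q$, single-sided leaf area $A$, a small residual wall
sink $k_{bg}$ of the conditioned empty chamber, and deposition velocity
$v_d$. The estimator works on quasi-steady phase means: the flux is the
difference in outlet molar flow between the planted and the empty
enclosure per leaf area,
$$\Phi = \frac{(\chi_{out} - \chi_{out,BG})\cdot 10^{-9}\, pQ/(RT)}{A},$$
so deposition gives $\Phi < 0$, and $v_d = -\Phi / c$ with $c$ the
plant-phase outlet concentration. Conversion yields are ratios of product
emission to parent deposition molar fluxes, per light condition, and are
scale-invariant in the mixing ratios. Uncertainties are replicate
standard deviations (default $N = 5$), matching the box-plot convention
(`summarize_boxstats()`, linear-interpolation quartiles).

The generator uses the analytic steady state of the same ODE per phase,
which makes the estimator-generator pair exactly consistent at zero
noise; the chamber volume only sets the (unrecorded) equilibration
transient. Noise is multiplicative lognormal with unit mean
(instrument-like, default CV 2%); the residual wall sink defaults to
0.5% of the through-flow — small and nonzero, as after surface
conditioning. Background correction subtracts molar flows, not raw
mixing ratios, so runs with different flows remain comparable.

Default study conditions: ~8 ppbv 1,2-ISOPOOH inlet, 20 L min$^{-1}$
flow, 0.1 m$^2$ leaf area, 45 L chamber, prescribed
$v_d$ = 0.79/0.12 cm s$^{-1}$ (day/night), yields 0.5/0.5 to MVK/MEK,
five replicates.

## Enzyme kinetics

The AOR velocity is the multiplicative two-substrate form
$$v = V_{max}\, \frac{S}{K_m^{MVK} + S}\, \frac{N}{K_m^{NADPH} + N}\, g(T),$$
with $g(T)$ a Gaussian in temperature normalised to 1 at the optimum
(default width 10 °C). A single-optimum response is the minimal shape
consistent with a reported optimum; it is isolated in one internal
function so a different response can be swapped in. Whether the enzyme
follows an ordered bi-bi mechanism rather than the multiplicative form is
not resolvable from initial-rate grids alone; the multiplicative form
reproduces all the quantities of interest.

Assay traces are fitted on initial slopes ($dA_{340}/dt =
-\varepsilon \ell v$, $\varepsilon$ = 6.22 AU mM$^{-1}$ cm$^{-1}$)
rather than full progress curves, matching the assay design and avoiding
substrate-depletion modelling. The fit is nonlinear least squares
(`minpack.lm::nlsLM`, bounded below at zero); the temperature parameters
are only fitted when the design spans at least three temperatures,
otherwise $g(T)$ is a constant absorbed into $V_{max}$. Reference values:
$K_m$ = 14.15 mM (MVK) and 0.049 mM (NADPH), optimum 35 °C; the working
assay runs NADPH at three times its $K_m$, i.e. 0.15 mM
(`recommended_assay_concentration()`).

## Leaf box model

Two compartments: chamber gas and apoplast liquid (no explicit
mesophyll/cytosol — the observations resolve no finer structure, and the
AOR step acts on the dissolved MVK pool directly). Gas species
(1,2-ISOPOOH, MVK, MEK) exchange through the parallel stomatal +
cuticular conductance $g = g_s + g_{cut}$ against the Henry-equilibrium
concentration $C_{eq} = c_{aq}/H^*$ (ideal-gas conversions explicit). In
the liquid, ISOPOOH decomposes at the first-order Fenton-type rate
$k_f$ into MVK + HCHO (1:1:1), and AOR reduces MVK to MEK with the
kinetics above; the NADPH pool is held constant per light state (zero in
the dark, so the AOR step switches off), not dynamically depleted. HCHO
is retained entirely in the liquid (very high effective solubility; no
HCHO emission is modelled). Integration uses `deSolve::lsoda` with
relative tolerance $10^{-8}$ and absolute $10^{-12}$ — the $H^*$ ratio
of $1.7\times10^6$ (ISOPOOH) to 44 (MVK) makes the system stiff.

Because the Fenton step turns one mole into two, plain molar totals are
not conserved; carbon is (5 C ISOPOOH $\to$ 4 C MVK + 1 C HCHO; 4 C MVK
$\to$ 4 C MEK). `leafbox_carbon_inventory()` audits gas + liquid +
net-through-flow carbon and closes to better than $10^{-6}$ relative on
every run.

The 50/50 ISOPOOH-to-MVK/MEK split is encoded as kinetic competition
between MVK volatilisation and AOR reduction, not as a branching
chemical step — the data cannot distinguish the two, and competition is
the mechanism that responds to light, temperature and NADPH the way the
observations suggest. A consequence worth noting: in an MVK fumigation
at steady state, the net MVK uptake equals the AOR throughput exactly,
so the MVK-to-MEK yield is structurally 1 — matching the complete
conversion observed.

`calibrate_leafbox()` solves the inverse problem over the four measured
targets (day/night $v_d$, MVK and MEK yields) with Nelder–Mead on the
log of the free parameters ($g_{s,day}$, $g_{cut}$, $k_f$,
$V_{max}$), evaluating each candidate through the full
simulate-then-estimate pipeline (two 7200-s phases, the final 20%
sampled). Identifiability is partial by design — $k_f$ mainly sets the
transient — so the contract is recovery of the forward targets, not of
the parameters. The apoplast volume per leaf area (default
0.05 L m$^{-2}$) is a configured assumption; calibration absorbs it (a
different volume rescales $k_f$ and $V_{max}$ at fixed targets), which
is why no target is built on those two parameters individually.

The optional stress feature closes stomata smoothly toward a residual
floor once the *accumulated* apoplast ISOPOOH dose (mM s) passes a
threshold; a dose, rather than the instantaneous concentration, is used
because oxidative damage integrates and closure is not observed to
revert when the load falls. With the feature on, the simulated outlet
mixing ratio dips during uptake and then rises upon closure — the
qualitative pattern seen in elevated-fumigation experiments.

## Dry deposition

`surface_resistance()` scales base resistances with the standard
solubility-reactivity factors: mesophyll
$r_m = 1/(H^*/3000 + 100 f_0)$, cuticle
$r_{lu} = r_{lu,base}/(10^{-5} H^* + f_0)$, and lower-canopy and ground
resistances with the same $(10^{-5}H^* + f_0)$ factor (the detailed
land-type tables are deliberately out of scope: the budget stage
consumes deposition totals, so base resistances come in per call). The
stomatal resistance is scaled by $\sqrt{M/18}$ (molecular diffusivity).
`total_vd()` combines the branches in parallel, reports
$v_d = 1/(r_a + r_b + r_c)$ in cm s$^{-1}$, flags the
no-surface-pathway case instead of raising, and returns the stomatal
fraction diagnostic. For ISOPOOH ($H^* = 1.7\times10^6$, $f_0 = 1$)
$r_m \approx 0.0015$ s m$^{-1}$ — effectively no residual resistance
once a molecule is inside.

`prescribed_vd()` returns the measured land constants — 0.79 (0.12)
cm s$^{-1}$ for 1,2-ISOPOOH and 0.22 (0.044) for MVK, day (night) —
and, over the ocean, a delegation marker rather than a number: the
caller must fall back to the resistance scheme there. Day/night
classification is a boolean input; the prescription is binary, so no
radiation dependence is modelled.

## Eddy covariance

Windows default to 30 min. Per window: MAD despiking (threshold 6, block
windows of 600 samples; a zero MAD flags nothing), lag determination by
maximising $|$cross-covariance$|$ over $\pm$`max_lag` samples (ties to
the smallest lag; significance judged against the off-peak spread of
the cross-covariance function), block-mean detrending (the simplest
defensible choice; linear detrending and recursive filters are
deliberately not layered in), and
$F = \overline{w'c'}\, p/(RT)$ converting ppbv m s$^{-1}$ to
nmol m$^{-2}$ s$^{-1}$. No WPL/density or spectral-loss corrections and
no coordinate rotation are applied. Emission ratios are ratios of
window-mean fluxes in percent, with a delta-method uncertainty from the
window-to-window spread.

The wind generator is AR(1) with coefficient 0.95 at 10 Hz and exact
stationary SD — enough structure for covariance/lag recovery, not a
realistic turbulence spectrum; scalar series embed the prescribed flux
through the exact covariance construction plus additive noise. Reference
scenarios: isoprene fluxes of about 10 and 1 nmol m$^{-2}$ s$^{-1}$
with MEK/isoprene ratios of 0.9% and 1.8%.

## Global budget

Molar accounting: deposited mass over parent molar mass, times the
molar yield, re-massed as MEK,
$$S_{MEK} = \left(\frac{D_{MVK}}{70.09} \cdot 1.0 +
\frac{D_{ISOPOOH}}{118.13} \cdot 0.5\right) \times 72.11 .$$
With $D$ = 3.7 and 8.8 Tg yr$^{-1}$ this gives 3.81 + 2.69 = 6.49
$\approx$ 6.5 Tg yr$^{-1}$; a mass-basis bookkeeping would give 8.1 and
is therefore not used, but both isoprene-fraction bases are always
reported (molar: 1.47% $\approx$ 1.5% of a 416 Tg yr$^{-1}$ isoprene
source; mass: 1.56%) so the basis is never implicit. The gridded route
(`grid_budget()`) applies the same conversion cellwise and equals the
scalar result by linearity. Lower/upper-bound scenarios take their own
deposition totals as inputs (`scenario_bounds()`); the bounding totals
are not derivable from the central numbers, so no default is invented
for them.

## What the synthetic data do and do not show

The generators emulate the *statistical structure the estimators
assume*: well-mixed steady states with lognormal instrument noise,
AR(1) wind with an embedded covariance and lag, linear initial-rate
assay segments with additive noise, nonnegative deposition fields with
exact totals. Passing recovery tests therefore demonstrates estimator
correctness and calibration identifiability — not that real enclosures
are perfectly mixed, real turbulence is AR(1), or real assays are free
of substrate depletion. Deviations of that kind (chamber mixing
gradients, low-frequency flux loss, progress-curve curvature) are
exactly what the tests cannot detect, and results on real data inherit
those assumptions.

## Numerical choices and limitations

* Problem sizes used in the shipped tests and acceptance script: five
  replicates and 30 samples per enclosure phase; 50 thirty-minute EC
  windows at 10 Hz per scenario; 30-trace assay grids; 7200-s leaf-box
  phases at 60–120 s output steps — sizes a single desktop core handles
  in seconds while leaving estimator noise well inside the tolerances
  tested.
* Quantiles use linear interpolation (R type 7) throughout.
* The calibration objective is the summed squared relative target
  mismatch; log-parameterisation keeps the search positive without
  constraints.
* Negative integrator states abort with an error rather than being
  clamped.
* Out of scope by design: chemistry-transport modelling (deposition
  totals are inputs), stomatal-conductance retrieval from H2O exchange,
  inhibition/pH kinetics, aerosol and wet deposition, storage and
  footprint terms in the EC stack.
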