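---
title: "Modelling gold-nanoparticle radiosensitization with dose-enhancement kernels and the local effect model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling gold-nanoparticle radiosensitization with dose-enhancement kernels and the local effect model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanolem)
```

## The problem

Gold nanoparticles (AuNPs) taken up by tumour cells locally amplify the dose
deposited by an X-ray beam: photoelectric and Auger interactions in the
high-Z gold release showers of short-range secondary electrons, producing
dose "spikes" within nanometres to micrometres of each particle. Under
clinical megavoltage (MV) beams this effect is weak on a macroscopic scale
but still measurable in clonogenic assays, because MV beams carry a small
low-energy photon component that grows with depth as the beam hardens and
scatters. `nanolem` implements the computational chain that connects a
nanoscale description of this enhancement to a prediction of cell survival:

1. **DER kernel** — a radial *dose enhancement ratio* around a single
   nanoparticle, the ratio of dose with a gold particle present to the dose
   with a same-sized water particle, tabulated on spherical shells measured
   from the particle surface.
2. **Cell model** — a 2-D cell (13.5 µm) with concentric nucleus (8 µm) in a
   17.5 µm square of extracellular matrix (ECM), loaded with point
   nanoparticles under either a *homogeneous* biodistribution (anywhere in
   the model, nucleus included) or a *cytoplasm* biodistribution (uniform by
   area over the annulus between nucleus and membrane, matching what
   electron microscopy shows for receptor-internalized particles).
3. **Local effect model (LEM)** — equal local dose causes equal local
   damage. The expected number of lethal events is the average of
   $-\ln S_x(D(x))$ over the nucleus, where $S_x$ is the (threshold)
   linear-quadratic response measured without nanoparticles, and survival is
   $S = e^{-\bar N}$.
4. **SER statistics** — survival curves are reduced to the mean inactivation
   dose $\mathrm{MID} = \int_0^\infty S(D)\,dD$ and compared through the
   sensitization enhancement ratio
   $\mathrm{SER} = \mathrm{MID}_{IR} / \mathrm{MID}_{IR+AuNP}$.

A synthetic-data module generates every input the pipeline needs — kernels,
paired radial dose tables, MV-like particle spectra, clonogenic colony
counts — with known ground truth, so the whole chain is testable without a
particle-transport code.

## The DER kernel and its normalization

The enhancement ratio in shell $r$ is

$$\mathrm{DER}(r) =
  \frac{D_{AuNP}(r)\, f_1\, f_{2,AuNP} + D_{bg}}
       {D_{WNP}(r)\, f_1\, f_{2,WNP} + D_{bg}},$$

where the $f$ factors are phase-space resampling ratios (samples drawn over
particles contained, and secondaries scored over samples drawn) that put the
gold and water tables on a common fluence scale, and $D_{bg}$ is the dose
the primary beam deposits in the nanoparticle volume itself. The background
dose anchors the far field: as $D_{bg}$ dominates, $\mathrm{DER}\to 1$.
A zero background is accepted with a warning, because the ratio then
degenerates to a pure secondary-dose ratio that need not approach 1.

The standard scoring grid is 200 shells of 1 nm followed by 200 shells of
50 nm (outer radius 10.2 µm), radii measured from the particle *surface*.
Per-shell doses are treated as shell-averaged values; kernel lookup is
piecewise constant on the shells (linear interpolation between midpoints is
available as an option), queries inside the first shell clamp to its value,
and queries beyond the support return exactly 1.

Spectrum bookkeeping follows the same phase-space conventions: oblique
particles are collapsed onto the beam axis by weight multiplication with
$1/\cos\theta$, with backward-going records dropped (the forward
reweighting is the only behaviour the underlying convention defines), and
beam-quality summaries use weighted means and a linearly interpolated
weighted median so that equal weights reduce to the ordinary median.

## Microdosimetry in the cell model

The nucleus is the sensitive region. A prescribed uniform base dose $D_0$
(2–8 Gy) is perturbed by the kernels of all placed nanoparticles. Because
physical dose is additive, overlapping kernels combine by **additive
excess**,

$$D(x) = D_0 \Big(1 + \sum_i \big(\mathrm{DER}(r_i) - 1\big)\Big),$$

with $r_i$ the distance from $x$ to particle $i$'s surface (clamped at 0).
A literal multiplicative rule $D_0 \prod_i \mathrm{DER}(r_i)$ is retained as
an option for sensitivity analysis, but it diverges when thousands of
kernels overlap and is not the default. The enhancement field
$D(x)/D_0$ does not depend on $D_0$, so each placement's field is computed
once and reused across all doses — this is what makes replicated curves
cheap.

$\bar N$ is estimated by Monte Carlo: i.i.d. uniform points in the nucleus
disc (inverse-CDF in $r^2$), with the standard error of the mean reported.
When the local dose is constant (no particles, or a unit kernel) the
estimate is exact with zero variance. The kernel spans nanometres to
micrometres, which is why a deterministic uniform grid fine enough for the
near field is impractical; the seeded stochastic integrator with a reported
standard error is the default throughout.

### Threshold form of the local response

The threshold LQ response is
$\ln S_x(D) = -\alpha D - \beta D^2$ for $D \le D_t$ and, beyond the
threshold, a linear tail of slope $S_{max} = \alpha + 2\beta D_t$ — the LQ
slope at $D_t$ — so the response is value- and slope-continuous and kills
*less* at high dose than the extrapolated LQ parabola, which is the
motivation for using a threshold at all. A variant that literally adds
$+S_{max}(D - D_t)$ to the LQ exponent is available as
`form = "as_printed"`; its tail curvature cancels the $S_{max}$ slope at
$D_t$, so it is offered only for sensitivity analysis. No default value of
$D_t$ is assumed: unset means pure LQ, and any thresholded analysis must
set it explicitly.

## Survival statistics

Plating efficiency is colonies over cells seeded; survival fraction is the
PE ratio against unirradiated controls, with first-order error propagation.
LQ fitting runs on $\ln SF$ (variance-stabilized, matching the LQ
exponent) by generalized least squares, with $\alpha$ and $\beta$
constrained non-negative — a negative $\beta$ makes the MID integral
divergent, and the two-parameter non-negative problem is solved exactly by
pinning a violated coefficient at zero. Every survival fraction shares the
*same* control plating efficiency, so the control's error is perfectly
correlated across dose points; the fit models it as an equicorrelated
covariance component on top of the per-point errors. Treating the points
as independent instead makes the intervals anti-conservative —
calibration simulations under the package's own generator put the nominal
95 % interval near 89 % coverage for the independent model and 92–94 %
for the correlated one. Confidence intervals use the residual-rescaled
parameter covariance with a $t$ reference on $n-2$ degrees of freedom.

The MID has a closed form for pure LQ,
$\sqrt{\pi/(4\beta)}\; e^{\alpha^2/(4\beta)}\,
\mathrm{erfc}\!\big(\alpha/(2\sqrt\beta)\big)$, evaluated through the
scaled complementary error function to avoid overflow at small $\beta$; it
is cross-checked against adaptive quadrature to $10^{-8}$ relative error in
the test suite. A trapezoid method integrates measured curves over their
dose range only (a documented truncation). SER uncertainty, when requested,
comes from a seeded parametric bootstrap (2000 draws by default) of the two
LQ fits' covariances, since no analytic form is standard for a ratio of
MIDs.

## The synthetic generators and what they do (and do not) emulate

* `gen_kernel()` produces the family
  $\mathrm{DER}(r) = 1 + (\mathrm{DER}_{max}-1)\,
  \big(r_{1/2}/(r_{1/2}+r)\big)^p$ with defaults $r_{1/2} = 20$ nm and
  $p = 1.5$. The depth presets `depth2.5` … `depth30` anchor the peak
  enhancement to the series 5.5, 7, 7.5, 8 observed for a 6 MV beam at
  2.5–30 cm depth. The *shape* parameters are declared package choices, not
  transport-derived: the power-law tail is heavier than transport-code
  kernels, so the synthetic family over-weights the far field and absolute
  SER values computed from it exceed transport-based values at equal
  particle counts. Orderings — across depth presets, particle loads and
  placement modes — are preserved, and those orderings are what the test
  suite asserts; absolute SERs from synthetic kernels should not be read as
  predictions.
* `gen_radial_dose()` inverts the DER definition algebraically, so the
  round trip through `compute_der()` is exact to machine precision at zero
  noise; multiplicative lognormal noise (unit mean) models counting scatter.
* `gen_spectrum()` mixes a lognormal MV photon component with a uniform
  sub-100-keV component and labels electrons at a target rate. It matches a
  target mean energy, low-energy fraction and electron fraction as $n$
  grows; it does not reproduce spectral lines (e.g. gold K-fluorescence) or
  the true MV spectral shape, so only the summary statistics are meaningful.
* `gen_clonogenic()` draws colony counts as
  $\mathrm{Binomial}(n_{seeded},\, pe_0 \cdot S_x(D))$ — binomial rather
  than Poisson so counts can never exceed seeding. The default seeding
  ladder escalates 4-fold per dose level (200 at control up to the highest
  dose), standard clonogenic practice that keeps the expected colony count
  well away from zero at 8 Gy; a flat seeding number is a valid argument
  but produces uncountable (zero-colony) dishes at high dose for realistic
  LQ parameters.

Passing tests on these generators demonstrate the *pipeline's* correctness
— normalization algebra, integration, fitting, ratio statistics — not the
fidelity of any transport physics, which is outside this package's scope.

## Mapping a per-cell load to the 2-D model

A measured load of ~10 pg of gold per cell corresponds to ≈ 292,900
particles of 15 nm (gold density 19.32 g/cm³; both densities are
configurable defaults, not measured quantities). How many of those belong
in a 2-D section is a modelling convention, not a measurement; the pipeline
therefore takes an explicit 2-D `count`, and the converters expose a
`slice_fraction` (default 1.0). Analyses in this package use
`slice_fraction = 0.005`, the fraction of a 13.5 µm cell contained in a
~70 nm section — the thickness of a typical TEM slice, which is also the
observation that motivates the cytoplasm biodistribution. The 2-D model is
used under the assumption that the planar particle distribution is similar
to the 3-D one; local doses are evaluated only at nucleus points, the
declared sensitive region.

## Numerical and design choices

* All stochastic stages take explicit integer seeds; replicate sub-seeds
  are derived deterministically from the master seed, and generator
  functions restore the caller's RNG state.
* Kernel radii are in nm, cell coordinates in µm, energies in MeV, doses in
  Gy; file formats carry unit-suffixed column names to prevent silent unit
  drift, and unknown configuration keys are rejected.
* The background dose is accepted in Gy on the same batch scale as the
  radial dose tables; no per-history rescaling is applied (the convention
  the tables are produced under is the caller's responsibility).
* Spectra may contain photons and electrons; kernel-source filtering by
  particle type is left to the caller since the conventions differ between
  transport setups.
* Degenerate inputs fail loudly: empty grids, zero phase-space counts, a
  zero denominator in any DER shell (reported with its shell index), fewer
  than three distinct doses in an LQ fit, all-equal survival fractions, and
  non-positive MIDs in an SER all raise errors; `d_bg = 0`, zero-colony
  groups and colonies exceeding seeding warn instead.

### Problem sizes used in the shipped analyses

The test suite and the acceptance script run the LEM pipeline at 300–1465
nanoparticles per placement, 500–1500 nucleus integration points, 3–50
replicate placements, and 200–500 simulated assays for coverage — sizes at
which the Monte Carlo standard errors are small relative to every asserted
difference, chosen so the full analysis re-runs in minutes on a single
core. Larger placements and point counts scale linearly and are entirely
driven by the `count`, `n_points` and `replicates` arguments.

## Known limitations

* 2-D geometry only; no 3-D cell models or empirically mapped particle
  positions.
* No particle transport: kernels come from files or the synthetic family.
* No repair kinetics, track structure, or reactive-oxygen chemistry — the
  LEM here is purely dosimetric, which makes its predictions conservative
  where chemical amplification matters.
* Point nanoparticles: no excluded volume or clustering, hence no
  self-shielding of clustered particles.
* SER uncertainties propagate fit covariance only, not systematic kernel or
  placement-model uncertainty.
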