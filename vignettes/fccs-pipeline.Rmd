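---
title: "Quantifying cytoplasmic protein concentrations and interactions by FCS/FCCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytoplasmic protein concentrations and interactions by FCS/FCCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`fccstools` implements a complete analysis chain for single-point,
two-channel fluorescence correlation spectroscopy (FCS) and dual-color
fluorescence cross-correlation spectroscopy (FCCS) of cytoplasmic
proteins, together with a Brownian-dynamics photon-trace simulator that
provides ground truth for every stage. The pipeline reproduces the kind
of single-cell screen in which fluorescently tagged proteins (e.g.
3myeGFP / 3mCherry fusions of yeast endocytic proteins) are measured one
cell at a time for tens of seconds, and each acquisition is reduced to a
small set of physical quantities: cytoplasmic concentration, diffusion
coefficient, molecular brightness (counts per particle per second,
cpps), the concentration of double-labeled complexes, and an apparent
dissociation constant for each tested protein pair. Per-strain
aggregates of these quantities form a quantitative interaction network.

# The measurement model

## Correlation functions

The detected intensity in channel $i$ is $F_i(t)$; its fluctuation about
the time average is $\delta F_i(t) = F_i(t) - \langle F_i \rangle$. All
inference starts from

$$G_{ij}(\tau) = \frac{\langle \delta F_i(t)\, \delta F_j(t+\tau)\rangle}
                      {\langle F_i\rangle \langle F_j\rangle},$$

with $i=j$ for the green and red autocorrelations and $i \ne j$ for the
cross-correlation. Normalizing by the mean intensities makes the
amplitude independent of laser power and detection efficiency.

## Diffusion model with photophysics

A single diffusing component in a 3D-Gaussian observation volume
(lateral $1/e^2$ radius $w_{xy}$, axial radius $w_z = \kappa w_{xy}$),
with a fast reversible dark state ("triplet-like" blinking, fraction
$\Theta$, lifetime $\tau_T$), is fitted as

$$G(\tau) = G_\infty + \frac{1}{N}
  \left[1 + \frac{\Theta}{1-\Theta} e^{-\tau/\tau_T}\right]
  \left(1 + \left(\tfrac{\tau}{\tau_D}\right)^{\alpha}\right)^{-1}
  \left(1 + \kappa^{-2}\left(\tfrac{\tau}{\tau_D}\right)^{\alpha}\right)^{-1/2}.$$

$N$ is the mean number of fluorescent particles in the effective volume
$V_\mathrm{eff} = \pi^{3/2} w_{xy}^2 w_z$; the amplitude identity
$G(0^+) = 1/N$ (after separating the triplet factor) converts amplitudes
into concentrations, $C = N / (V_\mathrm{eff} N_A)$. Reference dyes are
fitted with free diffusion ($\alpha = 1$); in vivo curves use the
anomalous model with $\alpha \in (0, 1]$ because crowded cytoplasm
subdiffuses. The diffusion coefficient follows from the focal dwell
time, $D = w_{xy}^2 / (4 \tau_D)$, and the molecular brightness from
$\mathrm{cpps} = (\langle F\rangle - B)/N$.

## Corrections

Three instrumental effects are corrected in a fixed order, each an exact
identity at its neutral value:

1. **Background** $B$ (measured in unlabeled cells) carries no
   correlation but dilutes the relative fluctuations:
   $N_\mathrm{corr} = N\,((F-B)/F)^2$, applied as an amplitude rescaling
   together with rate subtraction.
2. **Spectral crosstalk**: a fraction $\beta$ of the green molecular
   signal reaches the red detector, creating false cross-correlation.
   The correction inverts the bleed-through algebra exactly on the
   unnormalized covariance amplitudes $c_{ij} = G_{ij} F_i F_j$:
   $c_{gr} = c_{gr}^\mathrm{meas} - \beta c_{gg}$,
   $c_{rr} = c_{rr}^\mathrm{meas} - 2\beta c_{gr}^\mathrm{meas} + \beta^2 c_{gg}$,
   then renormalizes with the corrected red rate $F_r - \beta F_g$.
3. **Maturation and volume overlap** are configured manually (defaults
   1): complexes carrying an immature, dark partner are invisible to
   cross-correlation, and imperfectly overlapping detection volumes
   attenuate the cross amplitude. The calibration reports an overlap
   estimate, but the applied correction is deliberately a configured
   factor: the estimate is a ratio of two noisy fitted volumes, and
   dividing by its square would amplify calibration noise into every
   complex concentration.

## FCCS: complex concentration and apparent K_D

The corrected cross-amplitude is proportional to the concentration of
double-labeled complexes:

$$C_{AB} = \frac{G_{gr}(0)}{G_{gg}(0)\, G_{rr}(0)\, V_{rg}\, N_A},$$

where $V_{rg}$ is the effective cross-correlation volume from the dye
calibration. Because FCS concentrations contain both free and complexed
protein, the apparent dissociation constant is

$$K_D^\mathrm{app} = \frac{([A]_\mathrm{FCS} - C_{AB})\,([B]_\mathrm{FCS} - C_{AB})}{C_{AB}}.$$

It is *apparent* because unlabeled complex partners and (for
self-interactions) same-label complexes are invisible, making the value
an upper bound for homo-oligomers. When $C_{AB}$ is zero or smaller than
its propagated uncertainty, the pair is outside the method's dynamic
range and the above-range sentinel (`Inf`, reported as "> 1 uM") is
returned; interactions are only called detected when the across-cell
median $K_D^\mathrm{app}$ lies below the ~1 uM reliable-detection bound
*and* a majority of cells give an in-range value. The median (not the
mean) drives classification because sentinel censoring skews means.

## Calibration

At the start of a session the observation volumes are calibrated from
2 nM reference-dye measurements with known diffusion coefficients
(defaults: green dye 435, red dye 341, dual-channel dye 420 um^2/s):
$w_{xy} = \sqrt{4 D_\mathrm{known} \tau_D^\mathrm{dye}}$ per channel,
and $V_{rg}$ from the dual-channel dye's cross-correlation. Two
numerical choices matter here:

* The three dye curves are fitted **jointly with one shared** $\kappa$.
  From a single dilute-dye curve, $\kappa$ sits on a flat ridge with
  $\tau_D$ (the axial term is a weak $(1+x/\kappa^2)^{-1/2}$ factor) and
  single-curve estimates scatter wildly; the three distinct dye
  diffusion times constrain one common pinhole geometry much better.
* Dye fits use lags up to 2 ms only. Beyond ~100 dwell times the curve
  carries no shape information but is the region most exposed to
  residual finite-segment estimator bias, which otherwise drags
  $\kappa$ down.

Even so, $\kappa$ from desk-scale calibration sessions (3 repeats of
20 s per dye) remains uncertain at the ~10% level — a genuine property
of dilute-dye calibration, not of the simulation. Stage-level recovery
tests therefore use the exactly known simulated geometry, while the
end-to-end scenarios (negative control, mid-affinity pair) run the full
dye calibration.

# The trace simulator

`simulate_trace()` propagates every labeled particle through a periodic
box by Brownian dynamics: per 10 us time step an isotropic Gaussian
displacement with per-axis SD $\sqrt{2 D \Delta t}$, detection through
two 3D-Gaussian profiles, triplet blinking as an exact two-state Markov
propagator (rates $k_\mathrm{off} = 1/\tau_T$,
$k_\mathrm{on} = k_\mathrm{off}\Theta/(1-\Theta)$, giving the stationary
dark fraction $\Theta$), irreversible per-fluorophore bleaching as
event-driven competing exponentials, and per-bin Poisson photon counts
from the integrated molecular rate plus background, with
$\beta \times$ (green molecular rate) added to the red channel.

Two implementation details are worth knowing:

* **Far-field jumps.** The Gaussian profile is truncated where it falls
  below $e^{-6} \approx 2.5\times10^{-3}$ of its peak (a < 0.5% effect
  on rates and amplitudes). Outside that region a particle emits
  nothing, so the propagator replaces runs of fine steps by a single
  statistically equivalent Gaussian jump sized such that reaching the
  detection region within the jump would be a > 2.5-sigma event per
  axis. Because the free-diffusion propagator is exactly divisible, this
  changes no observable statistic (verified against brute-force
  correlation of fully resolved simulations) but makes dilute boxes
  hundreds of times cheaper.
* **Reproducibility.** Every particle owns an RNG substream derived from
  the user seed (splitmix64-seeded xoshiro256++ with a ziggurat normal
  sampler), so results are independent of iteration order, identical
  initial configurations are shared between `populate_box()` and
  `simulate_trace()`, and any single cell of a screen can be
  re-simulated in isolation from its `cell_seed()`.

Binding pairs are simulated as a *static equilibrium*: free A, free B
and the complex AB are distinct species with concentrations from the
mass-action quadratic (`solve_binding_equilibrium()`), because FCCS
amplitudes depend only on equilibrium fractions, not on exchange
kinetics. The complex diffuses with
$D_{AB} = (D_A^{-3} + D_B^{-3})^{-1/3}$ (additive hydrodynamic volumes).
A triple-fluorophore tag (e.g. 3myeGFP) is modeled as one emitter unit
with the tag's aggregate brightness; oligomer "stoichiometry" counts tag
units, which is the quantity the cpps ladder measures.

## Default study conditions

The generator defaults emulate the published acquisition regime:

| Parameter | Default | Rationale |
|---|---|---|
| box | 3 x 3 x 6 um, periodic | >= 10 lateral radii margin; <= ~2e4 particles at 1.2 uM |
| `w_xy` | 0.2 um, $\kappa$ = 5 | water-immersion confocal, 488/561 nm |
| time step / bin width | 10 us | $\ll \tau_D \ge 0.2$ ms for all in-scope species |
| duration | 20 s (45-60 s in the emulated acquisitions) | desk-scale runtime |
| brightness | 9000 (green tag), 5000 (red tag) counts/s | triple-tag fusions, a few kHz per fluorophore |
| $\Theta$, $\tau_T$ | 0.15, 50 us | fluorescent-protein dark-state flicker |
| bleach rate | 0.005 /s per fluorophore | "mild" bleaching, ~10% over 20 s |
| background | 10% of molecular signal | unlabeled-cell autofluorescence level |
| crosstalk $\beta$ | 0.05 (green to red only) | GFP emission tail in the red channel |

What the simulator deliberately does **not** model: association and
dissociation kinetics during a trace, detector afterpulsing and dead
time, diffraction-accurate (non-Gaussian) point-spread functions, raster
scanning, and cellular heterogeneity beyond Poisson particle numbers.
Passing recovery tests on these traces therefore validates the
*estimators* under realistic photon statistics and instrumental
distortions; they cannot certify behavior under, say, strong vesicular
motion, which the artifact-rejection stage only emulates with injected
bursts.

# The correlator

`correlate()` implements a multi-tau scheme: 16 linear lags per octave
with pairwise bin doubling, the zero-lag (shot-noise) bin excluded, and
the symmetric normalization (lag-dependent means) that removes the
leading finite-length bias. The retained trace is divided into 10 equal
chunks; the curve is the chunk average and the per-lag SEM comes from
the between-chunk scatter. The estimator is verified lag-by-lag against
a brute-force evaluation of the defining formula (`correlate_direct()`,
pure R) on short traces.

Before correlation, two conditioning steps reproduce manual practice:

* **Bleach detrending** (`detrend_local_average()`): a moving local mean
  $\bar F(t)$ (window 2 s — long against millisecond dwell times, short
  against the acquisition) rescales the trace as
  $F_c = F/\sqrt{\bar F/\bar F_0} + \bar F_0 (1 - \sqrt{\bar F/\bar F_0})$.
  The square root preserves the local shot-noise variance scaling; the
  additive term restores the mean. A noise-free decay maps onto a
  constant, and the corrected trace is trend-free. The *anchor*
  $\bar F_0$ is the global trace mean: anchoring at the initial local
  mean instead would multiply every correlation amplitude by the first
  window's random sampling factor (a few percent per trace), whereas the
  global anchor makes the correction an exact no-op on stationary traces
  and gives bleached traces time-average semantics. Photon rates for
  brightness always use the uncorrected counts of the retained bins.
* **Artifact rejection** (`reject_artifacts()`): windows (0.2 s) whose
  mean exceeds the robust trace level (median) by 5 robust SDs in either
  channel — a vesicle crossing the volume, a cell lurch — are cut out
  with one window of padding; traces retaining < 50% are flagged for
  discarding. The published screens did this manually; the automated
  rule keeps the threshold in configuration and logs every rejected
  interval.

# Fitting

Weighted Levenberg-Marquardt (via `minpack.lm`) with weights
$1/\mathrm{SEM}^2$. The raw per-lag SEMs (10 chunks) are themselves
noisy and correlated with the fluctuations they weight, which measurably
biases weighted fits (amplitudes recovered ~10% low in dye-curve
experiments); the weights therefore use a running geometric mean of the
SEM across neighboring lags, which keeps the orders-of-magnitude lag
dependence but decorrelates weight from point noise. Initialization
follows the curve itself: $N_0 = 1/G$ at the first fitted lag, $\tau_0$
from the half-width (the lag where $G$ first falls below half its
initial value), $\Theta_0 = 0.1$, $\tau_{T,0} = 10$ us. Bounds keep all
parameters physical; $\kappa$ is fixed from calibration for in vivo fits
(floated only in dye calibration); cross-correlation curves are fitted
without a triplet term (blinking of the two labels is uncorrelated). A
fit that does not converge is reported as such, never silently replaced;
for near-zero cross-correlations the amplitude falls back to the mean of
the first lags with its scatter-based uncertainty, which feeds the
above-range decision.

# Desk-scale problem sizes

All statistical checks run on simulated data sized for a workstation
session; the choices below are the package's test conditions and are
asserted in `tests/testthat/`:

* parameter recovery: D in {0.5, 1, 3, 9} um^2/s at 100 nM and C in
  {20 nM, 200 nM, 1 uM} at D = 3, 12 cells per condition, 8 s traces
  (4 s at 1 uM), medians within 15% of truth;
* end-to-end screen: strains with true K_D in {100, 300, 500, 700} nM at
  300 nM totals plus a non-interacting 200 nM pair, 8 cells of 6 s each,
  full pipeline including dye calibration, 10% background, 5% crosstalk;
  median apparent K_D within a factor 1.5, the 500 nM pair detected
  within the 1 uM bound, the negative control above it;
* cpps ladder: 1- to 4-mers at 100 nM, 6 cells of 5 s, ratios linear in
  n within 10%;
* bleach robustness: 20% intensity loss over the acquisition, detrended
  fits unbiased within 15% of the time-averaged truth.

`scripts/acceptance.R` re-runs the negative-control and mid-affinity
scenarios at full scale (12 cells, 20 s traces) from a single seed.

# Known limitations

* $K_D^\mathrm{app}$ values for self-interactions are upper bounds
  (same-label complexes are invisible), and all apparent affinities
  depend on the cellular context — unlabeled partners, competing
  complexes — so they are interaction *strengths under the given
  conditions*, not thermodynamic constants.
* The calibration's structure parameter carries ~10% uncertainty at
  desk scale, which propagates into effective volumes and hence
  concentrations; repeated or longer dye sessions tighten it.
* A brightness mixture reports the brightness-squared-weighted mean
  cpps: the amplitude-derived particle number of a mixture is
  $N_\mathrm{app} = (\sum c_i q_i)^2 / \sum c_i q_i^2 \times V N_A$, so
  a 1:1 monomer/trimer mix reads 2.5x (not 2x) the monomer brightness.
  This is a property of the measurement, shared with the real
  instrument, and is asserted as such in the tests.
* One-component fits only: mixtures of very different diffusion times
  are reported as a single effective component, as in the emulated
  screen.
* No multiple-testing control is applied across tested pairs; detection
  calls are per-pair threshold decisions.
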