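---
title: "Models and methods behind fueldrops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fueldrops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the kinetic
model and its assumptions, how the packaged rate constants were obtained,
what every tunable default means, the numerical choices, and what the
synthetic-data validation does and does not demonstrate.

## The reaction cycle

The system couples complex coacervation between a +3-charged transient
peptide anhydride and poly-U RNA to a carbodiimide fuel cycle. Five
species evolve in one well-mixed compartment (mM, minutes):

* `F` — fuel (EDC), consumed irreversibly;
* `P` — precursor peptide (+1 charge), the resting state;
* `I` — O-acylisourea, the reactive intermediate;
* `A` — anhydride product (+3), the coacervating species;
* `W` — waste (EDU).

The wiring is the standard carbodiimide scheme: fuel hydrolyses directly
(`k0`) or condenses with the precursor's aspartate (`k1`); the
intermediate either cyclises to the anhydride (`k2`) or hydrolyses
futilely back to the precursor (`k3`); the anhydride deactivates to the
precursor (`k4`). This is the only five-species wiring in which
activation and deactivation run simultaneously for as long as fuel
persists, which is what the experiments show. Two consequences are used
as run-time checks on every integration: peptide (`P+I+A`) and
carbodiimide (`F+I+W`) conservation, enforced at 1e-6 relative tolerance.

Assumptions worth stating explicitly:

* **Single compartment.** One rate-constant set describes the whole
  sample; no separate in-droplet kinetics. The experimental observation
  that one parameter set predicts the kinetics across fuel levels
  justifies this, and the droplet volume fraction (~0.1%) makes any
  droplet-phase contribution to the whole-sample balance small.
* **Deterministic mass-action kinetics** at mM concentrations; no
  stochastic effects, no spatial structure, no temperature dependence.
* The RNA concentration does not enter the kinetics at all; it matters
  only for phase behaviour.

## Where the packaged rate constants come from

The numeric rate constants are configuration
(`inst/extdata/rate_constants.json`), not hard-coded values, and
`fit_rate_constants()` exists to re-derive them from any HPLC time-course
data. The packaged set was calibrated by least squares of the model's
observables against the system's published macroscopic benchmarks at
standard conditions (23 mM precursor, 200 mM MES pH 5.3, 25 °C):

* peak anhydride of ~0.9 mM at 7.5 mM fuel — the fuel level at which
  turbidity first appears, which ties the fuel onset to the critical
  coacervation concentration;
* anhydride peak near 3 min and re-crossing of the 0.9 mM threshold near
  18 min at 25 mM fuel — the observed droplet window;
* ~3.1 mM total anhydride at 2 min of the 25 mM course, so that the
  measured 1.7 mM filtrate concentration is ~55% of the total.

The resulting values (min^-1; `k1` in mM^-1 min^-1) are
`k0 = 0.0823`, `k1 = 0.0443`, `k2 = 1.319`, `k3 = 6.343`,
`k4 = 0.0907`: fast intermediate turnover with roughly one in six
intermediates reaching the anhydride, fuel consumed over tens of
minutes, and a ~11 min anhydride deactivation half-life.

**A documented tension.** Under this single-compartment scheme the
late-time anhydride tail decays at `min(k0 + k1*P0, k4)` in every
course. Requiring the 25 mM course to stay above 0.9 mM until ~18 min
(tail rate ≈ 0.09 min^-1) is therefore incompatible with the 60 mM
course dropping from its ~7 mM peak below 0.1 mM within ~30 min (which
would need ≈ 0.16 min^-1) — no rate-constant set satisfies both, as a
constrained search over all five constants confirms. The packaged
constants prioritise the threshold and droplet-window observables; they
predict fuel/product depletion of the 60 mM course near 51 min rather
than 30 min, and the corresponding end-to-end check is expected to fail
under this model. Resolving it would need either measured fuel decay
curves at high fuel or a mechanism (e.g. ionic-strength dependence of
hydrolysis) outside this model's scope.

## Calibration machinery

`fit_rate_constants()` minimises relative (proportional-error) least
squares: fuel spans tens of mM while the anhydride stays sub-mM, so
absolute weighting would fit only the fuel. Each residual is scaled by
`max(|obs|, 0.02 * species max)` to keep near-zero tail points from
dominating. Optimisation is Levenberg-Marquardt on log-constants
(positivity for free), with three refinements that experience with this
model made necessary:

* **Early sampling matters.** `k2` and `k3` are separable only through
  the intermediate's sub-minute equilibration; calibration schedules
  must sample the first minute.
* **Joint multi-experiment fits.** `k0*F` and `k1*F*P` are nearly
  collinear when the precursor barely moves (low fuel). Passing rows
  from several fuel levels (`F0_mM` column) fits one constant set
  jointly; the strong precursor draw-down at high fuel separates the
  two channels. This mirrors how the experiments were actually used: a
  single parameter set across all conditions.
* **Numerics.** The finite-difference Jacobian uses steps well above
  the ODE solver's error (`epsfcn = 1e-8`), and a small deterministic
  multistart across the `k0`/`k1` ridge protects against stalls in its
  shallow valley. Solver failures during parameter excursions return a
  large penalty instead of aborting the fit.

The quench correction for filtrate samples inverts the forward model:
the reported value is the anhydride concentration at filtration time
whose evolution over the recorded delay (default 20 s, the midpoint of
the typical 15–25 s handling time) reproduces the quenched measurement.
Three fixed-point sweeps of `corrected <- corrected - (A(delay) -
measured)` contract the residual to below 0.1% for delays up to a
minute anywhere in the cycle; the filtrate composition for `F`, `P`,
`I` is taken from the model at filtration time, since the intermediate
is not measurable by the quench assay.

The ITC fit is the standard single-site (Wiseman) isotherm with
per-injection dilution and displaced-volume accounting; the first
injection is excluded by default (partial-delivery artefact), and `n`,
`Kd` are fitted on the log scale. At this titration's c-value (~0.4)
the parameters are strongly correlated: the fit flags `low_c` and wide
intervals instead of failing. The forward model `wiseman_heats()` is
shared with the generator deliberately — the recovery tests are
self-consistency checks of the estimation machinery, not evidence about
the functional form.

## Phase analysis defaults

| Parameter | Default | Meaning |
|---|---|---|
| `A_crit` | 0.9 mM | critical coacervation concentration of the product |
| `fuel_lower` | 7.5 mM | fuel onset of droplet formation, RNA-independent |
| boundary anchors | (1.4, 25), (4.1, 40) mM | dynamic-to-metastable boundary in the (RNA, fuel) plane, linear between anchors, clamped outside |
| detection limit | 0.1 mM | HPLC notion of a species being "absent" |
| turbidity cutoff | 0.01 a.u. | "clear" solution; lifetime threshold |
| charge model | +3 product, -1 per RNA monomer | precursor (+1) excluded by default |
| droplet volume fraction | 0.0014 (input) | measured by centrifugation; never computed |
| RNA droplet fraction | 0.9 dynamic / 1.0 metastable | from supernatant fluorescence |

Two of these deserve justification. The charge ratio excludes the
precursor because the precursor does not coacervate — it is the
product/RNA stoichiometry that distinguishes dynamic (~1.1) from
metastable (~2.0) droplets; the `charge_model()` switch restores it if
wanted. The droplet volume fraction is an *input*: it was measured by
comparing a centrifuged pellet against size standards, a procedure with
no software counterpart, and the default 0.0014 is the value consistent
with the measured 1.7 mM filtrate and ~0.9 M in-droplet concentration
two minutes into the 25 mM course.

The regime classifier is deliberately empirical: metastability is
kinetic arrest, for which no mechanistic model is attempted; the
classifier encodes the observed boundaries and nothing more.

## Imaging

Segmentation is Otsu thresholding (on the intensity-normalised frame;
a fixed threshold is available for full determinism) followed by
connected components, discarding objects under 4 px². Touching droplets
are not split — fusion makes merged objects physically real here.
Volumes assume perfect spheres over the 2-D equivalent diameter, the
same assumption the original particle analysis made. Vacuolated
droplets count once; an optional annotation flags droplets whose filled
outline contains interior holes.

The partition coefficient is the ratio of median interior to median
background intensity, with the interior eroded and the background
dilated by 2 px so the blurred rim biases neither side. Medians make
the estimate robust to shot noise and to the vacuole-induced intensity
dips. The estimator carries a small negative bias (~3% at a planted
ratio of 37) because the PSF mixes background into droplet interiors;
at the 10% validation tolerance this is acceptable and is reported, not
hidden.

Time-lapse statistics bin per-droplet measurements into 5-min bins
(right-closed, so frames at minutes 1–5 share a bin), averaging droplet
counts per frame and pooling volumes/intensities within the bin; empty
bins are absent, not zero.

## Synthetic data: what it does and does not show

Every generator is a pure function of (truth, design, seed) and emits
its ground truth alongside the data. Noise models: multiplicative
Gaussian for HPLC and ITC (instrument-proportional), additive Gaussian
for turbidity, Poisson shot noise plus Gaussian read noise for images
(background 30 counts puts the shot-noise SNR near 5.5). The turbidity
generator encodes the regime distinction directly: dynamic absorbance
tracks `scale * max(0, A - A_crit)`; metastable absorbance holds its
peak (hysteresis) and collapses at the persistence time (default
76 min). The droplet-count law tying frame content to `A(t)` in
`synth_timelapse()` is an explicit artifact invention that exists to
exercise the estimators; it has no physical standing.

Passing recovery tests therefore demonstrate that the estimators are
unbiased and stable under the stated noise models — not that real
chromatograms, plates or micrographs obey those models. In particular,
absolute droplet counts and volumes of the real time-lapses, and
absolute turbidity magnitudes, are not reproducible from published
information; they are covered only by recovery properties on synthetic
frames. Real-image effects deliberately out of scope: confocal
sectioning, bleaching, droplet motion between frames, and fragmentation
events.

## Numerical choices and problem sizes

* ODE integration: `deSolve::ode` (lsoda), `atol` 1e-9 mM, `rtol` 1e-8,
  default output step 0.1 min; conservation checked at 1e-6 relative.
* Threshold crossings, depletion and turbidity lifetimes interpolate
  linearly between output points; the fuel scan brackets coarsely, then
  bisects, and reports on the requested resolution grid (0.5 mM for the
  onset scan).
* Validation sizes, chosen as the package's own test scale: 20 seeded
  replicates for Monte-Carlo recovery (kinetics at 5% noise, ITC at 2%,
  partition at SNR ~5.5), 512x512 px frames with ≥20 droplets for the
  headline partition recovery, 96–256 px frames for unit tests; the
  fixed-step Euler cross-check runs at 1e-4 min steps over 20 random
  parameter draws.

## Known limitations

* The 60 mM depletion-time discrepancy described above: a structural
  limit of the single-compartment scheme, not a numerical artefact.
* `k0` remains weakly identified from any single-fuel dataset; joint
  fits or a fuel-only control are required for unbiased recovery.
* Low-c ITC: `Kd` point estimates are robust at 2% noise, but `n` and
  `dH` individually carry wide intervals, as flagged.
* No droplet tracking, fusion/fragmentation detection or 3-D
  reconstruction; the imaging module measures single frames.
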