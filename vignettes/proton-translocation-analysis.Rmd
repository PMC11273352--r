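---
title: "Quantifying proton translocation across lipid bilayers from SH imaging and I-V recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying proton translocation across lipid bilayers from SH imaging and I-V recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonflux)
```

## The measurement problem

Free-standing planar lipid bilayers (Montal-Müller membranes) separate two
aqueous compartments. When the bottom compartment is acidified (pH 7.3 to
4.1 by HCl addition), protons cross the membrane far more readily than
chloride, and two independent observables track that translocation:

* **Electrophysiology.** Current-voltage sweeps across the membrane give a
  conductance (slope) and a reversal potential (zero-current voltage). The
  reversal potential encodes the relative H⁺/Cl⁻ permeability through the
  Goldman equation; the current at a known bias, through the
  Goldman-Hodgkin-Katz (GHK) flux equation, gives an absolute proton
  permeability.
* **Second-harmonic (SH) wide-field imaging.** Nonresonant SH photons are
  generated only where interfacial symmetry is broken, so a symmetric
  bilayer is dark and local protonation of one leaflet lights up.
  The recorded intensity is a quadratic function of the local transmembrane
  potential, so intensity maps convert to potential maps. Transient bright
  domains carry the potential statistics; the slow rise-then-decay of the
  signal after acid addition carries the translocation kinetics.

`protonflux` implements the full inference chain from both observables to
permeabilities, per-region translocation kinetics, interfacial charge
accounting, and the chain-coordinate permeability profile of the
water-needle transport model, together with seeded generators that emulate
the microscope and the patch amplifier so that every stage is testable
against known ground truth.

## Electrochemical models

### Goldman reversal potential and its inversion

For a membrane conducting H⁺ and Cl⁻ with permeability ratio
$r = P_\mathrm{H}/P_\mathrm{Cl}$,

$$V_m = \frac{RT}{F}\ln\frac{r\,[\mathrm{H}]_b + [\mathrm{Cl}]_t}
{r\,[\mathrm{H}]_t + [\mathrm{Cl}]_b},$$

with $b$/$t$ the bottom/top compartments. The arrangement is fixed so that
acid added to the bottom with $r > 1$ yields $V_m > 0$. The expression is
monotone in $r$, so a measured $V_m$ inverts uniquely
(`permeability_ratio_from_reversal()`); the inversion is algebraic and is
cross-checked in the tests against a bisection oracle. $V_m$ must lie
strictly between the two single-ion Nernst potentials — outside that
interval no ratio exists and the function says so.

### GHK flux equation

The single-ion GHK current is linear in the permeability, so
`permeability_from_current()` inverts it exactly. Two conventions matter
and are fixed as package defaults:

* the "inside" compartment is the **top** (pH 7.3) side — with the bottom
  side acidified, a negative bias then drives a negative proton current,
  and the measured (−7.6 pA, −0.06 V) pair over a 9503 µm² membrane
  returns a permeability of 4.0 × 10⁻⁶ cm/s, consistent with the
  3.7 × 10⁻⁶ cm/s obtained from the printed two-digit inputs;
* concentrations equal activities ($[\mathrm{H}^+] = 10^{-\mathrm{pH}}$),
  as no activity model is warranted by the data.

At $U = 0$ the implementation switches to the series expansion of the
flux equation (the diffusion-limited current), avoiding the 0/0.

### Compartment composition and temperature

The default `ion_conditions()` encode the acid-gradient experiment:
chloride 50 mM on top (KCl only) and 61 mM on the bottom, the latter from
the total ionic strength reached when ~11 mM HCl titrates the phosphate
buffer to pH 4.1. The temperature of the experiment is not part of the
record; the default is 296.15 K (room temperature), configurable
everywhere, and the permeability results move by less than ±15% over
293–298 K — the tolerance used in the tests.

### Gouy-Chapman-Stern solver

`gcs_surface_potential()` solves the Grahame relation for a 1:1
electrolyte in closed form (asinh) and adds an optional Stern-layer drop
$\sigma/C_\mathrm{Stern}$. Because the diffuse-layer potential grows only
logarithmically with charge density, potentials of ~350 mV at 60 mM ionic
strength are unreachable for any plausible lipid charge density without a
condensed layer — the package reproduces this argument quantitatively
(`gcs_charge_for_potential()`).

## SH intensity to potential, and charge accounting

The forward model is $I = s\,(\chi^{(2)}_\mathrm{eff} +
\chi^{(3)\prime}\Delta\Phi_0)^2$. For compositionally symmetric bilayers
the chemical term cancels ($\chi^{(2)}_\mathrm{eff} = 0$) and
$\Delta\Phi_0 \propto \sqrt{I}$. Two consequences shape the design:

* intensity does not carry the sign of the potential — the package reports
  magnitudes throughout;
* the calibration constant $s\,\chi^{(3)\prime 2}$ is instrument-specific.
  It is supplied either directly or by anchoring one reference intensity
  to a known potential (`calibrate_to_reference()`), e.g. from capacitance
  minimization.

Charge accounting treats the hydrophobic core as a parallel-plate
capacitor with $\varepsilon = 2.1$ and $d = 4$ nm
($C = \varepsilon_0\varepsilon/d \approx 0.46\ \mu\mathrm{F/cm^2}$). A
domain potential converts to a surface-charge-density difference
$\Delta\sigma = C\,\Delta\Phi$, then to a proton count
$N = \Delta\sigma A/e$. Accounting is linear, so summing disjoint domains
equals accounting over their union; each domain is treated independently
(no lateral coupling), mirroring the per-domain arithmetic of the
measurement.

The ratio of electrically transported moles to interface-bound moles is
the retention fraction, reported as "1 out of X" with X at two significant
figures (5.7 × 10⁻¹⁴ mol vs 1.1 × 10⁻¹⁷ mol gives 1 out of 5.2 × 10³).

## Image pipeline

### Segmentation

Domains are bright, few-micrometer regions. Thresholding at the background
median plus `k_sigma` robust standard deviations (MAD), 4-connected
labeling (EBImage), and a minimum-area filter give the domain catalog. The
criteria the original analysis used are not on record, so the defaults are
the conventional `k_sigma = 3` and `min_area_px = 4`, both configurable;
all recovery tests compare against generator ground truth rather than
against these constants.

### Decay kinetics

The post-acid signal rises in ~2 min and decays exponentially with a
spatially varying constant τ. Numerical choices:

* **Window averaging before conversion.** Frames are averaged within each
  observation window (the 20 × 1 s frames of the standard acquisition)
  *before* background subtraction and any square-root conversion.
  Converting individual noisy frames first would rectify zero-mean shot
  noise into a signal-dependent pedestal.
* **Background from single frames.** The background level is the median
  over the window's *raw frames*. Within a single frame, domains are
  sparse and the median is clean; in the window-averaged image most pixels
  carry some domain signal, and a median taken there would track the
  signal and flatten the decay.
* **Decay fits run on intensity, not potential.** The quadratic SH
  response makes intensity decay at exactly twice the potential rate, so
  the pipeline fits the background-subtracted intensity (whose noise is
  zero-mean at all times) and doubles the fitted constant. Fitting the
  square-root signal instead would push the late-time signal into a
  clamped-noise floor and bias τ low.
* **Global decay onset.** The onset of the decay is set by the acid
  addition and is common to the whole field, so per-ROI fits share the
  `t_start` detected on the whole-field series (the post-smoothing
  maximum); only τ varies spatially.
* **Fixed zero baseline for ROI fits.** After background subtraction the
  true baseline is zero; fixing it removes the classic τ-baseline
  degeneracy that destabilizes slow decays in noisy series.
* **Relative-error weighting.** The dominant ROI noise is the Poisson
  fluctuation of the number of domains per window — multiplicative noise —
  so `fit_exponential_decay()` refits with inverse-squared-fitted-value
  weights after an unweighted first pass.

Fits that fail or are flagged (near-zero amplitude, τ at its bound,
non-decaying) enter the τ map as missing values and are excluded from
histograms.

### From τ to flux and permeability

Decay constants convert to fluxes by inverse proportionality with a single
anchor pair: τ_ref = 67 min corresponds to F_ref = 7.5 × 10⁶ ions/s, the
unsaturated-membrane whole-field values; `tau_to_flux()` then maps
τ = 42 min to 1.2 × 10⁷ ions/s, consistent with both printed fluxes. The
flux converts to a permeability through $P = F/(N_A\,A\,\Delta c)$ with
$\Delta c$ the proton concentration difference.

## Water-needle model

`needle_stabilization_energy()` evaluates the dielectric-replacement
energy of a water cylinder (radius $r$, permittivity $\varepsilon_w$)
spanning the hydrophobic core (thickness $d$, permittivity
$\varepsilon_m$) in the uniform field $U/d$:

$$\Delta W = \tfrac12\,\varepsilon_0(\varepsilon_w - \varepsilon_m)
\left(\frac{U}{d}\right)^2 \pi r^2 d \cdot N_A.$$

It is quadratic in both $U$ and $r$; at $r = 3$ Å and $U = 300$ mV it
gives 1.3 kJ/mol — the "only of order 1 kJ/mol" stabilization that
explains why moderate potential fluctuations barely change needle
energetics. The tests verify it against a finite-difference field-energy
oracle (per-column capacitance of a discretized cross-section) to 5%.
The model keeps only the electrostatic leading term; line tension and Born
contributions to needle formation are outside its scope.

`permeability_profile()` combines a defect-formation free-energy profile
$\Delta G(\xi_{ch})$ with a flux profile $F(\xi_{ch})$ along the chain
coordinate ($\xi_{ch} = 0.1$: intact membrane; ~0.74: water needle; 1:
open pore):

$$P(\xi_{ch}) \propto F(\xi_{ch})\,e^{-\beta\Delta G(\xi_{ch})}.$$

Values are reported in relative units with an optional prefactor: the
absolute scale would require the MD-derived flux calibration, which is not
part of this package. Ratios between membranes and the location of the
dominant window (the smallest ξ interval holding ≥ 90% of the integral)
are the meaningful outputs; a constant shift of ΔG rescales P globally and
leaves both unchanged, which sidesteps the normalization question for the
Boltzmann weight. ΔG tables use kJ/mol and are re-anchored to
ΔG(ξ_min) = 0 on reading.

## The synthetic-data generators

`gen_sh_stack()` emulates the acid-gradient imaging experiment; its
defaults are the study conditions and were chosen once:

* 45 µm field at 0.5 µm/pixel (90 × 90), so a 10 × 10 grid of
  4.5 µm ROIs tiles the field as in the τ-map analysis;
* 60 observation windows of 20 × 1 s frames, spaced 2.5 min over ~2.5 h,
  acid added at t = 10 min, envelope rise time 2 min — long enough that
  tiles with τ near 100 min still decay visibly within the record;
* domain potentials N(0.12 V, 0.05 V) truncated positive; τ field
  N(42, 24) min truncated above 5 min, piecewise constant on 4.5 µm tiles;
* domain lifetime of one frame (intensity fluctuations are uncorrelated in
  time at 1 s resolution — the generated stacks satisfy a lag-1
  occupancy-autocorrelation ≈ 0 test);
* 60 domain births per frame (≈9% area occupancy): dense domain texture
  comparable to the published images, and enough signal per ROI-window for
  per-tile kinetics to be estimable;
* lognormal domain radii (median 1 µm) — a placeholder, as the real size
  distribution is not on record;
* Poisson shot noise on counts plus Gaussian read noise (SD 2 counts) on a
  baseline of 20 counts, with the calibration mapping 0.35 V to ~2450
  counts — photon-starved but workable, as nonresonant SH imaging is.

The envelope multiplies the potential field per pixel with the pixel's own
τ: the decay constant is a property of the local membrane patch, not of
the transient domain sitting on it. Every generator emits its ground truth
(per-domain table, per-pixel τ field, envelope parameters), and all
recovery tests compare against it, never against hard-coded constants.

What the generator does **not** emulate: optical point-spread and speckle,
drift, flat-field structure, photobleaching, or any spatial correlation of
domain appearances. Passing the recovery tests therefore demonstrates that
the analysis chain is correct and unbiased under the stated statistical
model, not that it is robust to every instrumental artifact of real
stacks.

### Parameter recovery, quantitatively

On the default stack, across 20 seeds, the pipeline recovers (each seed
compared to its own realized ground truth):

* domain-potential Gaussian μ and σ within ±0.007 V,
* the whole-field decay constant within 10% of a fit to the noiseless
  truth-implied series,
* the τ-field mean within ±3 min and spread within ±4 min, with ≥95 of
  100 ROIs fitted.

These are the bounds asserted in `test-acceptance.R`; typical errors are
about half the bounds. The problem sizes (90 × 90 px, 1200 frames, 20
seeds) keep the full suite a few minutes long while leaving the per-ROI
statistics representative.

## Degenerate inputs and edge behavior

Symmetric compartments make the permeability ratio ill-posed — the
pipeline flags it and continues. Flat I-V sweeps give zero conductance
with the reversal potential marked undefined. Constant or rising series
are fitted but flagged rather than silently reported. Windows with no
detected domains enter the potential series as missing, not zero. A
reversal potential outside the Nernst interval, mismatched profile grids,
and sign-inconsistent current/voltage pairs raise errors that name the
convention being violated.

## Known limitations

* Potential magnitudes only; per-leaflet decomposition of the SH signal is
  not attempted.
* The τ→flux conversion rests on a single anchor pair; an independent
  absolute calibration (e.g. from the retention-corrected charge budget)
  is not reconstructible from the available record.
* Chain-coordinate permeability profiles are relative; absolute MD-derived
  permeabilities are out of scope.
* The GHK treatment considers H⁺ and Cl⁻ only; buffer species enter only
  through the ionic strength of the GCS model.
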