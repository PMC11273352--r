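# protonflux

Quantifies proton translocation across free-standing lipid bilayer
membranes from two complementary measurements: wide-field second-harmonic
(SH) microscopy of the membrane interface, and current–voltage recordings
across the bilayer. It is written for membrane biophysicists who have
either kind of data (or both) and want permeabilities, per-region
translocation kinetics, and interfacial charge budgets out of them — plus
seeded synthetic-data generators that emulate the microscope and the patch
amplifier, so the whole chain is testable without instrument data.

## What it computes

**From I–V sweeps.** The slope of a sweep is the membrane conductance G;
the zero-current crossing is the reversal potential V_m. For a membrane
conducting H⁺ and Cl⁻ with permeability ratio r = P_H/P_Cl, the Goldman
equation

    V_m = (RT/F) · ln[(r·[H]_b + [Cl]_t) / (r·[H]_t + [Cl]_b)]

is monotone in r, so a measured V_m inverts uniquely
(`permeability_ratio_from_reversal`). The proton current i at a known bias
U inverts the Goldman–Hodgkin–Katz flux equation for the absolute proton
permeability P (`permeability_from_current`), and the zero-bias current
integrates to the number of translocated protons (`transported_moles`).

**From SH stacks.** SH intensity is quadratic in the local transmembrane
potential, I ∝ (χ⁽²⁾ + χ⁽³⁾′·ΔΦ₀)², with the chemical term vanishing for
symmetric bilayers, so intensity maps convert to potential-magnitude maps
(`potential_from_intensity`). The pipeline segments transient bright
domains (4-connected components above a robust threshold), fits a Gaussian
to the domain-potential occurrence histogram, fits the rise-then-decay of
the signal after acid addition with exponentials per 4.5 µm ROI
(`roi_tau_map`), converts decay constants to fluxes by anchor-calibrated
inverse proportionality (`tau_to_flux`), and fluxes to permeabilities via
P = F/(N_A·A·Δc). A parallel-plate capacitor model (ε = 2.1, d = 4 nm)
converts domain potentials to surface-charge changes and bound-proton
counts; combined with the electrical count this gives the fraction of
translocated protons retained at the interface.

**Water-needle energetics.** An analytic dielectric-replacement model
gives the electrostatic stabilization of a thin water needle by a
transmembrane potential, ΔW = ½ε₀(ε_w−ε_m)(U/d)²·πr²d·N_A — about
1 kJ/mol at r = 3 Å and 300 mV. Free-energy and flux profiles along the
chain coordinate ξ_ch combine into a relative permeability profile
P(ξ) ∝ F(ξ)·exp(−βΔG(ξ)) with its dominant window
(`permeability_profile`).

## Worked example

The package ships a small example dataset: two synthetic I–V sweeps
(pre-acid, and after acidifying the bottom compartment to pH 4.1 with a
15 mV reversal potential) and a pair of chain-coordinate profile tables.

```r
library(protonflux)

config <- read_run_config(system.file("extdata", "run_example.yaml",
                                      package = "protonflux"))
cr <- run_conductivity_analysis(config)
nr <- run_needle_analysis(config)
print(assemble_report(cr, needle = nr, config = config))
```

```
== protonflux report ==
Conductivity analysis
  2 sweep(s); selected #2: G = 1.093e-10 S (1.15e-06 S/cm^2), V_m = 0.01234 V
  P_H/P_Cl = 617
  GHK proton permeability = 4.02e-06 cm/s
  transported H+ over 3600 s: 5.71e-14 mol
Needle analysis
Permeability profile 'profiles_unsaturated.csv': integral = 1902 (rel.), dominant window xi = [0.60, 0.76]
Permeability profile 'profiles_branched.csv': integral = 4.311 (rel.), dominant window xi = [0.60, 0.76]
  integrated permeability ratio (1/2): 441
  stabilization energy grid (kJ/mol):
     U_100mV U_200mV U_300mV
r_1A   0.016   0.065   0.147
r_2A   0.065   0.261   0.587
r_3A   0.147   0.587   1.321
```

Reading the numbers: the analysis picked the post-acid sweep (the one with
the maximal slope), whose specific conductance is 1.15 µS/cm² over the
9503 µm² membrane. Its ~12 mV reversal potential implies the membrane
conducts protons ~600× better than chloride — far above the ≥50× bound
that the printed reversal potentials imply. The −7.6 pA proton current at
−60 mV bias inverts to a GHK permeability of 4.0 × 10⁻⁶ cm/s, and one
hour of the zero-bias current moves 5.7 × 10⁻¹⁴ mol of protons. On the
needle side, the membrane whose defect-formation free energy is
15 kJ/mol lower is ~440× (= e^{βΔΔG}, two orders of magnitude) more
proton-permeable, the permeation mass sits at chain coordinates
ξ ≈ 0.6–0.76 — water needles, not open pores — and a 300 mV potential
stabilizes a 3 Å needle by only ~1.3 kJ/mol.

An SH imaging run works the same way: `gen_sh_stack(sh_stack_spec(seed = 1))`
produces a stack plus ground truth, and
`run_imaging_analysis(run_config(), stack = <stack>)` returns the domain
histogram, whole-field and per-ROI decay constants, flux and permeability.
A thin command-line wrapper is at `inst/scripts/protonflux.R`
(`conduct | image | needle | all | synth` subcommands).

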