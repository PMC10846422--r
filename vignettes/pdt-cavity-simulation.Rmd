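---
title: "Modeling intraoperative PDT of a glioblastoma resection cavity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling intraoperative PDT of a glioblastoma resection cavity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After surgical resection of a glioblastoma (GBM), a rim of infiltrative
tumor — up to about 2 mm thick — almost always remains in the cavity wall,
and most recurrences arise within centimeters of it. Intraoperative
photodynamic therapy (PDT) attacks this remnant: the patient receives
5-aminolevulinic acid, which tumor cells convert to the photosensitizer
protoporphyrin IX (PpIX); an intralipid-filled balloon coupled to a 635 nm
laser is inflated into the cavity; and the diffusely illuminated wall
produces cytotoxic singlet oxygen where light, PpIX and tissue oxygen
coincide.

`pdtsim` couples the four physical components of this treatment in one
reproducible pipeline:

1. **Scene** — a voxelized phantom of the cavity (balloon, saline gap,
   residual GBM rim, solid tumor sphere, white/gray matter).
2. **Light** — Monte Carlo radiative transport giving the per-voxel fluence
   rate per watt of source power.
3. **Chemistry** — macroscopic singlet-oxygen kinetics with photobleaching,
   oxygen depletion and perfusion-driven recovery, and a cumulative-dose
   kill threshold.
4. **Heat** — explicit finite-difference conduction with the absorbed
   light as source, tracking the maximum tissue temperature against a
   48 °C damage threshold.

## The model, piece by piece

### Scene and optics

Each voxel carries fractions $F_m$ of five materials (white matter, gray
matter, GBM, intralipid, saline) that sum to one. Optical properties are
fraction-weighted averages, e.g.

$$\mu_a = \sum_m F_m\,\mu_{a,m} + C_{\mathrm{PpIX}}\,\varepsilon_{630},$$

with $C_{\mathrm{PpIX}} = \mathrm{PpIX}_0\,F_{\mathrm{GBM}}$ the local
photosensitizer concentration (µM) and
$\varepsilon_{630} = 0.0265\ \mathrm{cm^{-1}(\mu g/ml)^{-1}}$. By default
the micromolar concentration multiplies $\varepsilon_{630}$ directly —
the convention under which 5 µM at 20 % GBM fraction contributes
0.0265 cm⁻¹ — because that is how the treatment-planning arithmetic this
package mirrors is defined. A unit-rigorous mode
(`ppix_absorption(..., unit_rigorous = TRUE)`) first converts µM to µg/ml
via the PpIX molecular weight (562.7 g/mol); it lowers the PpIX term by
about 2×, which is negligible against tissue absorption either way.

The synthetic phantom (`make_phantom()`) emulates the treatment geometry
rather than any patient: an ellipsoidal balloon (default 7 × 4 × 3 cm,
44 cm³), a configurable saline gap where the balloon does not touch the
wall (default 1 mm), and a rim in which $F_{\mathrm{GBM}}$ falls
*linearly* from 1 at the cavity wall to 0 at the rim depth (default 2 mm).
The linear falloff is a modeling choice: the residual-disease literature
specifies only that density becomes very low by ~2 mm, and a linear
profile is the simplest shape consistent with that. Optional smooth
multiplicative heterogeneity (`rim_noise`, seeded, default off) emulates
the patchiness of real infiltration. Background brain is a constant
70/30 white/gray mixture — a white-matter-dominant resection bed; the
phantom makes no attempt at cortical anatomy. A solid tumor sphere
(default 3 mm radius; size is a free choice, no canonical value exists)
sits on the cavity wall in the +x/+y "top-right corner", the location a
surgeon is most likely to miss. The balloon may exceed the grid on the
side away from the sphere (it is truncated there); at least `margin_cm`
of brain is required on the sphere side.

What the phantom does **not** emulate: real white/gray anatomy,
patient-specific cavity shapes, necrotic cores, vasculature, or CSF.
Passing tests therefore demonstrate correct physics and internal
consistency on a controlled scene — not clinical dose predictions, which
depend strongly on geometry.

### Monte Carlo transport

Photon packets start at an isotropic point source at the balloon centroid
(the intralipid's scattering is what produces diffuse wall illumination;
the source position is configurable, and a pencil-beam mode exists for
validation). Propagation uses exponential free paths in
$\mu_t = \mu_a + \mu_s$, Henyey–Greenstein scattering with the local $g$,
implicit capture (weight times albedo at each interaction) and Russian
roulette below weight $10^{-4}$ with survival probability 0.1. Fluence is
scored with the track-length estimator: every path segment adds
weight × length to its voxel, normalized by voxel volume and packet
count to mW cm⁻² per source watt. Dimensional analysis of the kinetics
coupling $\xi$ (cm² mW⁻¹ s⁻¹) requires fluence *rate per area*, which is
what the estimator produces and what the package stores.

Choices worth knowing:

* **Fresnel interfaces.** Voxel faces where the refractive index changes
  (1.33 ↔ 1.38) reflect/refract unpolarized packets; a flag disables this
  for speed. The effect is small at these indices.
* **Grid edges absorb.** Escaping weight is tallied, never reflected; the
  ledger (absorbed + escaped + roulette-discarded) closes in expectation,
  with realized discrepancy well below the 10⁻³ roulette budget.
* **RNG.** One counter-seeded xoshiro256** stream per packet, so results
  are bit-reproducible per seed and independent of execution order.
* **Zero-attenuation voxels** free-stream (needed for vacuum validation
  and harmless in tissue).

One fluence map per geometry suffices for *all* protocols: the map is per
watt (power is a multiplier) and is computed from PpIX-free optics, since
the PpIX term is negligible against tissue absorption. This is also why
sweeps over concentration, power, time and threshold share a single
transport run.

### Singlet-oxygen kinetics

Per voxel, with fluence rate $\Psi$:

$$\frac{dS_0}{dt} = -\xi\sigma\Psi\,S_0(S_0+\varrho)\frac{[^3O_2]}{[^3O_2]+\beta},\qquad
\frac{d[^1O_2]_{rx}}{dt} = \xi\Psi S_0\frac{[^3O_2]}{[^3O_2]+\beta},$$

$$\frac{d[^3O_2]}{dt} = -\xi\Psi S_0\frac{[^3O_2]}{[^3O_2]+\beta}
 + \Phi(t)\Big(1-\frac{[^3O_2]}{[^3O_2]_0}\Big),$$

with defaults $\xi = 3.7\times10^{-3}$ cm² mW⁻¹ s⁻¹,
$\sigma = 9\times10^{-5}$ µM⁻¹, $\varrho = 33$ µM, $\beta = 11.9$ µM.
$\Phi(t)$ is the Krogh-cylinder-derived perfusion rate: a quartic
rational polynomial in $t' = (t-750)/632.1$ scaled by
$\Phi_0 = 21.6$ µM s⁻¹, with long-time asymptote $0.99\,\Phi_0$. The
$t$ in $\Phi(t)$ is the global clock starting at first light-on and
running through the dark breaks — the simplest consistent reading, since
perfusion does not pause when the laser does. The cerebral metabolic
consumption scale $q_0 = 26.3$ µM s⁻¹ (derived by scaling a skin rate by
the cerebral/skin consumption ratio, see `metabolic_q0()`) enters through
the calibration of $\Phi$; it is exposed in the parameter set but adds no
separate sink term.

The equilibrium oxygen is $[^3O_2]_0 = \alpha\,P_{tiO_2} =
1.295 \times 30 = 38.85$ µM. A rounded value of 38 µM circulates in
tabulations; the package uses the formula value by default and accepts
any override via `kinetics_params(o2_init = ...)`.

**Integration.** The outer loop advances one second at a time (the
protocol clock; schedules with fractional seconds are quantized by
rounding the *cumulative* schedule so total time and on-time are
preserved). Each second is integrated with 10 fixed RK4 sub-steps; states
are clamped at zero. Against an adaptive stiff integrator (`deSolve::lsoda`
at rtol 10⁻⁹) the per-second result agrees to well within 0.1 % relative —
the system's fastest scale is the oxygen relaxation
$\Phi_0/[^3O_2]_0 \approx 0.56\ \mathrm{s^{-1}}$, comfortably resolved at
$h = 0.1$ s.

**Kill accounting.** A voxel dies when its *cumulative* reacted singlet
oxygen reaches 560 µM (±25 % gives the 420/700 µM sensitivity bounds).
The threshold is bookkeeping, not a dynamics switch: dead voxels continue
to bleach and consume oxygen, as nothing in the underlying photochemistry
stops at cell death. "% GBM remaining" weights voxels by their GBM
fraction, not voxel counts. Only voxels with $F_{\mathrm{GBM}} > 0$ carry
photosensitizer and are integrated; elsewhere the dynamics are identically
zero.

`fixed_oxygen = TRUE` freezes $[^3O_2]$ at its initial value exactly
(both depletion and perfusion terms are skipped), reproducing the
no-depletion variant of the protocol studies.

### Heat

The temperature sub-grid (`thermal_subgrid()`) covers a cube around the
tumor-sphere corner — the hottest region — resampled from the scene by
nearest neighbor, with fraction-weighted $\rho$, $c_p$, $\kappa$. The
solver is forward Euler on
$\rho c_p \partial T/\partial t = \nabla\cdot(\kappa\nabla T) + \dot q$
with harmonic-mean face conductivities and $\dot q = \mu_a \Psi P$
(converted to W m⁻³) while the light is on. The time step is 0.9× the
explicit stability limit $\Delta x^2 \rho c_p / 6\kappa_{\max}$,
sub-stepped to land on whole seconds. Initial temperatures are 37 °C in
brain and 22 °C (room) in balloon/saline; brain-facing boundary voxels
have a 37 °C floor clamp standing in for metabolic regulation, other
boundary voxels are fixed at 22 °C, and pure conduction does the rest —
no Pennes perfusion term, so in-tissue perfusion cooling is represented
only by that boundary clamp. Optical properties and the fluence map are
held constant over the treatment.

Thermal material constants are *not* part of the optical literature the
rest of the package rests on; the package uses documented
literature-typical values (brain ρ = 1046 kg m⁻³, c_p = 3630 J kg⁻¹ K⁻¹,
κ = 0.51 W m⁻¹ K⁻¹; intralipid/saline as water), all overridable in
`material_table()`. Absolute temperature maxima are therefore
indicative, not calibrated; the package asserts conduction *physics*
(maximum principle, analytic benchmarks, saw-tooth fractionation
response, monotonicity in power) rather than specific peak temperatures.

### Protocols

`treatment_time_from_volume()` implements the clinical dosimetry rule
$t(\min) = 0.1176\,V_{\mathrm{intralipid}}(\mathrm{ml}) + 3.4276$,
rounded to 0.1 min *before* schedule construction (44 ml → 8.6 min).
The standard protocol splits the irradiation into five equal fractions
with 2 min dark breaks: 5 × 103.2 s on + 4 × 120 s off = 16.6 min.
Variants toggle fractionation, hold oxygen fixed, scale the threshold, or
change power/time/concentration; `run_sweep()` runs one axis at a time
against a shared fluence map and asserts nothing — it just tabulates.

## Reproducibility and problem sizes

Everything is deterministic given (configuration, seed): the transport
RNG is counter-seeded per packet, the phantom's optional noise field is
seeded, and the integrators are fixed-step. Two runs with the same seed
hash identically.

The test suite and the worked examples run on a desk-scale scene
(`demo_phantom()`: 48³ voxels at 0.5 mm, a 1.8 × 1.4 × 1.2 cm balloon,
2 × 10⁴ packets), chosen so the full pipeline — transport, 996 s of
kinetics, equilibration plus treatment conduction — completes in tens of
seconds while keeping every structural feature of the full-size scene.
The full-size geometry (250 × 231 × 155 voxels, 7 × 4 × 3 cm balloon) is
the package default for `make_phantom()` and runs the same code
unchanged; expect minutes-to-hours depending on packet count.

Because the desk phantom's cavity is smaller than the full-size one, the
same 2 W × 8.6 min deposits a higher wall fluence (≈330 J cm⁻² median at
the rim vs the 200 J cm⁻² design value), so its absolute kill fractions
are higher than full-geometry figures; directional and structural
behavior (kill front ≲ 1–2 mm, monotone parameter responses, ≲ 1–2-point
effect of oxygen depletion, saw-tooth heating) is preserved, and those
are what the tests assert.

## Known limitations

* Voxelized geometry only; no mesh surfaces, no time-resolved transport,
  no polarization, and no 420 nm component (its penetration is too
  shallow to matter here).
* The Krogh-cylinder perfusion term idealizes brain microvasculature;
  real capillary networks are irregular, so oxygen recovery is
  approximate.
* The 560 µM threshold was measured with a different photosensitizer
  (Photofrin); no measured PpIX value exists, hence the ±25 % sensitivity
  machinery.
* Kill percentages are geometry-specific. Comparisons *between* protocols
  on the same scene are the meaningful output.
* The thermal model is conduction-only with uncalibrated constants (see
  above).
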