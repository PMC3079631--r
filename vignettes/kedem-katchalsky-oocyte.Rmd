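---
title: "Modelling water and cryoprotectant transport in Xenopus oocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling water and cryoprotectant transport in Xenopus oocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

## The model

An oocyte is treated as a two-compartment osmometer: an osmotically
inactive volume $V_b$ (yolk, bound water and solids; 75% of the initial
volume for stage V/VI *Xenopus laevis* oocytes) plus free water in which
the internal impermeant osmoles $N_{imp}$ and the permeant solute amount
$N_s$ are dissolved. The Kedem–Katchalsky description of coupled water and
solute movement across the oolemma uses three phenomenological
coefficients — hydraulic conductivity $L_p$, solute permeability $P_s$ and
reflection coefficient $\sigma$:

$$\frac{dV}{dt} = J_v S, \qquad
J_v = L_p RT\left[(C_{imp}^{in} - C_{imp}^{out})
      + \sigma (C_s^{in} - C_s^{out})\right]$$

$$\frac{dN_s}{dt} = P_s S (C_s^{out} - C_s^{in})
      + (1 - \sigma)\,\bar{C}_s\, J_v S$$

with internal concentrations on the free-water basis
$C^{in} = N/(V - V_b - N_s \bar v_s)$ and $\bar{C}_s$ the arithmetic mean
of the internal and external permeant concentrations. The solvent-drag
term $(1-\sigma)\bar C_s J_v S$ is retained because $\sigma$ is a fitted,
reported quantity; without it $\sigma$ would only rescale the osmotic term
and the two-parameter form would make it largely inert. A `drag = FALSE`
switch selects the drag-free form for sensitivity checks. The
mean-concentration convention is the common choice in cryobiology
treatments of cell-volume dynamics; which exact variant the historical
fitting software used is not recoverable, so this choice is stated rather
than inherited.

Constants (all overridable through `physical_constants()`): $\bar V_w =
18$ cm³/mol, $\bar v_s = 54$ cm³/mol for ethylene glycol, $R = 82.3$
cm³·atm/(mol·K), $T = 293.15$ K (room temperature), and a 9× membrane
folding factor for the apparent sphere area. Solutions are ideal: 1 mOsm
= $10^{-6}$ osmol/cm³; quoted molarity/osmolarity pairs (0.9 M sucrose ≈
1450–1460 mOsm) are taken as supplied, never recomputed.

## Which membrane area?

The 9× folded area is the established convention for the *slope-based*
$P_f$ formula, and `compute_pf()`/`compute_ps()` use it. For the dynamic
K-K simulation and fitting the package defaults to the *apparent*
(geometric) sphere area, for a reason that is easy to demonstrate: with
the folded area and the permeability magnitudes typical of
aquaporin-expressing oocytes ($L_p \sim 2.6$ μm·min⁻¹·atm⁻¹, $P_{EG} \sim
25\times10^{-3}$ cm/min), the entire shrink–swell transient under 1.3 M
ethylene glycol completes within a single 10-s sample of the standard
recording grid, and the per-oocyte fit becomes numerically
non-identifiable. With the apparent area the transient spans the first
minute and every round-trip fit in the test suite recovers its generating
parameters to $10^{-6}$. Both bases are available via `area_basis=`; what
matters for internal consistency is that simulation and fitting use the
same one. The $P_f = L_p RT/\bar V_w$ identity is a unit conversion and
involves no area.

## Estimators

* `compute_pf()` — initial-slope osmotic water permeability,
  $P_f = V_0 \frac{d(V/V_0)}{dt} / (S \bar V_w \Delta Osm)$, default
  window the first 20 s of a hypotonic challenge.
* `compute_ps()` — solute permeability from isotonic solute substitution,
  $P_s = \frac{d(V/V_0)}{dt} / (S/V_0)$, default window 1 min.
* `estimate_lp_linear()` — the 2-min/10-min secant $L_p$ from hypertonic
  shrinkage. Because the volume decay is convex, the secant underestimates
  the tangent $L_p$, more severely at 10 min than at 2 min; the package
  reproduces that ordering rather than hiding it. The bias-free
  alternative is the model-based refit (`fit_kk()` with `t_max = 2`).
* `fit_kk()` — bounded nonlinear least squares of the simulator against an
  observed relative-volume trajectory, the per-oocyte $(L_p, P_s, \sigma)$
  estimator. Deterministic: a fixed 8-point multistart feeding
  `stats::nlminb`, best solution polished once; standard errors from the
  Gauss–Newton curvature at the optimum. Sum-of-squares residuals are
  taken on relative volume, which equalises oocyte sizes. With
  impermeant-only (sucrose) data, fit only $L_p$ (`fit_spec(free =
  "Lp")`): $\sigma$ and $P_s$ enter no active term and are
  non-identifiable there.

## Identifiability, honestly

Even with a permeant, the three-parameter fit on the standard 10-min,
10-s protocol is only marginally identified. For a fast transporter the
volume undershoot is ~0.04 relative units deep; with 1% measurement noise
there is a second, physically degenerate least-squares mode (very large
$L_p$, $\sigma \approx 0.03$, tiny $P_s$) in which water is in
quasi-static equilibrium and the shrink–swell shape is mimicked by the
impermeant balance alone. On roughly a third of noise realisations that
mode attains *lower* RSS than the truth basin, so no optimiser can rescue
the $\sigma$-free median. Consequences drawn here:

* `profile_identifiability()` exposes the $\sigma$ ridge (RSS as a
  function of fixed $\sigma$ with $(L_p, P_s)$ refitted) so users can see
  when $\sigma$ is determined by their data.
* The stochastic calibration in the acceptance suite fixes $\sigma$ at its
  generating value and measures $(L_p, P_s)$ recovery — the standard
  design when a nuisance parameter is unidentified. Under 1% noise and 50
  seeds the medians recover within 5% and the curvature standard errors
  sit within 5% of the empirical spread.
* Noise-free round trips (any parameters in bounds, 10-min trajectory)
  recover all three parameters to better than $10^{-3}$ relative; this is
  tested property-style over random draws.

## Uptake arithmetic

`intracellular_concentration()` implements the scintillation conversion
$[(T_{10}-T_0)/73000] \times 1.3\ \mu\mathrm{mol} / V$ with the final
volume $V$ in μl taken from the observed or simulated hypertonic
trajectory (a 0.12 cm oocyte is ~0.9 μl, shrinking to ~0.75–0.85 μl).
Negative net counts clamp to zero with a warning — they are measurement
noise, not errors. `isotonic_uptake_rate()` converts tracer counts to
pmol/min through the specific activity (counting efficiency defaults to 1,
i.e. cpm ≡ dpm, configurable). `predicted_concentration_from_kk()` closes
the loop between the simulator and the assay; note that on the
total-volume basis the long-time concentration plateaus near the bath
concentration times the free-water fraction, not the bath concentration
itself — consistent with measured intracellular values (0.1–0.4 mol/l)
sitting far below a 1.3 M bath.

## Sequence bookkeeping

Construct names (`"H53A/G54H/T85A"`) parse into ordered point-mutation
specs; `apply_mutations()` applies them on full-length coordinates or on
loop fragments via explicit offsets. The packaged fragment table of the
zebrafish Aqp3b loops A–E ships with offsets *inferred* from the named
mutation positions (H53, T85, H154, Y182, A217) because full-length
coordinates of the fragments are not part of the table; the offsets file
flags this. `verify_table2()` proves the internal consistency of the
fixture: every one of the 15 mutant rows derives exactly from the WT
fragments. `find_np_motifs()` scans N-P-X boxes and classifies the
canonical NPA against the NPT/NPS variants; the wild-type first box here
is the NPT variant, restored to NPA by T85A.

## The synthetic generator — what it does and does not emulate

`generate_batch()` stands in for raw oocyte recordings, which are not
publicly available. It draws per-oocyte $(L_p, P_s)$ lognormally around
population medians (permeabilities are positive and right-skewed; the true
inter-oocyte variability structure is unknowable from summary statistics,
so the default CV of 0.1 is an assumption), Gaussian diameters around 0.12
cm, simulates each protocol with the K-K model, applies multiplicative
Gaussian noise (default SD 0.01) to the relative volumes, and synthesises
Poisson scintillation counts around the noise-free predicted uptake. A
single seed expands deterministically into per-oocyte substreams, so any
subset of a batch is reproducible bit-for-bit.

It does **not** emulate: video/image noise structure (correlated errors,
drift), oocyte non-sphericity, membrane bursting under extreme pH,
unstirred-layer effects, or any pH dependence — pH is metadata attached to
baths and fixtures, acting only through the permeability values users
supply. A green test therefore establishes that the estimators invert the
model faithfully at realistic noise levels, not that the model captures
every feature of real recordings.

## Numerical choices

* Integrator: adaptive Dormand–Prince 5(4) in C++, default `rtol = 1e-8`,
  `atol = 1e-12` (`1e-10`/`1e-14` inside fits), steps clipped to land
  exactly on sample times; halving the tolerance moves sampled volumes by
  less than $10^{-6}$ (tested).
* Free-water floor: if $V - V_b - N_s \bar v_s$ reaches zero the model has
  broken down and the solver stops with an error rather than continuing.
* $N_s$ is floored at zero inside the right-hand side; transient tiny
  negatives from the drag term cannot propagate.
* Optimiser bounds: $L_p \in [0, 100]$ μm·min⁻¹·atm⁻¹, $P_s \in [0, 1]$
  cm/min, $\sigma \in [0, 1]$; internal scaling puts all free parameters
  on O(1)–O(100) so `nlminb` is well conditioned. Ties between multistarts
  resolve to the first-best, making results reproducible.
* The two printed osmolarities for 0.9 M sucrose are both honoured: 1450
  mOsm in the inactive-fraction context, 1460 mOsm in the hypertonic
  fitting context.

## Known limitations

Single permeant per protocol (no mixtures), no temperature ramps or
freezing physics, a single membrane (no separate vitelline envelope), no
hierarchical multi-oocyte fitting (per-oocyte fits plus
`summarize_batch()` mirror the per-oocyte analysis convention), and no
image processing — inputs begin at extracted diameters or volumes.
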