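# aquaflux

Quantitative analysis of water and cryoprotectant transport in *Xenopus
laevis* oocytes expressing aquaporins — the standard expression system for
characterising aquaglyceroporin permeability in cryobiology and membrane
biophysics.

Oocyte swelling/shrinkage assays yield time series of relative cell
volume under controlled bath changes. `aquaflux` turns those trajectories
into membrane transport coefficients:

* **Kedem–Katchalsky (K-K) simulation** of the two-compartment osmometer
  (osmotically inactive fraction `vb`, default 0.75) under step changes of
  bath composition:

  `dV/dt = Lp·S·RT·[(C_imp_in − C_imp_out) + σ(C_s_in − C_s_out)]`

  `dNs/dt = Ps·S·(C_s_out − C_s_in) + (1 − σ)·C̄s·Jv·S`

  with concentrations on the free-water basis (compiled adaptive
  Dormand–Prince integrator).
* **Per-oocyte nonlinear fitting** of `(Lp, Ps, σ)` from hypertonic
  shrink–swell trajectories (`fit_kk`), with a deterministic multistart,
  Gauss–Newton standard errors, and a `σ`-profile identifiability
  diagnostic.
* **Slope-based estimators**: osmotic water permeability
  `Pf = V0·d(V/V0)/dt / (S·Vw·ΔOsm)` from hypotonic swelling, solute
  permeability `Ps = d(V/V0)/dt / (S/V0)` from isotonic solute
  substitution, and the 2-/10-min secant `Lp` from hypertonic shrinkage;
  `Pf = Lp·RT/Vw` conversion.
* **Boyle–van't Hoff handling** of the osmotically inactive volume:
  `V_eq/V0 = vb + (1 − vb)·Osm_iso/Osm_bath`.
* **Radiolabel uptake arithmetic**: scintillation counts to intracellular
  cryoprotectant concentration, `[(T_t − T_0)/cal] × C_bath / V`, plus
  isotonic tracer uptake rates.
* **Aquaporin construct bookkeeping**: `H53A/G54H/T85A`-style mutation
  parsing, loop-fragment mutation application, NPA-box motif scanning
  (the wild-type studied here carries a variant NPT first box), and a
  self-verifying packaged fragment table.
* **Synthetic data generator** for end-to-end benchmarking: seeded
  batches with lognormal inter-oocyte variability, multiplicative
  trajectory noise and Poisson count tables.

## Worked example

Simulate a fast ethylene-glycol transporter (a 0.12 cm oocyte in 1.3 M
ethylene glycol + 200 mOsm impermeant) and refit its parameters:

```r
library(aquaflux)

geom <- oocyte_geometry(0.12)
geom
#> Oocyte geometry: d = 0.12 cm, V0 = 0.0009048 cm^3, A = 0.04524 cm^2, S = 0.4072 cm^2

bath <- bath_solution(200, 1.3, "ethylene_glycol")
tr <- kk_simulate(kk_parameters(Lp = 2.64, Ps = 25.49e-3, sigma = 0.8),
                  geom, bath, duration = 10)   # 10-s sampling
tr
#> Volume trajectory: 61 samples over 10 min, V0 = 0.0009048 cm^3
#>   rel volume range [0.9568, 1.0099]
```

The oocyte shrinks to 95.7% of its volume in the first half minute (water
leaves faster than the cryoprotectant enters), then re-swells past its
initial volume as ethylene glycol and water follow. Fitting the three
K-K coefficients back from the trajectory:

```r
fit_kk(tr, geom, bath)
#> K-K fit (61 samples, RSS 1.19e-17, 2/8 starts converged)
#>   Lp    = 2.64 um/(min.atm)  (SE 1.32e-08)
#>   Ps    = 0.02549 cm/min  (SE 5e-10)
#>   sigma = 0.8   (SE 1.55e-08)
```

Slope-based water permeability and the count conversion:

```r
pf_from_lp(2.57)                     # Lp (um/min/atm) -> Pf (cm/min)
#> [1] 0.3444692

m <- uptake_measurement(cpm_t = 27305, cpm_t0 = 0, V_final = 1.13)
intracellular_concentration(m)       # mol/l after hypertonic exposure
#> [1] 0.4303128
```

A trajectory measured at 10-s intervals that shrinks by 4% and re-swells
within 10 minutes, fit to `Lp ≈ 2.6` μm/(min·atm) and `Ps ≈ 25×10⁻³`
cm/min, is the signature of a highly ethylene-glycol-permeable
aquaglyceroporin; a water-injected control fits near `Lp ≈ 0.4` and
`Ps ≈ 0.5×10⁻³`.

Command line (installed launcher):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","aquaflux.R",package="aquaflux"))')" \
  simulate --Lp 2.57 --osm_impermeant 1460 --duration 10 --out out/
```

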