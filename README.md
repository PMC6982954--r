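# bmcal — bimaterial microcantilever calorimetry

`bmcal` models an optically heated bimaterial microcantilever (BMC) used as a
micro-calorimeter, and inverts its deflection response to the heat capacity of
a micro-scale sample — a single yeast cell, say — resting on the beam. It is
aimed at people designing or simulating BMC thermal sensors who want a tested,
scriptable reference implementation of the measurement chain: forward thermal
model → bimorph mechanics → time-constant regression → heat-capacity
inversion, plus a synthetic-data generator so every stage can be exercised
without instrument data.

## The model

A two-layer beam (Si₃N₄ structural layer over an Al coating) absorbs a uniform
optical flux *q_s* and loses heat by convection with coefficient *h*. Because
the Biot number *Bi = hD/k* is tiny (≈0.003 for a 5 µm yeast cell, far
smaller still for the beam), the beam is a *lumped mass*: its temperature
*T(t)* is spatially uniform and obeys

    t_c dT/dt + (T − T_amb) = q_s / h_eff,      t_c = C_A / h_eff,

where *C_A = Σ ρᵢCpᵢtᵢ* is the areal heat capacity of the stack and
*h_eff* counts the convecting faces. The solution is the first-order step
response, and since the mismatch of thermal expansion coefficients makes tip
deflection exactly linear in temperature (curvature
*κ = 6Δα·ΔT·(t₁+t₂)/(t₂²K)*, the classical bimetal-strip result), the
measured tip trace is

    v(t) = v_∞ − (v_∞ − v₀) e^(−t/τ).

Fitting a bare-beam (calibration) trace and a sample-loaded trace gives two
time constants τ_B < τ_T. With the per-body relation *τ = ρCp·L_c/h* and the
volume-weighted mixture rule

    (ρCp)_T = [(ρCp)_B V_B + (ρCp)_S V_S] / (V_B + V_S),

the sample's volumetric heat capacity follows from the pair of fits. A 1-D
distributed conduction–convection model is included to *certify* the lumped
assumption (spatial spread ≪ temperature rise) rather than assume it.

## Worked example

Calibrate on a bare beam, measure with a yeast-like cell loaded at the beam
centre (volume pinned so V_B/V_S = 34), both at 1 % Gaussian noise:

```r
library(bmcal)
mats  <- default_materials()
stack <- layer_stack(mats$si3n4, mats$aluminium, t_top = 1e-6, t_bottom = 0.5e-6)
beam  <- beam_geometry(600e-6, 76e-6, stack)
cell  <- sample_spec(mats$yeast, length = 5e-6, height = 2e-6, width = 5e-6,
                     position_on_beam = 300e-6,
                     volume_override = beam_volume(beam) / 34)
loaded <- beam_model(beam, environment_spec(), irradiation(), sample = cell)
bare   <- beam_model(beam, environment_spec(), irradiation())

lumped_params(bare)
#> <bmc_lumped_params> tc = 84.62 ms, T_inf = 305.6 K (rise 12.5 K), h_eff = 40 W/m^2K

cal  <- generate_trace(synthetic_spec(bare,   noise_sigma = 0.01, seed = 1))
meas <- generate_trace(synthetic_spec(loaded, noise_sigma = 0.01, seed = 2))
fit_cal  <- fit_exponential(cal)
fit_meas <- fit_exponential(meas)
fit_report(fit_cal)
#> Exponential step-response fit: v(t) = v_inf - (v_inf - v0) exp(-t/tau)
#>   v_inf = 27.7527 um (se 0.0213 um)
#>   v0    = 0.048103 um (se 0.0634 um)
#>   tau   = 84.686 ms (se 0.362 ms)
#>   n = 500, rss = 3.90866e-11 m^2, residual sd = 0.2804 um, R^2 = 0.99820896
#>   converged: TRUE

estimate_heat_capacity(fit_cal, fit_meas, loaded, density = 1100)
#> <bmc_estimate> (eq_shortcut)
#>   tau_B = 84.686 ms, tau_T = 87.47 ms -> tau_S = 5077.9 ms
#>   (rhoCp)_S = 2.5241e+06 J/(m^3 K) (se 4.77e+05), V_B/V_S = 34
#>   cp_S = 2.2946 kJ/(kg K)
```

The loaded beam is ~2.8 ms slower than the bare one; inverting that small
difference (amplified by V_B/V_S = 34 — hence the large standard error)
returns (ρCp)_S = 2.52 MJ/(m³K) against a generator truth of 2.39 MJ/(m³K),
i.e. a 5.7 % error at this noise level and seed; the noiseless chain is exact
to machine precision. Dividing by the supplied density gives the specific
heat in kJ/(kg K).

`reference_demo()` audits the bundled published reference configuration,
including two values it deliberately does *not* reproduce: the shortcut
inversion formula evaluated on the published fitted time constants gives
≈181 ms where the published text states 230 ms, and the published specific
heat requires a density that is not part of the published inputs. Both are
reported side by side and flagged rather than tuned away.

## Command line

A thin wrapper over the same functions lives in `inst/cli/bmc.R`:

```sh
Rscript inst/cli/bmc.R simulate --out trace.csv --noise 0.01 --seed 1
Rscript inst/cli/bmc.R fit --in trace.csv --out fit.json
Rscript inst/cli/bmc.R invert --calib fitB.json --loaded fitT.json \
        --config loaded.json --out estimate.json
Rscript inst/cli/bmc.R demo
```

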