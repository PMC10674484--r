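# lipoaggr

Quantitative analysis of lipopeptide self-assembly from fluorescence and
coordinate data. The package implements the full measurement-to-size chain
used to characterize aggregating peptide drugs (here modelled on a
Liraglutide-like lipopeptide):

- **TCSPC decay analysis** — multi-exponential fits of time-correlated
  single-photon-counting histograms (Poisson-weighted Levenberg–Marquardt,
  optional IRF reconvolution) and amplitude/intensity-weighted average
  lifetimes.
- **Anisotropy → size** — the Perrin spherical-rotor relation
  `r0/r = 1 + τ/σ` and the Stokes–Einstein–Debye relation
  `σ = η·Vh(molar)/RT` convert a steady-state anisotropy `r` and lifetime
  `τ` into a rotational correlation time `σ`, a per-molecule hydrodynamic
  volume `Vh = σRT/(ηN_A)` and radius `Rh = (3Vh/4π)^(1/3)`.
- **cac estimation** — the pyrene I1/I3 vibronic ratio versus
  log10(concentration) is fitted with two straight lines over all
  admissible splits of the points; the critical aggregation concentration
  is the concentration at their intersection, with a seeded bootstrap CI
  and an explicit `no_breakpoint` flag for degenerate data.
- **Structure metrics** — radius of gyration, Kirkwood hydrodynamic radius
  `Rh = ⟨r_ij⁻¹⟩⁻¹` over carbon atoms, sphere volumes from the mean radii,
  and per-residue Cα RMSF (Kabsch superposition) from multi-MODEL PDB
  trajectories.
- **Synthetic data** — seeded generators for every input (decays with
  Poisson noise and Gaussian IRF, piecewise-linear titrations, helix and
  uniform-ball coordinate fixtures with closed-form reference metrics), so
  the entire chain runs offline and is testable end to end.

## Worked example

```r
library(lipoaggr)

# anisotropy chain at the measured conditions (water, 298 K, r0 = 0.260)
h <- hydro_chain(r = 0.110, tau_ns = 3.0, hydro_conditions(), r_se = 0.001)
round(c(sigma_ns = h$sigma_ns, Vh_nm3 = h$Vh_nm3, Rh_A = h$Rh_A), 2)
#> sigma_ns   Vh_nm3     Rh_A
#>     2.20    10.17    13.44

# simulate a tri-exponential decay and recover its components
tr  <- generate_decay(decay_sim_spec(peak_counts = 1e4, seed = 101))
fit <- fit_multiexponential(tr, n_components = 3)
round(fit$components, 3)
#>   alpha tau_ns
#> 1 0.446  1.222
#> 2 0.413  3.629
#> 3 0.142  7.384
round(fit$average_lifetime_ns, 2)
#> [1] 3.09

# cac from a noiseless synthetic titration with a 4.3 uM breakpoint
ts <- generate_titration(titration_sim_spec(noise_sd = 0))
fit_cac_segmented(ts, n_bootstrap = 0)$cac_uM
#> [1] 4.3
```

The interpretation: a ~2.2 ns rotational correlation time at a 3 ns
lifetime corresponds to a ~10 nm³, ~13 Å object — a small oligomer rather
than a monomer — and the pyrene assay places the onset of large-scale
aggregation at 4.3 μM.

## Analysis workflow

The `analysis/` scripts run the chain as a narrative, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R       # synthetic decay, titration, helix PDB
Rscript analysis/02_fit_decay.R      # 1-3 component fits, <tau>
Rscript analysis/03_hydrodynamics.R  # concentration series -> sigma, Vh, Rh
Rscript analysis/04_cac.R            # segmented cac fit + bootstrap CI
Rscript analysis/05_structure.R      # Rg/Rh/RMSF of the helix trajectory
```

`run_pipeline(run_config(...))` exposes the same stages programmatically
with JSON reports per stage and a recorded seed.

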