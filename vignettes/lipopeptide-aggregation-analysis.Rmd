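---
title: "Quantifying lipopeptide self-assembly: from photons and coordinates to sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipopeptide self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipoaggr)
```

## The problem

Amphiphilic peptides — here a Liraglutide-like lipopeptide carrying an
18-carbon chain on a lysine side chain — self-assemble in water once their
concentration crosses a critical aggregation concentration (cac). Three
experimental windows on that process are quantified by this package:

1. **Time-resolved fluorescence** of the peptide's tryptophan reports the
   conformational heterogeneity of the monomer/oligomer ensemble through a
   multi-exponential intensity decay, and supplies the average lifetime
   needed by the anisotropy analysis.
2. **Steady-state fluorescence anisotropy** reports the rotational mobility
   of the emitting species, which the Perrin and Stokes–Einstein–Debye
   relations convert into a hydrodynamic volume and radius.
3. **The pyrene assay** locates the cac as the kink in the I1/I3 vibronic
   ratio versus log-concentration.

A fourth, computational window takes atomic coordinates (e.g. MD snapshots
saved as multi-MODEL PDB) and computes the same kind of size descriptors —
radius of gyration, Kirkwood hydrodynamic radius, sphere volumes — plus
per-residue RMSF, so that simulated aggregates can be compared with the
spectroscopic sizes on one scale.

## Models and assumptions

### Multi-exponential TCSPC decays

A TCSPC histogram has expectation
$m(t) = B + \sum_i A_i e^{-t/\tau_i}$ (optionally convolved with the
instrument response) and Poisson counting noise. `fit_multiexponential()`
minimizes the Poisson-weighted squared residuals with Levenberg–Marquardt
on log-parameters (enforcing $\tau_i, A_i > 0$; the background is floated
and clipped at zero).

The counting variance is taken from the **model**, not the observed counts
(`weighting = "pearson"`). Observed-count weighting ("neyman") is offered
for comparison, but it systematically distorts multi-exponential fits: tail
channels that fluctuate low receive too much weight, and at a 10^4-count
peak the middle lifetime of a tri-exponential decay is misestimated by
>10% on average, versus 2–3% with model weighting. This is a property of
the estimator, not the optimizer — starting the fit at the true parameters
reproduces the same bias.

Initialization is a deterministic multi-start: a count-weighted log-linear
slope gives a single-lifetime scale, around which candidate lifetime sets
are spread geometrically (spreads 2, 3, 5; two center shifts); amplitudes
start from a weighted linear solve with lifetimes fixed. The lowest-
deviance converged start wins, so the fit is reproducible without any
random numbers. Fits whose adjacent lifetimes approach within 5% are
flagged ill-conditioned; non-convergence raises an error rather than
returning garbage.

The average lifetime is amplitude-weighted by default,
$\langle\tau\rangle = \sum_i \alpha_i \tau_i / \sum_i \alpha_i$, which is
the convention that reproduces the published 3.0 ns from
$\alpha = (0.45, 0.41, 0.14)$, $\tau = (1.22, 3.66, 7.40)$ ns (the direct
sum gives 3.09 ns; the printed value is rounded). Intensity weighting
($\sum \alpha_i\tau_i^2 / \sum \alpha_i\tau_i \approx 4.5$ ns) is provided
but is not the default, since it is incompatible with the downstream
hydrodynamic chain calibrated on 3.0 ns.

```{r lifetimes}
fit <- data.frame(alpha = c(0.45, 0.41, 0.14), tau_ns = c(1.22, 3.66, 7.40))
average_lifetime(fit, "amplitude")
average_lifetime(fit, "intensity")
```

### The anisotropy chain

For a spherical rotor the Perrin relation links the steady-state
anisotropy $r$, the limit anisotropy $r_0$, the fluorescence lifetime
$\tau$ and the rotational correlation time $\sigma$:

$$\frac{r_0}{r} = 1 + \frac{\tau}{\sigma}
  \quad\Longrightarrow\quad \sigma = \frac{\tau}{r_0/r - 1},$$

and the Stokes–Einstein–Debye relation converts $\sigma$ into a
hydrodynamic volume, $\sigma = \eta V_h^{molar}/RT$. The printed SED form
is dimensionally molar; the per-molecule volume therefore divides by
Avogadro's number:

$$V_h = \frac{\sigma R T}{\eta N_A}, \qquad
  R_h = \left(\frac{3 V_h}{4\pi}\right)^{1/3}.$$

This convention is verified by the chain reproducing 10.2 nm³ and 13.4 Å
from $r = 0.110$, $\tau = 3$ ns, $\eta = 0.89$ cP, $T = 298$ K,
$r_0 = 0.260$:

```{r chain}
h <- hydro_chain(0.110, 3.0, hydro_conditions(), r_se = 0.001)
round(c(sigma_ns = h$sigma_ns, Vh_nm3 = h$Vh_nm3, Rh_A = h$Rh_A), 2)
```

Defaults: $r_0 = 0.260$ (tryptophan excited at 295 nm), g-factor 1 (no
instrument polarization correction is modelled). Anisotropies at or above
$r_0$ are rejected — the rotor equation has no finite solution there.
Uncertainties propagate first-order from the standard error on $r$.
Non-spherical (Perrin-factor) rotors and microviscosity corrections are
out of scope.

### cac by segmented regression

The assay descends from the solvatochromism of pyrene: its I1/I3 vibronic
ratio is high in water and drops when the probe partitions into an apolar
aggregate interior. Below the cac the ratio is nearly constant in
log-concentration; above it, it falls steeply. `fit_cac_segmented()`
implements the two-line reading of that curve: every split of the sorted
points into a left and a right set (each ≥ 3 points — a two-point line has
zero residual and would overfit) is fitted with one line per side in
$(\log_{10} c, \text{ratio})$ space; a split is admissible when the lines
intersect between its bracketing concentrations, and the admissible split
with the smallest total SSE wins. The cac is $10^{x^*}$ at the
intersection abscissa $x^*$. Discrete split search was chosen over
continuous breakpoint optimization for determinism and robustness at the
assay's typical 10–12 points. A sigmoid ("inflection point") model was
deliberately not used: the two-regime geometry is the operational
definition here.

Degeneracy is handled explicitly: if no split is admissible, or the two
slopes agree within their joint standard error, the fit is flagged
`no_breakpoint` instead of returning a spurious intersection. Confidence
intervals come from a seeded nonparametric bootstrap over points
(default 500 resamples). The estimator is exactly scale-equivariant in
concentration and invariant to adding a constant to all ratios.

```{r cac}
ts <- generate_titration(titration_sim_spec(noise_sd = 0))
fit_cac_segmented(ts, n_bootstrap = 0)$cac_uM
```

### Coordinate descriptors

For a frame of coordinates (Å) with masses $m_i$:

- $R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}$, mass-weighted
  by default to match the GROMACS `gyrate` convention.
- Kirkwood $R_h = \langle r_{ij}^{-1} \rangle^{-1}$ over unordered pairs
  of the selected atoms. The selection defaults to **all carbon atoms** —
  the formula's "C atoms" is read literally, not as Cα-only — with a
  selection argument for sensitivity checks. Coincident atoms are rejected
  with the offending pair named. For trajectories the radius is computed
  per frame and then averaged (mean ± sd); the alternative placement of
  the ensemble average (averaging $1/r_{ij}$ over frames first) is a
  documented convention choice, not derivable from the formula itself.
- $V_g$ and $V_h$ apply the sphere formula $(4/3)\pi(R/10)^3$ to the
  **mean** radii — the convention under which each published volume equals
  the cube of its printed radius.
- RMSF: frames are rigid-body superposed (Kabsch) onto the selection's
  mean structure, the mean is recomputed once after the first fit, and
  $\text{rmsf}_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}$.
  Whether the original analysis superposed before averaging is not
  documented; both modes are provided (`superpose = TRUE/FALSE`).

$R_h \le R_g$ is *not* asserted anywhere: the two metrics respond
differently to shape, and for compact clusters Kirkwood $R_h$ can exceed
or fall below $R_g$.

## What the synthetic generators emulate — and what they do not

All inputs can be simulated, so the whole chain runs and is tested with no
external data. Each generator reproduces exactly the statistical structure
its analysis assumes:

- `generate_decay()` — multi-exponential mean, optional Gaussian IRF
  (normalized on the channel grid, centred five sigma into the window;
  edge effects ignored since the 50 ns window dwarfs both the lifetimes
  and the ~1 ns pulse), peak scaled to the requested counts, Poisson
  noise. It does **not** emulate detector afterpulsing, dead-time, or
  wavelength-dependent IRF shift, so passing tests say nothing about those
  artefacts.
- `generate_titration()` — exact piecewise-linear ratio in log-c with one
  kink and homoscedastic Gaussian noise. The assay's real noise magnitude
  is not published; the 0.02 default is a conventional spectrofluorometer
  repeatability, and the simulated kink is perfectly sharp whereas
  micellization produces a rounded transition over a finite concentration
  band. Recovery results on this generator therefore bound the
  breakpoint-location error of the *estimator*, not of the chemistry.
- `generate_pyrene_spectra()` — two Gaussian vibronic bands whose height
  ratio follows the titration model, with monotone self-quenching that
  leaves the ratio untouched (ratios are intensity-normalized by
  construction, so quenching is deliberately ignored downstream).
- `build_helix()` / `sample_uniform_ball()` — geometry fixtures with
  closed-form or brute-force-verifiable metrics: a uniform ball has
  $R_g \to \sqrt{3/5}\,R$ and Kirkwood $R_h \to (5/6) R$ as $n \to
  \infty$.

Every generator is bit-reproducible given its seed, and noiseless outputs
round-trip through their analyses at machine precision.

## Numerical choices

- Decay fits run on log-parameters; convergence tolerances are
  `ftol = ptol = 1e-12`, 500 iterations, and the reduced chi-square uses
  $N - (2k+1)$ degrees of freedom.
- The tail fit starts at the count maximum when no start is given;
  reconvolution fits the full trace instead. Which mode the original
  lifetime analysis used is not stated; both are provided and neither is
  asserted as "the" published procedure.
- Segment fits use closed-form simple regression (the breakpoint search
  and bootstrap evaluate thousands of small fits; `lm()` overhead would
  dominate otherwise). The intersection-consistency of the returned
  segments holds to 1e-9.
- Degenerate inputs fail loudly: zero I3 intensity, coincident atoms,
  anisotropy above the limit value, non-uniform time grids and
  inconsistent model atom counts are all rejected with messages naming
  the offending quantity.

## Problem sizes in the shipped analyses and tests

The packaged analysis scripts and the test-suite work at the study's own
scales: 1024-channel, 50 ns decays at a 10^4-count peak (50 seeded
replicates for the recovery statistics), 12-point titrations over
0.2–21 μM at 2% ratio noise (200 seeds), 2×10^4-point ball fixtures for
the closed-form checks, and a 20-frame, 32-residue helix trajectory for
the RMSF and summary paths.

## Known limitations

- Only spherical rotors: no Perrin ellipsoid factors, no segmental-motion
  (wobble-in-cone) models; the hydrodynamic sizes inherit every caveat of
  the rigid-sphere picture.
- No time-resolved anisotropy decay $r(t)$ and no lifetime-distribution
  (maximum-entropy) analysis; component counts are chosen by the user and
  compared via reduced chi-square.
- The PDB reader handles multi-MODEL files; binary trajectory formats
  (XTC/GRO) are an extension point, not implemented.
- Instrument-level observables with no computable procedure here — DLS
  size distributions, zeta potentials, amyloid-signature emission bands —
  are outside the package's scope.
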