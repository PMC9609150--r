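# anisofret

Quantitative analysis of carotenoid delivery into fluorescently labelled
lipid membranes, from polarized time-correlated single photon counting
(TCSPC) histograms to physical quantities: rotational correlation time,
membrane microviscosity, and FRET-based estimates of how much carotenoid
actually arrived in the bilayer.

The intended user is a membrane-biophysics lab measuring a lipophilic
rotor probe (e.g. a BODIPY) in liposomes before and after adding a
carotenoid — either loaded directly during liposome synthesis or carried
in by a water-soluble carotenoprotein — and wanting numbers, not just
decay curves.

## What it computes

**Anisotropy → microviscosity.** From the four polarizer geometries
(I_VV, I_VH, I_HV, I_HH) the package estimates the detector sensitivity
ratio G = I_HV/I_HH, builds the anisotropy decay

    r(t) = (I_VV − G·I_VH) / (I_VV + 2G·I_VH),

fits it with a multiexponential r(t) = Σ Ã_j exp(−t/θ_j), summarizes with
the amplitude-weighted correlation time θ = Σ Ã_j θ_j / Σ Ã_j, and
converts to microviscosity by the Stokes–Einstein–Debye relation
η = 3 k_B T θ / (4π R³).

**Lifetimes → FRET.** Intensity decays I(t) = I_VV + 2G·I_VH are fitted
with f(t) = Σ A_i exp(−t/τ_i) (tail fit or IRF reconvolution), giving the
amplitude-weighted lifetime τ_av. Förster theory then yields the overlap
integral J, the Förster distance R0 = 0.211·(κ² n⁻⁴ Φ_D J)^(1/6) Å, the
transfer efficiency W = 1 − τ_DA/τ_D, the mean donor–acceptor distance
R = R0·(1/W − 1)^(1/6), and the minimum delivered acceptor concentration
(fast-component amplitude share × probe concentration).

**Orientation statistics.** Per-frame κ² = (d·a − 3(d·r)(a·r))² factors
and their dynamic (time) average from molecular-axis series, tilt-angle
and membrane-depth probability densities, and angular state occupancies.

**Synthetic data.** A seeded generator emulates the polarized TCSPC
instrument (photoselection forward model, Gaussian IRF, detector bias,
Poisson counting), Gaussian band spectra and unit-vector orientation
ensembles, so the entire chain is testable with known ground truth.

## Worked example

Simulate a donor-quenching measurement (82% of a fast 1.45 ns component,
18% of 5.601 ns; r0 = 0.35, θ = 2 ns, detector bias G = 1.2, 5·10⁶
photons) and analyze it back:

```r
library(anisofret)

truth <- ground_truth(
  intensity_components = cbind(c(0.82, 0.18), c(1.45, 5.601)),
  anisotropy_r0 = 0.35, anisotropy_components = cbind(1, 2),
  g_true = 1.2, total_counts = 5e6, irf_fwhm = 0, seed = 42)
sim <- simulate_polarized_decays(truth, time_max = 30, n_channels = 2048)

g <- compute_g_factor(sim$HV, sim$HH)
#> G = 1.202518 +/- 0.001501          # true 1.2, inside 2 SE

aniso <- build_anisotropy(sim$VV, sim$VH, as.numeric(g))
rot <- fit_rotational_correlation(aniso, n_components = 1)
#> theta (amplitude-weighted) = 1.978 ns, fitted r0 = 0.3493

microviscosity(rot$theta_ns, temperature_K = 293.15, probe_radius_nm = 0.5)
#> Microviscosity: 15.29 mPa s (theta = 1.978 ns, T = 293.15 K, R = 0.5 nm)

fit <- fit_multiexp(aniso$total, n_components = 2)
#> A1 = 2.738e+04 (81.95%), time = 1.445 +/- 0.0043 ns
#> A2 = 6033 (18.05%),     time = 5.57  +/- 0.022  ns
amplitude_weighted_mean(fit)
#> 2.1899                             # true 0.82*1.45 + 0.18*5.601 = 2.197
```

Both lifetimes, their amplitude split, G, θ and r0 come back within a few
standard errors of the generating truth. The FRET arithmetic on measured
lifetimes works the same way on real data:

```r
efficiency_from_lifetimes(5.601, 4.971)   # donor-only vs donor+acceptor
#> 0.1125
distance_from_efficiency(59, 0.310)       # R0 = 59 A, W = 31.0%
#> 67.4                                   # mean donor-acceptor distance, A
delivered_concentration(0.1819, 1000)     # fast share 18.19%, 1 uM probe
#> 181.9                                  # nM of delivered acceptor, minimum
```

A thin command-line front end over the same functions lives in
`inst/cli/anisofret.R` (subcommands `simulate`, `fit-decay`, `gfactor`,
`anisotropy`, `viscosity`, `fret`, `kappa2`, `orientation-density`,
`run`).

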