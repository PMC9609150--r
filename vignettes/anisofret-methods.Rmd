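---
title: "From polarized photon histograms to membrane microviscosity and carotenoid delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From polarized photon histograms to membrane microviscosity and carotenoid delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisofret)
```

## The measurement model

A pulsed laser excites a fluorescent rotor probe (a lipophilic BODIPY)
embedded in liposome membranes, and a TCSPC board histograms photon arrival
times behind an emission polarizer. Four polarizer geometries are recorded
(first letter excitation, second detection): `VV`, `VH` with vertical
excitation, and `HV`, `HH` with horizontal excitation. Photoselection
splits the emission into components parallel and perpendicular to the
excitation polarization,

$$I_\parallel(t) = \tfrac{1}{3} I(t)\,[1 + 2r(t)], \qquad
  I_\perp(t) = \tfrac{1}{3} I(t)\,[1 - r(t)],$$

where $I(t)$ is the polarization-free intensity decay and $r(t)$ the
anisotropy decay. The detector chain is more sensitive to one polarization
than the other; with horizontal excitation both analyzer settings view the
same emission, so the ratio

$$G = I_{HV} / I_{HH}$$

isolates that sensitivity ratio. `compute_g_factor()` estimates $G$ from
*integrated* window counts rather than a channel-wise ratio: the integrated
form is the ratio of two Poisson sums and remains stable at low
per-channel counts. The anisotropy and total intensity are then

$$r(t) = \frac{I_{VV} - G\,I_{VH}}{I_{VV} + 2G\,I_{VH}}, \qquad
  I(t) = I_{VV} + 2G\,I_{VH}.$$

Both decays are approximated by multiexponential models,
$f(t) = \sum_i A_i e^{-t/\tau_i}$ and
$r(t) = \sum_j \tilde A_j e^{-t/\theta_j}$, and summarized by their
amplitude-weighted means
$\tau_{av} = \sum A_i \tau_i / \sum A_i$ and
$\theta = \sum \tilde A_j \theta_j / \sum \tilde A_j$
(`amplitude_weighted_mean()`).

An important practical point the package enforces through its pipeline: in
an anisotropic sample the raw `VV` histogram is *not* a pure
multiexponential — it carries products of intensity and anisotropy
exponentials. Lifetimes are therefore fitted on the reconstructed total
$I(t)$ (or on magic-angle data), which is exactly multiexponential.

## Rotational correlation time and microviscosity

For a spherical rotor of hydrodynamic radius $R$ in a medium of viscosity
$\eta$ the Stokes–Einstein–Debye relation gives

$$\theta = \frac{4 \pi \eta R^3}{3 k_B T}
  \quad\Longleftrightarrow\quad
  \eta = \frac{3 k_B T \theta}{4 \pi R^3}.$$

`microviscosity()` reports $\eta$ in mPa·s (numerically equal to
centipoise); `theta_from_viscosity()` is the exact algebraic inverse and
round-trips to better than $10^{-12}$ relative. $\eta$ is linear in
$\theta$ and in $T$; both linearities are asserted numerically in the test
suite. The probe radius is a required user input — it enters cubed, and no
consensus hydrodynamic radius exists for membrane-embedded BODIPY rotors,
so absolute viscosities inherit the radius uncertainty while *relative*
comparisons across temperature or composition do not.

## FRET quantification of carotenoid delivery

When a carotenoid acceptor enters the membrane within Förster range of the
probe, the donor decay gains a fast quenched component. The chain
implemented in `fret_quant`-land is standard Förster theory:

* **Overlap integral** (`overlap_integral()`):
  $J = \int F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4 d\lambda \big/
  \int F_D(\lambda)\,d\lambda$, trapezoidal on the union grid with linear
  interpolation, zero outside each spectrum's support. $J$ is invariant to
  donor rescaling; the acceptor must be on the molar-extinction scale, and
  `scale_to_extinction()` pins an arbitrary-unit spectrum to a literature
  peak coefficient (defaults: 75,300 M⁻¹cm⁻¹ for echinenone, 125,300 for
  β-carotene).
* **Förster distance** (`forster_distance()`):
  $R_0 = 0.211\,(\kappa^2 n^{-4} \Phi_D J)^{1/6}$ Å with $J$ in
  M⁻¹cm⁻¹nm⁴. Conventions for the prefactor differ across the literature
  depending on the units carried by $J$; this package pins the
  0.211/nm⁴ convention and documents it, since silent unit mismatches in
  $R_0$ are a classic failure mode. Defaults $\Phi_D = 0.95$ and
  $n = 1.4251$ describe the BODIPY probe in a soy-lecithin emulsion.
* **Efficiency from lifetime quenching** (`efficiency_from_lifetimes()`):
  $W = 1 - \tau_{DA}/\tau_D$, with amplitude-weighted mean lifetimes as
  inputs when decays are multiexponential. A $\tau_{DA} > \tau_D$ input is
  rejected rather than returned as a negative efficiency, because it almost
  always means the two lifetimes were swapped.
* **Distance** (`distance_from_efficiency()`):
  $R = R_0 (1/W - 1)^{1/6}$, with `efficiency_from_distance()` as the
  exact inverse.
* **Delivered concentration** (`delivered_concentration()`): the amplitude
  share of the fast component is the fraction of donors engaged in
  transfer; multiplied by the probe concentration (default 1 donor per
  acceptor, exposed as `acceptors_per_donor`) it bounds the delivered
  acceptor concentration from below. Acceptors beyond transfer range are
  invisible to this estimate, hence "minimum".

## Orientation statistics

Membrane molecular-dynamics trajectories (generated elsewhere; the package
deliberately reads only plain delimited text, since any MD engine can
export per-frame vectors) supply donor dipole, acceptor dipole and
separation direction per frame. `kappa2_frame()` evaluates
$\kappa = \hat d \cdot \hat a - 3(\hat d \cdot \hat r)(\hat a \cdot \hat
r)$ and returns $\kappa^2 \in [0, 4]$. `kappa2_ensemble()` averages
$\kappa^2$ *per frame* and then over time — the dynamic-averaging regime,
appropriate when reorientation is fast relative to the transfer time. The
alternative (κ of time-averaged vectors) answers a different question and
is intentionally not offered. The reported spread is the population SD of
the time series, the natural descriptive "±" for a trajectory.

Tilt angles are computed as $\varphi = \arccos|\hat u \cdot \hat n|$,
folded into [0°, 90°]: transition dipoles and polyene long axes are
headless, so $\hat u$ and $-\hat u$ are the same orientation.
`angle_density()` returns a raw per-degree density by default; a
`sin_correction` flag converts to density per solid angle, because
published tilt histograms are frequently shown in either convention
without saying which. `depth_density()` histograms the center-of-mass
position along the bilayer normal, clipping out-of-bilayer excursions into
the edge bins with an explicit clipped-frame count. `state_occupancy()`
takes the angular boundary between orientational states as an explicit
parameter rather than hard-coding one, since any boundary between a
membrane-spanning and a membrane-parallel pose is a judgment call.

## What the synthetic generator emulates — and what it does not

`simulate_polarized_decays()` is the package's test surface. It produces
the four geometries from a `ground_truth()` record by the forward model
above, then:

* convolves with a Gaussian IRF of configurable FWHM (default 0.1 ns; the
  true instrument response of a ps-pulsed diode is narrower but
  asymmetric, and a Gaussian captures the width without pretending to know
  the shape). `irf_fwhm = 0` gives the ideal delta-response used by the
  forward-model oracle tests;
* applies the detector bias as a single scale factor $1/G$ on the
  horizontal-analyzer channels — a wavelength-independent bias is all the
  $G$-factor formalism can identify anyway;
* scales so the expected *isotropic total* $I_{VV} + 2G\,I_{VH}$ carries
  `total_counts` photons (this normalization makes photon conservation
  exact in expectation), adds a constant background rate, and draws
  per-channel independent Poisson counts under a fixed seed.

The default grid is 0–25 ns in 4096 channels, a standard TCSPC board depth
at a 25 MHz-class repetition window. Not modelled: pile-up, dead time,
afterpulsing, homoFRET between probe molecules, probe partitioning
kinetics, and liposome size dispersity. Passing the recovery suites
therefore demonstrates correctness of the *analysis chain* under ideal
counting statistics, not robustness to every instrument artifact.

`simulate_spectrum()` builds Gaussian-band spectra (band width is the
Gaussian σ, in nm); `simulate_orientation_ensemble()` draws unit vectors
uniformly on the sphere, uniformly within a spherical cap, or as a fixed
axis — enough to generate known-truth ensembles for every orientation
statistic.

## Numerical choices

* **Fitting.** Bounded Levenberg–Marquardt (`minpack.lm`) on a residual
  vector weighted by per-channel σ. Poisson weighting uses
  σ² = max(counts, 1), the standard Neyman weighting; anisotropy fits use
  the delta-method variance of $r$ propagated from the VV/VH counts inside
  `build_anisotropy()`. Initial lifetimes are log-spaced about the
  empirical 1/e time of the tail, with amplitudes from linear least
  squares at those lifetimes; a fixed five-point multi-start schedule
  (scale factors 1, 1/3, 3, 1/10, 10 on the lifetime ladder) makes results
  deterministic while escaping poor starts. Tail fits begin at the peak
  channel by default; reconvolution fits use the full grid.
* **Failure is a value.** Non-convergence returns a flagged
  `multiexp_fit` with `converged = FALSE` rather than an error or a
  silent bad fit; a singular information matrix or any relative standard
  error above 100 % clears the `identifiable` flag with a warning. Exact
  (noise-free) fits skip the identifiability judgment: with zero residual
  variance, standard errors carry no information.
* **Masking, not clamping.** Anisotropy channels whose denominator
  $I_{VV} + 2G\,I_{VH}$ falls below 30 counts are masked; at that
  threshold the per-channel SD of $r$ stays below roughly 0.03. Clamping
  $r$ into its physical range would bias the tail fit.
* **No $r_\infty$ term by default.** The anisotropy model is a pure
  multiexponential, matching the analysis convention for freely rotating
  rotor probes; a hindered-rotor plateau can be freed with
  `offset = TRUE`.
* **Model order is manual.** `n_components` is an argument (mono- vs
  bi-exponential is a scientific choice in this workflow), and no
  information criterion second-guesses it.

## Problem sizes in the test suite

Unit tests run on 512–2048-channel grids with 10⁵–5·10⁶ photons; the
parameter-recovery suite uses 20 Poisson replicates of a two-component
fixture (82 % of 1.45 ns + 18 % of 5.601 ns, $r_0 = 0.35$, θ = 2 ns,
G = 1.2, 5·10⁶ photons) and checks median lifetime errors below 5 % and
the G estimate within its propagated uncertainty. Orientation moment and
sine-law checks use 10⁵–10⁶ frames. These sizes give comfortable
statistical margins for 3·SE-style assertions while keeping the whole
suite in seconds.

## Known limitations

* Weighted least squares, not Poisson maximum likelihood: at very low
  counts (peak counts below ~100) the Neyman weights bias lifetimes
  slightly; the fixtures here are far from that regime.
* The G-factor estimate assumes the horizontal-excitation pair shares the
  emission decay exactly; scattered excitation light is not modelled.
* Absolute microviscosity requires the probe radius (see above) and
  assumes stick-boundary spherical rotation, which is an idealization for
  a disk-like BODIPY core.
* The delivered-concentration estimate is a lower bound under the
  1-donor:1-acceptor assumption, and inherits any error in the
  fast/slow amplitude decomposition.
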