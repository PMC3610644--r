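---
title: "Spin-label CW-ESR analysis: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin-label CW-ESR analysis: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinprobe)
```

## The measurement problem

Nitroxide spin labels — MTSSL attached to an engineered cysteine of a
protein (the R1 side chain), or doxyl groups placed at carbon 5, 12 or 16 of
stearic acid (n-SASL) and incorporated into a micelle or bilayer — report
the mobility, ordering and polarity of their immediate surroundings through
the shape of their continuous-wave X-band ESR spectrum. The recorded signal
is the first derivative of the absorption versus magnetic field; the
nitrogen nucleus (I = 1) splits it into three hyperfine manifolds
m = +1, 0, −1 from low to high field.

`spinprobe` covers the full empirical analysis chain for such spectra:

* simulation of the two canonical regimes (fast isotropic tumbling; axially
  ordered anisotropic averaging) and of noisy two-component mixtures, with
  known ground truth;
* feature extraction: line centres, peak-to-peak heights and widths, outer
  and inner hyperfine splittings;
* derived parameters: order parameter $S$, rotational correlation time
  $\tau_C$, mobility $\delta^{-1}$, polarity $a_N$, and mean residue
  ellipticity for accompanying CD data;
* two-component spectral unmixing and subtraction;
* control-versus-treated comparison reports.

## Models

### Fast-motion triplet

In the motional-narrowing regime each manifold is a Lorentzian centred at
$B_0 - m\,a_N$ ($m = +1$ is the low-field line) whose peak-to-peak width
depends on $m$:

$$W(m) = W_0 + B\,m + C\,m^2 .$$

All three manifolds carry the same spin population (equal double
integrals), so peak-to-peak heights scale as $1/W(m)^2$ — the property that
connects heights to widths throughout the package. The correlation time is
estimated from the height pattern:

$$\tau_C = k\, W_0 \left(\sqrt{h_0/h_{+1}} + \sqrt{h_0/h_{-1}} - 2\right),$$

with $k = 6.5\times10^{-10}$ s/G by default (the standard pseudoisotropic
constant; it is a configurable parameter of `correlation_time()` and
`esr_config()`). Substituting the height–width relation shows that for a
purely quadratic width dependence $\tau_C = 2kC$; `width_coef_for_tauc()`
inverts this closed relation so the simulator can target any $\tau_C$
without circular use of the measurement code: the recovery tests measure
heights and widths from the lineshape, they never read $C$ back.

### Ordered axial powder

A probe undergoing fast but orientationally restricted motion in an axially
symmetric environment shows effective couplings $A_\parallel$ and
$A_\perp$. The absorption is the orientational average

$$A(B) \propto \int_0^{\pi/2} \sin\theta \sum_m
  L\!\left(B - B_0 + m\,A_\mathrm{eff}(\theta)\right)\, d\theta,
  \qquad
  A_\mathrm{eff}(\theta) = \sqrt{A_\parallel^2\cos^2\theta +
  A_\perp^2\sin^2\theta},$$

with $L$ a Lorentzian of the intrinsic width; the simulator returns its
field derivative, evaluated analytically per orientation. g-anisotropy is
neglected (one centre field): at X-band the nitrogen hyperfine coupling
dominates the outer splitting, which is the only quantity the order
parameter uses. The order parameter normalizes the measured anisotropy by
the rigid-limit tensor:

$$S = \frac{A_\parallel - A_\perp}{A_{zz} - (A_{xx}+A_{yy})/2},$$

with $(A_{xx}, A_{yy}, A_{zz}) = (6.0, 6.0, 32.0)$ G by default, the
standard doxyl stearate values. An optional polarity correction multiplies
by $[(A_{xx}+A_{yy}+A_{zz})/3]\,/\,[(A_\parallel+2A_\perp)/3]$; it is off
by default, and both forms always travel with the result as attributes, so
the choice is transparent. No fixed empirical offset is added to the
measured inner splitting: published analyses sometimes correct
$A_\perp$ by a constant, but any such correction here must be made
explicitly by the caller.

### Empirical mobility and polarity

For R1 side chains and mid-chain probes the package reports the model-free
parameters $\delta^{-1} = 1/W_0$ (inverse central linewidth; larger means
more mobile) and the measured $a_N$ (half the distance between the outer
zero crossings; larger means more polar surroundings).

### Two-component spectra

Protein-bound and free label, or bulk and boundary lipid, superpose
linearly. After unit-spin normalization (double integral = 1), amplitudes
in a non-negative least-squares fit of two basis spectra are spin-count
fractions. With only two components the NNLS solution is the unconstrained
least-squares solution when feasible and otherwise the better single-basis
boundary solution, which is solved exactly. A small per-component field
shift (±2 G) is optionally fitted by one-dimensional minimization of the
residual, two coordinate sweeps, so sub-Gauss centre offsets between bases
and composite do not bias fractions.

## What the generator emulates — and what it does not

The synthetic spectra are the package's study material, standing in for
instrument data. Defaults (chosen once, as typical X-band nitroxide
conditions):

* centre field 3350 G; axis step 0.05 G (a 160 G sweep at 3200 points);
* $a_N$ near 15 G, central widths 1.5–2 G for mobile probes;
* ordered spectra parameterized through `powder_params_for_order()`, which
  fixes the isotropic average $(A_\parallel + 2A_\perp)/3$ at a
  membrane-like 15 G so the anisotropy is controlled by $S$ alone;
  intrinsic width 1 G;
* orientational quadrature: Gauss–Legendre on $\cos\theta$ with 500 nodes
  (the integrand is smooth, so convergence is spectral);
* noise: i.i.d. Gaussian per field point; the signal-to-noise ratio is
  defined as max |intensity| / sigma.

Simulated spectra are returned normalized to unit double integral on their
axis, so spin-count bookkeeping (mixture fractions, subtraction areas) is
exact by construction even though Lorentzian tails extend beyond any finite
sweep.

Not emulated: g-anisotropy and its field-dependent line positions,
slow-motion lineshapes outside the motional-narrowing regime (no
stochastic-Liouville treatment), inhomogeneous (Gaussian) broadening from
unresolved proton couplings, modulation over-broadening, and the noise
correlation introduced by the modulation filter. Passing recovery tests
therefore demonstrates correctness of the analysis chain under its own
lineshape assumptions, not robustness to every distortion of real
instrument data — in particular, peak-to-peak quantities from heavily
modulation-broadened spectra will be biased in ways these tests do not
probe.

## Numerical choices

**Integration.** Both passes of the double integral use the trapezoidal
rule: exact for piecewise-linear data, no tuning, and linear — which is
what makes areas compose.

**Extremum detection.** Local extrema are pruned by prominence: adjacent
max/min pairs whose amplitude difference is below max(6 sigma, 1e-5 of the
range) are removed iteratively, with sigma estimated from the outer 5% of
the sweep. Pair pruning cannot remove a lone baseline bump at either end of
the extremum sequence, so an amplitude floor of 5 sigma is applied
afterwards, and the triplet detector additionally discards weak leading and
trailing extrema while more than three lines remain. When noise creates
duplicate candidates for the hyperfine extrema, the candidate farthest from
the spectrum centre wins for the outer pair and the nearest for the inner
pair.

**Extremum refinement.** Positions and values are refined by a local cubic
fit (±3 samples initially, then a window scaled to about 0.3 of the
measured line width, capped at ±12 samples). A parabola — the more common
choice — ignores the odd cubic term of a derivative Lorentzian around its
extremum and biases peak-to-peak widths outward by about
$(\mathrm{window}/\mathrm{width})^2$, which exceeds 1% for a 1 G line on a
0.05 G grid; the cubic removes that leading-order bias and falls back to a
parabola only for degenerate fits.

**Overlap correction.** The three triplet lines have overlapping tails that
displace each other's extrema; for broad lines ($W_0 = 4$ G at
$a_N = 14$ G) the apparent central width is biased by ~2.6%. Since the
lineshape model is a sum of Lorentzians, `locate_triplet()` iterates:
model the two neighbouring lines from their measured centre, width and
height, subtract them, and re-measure the line on the cleaned signal (two
rounds by default). After correction, zero-noise width and splitting
recovery is better than 0.5% across $W_0 \in [1, 4]$ G.

**Line centres.** Zero crossings, not midpoints of extrema: the zero
crossing of a derivative Lorentzian is its resonance field exactly,
independent of width.

**Smoothing.** Off by default, because any smoothing widens peak-to-peak
features; a quadratic Savitzky–Golay filter (odd window, 5–11 points) is
available behind a flag for noisy data.

**Alignment.** `resample_align()` interpolates both spectra onto one
uniform grid and maximizes the integer-lag cross-correlation with parabolic
peak refinement, default window ±5 G: genuine free-versus-bound centre
shifts are sub-Gauss, so a larger required shift indicates a data problem.
A limitation follows from the windowed search: a true offset far beyond the
window on a periodic three-line signal can alias to an interior correlation
maximum instead of hitting the window boundary, in which case no error can
be raised; the error is guaranteed only when the correlation peak lands on
the boundary.

**Degenerate inputs.** A powder spectrum fed to the triplet detector fails
the three-resolved-lines pattern check; an isotropic spectrum fed to the
extrema detector is rejected because its outer and inner separations differ
by only about two line widths (threshold: four central widths); a fully
subtracted composite ("empty remainder") and non-positive double integrals
raise errors rather than propagating nonsense.

## Problem sizes

The test-suite and reproduction-script simulations use 160 G sweeps at
0.05 G per point (2000–3200 points), 500 quadrature nodes, sweeps of 27
parameter combinations for triplet recovery, four order-parameter targets,
and 20 random mixtures at two noise levels — sizes chosen to exercise every
code path at the instrument-realistic digitization while keeping the whole
suite under a minute.

## Known limitations

* The correlation-time expression assumes the fast-motion regime; for
  $\tau_C$ beyond a few nanoseconds at X-band the height-ratio formula
  degrades and a slow-motion treatment (out of scope here) is required.
* The order parameter uses raw measured splittings; near the motional
  collapse of the inner extrema ($S \lesssim 0.2$) `measure_extrema()`
  will refuse rather than extrapolate.
* Unmixing supports exactly two components; spectra with three resolvable
  populations need a different tool.
* `read_spectrum()` accepts plain-text two-column files only; proprietary
  spectrometer formats must be exported to text first.

## A worked example

```{r example, eval = FALSE}
library(spinprobe)

# an ordering increase seen by a headgroup-region probe
tensor <- hyperfine_tensor(6, 6, 32)
ctrl <- simulate_axial_powder(powder_params_for_order(0.45, tensor),
                              field_axis(3350, 40))
prot <- simulate_axial_powder(powder_params_for_order(0.58, tensor),
                              field_axis(3350, 40))
analyze_pair(ctrl, prot, probe = "5-SASL", lipid = "LPG")

# quantifying a boundary-lipid population
mobile <- triplet_params(a_N_G = 15.2, W0_G = 1.8)
bound <- powder_params(3350, 25.4, 9.8, intrinsic_width_G = 2.5)
axis <- field_axis(3350, 55)
obs <- simulate_mixture(
  mixture_spec(list(mobile, bound), c(0.7, 0.3),
               noise_sigma = 2e-4, seed = 1), axis)
unmix(obs$spectrum,
      list(simulate_isotropic_triplet(mobile, axis),
           simulate_axial_powder(bound, axis)))
```
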