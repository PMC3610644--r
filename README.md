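# spinprobe

Analysis of continuous-wave ESR spectra of nitroxide spin labels, for
researchers using site-directed spin labeling (the MTSSL/R1 side chain on
proteins) or positional lipid probes (5-, 12-, 16-doxyl stearic acid,
n-SASL) to follow protein–membrane interactions.

A CW-ESR spectrum is the first derivative of absorption versus magnetic
field; a nitroxide splits it into three nitrogen hyperfine lines whose
positions, widths and heights encode the probe's mobility, ordering and
the polarity of its environment. `spinprobe` implements the standard
empirical analysis chain:

* **Order parameter** of an ordered (micelle- or bilayer-bound) probe from
  the outer (2A∥) and inner (2A⊥) hyperfine splittings,

  S = (A∥ − A⊥) / (A_zz − (A_xx + A_yy)/2),

  with the rigid-limit tensor defaulting to (6.0, 6.0, 32.0) G and an
  optional polarity-correction factor.
* **Rotational correlation time** of a fast-tumbling probe from
  m-dependent motional narrowing,

  τ_C = k · W₀ · (√(h₀/h₊₁) + √(h₀/h₋₁) − 2),   k = 6.5×10⁻¹⁰ s/G,

  where W₀ is the central peak-to-peak width and h₊₁, h₀, h₋₁ the low-,
  centre- and high-field line heights.
* **Mobility and polarity**: δ⁻¹ = 1/W₀ and the measured isotropic
  hyperfine splitting a_N.
* **Spectral unmixing**: non-negative least squares on unit-spin-normalized
  bases, so amplitudes are spin-count fractions — for quantifying
  immobilized ("boundary lipid") populations or subtracting free label.
* **Simulation** of fast-motion triplets, axial powder patterns and noisy
  mixtures with known ground truth, used both for validation and as
  synthetic study data.
* **Reports**: control-versus-treated comparison tables with percent
  changes, written as deterministic CSV.

Everything flows through one container, `esr_spectrum` (field axis in
Gauss + first-derivative intensity + acquisition metadata), readable from
and writable to plain-text two-column files.

## Worked example

An ordering increase seen by a headgroup-region probe (control S = 0.45
versus protein-bound S = 0.58, simulated, then re-measured end-to-end):

```r
library(spinprobe)
tensor <- hyperfine_tensor(6, 6, 32)
ctrl <- simulate_axial_powder(powder_params_for_order(0.45, tensor),
                              field_axis(3350, 40))
prot <- simulate_axial_powder(powder_params_for_order(0.58, tensor),
                              field_axis(3350, 40))
analyze_pair(ctrl, prot, probe = "5-SASL", lipid = "LPG")
#>    probe lipid parameter control_value treated_value percent_change
#> 1 5-SASL   LPG         S     0.4602961      0.590353       28.25505
#>   percent_change_rounded
#> 1                     28
```

The measured order parameters land within 0.011 of the simulation ground
truth (the residual bias comes from the finite intrinsic linewidth shifting
the inner hyperfine extrema), and the percent change reproduces the
ground-truth 29% to within a point.

Quantifying a two-population spectrum — 70% mobile lipid probe, 30%
motionally restricted by a bound protein:

```r
mobile <- triplet_params(a_N_G = 15.2, W0_G = 1.8)
bound  <- powder_params(3350, 25.4, 9.8, intrinsic_width_G = 2.5)
axis   <- field_axis(3350, 55)
obs <- simulate_mixture(
  mixture_spec(list(mobile, bound), c(0.7, 0.3),
               noise_sigma = 2e-4, seed = 1), axis)
unmix(obs$spectrum,
      list(simulate_isotropic_triplet(mobile, axis),
           simulate_axial_powder(bound, axis)))
#> <esr_unmix> two-component fit
#>   fractions: 0.6972 / 0.3028
#>   shifts: -0.000 / +0.004 G, residual rms 0.00021
```

And a tumbling-rate measurement from a chain-end probe:

```r
s <- simulate_isotropic_triplet(
  triplet_params(a_N_G = 15.29, W0_G = 1.6,
                 C_coef_G = width_coef_for_tauc(1.48)),
  field_axis(3350, 50))
f <- locate_triplet(s)
f
#> <triplet_features>
#>   centers: 3334.710 / 3350.000 / 3365.290 G
#>   heights h+1/h0/h-1: 0.02609 / 0.07637 / 0.02609
#>   W0 = 1.609 G, a_N = 15.290 G
correlation_time(f)   # 1.487 ns, ground truth 1.48 ns
```

The methods vignette (`vignettes/spin-label-esr.Rmd`) documents the
lineshape models, the numerical choices behind the feature extraction, and
what the synthetic data do and do not emulate. A thin command-line wrapper
for file-based comparisons is installed at
`inst/scripts/esr-compare.R`.

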