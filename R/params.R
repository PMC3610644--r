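# Derived molecular parameters: order parameter, rotational correlation
# time, empirical mobility and polarity, percent changes, and CD mean
# residue ellipticity.

#' Rigid-limit nitroxide hyperfine tensor
#'
#' Principal components of the nitrogen hyperfine tensor used to normalize
#' measured splittings into an order parameter. The defaults (6.0, 6.0,
#' 32.0 G) are the standard values for doxyl stearate probes.
#'
#' @param Axx_G,Ayy_G,Azz_G Principal values in Gauss; `Azz_G` must exceed
#'   `(Axx_G + Ayy_G) / 2` or the order-parameter denominator collapses.
#'
#' @return An object of class `hyperfine_tensor`.
#' @export
hyperfine_tensor <- function(Axx_G = 6.0, Ayy_G = 6.0, Azz_G = 32.0) {
  if (Azz_G <= (Axx_G + Ayy_G) / 2) {
    stop("need Azz_G > (Axx_G + Ayy_G) / 2")
  }
  structure(list(Axx_G = Axx_G, Ayy_G = Ayy_G, Azz_G = Azz_G),
            class = "hyperfine_tensor")
}

#' Order parameter from hyperfine extrema
#'
#' Computes the segmental order parameter of an ordered nitroxide from the
#' measured outer and inner hyperfine splittings, with `A_par =
#' two_A_par_G / 2` and `A_perp = two_A_perp_G / 2`:
#'
#' \deqn{S = \frac{A_\parallel - A_\perp}{A_{zz} - (A_{xx}+A_{yy})/2}}
#'
#' S is 0 for isotropic motion and 1 at the rigid limit. With
#' `polarity_correction = TRUE` the base form is multiplied by the ratio of
#' isotropic couplings \eqn{[(A_{xx}+A_{yy}+A_{zz})/3] / [(A_\parallel +
#' 2A_\perp)/3]}, which compensates polarity differences between the crystal
#' reference and the membrane environment. Both forms are always computed and
#' attached as attributes `S_base` and `S_corrected`; the base form is the
#' default result.
#'
#' Values marginally outside [0, 1] from measurement error are returned with
#' a warning, not clipped.
#'
#' @param e An `extrema_features` object from [measure_extrema()], or a list
#'   with elements `two_A_par_G`, `two_A_perp_G`.
#' @param tensor A [hyperfine_tensor()].
#' @param polarity_correction Apply the isotropic-coupling ratio?
#'
#' @return The order parameter (numeric scalar) with attributes `S_base`,
#'   `S_corrected` and `form`.
#' @export
order_parameter <- function(e, tensor = hyperfine_tensor(),
                            polarity_correction = FALSE) {
  stopifnot(inherits(tensor, "hyperfine_tensor"))
  A_par <- e$two_A_par_G / 2
  A_perp <- e$two_A_perp_G / 2
  if (!is.finite(A_par) || !is.finite(A_perp) || A_perp <= 0) {
    stop("invalid hyperfine extrema")
  }
  if (A_par < A_perp) {
    stop("A_par smaller than A_perp: not an ordered spectrum")
  }
  denom <- tensor$Azz_G - (tensor$Axx_G + tensor$Ayy_G) / 2
  if (denom <= 0) stop("non-positive order-parameter denominator")
  S_base <- (A_par - A_perp) / denom
  a_crystal <- (tensor$Axx_G + tensor$Ayy_G + tensor$Azz_G) / 3
  a_meas <- (A_par + 2 * A_perp) / 3
  S_corr <- S_base * a_crystal / a_meas
  S <- if (polarity_correction) S_corr else S_base
  if (S < -0.05 || S > 1.05) {
    warning(sprintf("order parameter %.3f far outside [0, 1]; check input",
                    S))
  } else if (S < 0 || S > 1) {
    warning(sprintf("order parameter %.3f marginally outside [0, 1]", S))
  }
  structure(S, S_base = S_base, S_corrected = S_corr,
            form = if (polarity_correction) "corrected" else "base")
}

#' Rotational correlation time from motional narrowing
#'
#' Estimates the rotational correlation time of a fast-tumbling nitroxide
#' from the m-dependence of its line heights, assuming pseudoisotropic
#' motion and Lorentzian lines:
#'
#' \deqn{\tau_C = k \, W_0 \left(\sqrt{h_0/h_{+1}} + \sqrt{h_0/h_{-1}} -
#'   2\right)}
#'
#' where `W0` is the peak-to-peak width of the central line (Gauss), the
#' `h` are peak-to-peak line heights and `k` (seconds per Gauss, default
#' 6.5e-10) is the standard pseudoisotropic proportionality constant,
#' exposed as a parameter.
#'
#' @param f A `triplet_features` object from [locate_triplet()], or a list
#'   with elements `W0_G`, `h_plus1`, `h_0`, `h_minus1`.
#' @param k_s_per_G Proportionality constant in s/G.
#'
#' @return Correlation time in nanoseconds.
#' @export
correlation_time <- function(f, k_s_per_G = 6.5e-10) {
  h <- c(f$h_plus1, f$h_0, f$h_minus1)
  if (any(!is.finite(h)) || any(h <= 0)) {
    stop("line heights must be positive")
  }
  if (!is.finite(f$W0_G) || f$W0_G <= 0) {
    stop("W0_G must be positive")
  }
  bracket <- sqrt(h[2L] / h[1L]) + sqrt(h[2L] / h[3L]) - 2
  if (bracket < -1e-6) {
    stop("inconsistent line heights: central line narrower than expected")
  }
  bracket <- max(bracket, 0)
  k_s_per_G * f$W0_G * bracket * 1e9
}

#' Empirical mobility and polarity parameters
#'
#' The inverse central linewidth `delta^-1 = 1 / W0` is the standard
#' empirical mobility parameter for an R1 side chain (larger = more mobile),
#' and the measured isotropic hyperfine splitting `a_N` reports the polarity
#' of the probe's surroundings (larger = more polar).
#'
#' @param f A `triplet_features` object from [locate_triplet()].
#'
#' @return A list with `delta_inv_per_G` (1/Gauss) and `a_N_G` (Gauss).
#' @export
mobility_polarity <- function(f) {
  if (!is.finite(f$W0_G) || f$W0_G <= 0) {
    stop("W0_G must be positive")
  }
  list(delta_inv_per_G = 1 / f$W0_G, a_N_G = f$a_N_meas_G)
}

#' Percent change between a control and a treated value
#'
#' Returns `100 * (treated - control) / control`, unrounded. Reporting code
#' rounds to the nearest integer (see [analyze_pair()]), which is the
#' convention for narrated percent changes; the unrounded value is what this
#' function returns.
#'
#' @param control Control value, strictly positive.
#' @param treated Treated value.
#'
#' @return Unrounded percent change (numeric scalar).
#' @export
percent_change <- function(control, treated) {
  if (!is.numeric(control) || !is.finite(control) || control <= 0) {
    stop("control must be a positive number")
  }
  100 * (treated - control) / control
}

#' Mean residue ellipticity from a raw CD signal
#'
#' Converts an observed ellipticity in millidegrees to mean residue
#' ellipticity in deg cm^2 dmol^-1:
#' `MRE = theta_mdeg / (10 * path_cm * conc_molar * (n_residues - 1))`,
#' using the number of peptide bonds (`n_residues - 1`).
#'
#' @param theta_mdeg Observed ellipticity in millidegrees (any sign).
#' @param n_residues Number of residues in the protein (at least 2).
#' @param conc_molar Protein concentration in mol/L.
#' @param path_cm Cuvette path length in cm.
#'
#' @return Mean residue ellipticity in deg cm^2 dmol^-1.
#' @export
mean_residue_ellipticity <- function(theta_mdeg, n_residues, conc_molar,
                                     path_cm) {
  if (n_residues < 2) stop("n_residues must be at least 2")
  if (conc_molar <= 0 || path_cm <= 0) {
    stop("concentration and path length must be positive")
  }
  theta_mdeg / (10 * path_cm * conc_molar * (n_residues - 1))
}
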