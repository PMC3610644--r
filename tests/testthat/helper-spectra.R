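# Shared fixtures: all synthetic, generated at test time.

x_band <- 3350

triplet_axis <- function(half = 45, step = 0.05) {
  field_axis(x_band, half, step)
}

# axis wide enough for a powder pattern with the given parameters
powder_axis <- function(p, pad = 2, step = 0.05) {
  field_axis(p$center_G, p$A_par_G + 10 * p$intrinsic_width_G + pad, step)
}

sim_triplet <- function(a_N = 15, W0 = 1.5, B = 0, C = 0, center = x_band,
                        half = 45, step = 0.05) {
  simulate_isotropic_triplet(
    triplet_params(center_G = center, a_N_G = a_N, W0_G = W0,
                   B_coef_G = B, C_coef_G = C),
    field_axis(center, half, step))
}

sim_powder_for_S <- function(S, width = 1, step = 0.05) {
  p <- powder_params_for_order(S, intrinsic_width_G = width)
  simulate_axial_powder(p, powder_axis(p, step = step))
}

# mobile triplet + immobilized powder bases on one grid, for unmixing tests
unmix_fixture <- function(step = 0.05) {
  mobile <- triplet_params(a_N_G = 15.2, W0_G = 1.8)
  bound <- powder_params(x_band, A_par_G = 25.4, A_perp_G = 9.8,
                         intrinsic_width_G = 2.5)
  axis <- field_axis(x_band, 55, step)
  list(mobile = mobile, bound = bound, axis = axis,
       bases = list(simulate_isotropic_triplet(mobile, axis),
                    simulate_axial_powder(bound, axis)))
}
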