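test_that("symmetric triplet has equal lines at the prescribed positions", {
  s <- sim_triplet(a_N = 15, W0 = 1.5)
  f <- locate_triplet(s)
  expect_equal(f$line_centers_G, c(3335, 3350, 3365), tolerance = 1e-3)
  # outer and central heights agree up to the small tail overlap between
  # lines; the symmetric pair agrees to grid precision
  expect_equal(f$h_plus1 / f$h_0, 1, tolerance = 1e-3)
  expect_equal(f$h_plus1, f$h_minus1, tolerance = 1e-6)

  # parameter validation
  expect_error(triplet_params(a_N_G = 20), "13, 17")
  expect_error(triplet_params(W0_G = 1, B_coef_G = -2), "positive")
  expect_error(simulate_isotropic_triplet(triplet_params(),
                                          field_axis(3350, 10)),
               "too narrow")
})

test_that("m-dependent widths follow the Lorentzian height-width relation", {
  s <- sim_triplet(a_N = 15, W0 = 1.5, C = 0.6)
  f <- locate_triplet(s)
  expect_lt(f$h_plus1, f$h_0)
  expect_equal(f$h_plus1, f$h_minus1, tolerance = 1e-4)
  # sqrt(h0 / h_m) should reproduce W(m) / W(0) = (W0 + C) / W0
  expect_equal(sqrt(f$h_0 / f$h_plus1), (1.5 + 0.6) / 1.5,
               tolerance = 0.01)
})

test_that("axial powder reduces to the isotropic triplet when A_par = A_perp", {
  draws <- list(c(A = 14, W = 1.2), c(A = 15.5, W = 2.0), c(A = 16.5, W = 0.8))
  for (d in draws) {
    p <- powder_params(3350, A_par_G = d[["A"]], A_perp_G = d[["A"]],
                       intrinsic_width_G = d[["W"]])
    axis <- powder_axis(p, pad = 30)
    pow <- simulate_axial_powder(p, axis)
    tri <- simulate_isotropic_triplet(
      triplet_params(a_N_G = d[["A"]], W0_G = d[["W"]]), axis)
    expect_lt(max(abs(pow$intensity - tri$intensity)) /
                max(abs(tri$intensity)), 1e-6)
  }
})

test_that("powder outer splitting matches 2 A_par and spin count is conserved", {
  p <- powder_params(3350, A_par_G = 32, A_perp_G = 6,
                     intrinsic_width_G = 0.8)
  axis <- powder_axis(powder_params(3350, 32, 6, intrinsic_width_G = 1.6))
  s <- simulate_axial_powder(p, axis)
  # brute-force outer extrema on the simulation grid
  lo_side <- axis < 3350 - 10
  hi_side <- axis > 3350 + 10
  lo <- axis[lo_side][which.max(s$intensity[lo_side])]
  hi <- axis[hi_side][which.min(s$intensity[hi_side])]
  expect_equal(hi - lo, 64, tolerance = 64 * 0.05)

  # double integral independent of intrinsic width and anisotropy
  wide <- simulate_axial_powder(
    powder_params(3350, 32, 6, intrinsic_width_G = 1.6), axis)
  expect_equal(double_integral(s), double_integral(wide), tolerance = 1e-6)
  other <- simulate_axial_powder(powder_params(3350, 25, 9, 0.8), axis)
  expect_equal(double_integral(other), double_integral(s), tolerance = 1e-4)
})

test_that("mixtures compose by spin fraction with seeded noise", {
  fx <- unmix_fixture()
  spec1 <- mixture_spec(list(fx$mobile), 1, noise_sigma = 0)
  m1 <- simulate_mixture(spec1, fx$axis)
  expect_equal(m1$spectrum$intensity, fx$bases[[1]]$intensity,
               tolerance = 1e-12)

  spec <- mixture_spec(list(fx$mobile, fx$bound), c(0.7, 0.3),
                       noise_sigma = 0)
  m <- simulate_mixture(spec, fx$axis)
  expect_equal(double_integral(m$spectrum), 1, tolerance = 1e-9)
  part <- m$spectrum
  part$intensity <- part$intensity - 0.3 * m$components[[2]]$intensity
  expect_equal(double_integral(part), 0.7, tolerance = 1e-6)

  noisy <- mixture_spec(list(fx$mobile, fx$bound), c(0.7, 0.3),
                        noise_sigma = 1e-4, seed = 11)
  n1 <- simulate_mixture(noisy, fx$axis)
  n2 <- simulate_mixture(noisy, fx$axis)
  expect_identical(n1$spectrum$intensity, n2$spectrum$intensity)
  other_seed <- mixture_spec(list(fx$mobile, fx$bound), c(0.7, 0.3),
                             noise_sigma = 1e-4, seed = 12)
  n3 <- simulate_mixture(other_seed, fx$axis)
  expect_gt(max(abs(n3$spectrum$intensity - n1$spectrum$intensity)), 0)

  expect_error(mixture_spec(list(fx$mobile, fx$bound), c(0.7, 0.4)),
               "sum to 1")
  expect_error(mixture_spec(list(fx$mobile), 1, noise_sigma = -1),
               "non-negative")
})

test_that("width coefficient inversion matches the closed tau_C relation", {
  k <- 6.5e-10
  for (tau in c(0.96, 1.12, 1.48)) {
    C <- width_coef_for_tauc(tau, k)
    expect_equal(2 * k * C * 1e9, tau, tolerance = 1e-12)
  }
  # and the ground-truth parameters reproduce the target isotropic coupling
  p <- powder_params_for_order(0.58)
  expect_equal((p$A_par_G + 2 * p$A_perp_G) / 3, 15, tolerance = 1e-12)
  expect_equal((p$A_par_G - p$A_perp_G) / 26, 0.58, tolerance = 1e-12)
})
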