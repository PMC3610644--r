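test_that("order parameter limits and hand-computed value", {
  tensor <- hyperfine_tensor(6, 6, 32)

  iso <- list(two_A_par_G = 30, two_A_perp_G = 30)
  expect_equal(as.numeric(order_parameter(iso, tensor)), 0)
  expect_equal(as.numeric(order_parameter(iso, tensor,
                                          polarity_correction = TRUE)), 0)

  rigid <- list(two_A_par_G = 64, two_A_perp_G = 12)
  expect_equal(as.numeric(order_parameter(rigid, tensor)), 1)
  # correction ratio is exactly 1 at the rigid limit with this tensor
  expect_equal(as.numeric(order_parameter(rigid, tensor,
                                          polarity_correction = TRUE)), 1)

  # base form by hand: (21.08 - 6) / 26
  e <- list(two_A_par_G = 2 * 21.08, two_A_perp_G = 2 * 6)
  expect_equal(as.numeric(order_parameter(e, tensor)), 0.58,
               tolerance = 1e-12)
  # both forms always travel with the result
  expect_equal(attr(order_parameter(e, tensor), "S_base"), 0.58,
               tolerance = 1e-12)
  expect_true(is.numeric(attr(order_parameter(e, tensor), "S_corrected")))
})

test_that("order parameter is monotone in the splittings (base form)", {
  tensor <- hyperfine_tensor()
  A_perp <- 6
  S_par <- vapply(seq(10, 30, by = 2), function(A_par) {
    as.numeric(order_parameter(list(two_A_par_G = 2 * A_par,
                                    two_A_perp_G = 2 * A_perp), tensor))
  }, numeric(1))
  expect_true(all(diff(S_par) > 0))
  S_perp <- vapply(seq(4, 14, by = 1), function(ap) {
    as.numeric(order_parameter(list(two_A_par_G = 2 * 28,
                                    two_A_perp_G = 2 * ap), tensor))
  }, numeric(1))
  expect_true(all(diff(S_perp) < 0))
})

test_that("order parameter rejects or flags unphysical input", {
  tensor <- hyperfine_tensor()
  expect_error(order_parameter(list(two_A_par_G = 10, two_A_perp_G = 20),
                               tensor), "smaller")
  expect_error(hyperfine_tensor(20, 20, 18), "Azz")
  expect_warning(order_parameter(list(two_A_par_G = 2 * 33,
                                      two_A_perp_G = 12), tensor),
                 "marginally outside")
  expect_warning(order_parameter(list(two_A_par_G = 2 * 40,
                                      two_A_perp_G = 12), tensor),
                 "far outside")
})

test_that("correlation time closed forms, scale invariance and errors", {
  eq <- list(W0_G = 2, h_plus1 = 5, h_0 = 5, h_minus1 = 5)
  expect_equal(correlation_time(eq), 0)

  # bracket = sqrt(4) + sqrt(4) - 2 = 2, so tau = 2 k W0 = 1.3 ns
  f <- list(W0_G = 1, h_plus1 = 1, h_0 = 4, h_minus1 = 1)
  expect_equal(correlation_time(f), 1.3, tolerance = 1e-12)
  expect_equal(correlation_time(f, k_s_per_G = 1e-10), 0.2,
               tolerance = 1e-12)

  # joint rescaling of the three heights changes nothing
  g <- lapply(f, function(v) v)
  g[c("h_plus1", "h_0", "h_minus1")] <-
    lapply(f[c("h_plus1", "h_0", "h_minus1")], function(h) h * 0.017)
  expect_equal(correlation_time(g), correlation_time(f), tolerance = 1e-12)

  bad <- list(W0_G = 1, h_plus1 = 4, h_0 = 1, h_minus1 = 4)
  expect_error(correlation_time(bad), "inconsistent")
  expect_error(correlation_time(list(W0_G = 1, h_plus1 = 0, h_0 = 1,
                                     h_minus1 = 1)), "positive")
})

test_that("mobility and polarity parameters", {
  f <- list(W0_G = 2, a_N_meas_G = 15.14)
  mp <- mobility_polarity(f)
  expect_equal(mp$delta_inv_per_G, 0.5)
  expect_equal(mp$a_N_G, 15.14)

  # broadening strictly decreases the mobility parameter
  widths <- c(1, 1.4, 2.2, 4)
  dinv <- vapply(widths, function(w) {
    mobility_polarity(list(W0_G = w, a_N_meas_G = 15))$delta_inv_per_G
  }, numeric(1))
  expect_true(all(diff(dinv) < 0))
  expect_error(mobility_polarity(list(W0_G = 0, a_N_meas_G = 15)),
               "positive")
})

test_that("percent change matches desk arithmetic and rounding convention", {
  expect_equal(round(percent_change(0.45, 0.58)), 29)
  expect_equal(round(percent_change(0.96, 1.48)), 54)
  expect_equal(round(percent_change(1.12, 1.48)), 32)
  expect_equal(percent_change(0.45, 0.58), 100 * 0.13 / 0.45,
               tolerance = 1e-12)
  expect_equal(percent_change(3.3, 3.3), 0)
  expect_error(percent_change(0, 1), "positive")
  expect_error(percent_change(-2, 1), "positive")
})

test_that("mean residue ellipticity conversion", {
  expect_equal(mean_residue_ellipticity(0, 131, 1.2e-5, 0.1), 0)
  # -10 mdeg, 131 residues, 12 uM, 1 mm cell
  expect_equal(mean_residue_ellipticity(-10, 131, 1.2e-5, 0.1),
               -10 / (10 * 0.1 * 1.2e-5 * 130), tolerance = 1e-12)
  expect_equal(mean_residue_ellipticity(-10, 131, 2.4e-5, 0.1),
               mean_residue_ellipticity(-10, 131, 1.2e-5, 0.1) / 2,
               tolerance = 1e-12)
  expect_error(mean_residue_ellipticity(-10, 1, 1.2e-5, 0.1), "at least 2")
  expect_error(mean_residue_ellipticity(-10, 131, 0, 0.1), "positive")
})
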