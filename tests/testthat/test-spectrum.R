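test_that("spectrum construction enforces the field-axis invariants", {
  f <- seq(3300, 3400, length.out = 128)
  y <- sin(f / 10)
  s <- esr_spectrum(f, y)
  expect_s3_class(s, "esr_spectrum")
  expect_length(s$field_G, 128)

  expect_error(esr_spectrum(f[1:32], y[1:32]), "at least 64")
  expect_error(esr_spectrum(rev(f), y), "non-monotone")
  expect_error(esr_spectrum(f, y[-1]), "same length")
  expect_error(esr_spectrum(f, replace(y, 5, NA)), "non-finite")
  expect_error(acquisition_meta(modulation_amplitude_G = -1), "positive")
})

test_that("write/read round trip reproduces data and metadata", {
  s <- sim_triplet(a_N = 14.9, W0 = 1.3)
  s$meta$label <- "16-SASL LPC control"
  for (dialect in c("whitespace", "csv", "tsv")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_spectrum(s, path, dialect = dialect)
    r <- read_spectrum(path)
    expect_equal(r$field_G, s$field_G, tolerance = 1e-9)
    expect_equal(r$intensity, s$intensity, tolerance = 1e-9)
    expect_identical(r$meta$label, s$meta$label)
    expect_equal(r$meta$modulation_amplitude_G,
                 s$meta$modulation_amplitude_G)
  }
})

test_that("reader uses the first two columns and rejects bad files", {
  f <- seq(3300, 3400, length.out = 100)
  y <- cos(f / 7)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%.10g,%.10g,%d", f, y, seq_along(f)), path)
  s <- read_spectrum(path)
  expect_length(s$field_G, 100)
  expect_equal(s$intensity, y, tolerance = 1e-9)

  path2 <- withr::local_tempfile()
  writeLines(sprintf("%.10g %.10g", rev(f), y), path2)
  expect_error(read_spectrum(path2), "non-monotone")

  path3 <- withr::local_tempfile()
  writeLines(sprintf("%.10g %.10g", f[1:20], y[1:20]), path3)
  expect_error(read_spectrum(path3), "too few")

  path4 <- withr::local_tempfile()
  writeLines(c(sprintf("%.10g %.10g", f, y), "oops not_a_number"), path4)
  expect_error(read_spectrum(path4))

  expect_error(read_spectrum(file.path(tempdir(), "does-not-exist.dat")),
               "not found")
})

test_that("unit-spin normalization fixes the double integral at one", {
  s <- sim_triplet()
  n <- normalize_to_unit_spins(s)
  expect_equal(double_integral(n), 1, tolerance = 1e-9)

  # scale invariance: a 7.3x brighter recording normalizes identically
  s2 <- s
  s2$intensity <- 7.3 * s$intensity
  expect_equal(normalize_to_unit_spins(s2)$intensity, n$intensity,
               tolerance = 1e-9)

  # idempotence
  expect_equal(normalize_to_unit_spins(n)$intensity, n$intensity,
               tolerance = 1e-12)

  inv <- s
  inv$intensity <- -inv$intensity
  expect_error(normalize_to_unit_spins(inv), "non-positive")
})

test_that("double integral is linear and mixtures split areas accordingly", {
  a <- sim_triplet(a_N = 15, W0 = 1.5)
  b <- sim_triplet(a_N = 14, W0 = 2.5)
  for (ab in list(c(1, 1), c(0.3, 1.7), c(2, 0))) {
    s <- a
    s$intensity <- ab[1] * a$intensity + ab[2] * b$intensity
    expect_equal(double_integral(s),
                 ab[1] * double_integral(a) + ab[2] * double_integral(b),
                 tolerance = 1e-9)
  }
  # equal-weight sum of two unit-spin spectra renormalized: each carries 1/2
  half <- a
  half$intensity <- 0.5 * (a$intensity + b$intensity)
  half <- normalize_to_unit_spins(half)
  part <- half
  part$intensity <- part$intensity - 0.5 * b$intensity
  expect_equal(double_integral(part), 0.5, tolerance = 1e-9)
})

test_that("baseline correction removes polynomial drift without touching a
           clean spectrum", {
  s <- sim_triplet()
  n <- length(s$field_G)
  edge <- c(1:floor(0.05 * n), (n - floor(0.05 * n) + 1):n)

  off <- s
  off$intensity <- off$intensity + 2.0
  fixed <- baseline_correct(off, order = 0)
  expect_lt(max(abs(fixed$intensity[edge] - s$intensity[edge])), 1e-6)

  # the edge fit is linear in the data, so adding a degree-1 ramp changes
  # the output not at all (the fit absorbs the ramp exactly)
  ramp <- s
  ramp$intensity <- ramp$intensity + 0.03 * (s$field_G - 3350) + 1.5
  fixed1 <- baseline_correct(ramp, order = 1)
  expect_lt(max(abs(fixed1$intensity - baseline_correct(s, 1)$intensity)),
            1e-6)

  # symmetric noiseless triplet: edge fit is ~0 so order 0 is the identity
  same <- baseline_correct(s, order = 0)
  expect_lt(max(abs(same$intensity - s$intensity)), 1e-9)

  expect_error(baseline_correct(s, order = 4), "between 0 and 3")
})

test_that("resample_align recovers constructed field offsets", {
  a <- sim_triplet(a_N = 15.1, W0 = 1.6)
  same <- resample_align(a, a)
  expect_equal(same$shift_G, 0, tolerance = 1e-6)

  # b carries a's lineshape displaced by +1.2 G on the field axis
  b <- esr_spectrum(a$field_G,
                    stats::approx(a$field_G, a$intensity,
                                  xout = a$field_G - 1.2, rule = 2)$y,
                    a$meta)
  al <- resample_align(a, b)
  expect_equal(al$shift_G, -1.2, tolerance = 0.05)
  expect_equal(al$b$intensity, al$a$intensity, tolerance = 1e-2)

  far <- esr_spectrum(a$field_G + 500, a$intensity, a$meta)
  expect_error(resample_align(a, far), "overlap")

  big <- esr_spectrum(a$field_G,
                      stats::approx(a$field_G, a$intensity,
                                    xout = a$field_G - 6, rule = 2)$y,
                      a$meta)
  expect_error(resample_align(a, big, max_shift_G = 5), "exceeds")
})
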