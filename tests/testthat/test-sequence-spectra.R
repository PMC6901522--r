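test_that("sequence masses follow the residue-plus-water bookkeeping", {
  expect_equal(sequence_props("G")$average_mass, 75.07, tolerance = 1e-4)
  expect_equal(sequence_props("GG")$average_mass, 132.12,
               tolerance = 1e-4)
  # additivity: mass(A + B) = mass(A) + mass(B) - water
  set.seed(41)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "W", "Y")
  for (i in 1:10) {
    s1 <- paste(sample(aa, 12, TRUE), collapse = "")
    s2 <- paste(sample(aa, 8, TRUE), collapse = "")
    m12 <- sequence_props(paste0(s1, s2))$average_mass
    expect_equal(m12, sequence_props(s1)$average_mass +
                   sequence_props(s2)$average_mass - 18.01524,
                 tolerance = 1e-9)
  }
  expect_error(sequence_props("GXZ"), "position 2")
})

test_that("disulfides remove two hydrogens and add to the extinction", {
  red <- sequence_props("ACCG", n_disulfides = 0)
  oxi <- sequence_props("ACCG", n_disulfides = 1)
  expect_equal(red$average_mass - oxi$average_mass, 2 * 1.00794,
               tolerance = 1e-6)
  expect_equal(oxi$extinction_280 - red$extinction_280, 125)
  expect_error(sequence_props("ACG", n_disulfides = 1), "cysteines")

  # ProtParam coefficient rule
  p <- sequence_props("WWYC")
  expect_equal(p$extinction_280, 2 * 5500 + 1490)
})

test_that("Beer's law concentration helper inverts absorbance", {
  expect_equal(beer_concentration(0.5, 10000, 1), 5e-5)
  p <- sequence_props("WWYC")
  expect_equal(beer_concentration(1.0, p, 0.5),
               1 / (p$extinction_280 * 0.5))
  expect_error(beer_concentration(1, 0), "epsilon > 0")
})

test_that("baseline subtraction is exact and grid-strict", {
  set.seed(42)
  g <- seq(200, 250, by = 1)
  sample_s <- xy_spectrum(g, rnorm(length(g)))
  buffer <- xy_spectrum(g, rnorm(length(g)))

  zero <- subtract_baseline(sample_s, sample_s)
  expect_true(all(zero$y == 0))
  unchanged <- subtract_baseline(sample_s, xy_spectrum(g, rep(0, length(g))))
  expect_equal(unchanged$y, sample_s$y)

  # subtract-then-add recovers the sample exactly
  diffd <- subtract_baseline(sample_s, buffer)
  expect_equal(diffd$y + buffer$y, sample_s$y, tolerance = 1e-12)

  other <- xy_spectrum(g + 0.5, rnorm(length(g)))
  expect_error(subtract_baseline(sample_s, other), "grids differ")
})

test_that("molar ellipticity conversion is the standard 1/(10 c l) scaling", {
  g <- seq(200, 210, by = 1)
  spec <- xy_spectrum(g, rep(10, length(g)), y_unit = "mdeg")
  conv <- to_molar_ellipticity(spec, conc_M = 5e-6, path_cm = 0.1)
  expect_equal(conv$y, rep(2e6, length(g)))
  expect_error(to_molar_ellipticity(spec, 0, 0.1), "positive")
  # doubling the concentration halves the converted signal
  half <- to_molar_ellipticity(spec, 1e-5, 0.1)
  expect_equal(conv$y, 2 * half$y)
  # zero signal converts to zero
  z <- to_molar_ellipticity(xy_spectrum(g, rep(0, 11)), 5e-6, 0.1)
  expect_true(all(z$y == 0))
  # mean-residue option divides by the peptide-bond count
  mr <- to_molar_ellipticity(spec, 5e-6, 0.1, mean_residue = TRUE,
                             n_residues = 101)
  expect_equal(conv$y / 100, mr$y)
})

test_that("Savitzky-Golay preserves polynomials up to the fit order", {
  g <- seq(190, 260, by = 1)
  const <- xy_spectrum(g, rep(3.3, length(g)))
  expect_equal(savgol_smooth(const)$y, const$y, tolerance = 1e-10)

  quad <- xy_spectrum(g, 0.01 * (g - 220)^2 - 2)
  for (w in c(5, 11, 21)) {
    for (p in 2:min(4, w - 2)) {
      sm <- savgol_smooth(quad, window = w, polyorder = p)
      expect_equal(sm$y, quad$y, tolerance = 1e-8)
    }
  }
  cubic <- xy_spectrum(g, 1e-4 * (g - 220)^3 + 0.05 * (g - 200))
  expect_equal(savgol_smooth(cubic, 11, 3)$y, cubic$y, tolerance = 1e-8)

  irregular <- xy_spectrum(c(g[-3], 400), rep(1, length(g)))
  expect_error(savgol_smooth(irregular), "uniform")
  expect_error(savgol_smooth(const, window = 10), "odd")
  expect_error(savgol_smooth(const, window = 5, polyorder = 4),
               "window - 2")
})

test_that("Savitzky-Golay interior points equal a direct sliding-window fit", {
  set.seed(43)
  g <- seq(305, 355, by = 0.5)
  spec <- xy_spectrum(g, rnorm(length(g)))
  sm <- savgol_smooth(spec, window = 11, polyorder = 3)
  half <- 5L
  for (i in seq(half + 1L, length(g) - half)) {
    idx <- (i - half):(i + half)
    fit <- lm(spec$y[idx] ~ poly(g[idx], 3, raw = TRUE))
    expect_equal(sm$y[i], unname(fitted(fit)[half + 1L]),
                 tolerance = 1e-8)
  }
})

test_that("polynomial peak maxima are located, flagged, and invariant", {
  g <- seq(305, 400, by = 0.5)
  # exact symmetric parabola
  par_spec <- xy_spectrum(g, -(g - 338)^2 + 100)
  pk <- polyfit_peak_max(par_spec)
  expect_equal(pk$wavelength, 338, tolerance = 1e-6)
  expect_false(pk$edge)

  # noiseless Gaussian emission: center recovered within half a grid step
  gauss <- make_emission_spectrum(center = 338, width = 25, noise_sd = 0,
                                  seed = 1)
  expect_equal(polyfit_peak_max(gauss)$wavelength, 338, tolerance = 0.5)

  # 1% noise: still within +/- 0.5 nm of the true center
  noisy <- make_emission_spectrum(center = 338, width = 25,
                                  noise_sd = 0.01, seed = 2)
  expect_equal(polyfit_peak_max(noisy)$wavelength, 338, tolerance = 0.5)

  # monotone data have no interior maximum
  mono <- xy_spectrum(g, 0.1 * g)
  expect_true(polyfit_peak_max(mono)$edge)

  # invariance under constant offset and positive scaling of y
  base <- polyfit_peak_max(gauss)$wavelength
  shifted <- xy_spectrum(gauss$x, gauss$y + 500)
  scaled <- xy_spectrum(gauss$x, gauss$y * 7)
  expect_equal(polyfit_peak_max(shifted)$wavelength, base,
               tolerance = 1e-6)
  expect_equal(polyfit_peak_max(scaled)$wavelength, base,
               tolerance = 1e-6)

  expect_error(polyfit_peak_max(xy_spectrum(1:5, rnorm(5)), degree = 6),
               "degree \\+ 2")
})

test_that("replicate spectra average pointwise before fitting", {
  g <- seq(305, 310, by = 0.5)
  s1 <- xy_spectrum(g, rep(1, 11)); s2 <- xy_spectrum(g, rep(3, 11))
  avg <- average_spectra(list(s1, s2))
  expect_equal(avg$y, rep(2, 11))
  s3 <- xy_spectrum(g + 1, rep(1, 11))
  expect_error(average_spectra(list(s1, s3)), "identical grid")
})
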