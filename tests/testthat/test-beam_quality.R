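test_that("simulated spectra respect the tube-potential endpoint and K-edge threshold", {
  sp120 <- simulate_spectrum(tube_setting(120))
  expect_true(all(sp120$energy_keV < 120))
  expect_true(any(sp120$fluence > 0))
  # below the tungsten K edge no characteristic contribution exists:
  # the spectrum is identical with the line generator switched off
  ts60 <- tube_setting(60, filtration = c(aluminum = 2))
  expect_identical(simulate_spectrum(ts60)$fluence,
                   simulate_spectrum(ts60, char_fraction = 0)$fluence)
  # above it the K-alpha bin locally exceeds the neighbouring continuum
  ts120 <- tube_setting(120, filtration = c(aluminum = 2))
  with_lines <- simulate_spectrum(ts120)
  ka1 <- which.min(abs(with_lines$energy_keV - 59.32))
  local_continuum <- mean(with_lines$fluence[c(ka1 - 6L, ka1 + 6L)])
  expect_gt(with_lines$fluence[ka1], 1.5 * local_continuum)
})

test_that("filtration is an exponential attenuation per bin", {
  sp <- simulate_spectrum(tube_setting(80, filtration = c(aluminum = 0)))
  expect_identical(apply_filtration(sp, "aluminum", 0), sp)
  two_steps <- apply_filtration(apply_filtration(sp, "aluminum", 1),
                                "aluminum", 1)
  one_step <- apply_filtration(sp, "aluminum", 2)
  expect_equal(two_steps$fluence, one_step$fluence, tolerance = 1e-12)
  # beam hardening: any positive Al thickness raises the mean energy
  for (t in c(0.5, 2, 10))
    expect_gt(spectrum_mean_energy(apply_filtration(sp, "aluminum", t)),
              spectrum_mean_energy(sp))
  expect_error(apply_filtration(sp, "aluminum", -1), ">= 0")
  expect_error(apply_filtration(sp, "lead", 1), "aluminum, air, tungsten")
  expect_error(tube_setting(120, filtration = c(lead = 1)),
               "unknown filtration material")
})

test_that("air kerma is the fluence-energy-absorption sum", {
  sp <- simulate_spectrum(tube_setting(100))
  k1 <- air_kerma_of(sp)
  expect_gt(k1, 0)
  doubled <- sp; doubled$fluence <- doubled$fluence * 2
  expect_equal(air_kerma_of(doubled), 2 * k1, tolerance = 1e-12)
  # degenerate single-bin spectrum: product of the three factors
  muen <- ref_interp(reference_table("mu_en_rho_air"), 60)
  mono <- structure(list(energy_keV = 60, fluence = 3),
                    class = "xray_spectrum")
  expect_equal(air_kerma_of(mono), 3 * 60 * muen, tolerance = 1e-12)
  # 60 vs 30 keV monoenergetic beams of equal fluence: brute-force ratio
  tab <- reference_table("mu_en_rho_air")
  mono30 <- structure(list(energy_keV = 30, fluence = 3),
                      class = "xray_spectrum")
  expect_equal(air_kerma_of(mono) / air_kerma_of(mono30),
               (60 * ref_interp(tab, 60)) / (30 * ref_interp(tab, 30)),
               tolerance = 1e-12)
})

test_that("HVL halves the kerma and follows the monoenergetic closed form", {
  mono <- structure(list(energy_keV = 60, fluence = 1),
                    class = "xray_spectrum")
  expect_equal(hvl_al(mono), hvl_from_energy(60), tolerance = 1e-3)
  sp <- simulate_spectrum(tube_setting(120))
  t_star <- hvl_al(sp)
  trans <- air_kerma_of(apply_filtration(sp, "aluminum", t_star)) /
    air_kerma_of(sp)
  expect_equal(trans, 0.5, tolerance = 1e-3)
  # pre-hardening the beam increases its HVL
  hardened <- apply_filtration(sp, "aluminum", 3)
  expect_gt(hvl_al(hardened), t_star)
})

test_that("effective energy inverts the monoenergetic HVL relation", {
  for (e in c(40, 60, 80, 100))
    expect_equal(effective_energy_from_hvl(hvl_from_energy(e)), e,
                 tolerance = 0.01)
  set.seed(42)
  for (e in runif(20, 35, 140))
    expect_equal(effective_energy_from_hvl(hvl_from_energy(e)), e,
                 tolerance = 0.01)
  # monotone: larger HVL, larger effective energy
  hvls <- hvl_from_energy(seq(35, 140, by = 5))
  ees <- vapply(hvls, effective_energy_from_hvl, 0)
  expect_true(all(diff(ees) > 0))
  expect_error(effective_energy_from_hvl(1e-4), "outside the invertible")
  expect_error(effective_energy_from_hvl(-1), "positive")
})

test_that("effective energy is non-decreasing in added Al filtration", {
  ees <- vapply(c(2, 5, 10, 16, 25), function(t) {
    effective_energy_of(simulate_spectrum(
      tube_setting(120, filtration = c(aluminum = t))))
  }, 0)
  expect_true(all(diff(ees) > 0))
})

test_that("calibrated 120 kVp beams reproduce the measured per-FOV effective energies", {
  anchors <- c("default" = 56.47, "80-MDCT S-size (24 cm)" = 55.74,
               "80-MDCT L-size (40 cm)" = 57.97,
               "320-MDCT S-size (24 cm)" = 54.87,
               "320-MDCT L-size (40 cm)" = 57.30)
  for (nm in names(anchors)) {
    bq <- beam_quality(tube_setting(
      120, filtration = c(aluminum = ct_default_filtration[[nm]]),
      fov_label = nm))
    expect_equal(bq$effective_energy, anchors[[nm]], tolerance = 0.02)
    expect_true(bq$effective_energy > 10 &&
                  bq$effective_energy < 120)
  }
  # measured-HVL path agrees with the simulated-spectrum path by design
  sp <- simulate_spectrum(tube_setting(120))
  bq2 <- beam_quality(tube_setting(120), measured_hvl = hvl_al(sp))
  expect_equal(bq2$effective_energy,
               beam_quality(tube_setting(120))$effective_energy,
               tolerance = 1e-6)
})

test_that("effective-energy summary uses the population-SD convention", {
  table3 <- c(55.74, 57.97, 54.87, 57.30)
  s <- summarize_effective_energy(table3)
  expect_equal(s[["mean"]], 56.47)
  expect_equal(s[["sd"]], 1.23)
  # the sample-SD convention would give 1.42 instead
  expect_equal(round(sd(table3), 2), 1.42)
  expect_equal(summarize_effective_energy(c(3, 3, 3))[["sd"]], 0)
  expect_error(summarize_effective_energy(56.5), "at least 2")
})
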