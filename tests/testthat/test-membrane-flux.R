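test_that("neutral passive flux is the linear diffusion law", {
  expect_equal(passive_flux_neutral(1e-4, 6.28e-12, 1, 1), 0)
  j1 <- passive_flux_neutral(1e-4, 6.28e-12, 2e-4, 1e-4)
  expect_equal(passive_flux_neutral(2e-4, 6.28e-12, 2e-4, 1e-4), 2 * j1)
  expect_equal(passive_flux_neutral(1e-4, 6.28e-12, 2e-4, 1e-4),
               6.28e-20, tolerance = 1e-12)
  expect_error(passive_flux_neutral(-1, 1, 1, 0), "non-negative")
})

test_that("GHK flux has the correct zero-voltage and Nernst limits", {
  # dpsi -> 0 reduces to simple diffusion
  expect_equal(ghk_flux(1e-5, 1, 0, 1e-4, 1e-3, 1e-12),
               1e-5 * 1e-12 * (1e-3 - 1e-4))
  # exactly zero at the Nernst potential, (RT/zF) ln(c_out/c_in)
  vN <- 8.314 * 298 / 96485 * log(10)           # 59.1265 mV for a 10x ratio
  expect_equal(vN, 0.0591265, tolerance = 1e-5)
  j0 <- abs(ghk_flux(1e-5, 1, 0, 1e-4, 1e-3, 1e-12))
  expect_lt(abs(ghk_flux(1e-5, 1, vN, 1e-4, 1e-3, 1e-12)), 1e-12 * j0)
  # anion with the inverted ratio is at equilibrium at the same potential
  expect_lt(abs(ghk_flux(1e-5, -1, vN, 1e-3, 1e-4, 1e-12)), 1e-12 * j0)
})

test_that("GHK flux matches an independent high-precision evaluation", {
  # frozen from a 50-digit evaluation of the constant-field expression
  # (P 1e-5 m/s, z +1, dpsi -0.1 V, c_in 1e-4, c_out 1e-3 mol/m^3,
  #  A 1e-12 m^2, 298 K)
  expect_equal(ghk_flux(1e-5, 1, -0.1, 1e-4, 1e-3, 1e-12, 298),
               3.9671683512828718e-20, tolerance = 1e-14)
})

test_that("GHK series expansion is continuous across the switchover", {
  u_to_dpsi <- 8.314 * 298 / 96485
  near <- c(-2e-8, -1e-8, -0.5e-8, 0.5e-8, 1e-8, 2e-8) * u_to_dpsi
  j <- vapply(near, function(v) ghk_flux(1e-5, 1, v, 1e-4, 1e-3, 1e-12),
              numeric(1))
  # values straddling the branch differ only at O(u^2)
  expect_lt(max(abs(diff(j))) / abs(j[1]), 1e-7)
})

test_that("GHK flux is monotone in voltage and sign-consistent", {
  set.seed(7)
  n <- 1e4
  z <- sample(c(-1, 1), n, TRUE)
  c_in <- 10^runif(n, -6, 0); c_out <- 10^runif(n, -6, 0)
  dpsi <- runif(n, -0.3, 0.3)
  j <- ghk_flux(1e-5, z, dpsi, c_in, c_out, 1e-12)
  # sign of the flux always agrees with minus the electrochemical
  # potential difference for inward transfer
  dG <- z * 96485 * dpsi + 8.314 * 298 * log(c_in / c_out)
  expect_true(all(sign(j) == -sign(dG) | dG == 0))
  # strict monotone decrease with dpsi for a cation (inward positive)
  v <- seq(-0.25, 0.25, length.out = 101)
  jj <- ghk_flux(1e-5, 1, v, 1e-4, 1e-3, 1e-12)
  expect_true(all(diff(jj) < 0))
})

test_that("GHK voltage reproduces symmetry, Nernst and exchange limits", {
  # identical compositions: 0 V
  expect_equal(ghk_voltage(c(1e-5, 1e-9), c(1, -1), c(1, 2), c(1, 2)), 0)
  # single permeant cation at 10x external excess: +59.1 mV
  expect_equal(ghk_voltage(1e-5, 1, 1e-4, 1e-3),
               8.314 * 298 / 96485 * log(10), tolerance = 1e-12)
  # equally permeant cation and anion with identical profiles cancel:
  # the anion's internal term mirrors the cation's external one
  expect_equal(ghk_voltage(c(1e-9, 1e-9), c(1, -1), c(2, 2), c(5, 5)), 0)
  expect_error(ghk_voltage(c(1e-5, 1e-5), c(1, -1), c(1, 0), c(0, 1)),
               "internal anions")
})

test_that("five-ion GHK voltage stays inside the physical band", {
  # compositions spanning the scenario families, including strong
  # SPAP-style Na+ depletion, stay within (-0.3, +0.3) V
  set.seed(11)
  for (i in 1:200) {
    P <- c(1e-5, 1e-5, 1e-11, 1e-11, 1e-11) * 10^runif(1, -1, 1)
    z <- c(1, -1, 1, 1, -1)
    c_out <- molar_to_si(c(10^runif(1, -10, -5), 10^runif(1, -9, -4),
                           0.4, 0.01, 0.41))
    c_in <- c_out * 10^runif(5, -3, 1)
    v <- ghk_voltage(P, z, c_in, c_out)
    expect_gt(v, -0.3); expect_lt(v, 0.3)
  }
})

test_that("ion and geometry constructors validate their invariants", {
  g <- membrane_geometry()
  expect_equal(g$area_acid, g$area_alk)
  expect_equal(g$area_acid + g$area_alk, 4 * pi * 1e-12)
  expect_equal(g$volume_L, 4 / 3 * pi * 1e-18 * 1e3)
  expect_error(membrane_geometry(-1), "positive")
  expect_error(membrane_geometry(1, 0), "between")
  ion <- ion_spec("Na", 1, 1e-9, 0.4, 0.4)
  expect_equal(ion$permeability, 1e-11)   # cm/s ingested to m/s
  expect_error(ion_spec("Mg", 2, 1, 1, 1), "unknown ion")
  expect_error(ion_spec("Na", 2, 1, 1, 1), "valence")
  expect_error(ion_spec("Na", 1, -1, 1, 1), ">= 0")
})
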