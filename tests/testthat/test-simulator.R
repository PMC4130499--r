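test_that("free energy reproduces the Mitchell-equation limits", {
  cfg <- protocell_config()
  # interior identical to the acid fluid, no potential: no driving force
  fe0 <- free_energy(c(H = 1e-7, Na = 0.4), cfg, dpsi = 0)
  expect_equal(fe0$minus_dG_H, 0, tolerance = 1e-12)
  expect_equal(fe0$minus_dG_Na, 0, tolerance = 1e-12)
  # a 3-pH-unit chemical gradient at 298 K: 2.303 RT x 3 = 17.12 kJ/mol
  fe3 <- free_energy(c(H = 1e-10, Na = 0.4), cfg, dpsi = 0)
  expect_equal(fe3$minus_dG_H, 8.314 * 298 * 3 * log(10) / 1000,
               tolerance = 1e-9)
  expect_equal(fe3$minus_dG_H, 17.12, tolerance = 1e-3)
  # a purely electrical 20 kJ/mol corresponds to ~207 mV
  expect_equal(20e3 / 96485, 0.2073, tolerance = 1e-3)
  fe_el <- free_energy(c(H = 1e-7, Na = 0.4), cfg, dpsi = -20e3 / 96485)
  expect_equal(fe_el$minus_dG_H, 20, tolerance = 1e-9)
  expect_error(free_energy(c(H = 0, Na = 0.4), cfg, dpsi = 0),
               "strictly")
})

test_that("reported -dG is the promiscuity-weighted combination", {
  cfg <- protocell_config()
  # both favourable: weighted mean lies between the components
  fe <- free_energy(c(H = 1e-9, Na = 0.04), cfg, dpsi = 0)
  expect_true(fe$minus_dG_reported <= max(fe$minus_dG_H, fe$minus_dG_Na))
  expect_true(fe$minus_dG_reported >= min(fe$minus_dG_H, fe$minus_dG_Na))
  expect_equal(sum(fe$weights), 1)
  # only H+ favourable: all weight on H+
  fe1 <- free_energy(c(H = 1e-9, Na = 0.5), cfg, dpsi = 0)
  expect_equal(fe1$minus_dG_reported, fe1$minus_dG_H)
  expect_equal(unname(fe1$weights["Na"]), 0)
})

test_that("ion balance vanishes at the protein-free fixed point", {
  cfg <- equilibrium_config()
  bal <- ion_balance(cfg$init, cfg)
  expect_lt(max(abs(bal$fluxes["total", ])), 1e-25)
  # the fixed point is preserved exactly by the integrator
  run <- run_protocell(cfg)
  n <- nrow(run$series)
  expect_equal(unlist(run$series[n, names(cfg$init)]),
               cfg$init[names(cfg$init)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("SPAP moves zero net charge in the full balance", {
  cfg <- protocell_config(spap = 0.05,
                          init_pH = 9)  # strong H+ drive at start
  bal <- ion_balance(cfg$init, cfg)
  expect_equal(bal$fluxes["spap", "H"], -bal$fluxes["spap", "Na"])
  expect_gt(bal$fluxes["spap", "H"], 0)
  # and per step along a whole trajectory, to machine precision
  a <- audit_run(protocell_config(spap = 0.05, t_end = 5))
  pf <- a$pathway_fluxes
  expect_equal(pf$protein_H, -pf$protein_Na, tolerance = 1e-12)
})

test_that("a single Euler step does exact bookkeeping", {
  cfg <- protocell_config(atpase = 0.01, perm_H_cm_s = 1e-3)
  st0 <- cfg$init
  bal <- ion_balance(st0, cfg)
  dt <- 1e-5
  st1 <- step_state(st0, dt, cfg)$internal
  vol <- cfg$geometry$volume_L
  # Na/K/Cl amounts move by flux x dt exactly
  for (ion in c("Na", "K", "Cl")) {
    expect_equal(st1[[ion]] - st0[[ion]],
                 bal$fluxes["total", ion] * dt / vol, tolerance = 1e-9)
  }
  # the H+/OH- pool conserves its proton-excess coordinate
  expect_equal((st1[["H"]] - st1[["OH"]]) - (st0[["H"]] - st0[["OH"]]),
               (bal$fluxes["total", "H"] - bal$fluxes["total", "OH"]) *
                 dt / vol, tolerance = 1e-9)
  # and is re-equilibrated to the water ion product
  expect_equal(st1[["H"]] * st1[["OH"]], 1e-14, tolerance = 1e-9)
})

test_that("the R reference stepper agrees with the compiled core", {
  # gentle gradient: the core accepts every step at the configured dt,
  # so the pure-R stepper can replay the identical trajectory
  cfg <- protocell_config(pH_acid = 7, pH_alk = 7.2, perm_H_cm_s = 1e-4,
                          dt = 1e-3, t_end = 0.2, record_dt = 1e-3,
                          steady_tol = 1e-15)
  run <- run_protocell(cfg)
  expect_equal(nrow(run$series), 201)   # no halvings: every step recorded
  st <- cfg$init
  for (i in seq_len(nrow(run$series) - 1)) {
    dt <- run$series$t[i + 1] - run$series$t[i]
    st <- step_state(st, dt, cfg)$internal
  }
  n <- nrow(run$series)
  for (ion in names(cfg$init))
    expect_equal(st[[ion]], run$series[[ion]][n], tolerance = 1e-12,
                 label = paste("ion", ion))
  # one step with the full protein complement, against the compiled core
  cfg2 <- protocell_config(atpase = 0.01, spap = 0.01, pump = 0.01,
                           init_pH = 8, dt = 1e-6, t_end = 1e-6,
                           record_dt = 1e-6, steady_tol = 1e-15)
  run2 <- run_protocell(cfg2)
  st2 <- step_state(cfg2$init, 1e-6, cfg2)$internal
  n2 <- nrow(run2$series)
  for (ion in names(cfg2$init))
    expect_equal(st2[[ion]], run2$series[[ion]][n2], tolerance = 1e-12,
                 label = paste("ion", ion))
})

test_that("every internal state keeps the water ion product", {
  run <- run_protocell(protocell_config(atpase = 0.05, spap = 0.01,
                                        pump = 0.01, t_end = 30))
  expect_lt(max(abs(run$series$H * run$series$OH / 1e-14 - 1)), 1e-9)
  expect_true(all(diff(run$series$t) > 0))
  expect_false(any(is.na(as.matrix(run$series))))
})

test_that("per-step conservation audit is at rounding level", {
  a <- audit_run(protocell_config(atpase = 0.01, spap = 0.05, pump = 0.01,
                                  perm_H_cm_s = 1e-3, t_end = 20))
  expect_lt(a$max_residual, 1e-9)
})

test_that("open-system reference clamps the interior to the alkaline fluid", {
  cfg <- protocell_config(atpase = 0.01, perm_H_cm_s = 1e-2)
  o <- open_system_reference(cfg)
  # chemical term of the 3-unit gradient, plus a small potential term
  chem <- 8.314 * 298 * 3 * log(10) / 1000
  expect_equal(o$minus_dG_H, chem - 96.485 * o$dpsi, tolerance = 1e-6)
  # no gradient: no reference free energy
  o0 <- open_system_reference(protocell_config(pH_acid = 7, pH_alk = 7))
  expect_equal(o0$minus_dG_reported, 0, tolerance = 1e-9)
})

test_that("halving the step changes the steady answer by <0.1%", {
  v1 <- run_protocell(leaky_config(dt = 1e-3, t_end = 30,
                                   steady_tol = 1e-9))$summary
  v2 <- run_protocell(leaky_config(dt = 5e-4, t_end = 30,
                                   steady_tol = 1e-9))$summary
  expect_equal(v1$minus_dG_reported, v2$minus_dG_reported,
               tolerance = 1e-3)
})

test_that("config validation rejects inconsistent bundles", {
  expect_error(protocell_config(pH_acid = 15), "\\[0, 14\\]")
  expect_error(protocell_config(atpase = 0.01, ocean_Na = 0), "no Na")
  expect_error(protocell_config(perm_H_cm_s = -1), "non-negative")
  expect_error(protocell_config(dt = 0), "positive")
  expect_error(protocell_config(protein_overrides = list(foo = list())),
               "keyed by protein kind")
})
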