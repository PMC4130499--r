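test_that("the preset registry covers every figure-level experiment", {
  expected <- c(paste0("fig3", letters[1:4]), paste0("fig4", letters[1:4]),
                paste0("fig5", letters[1:3]), paste0("fig6", letters[1:4]),
                paste0("figS", 1:5), "open_system")
  expect_setequal(list_scenarios()$name, expected)
  # every preset resolves to a fully specified, runnable config
  for (nm in expected) {
    sc <- resolve_scenario(nm)
    cfg <- do.call(protocell_config, protomotive:::route_protein_keys(sc$base))
    expect_s3_class(cfg, "protocell_config")
  }
})

test_that("scenario resolution applies presets and user overrides", {
  sc <- resolve_scenario("fig5b")
  expect_equal(sc$base$atpase, 0.01)
  expect_equal(sc$base$perm_H_cm_s, 1e-3)
  expect_setequal(sc$sweep$spap, c(0, 0.01, 0.05, 0.10))
  expect_equal(sc$sweep$gradient$pH_acid, c(7, 6, 5))
  # overrides win over preset values
  sc2 <- resolve_scenario("fig5b", list(perm_H_cm_s = 1e-4, t_end = 60))
  expect_equal(sc2$base$perm_H_cm_s, 1e-4)
  expect_equal(sc2$base$t_end, 60)
  expect_error(resolve_scenario("fig9z"), "available")
  expect_error(resolve_scenario("fig3a", list(42)), "named")
  # fig4c/d probe the no-gradient condition: identical external fluids
  sc4 <- resolve_scenario("fig4c")
  expect_equal(sc4$base$pH_acid, sc4$base$pH_alk)
})

test_that("dotted sweep keys reach individual protein constants", {
  sc <- resolve_scenario("figS2")
  expect_equal(sc$sweep[["atpase.ions_per_cycle"]], c(3.3, 6))
  args <- protomotive:::route_protein_keys(c(sc$base, list(atpase.ions_per_cycle = 6)))
  cfg <- do.call(protocell_config, args)
  expect_equal(cfg$proteins$atpase$ions_per_cycle, 6)
})

test_that("run_sweep executes the Cartesian product deterministically", {
  sw <- run_sweep("fig3a", list(t_end = 20))
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 5)
  expect_equal(sw$perm_H_cm_s, 10^seq(-6, -2))
  expect_true(all(is.na(sw$error)))
  # a degenerate single-cell sweep equals the plain run
  sc <- resolve_scenario("fig3a", list(t_end = 20))
  sc$sweep$perm_H_cm_s <- 1e-3
  one <- run_sweep(sc)
  expect_equal(nrow(one), 1)
  direct <- run_protocell(protocell_config(atpase = 0.01,
                                           perm_H_cm_s = 1e-3, t_end = 20))
  expect_equal(one$minus_dG_reported, direct$summary$minus_dG_reported)
})

test_that("a failing sweep cell is recorded in-row and the sweep continues", {
  sc <- resolve_scenario("fig3a", list(t_end = 5))
  sc$sweep$ocean_Na <- c(0.4, 0)   # second cell invalid with an ATPase
  sw <- run_sweep(sc)
  expect_equal(nrow(sw), 10)
  bad <- sw[sw$ocean_Na == 0, ]
  expect_true(all(!is.na(bad$error)))
  expect_true(all(is.na(sw$error[sw$ocean_Na == 0.4])))
})

test_that("fluctuating runs are seeded, bounded and degenerate correctly", {
  cfg <- protocell_config(atpase = 0.01, t_end = 40)
  spec <- fluctuation_spec("acid", amplitude = 0.4, seed = 11,
                           bounds = c(6, 8))
  a <- fluctuating_run(cfg, spec)
  b <- fluctuating_run(cfg, spec)
  expect_identical(a$run$series, b$run$series)   # same seed, same bits
  expect_true(all(a$schedule$pH_acid >= 6 & a$schedule$pH_acid <= 8))
  expect_false(identical(
    a$run$series,
    fluctuating_run(cfg, fluctuation_spec("acid", amplitude = 0.4,
                                          seed = 12, bounds = c(6, 8)))$run$series))
  # zero amplitude reproduces the static run
  calm <- fluctuating_run(cfg, fluctuation_spec("acid", amplitude = 0))
  cfg_static <- cfg; cfg_static$sim$steady_tol <- 1e-12
  static <- run_protocell(cfg_static)
  expect_equal(calm$run$series$minus_dG_reported,
               static$series$minus_dG_reported, tolerance = 1e-12)
  expect_equal(sum(a$histogram$count), nrow(a$run$series))
  # alkaline-side fluctuations leave the acid side untouched
  alk <- fluctuating_run(cfg, fluctuation_spec("alk", seed = 3))
  expect_true(all(alk$schedule$pH_acid == 7))
})

test_that("the acid-adaptation sweep reproduces the figure orderings", {
  # drop the two middle permeabilities to keep the grid light; the
  # tight cells need the full preset horizon for the pump to charge
  # the Na+ pool through the antiporter
  sc <- resolve_scenario("figS5")
  sc$sweep$perm_H_cm_s <- c(1e-6, 1e-2)
  sw <- run_sweep(sc)
  expect_equal(nrow(sw), 6)
  leaky <- sw[sw$perm_H_cm_s == 1e-2, ]
  # at high permeability the most acidic 3-unit gradient is the worst
  expect_equal(leaky$pH_acid[which.min(leaky$minus_dG_reported)], 5)
  # at low permeability the pump powers all three gradients;
  # removing it collapses each
  tight <- sw[sw$perm_H_cm_s == 1e-6, ]
  expect_true(all(tight$minus_dG_reported > 10))
  sc0 <- resolve_scenario("figS5", list(pump = 0, t_end = 600))
  sc0$sweep$perm_H_cm_s <- 1e-6
  tight0 <- run_sweep(sc0)
  expect_true(all(tight0$minus_dG_reported < 0.2 * tight$minus_dG_reported))
})
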