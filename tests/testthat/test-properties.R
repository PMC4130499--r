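# Model-level behaviour of the simulated protocell: the qualitative
# phenomenology that the scenario families probe.

test_that("steady free energy is monotone in lipid H+ permeability", {
  v <- vapply(10^seq(-6, -2),
              function(p) steady_mdg(atpase = 0.01, perm_H_cm_s = p),
              numeric(1))
  expect_false(is.unsorted(v))
  # proton-tight membranes die at electrochemical equilibrium:
  # under 10% of the open-system reference
  open <- open_system_reference(leaky_config())$minus_dG_reported
  expect_lt(v[1], 0.1 * open)   # 1e-6 cm/s
  expect_lt(v[2], 0.1 * open)   # 1e-5 cm/s
  # leaky membranes retain most of the reference
  expect_gt(v[5], 0.85 * open)
})

test_that("equal 3-unit gradients weaken as the environment acidifies", {
  v <- c(steady_mdg(pH_acid = 7, pH_alk = 10, atpase = 0.01),
         steady_mdg(pH_acid = 6, pH_alk = 9, atpase = 0.01),
         steady_mdg(pH_acid = 5, pH_alk = 8, atpase = 0.01))
  expect_true(all(diff(v) < 0))          # 7:10 > 6:9 > 5:8
  expect_lt(v[3], 0.2 * v[1])            # 5:8 close to collapse
})

test_that("protein crowding collapses the gradient even in leaky membranes", {
  v <- vapply(c(0.01, 0.05, 0.10, 0.50),
              function(f) steady_mdg(atpase = f, perm_H_cm_s = 1e-3),
              numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(v[4], 0.25 * v[1])           # 50% ATPase is ruinous
  # Ech, with double the per-unit proton rate, collapses at least as hard
  e <- vapply(c(0.01, 0.50),
              function(f) steady_mdg(ech = f, perm_H_cm_s = 1e-3),
              numeric(1))
  expect_true(all(diff(e) < 0))
  expect_lte(e[2], v[4] + 0.01)
})

test_that("pumping without SPAP is futile; with SPAP it pays off", {
  perms <- 10^seq(-6, -2)
  alone <- vapply(perms, function(p)
    steady_mdg(atpase = 0.01, pump = 0.01, perm_H_cm_s = p,
               t_end = 1500, steady_window = 60), numeric(1))
  # futility: tightening the membrane never beats the leaky cell
  expect_lte(alone[2], alone[5])         # 1e-5 vs 1e-2 cm/s
  expect_true(all(alone <= alone[5] + 0.01))
  # with 1% SPAP and a 5% pump the gain amplifies as permeability falls
  with_spap <- vapply(perms, function(p)
    steady_mdg(atpase = 0.01, spap = 0.01, pump = 0.05, perm_H_cm_s = p,
               t_end = 1500, steady_window = 60), numeric(1))
  expect_true(all(diff(with_spap) < 0))  # monotone rise as perm falls
  expect_gt(with_spap[1], alone[1] + 5)  # pump-powered tight cell
})

test_that("without a gradient, leaky pumped cells stay under 15 kJ/mol", {
  v <- vapply(c(1e-4, 1e-3, 1e-2), function(p)
    steady_mdg(pH_acid = 7, pH_alk = 7, atpase = 0.01, pump = 0.05,
               perm_H_cm_s = p, t_end = 1500, steady_window = 60),
    numeric(1))
  expect_true(all(v < 15))
})

test_that("SPAP first collapses the driving force, then rebuilds it", {
  run <- run_protocell(protocell_config(atpase = 0.01, spap = 0.05,
                                        perm_H_cm_s = 1e-3, t_end = 900,
                                        steady_tol = 1e-6,
                                        steady_window = 120))
  s <- run$series
  early <- s$minus_dG_reported[s$t <= 60]
  final <- run$summary$minus_dG_reported
  expect_lt(min(early), 0.1 * final)     # deep initial collapse
  expect_gt(final, 10)                   # recovery within minutes
  # the recovery is carried by the sodium gradient the antiporter built
  expect_lt(run$summary$internal[["Na"]], 0.01)
  expect_equal(run$summary$minus_dG_H, run$summary$minus_dG_Na,
               tolerance = 0.05)
})

test_that("protein fluxes never exceed their turnover bounds in situ", {
  a <- audit_run(protocell_config(atpase = 0.02, spap = 0.01, pump = 0.01,
                                  init_pH = 9, t_end = 10))
  cfg <- protocell_config(atpase = 0.02, spap = 0.01, pump = 0.01)
  geo <- cfg$geometry
  cap <- function(kind) {
    p <- cfg$proteins[[kind]]
    unit_count(p, geo) * p$max_turnover * p$efficiency_scale *
      p$ions_per_cycle / 6.02214076e23
  }
  total_cap <- cap("atpase") + cap("spap") + cap("pump")
  expect_true(all(abs(a$pathway_fluxes$protein_H) <= total_cap * (1 + 1e-9)))
  expect_true(all(abs(a$pathway_fluxes$protein_Na) <= total_cap * (1 + 1e-9)))
})

test_that("efficiency and stoichiometry shift the outcome only mildly", {
  base <- steady_mdg(atpase = 0.01, spap = 0.01, pump = 0.05,
                     t_end = 1500, steady_window = 60)
  for (eff in c(0.5, 1.0)) {
    v <- steady_mdg(atpase = 0.01, spap = 0.01, pump = 0.05,
                    efficiency_scale = eff, t_end = 1500,
                    steady_window = 60)
    expect_equal(v, base, tolerance = 0.35)
  }
})
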