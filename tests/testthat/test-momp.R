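test_that("building a network from a profile sets measured initials only", {
  p <- protein_profile("HCC1143", bcl2 = 0.907, mcl1 = 0.330, bak = 3.173,
                       bax = 0.638, bclxl = 0.317)
  net <- build_momp_network(p)
  y0 <- setNames(vapply(net$species, `[[`, numeric(1), "initial"),
                 species_ids(net))
  expect_equal(unname(y0["BAK"]), 3.173)
  expect_equal(unname(y0["BCL2"]), 0.907)
  expect_equal(unname(y0["BCLXL"]), 0.317)
  # BH3-only initiators keep their model-definition defaults (zero: they
  # are induced by stress, not constitutive)
  expect_equal(unname(y0[c("BIM", "PUMA", "NOXA")]), c(0, 0, 0))
})

test_that("a zero antagonist dose leaves the network untouched", {
  p <- toy_profile()
  model <- toy_momp_model()
  base <- build_momp_network(p, model)
  zero <- build_momp_network(p, model,
                             list(list(antagonist = antagonist("d", "BCL2",
                                                               10),
                                       dose = 0)))
  expect_identical(base, zero)
})

test_that("antagonists enter at half the nominal dose against their target", {
  p <- toy_profile()
  model <- toy_momp_model()
  drug <- antagonist("TestDrug", "BCL2", kd_nM = 10)
  net <- build_momp_network(p, model,
                            list(list(antagonist = drug, dose = 2)))
  expect_equal(length(net$species), length(model$species) + 2)
  expect_equal(length(net$reactions), length(model$reactions) + 2)
  y0 <- setNames(vapply(net$species, `[[`, numeric(1), "initial"),
                 species_ids(net))
  expect_equal(unname(y0["TESTDRUG"]), 0.5 * 2)  # bioavailability 0.5
  # only two reactions reference the drug, both against the target A
  touch <- vapply(net$reactions, function(r)
    "TESTDRUG" %in% c(names(r$reactants), names(r$products)), logical(1))
  expect_equal(sum(touch), 2)
  expect_error(build_momp_network(p, model,
                                  list(list(antagonist = drug, dose = -1))),
               "finite and >= 0")
})

test_that("binding rates follow detailed balance with nM to uM conversion", {
  r <- binding_rates_from_kd(1000, 360)
  expect_equal(r$k_reverse, 1.0 * 360)
  expect_equal(r$k_reverse / r$k_forward, 1.0)  # K_D in uM, exactly
  r2 <- binding_rates_from_kd(0.5, 100)
  expect_equal(r2$k_reverse / r2$k_forward, 0.5 / 1000)
  expect_error(binding_rates_from_kd(-1, 360), "positive")
  expect_error(binding_rates_from_kd(1, 0), "positive")
})

test_that("tighter binders occupy more target, matching the isotherm", {
  # simulate drug-target binding alone and compare the equilibrium
  # occupancy to the analytic single-site quadratic
  occupancy <- function(kd_uM, dose) {
    net <- reaction_network(
      list(species("D", dose), species("T", 1), species("DT", 0)),
      list(reaction(c("D", "T"), "DT", 360, "association"),
           reaction("DT", c("D", "T"), kd_uM * 360, "dissociation")))
    tr <- simulate_network(net, 500, atol = 1e-12, rtol = 1e-10)
    unname(tr$concentrations["DT", ncol(tr$concentrations)])
  }
  occ_tight <- occupancy(0.01, 0.5)
  occ_weak <- occupancy(1, 0.5)
  expect_gt(occ_tight, occ_weak)
  expect_equal(occ_tight, binding_equilibrium(0.5, 1, 0.01),
               tolerance = 1e-5)
  expect_equal(occ_weak, binding_equilibrium(0.5, 1, 1), tolerance = 1e-5)
})

test_that("no effectors means no pores and a resistant verdict", {
  model <- toy_momp_model()
  p0 <- protein_profile("noeff", bcl2 = 0.5, mcl1 = 0, bclxl = 0,
                        bax = 0, bak = 0)
  net <- build_momp_network(p0, model)
  tr <- simulate_network(net, 12, inputs = production_input(c(X = 1), 0, 12))
  expect_true(all(pore_timecourse(tr, model)$pore == 0))
  sd <- compute_eta(p0, model = model)
  expect_equal(sd$status, "resistant_beyond_bound")
  expect_true(is.na(sd$eta))
  expect_false(sd$momp_reached)
})

test_that("a degenerate pore threshold yields eta = 0", {
  sd <- compute_eta(toy_profile(), momp_config(pore_threshold = 0),
                    model = toy_momp_model())
  expect_equal(sd$eta, 0)
  expect_equal(sd$status, "momp_at_zero")
})

test_that("bisection agrees with a grid-search oracle on the toy model", {
  model <- toy_momp_model()
  p <- toy_profile(a = 0.5, e = 1)
  cfg <- momp_config(eta_upper_bound = 1)
  sd <- compute_eta(p, cfg, model = model)
  expect_equal(sd$status, "ok")
  oracle <- grid_search_eta(model, p, upper = 1, n = 200, config = cfg)
  grid_step <- 1 / 200
  expect_lt(abs(sd$eta - oracle),
            grid_step + cfg$bisection_rel_tol * oracle)
})

test_that("eta rises with the buffer and falls under an antagonist (toy)", {
  model <- toy_momp_model()
  cfg <- momp_config(eta_upper_bound = 2)
  eta_a <- function(a) compute_eta(toy_profile(a = a), cfg,
                                   model = model)$eta
  expect_gt(eta_a(0.8), eta_a(0.4))

  drug <- antagonist("blocker", "BCL2", kd_nM = 1)
  curve <- eta_dose_curve(toy_profile(a = 0.5), drug, doses = c(0, 0.5, 2),
                          config = cfg, model = model)
  base <- compute_eta(toy_profile(a = 0.5), cfg, model = model)
  expect_identical(curve$eta[1], base$eta)  # zero dose is exactly baseline
  expect_true(all(diff(curve$eta) <= 1e-12))
})

test_that("an antagonist without expressed target does nothing (toy)", {
  model <- toy_momp_model()
  p <- protein_profile("nobuffer", bcl2 = 0, mcl1 = 0, bclxl = 0,
                       bax = 1, bak = 0)
  cfg <- momp_config(eta_upper_bound = 0.5)
  drug <- antagonist("blocker", "BCL2", kd_nM = 1)
  e0 <- compute_eta(p, cfg, model = model)$eta
  e3 <- compute_eta(p, cfg,
                    antagonist_doses = list(list(antagonist = drug,
                                                 dose = 3)),
                    model = model)$eta
  expect_lt(abs(e3 - e0) / e0, 1e-6)
})

test_that("pore synergy grids are marginally consistent (toy)", {
  model <- toy_momp_model()
  drug <- antagonist("blocker", "BCL2", kd_nM = 1)
  g <- pore_synergy_grid(toy_profile(a = 0.5), drug,
                         antagonist_doses = c(0, 0.5, 1),
                         stress_doses = c(0, 0.2, 0.6),
                         model = model)
  # the zero-antagonist row is the stress-only dose response
  base_net <- build_momp_network(toy_profile(a = 0.5), model)
  for (j in seq_along(g$stress_doses)) {
    eta <- g$stress_doses[j]
    inp <- if (eta > 0) production_input(c(X = eta / 12), 0, 12) else NULL
    tr <- simulate_network(base_net, 12, inputs = inp)
    expect_equal(g$pore[1, j], max(pore_timecourse(tr, model)$pore),
                 tolerance = 1e-10)
  }
  # antagonist alone produces no pores above threshold (no stress input)
  expect_true(all(g$pore[, 1] <= model$meta$momp$pore_threshold))
  # pore amount grows along both axes; CI defined only off the margins
  expect_true(all(diff(g$pore[, 3]) >= -1e-9))
  expect_true(all(is.na(g$ci[1, ])) && all(is.na(g$ci[, 1])))
  expect_false(anyNA(g$ci[-1, -1]))
})

test_that("eta ranking of the panel is stable under solver tolerances", {
  profs <- table1_profiles()
  cfg_tight <- momp_config()                      # atol = rtol = 1e-6
  cfg_loose <- momp_config(atol = 1e-5, rtol = 1e-5)
  et1 <- eta_table(profs, cfg_tight)
  et2 <- eta_table(profs, cfg_loose)
  expect_equal(order(et1$eta), order(et2$eta))
  expect_equal(et1$eta, et2$eta, tolerance = 0.02)
})
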