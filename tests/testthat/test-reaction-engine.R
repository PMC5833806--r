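test_that("network construction validates species, reactions and groups", {
  expect_error(species("A", -1), "finite and >= 0")
  expect_error(reaction_network(list(species("A"), species("A")), list()),
               "duplicate species ids")
  expect_error(
    reaction_network(list(species("A")),
                     list(reaction("A", "B", 1, "conversion"))),
    "undeclared species")
  expect_error(reaction(c("A", "A", "B"), "C", 1), "order must be <= 2")
  expect_error(reaction(c("A"), "B", -1), "rate constant")
  expect_error(reaction("A", "B", 1, kind = "production"),
               "no reactants")
  expect_error(reaction("A", "B", 1, kind = "degradation"), "no products")
  # a declared group that the stoichiometry does not conserve is rejected
  expect_error(
    reaction_network(
      list(species("A", 1), species("B", 1)),
      list(reaction("A", "B", 1, "conversion")),
      conservation = list(bad = c(A = 1, B = 2))),
    "not conserved by the declared stoichiometry")
})

test_that("a network without reactions keeps all species constant", {
  net <- reaction_network(list(species("A", 2), species("B", 0.5)), list())
  tr <- simulate_network(net, horizon = 5)
  expect_equal(unname(tr$concentrations["A", ]),
               rep(2, length(tr$times)))
  expect_equal(unname(tr$concentrations["B", ]),
               rep(0.5, length(tr$times)))
})

test_that("zero initial state without input is a fixed point", {
  net <- binding_pair(a0 = 0, b0 = 0)
  tr <- simulate_network(net, horizon = 10)
  expect_true(all(tr$concentrations == 0))
})

test_that("bimolecular binding reaches the analytic quadratic equilibrium", {
  # A0 = B0 = 1, KD = 0.1: [AB]* = ((A0+B0+KD) - sqrt((A0+B0+KD)^2-4))/2
  net <- binding_pair(a0 = 1, b0 = 1, kd = 0.1)
  tr <- simulate_network(net, horizon = 100, atol = 1e-12, rtol = 1e-10)
  ab <- unname(tr$concentrations["AB", ncol(tr$concentrations)])
  expect_equal(ab, binding_equilibrium(1, 1, 0.1), tolerance = 1e-6)
  expect_equal(ab, 0.7298438, tolerance = 1e-6)
})

test_that("second-order self-reactions follow the closed-form decay", {
  # 2A -> A2 at rate k[A]^2: d[A]/dt = -2k[A]^2, [A](t) = A0/(1+2kA0t)
  net <- reaction_network(
    list(species("A", 1), species("A2", 0)),
    list(reaction(c("A", "A"), "A2", 5, "association")))
  tr <- simulate_network(net, horizon = 2, atol = 1e-10, rtol = 1e-10)
  expect_equal(unname(tr$concentrations["A", ]),
               1 / (1 + 2 * 5 * 1 * tr$times), tolerance = 1e-6)
})

test_that("step production input ramps linearly then stops", {
  net <- reaction_network(list(species("A", 0)), list())
  tr <- simulate_network(net, horizon = 20,
                         inputs = production_input(c(A = 0.25), 0, 12))
  expect_equal(unname(tr$concentrations["A", ]),
               0.25 * pmin(tr$times, 12), tolerance = 1e-6)
  expect_error(
    simulate_network(net, 20, inputs = production_input(c(Z = 1), 0, 12)),
    "unknown species")
})

test_that("conservation check reports drift and flags open groups", {
  tr <- simulate_network(binding_pair(), horizon = 12)
  cc <- check_conservation(tr, binding_pair())
  expect_true(all(cc$max_drift < 1e-6))
  expect_true(all(cc$conserved_expected))

  # two independent closed binding pairs conserve both totals
  net2 <- reaction_network(
    list(species("A", 1), species("B", 1), species("AB", 0),
         species("C", 2), species("D", 0.5), species("CD", 0)),
    list(reaction(c("A", "B"), "AB", 360, "association"),
         reaction("AB", c("A", "B"), 36, "dissociation"),
         reaction(c("C", "D"), "CD", 100, "association"),
         reaction("CD", c("C", "D"), 10, "dissociation")),
    conservation = list(A = c(A = 1, AB = 1), C = c(C = 1, CD = 1)))
  cc2 <- check_conservation(simulate_network(net2, 12), net2)
  expect_true(all(cc2$max_drift < 1e-6))

  # an active degradation reaction marks the touched group as open
  net3 <- reaction_network(
    list(species("A", 1), species("B", 1), species("AB", 0)),
    list(reaction(c("A", "B"), "AB", 360, "association"),
         reaction("AB", c("A", "B"), 36, "dissociation"),
         reaction("A", character(), 0.1, "degradation")),
    conservation = list(B = c(B = 1, AB = 1)))
  net3$conservation$A <- c(A = 1, AB = 1)  # group around the degraded species
  cc3 <- check_conservation(simulate_network(net3, 12), net3)
  expect_false(cc3[cc3$group == "A", "conserved_expected"])
  expect_true(cc3[cc3$group == "B", "conserved_expected"])

  expect_error(check_conservation(tr, reaction_network(list(species("A")),
                                                       list())),
               "no conservation groups")
})

test_that("simulation is deterministic and non-negative", {
  net <- build_momp_network(toy_profile(), toy_momp_model())
  inp <- production_input(c(X = 0.05), 0, 12)
  t1 <- simulate_network(net, 12, inputs = inp)
  t2 <- simulate_network(net, 12, inputs = inp)
  expect_identical(t1$concentrations, t2$concentrations)
  expect_true(all(t1$concentrations >= 0))
})

test_that("trajectory export is tidy and round-trips through CSV", {
  tr <- simulate_network(binding_pair(), horizon = 1)
  df <- as.data.frame(tr)
  expect_named(df, c("time", "species", "concentration"))
  expect_equal(nrow(df), 3 * length(tr$times))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$concentration, df$concentration)
  unlink(path)
})
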