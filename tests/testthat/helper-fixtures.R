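# Fixtures built in code: small networks and curves reused across tests.

# Single reversible binding pair A + B <-> AB.
binding_pair <- function(a0 = 1, b0 = 1, kd = 0.1, k_on = 360) {
  reaction_network(
    list(species("A", a0), species("B", b0), species("AB", 0)),
    list(reaction(c("A", "B"), "AB", k_on, "association"),
         reaction("AB", c("A", "B"), kd * k_on, "dissociation")),
    conservation = list(A = c(A = 1, AB = 1), B = c(B = 1, AB = 1)))
}

# Analytic equilibrium complex concentration of the bimolecular pair.
binding_equilibrium <- function(a0, b0, kd) {
  s <- a0 + b0 + kd
  (s - sqrt(s^2 - 4 * a0 * b0)) / 2
}

# Reduced toy MOMP model: one anti-apoptotic buffer A, one effector E.
# Stress species X is produced, is sequestered by A, and catalytically
# activates E; active Ea dimerises irreversibly into the pore species.
# Carries a momp block so the compute_eta machinery runs unchanged.
toy_momp_model <- function(pore_threshold = 0.05) {
  sp <- list(species("X", 0), species("A", 0), species("XA", 0),
             species("E", 0), species("Ea", 0), species("PORE", 0))
  rxn <- list(
    reaction(c("X", "A"), "XA", 360, "association"),
    reaction("XA", c("X", "A"), 3.6, "dissociation"),
    reaction(c("X", "E"), c("X", "Ea"), 36, "conversion"),
    reaction(c("Ea", "Ea"), "PORE", 36, "association"),
    reaction(character(), "X", 0, "production"))
  net <- reaction_network(sp, rxn,
    conservation = list(A = c(A = 1, XA = 1),
                        E = c(E = 1, Ea = 1, PORE = 2)),
    meta = list(momp = list(
      pore_species = "PORE", pore_threshold = pore_threshold,
      bh3_species = "X",
      profile_map = list(bcl2 = "A", mcl1 = "A", bclxl = "A",
                         bax = "E", bak = "E"),
      antagonist_targets = list(BCL2 = "A", BCLXL = "A", MCL1 = "A"),
      reference_forward_rate = 360)),
    name = "toy_momp")
  net
}

# The toy model maps bcl2/mcl1/bclxl all onto A and bax/bak onto E, so
# split totals across the mapped fields to set A and E directly.
toy_profile <- function(a = 0.5, e = 1) {
  protein_profile("toy", bcl2 = a, mcl1 = 0, bclxl = 0, bax = e, bak = 0)
}

# Grid-search oracle for the minimal MOMP-inducing stress dose: scans a
# uniform dose grid and returns the smallest dose whose peak pore amount
# reaches the threshold. Independent of the bisection path.
grid_search_eta <- function(model, profile, upper, n = 1000,
                            config = momp_config()) {
  net <- build_momp_network(profile, model)
  momp <- model$meta$momp
  threshold <- momp$pore_threshold
  dur <- config$production_duration
  grid <- seq(0, upper, length.out = n + 1)
  for (eta in grid) {
    inp <- if (eta > 0)
      production_input(stats::setNames(rep(eta / dur,
                                           length(momp$bh3_species)),
                                       unlist(momp$bh3_species)),
                       0, dur) else NULL
    tr <- simulate_network(net, horizon = dur, inputs = inp)
    if (max(pore_timecourse(tr, model)$pore) >= threshold) return(eta)
  }
  NA_real_
}

# Four-parameter logistic used to build synthetic dose-response data.
logistic4 <- function(d, floor = 0, ceiling = 1, e50 = 30, hill = 2) {
  ifelse(d > 0, floor + (ceiling - floor) * d^hill / (d^hill + e50^hill),
         floor)
}

table1_profiles <- function() tnbc_panel()
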