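#' Per-cell-line BCL-2 protein profile
#'
#' Absolute concentrations (uM) of the five measured BCL-2 family proteins,
#' as obtained by quantitative immunoblotting.
#'
#' @param cell_line Cell line name.
#' @param bcl2,mcl1,bak,bax,bclxl Concentrations in uM (>= 0, finite).
#' @return An object of class `protein_profile`.
#' @export
#' @examples
#' protein_profile("HCC1143", bcl2 = 0.907, mcl1 = 0.330, bak = 3.173,
#'                 bax = 0.638, bclxl = 0.317)
protein_profile <- function(cell_line, bcl2, mcl1, bak, bax, bclxl) {
  vals <- c(bcl2 = bcl2, mcl1 = mcl1, bak = bak, bax = bax, bclxl = bclxl)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("protein concentrations must be finite and >= 0")
  structure(c(list(cell_line = as.character(cell_line)), as.list(vals)),
            class = "protein_profile")
}

#' @export
print.protein_profile <- function(x, ...) {
  cat("<protein_profile> ", x$cell_line, "\n", sep = "")
  v <- unlist(x[c("bcl2", "mcl1", "bak", "bax", "bclxl")])
  print(round(v, 4))
  invisible(x)
}

#' Selective BCL-2 family antagonist descriptor
#'
#' Describes a small-molecule inhibitor of one anti-apoptotic protein by its
#' dissociation constant. Doses applied in silico are multiplied by the
#' bioavailability factor (default 0.5, accounting for drug degradation and
#' active extrusion) before entering the network.
#'
#' @param name Drug name.
#' @param target One of `"BCL2"`, `"BCLXL"`, `"MCL1"`.
#' @param kd_nM Dissociation constant in nM (> 0).
#' @param bioavailability_factor In (0, 1]; default 0.5.
#' @return An object of class `antagonist`.
#' @export
#' @examples
#' antagonist("WEHI-539", "BCLXL", kd_nM = 1.1)
antagonist <- function(name, target = c("BCL2", "BCLXL", "MCL1"), kd_nM,
                       bioavailability_factor = 0.5) {
  target <- match.arg(target)
  if (!is.numeric(kd_nM) || kd_nM <= 0 || !is.finite(kd_nM))
    stop("kd_nM must be a positive dissociation constant in nM")
  if (bioavailability_factor <= 0 || bioavailability_factor > 1)
    stop("bioavailability_factor must be in (0, 1]")
  structure(list(name = name, target = target, kd_nM = kd_nM,
                 bioavailability_factor = bioavailability_factor),
            class = "antagonist")
}

#' Default antagonist panel
#'
#' ABT-199/Venetoclax (BCL2), WEHI-539 (BCL(X)L) and A-1210477 (MCL1) with
#' literature-typical dissociation constants. The exact published values
#' vary by assay; these defaults are starting points meant to be overridden
#' via [antagonist()] when authoritative constants are available.
#'
#' @return Named list of [antagonist()] objects.
#' @export
default_antagonists <- function() {
  list(
    abt199 = antagonist("ABT-199", "BCL2", kd_nM = 0.01),
    wehi539 = antagonist("WEHI-539", "BCLXL", kd_nM = 1.1),
    a1210477 = antagonist("A-1210477", "MCL1", kd_nM = 0.45))
}

#' Forward/reverse binding rates from a dissociation constant
#'
#' Antagonist binding reuses the model's generic protein-protein forward
#' rate; the reverse rate follows from detailed balance,
#' `k_reverse / k_forward = K_D` (with K_D converted from nM to uM).
#'
#' @param kd_nM Dissociation constant in nM (> 0).
#' @param reference_forward_rate Forward rate in 1/(uM h) (> 0).
#' @return Named list with `k_forward` (1/(uM h)) and `k_reverse` (1/h).
#' @export
#' @examples
#' binding_rates_from_kd(1000, 360)  # k_reverse = 1 uM * 360
binding_rates_from_kd <- function(kd_nM, reference_forward_rate) {
  if (!is.numeric(kd_nM) || kd_nM <= 0 || !is.finite(kd_nM))
    stop("kd_nM must be positive and finite")
  if (!is.numeric(reference_forward_rate) || reference_forward_rate <= 0)
    stop("reference_forward_rate must be positive")
  list(k_forward = reference_forward_rate,
       k_reverse = (kd_nM / 1000) * reference_forward_rate)
}

#' MOMP scoring configuration
#'
#' @param production_duration Stress window in hours (default 12): BH3-only
#'   production is a step function, on at a constant rate over this window.
#' @param pore_threshold Pore amount (uM) defining MOMP; `NULL` uses the
#'   model file's value.
#' @param post_production_horizon Extra simulated hours after the window
#'   (default 0: the simulation horizon equals the stress duration).
#' @param bisection_rel_tol Relative tolerance on eta (default 1e-3).
#' @param max_iterations Bisection iteration cap (default 40).
#' @param eta_upper_bound Upper bracket on eta in uM; `NULL` defaults to
#'   10x the summed anti-apoptotic concentration of the profile.
#' @param atol,rtol ODE solver tolerances.
#' @return An object of class `momp_config`.
#' @export
momp_config <- function(production_duration = 12, pore_threshold = NULL,
                        post_production_horizon = 0,
                        bisection_rel_tol = 1e-3, max_iterations = 40,
                        eta_upper_bound = NULL, atol = 1e-6, rtol = 1e-6) {
  stopifnot(production_duration > 0, post_production_horizon >= 0,
            bisection_rel_tol > 0, max_iterations >= 1)
  structure(list(production_duration = production_duration,
                 pore_threshold = pore_threshold,
                 post_production_horizon = post_production_horizon,
                 bisection_rel_tol = bisection_rel_tol,
                 max_iterations = max_iterations,
                 eta_upper_bound = eta_upper_bound,
                 atol = atol, rtol = rtol),
            class = "momp_config")
}

#' Instantiate the BCL-2 network for a cell line
#'
#' Sets the initial concentrations of the five measured proteins from the
#' profile (BH3-only initiators keep their model-definition defaults) and,
#' for each antagonist given a dose > 0, adds one drug species at effective
#' concentration `bioavailability_factor * dose` plus association and
#' dissociation reactions against its target only.
#'
#' @param profile A [protein_profile()].
#' @param model A [reaction_network()] from [default_model()] or
#'   [read_model_definition()].
#' @param antagonist_doses Optional named list mapping antagonist objects to
#'   nominal doses: a list of `list(antagonist =, dose =)` entries, or a
#'   named numeric vector of doses with names matching
#'   [default_antagonists()].
#' @return A [reaction_network()] ready for [simulate_network()].
#' @export
build_momp_network <- function(profile, model = default_model(),
                               antagonist_doses = NULL) {
  stopifnot(inherits(profile, "protein_profile"))
  momp <- model$meta$momp
  if (is.null(momp)) stop("model definition lacks a 'momp' block")
  pm <- momp$profile_map
  init <- stats::setNames(
    vapply(names(pm), function(f) profile[[f]], numeric(1)),
    unlist(pm))
  net <- set_initial(model, init)

  doses <- normalize_antagonist_doses(antagonist_doses)
  for (entry in doses) {
    drug <- entry$antagonist
    dose <- entry$dose
    if (!is.numeric(dose) || dose < 0 || !is.finite(dose))
      stop("antagonist dose must be finite and >= 0")
    if (dose == 0) next
    target <- momp$antagonist_targets[[drug$target]]
    if (is.null(target) || !target %in% species_ids(net))
      stop("antagonist target '", drug$target,
           "' is not a species of the model definition")
    rates <- binding_rates_from_kd(drug$kd_nM, momp$reference_forward_rate)
    drug_id <- gsub("[^A-Za-z0-9]", "", toupper(drug$name))
    cx_id <- paste0(drug_id, ".", target)
    net$species <- c(net$species,
                     list(species(drug_id,
                                  initial = drug$bioavailability_factor * dose,
                                  name = drug$name),
                          species(cx_id)))
    net$reactions <- c(net$reactions, list(
      reaction(c(drug_id, target), cx_id, rates$k_forward, "association"),
      reaction(cx_id, c(drug_id, target), rates$k_reverse, "dissociation")))
    # the target's conservation group gains its drug-bound form
    if (!is.null(net$conservation[[target]]))
      net$conservation[[target]][cx_id] <- 1
  }
  # re-validate after modification
  reaction_network(net$species, net$reactions, conservation = net$conservation,
                   meta = net$meta, name = net$name)
}

normalize_antagonist_doses <- function(antagonist_doses) {
  if (is.null(antagonist_doses) || length(antagonist_doses) == 0L)
    return(list())
  if (is.numeric(antagonist_doses)) {
    panel <- default_antagonists()
    bad <- setdiff(names(antagonist_doses), names(panel))
    if (length(bad))
      stop("unknown antagonist name(s): ", paste(bad, collapse = ", "))
    return(lapply(names(antagonist_doses), function(n)
      list(antagonist = panel[[n]], dose = antagonist_doses[[n]])))
  }
  lapply(antagonist_doses, function(e) {
    if (inherits(e, "antagonist")) stop("supply list(antagonist =, dose =)")
    stopifnot(inherits(e$antagonist, "antagonist"), is.numeric(e$dose))
    e
  })
}

#' Pore amount over time
#'
#' Sums the concentrations of the species designated as pores in the model
#' definition's `momp` block (mixed BAXa/BAKa oligomers of size >= 6 in the
#' default model).
#'
#' @param trajectory A `bcl_trajectory` from a MOMP-built network.
#' @param model The model definition the network derives from (used for the
#'   pore designation); defaults to the trajectory's own network when built
#'   through [build_momp_network()].
#' @return Data frame with columns `time` (h) and `pore` (uM).
#' @export
pore_timecourse <- function(trajectory, model) {
  momp <- model$meta$momp
  if (is.null(momp) || is.null(momp$pore_species))
    stop("model definition lacks a pore designation in its 'momp' block")
  ps <- unlist(momp$pore_species)
  miss <- setdiff(ps, rownames(trajectory$concentrations))
  if (length(miss))
    stop("trajectory lacks designated pore species: ",
         paste(miss, collapse = ", "))
  pore <- colSums(trajectory$concentrations[ps, , drop = FALSE])
  data.frame(time = trajectory$times, pore = as.numeric(pore))
}

# Simulate one stress episode and report the peak pore amount.
peak_pore <- function(net, rate, config, momp) {
  horizon <- config$production_duration + config$post_production_horizon
  inp <- if (rate > 0) {
    production_input(stats::setNames(rep(rate, length(momp$bh3_species)),
                                     unlist(momp$bh3_species)),
                     start = 0, stop = config$production_duration)
  } else NULL
  tr <- simulate_network(net, horizon = horizon, inputs = inp,
                         atol = config$atol, rtol = config$rtol)
  max(pore_timecourse(tr, net)$pore)
}

#' Stress dose eta required for MOMP
#'
#' Computes eta, the total production of each BH3-only initiator (BIM, PUMA
#' and NOXA, produced at identical constant rates over the stress window)
#' minimally required for the peak pore amount to reach the MOMP threshold
#' within the simulation horizon. The minimal dose is located by bisection
#' on the production rate; eta = rate x window duration. Higher eta means
#' the modelled cell tolerates more stress, i.e. is more resistant to
#' mitochondrial apoptosis.
#'
#' @param profile A [protein_profile()].
#' @param config A [momp_config()].
#' @param antagonist_doses As in [build_momp_network()].
#' @param model Model definition network.
#' @return An object of class `stress_dose` with fields `eta` (uM; `NA` if
#'   MOMP is unreachable), `production_rate` (uM/h), `momp_reached`,
#'   `status` (`"ok"`, `"momp_at_zero"`, or `"resistant_beyond_bound"`),
#'   `bisection_iterations`, `bracket`, `pore_threshold` and `cell_line`.
#' @export
#' @examples
#' \donttest{
#' p <- protein_profile("HCC1143", 0.907, 0.330, 3.173, 0.638, 0.317)
#' compute_eta(p)
#' }
compute_eta <- function(profile, config = momp_config(),
                        antagonist_doses = NULL, model = default_model()) {
  stopifnot(inherits(config, "momp_config"))
  net <- build_momp_network(profile, model, antagonist_doses)
  momp <- model$meta$momp
  threshold <- if (!is.null(config$pore_threshold)) config$pore_threshold
               else momp$pore_threshold
  if (is.null(threshold)) stop("no pore threshold configured")

  mk <- function(eta, momp_reached, status, iters, bracket) {
    structure(list(eta = eta,
                   production_rate = if (is.na(eta)) NA_real_
                                     else eta / config$production_duration,
                   momp_reached = momp_reached, status = status,
                   bisection_iterations = iters, bracket = bracket,
                   pore_threshold = threshold,
                   cell_line = profile$cell_line),
              class = "stress_dose")
  }

  if (threshold <= 0) return(mk(0, TRUE, "momp_at_zero", 0L, c(0, 0)))

  anti_total <- profile$bcl2 + profile$mcl1 + profile$bclxl
  ub <- if (!is.null(config$eta_upper_bound)) config$eta_upper_bound
        else 10 * anti_total
  if (ub <= 0) ub <- 1  # profile with no anti-apoptotic proteins at all
  dur <- config$production_duration

  momp_at <- function(eta) peak_pore(net, eta / dur, config, momp) >= threshold

  if (momp_at(0)) return(mk(0, TRUE, "momp_at_zero", 0L, c(0, 0)))
  if (!momp_at(ub)) return(mk(NA_real_, FALSE, "resistant_beyond_bound", 0L,
                              c(0, ub)))

  lo <- 0; hi <- ub; iters <- 0L
  while (iters < config$max_iterations &&
         (hi - lo) > config$bisection_rel_tol * hi) {
    mid <- (lo + hi) / 2
    if (momp_at(mid)) hi <- mid else lo <- mid
    iters <- iters + 1L
  }
  mk(hi, TRUE, "ok", iters, c(lo, hi))
}

#' @export
print.stress_dose <- function(x, ...) {
  cat("<stress_dose> ", x$cell_line, "\n", sep = "")
  if (x$status == "resistant_beyond_bound") {
    cat("  MOMP not reached below eta = ", signif(x$bracket[2], 4),
        " uM (resistant beyond bound)\n", sep = "")
  } else {
    cat("  eta = ", signif(x$eta, 4), " uM  (production rate ",
        signif(x$production_rate, 4), " uM/h, threshold ",
        signif(x$pore_threshold, 4), " uM, ", x$bisection_iterations,
        " bisection iterations)\n", sep = "")
    if (x$status == "momp_at_zero")
      cat("  note: MOMP occurs without any stress input\n")
  }
  invisible(x)
}

#' Stress dose for a set of profiles
#'
#' @param profiles List of [protein_profile()] objects (e.g. from
#'   [read_profiles()]).
#' @inheritParams compute_eta
#' @return Data frame with columns `cell_line`, `eta`, `status`.
#' @export
eta_table <- function(profiles, config = momp_config(),
                      antagonist_doses = NULL, model = default_model()) {
  rows <- lapply(profiles, function(p) {
    sd <- compute_eta(p, config, antagonist_doses, model)
    data.frame(cell_line = p$cell_line, eta = sd$eta, status = sd$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Eta as a function of antagonist dose
#'
#' Recomputes the stress dose over a grid of nominal antagonist doses. At
#' dose 0 the antagonist-free network is used, so the curve starts exactly
#' at the baseline eta; for an expressed target the curve is non-increasing
#' (the drug frees pro-apoptotic capacity).
#'
#' @param profile A [protein_profile()].
#' @param antagonist An [antagonist()].
#' @param doses Numeric vector of nominal doses in uM (>= 0).
#' @inheritParams compute_eta
#' @return Data frame with columns `dose`, `eta`, `status`, of class
#'   `eta_dose_curve`.
#' @export
eta_dose_curve <- function(profile, antagonist, doses,
                           config = momp_config(), model = default_model()) {
  stopifnot(inherits(antagonist, "antagonist"), all(doses >= 0))
  rows <- lapply(doses, function(d) {
    sd <- compute_eta(profile, config,
                      antagonist_doses = list(list(antagonist = antagonist,
                                                   dose = d)),
                      model = model)
    data.frame(dose = d, eta = sd$eta, status = sd$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cell_line") <- profile$cell_line
  attr(out, "antagonist") <- antagonist$name
  class(out) <- c("eta_dose_curve", class(out))
  out
}

#' @export
plot.eta_dose_curve <- function(x, ...) {
  graphics::plot(x$dose, x$eta, type = "b", pch = 16,
                 xlab = paste0(attr(x, "antagonist"), " dose (uM)"),
                 ylab = "eta (uM)",
                 main = attr(x, "cell_line"), ...)
  invisible(x)
}

#' In-silico pore/synergy grid for antagonist plus genotoxic stress
#'
#' Simulates a full dose matrix of antagonist dose x BH3-only stress dose
#' and records the peak pore amount in each cell. Effect fractions are
#' derived by normalising pore amounts to the grid maximum, and a Webb
#' fractional-product combination index is computed for each nonzero dose
#' pair via [webb_ci()].
#'
#' @param profile A [protein_profile()].
#' @param antagonist An [antagonist()].
#' @param antagonist_doses Nominal antagonist doses (uM), including 0.
#' @param stress_doses Stress doses eta (uM), including 0.
#' @inheritParams compute_eta
#' @return List of class `pore_synergy_grid` with matrices `pore`,
#'   `fraction_affected` and `ci` (CI is `NA` on zero-dose rows/columns).
#' @export
pore_synergy_grid <- function(profile, antagonist, antagonist_doses,
                              stress_doses, config = momp_config(),
                              model = default_model()) {
  stopifnot(length(antagonist_doses) > 0, length(stress_doses) > 0,
            0 %in% antagonist_doses, 0 %in% stress_doses)
  momp <- model$meta$momp
  dur <- config$production_duration
  pore <- matrix(NA_real_, length(antagonist_doses), length(stress_doses),
                 dimnames = list(antagonist_doses, stress_doses))
  for (i in seq_along(antagonist_doses)) {
    net <- build_momp_network(profile, model,
                              list(list(antagonist = antagonist,
                                        dose = antagonist_doses[i])))
    for (j in seq_along(stress_doses)) {
      pore[i, j] <- peak_pore(net, stress_doses[j] / dur, config, momp)
    }
  }
  pmax_ <- max(pore)
  fa <- if (pmax_ > 0) pore / pmax_ else pore * 0
  fu <- 1 - fa
  ci <- matrix(NA_real_, nrow(fa), ncol(fa), dimnames = dimnames(fa))
  for (i in seq_along(antagonist_doses)[-1]) {
    for (j in seq_along(stress_doses)[-1]) {
      ci[i, j] <- webb_ci(fu[i, 1], fu[1, j], fu[i, j])
    }
  }
  structure(list(pore = pore, fraction_affected = fa, ci = ci,
                 antagonist = antagonist$name, cell_line = profile$cell_line,
                 antagonist_doses = antagonist_doses,
                 stress_doses = stress_doses),
            class = "pore_synergy_grid")
}

#' @export
print.pore_synergy_grid <- function(x, ...) {
  cat("<pore_synergy_grid> ", x$cell_line, " x ", x$antagonist, "\n",
      sep = "")
  cat("peak pore amount (uM), antagonist dose (rows) x stress dose (cols):\n")
  print(round(x$pore, 4))
  invisible(x)
}
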