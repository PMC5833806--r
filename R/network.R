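#' Declare a chemical species
#'
#' Species are the state variables of a mass-action reaction network.
#' Concentrations are in micromolar throughout the package; time is in hours.
#'
#' @param id Short unique identifier (used in reactions and trajectories).
#' @param initial Initial concentration in uM (non-negative, finite).
#' @param name Optional display name; defaults to `id`.
#' @return An object of class `bcl_species`.
#' @export
#' @examples
#' species("BCL2", initial = 0.9)
species <- function(id, initial = 0, name = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(initial) || length(initial) != 1L || !is.finite(initial) ||
      initial < 0) {
    stop("initial concentration of '", id, "' must be finite and >= 0")
  }
  structure(list(id = id, name = name, initial = as.numeric(initial)),
            class = "bcl_species")
}

.reaction_kinds <- c("association", "dissociation", "production",
                     "degradation", "conversion")

#' Declare a mass-action reaction
#'
#' Reactions are elementary mass-action steps of order at most two. A
#' production reaction has no reactants (zeroth order, rate in uM/h); a
#' degradation reaction has no products. Rate constant units follow the
#' reaction order: uM/h (order 0), 1/h (order 1), 1/(uM h) (order 2).
#'
#' @param reactants,products Character vectors of species ids. Repeat an id
#'   for stoichiometry 2 (e.g. `c("BAXa", "BAXa")`), or pass a named numeric
#'   vector of stoichiometries.
#' @param rate Non-negative mass-action rate constant.
#' @param kind One of `"association"`, `"dissociation"`, `"production"`,
#'   `"degradation"`, `"conversion"`.
#' @return An object of class `bcl_reaction`.
#' @export
#' @examples
#' reaction(c("BCL2", "BIM"), "BCL2.BIM", rate = 360, kind = "association")
reaction <- function(reactants, products, rate, kind = "conversion") {
  kind <- match.arg(kind, .reaction_kinds)
  as_stoich <- function(x) {
    if (is.null(x) || length(x) == 0L) return(numeric(0))
    if (is.numeric(x)) {
      if (is.null(names(x)) || any(!nzchar(names(x))))
        stop("numeric stoichiometry must be a named vector")
      return(x)
    }
    tab <- table(x)
    stats::setNames(as.numeric(tab), names(tab))
  }
  re <- as_stoich(reactants)
  pr <- as_stoich(products)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("rate constant must be finite and >= 0")
  if (sum(re) > 2) stop("mass-action order must be <= 2 (got ", sum(re), ")")
  if (kind == "production" && length(re) > 0L)
    stop("production reactions must have no reactants")
  if (kind == "degradation" && length(pr) > 0L)
    stop("degradation reactions must have no products")
  if (kind != "production" && length(re) == 0L)
    stop("only production reactions may have empty reactants")
  structure(list(reactants = re, products = pr, rate = as.numeric(rate),
                 kind = kind),
            class = "bcl_reaction")
}

#' Assemble a reaction network
#'
#' Validates that every reaction references declared species, that species
#' ids are unique, and that declared conservation groups are consistent with
#' the stoichiometry of the network: a group is conserved by construction if
#' the weighted sum of its species is unchanged by every reaction that is not
#' a production or degradation step.
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param conservation Optional named list; each element is a named numeric
#'   vector of per-species weights whose weighted sum should be conserved
#'   absent production and degradation.
#' @param meta Optional metadata list carried along (e.g. MOMP settings).
#' @param name Optional network name.
#' @return An object of class `bcl_network`.
#' @export
reaction_network <- function(species, reactions, conservation = list(),
                             meta = list(), name = "network") {
  ids <- vapply(species, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate species ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (r in reactions) {
    bad <- setdiff(c(names(r$reactants), names(r$products)), ids)
    if (length(bad))
      stop("reaction references undeclared species: ",
           paste(bad, collapse = ", "))
  }
  net <- structure(list(species = species, reactions = reactions,
                        conservation = conservation, meta = meta,
                        name = name),
                   class = "bcl_network")
  # verify conservation groups against the stoichiometry matrix
  if (length(conservation)) {
    N <- stoichiometry(net)
    for (g in names(conservation)) {
      w <- conservation[[g]]
      bad <- setdiff(names(w), ids)
      if (length(bad))
        stop("conservation group '", g, "' references unknown species: ",
             paste(bad, collapse = ", "))
      wv <- stats::setNames(numeric(length(ids)), ids)
      wv[names(w)] <- w
      keep <- vapply(reactions,
                     function(r) !r$kind %in% c("production", "degradation"),
                     logical(1))
      if (any(keep)) {
        drift <- as.vector(wv %*% N[, keep, drop = FALSE])
        if (any(abs(drift) > 1e-12))
          stop("conservation group '", g,
               "' is not conserved by the declared stoichiometry")
      }
    }
  }
  net
}

#' Stoichiometry matrix of a network
#'
#' @param network A [reaction_network()].
#' @return Numeric matrix, species x reactions, of net stoichiometric
#'   coefficients.
#' @export
stoichiometry <- function(network) {
  ids <- species_ids(network)
  nr <- length(network$reactions)
  N <- matrix(0, length(ids), nr, dimnames = list(ids, NULL))
  for (j in seq_len(nr)) {
    r <- network$reactions[[j]]
    for (s in names(r$reactants)) N[s, j] <- N[s, j] - r$reactants[[s]]
    for (s in names(r$products)) N[s, j] <- N[s, j] + r$products[[s]]
  }
  N
}

#' @export
print.bcl_network <- function(x, ...) {
  cat("<bcl_network> ", x$name, "\n", sep = "")
  cat("  species:   ", length(x$species), "\n", sep = "")
  cat("  reactions: ", length(x$reactions), "\n", sep = "")
  kinds <- table(vapply(x$reactions, `[[`, character(1), "kind"))
  cat("  kinds:     ",
      paste(names(kinds), as.integer(kinds), sep = "=", collapse = ", "),
      "\n", sep = "")
  if (length(x$conservation))
    cat("  conservation groups: ",
        paste(names(x$conservation), collapse = ", "), "\n", sep = "")
  invisible(x)
}

species_ids <- function(network) {
  vapply(network$species, function(s) s$id, character(1))
}

initial_state <- function(network) {
  stats::setNames(vapply(network$species, function(s) s$initial, numeric(1)),
                  species_ids(network))
}

#' Modify initial concentrations or rate constants
#'
#' @param network A [reaction_network()].
#' @param initial Named numeric vector of initial concentrations to set.
#' @return The modified network.
#' @export
set_initial <- function(network, initial) {
  ids <- species_ids(network)
  bad <- setdiff(names(initial), ids)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  for (nm in names(initial)) {
    i <- match(nm, ids)
    if (!is.finite(initial[[nm]]) || initial[[nm]] < 0)
      stop("initial concentration of '", nm, "' must be finite and >= 0")
    network$species[[i]]$initial <- as.numeric(initial[[nm]])
  }
  network
}

#' Zero out the rate of all reactions of the given kinds
#'
#' Used e.g. to run a network as a closed system (no production, no
#' degradation) for conservation checks.
#'
#' @param network A [reaction_network()].
#' @param kinds Character vector of reaction kinds to disable.
#' @return The modified network.
#' @export
disable_reactions <- function(network, kinds) {
  kinds <- match.arg(kinds, .reaction_kinds, several.ok = TRUE)
  network$reactions <- lapply(network$reactions, function(r) {
    if (r$kind %in% kinds) r$rate <- 0
    r
  })
  network
}

# Compile the network to index vectors for a fast mass-action RHS.
# Order <= 2: each reaction has up to two reactant slots; a dummy index
# (n_species + 1) multiplies by 1.
compile_network <- function(network) {
  ids <- species_ids(network)
  ns <- length(ids)
  nr <- length(network$reactions)
  i1 <- rep.int(ns + 1L, nr)
  i2 <- rep.int(ns + 1L, nr)
  k <- numeric(nr)
  for (j in seq_len(nr)) {
    r <- network$reactions[[j]]
    k[j] <- r$rate
    slots <- rep(match(names(r$reactants), ids), times = r$reactants)
    if (length(slots) >= 1L) i1[j] <- slots[1L]
    if (length(slots) >= 2L) i2[j] <- slots[2L]
  }
  list(i1 = i1, i2 = i2, k = k, N = stoichiometry(network), ns = ns)
}

#' Constant production input over a time window
#'
#' Describes a step-function inflow: each named species is produced at a
#' constant rate (uM/h) between `start` and `stop`, and not at all outside
#' that window.
#'
#' @param rates Named numeric vector of production rates in uM/h.
#' @param start,stop Window bounds in hours.
#' @return An object of class `production_input`.
#' @export
production_input <- function(rates, start = 0, stop = 12) {
  stopifnot(is.numeric(rates), !is.null(names(rates)), all(nzchar(names(rates))))
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("production rates must be finite and >= 0")
  stopifnot(stop > start, start >= 0)
  structure(list(rates = rates, start = start, stop = stop),
            class = "production_input")
}

#' Simulate a reaction network
#'
#' Integrates the mass-action ODE system with a stiff-capable solver
#' (`deSolve::lsoda`, which switches between Adams and BDF methods). A
#' step-function production input may be supplied; integration is split at
#' the input discontinuities so the solver never steps across them.
#'
#' @param network A [reaction_network()].
#' @param horizon Simulation horizon in hours (> 0).
#' @param inputs Optional [production_input()].
#' @param times Optional explicit output time grid; defaults to 241 points
#'   over `[0, horizon]`.
#' @param atol,rtol Solver tolerances (uM, relative). Defaults 1e-6.
#' @return An object of class `bcl_trajectory`: list with `times`,
#'   `concentrations` (species x time matrix, uM), and `solver_metadata`.
#' @export
#' @examples
#' net <- reaction_network(
#'   list(species("A", 1), species("B", 1), species("AB", 0)),
#'   list(reaction(c("A", "B"), "AB", 360, "association"),
#'        reaction("AB", c("A", "B"), 36, "dissociation")),
#'   conservation = list(A = c(A = 1, AB = 1)))
#' tr <- simulate_network(net, horizon = 1)
simulate_network <- function(network, horizon, inputs = NULL, times = NULL,
                             atol = 1e-6, rtol = 1e-6) {
  stopifnot(inherits(network, "bcl_network"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be a positive duration in hours")
  cmp <- compile_network(network)
  ids <- species_ids(network)
  if (is.null(times)) times <- seq(0, horizon, length.out = 241L)
  times <- sort(unique(c(0, times[times <= horizon + 1e-12], horizon)))

  inflow0 <- stats::setNames(numeric(cmp$ns), ids)
  breaks <- c(0, horizon)
  if (!is.null(inputs)) {
    stopifnot(inherits(inputs, "production_input"))
    bad <- setdiff(names(inputs$rates), ids)
    if (length(bad))
      stop("production input references unknown species: ",
           paste(bad, collapse = ", "))
    breaks <- sort(unique(c(breaks, inputs$start, inputs$stop)))
    breaks <- breaks[breaks >= 0 & breaks <= horizon]
  }

  i1 <- cmp$i1; i2 <- cmp$i2; k <- cmp$k; N <- cmp$N
  make_rhs <- function(inflow) {
    force(inflow)
    function(t, y, p) {
      yy <- c(y, 1)
      list(as.vector(N %*% (k * yy[i1] * yy[i2])) + inflow)
    }
  }

  y <- initial_state(network)
  out_times <- numeric(0)
  out_conc <- NULL
  total_steps <- 0L
  for (seg in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[seg]; t1 <- breaks[seg + 1L]
    inflow <- inflow0
    if (!is.null(inputs) && t0 >= inputs$start - 1e-12 &&
        t1 <= inputs$stop + 1e-12) {
      inflow[names(inputs$rates)] <- inputs$rates
    }
    seg_times <- sort(unique(c(t0, times[times > t0 & times < t1], t1)))
    sol <- tryCatch(
      deSolve::lsoda(y, seg_times, make_rhs(inflow), NULL,
                     atol = atol, rtol = rtol, maxsteps = 50000),
      warning = function(w) {
        stop("ODE solver failed to converge on interval [",
             signif(t0, 4), ", ", signif(t1, 4), "] h: ",
             conditionMessage(w), call. = FALSE)
      })
    diag <- attr(sol, "istate")
    total_steps <- total_steps + if (!is.null(diag)) diag[12L] else NA_integer_
    y <- sol[nrow(sol), -1L]
    keep <- if (seg == 1L) seq_len(nrow(sol)) else -1L
    out_times <- c(out_times, sol[keep, 1L])
    blk <- t(sol[keep, -1L, drop = FALSE])
    out_conc <- if (is.null(out_conc)) blk else cbind(out_conc, blk)
  }
  rownames(out_conc) <- ids

  # negative concentrations only within solver tolerance are clipped
  neg_floor <- -100 * atol
  worst <- min(out_conc)
  if (worst < neg_floor)
    warning("concentrations fell below -100*atol (min = ", signif(worst, 3),
            " uM); consider tightening tolerances")
  out_conc[out_conc < 0] <- 0

  structure(list(times = out_times, concentrations = out_conc,
                 solver_metadata = list(atol = atol, rtol = rtol,
                                        steps = total_steps,
                                        segments = length(breaks) - 1L,
                                        min_concentration = worst)),
            class = "bcl_trajectory")
}

#' @export
print.bcl_trajectory <- function(x, ...) {
  cat("<bcl_trajectory> ", nrow(x$concentrations), " species x ",
      length(x$times), " time points over [",
      signif(min(x$times), 4), ", ", signif(max(x$times), 4), "] h\n",
      sep = "")
  invisible(x)
}

#' Tidy data frame export of a trajectory
#'
#' @param x A `bcl_trajectory`.
#' @param row.names,optional Ignored (S3 signature).
#' @param species Optional subset of species ids.
#' @param ... Ignored.
#' @return Data frame with columns `time`, `species`, `concentration`.
#' @export
as.data.frame.bcl_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, species = NULL,
                                         ...) {
  ids <- rownames(x$concentrations)
  if (!is.null(species)) {
    bad <- setdiff(species, ids)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    ids <- species
  }
  data.frame(
    time = rep(x$times, each = length(ids)),
    species = rep(ids, times = length(x$times)),
    concentration = as.vector(x$concentrations[ids, , drop = FALSE]),
    stringsAsFactors = FALSE)
}

#' @export
plot.bcl_trajectory <- function(x, species = NULL, log = "", ...) {
  ids <- rownames(x$concentrations)
  if (is.null(species)) {
    tot <- apply(x$concentrations, 1, max)
    species <- ids[order(tot, decreasing = TRUE)][seq_len(min(8L, length(ids)))]
  }
  m <- t(x$concentrations[species, , drop = FALSE])
  graphics::matplot(x$times, m, type = "l", lty = 1,
                    xlab = "time (h)", ylab = "concentration (uM)",
                    log = log, ...)
  graphics::legend("topright", legend = species, col = seq_along(species),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Maximum relative conservation drift per group
#'
#' For each conservation group declared in the network, computes the maximum
#' over the trajectory of `|sum(t) - sum(0)| / sum(0)` where `sum` is the
#' group's weighted species total. Groups whose species are touched by an
#' active production or degradation reaction are reported with
#' `conserved_expected = FALSE` rather than treated as an error.
#'
#' @param trajectory A `bcl_trajectory` produced from `network`.
#' @param network The [reaction_network()] declaring conservation groups.
#' @return Data frame with columns `group`, `initial_total`, `max_drift`,
#'   `conserved_expected`.
#' @export
check_conservation <- function(trajectory, network) {
  if (!length(network$conservation))
    stop("network declares no conservation groups")
  ids <- rownames(trajectory$concentrations)
  res <- lapply(names(network$conservation), function(g) {
    w <- network$conservation[[g]]
    wv <- stats::setNames(numeric(length(ids)), ids)
    wv[names(w)] <- w
    tot <- as.vector(wv %*% trajectory$concentrations)
    t0 <- tot[1L]
    drift <- if (t0 > 0) max(abs(tot - t0)) / t0 else ifelse(max(tot) > 0, Inf, 0)
    open <- any(vapply(network$reactions, function(r) {
      r$kind %in% c("production", "degradation") && r$rate > 0 &&
        length(intersect(c(names(r$reactants), names(r$products)),
                         names(w))) > 0
    }, logical(1)))
    data.frame(group = g, initial_total = t0, max_drift = drift,
               conserved_expected = !open, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write a trajectory to tidy CSV
#'
#' @param trajectory A `bcl_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
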