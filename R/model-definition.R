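#' Read a model-definition file
#'
#' Model definitions are JSON documents describing a mass-action network:
#'
#' ```
#' {
#'   "name": "...", "schema_version": 1,
#'   "units": {"concentration": "uM", "time": "h"},
#'   "species": [{"id": "BCL2", "name": "Bcl-2", "initial": 0}, ...],
#'   "reactions": [{"reactants": {"BCL2": 1, "BIM": 1},
#'                  "products": {"BCL2.BIM": 1},
#'                  "rate": 360, "kind": "association"}, ...],
#'   "conservation": {"BAX": {"BAX": 1, "BAXa": 1, ...}, ...},
#'   "momp": {"pore_species": [...], "pore_threshold": 0.05,
#'            "bh3_species": [...], "profile_map": {...},
#'            "antagonist_targets": {...}, "reference_forward_rate": 360}
#' }
#' ```
#'
#' The optional `momp` block designates which species constitute pores,
#' which species receive the BH3-only stress input, how measured protein
#' concentrations map onto species ids, and the generic protein-protein
#' forward rate constant reused for antagonist binding.
#'
#' @param path Path to a JSON model-definition file.
#' @return A [reaction_network()] with the `momp` block in `$meta$momp`.
#' @seealso [default_model()], [write_model_definition()]
#' @export
read_model_definition <- function(path) {
  if (!file.exists(path)) stop("model definition not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("species", "reactions"))
    if (is.null(doc[[field]]) || length(doc[[field]]) == 0L)
      stop("model definition lacks '", field, "'")
  species_list <- lapply(doc$species, function(s) {
    species(s$id,
            initial = if (!is.null(s$initial)) s$initial else 0,
            name = if (!is.null(s$name)) s$name else s$id)
  })
  to_named <- function(x) {
    if (is.null(x) || length(x) == 0L) return(numeric(0))
    stats::setNames(as.numeric(unlist(x)), names(x))
  }
  reaction_list <- lapply(doc$reactions, function(r) {
    reaction(to_named(r$reactants), to_named(r$products),
             rate = r$rate, kind = r$kind)
  })
  conservation <- lapply(doc$conservation, to_named)
  meta <- list()
  if (!is.null(doc$momp)) meta$momp <- doc$momp
  if (!is.null(doc$units)) {
    if (!identical(tolower(doc$units$concentration), "um") ||
        !identical(tolower(doc$units$time), "h"))
      stop("model definition must use uM / h units")
    meta$units <- doc$units
  }
  reaction_network(species_list, reaction_list, conservation = conservation,
                   meta = meta,
                   name = if (!is.null(doc$name)) doc$name else "model")
}

#' Write a network to a model-definition file
#'
#' @param network A [reaction_network()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_definition <- function(network, path) {
  doc <- list(
    name = network$name,
    schema_version = 1L,
    units = list(concentration = "uM", time = "h"),
    species = data.frame(
      id = species_ids(network),
      name = vapply(network$species, `[[`, character(1), "name"),
      initial = vapply(network$species, `[[`, numeric(1), "initial"),
      stringsAsFactors = FALSE),
    reactions = lapply(network$reactions, function(r) {
      list(reactants = as.list(r$reactants), products = as.list(r$products),
           rate = r$rate, kind = r$kind)
    }),
    conservation = lapply(network$conservation, as.list))
  if (!is.null(network$meta$momp)) doc$momp <- network$meta$momp
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' The default BCL-2 interaction network
#'
#' Loads the model-definition file shipped with the package
#' (`bcl2_network_reconstructed.json`), a reconstruction of the published
#' DR_MOMP architecture: BH3-only initiators (BIM, PUMA, NOXA) produced
#' under stress, sequestration of initiators and of active effectors by the
#' anti-apoptotic proteins (BCL2, BCL(X)L, MCL1), direct and
#' auto-catalytic activation of the effectors BAX and BAK, and irreversible
#' assembly of active effectors into mixed pore oligomers. The network
#' comprises 126 reactions over 71 species. Because the original reaction
#' inventory is published only in supplementary material, the shipped file
#' is a reconstruction with literature-style rate constants, not a verbatim
#' transcription; see the package vignette for the construction rules.
#'
#' @return A [reaction_network()].
#' @export
#' @examples
#' net <- default_model()
#' length(net$reactions)
default_model <- function() {
  path <- system.file("extdata", "bcl2_network_reconstructed.json",
                      package = "bcl2dose", mustWork = TRUE)
  read_model_definition(path)
}

#' Construct the default BCL-2 network programmatically
#'
#' This is the generator that produced the shipped model-definition file;
#' it is exported so that variants (different rate constants, restricted
#' binding spectra) can be built without hand-editing JSON.
#'
#' Architecture (all concentrations uM, time h):
#' * BH3-only initiators BIM, PUMA, NOXA; effectors BAX, BAK with active
#'   forms BAXa, BAKa; anti-apoptotic BCL2, BCL(X)L, MCL1.
#' * Reversible sequestration of each BH3-only protein by each
#'   anti-apoptotic protein (selectivity encoded in dissociation constants;
#'   NOXA is effectively MCL1-selective).
#' * Reversible sequestration of BAXa/BAKa by the anti-apoptotic proteins
#'   (Mode-2 inhibition; BCL2 binds BAKa only weakly).
#' * Direct activation: BIM or PUMA binds inactive BAX/BAK reversibly and
#'   converts it to the active form, releasing the activator (catalytic).
#' * Auto-activation: BAXa + BAX -> 2 BAXa (and likewise BAK).
#' * Pore assembly: irreversible monomer addition building mixed BAXa/BAKa
#'   oligomers of sizes 2..8; oligomers of size >= 6 are counted as pores.
#' * Step-function production of the three BH3-only proteins (the stress
#'   input; rate 0 at rest) and first-order turnover of the ten monomeric
#'   species.
#'
#' @param kd Optional named list overriding dissociation constants (uM);
#'   names like `"BCL2.BIM"`. Set a value to `Inf` to remove the pair
#'   (presence/absence of individual binding pairs is configurable).
#' @param k_on Generic protein-protein association rate, 1/(uM h).
#' @param pore_threshold Pore amount (uM) defining MOMP, stored in the
#'   `momp` block.
#' @return A [reaction_network()] with 71 species and 126 reactions (for
#'   the default arguments).
#' @export
bcl2_model <- function(kd = list(), k_on = 360, pore_threshold = 0.05) {
  antis <- c("BCL2", "BCLXL", "MCL1")
  bh3 <- c("BIM", "PUMA", "NOXA")
  effectors <- c(BAX = "BAXa", BAK = "BAKa")

  # dissociation constants, uM
  kd0 <- list(
    BCL2.BIM = 0.005, BCLXL.BIM = 0.008, MCL1.BIM = 0.008,
    BCL2.PUMA = 0.018, BCLXL.PUMA = 0.009, MCL1.PUMA = 0.018,
    BCL2.NOXA = 26, BCLXL.NOXA = 19, MCL1.NOXA = 0.019,
    BCL2.BAXa = 0.02, BCLXL.BAXa = 0.013, MCL1.BAXa = 0.025,
    BCL2.BAKa = 1.0, BCLXL.BAKa = 0.05, MCL1.BAKa = 0.01)
  kd0[names(kd)] <- kd

  k_act_on <- 36      # activator binding to inactive effector, 1/(uM h)
  k_act_off <- 36     # 1/h (transient, KD ~ 1 uM)
  k_act_cat <- 10     # conversion of the activation complex, 1/h
  k_auto <- 3.6       # auto-activation, 1/(uM h)
  k_olig <- 36        # pore assembly monomer addition, 1/(uM h)
  deg <- c(BIM = 0.15, PUMA = 0.15, NOXA = 0.15, BAX = 0.02, BAK = 0.02,
           BAXa = 0.05, BAKa = 0.05, BCL2 = 0.02, BCLXL = 0.02, MCL1 = 0.15)

  sp <- lapply(c(bh3, "BAX", "BAK", "BAXa", "BAKa", antis), species)
  rxn <- list()
  add_sp <- function(id) sp[[length(sp) + 1L]] <<- species(id)
  add_rx <- function(re, pr, k, kind)
    rxn[[length(rxn) + 1L]] <<- reaction(re, pr, k, kind)

  # anti-apoptotic sequestration of BH3-only proteins
  for (a in antis) for (b in bh3) {
    key <- paste0(a, ".", b)
    if (is.infinite(kd0[[key]])) next
    add_sp(key)
    add_rx(c(a, b), key, k_on, "association")
    add_rx(key, c(a, b), kd0[[key]] * k_on, "dissociation")
  }
  # anti-apoptotic sequestration of active effectors
  for (a in antis) for (ea in effectors) {
    key <- paste0(a, ".", ea)
    if (is.infinite(kd0[[key]])) next
    add_sp(key)
    add_rx(c(a, ea), key, k_on, "association")
    add_rx(key, c(a, ea), kd0[[key]] * k_on, "dissociation")
  }
  # direct activation by BIM and PUMA
  for (b in c("BIM", "PUMA")) for (e in names(effectors)) {
    key <- paste0(b, ".", e)
    add_sp(key)
    add_rx(c(b, e), key, k_act_on, "association")
    add_rx(key, c(b, e), k_act_off, "dissociation")
    add_rx(key, c(b, effectors[[e]]), k_act_cat, "conversion")
  }
  # auto-activation
  add_rx(c("BAXa", "BAX"), c("BAXa", "BAXa"), k_auto, "conversion")
  add_rx(c("BAKa", "BAK"), c("BAKa", "BAKa"), k_auto, "conversion")
  # mixed pore oligomers, sizes 2..8, by irreversible monomer addition
  oname <- function(i, j) sprintf("OLG_%dX%dK", i, j)
  for (n in 2:8) for (i in 0:n) add_sp(oname(i, n - i))
  add_rx(c("BAXa", "BAXa"), oname(2, 0), k_olig, "association")
  add_rx(c("BAXa", "BAKa"), oname(1, 1), k_olig, "association")
  add_rx(c("BAKa", "BAKa"), oname(0, 2), k_olig, "association")
  for (n in 3:8) for (i in 0:n) {
    j <- n - i
    if (i >= 1) add_rx(c(oname(i - 1, j), "BAXa"), oname(i, j), k_olig,
                       "association")
    if (j >= 1) add_rx(c(oname(i, j - 1), "BAKa"), oname(i, j), k_olig,
                       "association")
  }
  # stress input: step production of the BH3-only initiators (0 at rest)
  for (b in bh3) add_rx(character(), b, 0, "production")
  # turnover of the monomeric species
  for (m in names(deg)) add_rx(m, character(), deg[[m]], "degradation")

  ids <- vapply(sp, `[[`, character(1), "id")
  olig <- grep("^OLG_", ids, value = TRUE)
  osize <- function(id) {
    m <- regmatches(id, regexec("^OLG_(\\d+)X(\\d+)K$", id))[[1]]
    c(bax = as.integer(m[2]), bak = as.integer(m[3]))
  }
  grp <- function(protein, singles, complex_pattern, olig_part = NULL) {
    w <- stats::setNames(rep(1, length(singles)), singles)
    cx <- grep(complex_pattern, ids, value = TRUE)
    w[cx] <- 1
    if (!is.null(olig_part)) {
      ow <- vapply(olig, function(o) osize(o)[[olig_part]], numeric(1))
      w <- c(w, ow[ow > 0])
    }
    w
  }
  conservation <- list(
    BAX = grp("BAX", c("BAX", "BAXa"), "\\.(BAX|BAXa)$", "bax"),
    BAK = grp("BAK", c("BAK", "BAKa"), "\\.(BAK|BAKa)$", "bak"),
    BIM = grp("BIM", "BIM", "(^BIM\\.)|(\\.BIM$)"),
    PUMA = grp("PUMA", "PUMA", "(^PUMA\\.)|(\\.PUMA$)"),
    NOXA = grp("NOXA", "NOXA", "\\.NOXA$"),
    BCL2 = grp("BCL2", "BCL2", "^BCL2\\."),
    BCLXL = grp("BCLXL", "BCLXL", "^BCLXL\\."),
    MCL1 = grp("MCL1", "MCL1", "^MCL1\\."))

  pore_species <- olig[vapply(olig, function(o) sum(osize(o)) >= 6, TRUE)]
  meta <- list(momp = list(
    pore_species = pore_species,
    pore_threshold = pore_threshold,
    bh3_species = bh3,
    profile_map = list(bcl2 = "BCL2", mcl1 = "MCL1", bak = "BAK",
                       bax = "BAX", bclxl = "BCLXL"),
    antagonist_targets = list(BCL2 = "BCL2", BCLXL = "BCLXL", MCL1 = "MCL1"),
    reference_forward_rate = k_on))
  reaction_network(sp, rxn, conservation = conservation, meta = meta,
                   name = "bcl2_network_reconstructed_v1")
}
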