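#' Densitometric calibration curve for one protein
#'
#' Linear calibration of blot intensity against loaded mass of recombinant
#' protein standard, used to convert band intensities of cell lysates into
#' absolute cellular concentrations via a reference cell volume.
#'
#' @param protein Protein name.
#' @param slope Intensity per ng of loaded protein (> 0).
#' @param intercept Intensity at zero load (default 0).
#' @param molecular_weight Molecular weight in kDa (> 0).
#' @param reference_cell_volume Cell volume in pL used to convert per-cell
#'   amounts to concentrations (default 3.1, a HeLa imaging estimate).
#' @param mass_range Calibrated loading range in ng (used to warn on
#'   extrapolation), default `c(0.1, 10)`.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(protein, slope, intercept = 0,
                              molecular_weight, reference_cell_volume = 3.1,
                              mass_range = c(0.1, 10)) {
  stopifnot(slope > 0, molecular_weight > 0, reference_cell_volume > 0)
  structure(list(protein = protein, slope = slope, intercept = intercept,
                 molecular_weight = molecular_weight,
                 reference_cell_volume = reference_cell_volume,
                 mass_range = mass_range),
            class = "calibration_curve")
}

#' Fit a calibration curve from standards
#'
#' @param protein Protein name.
#' @param standard_mass_ng Loaded masses of the recombinant standard (ng).
#' @param intensity Measured densitometric intensities.
#' @param ... Passed to [calibration_curve()] (e.g. `molecular_weight`).
#' @return A `calibration_curve`.
#' @export
fit_calibration <- function(protein, standard_mass_ng, intensity, ...) {
  fit <- stats::lm(intensity ~ standard_mass_ng)
  cf <- stats::coef(fit)
  calibration_curve(protein, slope = unname(cf[2]),
                    intercept = unname(cf[1]),
                    mass_range = range(standard_mass_ng), ...)
}

#' Cellular concentration from blot intensity
#'
#' Converts a lysate band intensity to an absolute cellular concentration:
#' the calibration curve gives the loaded mass, division by the number of
#' cells loaded gives the per-cell mass, and
#' `concentration = (per-cell mass / molecular weight) / cell volume`
#' with consistent unit conversion to uM. Alternatively a per-cell mass in
#' grams can be supplied directly.
#'
#' @param intensity Densitometric intensity of the lysate band.
#' @param curve A [calibration_curve()].
#' @param cells_per_lane Number of cells loaded in the lane.
#' @param per_cell_mass_g Per-cell protein mass in grams (bypasses
#'   `intensity`/`cells_per_lane`).
#' @return Concentration in uM. Intensities below the blank map to 0 with
#'   a `flag` attribute; loads outside the calibrated range trigger an
#'   extrapolation warning.
#' @export
#' @examples
#' cc <- calibration_curve("BCL2", slope = 1, molecular_weight = 20)
#' lysate_concentration(curve = cc, per_cell_mass_g = 1e-16)  # ~1.61e-3 uM
lysate_concentration <- function(intensity = NULL, curve,
                                 cells_per_lane = NULL,
                                 per_cell_mass_g = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  flag <- NULL
  if (is.null(per_cell_mass_g)) {
    if (is.null(intensity) || is.null(cells_per_lane))
      stop("supply either per_cell_mass_g or intensity + cells_per_lane")
    mass_ng <- (intensity - curve$intercept) / curve$slope
    if (any(mass_ng < 0)) {
      flag <- "below_blank"
      mass_ng <- pmax(mass_ng, 0)
    }
    out_rng <- mass_ng > 0 & (mass_ng < curve$mass_range[1] |
                              mass_ng > curve$mass_range[2])
    if (any(out_rng))
      warning("loaded mass outside the calibrated range; extrapolating")
    per_cell_mass_g <- mass_ng * 1e-9 / cells_per_lane
  }
  mol_per_cell <- per_cell_mass_g / (curve$molecular_weight * 1000)
  molar <- mol_per_cell / (curve$reference_cell_volume * 1e-12)
  conc <- molar * 1e6
  if (!is.null(flag)) attr(conc, "flag") <- flag
  conc
}

#' Pro-apoptotic to anti-apoptotic protein ratio
#'
#' The summed pro-apoptotic effector concentrations (BAK + BAX) divided by
#' the summed anti-apoptotic concentrations (BCL2 + MCL1 + BCL(X)L). Ratios
#' below 1 indicate dominance of the anti-apoptotic proteins.
#'
#' @param profile A [protein_profile()] (or a list of them).
#' @return Numeric ratio(s).
#' @export
#' @examples
#' p <- protein_profile("HCC1143", 0.907, 0.330, 3.173, 0.638, 0.317)
#' pa_aa_ratio(p)  # ~2.452
pa_aa_ratio <- function(profile) {
  if (is.list(profile) && !inherits(profile, "protein_profile"))
    return(vapply(profile, pa_aa_ratio, numeric(1)))
  stopifnot(inherits(profile, "protein_profile"))
  aa <- profile$bcl2 + profile$mcl1 + profile$bclxl
  if (aa <= 0) stop("anti-apoptotic sum is zero; PA/AA ratio undefined")
  (profile$bak + profile$bax) / aa
}

#' Correlation between two measurements
#'
#' Thin wrapper around [stats::cor.test()] reporting the coefficient, its
#' square (the R^2 convention used alongside rank correlations in this
#' field) and the two-sided p-value. Spearman handles ties by average
#' ranks.
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `estimate`, `r_squared`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  est <- unname(ct$estimate)
  list(estimate = est, r_squared = est^2, p_value = ct$p.value,
       method = method, n = length(x))
}

#' Cluster protein profiles
#'
#' Agglomerative clustering with complete linkage, or k-means with multiple
#' restarts, on the raw uM concentration vectors (Euclidean distance; set
#' `standardize = TRUE` to z-score each protein first).
#'
#' @param profiles List of [protein_profile()] objects.
#' @param method `"complete"` (hierarchical, deterministic) or `"kmeans"`.
#' @param k Number of clusters (1 <= k <= number of profiles).
#' @param standardize Z-score columns before clustering (default FALSE,
#'   i.e. absolute concentrations).
#' @param nstart Restarts for k-means (best inertia kept).
#' @param seed RNG seed for k-means (restored on exit).
#' @return List with `labels` (named integer vector) and, for complete
#'   linkage, the `hclust` merge tree as `tree`.
#' @export
cluster_profiles <- function(profiles, method = c("complete", "kmeans"),
                             k, standardize = FALSE, nstart = 25,
                             seed = 1) {
  method <- match.arg(method)
  if (k <= 0 || k != round(k)) stop("k must be a positive integer")
  if (k > length(profiles)) stop("k exceeds the number of profiles")
  m <- do.call(rbind, lapply(profiles, function(p)
    unlist(p[c("bcl2", "mcl1", "bak", "bax", "bclxl")])))
  rownames(m) <- vapply(profiles, `[[`, character(1), "cell_line")
  if (standardize) m <- scale(m)
  if (method == "complete") {
    tree <- stats::hclust(stats::dist(m), method = "complete")
    labels <- stats::cutree(tree, k = k)
    return(list(labels = labels, tree = tree))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = nstart)
  list(labels = stats::setNames(km$cluster, rownames(m)))
}

#' IC50 by variable-slope logistic regression
#'
#' Fits a four-parameter logistic to a viability curve (via [fit_drc()] on
#' the fraction affected) and reports the fitted midpoint dose.
#'
#' @param doses Dose grid (uM), >= 4 levels spanning the transition.
#' @param viability Viability fractions in \[0, 1\].
#' @return List with `ic50` (uM), the fitted `curve`, and `diagnostic`
#'   (`"ok"` or `"unbounded_fit"` when no transition occurs in range).
#' @export
#' @examples
#' d <- c(0, 3, 10, 30, 100, 300)
#' v <- 1 - d^2 / (d^2 + 30^2)
#' fit_ic50(d, v)$ic50  # 30
fit_ic50 <- function(doses, viability) {
  fa <- fraction_affected(viability)
  curve <- fit_drc(doses, fa)
  if (isTRUE(curve$inactive) || curve$type != "logistic4" ||
      (curve$ceiling - curve$floor) < 0.1 ||
      curve$e50 > max(doses) || curve$e50 < min(doses[doses > 0]) / 10) {
    return(list(ic50 = NA_real_, curve = curve,
                diagnostic = "unbounded_fit"))
  }
  list(ic50 = curve$e50, curve = curve, diagnostic = "ok")
}
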