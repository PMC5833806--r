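#' Configuration for the synthetic-data generators
#'
#' The generators emulate the statistical structure of the measured data:
#' per-protein concentration ranges spanning the observed panel (which
#' covers more than three orders of magnitude, hence log-uniform
#' sampling), a monotone link from the stress dose eta to the surviving
#' fraction, and truncated Gaussian measurement noise. Every stochastic
#' generator takes its randomness exclusively from `seed`.
#'
#' @param n_cell_lines Number of synthetic cell lines.
#' @param concentration_ranges Named list of `c(min, max)` uM ranges for
#'   `bcl2`, `mcl1`, `bak`, `bax`, `bclxl`; defaults are the observed
#'   per-protein ranges of the measured TNBC panel.
#' @param survival_link Parameters of the monotone increasing link from
#'   eta to surviving fraction: a scaled logistic in log eta,
#'   `s(eta) = s_min + (s_max - s_min) * plogis(slope * (log(eta) -
#'   log(eta_ref)))`; `eta_ref = NULL` uses the geometric mean of the
#'   supplied etas.
#' @param noise_sd Gaussian noise SD on the surviving fraction (>= 0).
#' @param seed Integer seed; mandatory for any stochastic call.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cell_lines = 8,
                             concentration_ranges = list(
                               bcl2 = c(0.061, 4.581),
                               mcl1 = c(0.001, 0.663),
                               bak = c(0.842, 3.173),
                               bax = c(0.484, 2.284),
                               bclxl = c(0.317, 1.415)),
                             survival_link = list(s_min = 0.05, s_max = 0.95,
                                                  slope = 1.5,
                                                  eta_ref = NULL),
                             noise_sd = 0.05, seed = 1) {
  stopifnot(n_cell_lines >= 0, noise_sd >= 0, is.numeric(seed))
  for (p in names(concentration_ranges)) {
    r <- concentration_ranges[[p]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2])
      stop("concentration range for '", p, "' must be positive and ordered")
  }
  structure(list(n_cell_lines = n_cell_lines,
                 concentration_ranges = concentration_ranges,
                 survival_link = survival_link,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample synthetic protein profiles
#'
#' Log-uniform draws within the configured per-protein ranges; a pure
#' function of the config (bitwise reproducible under a fixed seed).
#'
#' @param config A [synthetic_config()].
#' @return List of [protein_profile()] objects (empty for
#'   `n_cell_lines = 0`).
#' @export
#' @examples
#' sample_profiles(synthetic_config(n_cell_lines = 3, seed = 7))
sample_profiles <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cell_lines
  if (n == 0) return(list())
  rng <- config$concentration_ranges
  with_seed(config$seed, {
    draws <- lapply(rng, function(r)
      exp(stats::runif(n, log(r[1]), log(r[2]))))
    lapply(seq_len(n), function(i)
      protein_profile(sprintf("SYN%02d", i),
                      bcl2 = draws$bcl2[i], mcl1 = draws$mcl1[i],
                      bak = draws$bak[i], bax = draws$bax[i],
                      bclxl = draws$bclxl[i]))
  })
}

eta_survival_link <- function(etas, link) {
  eta_ref <- link$eta_ref
  if (is.null(eta_ref)) eta_ref <- exp(mean(log(etas[etas > 0])))
  link$s_min + (link$s_max - link$s_min) *
    stats::plogis(link$slope * (log(pmax(etas, 1e-12)) - log(eta_ref)))
}

#' Synthetic surviving fractions from stress doses
#'
#' Applies the monotone survival link to the supplied eta values (higher
#' eta = more resistant = higher survival) and adds truncated Gaussian
#' noise, clipping to \[0, 1\].
#'
#' @param etas Stress doses (uM), finite.
#' @param config A [synthetic_config()].
#' @param cell_lines Optional names; default `SYN01`, ...
#' @param treatment,timepoint_h Annotation columns of the output.
#' @return Data frame of survival records: `cell_line`, `treatment`,
#'   `timepoint_h`, `surviving_fraction`.
#' @export
survival_from_eta <- function(etas, config = synthetic_config(),
                              cell_lines = NULL,
                              treatment = "synthetic_stress",
                              timepoint_h = 24) {
  stopifnot(all(is.finite(etas)))
  if (is.null(cell_lines))
    cell_lines <- sprintf("SYN%02d", seq_along(etas))
  s <- eta_survival_link(etas, config$survival_link)
  s_noisy <- with_seed(config$seed,
                       pmin(pmax(s + stats::rnorm(length(s),
                                                  sd = config$noise_sd),
                                 0), 1))
  data.frame(cell_line = cell_lines, treatment = treatment,
             timepoint_h = timepoint_h, surviving_fraction = s_noisy,
             stringsAsFactors = FALSE)
}

#' Synthetic 6x6 dose matrix with known interaction ground truth
#'
#' Builds a fraction-affected grid from two four-parameter logistic
#' single-agent curves under a stated interaction model:
#'
#' * `bliss`: independent action, `fu = fu_a * fu_b` (Webb CI = 1 at every
#'   nonzero pair by construction);
#' * `loewe_additive`: sham combination of one shared curve,
#'   `fa(da, db) = C(da + db)` (Loewe excess 0 by construction);
#' * `synergistic` / `antagonistic`: Bliss with the combination unaffected
#'   fraction raised to `1 + boost` / `1 - boost` on cells where both
#'   doses are positive (so CI < 1 resp. > 1 there, while the single-agent
#'   margins remain exact).
#'
#' @param truth One of `"bliss"`, `"loewe_additive"`, `"synergistic"`,
#'   `"antagonistic"`.
#' @param curve_params List with 4PL parameters for the two agents:
#'   `a = c(floor, ceiling, e50, hill)`, `b = likewise` (for
#'   `loewe_additive` only `a` is used, shared by both margins).
#' @param doses_a,doses_b Dose grids including 0 (default 6-point
#'   log-spaced grids).
#' @param boost Interaction strength for the synergistic/antagonistic
#'   truths (default 0.5).
#' @param noise_sd Gaussian noise SD on fraction affected.
#' @param seed Integer seed.
#' @return A [dose_matrix()].
#' @export
synth_dose_matrix <- function(truth = c("bliss", "loewe_additive",
                                        "synergistic", "antagonistic"),
                              curve_params = list(a = c(0, 1, 3, 1.5),
                                                  b = c(0, 1, 30, 2)),
                              doses_a = c(0, 0.3, 1, 3, 10, 30),
                              doses_b = c(0, 3, 10, 30, 100, 300),
                              boost = 0.5, noise_sd = 0, seed = 1) {
  truth <- match.arg(truth)
  p4 <- function(d, p) {
    ifelse(d > 0, p[1] + (p[2] - p[1]) * d^p[4] / (d^p[4] + p[3]^p[4]), p[1])
  }
  pa <- curve_params$a
  pb <- if (truth == "loewe_additive") curve_params$a else curve_params$b
  fa_a <- p4(doses_a, pa)
  fa_b <- p4(doses_b, pb)
  n_a <- length(doses_a); n_b <- length(doses_b)
  fa <- matrix(NA_real_, n_a, n_b)
  for (i in seq_len(n_a)) for (j in seq_len(n_b)) {
    if (truth == "loewe_additive") {
      fa[i, j] <- p4(doses_a[i] + doses_b[j], pa)
    } else {
      fu <- (1 - fa_a[i]) * (1 - fa_b[j])
      expo <- 1
      if (doses_a[i] > 0 && doses_b[j] > 0) {
        if (truth == "synergistic") expo <- 1 + boost
        if (truth == "antagonistic") expo <- 1 - boost
      }
      fa[i, j] <- 1 - fu^expo
    }
  }
  if (noise_sd > 0) {
    fa <- with_seed(seed, pmin(pmax(fa + stats::rnorm(length(fa),
                                                      sd = noise_sd), 0), 1))
  }
  dose_matrix(doses_a, doses_b, fa, drug_a = "synthetic A",
              drug_b = "synthetic B")
}
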