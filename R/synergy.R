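#' Fraction affected from viability
#'
#' @param viability_fraction Numeric vector of viability fractions in
#'   \[0, 1\]. Values marginally outside are clamped with a warning; `NaN`
#'   propagates as a missing cell.
#' @return `1 - viability`, in \[0, 1\].
#' @export
#' @examples
#' fraction_affected(c(1, 0.65, 0))
fraction_affected <- function(viability_fraction) {
  v <- viability_fraction
  out_of_range <- !is.na(v) & (v < 0 | v > 1)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " viability value(s) outside [0, 1] clamped")
    v <- pmin(pmax(v, 0), 1)
  }
  1 - v
}

#' Webb fractional-product combination index
#'
#' Under Bliss-type independence the expected unaffected fraction of a
#' combination is the product of the single-agent unaffected fractions;
#' the combination index is the observed over the expected:
#' `CI = fu_combo / (fu_a * fu_b)`. CI < 1 indicates synergy, CI = 1
#' additivity, CI > 1 antagonism.
#'
#' @param fu_a,fu_b Single-agent unaffected (viable) fractions in (0, 1\].
#' @param fu_combo Observed combination unaffected fraction.
#' @return CI values; `NA` where `fu_a * fu_b == 0` (undefined).
#' @export
#' @examples
#' webb_ci(0.8, 0.5, 0.4)  # exactly the fractional product: CI = 1
#' webb_ci(0.8, 0.5, 0.2)  # CI = 0.5, synergy
webb_ci <- function(fu_a, fu_b, fu_combo) {
  expected <- fu_a * fu_b
  ci <- ifelse(!is.na(expected) & expected > 0, fu_combo / expected,
               NA_real_)
  ci
}

#' Classify combination-index values
#'
#' Thresholds: CI < 0.3 strong synergy; 0.3 <= CI < 1 synergy; CI = 1
#' additive; CI > 1 antagonistic.
#'
#' @param ci Numeric CI values.
#' @return Factor with levels `strong synergy`, `synergy`, `additive`,
#'   `antagonistic`.
#' @export
classify_ci <- function(ci) {
  lab <- ifelse(is.na(ci), NA_character_,
         ifelse(ci < 0.3, "strong synergy",
         ifelse(ci < 1, "synergy",
         ifelse(ci > 1, "antagonistic", "additive"))))
  factor(lab, levels = c("strong synergy", "synergy", "additive",
                         "antagonistic"))
}

#' Dose-matrix container
#'
#' A rectangular fraction-affected grid for two drugs, rows indexed by
#' doses of drug A and columns by doses of drug B; both grids must be
#' strictly increasing and include 0, so the first row and column carry the
#' single-agent data and entry (0, 0) the baseline.
#'
#' @param doses_a,doses_b Ascending dose grids (uM), each including 0.
#' @param fraction_affected Matrix in \[0, 1\], `length(doses_a)` x
#'   `length(doses_b)`. Values marginally outside \[0, 1\] are clamped with
#'   a warning.
#' @param drug_a,drug_b Drug names.
#' @return An object of class `dose_matrix`.
#' @export
dose_matrix <- function(doses_a, doses_b, fraction_affected,
                        drug_a = "drug A", drug_b = "drug B") {
  if (any(diff(doses_a) <= 0) || any(diff(doses_b) <= 0))
    stop("dose grids must be strictly increasing")
  if (doses_a[1] != 0 || doses_b[1] != 0)
    stop("dose grids must include 0 as their first element")
  fa <- as.matrix(fraction_affected)
  if (nrow(fa) != length(doses_a) || ncol(fa) != length(doses_b))
    stop("fraction_affected must be length(doses_a) x length(doses_b)")
  bad <- !is.na(fa) & (fa < 0 | fa > 1)
  if (any(bad)) {
    warning(sum(bad), " fraction-affected value(s) outside [0, 1] clamped")
    fa <- pmin(pmax(fa, 0), 1)
  }
  dimnames(fa) <- list(doses_a, doses_b)
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 doses_a = doses_a, doses_b = doses_b,
                 fraction_affected = fa),
            class = "dose_matrix")
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat("<dose_matrix> ", x$drug_a, " x ", x$drug_b, " (",
      length(x$doses_a), " x ", length(x$doses_b), ")\n", sep = "")
  print(round(x$fraction_affected, 3))
  invisible(x)
}

#' Fit a single-agent dose-response curve
#'
#' Fits a variable-slope four-parameter logistic
#' `fa(d) = floor + (ceiling - floor) * d^h / (d^h + e50^h)` by
#' Levenberg-Marquardt least squares. If the data are non-monotone beyond
#' tolerance or the fit fails, falls back to isotonic regression followed
#' by monotone interpolation, with a warning.
#'
#' @param doses Dose grid (>= 4 levels recommended; zero dose allowed).
#' @param fa Fraction affected at each dose.
#' @param monotone_tol Tolerated total decrease between consecutive doses
#'   before the isotonic fallback is used (default 0.15).
#' @return An object of class `drc` with `coef()`, `predict()` and
#'   [inverse_dose()] support. Inactive agents (no effect range) are
#'   flagged via `$inactive`.
#' @export
#' @examples
#' d <- c(0, 1, 3, 10, 30, 100)
#' fa <- d^2 / (d^2 + 30^2)
#' fit <- fit_drc(d, fa)
#' coef(fit)["e50"]
fit_drc <- function(doses, fa, monotone_tol = 0.15) {
  stopifnot(length(doses) == length(fa), length(doses) >= 2)
  ok <- !is.na(fa)
  doses <- doses[ok]; fa <- fa[ok]
  o <- order(doses); doses <- doses[o]; fa <- fa[o]

  rng <- range(fa)
  if (diff(rng) < 1e-9) {
    return(structure(list(type = "inactive", floor = rng[1], ceiling = rng[2],
                          doses = doses, fa = fa, inactive = TRUE),
                     class = "drc"))
  }

  decrease <- sum(pmax(0, -diff(fa)))
  fit <- NULL
  if (decrease <= monotone_tol) {
    start <- list(fl = max(min(fa), 0),
                  ce = min(max(fa), 1),
                  le50 = log(stats::approx(
                    x = fa + seq_along(fa) * 1e-12, y = pmax(doses, min(doses[doses > 0]) / 10),
                    xout = mean(rng))$y),
                  h = 1.5)
    if (!is.finite(start$le50)) start$le50 <- log(stats::median(doses[doses > 0]))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fa ~ fl + (ce - fl) * ifelse(doses > 0,
                                     doses^h / (doses^h + exp(le50 * h)), 0),
        start = start,
        lower = c(fl = 0, ce = 0, le50 = log(min(doses[doses > 0]) / 100),
                  h = 0.1),
        upper = c(fl = 1, ce = 1, le50 = log(max(doses) * 100), h = 10),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(structure(list(type = "logistic4",
                          floor = unname(cf["fl"]), ceiling = unname(cf["ce"]),
                          e50 = unname(exp(cf["le50"])), hill = unname(cf["h"]),
                          doses = doses, fa = fa, inactive = FALSE),
                     class = "drc"))
  }
  warning("dose-response data non-monotone or logistic fit failed; ",
          "falling back to isotonic interpolation")
  iso <- stats::isoreg(doses, fa)  # doses already sorted ascending
  yf <- iso$yf
  structure(list(type = "isotonic", floor = min(yf), ceiling = max(yf),
                 doses = doses, fa = yf, inactive = diff(range(yf)) < 1e-9),
            class = "drc")
}

#' @export
coef.drc <- function(object, ...) {
  if (object$type == "logistic4")
    c(floor = object$floor, ceiling = object$ceiling, e50 = object$e50,
      hill = object$hill)
  else c(floor = object$floor, ceiling = object$ceiling)
}

#' @export
print.drc <- function(x, ...) {
  cat("<drc> ", x$type, if (isTRUE(x$inactive)) " (inactive agent)", "\n",
      sep = "")
  print(round(coef(x), 5))
  invisible(x)
}

#' @export
predict.drc <- function(object, doses, ...) {
  d <- doses
  switch(object$type,
    logistic4 = {
      fl <- object$floor; ce <- object$ceiling
      h <- object$hill; e50 <- object$e50
      ifelse(d > 0, fl + (ce - fl) * d^h / (d^h + e50^h), fl)
    },
    isotonic = stats::approx(object$doses, object$fa, xout = d, rule = 2)$y,
    inactive = rep(object$floor, length(d)))
}

#' Inverse dose-response: dose achieving a given effect
#'
#' @param curve A `drc` from [fit_drc()].
#' @param fa Target fraction affected.
#' @return Dose in uM; `NA` outside the achieved effect range (with the
#'   curve flagged inactive the inverse is undefined everywhere).
#' @export
inverse_dose <- function(curve, fa) {
  if (isTRUE(curve$inactive)) return(rep(NA_real_, length(fa)))
  switch(curve$type,
    logistic4 = {
      fl <- curve$floor; ce <- curve$ceiling
      ifelse(fa <= fl | fa >= ce, NA_real_,
             curve$e50 * ((fa - fl) / (ce - fa))^(1 / curve$hill))
    },
    isotonic = {
      vapply(fa, function(f) {
        if (f < min(curve$fa) || f > max(curve$fa)) return(NA_real_)
        stats::approx(curve$fa + cumsum(rep(1e-12, length(curve$fa))),
                      curve$doses, xout = f, rule = 2)$y
      }, numeric(1))
    })
}

#' Loewe-additive predicted effect of a dose pair
#'
#' Solves the Loewe additivity equation
#' `dose_a / D_A(fa) + dose_b / D_B(fa) = 1` for the predicted fraction
#' affected by bracketed root finding, where `D_A`, `D_B` are the inverse
#' single-agent curves. When the equation has no solution within the
#' jointly achievable effect range the range boundary is returned with a
#' saturation flag.
#'
#' @param dose_a,dose_b Doses (uM).
#' @param curve_a,curve_b `drc` objects from [fit_drc()].
#' @return List with `fa` (predicted fraction affected) and `saturated`.
#' @export
loewe_prediction <- function(dose_a, dose_b, curve_a, curve_b) {
  if (dose_a == 0 && dose_b == 0)
    return(list(fa = max(curve_a$floor, curve_b$floor), saturated = FALSE))
  if (isTRUE(curve_a$inactive) && dose_b == 0)
    return(list(fa = curve_a$floor, saturated = FALSE))
  if (isTRUE(curve_b$inactive) && dose_a == 0)
    return(list(fa = curve_b$floor, saturated = FALSE))
  # single-agent marginals and inactive partners reduce to one curve
  if (dose_b == 0 || isTRUE(curve_b$inactive))
    return(list(fa = predict(curve_a, dose_a), saturated = FALSE))
  if (dose_a == 0 || isTRUE(curve_a$inactive))
    return(list(fa = predict(curve_b, dose_b), saturated = FALSE))

  lo <- max(curve_a$floor, curve_b$floor)
  hi <- min(curve_a$ceiling, curve_b$ceiling)
  eps <- 1e-9 * max(1, hi - lo)
  g <- function(f) {
    da <- inverse_dose(curve_a, f); db <- inverse_dose(curve_b, f)
    dose_a / da + dose_b / db - 1
  }
  f_lo <- lo + 1e-7 * (hi - lo)
  f_hi <- hi - 1e-7 * (hi - lo)
  if (f_hi <= f_lo) return(list(fa = hi, saturated = TRUE))
  g_hi <- g(f_hi)
  if (!is.finite(g_hi) || g_hi > 0)
    return(list(fa = hi, saturated = TRUE))  # effect saturates
  g_lo <- g(f_lo)
  if (!is.finite(g_lo) || g_lo < 0)
    return(list(fa = lo, saturated = TRUE))
  root <- stats::uniroot(g, c(f_lo, f_hi), tol = 1e-10)
  list(fa = root$root, saturated = FALSE)
}

#' Loewe excess and Webb CI over a dose matrix
#'
#' Fits single-agent curves from the zero-dose row and column, predicts
#' each combination cell under Loewe additivity and reports the excess
#' (observed minus predicted; positive = synergy). Single-agent cells have
#' excess 0 by construction. Also computes the Webb fractional-product CI
#' and its classification for every nonzero dose pair, plus their mean and
#' SD (the aggregation over the matrix is a summary convention of this
#' package).
#'
#' @param matrix A [dose_matrix()].
#' @return An object of class `synergy_result` with matrices
#'   `loewe_excess`, `ci`, factor matrix `labels`, fitted `curve_a`,
#'   `curve_b`, logical matrix `saturated`, and `ci_summary`.
#' @export
loewe_excess_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "dose_matrix"))
  fa <- matrix$fraction_affected
  da <- matrix$doses_a; db <- matrix$doses_b
  curve_a <- fit_drc(da, fa[, 1])
  curve_b <- fit_drc(db, fa[1, ])
  if (isTRUE(curve_a$inactive) || isTRUE(curve_b$inactive))
    warning("inactive single agent: Loewe prediction reduces to the ",
            "other agent's marginal for affected cells")
  excess <- fa * 0
  saturated <- fa == Inf  # all-FALSE logical with dims
  for (i in seq_along(da)[-1]) {
    for (j in seq_along(db)[-1]) {
      pred <- loewe_prediction(da[i], db[j], curve_a, curve_b)
      excess[i, j] <- fa[i, j] - pred$fa
      saturated[i, j] <- pred$saturated
    }
  }
  fu <- 1 - fa
  ci <- fa * NA_real_
  for (i in seq_along(da)[-1]) for (j in seq_along(db)[-1])
    ci[i, j] <- webb_ci(fu[i, 1], fu[1, j], fu[i, j])
  ci_vals <- ci[!is.na(ci)]
  structure(list(loewe_excess = excess, ci = ci,
                 labels = array(classify_ci(ci), dim = dim(ci),
                                dimnames = dimnames(ci)),
                 saturated = saturated,
                 curve_a = curve_a, curve_b = curve_b,
                 ci_summary = c(mean = mean(ci_vals), sd = stats::sd(ci_vals),
                                n = length(ci_vals)),
                 drug_a = matrix$drug_a, drug_b = matrix$drug_b),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("<synergy_result> ", x$drug_a, " x ", x$drug_b, "\n", sep = "")
  cat("Loewe excess (positive = synergy):\n")
  print(round(x$loewe_excess, 3))
  cat("Webb CI over nonzero dose pairs: mean ",
      signif(x$ci_summary["mean"], 3), " +/- ",
      signif(x$ci_summary["sd"], 3), " (n = ",
      as.integer(x$ci_summary["n"]), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.synergy_result <- function(x, what = c("loewe_excess", "ci"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  xlab = x$drug_a, ylab = x$drug_b, axes = FALSE,
                  main = what, ...)
  graphics::axis(1, seq_len(nrow(m)), rownames(m))
  graphics::axis(2, seq_len(ncol(m)), colnames(m))
  invisible(x)
}

#' Iso-effect contour (isobologram)
#'
#' Interpolates the dose pairs achieving a given effect level from the
#' matrix and returns them together with the straight additivity segment
#' joining the single-agent iso-effect doses; contour points below that
#' line indicate synergy.
#'
#' @param matrix A [dose_matrix()].
#' @param effect_level Fraction affected defining the contour (default
#'   0.5). `effect_level = 0` yields the degenerate contour at the origin,
#'   flagged.
#' @return An object of class `isobologram` with `points` (data frame of
#'   `dose_a`, `dose_b`), `line` (the additivity endpoints), and
#'   `degenerate`. If the effect level is never reached, `points` is empty
#'   and a diagnostic message is attached.
#' @export
isobologram <- function(matrix, effect_level = 0.5) {
  stopifnot(inherits(matrix, "dose_matrix"))
  fa <- matrix$fraction_affected
  da <- matrix$doses_a; db <- matrix$doses_b
  if (effect_level == 0) {
    return(structure(list(points = data.frame(dose_a = 0, dose_b = 0),
                          line = data.frame(dose_a = c(0, 0),
                                            dose_b = c(0, 0)),
                          effect_level = 0, degenerate = TRUE,
                          diagnostic = "degenerate contour at zero effect"),
                     class = "isobologram"))
  }
  if (max(fa, na.rm = TRUE) < effect_level) {
    return(structure(list(points = data.frame(dose_a = numeric(0),
                                              dose_b = numeric(0)),
                          line = NULL, effect_level = effect_level,
                          degenerate = FALSE,
                          diagnostic = paste0("effect level ", effect_level,
                                              " not attained in the matrix")),
                     class = "isobologram"))
  }
  cross <- function(doses, vals) {
    # first monotone-interpolated crossing of effect_level along a margin
    if (max(vals, na.rm = TRUE) < effect_level) return(NA_real_)
    for (k in seq_len(length(vals) - 1L)) {
      v1 <- vals[k]; v2 <- vals[k + 1L]
      if (is.na(v1) || is.na(v2)) next
      if ((v1 < effect_level && v2 >= effect_level)) {
        return(doses[k] + (effect_level - v1) / (v2 - v1) *
                 (doses[k + 1L] - doses[k]))
      }
      if (v1 >= effect_level) return(doses[k])
    }
    NA_real_
  }
  pts <- lapply(seq_along(da), function(i) {
    b <- cross(db, fa[i, ])
    if (is.na(b)) NULL else data.frame(dose_a = da[i], dose_b = b)
  })
  points <- do.call(rbind, pts)
  a50 <- cross(da, fa[, 1])
  b50 <- cross(db, fa[1, ])
  line <- if (!is.na(a50) && !is.na(b50))
    data.frame(dose_a = c(a50, 0), dose_b = c(0, b50)) else NULL
  structure(list(points = points, line = line, effect_level = effect_level,
                 degenerate = FALSE, diagnostic = NULL,
                 drug_a = matrix$drug_a, drug_b = matrix$drug_b),
            class = "isobologram")
}

#' @export
print.isobologram <- function(x, ...) {
  cat("<isobologram> effect level ", x$effect_level, "\n", sep = "")
  if (!is.null(x$diagnostic)) cat("  ", x$diagnostic, "\n", sep = "")
  if (!is.null(x$points) && nrow(x$points)) print(round(x$points, 4))
  invisible(x)
}

#' @export
plot.isobologram <- function(x, ...) {
  if (is.null(x$points) || !nrow(x$points)) {
    stop("empty isobologram: ", x$diagnostic)
  }
  rng_a <- range(c(x$points$dose_a, x$line$dose_a))
  rng_b <- range(c(x$points$dose_b, x$line$dose_b))
  graphics::plot(x$points$dose_a, x$points$dose_b, pch = 16,
                 xlim = rng_a, ylim = rng_b,
                 xlab = paste(x$drug_a, "(uM)"),
                 ylab = paste(x$drug_b, "(uM)"), ...)
  if (!is.null(x$line))
    graphics::lines(x$line$dose_a, x$line$dose_b, lty = 2)
  invisible(x)
}
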