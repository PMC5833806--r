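norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

.profile_cols <- c(cellline = "cell_line", bcl2 = "bcl2", mcl1 = "mcl1",
                   bak = "bak", bax = "bax", bclxl = "bclxl")

#' Read protein profiles from CSV
#'
#' Expects columns `cell_line, BCL2, MCL1, BAK, BAX, BCL(X)L` (header
#' matching is case-insensitive and ignores punctuation, so `BCL(X)L`,
#' `BCLXL` and `bclxl` are equivalent; column order is irrelevant).
#' Concentrations are in uM.
#'
#' @param path CSV path.
#' @return List of [protein_profile()] objects.
#' @export
#' @examples
#' path <- system.file("extdata", "tnbc_panel_profiles.csv",
#'                     package = "bcl2dose")
#' profiles <- read_profiles(path)
#' length(profiles)
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("empty profile file: ", path)
  names(df) <- norm_header(names(df))
  miss <- setdiff(names(.profile_cols), names(df))
  if (length(miss))
    stop("profile file lacks column(s): ",
         paste(.profile_cols[miss], collapse = ", "))
  if (anyDuplicated(df$cellline)) {
    dup <- unique(df$cellline[duplicated(df$cellline)])
    stop("duplicate cell line(s): ", paste(dup, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    vals <- vapply(c("bcl2", "mcl1", "bak", "bax", "bclxl"),
                   function(cn) as.numeric(df[[cn]][i]), numeric(1))
    if (any(!is.finite(vals)) || any(vals < 0))
      stop("row ", i, " (", df$cellline[i],
           "): concentrations must be finite and >= 0")
    protein_profile(df$cellline[i], vals[["bcl2"]], vals[["mcl1"]],
                    vals[["bak"]], vals[["bax"]], vals[["bclxl"]])
  })
}

#' Write protein profiles to CSV
#'
#' @param profiles List of [protein_profile()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(cell_line = p$cell_line, BCL2 = p$bcl2, MCL1 = p$mcl1,
               BAK = p$bak, BAX = p$bax, `BCL(X)L` = p$bclxl,
               check.names = FALSE, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' The measured TNBC panel profiles shipped with the package
#'
#' Absolute concentrations (uM) of BCL2, MCL1, BAK, BAX and BCL(X)L for
#' the eight-line triple negative breast cancer panel, as determined by
#' quantitative immunoblot calibration.
#'
#' @return List of 8 [protein_profile()] objects.
#' @export
tnbc_panel <- function() {
  read_profiles(system.file("extdata", "tnbc_panel_profiles.csv",
                            package = "bcl2dose", mustWork = TRUE))
}

#' Read a dose-matrix CSV
#'
#' Layout: header row holds the doses of drug B, the first column the doses
#' of drug A, and cells the viability fraction (converted to fraction
#' affected on read).
#'
#' @param path CSV path.
#' @param drug_a,drug_b Drug names for labelling.
#' @param values Either `"viability"` (default; converted via
#'   [fraction_affected()]) or `"fraction_affected"`.
#' @return A [dose_matrix()].
#' @export
read_dose_matrix <- function(path, drug_a = "drug A", drug_b = "drug B",
                             values = c("viability", "fraction_affected")) {
  values <- match.arg(values)
  if (!file.exists(path)) stop("dose matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  doses_a <- as.numeric(df[[1]])
  doses_b <- as.numeric(names(df)[-1])
  if (any(is.na(doses_b)))
    stop("dose matrix header must hold numeric doses of drug B")
  m <- as.matrix(df[, -1, drop = FALSE])
  fa <- if (values == "viability") fraction_affected(m) else m
  dose_matrix(doses_a, doses_b, fa, drug_a = drug_a, drug_b = drug_b)
}

#' Write a dose matrix to CSV
#'
#' @param matrix A [dose_matrix()].
#' @param path Output CSV path.
#' @param values Write `"fraction_affected"` (default) or `"viability"`.
#' @return `path`, invisibly.
#' @export
write_dose_matrix <- function(matrix, path,
                              values = c("fraction_affected", "viability")) {
  values <- match.arg(values)
  m <- matrix$fraction_affected
  if (values == "viability") m <- 1 - m
  df <- data.frame(dose_a = matrix$doses_a, m, check.names = FALSE)
  names(df) <- c("dose_a", matrix$doses_b)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read antagonist descriptors from JSON
#'
#' Expects a JSON array of objects with fields `name`, `target`, `kd_nM`
#' and optional `bioavailability_factor`.
#'
#' @param path JSON path.
#' @return Named list of [antagonist()] objects (lower-cased, punctuation
#'   stripped names).
#' @export
read_antagonists <- function(path) {
  if (!file.exists(path)) stop("antagonist config not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- lapply(doc, function(e) {
    antagonist(e$name, e$target, e$kd_nM,
               if (!is.null(e$bioavailability_factor))
                 e$bioavailability_factor else 0.5)
  })
  names(out) <- vapply(out, function(a)
    gsub("[^a-z0-9]", "", tolower(a$name)), character(1))
  out
}

#' Pipeline run configuration
#'
#' @param profiles_path Path to the profile CSV (default: shipped panel).
#' @param model_path Path to the model-definition JSON (default: shipped
#'   reconstruction).
#' @param antagonists_path Optional antagonist JSON (default: shipped
#'   defaults).
#' @param scan_doses Antagonist dose grid (uM) for eta dose scans; `NULL`
#'   skips the scan stage.
#' @param scan_cell_lines Cell lines to scan (default: all).
#' @param dose_matrix_paths Named list of dose-matrix CSVs for synergy
#'   analysis; `NULL` skips the stage.
#' @param survival_path Optional survival CSV (`cell_line, treatment,
#'   timepoint_h, surviving_fraction`) for the correlation stage.
#' @param out_dir Output directory; `NULL` for no files.
#' @param config A [momp_config()].
#' @param seed Integer seed governing any stochastic stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(profiles_path = NULL, model_path = NULL,
                       antagonists_path = NULL, scan_doses = NULL,
                       scan_cell_lines = NULL, dose_matrix_paths = NULL,
                       survival_path = NULL, out_dir = NULL,
                       config = momp_config(), seed = 1) {
  paths <- c(profiles_path, model_path, antagonists_path, survival_path,
             unlist(dose_matrix_paths))
  for (p in paths) if (!is.null(p) && !file.exists(p))
    stop("referenced file does not exist: ", p)
  structure(list(profiles_path = profiles_path, model_path = model_path,
                 antagonists_path = antagonists_path,
                 scan_doses = scan_doses, scan_cell_lines = scan_cell_lines,
                 dose_matrix_paths = dose_matrix_paths,
                 survival_path = survival_path, out_dir = out_dir,
                 config = config, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) read profiles; (2) stress-dose table; (3) antagonist eta
#' dose scans; (4) dose-matrix synergy analysis; (5) profile statistics
#' (PA/AA ratios, clustering, and correlation of eta against survival when
#' survival data are supplied). Stage failures are isolated: a failing
#' stage is recorded in `$errors` and stages depending on its output are
#' skipped, while independent stages still run. Outputs are deterministic
#' given the configuration and seed; when `out_dir` is set, result CSVs
#' and a provenance JSON (configuration, package version, seed) are
#' written there.
#'
#' @param rc A [run_config()].
#' @return List of class `pipeline_result` with elements `eta`,
#'   `scans`, `synergy`, `stats`, `errors`, `provenance`.
#' @export
run_pipeline <- function(rc = run_config()) {
  stopifnot(inherits(rc, "run_config"))
  errors <- list()
  res <- list()
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  profiles <- try_stage("profiles", {
    if (is.null(rc$profiles_path)) tnbc_panel()
    else read_profiles(rc$profiles_path)
  })
  model <- try_stage("model", {
    if (is.null(rc$model_path)) default_model()
    else read_model_definition(rc$model_path)
  })

  res$eta <- if (!is.null(profiles) && !is.null(model))
    try_stage("eta", eta_table(profiles, rc$config, model = model)) else NULL

  res$scans <- NULL
  if (!is.null(rc$scan_doses) && !is.null(profiles) && !is.null(model)) {
    antagonists <- try_stage("antagonists", {
      if (is.null(rc$antagonists_path)) default_antagonists()
      else read_antagonists(rc$antagonists_path)
    })
    if (!is.null(antagonists)) {
      lines <- if (is.null(rc$scan_cell_lines))
        vapply(profiles, `[[`, character(1), "cell_line")
      else rc$scan_cell_lines
      sel <- profiles[vapply(profiles, function(p)
        p$cell_line %in% lines, logical(1))]
      res$scans <- try_stage("scans", {
        out <- list()
        for (p in sel) for (a in antagonists) {
          curve <- eta_dose_curve(p, a, rc$scan_doses, rc$config, model)
          curve$cell_line <- p$cell_line
          curve$antagonist <- a$name
          out[[length(out) + 1L]] <- as.data.frame(curve)
        }
        do.call(rbind, out)
      })
    }
  }

  res$synergy <- NULL
  if (!is.null(rc$dose_matrix_paths)) {
    res$synergy <- try_stage("synergy", {
      lapply(rc$dose_matrix_paths, function(p)
        loewe_excess_matrix(read_dose_matrix(p)))
    })
  }

  res$stats <- if (!is.null(profiles)) try_stage("stats", {
    out <- list(pa_aa = stats::setNames(pa_aa_ratio(profiles),
                                        vapply(profiles, `[[`, character(1),
                                               "cell_line")))
    if (length(profiles) >= 3)
      out$clusters <- cluster_profiles(profiles, "complete",
                                       k = min(3, length(profiles)))$labels
    if (!is.null(rc$survival_path) && !is.null(res$eta)) {
      surv <- utils::read.csv(rc$survival_path, stringsAsFactors = FALSE)
      m <- merge(res$eta, surv, by = "cell_line")
      if (nrow(m) >= 3)
        out$eta_survival <- correlate(m$eta, m$surviving_fraction,
                                      "spearman")
    }
    out
  }) else NULL

  provenance <- list(package = "bcl2dose",
                     version = as.character(utils::packageVersion("bcl2dose")),
                     seed = rc$seed,
                     timestamp = format(Sys.time(), tz = "UTC"),
                     config = unclass(rc$config))

  if (!is.null(rc$out_dir)) {
    dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$eta))
      utils::write.csv(res$eta, file.path(rc$out_dir, "eta_table.csv"),
                       row.names = FALSE)
    if (!is.null(res$scans))
      utils::write.csv(res$scans, file.path(rc$out_dir, "eta_scans.csv"),
                       row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(rc$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  structure(c(res, list(errors = errors, provenance = provenance)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$eta)) {
    cat("stress-dose table:\n")
    print(x$eta)
  }
  if (length(x$errors)) {
    cat("stage errors:\n")
    for (n in names(x$errors)) cat("  ", n, ": ", x$errors[[n]], "\n",
                                   sep = "")
  }
  invisible(x)
}
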