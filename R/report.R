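#' Write a per-residue profile as a tab-separated table
#'
#' Serializes the per-window table of an [es_profile()] or the per-residue
#' table of a [fod_analysis()] result as UTF-8 TSV with a header row — the
#' plot-ready form of the per-residue accordance profiles.
#'
#' @param result An `es_profile` or `fod_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(result, path) {
  UseMethod("write_profile")
}

#' @export
write_profile.es_profile <- function(result, path) {
  utils::write.table(result$windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
write_profile.fod_result <- function(result, path) {
  utils::write.table(result$residues, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Combined early-stage / late-stage analysis of one chain
#'
#' Runs both stages on a single chain with shared parsing and returns the
#' combined report: D_average from the ES geometry, O/T and O/R from the
#' fuzzy-oil-drop analysis, and the two verdicts (ES accordance:
#' D_average < 1; LS accordance: O/T < O/R). Optionally writes
#' `es_profile.tsv`, `fod_profile.tsv`, `summary.txt` and B-factor-colored
#' PDBs to an output directory. If one stage fails its error is recorded and
#' the other stage's results are still returned.
#'
#' @param path PDB file path.
#' @param chain Chain identifier (`NULL` = first chain).
#' @param cal An [es_calibration()]; `NULL` uses the package's cached
#'   analytic calibration ([default_calibration()]).
#' @param scale A [hydrophobicity_scale()].
#' @param c Levitt cutoff, Angstrom.
#' @param out_dir Optional output directory for TSV/summary/PDB files.
#' @param bfactor_pdb Also write `es.bfactor.pdb` / `fod.bfactor.pdb` with
#'   deviations / KL terms in the B-factor column (default `FALSE`).
#' @param id Label used in the report (default: file base name).
#' @return An object of class `combined_report`: list with `id`,
#'   `d_average`, `o_t`, `o_r`, `es_accordant`, `ls_accordant`, `es`
#'   (es_profile), `fod` (fod_result), `errors`.
#' @export
analyze <- function(path, chain = NULL, cal = NULL,
                    scale = hydrophobicity_scale(), c = 9,
                    out_dir = NULL, bfactor_pdb = FALSE, id = NULL) {
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  s <- read_structure(path, chain = chain)
  if (is.null(cal)) cal <- default_calibration()
  errors <- list()

  es <- tryCatch(es_profile(s, cal), error = function(e) {
    errors$es <<- conditionMessage(e)
    NULL
  })
  fod <- tryCatch(fod_analysis(s, scale = scale, c = c), error = function(e) {
    errors$fod <<- conditionMessage(e)
    NULL
  })

  rep <- structure(list(
    id = id,
    n_residues = n_residues(s),
    d_average = if (!is.null(es)) es$d_average else NA_real_,
    o_t = if (!is.null(fod)) fod$o_t else NA_real_,
    o_r = if (!is.null(fod)) fod$o_r else NA_real_,
    es_accordant = if (!is.null(es)) es$d_average < 1 else NA,
    ls_accordant = if (!is.null(fod)) fod$accordant else NA,
    es = es, fod = fod, errors = errors,
    config = list(chain = s$chain, cutoff = c,
                  scale = attr(scale, "scale_name"),
                  calibration = cal$provenance)
  ), class = "combined_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(es)) write_profile(es, file.path(out_dir, "es_profile.tsv"))
    if (!is.null(fod)) write_profile(fod, file.path(out_dir, "fod_profile.tsv"))
    writeLines(utils::capture.output(print(rep)),
               file.path(out_dir, "summary.txt"))
    if (bfactor_pdb && !is.null(es)) {
      # map window deviations onto their central residues; ends carry 0
      devs <- rep(0, n_residues(s))
      ok <- !es$windows$skipped
      devs[es$windows$central_residue[ok]] <- es$windows$deviation[ok]
      write_bfactor_pdb(s, devs, file.path(out_dir, "es.bfactor.pdb"))
    }
    if (bfactor_pdb && !is.null(fod)) {
      write_bfactor_pdb(s, fod$residues$kl_term,
                        file.path(out_dir, "fod.bfactor.pdb"))
    }
  }
  rep
}

#' @export
print.combined_report <- function(x, ...) {
  cat(sprintf("fodes %s | chain %s | %d residues | scale %s | cutoff %g A | calibration %s\n",
              as.character(utils::packageVersion("fodes")), x$config$chain,
              x$n_residues, x$config$scale, x$config$cutoff,
              x$config$calibration))
  cat(sprintf("protein: %s\n", x$id))
  cat(sprintf("  ES  D_average = %.4f  -> %s\n", x$d_average,
              if (isTRUE(x$es_accordant)) "ES-accordant (D_average < 1)"
              else if (isFALSE(x$es_accordant)) "not ES-accordant"
              else "unavailable"))
  cat(sprintf("  LS  O/T = %.4f  O/R = %.4f  -> %s\n", x$o_t, x$o_r,
              if (isTRUE(x$ls_accordant)) "accordant (O/T < O/R)"
              else if (isFALSE(x$ls_accordant)) "discordant (O/T > O/R)"
              else "unavailable"))
  for (nm in names(x$errors)) {
    cat(sprintf("  [%s stage error] %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

.fodes_env <- new.env(parent = emptyenv())

#' Cached default analytic calibration
#'
#' The package-default [calibrate_analytic()] result (2 degree grid step,
#' 20-residue homopolymers), computed once per session and cached.
#'
#' @param step Grid step in degrees.
#' @return An [es_calibration()].
#' @export
default_calibration <- function(step = 2) {
  key <- paste0("cal_", step)
  if (is.null(.fodes_env[[key]])) {
    .fodes_env[[key]] <- calibrate_analytic(step = step)
  }
  .fodes_env[[key]]
}
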