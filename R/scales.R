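#' Residue hydrophobicity scales
#'
#' Loads a per-residue hydrophobicity scale as a named vector over the 20
#' standard three-letter amino-acid codes, min-max normalized to `[0, 1]`.
#' The packaged default is the Aboderin chromatographic-mobility scale, the
#' scale conventionally used to parameterize observed hydrophobicity in
#' fuzzy-oil-drop analyses. Alternate scales can be supplied as a plain-text
#' two-column table (three-letter code, value; `#` comments allowed).
#'
#' @param name Name of a packaged scale (currently `"aboderin"`) or a path to
#'   a scale file.
#' @param normalize Min-max normalize the raw values to `[0, 1]` (default
#'   `TRUE`, the convention assumed by [observed_distribution()]).
#' @return A named numeric vector of length 20 with class `"hydro_scale"` and
#'   a `"scale_name"` attribute.
#' @examples
#' sc <- hydrophobicity_scale("aboderin")
#' sc[["LEU"]]  # most hydrophobic, 1.0
#' sc[["CYS"]]  # least mobile in this scale, 0.0
#' @export
hydrophobicity_scale <- function(name = "aboderin", normalize = TRUE) {
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("extdata", paste0(name, "_scale.tsv"), package = "fodes")
    if (!nzchar(p)) stop("unknown hydrophobicity scale: ", name)
    p
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("residue", "value"),
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(as.numeric(tab$value), toupper(tab$residue))
  if (anyDuplicated(names(vals))) stop("duplicate residue entries in scale")
  missing <- setdiff(STANDARD_AA, names(vals))
  if (length(missing)) {
    stop("scale is missing residues: ", paste(missing, collapse = ", "))
  }
  vals <- vals[STANDARD_AA]
  if (normalize) {
    rng <- range(vals)
    if (diff(rng) <= 0) stop("degenerate scale: all values identical")
    vals <- (vals - rng[1]) / diff(rng)
  }
  structure(vals, class = "hydro_scale",
            scale_name = if (file.exists(name)) basename(name) else name)
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat("<hydrophobicity scale:", attr(x, "scale_name"), ">\n")
  print(unclass(x), ...)
  invisible(x)
}

# The 20 standard amino acids, three-letter codes.
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
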