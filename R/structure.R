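#' @title Single-chain protein structures
#'
#' @description
#' `fod_structure` objects hold one ordered protein chain: per-residue
#' backbone coordinates (N, CA, C, O), side-chain heavy-atom coordinates and
#' the original PDB numbering. They are produced by [read_structure()] and by
#' the synthetic fixture builders, and consumed by the early-stage geometry
#' and fuzzy-oil-drop analyses.
#'
#' @name fod_structure
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

new_fod_structure <- function(chain, resno, insert, resid, n, ca, c, o, sc, atoms) {
  stopifnot(length(resid) == nrow(ca), length(sc) == nrow(ca))
  structure(list(chain = chain, resno = as.integer(resno), insert = insert,
                 resid = resid, n = n, ca = ca, c = c, o = o, sc = sc,
                 atoms = atoms),
            class = "fod_structure")
}

#' Number of residues in a structure
#' @param s A `fod_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(s) length(s$resid)

#' @export
print.fod_structure <- function(x, ...) {
  cat(sprintf("<fod_structure: chain %s, %d residues (%s...%s)>\n",
              x$chain, n_residues(x), x$resid[1], x$resid[n_residues(x)]))
  invisible(x)
}

#' Read a single protein chain from a PDB file
#'
#' Parses a PDB file (via bio3d), selects one chain and one model, and
#' reduces it to the ordered residue representation used throughout the
#' package. Waters and hetero groups are dropped, except selenomethionine
#' (MSE), which is mapped to MET (SE renamed SD). Alternate locations are
#' resolved by keeping the highest-occupancy copy (ties: first encountered).
#' Hydrogens are retained in the atom table but never enter side-chain
#' centers. Insertion codes are preserved in the residue numbering.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier; `NULL` selects the first chain present.
#' @param model_index Model to use for multi-model (NMR) files; default 1.
#' @param require_backbone If `TRUE` (default) every residue must have N, CA
#'   and C, and O may be absent only at the chain terminus; CA-only
#'   pseudo-structures (e.g. toy globules) are read with `FALSE`.
#' @return A [fod_structure] object.
#' @seealso [effective_atoms()], [write_bfactor_pdb()]
#' @export
read_structure <- function(path, chain = NULL, model_index = 1L,
                           require_backbone = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE))
  at <- pdb$atom
  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1 || model_index > nmodels) {
    stop("model_index ", model_index, " out of range (", nmodels, " models)")
  }
  if (is.matrix(pdb$xyz) && nmodels > 1) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  # selenomethionine rescue, then drop remaining hetero records (incl. waters)
  mse <- at$type == "HETATM" & at$resid == "MSE"
  if (any(mse)) {
    at$type[mse] <- "ATOM"
    at$resid[mse] <- "MET"
    at$elety[mse][at$elety[mse] == "SE"] <- "SD"
    at$elesy[mse][!is.na(at$elesy[mse]) & at$elesy[mse] == "SE"] <- "S"
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("chain not found: no ATOM records in ", path)

  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop("chain not found: '", chain, "' (available: ",
         paste(chains, collapse = ", "), ")")
  }
  at <- at[at$chain %in% chain, , drop = FALSE]

  bad <- setdiff(unique(at$resid), STANDARD_AA)
  if (length(bad)) {
    stop("unsupported residue(s) in chain ", chain, ": ",
         paste(bad, collapse = ", "))
  }

  # alternate locations: keep highest occupancy per (residue, atom name)
  at$insert[is.na(at$insert)] <- ""
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, at$insert, at$elety, sep = "|")
  ord <- order(-occ, seq_len(nrow(at)))
  keep_rows <- ord[!duplicated(key[ord])]
  at <- at[sort(keep_rows), , drop = FALSE]

  rkey <- paste(at$resno, at$insert, sep = "|")
  ridx <- match(rkey, unique(rkey))
  nres <- max(ridx)

  grab <- function(name) {
    m <- matrix(NA_real_, nres, 3)
    sel <- which(at$elety == name)
    m[ridx[sel], ] <- cbind(at$x[sel], at$y[sel], at$z[sel])
    m
  }
  n_m <- grab("N"); ca_m <- grab("CA"); c_m <- grab("C"); o_m <- grab("O")

  is_h <- !is.na(at$elesy) & at$elesy %in% c("H", "D")
  sc <- lapply(seq_len(nres), function(i) {
    sel <- ridx == i & !(at$elety %in% c(BACKBONE_ATOMS, "OXT")) & !is_h
    unname(cbind(at$x[sel], at$y[sel], at$z[sel]))
  })

  first <- !duplicated(ridx)
  resid <- at$resid[first]
  resno <- at$resno[first]
  insert <- at$insert[first]

  if (require_backbone) {
    for (i in seq_len(nres)) {
      miss <- BACKBONE_ATOMS[c(anyNA(n_m[i, ]), anyNA(ca_m[i, ]),
                               anyNA(c_m[i, ]), anyNA(o_m[i, ]))]
      miss <- setdiff(miss, if (i == nres) "O" else character())
      if (length(miss)) {
        stop(sprintf("incomplete backbone: residue %s%d%s missing %s",
                     resid[i], resno[i], insert[i],
                     paste(miss, collapse = ",")))
      }
    }
  } else if (anyNA(ca_m)) {
    stop("incomplete backbone: residue without CA")
  }

  atoms <- data.frame(resindex = ridx, elety = at$elety, x = at$x, y = at$y,
                      z = at$z, elesy = ifelse(is.na(at$elesy), "", at$elesy),
                      stringsAsFactors = FALSE)
  new_fod_structure(chain, resno, insert, resid, n_m, ca_m, c_m, o_m, sc, atoms)
}

#' Write a structure to a PDB file
#'
#' Serializes the atom table of a [fod_structure] using the standard fixed
#' columns, optionally carrying per-atom B-factors.
#'
#' @param s A `fod_structure`.
#' @param path Output file path.
#' @param b Optional numeric vector of per-atom B-factors (length = atom
#'   count); default all zero.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path, b = NULL) {
  at <- s$atoms
  if (is.null(b)) b <- rep(0, nrow(at))
  if (length(b) != nrow(at)) stop("b-factor length mismatch")
  name4 <- ifelse(nchar(at$elety) < 4, sprintf(" %-3s", at$elety), at$elety)
  lines <- sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(at)) %% 100000, name4,
                   s$resid[at$resindex], s$chain,
                   s$resno[at$resindex] %% 10000, s$insert[at$resindex],
                   at$x, at$y, at$z, 1, b, at$elesy)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "TER", "END"), con)
  invisible(path)
}

#' Color a structure by per-residue values via the B-factor column
#'
#' Writes a PDB file identical to the structure's atoms except that the
#' B-factor column of every atom carries the supplied per-residue value
#' (e.g. ES deviations or per-residue KL terms, for molecular-viewer
#' coloring of accordant/deviant residues).
#'
#' @param s A `fod_structure`.
#' @param per_residue_values Numeric vector, one value per residue.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bfactor_pdb <- function(s, per_residue_values, path) {
  if (length(per_residue_values) != n_residues(s)) {
    stop("value list length (", length(per_residue_values),
         ") does not match residue count (", n_residues(s), ")")
  }
  write_structure_pdb(s, path, b = per_residue_values[s$atoms$resindex])
}

#' Reduce a structure to effective atoms with hydrophobicity parameters
#'
#' Each residue is represented by a single point — the geometric center
#' (unweighted mean) of its side-chain heavy atoms, or the CA position when
#' the side chain is empty (GLY, CA-only pseudo-residues) — carrying the
#' residue's hydrophobicity parameter from the active scale. This is the
#' residue-level grid on which the fuzzy-oil-drop distributions are defined.
#'
#' @param s A `fod_structure`.
#' @param scale A [hydrophobicity_scale()] vector.
#' @param mode `"side-chain"` (default) averages side-chain heavy atoms;
#'   `"all-atom"` averages all heavy atoms of the residue.
#' @return A data.frame with columns `index`, `resid`, `x`, `y`, `z`, `h`
#'   (one row per residue, chain order preserved).
#' @export
effective_atoms <- function(s, scale = hydrophobicity_scale(),
                            mode = c("side-chain", "all-atom")) {
  mode <- match.arg(mode)
  if (n_residues(s) == 0) stop("empty structure")
  missing <- setdiff(unique(s$resid), names(scale))
  if (length(missing)) {
    stop("no scale entry for residue(s): ", paste(missing, collapse = ", "))
  }
  pos <- t(vapply(seq_len(n_residues(s)), function(i) {
    pts <- s$sc[[i]]
    if (mode == "all-atom") {
      bb <- rbind(s$n[i, ], s$ca[i, ], s$c[i, ], s$o[i, ])
      pts <- rbind(pts, bb[!apply(bb, 1, anyNA), , drop = FALSE])
    }
    if (is.null(pts) || nrow(pts) == 0) s$ca[i, ] else colMeans(pts)
  }, numeric(3)))
  out <- data.frame(index = seq_len(n_residues(s)), resid = s$resid,
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    h = unname(scale[s$resid]), stringsAsFactors = FALSE)
  class(out) <- c("effective_atoms", "data.frame")
  out
}
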