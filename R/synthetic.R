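#' @title Synthetic structure fixtures
#'
#' @description
#' Download-free structures with known geometry and hydrophobic architecture:
#' constant-dihedral poly-ALA backbones (helix, extended, or any custom
#' phi/psi) for the early-stage geometry, and seeded "toy globules" whose
#' hydrophobic residues are placed centrally (or anti-centrally) for the
#' fuzzy-oil-drop analysis. All builders are deterministic: the same
#' specification and seed reproduce the same coordinates bitwise.
#'
#' @name synthetic_structures
NULL

# Ideal peptide stereochemistry used by the backbone builder (lengths in
# Angstrom, angles in degrees). Kept in one table so tests can assert the
# constructed geometry against it.
IDEAL_GEOMETRY <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, dih_cb = -122.6, omega = 180
)

#' Build an ideal-geometry poly-ALA backbone at given dihedrals
#'
#' Constructs an N, CA, C, O, CB chain with ideal bond lengths and angles,
#' trans peptide bonds (omega = 180 deg) and the supplied phi/psi dihedrals.
#' Presets: `"helix"` uses (-57, -47), the ideal right-handed alpha helix;
#' `"extended"` uses (180, 180), the fully extended chain.
#'
#' @param length Number of residues (>= 5, so pentapeptide windows exist).
#' @param kind `"helix"`, `"extended"` or `"custom"`.
#' @param phi,psi Backbone dihedrals in degrees, used when `kind = "custom"`;
#'   either scalars (constant conformation) or vectors of length `length`
#'   (phi\[1\] and psi\[length\] are undefined and ignored).
#' @return A [fod_structure] (chain "A", residues numbered from 1).
#' @examples
#' h <- build_backbone(10, "helix")
#' v_angle(h, 1)  # near 0 degrees for a helix
#' @export
build_backbone <- function(length, kind = c("helix", "extended", "custom"),
                           phi = NULL, psi = NULL) {
  kind <- match.arg(kind)
  if (length < 5) stop("length must be >= 5 (pentapeptide windows)")
  n <- as.integer(length)
  if (kind == "helix") { phi <- -57; psi <- -47 }
  if (kind == "extended") { phi <- 180; psi <- 180 }
  if (is.null(phi) || is.null(psi)) stop("custom kind needs phi and psi")
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  g <- IDEAL_GEOMETRY

  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * DEG
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_n, g$ang_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$n_ca, g$ang_c_n_ca, g$omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c, g$ang_n_ca_c, phi[i + 1])
    # carbonyl O in the peptide plane, opposite N(i+1)
    O[i, ] <- place_atom(N[i + 1, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o, 180)
  }
  O[n, ] <- place_atom(N[n, ], CA[n, ], C[n, ], g$c_o, g$ang_ca_c_o, psi[n] + 180)
  for (i in seq_len(n)) {
    CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], g$ca_cb, g$ang_n_ca_cb, g$dih_cb)
  }

  atoms <- data.frame(
    resindex = rep(seq_len(n), each = 5),
    elety = rep(c("N", "CA", "C", "O", "CB"), n),
    x = as.vector(t(cbind(N[, 1], CA[, 1], C[, 1], O[, 1], CB[, 1]))),
    y = as.vector(t(cbind(N[, 2], CA[, 2], C[, 2], O[, 2], CB[, 2]))),
    z = as.vector(t(cbind(N[, 3], CA[, 3], C[, 3], O[, 3], CB[, 3]))),
    elesy = rep(c("N", "C", "C", "O", "C"), n),
    stringsAsFactors = FALSE
  )
  new_fod_structure("A", seq_len(n), rep("", n), rep("ALA", n),
                    N, CA, C, O, sc = lapply(seq_len(n), function(i) CB[i, , drop = FALSE]),
                    atoms = atoms)
}

#' Measure phi/psi dihedrals from a structure
#'
#' @param s A [fod_structure] with complete backbone.
#' @return A data.frame with columns `phi` and `psi` (degrees; NA at chain
#'   ends where undefined).
#' @export
backbone_dihedrals <- function(s) {
  n <- n_residues(s)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) phi[i] <- dihedral4(s$c[i - 1, ], s$n[i, ], s$ca[i, ], s$c[i, ])
    if (i < n) psi[i] <- dihedral4(s$n[i, ], s$ca[i, ], s$c[i, ], s$n[i + 1, ])
  }
  data.frame(phi = phi, psi = psi)
}

#' Build a seeded toy globule with a designed hydrophobic core
#'
#' Samples CA-only pseudo-residue positions from an anisotropic Gaussian
#' cloud and assigns high-hydrophobicity identities (LEU) to the points
#' nearest the center and low-hydrophobicity identities (ASN) to the rest.
#' Such a globule realizes the fuzzy-oil-drop premise — hydrophobic residues
#' buried, hydrophilic exposed — so its observed distribution should track
#' the Gaussian theoretical one (O/T < O/R). With `invert = TRUE` the
#' identities are swapped (hydrophobics outside), the anti-accordant control.
#'
#' @param n Number of residues.
#' @param core_fraction Fraction of residues (nearest the center) assigned
#'   the hydrophobic identity; in `[0, 1]`.
#' @param seed Integer seed; same seed, same coordinates.
#' @param sds Axis standard deviations of the Gaussian cloud (Angstrom).
#' @param invert Swap hydrophobic/hydrophilic identities.
#' @return A [fod_structure] with CA-only residues.
#' @export
build_toy_globule <- function(n = 60, core_fraction = 0.4, seed = 1,
                              sds = c(12, 9, 6), invert = FALSE) {
  if (core_fraction < 0 || core_fraction > 1) {
    stop("core_fraction must be in [0, 1]")
  }
  set.seed(seed)
  pts <- cbind(stats::rnorm(n, 0, sds[1]), stats::rnorm(n, 0, sds[2]),
               stats::rnorm(n, 0, sds[3]))
  # distance from center in cloud-scaled units, so "core" is elliptically central
  d <- sqrt((pts[, 1] / sds[1])^2 + (pts[, 2] / sds[2])^2 + (pts[, 3] / sds[3])^2)
  ncore <- round(core_fraction * n)
  core <- rank(d, ties.method = "first") <= ncore
  if (invert) core <- !core
  resid <- ifelse(core, "LEU", "ASN")

  atoms <- data.frame(resindex = seq_len(n), elety = "CA",
                      x = pts[, 1], y = pts[, 2], z = pts[, 3],
                      elesy = "C", stringsAsFactors = FALSE)
  na <- matrix(NA_real_, n, 3)
  new_fod_structure("A", seq_len(n), rep("", n), resid,
                    n = na, ca = pts, c = na, o = na,
                    sc = replicate(n, matrix(numeric(0), 0, 3), simplify = FALSE),
                    atoms = atoms)
}
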