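#' @title Fuzzy-oil-drop hydrophobic core analysis
#'
#' @description
#' The late-stage (LS) model treats the water environment as an external
#' hydrophobic field shaped like a 3D Gaussian: idealized hydrophobicity
#' density is maximal at the molecular center and near zero at the surface.
#' A protein's observed hydrophobicity density (the Levitt pairwise
#' collection function over effective atoms, 9 A cutoff) is compared with
#' the Gaussian theoretical density and with a uniform random reference via
#' Kullback-Leibler divergence; O/T < O/R classifies the hydrophobic core
#' as accordant with the model.
#'
#' @name fuzzy_oil_drop
NULL

SIGMA_FLOOR <- 1.0  # Angstrom; guards flat/degenerate molecules

atom_matrix <- function(atoms) {
  if (is.matrix(atoms)) atoms else as.matrix(atoms[, c("x", "y", "z")])
}

#' Canonical orientation and Gaussian drop parameters
#'
#' Translates the effective atoms so their geometric center is at the
#' origin and rotates them onto the principal axes of their covariance,
#' ordered so the longest extent lies along x, then y, then z (sign fixed by
#' making the largest-magnitude coordinate positive on each axis). Each
#' Gaussian sigma is one third of the longest distance between two effective
#' atoms along its axis, i.e. one third of the coordinate range; sigmas are
#' floored at 1 A (with a warning) for flat or linear point sets.
#'
#' @param atoms An [effective_atoms()] data.frame (or an `n x 3` matrix).
#' @return A list with `atoms` (the input with rotated coordinates) and
#'   `gauss` (class `gauss_parameters`: `center` = origin, `sigma` =
#'   c(x, y, z)).
#' @export
orient <- function(atoms) {
  P <- atom_matrix(atoms)
  if (nrow(P) < 2) stop("degenerate geometry: need at least 2 effective atoms")
  Pc <- sweep(P, 2, colMeans(P))
  if (max(abs(Pc)) < 1e-9) stop("degenerate geometry: all atoms coincident")
  ev <- eigen(crossprod(Pc) / nrow(Pc), symmetric = TRUE)
  Q <- Pc %*% ev$vectors
  extents <- apply(Q, 2, function(v) diff(range(v)))
  ord <- order(extents, decreasing = TRUE)
  Q <- Q[, ord, drop = FALSE]
  extents <- extents[ord]
  for (k in 1:3) {
    if (abs(min(Q[, k])) > abs(max(Q[, k]))) Q[, k] <- -Q[, k]
  }
  sigma <- extents / 3
  if (any(sigma < SIGMA_FLOOR)) {
    warning("near-degenerate extent: sigma floored at ", SIGMA_FLOOR, " A")
    sigma <- pmax(sigma, SIGMA_FLOOR)
  }
  out <- atoms
  if (is.matrix(out)) {
    out <- Q
  } else {
    out$x <- Q[, 1]; out$y <- Q[, 2]; out$z <- Q[, 3]
  }
  list(atoms = out,
       gauss = structure(list(center = c(0, 0, 0),
                              sigma = stats::setNames(sigma, c("x", "y", "z"))),
                         class = "gauss_parameters"))
}

#' @export
print.gauss_parameters <- function(x, ...) {
  cat(sprintf("<gauss_parameters: sigma = (%.2f, %.2f, %.2f) A>\n",
              x$sigma[1], x$sigma[2], x$sigma[3]))
  invisible(x)
}

new_hydro_distribution <- function(values, role) {
  s <- sum(values)
  if (!is.finite(s) || s <= 0) stop("cannot normalize: non-positive total")
  structure(values / s, role = role, class = "hydro_distribution")
}

#' @export
print.hydro_distribution <- function(x, ...) {
  cat(sprintf("<hydro_distribution (%s), n = %d>\n", attr(x, "role"), length(x)))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Theoretical (Gaussian) hydrophobicity distribution
#'
#' Evaluates the 3D Gauss function at every (already oriented) effective
#' atom and normalizes over the molecule: the idealized hydrophobicity
#' density of the fuzzy oil drop, maximal at the center.
#'
#' @param atoms Oriented effective atoms (from [orient()]).
#' @param g The `gauss_parameters` from [orient()].
#' @return A `hydro_distribution` (role `"T"`), values summing to 1.
#' @export
theoretical_distribution <- function(atoms, g) {
  if (any(g$sigma <= 0)) stop("sigma must be > 0")
  P <- atom_matrix(atoms)
  t_raw <- exp(-P[, 1]^2 / (2 * g$sigma[1]^2)) *
    exp(-P[, 2]^2 / (2 * g$sigma[2]^2)) *
    exp(-P[, 3]^2 / (2 * g$sigma[3]^2))
  new_hydro_distribution(t_raw, "T")
}

#' Levitt distance kernel
#'
#' The even polynomial weight of the Levitt hydrophobicity collection
#' function: `B(r) = 1 - 1/2 (7 t^2 - 9 t^4 + 5 t^6 - t^8)` with `t = r/c`
#' for `r <= c`, and 0 beyond the cutoff. `B(0) = 1` and `B(c) = 0`, so the
#' kernel is continuous at the cutoff.
#'
#' @param r Distance(s), Angstrom.
#' @param c Cutoff distance, Angstrom (default 9).
#' @return Kernel value(s) in `[0, 1]`.
#' @export
levitt_kernel <- function(r, c = 9) {
  t2 <- (r / c)^2
  ifelse(r <= c, 1 - 0.5 * (7 * t2 - 9 * t2^2 + 5 * t2^3 - t2^4), 0)
}

#' Observed hydrophobicity distribution (Levitt function)
#'
#' Collects hydrophobicity at each effective atom j as
#' `O_j = sum_i (H_i + H_j) B(r_ij)` over all residues i (the i = j
#' self-term included, with `B(0) = 1`), then normalizes over the molecule.
#' Depends only on pairwise distances, so it is rigid-motion invariant.
#'
#' @param atoms An [effective_atoms()] data.frame carrying hydrophobicity
#'   parameters in `$h`.
#' @param c Cutoff distance in Angstrom (default 9, the Levitt value).
#' @param exclude_self Drop the i = j term (sensitivity analysis; default
#'   `FALSE`).
#' @return A `hydro_distribution` (role `"O"`), values summing to 1.
#' @export
observed_distribution <- function(atoms, c = 9, exclude_self = FALSE) {
  h <- atoms$h
  if (is.null(h)) stop("atoms must carry hydrophobicity parameters in $h")
  if (any(h < 0)) stop("negative hydrophobicity scale values are not allowed")
  P <- atom_matrix(atoms)
  B <- levitt_kernel(as.matrix(stats::dist(P)), c = c)
  diag(B) <- if (exclude_self) 0 else 1
  hh <- outer(h, h, "+")  # (H_i + H_j)
  o_raw <- colSums(hh * B)
  new_hydro_distribution(o_raw, "O")
}

#' Uniform random reference distribution
#'
#' The maximum-entropy reference against which the observed distribution is
#' compared: `R_i = 1/n` for every residue.
#'
#' @param n Number of residues (>= 1).
#' @return A `hydro_distribution` (role `"R"`).
#' @export
random_distribution <- function(n) {
  if (n < 1) stop("n must be >= 1")
  new_hydro_distribution(rep(1, n), "R")
}

#' Kullback-Leibler divergence in bits
#'
#' `D_KL(p || q) = sum_i p_i log2(p_i / q_i)`, with the `0 log 0 := 0`
#' convention. Non-negative by Gibbs' inequality, zero iff `p == q`.
#'
#' @param p,q Distributions (numeric vectors summing to 1, equal length);
#'   `q` must be strictly positive wherever `p > 0`.
#' @return Divergence in bits.
#' @export
kl_divergence <- function(p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != length(q)) stop("length mismatch between distributions")
  if (any(q <= 0 & p > 0)) {
    stop("unsupported support: q is zero where p is positive")
  }
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

#' Full fuzzy-oil-drop analysis of a structure
#'
#' Composes the LS pipeline: effective atoms -> canonical orientation ->
#' theoretical (T), observed (O) and random (R) distributions -> the
#' divergences `O/T = D_KL(O || T)` and `O/R = D_KL(O || R)`. The hydrophobic
#' core is classified accordant with the fuzzy-oil-drop model when
#' O/T < O/R. Per-residue KL terms `O_i log2(O_i / T_i)` are reported, with
#' residues flagged core-accordant when |term| < `residue_threshold`.
#'
#' @param s A [fod_structure] (>= 4 residues).
#' @param scale A [hydrophobicity_scale()].
#' @param c Levitt cutoff distance, Angstrom (default 9).
#' @param exclude_self Passed to [observed_distribution()].
#' @param mode Effective-atom mode, passed to [effective_atoms()].
#' @param residue_threshold Per-residue accordance threshold on the absolute
#'   KL term (default 0.01 bits).
#' @return An object of class `fod_result`: list with `o_t`, `o_r` (bits),
#'   `accordant` (`o_t < o_r`), `gauss`, and `residues` (data.frame with
#'   `index`, `resid`, `T`, `O`, `R`, `kl_term`, `accordant`).
#' @export
fod_analysis <- function(s, scale = hydrophobicity_scale(), c = 9,
                         exclude_self = FALSE,
                         mode = c("side-chain", "all-atom"),
                         residue_threshold = 0.01) {
  if (n_residues(s) < 4) stop("structure must have >= 4 residues")
  ea <- effective_atoms(s, scale, mode = match.arg(mode))
  ori <- orient(ea)
  Td <- theoretical_distribution(ori$atoms, ori$gauss)
  Od <- observed_distribution(ori$atoms, c = c, exclude_self = exclude_self)
  Rd <- random_distribution(nrow(ea))
  o_t <- kl_divergence(Od, Td)
  o_r <- kl_divergence(Od, Rd)
  o <- as.numeric(Od)
  t_ <- as.numeric(Td)
  term <- ifelse(o > 0, o * log2(ifelse(o > 0, o / t_, 1)), 0)
  residues <- data.frame(index = ea$index, resid = ea$resid,
                         T = t_, O = o, R = as.numeric(Rd),
                         kl_term = term,
                         accordant = abs(term) < residue_threshold,
                         stringsAsFactors = FALSE)
  structure(list(o_t = o_t, o_r = o_r, accordant = o_t < o_r,
                 gauss = ori$gauss, residues = residues,
                 cutoff = c, residue_threshold = residue_threshold),
            class = "fod_result")
}

#' @export
print.fod_result <- function(x, ...) {
  cat(sprintf("<fod_result: O/T = %.4f, O/R = %.4f -> %s>\n",
              x$o_t, x$o_r,
              if (x$accordant) "accordant (O/T < O/R)" else "discordant (O/T > O/R)"))
  invisible(x)
}
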