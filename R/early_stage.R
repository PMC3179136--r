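#' @title Early-stage backbone geometry
#'
#' @description
#' The early-stage (ES) folding intermediate is characterized by two backbone
#' parameters: the V-angle — the dihedral tilt between two sequential peptide
#' bond planes, near 0 deg for helices and near 180 deg for extended/beta
#' forms — and the radius of curvature R of the pentapeptide CA trace, small
#' for helices and very large (theoretically infinite) for extended chains,
#' used on a natural-log scale. The two are related by a calibrated
#' second-degree polynomial ln R = a2 V^2 + a1 V + a0; the mean per-window
#' distance from that curve (D_average, measured along the ln R axis) scores
#' how ES-like a chain is, with D_average < 1 indicating accordance.
#'
#' @name early_stage
NULL

MAX_RADIUS <- 1e4  # Angstrom cap for near-straight traces ("infinite" R)
CHAIN_BREAK_CUTOFF <- 2.5  # Angstrom on the C(i)-N(i+1) peptide bond

check_bond <- function(s, i) {
  d <- vnorm(s$n[i + 1, ] - s$c[i, ])
  if (!is.finite(d) || d > CHAIN_BREAK_CUTOFF) {
    stop(sprintf("chain break between residues %d and %d (C-N %.2f A)",
                 i, i + 1, d))
  }
}

#' V-angle between sequential peptide bond planes
#'
#' Computes the unsigned dihedral tilt between the plane of peptide bond
#' i -> i+1 and the plane of bond i+1 -> i+2: the torsion angle
#' O(i)-C(i)-C(i+1)-O(i+1), folded into `[0, 180]` degrees. The carbonyl
#' C=O lies in its peptide plane and fixes the plane's orientation, so this
#' torsion about the axis joining the two carbonyl carbons measures the
#' twist between the sequential peptide plates: near 0 deg for helices
#' (plates aligned), near 180 deg for extended and beta-like forms (plates
#' alternating).
#'
#' @param s A [fod_structure].
#' @param i Index of the first residue of the first peptide bond; residues
#'   `i`, `i+1`, `i+2` must exist with complete backbone.
#' @return Angle in degrees in `[0, 180]`.
#' @export
v_angle <- function(s, i) {
  if (i < 1 || i + 2 > n_residues(s)) stop("residues i..i+2 must exist")
  check_bond(s, i)
  check_bond(s, i + 1)
  if (anyNA(s$o[i, ]) || anyNA(s$o[i + 1, ])) {
    stop("missing carbonyl O in peptide plane at residue ", i)
  }
  abs(dihedral4(s$o[i, ], s$c[i, ], s$c[i + 1, ], s$o[i + 1, ]))
}

#' ln radius of curvature of a pentapeptide fragment
#'
#' Measures the curvature of the chain axis over residues
#' `window_start .. window_start+4`. The CA trace zig-zags about the chain
#' axis, so the raw CA positions of an extended chain lie on a circle of
#' modest radius even though the chain itself is straight; the trace is
#' therefore smoothed to consecutive CA-CA midpoints (which lie exactly on
#' the local screw axis of a regular conformation), a least-squares circle
#' is fitted to the smoothed points after projection onto their best-fit
#' plane, and the natural log of the fitted radius is returned. This makes
#' the extended chain's radius diverge as the model requires; it is capped
#' at `1e4` Angstrom before the log. Set `smooth = FALSE` to fit the five
#' raw CA coordinates directly (exact on points lying on a true circle).
#'
#' @param s A [fod_structure].
#' @param window_start First residue of the pentapeptide window.
#' @param smooth Fit the CA-CA midpoint trace (default) rather than the raw
#'   CA positions.
#' @return `ln R` in ln-Angstrom.
#' @export
radius_of_curvature <- function(s, window_start, smooth = TRUE) {
  w <- window_start
  if (w < 1 || w + 4 > n_residues(s)) stop("pentapeptide window out of range")
  pts <- s$ca[w:(w + 4), , drop = FALSE]
  if (anyNA(pts)) stop("missing CA coordinates in window")
  if (smooth) pts <- (pts[-1, , drop = FALSE] + pts[-5, , drop = FALSE]) / 2
  log(min(fit_window_radius(pts), MAX_RADIUS))
}

fit_window_radius <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  xy <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2])  # best-fit plane coords
  fit_circle_2d(xy)$radius
}

#' ES calibration: the polynomial relating V-angle and ln R
#'
#' Constructs the calibration object holding the coefficients of
#' `lnR_pred(V) = a2 V^2 + a1 V + a0` (V in degrees, lnR in ln-Angstrom).
#' Usually produced by [calibrate_analytic()]; published coefficients can be
#' supplied directly (or via [read_calibration()]) to reproduce external
#' analyses exactly.
#'
#' @param a2,a1,a0 Polynomial coefficients.
#' @param provenance One of `"analytic-grid"`, `"reference-set"`,
#'   `"user-supplied"`.
#' @param points Optional data.frame of the `(phi, psi, V, lnR)` point cloud
#'   the fit was computed from.
#' @return An object of class `es_calibration`.
#' @export
es_calibration <- function(a2, a1, a0, provenance = "user-supplied",
                           points = NULL) {
  provenance <- match.arg(provenance,
                          c("analytic-grid", "reference-set", "user-supplied"))
  cal <- structure(list(coefficients = c(a2 = a2, a1 = a1, a0 = a0),
                        domain = c(0, 180), provenance = provenance,
                        points = points),
                   class = "es_calibration")
  if (predict(cal, 5) >= predict(cal, 175)) {
    warning("calibration is not increasing from the helical (V ~ 0) to the ",
            "extended (V ~ 180) end; check its source")
  }
  cal
}

#' @export
predict.es_calibration <- function(object, v, ...) {
  co <- object$coefficients
  # observed lnR is capped at ln(MAX_RADIUS); predictions live on the same
  # capped scale so accordant near-straight fragments are not penalized
  pmin(co[["a2"]] * v^2 + co[["a1"]] * v + co[["a0"]], log(MAX_RADIUS))
}

#' @export
print.es_calibration <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<es_calibration (%s): lnR = %.6g V^2 + %.6g V + %.6g>\n",
              x$provenance, co[["a2"]], co[["a1"]], co[["a0"]]))
  invisible(x)
}

#' Read / write calibration coefficients
#'
#' Plain-text format: lines starting with `#` are provenance comments; the
#' first data line holds the three floats `a2 a1 a0`.
#'
#' @param path File path.
#' @rdname read_calibration
#' @return `read_calibration()` returns an [es_calibration()] object.
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  data <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(data)) stop("no coefficient line in ", path)
  co <- as.numeric(strsplit(trimws(data[1]), "\\s+")[[1]])
  if (length(co) != 3 || anyNA(co)) stop("expected three floats: a2 a1 a0")
  es_calibration(co[1], co[2], co[3], provenance = "user-supplied")
}

#' @param cal An `es_calibration`.
#' @rdname read_calibration
#' @export
write_calibration <- function(cal, path) {
  co <- cal$coefficients
  writeLines(c(sprintf("# es_calibration provenance: %s", cal$provenance),
               sprintf("%.12g %.12g %.12g",
                       co[["a2"]], co[["a1"]], co[["a0"]])), path)
  invisible(path)
}

# Low-energy Ramachandran regions (degrees) used by the analytic calibration:
# rectangles around the right-handed alpha and beta basins plus the
# left-handed alpha mirror.
RAMACHANDRAN_REGIONS <- list(
  alpha_R = list(phi = c(-90, -40), psi = c(-70, -10)),
  beta = list(phi = c(-170, -70), psi = c(100, 180)),
  alpha_L = list(phi = c(40, 90), psi = c(10, 70))
)

# (V, lnR) of the central pentapeptide window of a constant-dihedral
# ideal-geometry homopolymer.
conformation_v_lnr <- function(phi, psi, chain_length = 20L) {
  s <- build_backbone(chain_length, "custom", phi = phi, psi = psi)
  w <- max(1L, (n_residues(s) - 4L) %/% 2L)
  c(v = v_angle(s, w + 1L), lnr = radius_of_curvature(s, w))
}

#' Analytic calibration of the V / ln R relation
#'
#' Regenerates the calibration from first principles: ideal-geometry
#' homopolymers are built at constant (phi, psi) over a grid covering the
#' low-energy Ramachandran regions (right-handed alpha, beta, left-handed
#' alpha), the V-angle and pentapeptide ln R are computed for each
#' conformation, and a second-degree polynomial is least-squares fitted to
#' the resulting (V, lnR) cloud.
#'
#' @param step Grid step in degrees (default 2).
#' @param chain_length Homopolymer length used per conformation (default 20).
#' @param regions Named list of regions, each `list(phi = c(lo, hi),
#'   psi = c(lo, hi))` in degrees.
#' @return An [es_calibration()] with provenance `"analytic-grid"` and the
#'   sampled point cloud attached.
#' @export
calibrate_analytic <- function(step = 2, chain_length = 20L,
                               regions = RAMACHANDRAN_REGIONS) {
  if (!length(regions)) stop("empty region definition")
  grids <- lapply(regions, function(r) {
    expand.grid(phi = seq(r$phi[1], r$phi[2], by = step),
                psi = seq(r$psi[1], r$psi[2], by = step))
  })
  grid <- do.call(rbind, grids)
  vl <- t(mapply(conformation_v_lnr, grid$phi, grid$psi,
                 MoreArgs = list(chain_length = chain_length)))
  pts <- data.frame(phi = grid$phi, psi = grid$psi, V = vl[, 1], lnR = vl[, 2])
  fit <- stats::lm(lnR ~ V + I(V^2), data = pts)
  co <- stats::coef(fit)
  es_calibration(a2 = unname(co["I(V^2)"]), a1 = unname(co["V"]),
                 a0 = unname(co["(Intercept)"]),
                 provenance = "analytic-grid", points = pts)
}

#' ES profile of a chain: per-window V, ln R, deviation and D_average
#'
#' For every pentapeptide window, V is taken for the window's central
#' peptide-plane pair (bonds between residues 2-3 and 3-4 of the window) and
#' ln R from the five-CA circle fit; the deviation from the calibration is
#' measured along the lnR axis only. D_average is the mean deviation over
#' valid windows; windows spanning a chain break (C-N distance > 2.5 A) are
#' skipped and reported with `skipped = TRUE`.
#'
#' @param s A [fod_structure] with at least 5 residues.
#' @param cal An [es_calibration()].
#' @param deviant_threshold Per-window deviation above which a window is
#'   flagged deviant (default 1 ln-Angstrom unit).
#' @return An object of class `es_profile`: a list with `windows` (data.frame
#'   with `window`, `central_residue`, `V`, `lnR_obs`, `lnR_pred`,
#'   `deviation`, `deviant`, `skipped`) and `d_average`.
#' @export
es_profile <- function(s, cal, deviant_threshold = 1) {
  n <- n_residues(s)
  if (n < 5) stop("structure must have >= 5 residues")
  nw <- n - 4L
  bond_ok <- vapply(seq_len(n - 1L), function(i) {
    d <- vnorm(s$n[i + 1, ] - s$c[i, ])
    is.finite(d) && d <= CHAIN_BREAK_CUTOFF
  }, logical(1))

  V <- lnr <- rep(NA_real_, nw)
  skipped <- logical(nw)
  for (w in seq_len(nw)) {
    if (!all(bond_ok[w:(w + 3L)])) {
      skipped[w] <- TRUE
      next
    }
    V[w] <- v_angle(s, w + 1L)
    lnr[w] <- radius_of_curvature(s, w)
  }
  pred <- predict(cal, V)
  dev <- abs(lnr - pred)
  windows <- data.frame(window = seq_len(nw),
                        central_residue = seq_len(nw) + 2L,
                        V = V, lnR_obs = lnr, lnR_pred = pred,
                        deviation = dev,
                        deviant = !is.na(dev) & dev > deviant_threshold,
                        skipped = skipped)
  structure(list(windows = windows,
                 d_average = mean(dev[!skipped]),
                 deviant_threshold = deviant_threshold,
                 calibration = cal),
            class = "es_profile")
}

#' @export
print.es_profile <- function(x, ...) {
  w <- x$windows
  cat(sprintf("<es_profile: %d windows (%d skipped), D_average = %.4f, %d deviant (> %g)>\n",
              nrow(w), sum(w$skipped), x$d_average, sum(w$deviant),
              x$deviant_threshold))
  invisible(x)
}
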