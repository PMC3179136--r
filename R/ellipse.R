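#' @title Elliptical Ramachandran subspace of ES-accordant conformations
#'
#' @description
#' Conformations whose (V, lnR) pair lies close to the calibrated polynomial
#' occupy a restricted region of the Ramachandran plot. Fitting an ellipse
#' to that region yields the limited conformational subspace proposed for
#' the early-stage intermediate: a single closed path passing through the
#' helical, beta and left-handed-helical basins.
#'
#' @name ellipse_subspace_model
NULL

# Direct least-squares ellipse fit (Halir & Flusser's numerically stable
# formulation of Fitzgibbon's method). Returns the conic coefficients
# (A, B, C, D, E, F) with the ellipse constraint 4AC - B^2 > 0.
fit_ellipse_conic <- function(x, y) {
  if (length(x) < 6) stop("cannot fit ellipse: fewer than 6 points")
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  # pick the eigenvector satisfying the ellipse constraint
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  idx <- which(cond > 0)
  if (!length(idx)) stop("cannot fit ellipse: no elliptical solution")
  a1 <- Re(ev$vectors[, idx[1]])
  c(a1, as.vector(Tm %*% a1))
}

conic_to_ellipse <- function(co) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  Q33 <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ctr <- solve(Q33, -c(D, E) / 2)
  f0 <- drop(t(ctr) %*% Q33 %*% ctr + sum(c(D, E) * ctr) + F)
  ev <- eigen(Q33, symmetric = TRUE)
  axes <- sqrt(-f0 / ev$values)  # semi-axes; -f0/lambda > 0 for an ellipse
  ord <- order(axes, decreasing = TRUE)
  angle <- atan2(ev$vectors[2, ord[1]], ev$vectors[1, ord[1]]) / DEG
  if (angle > 90) angle <- angle - 180
  if (angle <= -90) angle <- angle + 180
  list(center = ctr, semi_axes = axes[ord], angle = angle)
}

#' Fit an ellipse to 2D points
#'
#' Direct least-squares conic fit constrained to an ellipse, converted to
#' geometric parameters.
#'
#' @param x,y Point coordinates (>= 6 points).
#' @return An object of class `ellipse_fit`: list with `center` (2-vector),
#'   `semi_axes` (major, minor), `angle` (degrees, in (-90, 90]) and the
#'   conic coefficients.
#' @export
fit_ellipse <- function(x, y) {
  co <- fit_ellipse_conic(x, y)
  geo <- conic_to_ellipse(co)
  structure(c(geo, list(conic = co)), class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse: center (%.2f, %.2f), semi-axes %.2f x %.2f, angle %.1f deg>\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2], x$angle))
  invisible(x)
}

#' Points on an ellipse
#' @param e An `ellipse_fit` (or compatible list).
#' @param n Number of points.
#' @return An `n x 2` matrix of (x, y) points on the ellipse.
#' @export
ellipse_points <- function(e, n = 360) {
  t <- seq(0, 2 * pi, length.out = n)
  a <- e$angle * DEG
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  xy <- cbind(e$semi_axes[1] * cos(t), e$semi_axes[2] * sin(t)) %*% t(R)
  sweep(xy, 2, e$center, "+")
}

# Signed "inside" measure: < 1 inside the ellipse, 1 on it, > 1 outside.
ellipse_level <- function(e, x, y) {
  a <- e$angle * DEG
  dx <- x - e$center[1]
  dy <- y - e$center[2]
  u <- dx * cos(a) + dy * sin(a)
  v <- -dx * sin(a) + dy * cos(a)
  (u / e$semi_axes[1])^2 + (v / e$semi_axes[2])^2
}

#' Elliptical conformational subspace of the early-stage model
#'
#' Scans a (phi, psi) grid over the full Ramachandran domain, keeps the
#' conformations whose (V, lnR) lies within `tolerance` (along lnR) of the
#' calibrated polynomial, and fits an ellipse to the retained (phi, psi)
#' points.
#'
#' @param cal An [es_calibration()].
#' @param tolerance Maximum |lnR - lnR_pred(V)| for a grid point to be
#'   retained (ln-Angstrom units, default 0.5).
#' @param step Grid step in degrees (default 5).
#' @return An object of class `ellipse_subspace`: the `ellipse_fit` plus the
#'   retained points in `$points` (data.frame `phi`, `psi`, `V`, `lnR`).
#' @export
ellipse_subspace <- function(cal, tolerance = 0.5, step = 5) {
  grid <- expand.grid(phi = seq(-180, 180, by = step),
                      psi = seq(-180, 180, by = step))
  vl <- t(mapply(conformation_v_lnr, grid$phi, grid$psi,
                 MoreArgs = list(chain_length = 5L)))
  keep <- abs(vl[, 2] - predict(cal, vl[, 1])) <= tolerance
  pts <- data.frame(phi = grid$phi[keep], psi = grid$psi[keep],
                    V = vl[keep, 1], lnR = vl[keep, 2])
  if (nrow(pts) < 6) stop("cannot fit ellipse: fewer than 6 retained points")
  fit <- fit_ellipse(pts$phi, pts$psi)
  structure(c(unclass(fit), list(points = pts, tolerance = tolerance)),
            class = c("ellipse_subspace", "ellipse_fit"))
}
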