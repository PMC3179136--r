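# Internal 3D geometry helpers shared by the backbone builder, the V-angle
# and the curvature fit. All angles at this level are in degrees.

DEG <- pi / 180

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

# Unsigned angle between two vectors, degrees in [0, 180].
angle_between <- function(a, b) {
  ct <- sum(vunit(a) * vunit(b))
  acos(max(-1, min(1, ct))) / DEG
}

# Signed dihedral p1-p2-p3-p4 (IUPAC convention), degrees in (-180, 180].
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) / DEG
}

# NeRF atom placement: position atom D bonded to C, with bond length |CD|,
# bond angle B-C-D and torsion A-B-C-D (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * DEG
  ph <- -torsion * DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

# Uniform random rotation matrix (used by property tests and invariance checks).
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(m)
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Least-squares circle through 2D points: Pratt's algebraic fit
# (A(x^2+y^2) + Bx + Cy + D = 0 with B^2 + C^2 - 4AD = 1), which degrades
# gracefully to a line (A -> 0, radius -> Inf) for near-collinear traces,
# followed by geometric refinement of the center when the arc is genuinely
# curved. Returns list(center, radius); radius may be Inf.
fit_circle_2d <- function(xy, refine = TRUE) {
  x <- xy[, 1] - mean(xy[, 1])
  y <- xy[, 2] - mean(xy[, 2])
  Z <- cbind(x^2 + y^2, x, y, 1)
  M <- crossprod(Z)
  Pinv <- matrix(c(0, 0, 0, -0.5,
                   0, 1, 0, 0,
                   0, 0, 1, 0,
                   -0.5, 0, 0, 0), 4, 4)
  ev <- eigen(Pinv %*% M)
  real <- abs(Im(ev$values)) < 1e-8 * (1 + abs(Re(ev$values)))
  vals <- Re(ev$values)
  ok <- which(real & vals > -1e-9 * max(1, abs(vals)))
  if (!length(ok)) return(list(center = c(mean(xy[, 1]), mean(xy[, 2])), radius = Inf))
  v <- Re(ev$vectors[, ok[which.min(vals[ok])]])
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]
  disc <- B^2 + C^2 - 4 * A * D
  if (abs(A) < 1e-12 || disc <= 0) {
    return(list(center = c(mean(xy[, 1]), mean(xy[, 2])), radius = Inf))
  }
  ctr <- c(-B, -C) / (2 * A)
  r <- sqrt(disc) / (2 * abs(A))
  if (refine && is.finite(r) && r < 1e6) {
    obj <- function(p) {
      d <- sqrt((x - p[1])^2 + (y - p[2])^2)
      sum((d - mean(d))^2)
    }
    opt <- stats::optim(ctr, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 500))
    if (opt$value <= obj(ctr)) ctr <- opt$par
    r <- mean(sqrt((x - ctr[1])^2 + (y - ctr[2])^2))
  }
  list(center = ctr + c(mean(xy[, 1]), mean(xy[, 2])), radius = r)
}
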