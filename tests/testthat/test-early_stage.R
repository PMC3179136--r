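test_that("V-angle limits: near 0 for helices, near 180 for extended chains", {
  h <- build_backbone(20, "helix")
  vh <- sapply(1:18, function(i) v_angle(h, i))
  expect_true(all(vh >= 0 & vh <= 180))
  expect_true(all(vh < 30))

  e <- build_backbone(20, "extended")
  ve <- sapply(1:18, function(i) v_angle(e, i))
  expect_true(all(ve > 150))

  # two identically oriented peptide planes (translated copies) -> 0 degrees
  s <- structure_from_ca(matrix(0, 3, 3))
  t <- c(3, 0, 0)
  s$ca[1, ] <- c(0, 0, 0);  s$c[1, ] <- c(1.5, 0.3, 0)
  s$o[1, ] <- c(1.5, 1.5, 0.3)
  s$n[2, ] <- s$c[1, ] + c(1.3, -0.2, 0)
  s$ca[2, ] <- s$ca[1, ] + t; s$c[2, ] <- s$c[1, ] + t; s$o[2, ] <- s$o[1, ] + t
  s$n[3, ] <- s$n[2, ] + t
  expect_equal(v_angle(s, 1), 0, tolerance = 1e-9)
})

test_that("chain breaks are detected by the peptide-bond distance", {
  h <- build_backbone(12, "helix")
  broken <- transform_structure(h, diag(3))
  shift <- c(50, 0, 0)
  for (i in 7:12) {
    broken$n[i, ] <- broken$n[i, ] + shift
    broken$ca[i, ] <- broken$ca[i, ] + shift
    broken$c[i, ] <- broken$c[i, ] + shift
    broken$o[i, ] <- broken$o[i, ] + shift
  }
  expect_error(v_angle(broken, 6), "chain break")
  prof <- es_profile(broken, exact_cal())
  expect_equal(nrow(prof$windows), 8)
  # windows 3..6 span the 6|7 break and are skipped
  expect_equal(which(prof$windows$skipped), 3:6)
  expect_false(anyNA(prof$d_average))
})

test_that("curvature: exact circles recovered, straight traces capped", {
  # five points on a circle of radius 2.27, nudged out of plane by < 1e-6
  th <- seq(0, 4.2, length.out = 5)
  ca <- cbind(2.27 * cos(th) + 5, 2.27 * sin(th) - 3, 1e-7 * c(1, -1, 1, -1, 1))
  s <- structure_from_ca(ca)
  expect_equal(radius_of_curvature(s, 1, smooth = FALSE), log(2.27),
               tolerance = 1e-6)

  # exactly collinear CA trace -> capped radius
  s2 <- structure_from_ca(cbind(3.8 * (0:4), 0, 0))
  expect_equal(radius_of_curvature(s2, 1, smooth = FALSE), log(1e4))
  expect_equal(radius_of_curvature(s2, 1), log(1e4))

  # helical window: small radius on the helix scale
  h <- build_backbone(10, "helix")
  expect_lt(exp(radius_of_curvature(h, 1)), 10)

  expect_error(radius_of_curvature(h, 7), "window")
})

test_that("V-angle and lnR are invariant under rigid motions", {
  s <- build_backbone(12, "custom", phi = c(-57, -60, -75, -139, -60, -57,
                                            -80, -119, -57, -65, -70, -57),
                      psi = c(-47, -40, 145, 135, -40, -47,
                              120, 113, -47, -35, -45, -47))
  v0 <- sapply(1:10, function(i) v_angle(s, i))
  r0 <- sapply(1:8, function(w) radius_of_curvature(s, w))
  set.seed(11)
  for (k in 1:25) {
    R <- fodes:::random_rotation()
    s2 <- transform_structure(s, R, rnorm(3, 0, 20))
    expect_equal(sapply(1:10, function(i) v_angle(s2, i)), v0, tolerance = 1e-8)
    expect_equal(sapply(1:8, function(w) radius_of_curvature(s2, w)), r0,
                 tolerance = 1e-6)
  }
})

test_that("analytic calibration is a rising quadratic and refits idempotently", {
  cal <- cached_cal()
  expect_s3_class(cal, "es_calibration")
  expect_named(cal$coefficients, c("a2", "a1", "a0"))
  expect_identical(cal$provenance, "analytic-grid")
  # helical end lies below the extended end
  expect_lt(predict(cal, 5), predict(cal, 175))
  # the point cloud covers both ends of the V range
  expect_lt(min(cal$points$V), 30)
  expect_gt(max(cal$points$V), 150)

  # refitting the polynomial on its own sampled curve reproduces it
  v <- seq(0, 180, by = 1)
  co <- cal$coefficients
  y <- co[["a2"]] * v^2 + co[["a1"]] * v + co[["a0"]]
  refit <- lm(y ~ v + I(v^2))
  expect_equal(unname(coef(refit)[c("I(v^2)", "v", "(Intercept)")]),
               unname(co), tolerance = 1e-9)

  expect_error(calibrate_analytic(regions = list()), "empty region")
})

test_that("es_profile bookkeeping: window count, flags, D_average", {
  cal <- exact_cal()
  h <- build_backbone(20, "helix")
  prof <- es_profile(h, cal)
  expect_equal(nrow(prof$windows), 20 - 4)
  expect_equal(prof$windows$central_residue, 3:18)
  expect_equal(prof$d_average,
               mean(prof$windows$deviation[!prof$windows$skipped]))
  expect_identical(prof$windows$deviant, prof$windows$deviation > 1)
  expect_gte(prof$d_average, 0)
  expect_error(es_profile(structure_from_ca(matrix(0, 4, 3)), cal), ">= 5")
})

test_that("a chain built on the calibration curve has zero deviation", {
  cal <- exact_cal()
  for (pp in exact_cal_conformations) {
    s <- build_backbone(15, "custom", phi = pp[1], psi = pp[2])
    expect_lt(es_profile(s, cal)$d_average, 1e-6)
  }
})

test_that("calibration coefficients round-trip through the text format", {
  cal <- exact_cal()
  tf <- withr::local_tempfile(fileext = ".txt")
  write_calibration(cal, tf)
  cal2 <- suppressWarnings(read_calibration(tf))
  expect_equal(cal2$coefficients, cal$coefficients, tolerance = 1e-10)
})

test_that("ellipse fitting recovers synthetic ellipses exactly", {
  t <- seq(0, 2 * pi, length.out = 40)[-40]
  a <- 50; b <- 20; ang <- 30 * pi / 180; ctr <- c(10, -20)
  x <- ctr[1] + a * cos(t) * cos(ang) - b * sin(t) * sin(ang)
  y <- ctr[2] + a * cos(t) * sin(ang) + b * sin(t) * cos(ang)
  fit <- fit_ellipse(x, y)
  expect_equal(unname(fit$center), ctr, tolerance = 1e-6)
  expect_equal(unname(fit$semi_axes), c(a, b), tolerance = 1e-6)
  expect_equal(fit$angle, 30, tolerance = 1e-6)
  expect_error(fit_ellipse(x[1:4], y[1:4]), "fewer than 6")
})

test_that("the elliptical subspace retains on-curve points and spans the helical basin", {
  es <- ellipse_subspace(cached_cal(), tolerance = 0.5, step = 10)
  cal <- cached_cal()
  # filter definition honored
  expect_true(all(abs(es$points$lnR - predict(cal, es$points$V)) <= 0.5))
  expect_gte(nrow(es$points), 6)
  # fitted ellipse stays within the Ramachandran domain
  pts <- ellipse_points(es)
  expect_true(all(abs(pts) <= 180 + 1e-6))
  # the right-handed helical basin intersects the ellipse interior
  expect_lt(fodes:::ellipse_level(es, -57, -47), 1)
})
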