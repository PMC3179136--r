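test_that("orientation implements the one-third-extent sigma rule", {
  # two atoms 9 A apart end up on the x axis with sigma_x = 3
  two <- matrix(c(0, 0, 0, 9, 0, 0), 2, 3, byrow = TRUE)
  expect_warning(o <- orient(two), "floored")
  expect_equal(unname(o$gauss$sigma[["x"]]), 3)
  expect_lt(max(abs(o$atoms[, 2:3])), 1e-9)

  # coincident atoms are degenerate
  expect_error(orient(matrix(1, 5, 3)), "degenerate")
})

test_that("orientation is rotation invariant and idempotent up to axis sign", {
  set.seed(5)
  P <- cbind(rnorm(40, 0, 10), rnorm(40, 0, 6), rnorm(40, 0, 3))
  base <- orient(P)
  for (k in 1:20) {
    R <- fodes:::random_rotation()
    o2 <- orient(sweep(P %*% R, 2, rnorm(3, 0, 15), "+"))
    expect_equal(unname(o2$gauss$sigma), unname(base$gauss$sigma),
                 tolerance = 1e-6)
  }
  # already centered and axis-aligned input comes back unchanged up to sign
  Q <- base$atoms
  o3 <- orient(Q)
  expect_equal(abs(o3$atoms), abs(Q), tolerance = 1e-9)
})

test_that("theoretical distribution: Gaussian mode, symmetry, uniformity", {
  g <- list(sigma = c(4, 3, 2))
  atoms <- rbind(c(0, 0, 0), c(3, 1, -1), c(-3, -1, 1), c(5, 2, 0))
  Td <- theoretical_distribution(atoms, g)
  expect_equal(sum(Td), 1, tolerance = 1e-12)
  expect_equal(which.max(Td), 1)           # center attains the maximum
  expect_equal(Td[[2]], Td[[3]], tolerance = 1e-12)  # mirror symmetry

  # sign-flip shell: all eight points share |x|,|y|,|z| -> uniform 1/8
  sh <- as.matrix(expand.grid(c(-1, 1), c(-2, 2), c(-3, 3)))
  Tu <- theoretical_distribution(sh, g)
  expect_equal(as.numeric(Tu), rep(1 / 8, 8), tolerance = 1e-12)

  expect_error(theoretical_distribution(atoms, list(sigma = c(1, 0, 1))),
               "sigma")
})

test_that("Levitt kernel endpoints and continuity at the cutoff", {
  expect_identical(levitt_kernel(0), 1)
  expect_identical(levitt_kernel(9), 0)
  expect_identical(levitt_kernel(12), 0)
  expect_lt(levitt_kernel(9 - 1e-5), 1e-4)
  expect_true(all(diff(levitt_kernel(seq(0, 9, by = 0.01))) < 0))
})

test_that("observed distribution matches hand values and a naive oracle", {
  sc <- hydrophobicity_scale()
  mk <- function(pos, h) {
    data.frame(index = seq_along(h), resid = "ALA",
               x = pos[, 1], y = pos[, 2], z = pos[, 3], h = h)
  }
  # two residues beyond the cutoff: self-terms only
  a2 <- mk(rbind(c(0, 0, 0), c(20, 0, 0)), c(0.3, 0.9))
  expect_equal(as.numeric(observed_distribution(a2)),
               c(0.3, 0.9) / 1.2, tolerance = 1e-12)

  # identical values, all pairs beyond the cutoff -> uniform
  far <- mk(cbind(seq(0, 120, by = 30), 0, 0), rep(0.5, 5))
  expect_equal(as.numeric(observed_distribution(far)), rep(0.2, 5))

  # naive double-loop reference, exact agreement for small N
  naive_o <- function(atoms, c = 9) {
    P <- as.matrix(atoms[, c("x", "y", "z")])
    n <- nrow(P)
    o <- numeric(n)
    for (j in 1:n) {
      for (i in 1:n) {
        r <- sqrt(sum((P[i, ] - P[j, ])^2))
        o[j] <- o[j] + (atoms$h[i] + atoms$h[j]) * levitt_kernel(r, c)
      }
    }
    o / sum(o)
  }
  set.seed(21)
  for (n in 2:6) {
    a <- mk(matrix(rnorm(3 * n, 0, 5), n, 3), runif(n))
    expect_equal(as.numeric(observed_distribution(a)), naive_o(a),
                 tolerance = 1e-14)
  }

  # the self-term switch removes 2 H_j from each residue's sum
  a3 <- mk(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), c(0.2, 0.5, 0.8))
  o_with <- observed_distribution(a3)
  o_without <- observed_distribution(a3, exclude_self = TRUE)
  expect_false(isTRUE(all.equal(as.numeric(o_with), as.numeric(o_without))))

  a3$h[1] <- -0.1
  expect_error(observed_distribution(a3), "negative")
})

test_that("random reference is uniform", {
  expect_equal(as.numeric(random_distribution(4)), rep(0.25, 4))
  expect_equal(as.numeric(random_distribution(1)), 1)
  expect_equal(sum(random_distribution(37)), 1, tolerance = 1e-12)
  expect_error(random_distribution(0), "n must be")
})

test_that("KL divergence: worked values, identity, positivity, support", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)),
               0.5 * log2(2) + 0.5 * log2(2 / 3), tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.25, 0.75)), 0.2075,
               tolerance = 1e-4)
  expect_identical(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  expect_identical(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)

  set.seed(9)
  for (k in 1:200) {
    n <- sample(3:30, 1)
    p <- rexp(n); p <- p / sum(p)
    q <- rexp(n); q <- q / sum(q)
    expect_gte(kl_divergence(p, q), 0)
  }
  expect_error(kl_divergence(c(1, 0), c(0.5, 0.5, 0)), "length")
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "unsupported support")
})

test_that("fod_analysis composes the pipeline and is rigid-motion invariant", {
  g <- build_toy_globule(50, 0.4, seed = 7)
  r <- fod_analysis(g)
  expect_equal(sum(r$residues$T), 1, tolerance = 1e-9)
  expect_equal(sum(r$residues$O), 1, tolerance = 1e-9)
  expect_equal(sum(r$residues$R), 1, tolerance = 1e-9)
  expect_equal(sum(r$residues$kl_term), r$o_t, tolerance = 1e-12)
  expect_identical(r$accordant, r$o_t < r$o_r)
  expect_identical(r$residues$accordant,
                   abs(r$residues$kl_term) < r$residue_threshold)

  set.seed(3)
  for (k in 1:10) {
    g2 <- transform_structure(g, fodes:::random_rotation(), rnorm(3, 0, 40))
    r2 <- fod_analysis(g2)
    expect_equal(r2$o_t, r$o_t, tolerance = 1e-6)
    expect_equal(r2$o_r, r$o_r, tolerance = 1e-6)
  }
})

test_that("designed hydrophobic cores are accordant; inverted ones are not", {
  for (sd in c(2, 5)) {
    expect_true(fod_analysis(build_toy_globule(60, 0.4, seed = sd))$accordant)
    expect_false(
      fod_analysis(build_toy_globule(60, 0.4, seed = sd, invert = TRUE))$accordant)
  }
})
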