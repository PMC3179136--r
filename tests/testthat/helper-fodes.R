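# Shared fixtures for the test suite. Everything is generated in code; the
# only packaged data is the hydrophobicity scale table.

.test_env <- new.env()

# Analytic calibration on a coarser grid than the package default: the same
# construction, sampled at 4 degrees, which is plenty for structural tests.
cached_cal <- function() {
  if (is.null(.test_env$cal)) {
    .test_env$cal <- calibrate_analytic(step = 4)
  }
  .test_env$cal
}

# Exact quadratic through the (V, lnR) points of three reference
# conformations: any chain built at one of these dihedral pairs lies exactly
# on this calibration curve.
exact_cal_conformations <- list(c(-57, -47), c(-49, -26), c(-75, 145))

exact_cal <- function() {
  if (is.null(.test_env$exact_cal)) {
    vl <- t(sapply(exact_cal_conformations, function(pp) {
      fodes:::conformation_v_lnr(pp[1], pp[2], chain_length = 20L)
    }))
    co <- solve(cbind(vl[, 1]^2, vl[, 1], 1), vl[, 2])
    .test_env$exact_cal <- suppressWarnings(
      es_calibration(co[1], co[2], co[3], provenance = "user-supplied")
    )
  }
  .test_env$exact_cal
}

# Minimal fod_structure directly from a CA coordinate matrix (other backbone
# atoms absent); enough for curvature fits and effective-atom geometry.
structure_from_ca <- function(ca, resid = rep("ALA", nrow(ca))) {
  n <- nrow(ca)
  na <- matrix(NA_real_, n, 3)
  fodes:::new_fod_structure(
    "A", seq_len(n), rep("", n), resid,
    n = na, ca = ca, c = na, o = na,
    sc = replicate(n, matrix(numeric(0), 0, 3), simplify = FALSE),
    atoms = data.frame(resindex = seq_len(n), elety = "CA",
                       x = ca[, 1], y = ca[, 2], z = ca[, 3], elesy = "C",
                       stringsAsFactors = FALSE)
  )
}

# Apply a rigid motion (rotation matrix + translation) to every coordinate
# block of a structure.
transform_structure <- function(s, R, tr = c(0, 0, 0)) {
  mv <- function(m) {
    out <- m
    ok <- !apply(m, 1, anyNA)
    out[ok, ] <- sweep(m[ok, , drop = FALSE] %*% R, 2, tr, "+")
    out
  }
  s$n <- mv(s$n); s$ca <- mv(s$ca); s$c <- mv(s$c); s$o <- mv(s$o)
  s$sc <- lapply(s$sc, function(m) {
    if (nrow(m)) sweep(m %*% R, 2, tr, "+") else m
  })
  xyz <- sweep(as.matrix(s$atoms[, c("x", "y", "z")]) %*% R, 2, tr, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# A hand-written PDB fixture exercising altlocs (B has higher occupancy),
# an MSE hetero residue and a water; written to `path`.
write_altloc_fixture <- function(path) {
  fmt <- function(serial, name, alt, resid, chain, resno, x, y, z, occ,
                  type = "ATOM", elesy = substr(name, 1, 1)) {
    sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, sprintf(" %-3s", name), alt, resid, chain, resno,
            x, y, z, occ, 0, elesy)
  }
  lines <- c(
    fmt(1, "N", " ", "ALA", "A", 1, 0, 0, 0, 1),
    fmt(2, "CA", "A", "ALA", "A", 1, 1.458, 0, 0, 0.4),
    fmt(3, "CA", "B", "ALA", "A", 1, 1.458, 0.5, 0, 0.6),
    fmt(4, "C", " ", "ALA", "A", 1, 2.0, 1.4, 0, 1),
    fmt(5, "O", " ", "ALA", "A", 1, 1.5, 2.5, 0, 1),
    fmt(6, "CB", " ", "ALA", "A", 1, 2.0, -1.2, 0.8, 1),
    fmt(7, "N", " ", "MSE", "A", 2, 3.3, 1.4, 0, 1, type = "HETATM"),
    fmt(8, "CA", " ", "MSE", "A", 2, 4.2, 2.5, 0, 1, type = "HETATM"),
    fmt(9, "C", " ", "MSE", "A", 2, 5.6, 2.0, 0, 1, type = "HETATM"),
    fmt(10, "O", " ", "MSE", "A", 2, 6.0, 0.9, 0, 1, type = "HETATM"),
    fmt(11, "SE", " ", "MSE", "A", 2, 4.4, 3.9, 1.2, 1, type = "HETATM",
        elesy = "SE"),
    fmt(12, "O", " ", "HOH", "A", 101, 9, 9, 9, 1, type = "HETATM"),
    "TER", "END"
  )
  writeLines(lines, path)
  path
}
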