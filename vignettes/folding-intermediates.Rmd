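---
title: "Methods: early-stage geometry and the fuzzy oil drop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early-stage geometry and the fuzzy oil drop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fodes)
```

This vignette is the package's account of its science: the two models it
implements, the parameters that matter, the numerical choices behind the
implementation, and what the synthetic fixtures do and do not demonstrate.

## The two-step picture

The folding pathway is compressed into two intermediates. The early stage
(ES) is assumed to be determined by backbone conformational preferences
alone; the late stage (LS) adds the influence of water, modelled as an
external hydrophobic field that drives hydrophobic side chains inward and
polar ones outward. The package scores any single-chain structure against
both idealizations; neither stage involves simulation — both are purely
analytical measurements on coordinates.

## Early-stage geometry

A chain fragment is described by two parameters: the tilt **V** between
sequential peptide bond planes and the radius of curvature **R** of its
pentapeptide CA trace, used as ln R.

**Defining V.** The literature defines V only verbally ("the dihedral angle
between two sequential peptide bond planes", near 0° for helices and 180°
for extended forms). The geometrically obvious candidate — the angle
between the plane normals, with the normal taken from cross products of the
in-plane bond vectors — does *not* satisfy those limits: for an ideal
α-helix successive peptide planes are rotated ≈100° about the helix axis,
so the normal-to-normal angle is ≈99°, nowhere near 0°. What does behave as
required is the *torsion* between the planes measured about the axis
joining their carbonyl carbons, with each plane's orientation fixed by its
in-plane C=O vector: `V(i) = |dihedral(O(i), C(i), C(i+1), O(i+1))|`. This
gives ≈18° for the ideal helix (φ, ψ = −57°, −47°), exactly 180° for the
fully extended chain, and ≈179° across the β basin — the stated limits. It
is the definition `v_angle()` implements; values are folded into [0°, 180°]
because the classification uses magnitude only.

**Defining ln R.** The CA trace of any regular conformation is a helix that
zig-zags about the chain axis. Fitting a circle directly through five raw
CA positions therefore measures the zig-zag, not the chain: a fully
extended (straight) chain would get R ≈ 42 Å rather than the "theoretically
infinite" radius the model assigns it. `radius_of_curvature()` consequently
smooths the window to its four consecutive CA–CA midpoints first. For a
conformation with local screw symmetry the midpoints lie exactly on the
screw axis, so the extended chain's midpoint trace is exactly collinear and
its radius diverges, while a helix keeps a small finite radius (≈2.4 Å for
the ideal α-helix window). The divergence is made finite by capping R at
10⁴ Å before the log (ln R = 9.21); polynomial predictions are clamped to
the same cap so that near-straight fragments sitting at the cap are not
scored as deviant against an unbounded extrapolation. `smooth = FALSE`
restores the raw five-point fit, which recovers points lying on a true
circle exactly.

**Circle fitting.** The smoothed points are projected onto their best-fit
plane (SVD; smallest principal direction removed) and a circle is fitted
with Pratt's algebraically constrained least squares, followed by a
geometric (Nelder-Mead) refinement of the center when the fitted radius is
below 10⁶ Å. Pratt's fit is used instead of the simpler Kåsa fit because it
degrades gracefully to a line for near-collinear traces; Kåsa collapses to
a spuriously small circle on symmetric zig-zag residuals, which is exactly
the data this method produces for extended fragments.

**Calibration.** The coefficients of `lnR_pred(V) = a2·V² + a1·V + a0` are
not tabulated anywhere usable, so `calibrate_analytic()` regenerates them
from first principles: ideal-geometry poly-ALA 20-mers are built at
constant (φ, ψ) over rectangles covering the low-energy Ramachandran
basins — right-handed α (φ ∈ [−90, −40], ψ ∈ [−70, −10]), β (φ ∈ [−170,
−70], ψ ∈ [100, 180]) and the left-handed α mirror (φ ∈ [40, 90], ψ ∈ [10,
70]) — at a 2° step (3703 conformations), and the quadratic is
least-squares fitted to the (V, lnR) cloud. Because the β basin saturates
at the radius cap, the cloud is sigmoid-like and the quadratic is a
compromise fit; this is inherent to prescribing a second-degree polynomial
on a saturating relation, and it is why externally calibrated coefficients
can be loaded via `read_calibration()` (or passed to `es_calibration()`)
when exact replication of another group's curve is needed. Tests use a 4°
step — the same construction, cheaper — plus an *exact* calibration drawn
through three conformations, for which a chain built at any of those
dihedrals must give `D_average = 0` to machine precision.

**Scoring.** Each pentapeptide window contributes `|lnR_obs − lnR_pred(V)|`
with V taken from the window's central peptide-plane pair (bonds 2–3 and
3–4 of the window — the symmetric choice; the sources do not specify the
pairing). The deviation is measured along the lnR axis only, not as
Euclidean distance in the (V, lnR) plane, matching how deviant residues are
flagged in the source analyses; `D_average` is the mean over valid windows
and windows with deviation > 1 ln-Å unit are flagged deviant. Windows
spanning a chain break (C–N peptide bond longer than 2.5 Å) are skipped and
reported, not silently dropped, so window bookkeeping (N − 4 windows for an
unbroken N-residue chain) stays auditable.

**The elliptical subspace.** `ellipse_subspace()` scans the full
Ramachandran grid, retains conformations within a tolerance (default
0.5 ln-Å) of the calibration curve, and fits a direct least-squares conic
constrained to an ellipse (the numerically stable Halir–Flusser
formulation). On synthetic points from a known ellipse the fit is exact to
1e-6; on the retained grid it produces a tilted ellipse through the α, β
and left-handed-α basins, the proposed ES conformational subspace.

## The fuzzy oil drop

**Effective atoms.** Each residue becomes one point: the unweighted mean of
its side-chain heavy atoms, or CA when the side chain is empty (GLY,
CA-only pseudo-structures). Hydrogens never enter the average — crystal
structures rarely carry them, and including them when present would
silently shift centers. An `all-atom` mode (backbone included) is kept as a
switch because the sources do not state which convention produced their
numbers.

**Hydrophobicity scale.** The packaged table is the Aboderin
chromatographic-mobility scale, min-max normalized to [0, 1] (CYS = 0,
LEU = 1). The scale is a plain-text two-column file and any alternative in
the same format can be passed to `hydrophobicity_scale()`.

**Orientation and σ.** The effective atoms are centered on their geometric
mean and rotated onto the principal axes of their covariance; axes are
ordered by coordinate extent (not eigenvalue) and each axis's sign is fixed
by making its largest-magnitude coordinate positive, so the result is
deterministic and rigid-motion invariant. σ per axis is one third of the
coordinate range — equivalently ⅓ of the longest pairwise distance
projected on that axis. Degenerate geometries: coincident points are an
error; flat or linear clouds get their small σs floored at 1 Å with a
warning rather than an error, since a two-point "molecule" is still a
well-posed test case for the ⅓ rule.

**Distributions and divergence.** T is the 3D Gaussian evaluated at the
oriented effective atoms; O is Levitt's pairwise function with the original
9 Å cutoff — the kernel satisfies B(0) = 1 and B(9) = 0 exactly, so O is
continuous as atoms cross the shell; R is uniform 1/N, the maximum-entropy
reference (the sources never define "random distribution" numerically;
uniform is the standard realization). The self-term i = j is included in
the Levitt sum, as the summation bound Σᵢ₌₁ᴺ implies (a switch removes it
for sensitivity analysis). All three are normalized to sum to 1; KL
divergence uses log base 2 (bits) with the 0·log 0 := 0 convention, erroring
if the reference is zero where the observation is not — T and R are
strictly positive, so this can only happen with user-supplied references.
The per-residue accordance flag uses |Oᵢ log2(Oᵢ/Tᵢ)| < 0.01 bits; the
absolute value is a package choice, since a residue can miss the ideal in
either direction.

## What the synthetic fixtures show — and what they don't

`build_backbone()` produces ideal-geometry poly-ALA chains (N–CA 1.458 Å,
CA–C 1.525 Å, C–N 1.329 Å, trans ω; constants in one table,
`IDEAL_GEOMETRY`) at exact dihedrals, so the geometric limits of the ES
model (helix V < 30°, R < 10 Å; extended V > 150°, R at cap) are
construction-verifiable. `build_toy_globule()` samples an anisotropic
Gaussian cloud (axis SDs 12, 9, 6 Å — a modest protein-sized ellipsoid) and
assigns LEU (h = 1) to the elliptically-nearest fraction of points and ASN
(h = 0.06) to the rest; by construction its observed distribution should
track the Gaussian ideal, and swapping identities should break that. The
test suite verifies both directions across ten seeds at n = 60 residues and
core fraction 0.4.

These fixtures validate the *machinery*, not the biology: real side chains
are not points drawn from the field they are scored against, real
hydrophobicity is not binary, and real backbones have non-ideal geometry,
cis prolines and breaks. Passing the synthetic suite therefore shows the
estimators are correct and invariant, not that any particular protein is an
ES or LS intermediate. The published reference comparison (the engrailed
homeodomain 1ENH and its L16A mutant 1ZTR) requires the experimental
coordinates, which are not redistributed with the package; the
corresponding test and acceptance-script entries activate when the files
are placed under `inst/extdata/reference/`. Exact-digit reproduction of
externally published D_average values additionally depends on the
unpublished calibration coefficients discussed above, which is why the
reference comparison uses tolerance bands and treats the qualitative
verdicts (which core is accordant, which chain is more ES-like) as the
decisive check.

## Problem sizes and runtime choices

The default calibration samples 3703 conformations of 20 residues and takes
on the order of ten seconds; it is computed once per session and cached
(`default_calibration()`). The subspace scan uses pentapeptides (the
central-window geometry of a constant-dihedral chain is length-invariant)
at a 5–10° grid. Property tests run 100 random rigid motions of a
45-residue globule and 1000 random divergence pairs; all sizes were chosen
so the full suite exercises every invariant in well under test-budget
scale while remaining statistically meaningful.

## Known limitations

- Single chain per analysis; no NMR ensemble averaging (one model index is
  selected), no mmCIF beyond what bio3d provides.
- Non-standard residues other than MSE (mapped to MET) are rejected rather
  than skipped, deliberately: silent skipping would shift pentapeptide
  windows.
- The quadratic calibration is a compromise on a saturating (V, lnR)
  relation, as discussed; D_average values are therefore comparable within
  one calibration but not across differently sourced calibrations.
- Sequence-based prediction of ES conformations and folding simulation
  under the hydrophobic field are out of scope; the package measures
  accordance of given coordinates.
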