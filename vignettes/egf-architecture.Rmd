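---
title: "Determining tandem EGF-domain architecture: models, conventions and choices"
author: "egfarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining tandem EGF-domain architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfarch)
```

# The problem

Receptors such as Notch present dozens of tandem EGF-like domains to the
extracellular space. Whether such a region behaves as a rigid rod, a bent
but rigid shape, or a chain with flexible joints is determined domain pair
by domain pair: a Ca²⁺-loaded cbEGF domain packs against its preceding
neighbour to form a rigid interface, while non-calcium-binding domains can
produce either a rigid bent interface or a genuinely flexible linkage.
No single experiment settles this. `egfarch` implements the four analysis
stages that together do: calcium-affinity measurement, fast-dynamics
mapping, residual-dipolar-coupling (RDC) tensor analysis, and rigid-body
geometry, plus a generator of synthetic inputs with known ground truth.

# Calcium binding

## Competition model

The chromophoric chelator (5,5′-Br₂BAPTA, K_d = 1.6 µM in the working
buffer) and the protein sites compete for a common free-calcium pool. For
total site concentrations $T_i$ and dissociation constants $K_i$, free
calcium $f$ solves

$$\mathrm{Ca}_{tot} = f + \sum_i \frac{T_i\, f}{f + K_i},$$

a monotone scalar equation solved by bracketed root-finding with Newton
polishing to better than $10^{-12}$ relative accuracy
(`solveFreeCa()`). The normalized absorbance signal is the Ca-free
chelator fraction $K_Q/(f+K_Q)$: 1 with no calcium, 0 at saturation, and
strictly decreasing in between. `fitCompetition()` minimizes the residual
sum of squares over log₁₀ K_d by Levenberg–Marquardt (via `minpack.lm`)
from five log-spaced starts, because the SSE surface is shallow whenever a
protein K_d sits near the chelator's. Standard errors come from the local
curvature; the two-site model uses two independent sites, each at the
protein total (the constructs of interest carry distinct sites on
different domains, not cooperative pairs). Model order is chosen by the F
test

$$F = \frac{(SSE_1 - SSE_2)/(p_2-p_1)}{SSE_2/(n-p_2)},$$

selecting two sites only when $p < \alpha$ (default 0.05).

Fits are flagged *ill-determined* when a K_d standard error exceeds the
estimate or the K_d lands beyond the highest total calcium titrated; the
competition method is only informative for K_d within roughly 1–20 µM, and
the flag makes that working-range limit explicit rather than silently
reporting an extrapolated number.

Signals are expected normalized to 1…0. Raw absorbance endpoints should be
normalized before fitting; the endpoint-nuisance variant is not
implemented, which keeps the parameter count of each model equal to its
number of sites.

## NMR titrations

Weaker sites (tens of µM to tens of mM) are fitted from a fast-exchange
observable proportional to the bound fraction, with ligand depletion
handled exactly through the quadratic solution for the bound complex
(`fitNMRTitration()`, parameters: amplitude and K_d). A curve with no
curvature in the sampled range is flagged rather than fitted.
`occupancy()` is the one-line saturation arithmetic: a 170 µM site is
89.2% occupied at 1.4 mM free Ca²⁺, a 60 µM site 95.9% — which is what
makes measured affinities in this range physiologically saturating.

# Heteronuclear NOE

`computeHetNOE()` forms the saturated/reference ratio per residue and
propagates the baseline noise by Monte Carlo: both peak heights are
resampled independently (they come from separate experiments) with
Gaussian noise of the baseline sd, 500 resamples by default, seeded and
reproducible. The Monte Carlo spread converges to the first-order
propagation value $ratio\sqrt{(\sigma/I_{sat})^2 + (\sigma/I_{ref})^2}$.
Residues with $|I_{ref}| < 3\sigma$ are flagged unreliable.

`flagFlexible()` calls a residue mobile when even the upper end of its
ratio ($ratio + \sigma$) stays below a threshold, and a linker
fast-flexible when any of its residues is mobile. The threshold default of
0.65 is a documented package choice, not a literature constant: it
separates a rigid-domain plateau near 0.78 from mobile termini and loops
near 0.3 with margin on both sides at typical noise levels. It is
configurable, and verdicts are invariant under uniform intensity
rescaling.

# RDC tensor analysis

## Conventions

A single set of conventions is applied everywhere, because the
flexibility test compares D_a values *including sign* between fits:

* Saupe order matrix $S$: symmetric, traceless, 5 free elements.
* Principal axes ordered $|S_{zz}| \ge |S_{yy}| \ge |S_{xx}|$.
* $D_a = S_{zz}/2$, so a bond along the principal z axis back-calculates
  to $2D_a$; rhombicity $R = 2(S_{xx}-S_{yy})/(3S_{zz}) \in [0, 2/3]$.
* $D = D_a[(3\cos^2\theta - 1) + \tfrac32 R \sin^2\theta\cos 2\phi]$
  in the principal frame; equivalently $D = \mathbf{v}^T S \mathbf{v}$.
  Both code paths are implemented and agree to $10^{-10}$.
* Q factor: $\sqrt{\sum(D_{obs}-D_{calc})^2}/\sqrt{\sum D_{obs}^2}$, the
  observed-rms normalization.

## Fitting and uncertainty

`fitTensorSVD()` solves the 5-column linear system by SVD (unweighted by
default, matching a uniform ~2 Hz experimental error; 1/σ weighting
optional), reports the design-matrix condition number, and refuses
rank-deficient bond-vector geometries by name rather than returning a
spurious tensor. The D_a standard error is propagated linearly through the
pseudoinverse with the principal axis held fixed; Monte Carlo refitting
(`mcTensorUncertainty()`, Gaussian noise on the observed couplings)
reproduces it on well-conditioned sets and exceeds it on minimal ones.
Amide hydrogens absent from X-ray coordinates are rebuilt along the
N-centered bisector of the N–CA and N–C(prev) directions at 1.02 Å;
prolines are excluded.

## Flexibility detection

Segments that tumble as one rigid body must share one alignment tensor.
`flexibilityTest()` declares a pair of segments flexible when any of three
clauses fires: opposite D_a signs; |ΔD_a| exceeding 5 combined standard
errors; or joint-fit Q exceeding the worst segment Q by more than 0.1. It
declares rigid only when no clause fires *and* the joint Q is within 0.05
of the worst segment Q, and indeterminate otherwise. The 5σ and 0.1
defaults are package choices on the conservative side — sign inversion,
the decisive observation for a flexible linkage, does not depend on them —
and the verdict records which clauses fired.

# Tilt/twist geometry

## Frame convention

Published tilt/twist values for EGF pairs follow conventions whose exact
atom sets are often not reproducible from the literature that cites them. The
package therefore defines an explicit, self-contained convention and uses
it uniformly: a domain's **long axis** is the principal inertia axis of
its Cys1–Cys6 Cα span, oriented N→C; the **twist reference** is the
Cys3→Cys4 Cα direction orthogonalized against the long axis; the origin is
the span centroid. **Tilt** is the angle between consecutive long axes;
**twist** is the signed rotation about the N-terminal long axis that
aligns the twist references after the tilt is removed (rotation about the
mutual perpendicular). Absolute angles may differ from other conventions
by a fixed offset, so cross-convention comparisons should be treated as
bounds rather than identities; within the convention, the forward
construction `buildPair()` and the measurement `tiltTwist()` are exact
inverses (round trip ≤ 10⁻⁶ degrees across the full grid; at tilt 0 or
180° the twist is defined only up to the degenerate-axis convention).
Near-degenerate tilts are computed with `atan2` of the cross-product norm,
which stays accurate where `acos` of a dot product loses precision.

## Assembly, feasibility, search

`assembleModel()` chains pairwise placements; recomputed geometries match
the inputs. `clashCheck()` counts inter-domain heavy-atom pairs below 2.5
Å (configurable), excluding the covalently constrained linker-terminal
residues on request, and checks each linker's Cys6–Cys1 Cα span against
3.5 Å per residue + 5 Å slack — an approximate maximal per-residue
extension with tolerance. This is what makes tightly folded-back,
U-shaped arrangements of two domains on a five-residue linker fail: they
either clash or demand an infeasible span. `orientationSearch()` scans a
10° tilt/twist grid, rotating only the bond vectors of the moving domain
(RDCs depend on orientation alone, so no coordinates need rebuilding),
then refines by Nelder–Mead, breaking grid ties toward smaller tilt; a Q
range below 0.01 across the grid is flagged ill-determined instead of
returning an arbitrary minimum. `superpose()` is a reflection-excluded
Kabsch fit that refuses collinear selections.

# The synthetic-data generator

`makeTemplateEGF()` builds an idealized elongated scaffold — backbone N,
CA, C and amide H along a compact helical curve with seeded 0.3 Å jitter,
six cysteines at canonical spacing, consensus residues placed on request —
**not** a folded EGF domain. Its purpose is controlled ground truth:
bond-vector sets of full rank for tensor fits, frames with a well-defined
inertia axis, sequences that exercise the classifier. Consequences to keep
in mind: geometric results on synthetic scaffolds are convention-internal
round trips; passing them validates the machinery, not the agreement of
any absolute angle with a crystal structure. The shipped
`egf11_13_synthetic.pdb` is such a scaffold assembly, built at tilt
16°/17° (mid-range of the crystallographic spread reported for the
near-linear ligand-binding tandem) and labelled synthetic for that reason.
Similarly `syntheticNotchSequences()` provides curated synthetic sequences
displaying the per-domain consensus features of the EGF4-13 region (which
domains carry the consensus, the D-at-third-site variants, the packing
aromatics including the tryptophan and histidine special cases, the
five-residue linker), not the real receptor sequence.

Generator defaults are the study conditions: chelator K_d 1.6 µM with
20–30 µM chelator and protein; RDC noise 2 Hz; hetNOE Monte Carlo n = 500;
rigid/mobile NOE means 0.78/0.3 (consistent with typical rigid-limit
plateaus and mobile termini; no numeric profile exists to copy); D_a
+14.9/−8.5 Hz for the flexible-construct scenario. Every generator is a
pure function of its seed.

# Numerical choices and degenerate inputs

* Free-calcium root: `uniroot` plus Newton polish; relative error < 10⁻¹².
* Nonlinear fits: `minpack.lm::nls.lm`, ftol/ptol 10⁻¹⁵, five log-spaced
  starts; best-of-starts reported with an honest convergence flag.
* SVD rank threshold 10⁻⁸ relative; condition number always reported.
* PDB I/O delegates to `bio3d` with a pre-scan that reports malformed
  ATOM/HETATM records by line number; alternate locations resolve to the
  first conformer; author numbering is never rewritten.
* Angles wrap to (−180°, 180°]; comparisons in tests use wrapped
  differences.

# Problem sizes

The test-suite and acceptance runs use four-domain models of 40-residue
scaffolds (~160 RDCs per fit), 100-seed repeats for detection rates, 100–
200 noisy realizations for model-selection rates, and 500–10⁴ Monte Carlo
resamples for error propagation — sizes chosen so the complete suite runs
in about two minutes while keeping every rate estimate's binomial error
well below the thresholds being asserted.

# Known limitations

* Absolute tilt/twist values are convention-dependent; only within-
  convention comparisons and round trips are exact.
* The competition fitter expects normalized signals; raw-absorbance
  endpoint fitting is out of scope.
* No cooperative (Hill) binding models; sites are independent.
* The scaffold generator does not emulate real EGF folds, disulfide
  geometry, or alignment-medium physics; RDC simulation applies a
  specified tensor rather than predicting one from molecular shape.
* Model-free (Lipari–Szabo) analysis and relaxation-rate fitting are not
  implemented; the hetNOE stage stops at ratio-based classification.
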