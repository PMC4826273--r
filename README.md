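# egfarch

Tools for determining the solution architecture of tandem calcium-binding
EGF-like (cbEGF) domain regions, of the kind that make up most of the Notch
receptor ectodomain. Regions of ten or more tandem EGF domains are too large
for a single structure determination, so their shape has to be assembled
from orthogonal measurements: per-interface Ca²⁺ affinities, fast-timescale
backbone dynamics, residual dipolar couplings (RDCs), and interdomain
geometry taken from fragment crystal structures. `egfarch` implements each
of those analysis stages as tested, reusable R functions, together with a
synthetic-data generator so every stage can be exercised against known
ground truth.

## What it computes

**Ca²⁺ dissociation constants.** High-affinity sites (≈1–20 µM) are fitted
from chromophoric-chelator competition curves: free calcium partitions
between a chelator of known K_d (1.6 µM for 5,5′-Br₂BAPTA under the working
buffer) and the protein sites, and the normalized absorbance equals the
Ca-free chelator fraction K_Q/(f + K_Q), with f solving the mass balance

    Ca_total = f + Σᵢ Tᵢ · f / (f + K_i).

One- and two-site models are compared with an F test. Weaker sites are
fitted from NMR titrations (observable ∝ bound fraction, with ligand
depletion). `occupancy()` converts a K_d into fractional saturation at a
given free Ca²⁺ — e.g. a 170 µM site is ~89% occupied at the extracellular
~1.4 mM.

**Heteronuclear NOE dynamics.** `computeHetNOE()` forms the {¹H}-¹⁵N
saturated/reference peak-height ratio per residue, with uncertainties from
Monte Carlo resampling at the baseline-noise level (500 resamples by
default), and `flagFlexible()` calls mobile residues and linkers.

**RDC alignment tensors.** `fitTensorSVD()` solves the five Saupe order
matrix elements by SVD from amide N–H bond vectors; conventions are
|S_zz| ≥ |S_yy| ≥ |S_xx|, D_a = S_zz/2, R = 2(S_xx − S_yy)/(3 S_zz), and
agreement is scored with Q = rms(obs − calc)/rms(obs). Fitting segments
independently and jointly (`fitSegments()` + `flexibilityTest()`) detects
interdomain flexibility: rigidly connected segments must share one tensor,
while independently aligning segments show incompatible D_a values (sign or
magnitude) and a degraded joint Q.

**Tilt/twist geometry and assembly.** A domain frame is its Cys1–Cys6 Cα
principal inertia axis (oriented N→C) plus an orthogonalized Cys3→Cys4
twist reference. `tiltTwist()` measures the interdomain inclination and
axial rotation; `buildPair()`/`assembleModel()` invert it exactly to build
rigid-body multidomain models; `clashCheck()` tests steric and linker-span
feasibility (3.5 Å per linker residue + 5 Å); `orientationSearch()` refines
an interface against RDCs by minimizing the joint-tensor Q;
`superpose()` is a reflection-excluded least-squares fit.

**Sequence classification.** `classifyCaBinding()` matches the cbEGF
consensus D/N-x-D/N-E/Q-x(m)-D/N\*-x(n)-Y/F in the N-terminal region (with
the D-for-E/Q variant accepted on request), `findPackingAromatic()` locates
the interdomain packing aromatic four residues after Cys5, and
`linkerLength()` counts residues between Cys6 and the next domain's Cys1.

## Worked example

Fit a simulated competition titration (true K_d 4 µM) and test a
four-domain construct for a flexible central linkage:

```r
library(egfarch)

t  <- simulateCompetition(4e-6, noise = 0.005, seed = 11)
f1 <- fitCompetition(t, 1); f2 <- fitCompetition(t, 2)
sel <- fTestSelect(f1, f2)
f1
#> BindingFit: 1 site(s), n = 25
#>   Kd1 = 4.059 +/- 0.065 uM
#>   sse = 0.0004079; converged = TRUE; ill-determined = FALSE
sel$selected
#> [1] 1

m   <- makeMultidomain(4, list(InterdomainGeometry(20, 100),
                               InterdomainGeometry(30, -120),
                               InterdomainGeometry(15, 130)), seed = 1)
rdc <- simulateRDCs(m, makeTensor(14.9, 0.25, c(20, 40, 60)), noise = 2,
                    seed = 1, flexibleLinkerIndex = 2,
                    tensorB = makeTensor(-8.5, 0.2, c(-50, 70, 10)))
defs <- lapply(modelFragments(m), `[[`, "definition")
vec  <- extractNHVectors(modelStructure(m), defs)
fits <- fitSegments(vec, rdc, list(c("EGF1", "EGF2"), c("EGF3", "EGF4")))
flexibilityTest(fits$segments, fits$joint)
#> FlexibilityVerdict EGF1+EGF2 vs EGF3+EGF4: flexible
#>   Da = 14.57 +/- 0.23 vs -7.92 +/- 0.27 Hz; Q joint 0.668, segments 0.121/0.240
#>    Da signs differ (14.57 vs -7.92 Hz); ...
```

The two segments report D_a of opposite sign and the joint single-tensor
fit degrades sharply, the signature of a flexible linkage between them;
the fitted K_d recovers the simulated 4 µM site and the F test correctly
keeps the one-site model.

A thin command-line wrapper over the same functions ships in
`inst/cli/egfarch-cli.R` (subcommands `fit-ca`, `hetnoe`, `rdc-fit`,
`tilt-twist`, `simulate`).

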