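---
title: "Models and methods behind essdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind essdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essdyn)
```

# The statistical picture

A trajectory of `n` conformations of `m` atoms is a `3m x n` matrix `X`;
after rigid-body alignment and per-DOF mean centering it becomes the data
matrix `A`, and all inference flows from the covariance model
`Q = A Aᵀ / (n − 1)` (Å²). Within a quasi-harmonic picture the eigenvectors
of `Q` are collective modes analogous to normal modes, with the largest
variance corresponding to the slowest motion; the few top modes span the
*essential subspace*. The correlation model `R` tracks correlated motion
without amplitude bias, and the partial-correlation model `P` isolates
direct pairwise coupling with all other variables conditioned away.

## Alignment

Frames are superposed on a reference conformation by the quaternion method:
the optimal rotation is the eigenvector of the smallest eigenvalue of the
4×4 Kearsley key matrix built from coordinate sums and differences of the
correspondence-set (ICS) atoms. This solves the same least-squares problem
as Kabsch superposition but can never return a reflection, and the smallest
eigenvalue itself is the residual sum of squares — a useful internal
consistency check (the unit tests compare against an independent Kabsch-SVD
oracle to 1e-8 Å). The transform fitted on the ICS is applied to all atoms.
Alignment is idempotent and preserves all inter-atomic distances to 1e-9 Å.
At least 3 non-collinear ICS atoms are required; collinear sets leave a
rotation axis undetermined and are rejected. Distance-pair features are
rotation/translation invariant, so distance-pair PCA skips alignment
entirely.

## Covariance estimation

The sample covariance is a poor estimator when `n` is not much larger than
`3m`, so three optional hardening stages wrap it, applied in a fixed order:

1. **Rare-event shrinkage (RES)** on the data: per DOF, values whose z score
   (or MAD score, scaled by 1.4826 so thresholds are comparable) exceeds a
   threshold are replaced by the DOF mean (median in MAD mode). The default
   threshold 1.96 is the two-sided 5% normal cutoff; a very large threshold
   disables the stage. Replacement can only reduce per-DOF variance, never
   increase it.
2. **Adaptive covariance shrinkage (ACS)** toward the
   diagonal-unequal-variances target `T = diag(Q)`, with intensity
   `λ* = clamp(Σ_{i≠j} Var̂(s_ij) / Σ_{i≠j} s_ij², 0, 1)` where
   `Var̂(s_ij) = n/(n−1)³ Σ_t (w_ij(t) − w̄_ij)²` over the centered
   per-frame products `w_ij(t) = a_i(t) a_j(t)`. Noisy off-diagonal entries
   (large sampling variance relative to magnitude) are damped; the diagonal
   is untouched. RES is run before ACS because RES edits the data while ACS
   edits the estimator; both switches are independent.
3. **Eigenvalue floor conditioning**: eigenvalues of `Q` below `10⁻⁶ Å²`
   are raised to that floor and `Q` is rebuilt from outer products. The
   floor reflects the 3-decimal coordinate precision of PDB data — a
   standard deviation below a thousandth of an Ångström is sub-noise — and
   guarantees an invertible `Q` for the partial-correlation model.

`P` is computed as `2I − D^{-1/2} Ω D^{-1/2}` with `Ω = Q⁻¹`. This is the
unique unit-diagonal matrix whose off-diagonals are the partial correlations
`−Ω_ij/√(Ω_ii Ω_jj)` and whose spectrum is bounded above by 2 (because the
scaled precision matrix is PSD with unit diagonal and trace `d`). The tests
assert the bound and `tr(P) = d` on random ensembles.

## Sampling adequacy

MSA per variable and the overall KMO statistic are the standard Kaiser
ratios of summed squared correlations to summed squared correlations plus
squared partial correlations. The degenerate diagonal-correlation case is
0/0 and is reported as 0 with a warning so downstream logic stays total;
zero-variance DOF likewise get skew/kurtosis 0 (flagged) rather than NaN.
Atom-level thresholding aggregates per-DOF moments by the maximum over the
atom's three coordinates: selection semantics are "keep the atom if any of
its coordinates reaches the threshold", which matches how mobile atoms are
picked for subset analysis.

# Hierarchical PCA

Each residue's locally centered coordinates (in the *single global
alignment* — per-residue re-alignment would destroy the common coordinate
system and is rejected) are decomposed; the top `h` local eigenvectors are
the residue's eigenresidues and `C_r = U_rᵀ A_r` its residuePC time series.
Stacking all `C_r` and decomposing their covariance gives level-2 modes,
convoluted back to atomic space through the block-diagonal eigenresidue
matrix. Because that map has orthonormal columns, atomic modes stay
orthonormal, and with `h` at full local rank the construction is an exact
orthogonal change of basis: hierarchical and direct PCA agree to machine
precision (asserted at 1e-8). Captured variance is nondecreasing in `h` and
bounded by the direct trace. Residues with fewer than `h` local DOF
(limited by `3m_r` or sample rank `n − 1`) contribute their full rank. The
default `h = 3` matches the cost of an alpha-carbon analysis while keeping
distributed all-atom information; `h = 1` suffices for large-scale motions.
The level-2 covariance is not re-shrunk by default — shrinkage belongs to
the level-1 data.

# Residue-pair coupling

For a residue pair, the union of the pair's atoms is aligned jointly to the
reference (joint alignment keeps the pair's relative geometry meaningful),
eigenresidues are computed per residue with `h` capped at the smaller local
rank, and the `2h` stacked residuePC series give the `2h × 2h` mode-coupling
covariance matrix. For mode `k`, `w1(k)` is the squared-component mass on
residue 1's rows and `w2(k)` on residue 2's; the weights close to 1 exactly
because eigenvectors are unit vectors. The score

`s = Σ_{k=1..h} g(w2(k) − w1(k)) λ(k) / tr(MCCM)`, score = 100·s,

uses a Gaussian `g` with σ = 0.25 normalized to `g(0) = 1`, so a residue
duplicated against its own trajectory — whose nonzero MCCM modes are all
perfectly balanced symmetric combinations carrying the full trace — scores
exactly 100, and statistically independent residues (modes localized,
`|w2 − w1| → 1`, `g(1) = e⁻⁸`) score near 0. The sum runs over the top `h`
of the `2h` modes, following the printed upper limit of the defining
formula; with the eigenvalue weighting the remaining modes contribute
little, and scores are stable once `h` exceeds the local scree point
(`h = 12` default). The diagonal of the all-pairs map is set to 100 by
convention (self-coupling is not computed). Symmetry in the pair order
holds to 1e-8 because swapping residues mirrors the weights.

# Subspace comparison

RMSIP between equal-dimension orthonormal bases, per-mode cumulative
overlap, and canonical principal angles (arccos of the singular values of
`UᵀV`, clamped before arccos) quantify similarity of essential subspaces.
Significance is judged against pairs of uniformly random subspaces obtained
by orthonormalizing Gaussian matrices. Note that while `E[RMSIP²] = k/d`
exactly, `E[RMSIP]` sits slightly below `√(k/d)` by Jensen's inequality;
the tests use the delta-method-corrected expectation
`√(k/d)·(1 − Var(RMSIP²)/(8(k/d)²))`, which matches simulation to well
within Monte-Carlo error. One z score is reported per iterated dimension.

# Sparsification

Off-diagonal entries of `R` or `P` with magnitude below a threshold are set
to zero (magnitudes, because correlations are signed and small magnitudes
are the noise-dominated ones); the diagonal is never sparsified so the
model remains decomposable. Sparsified matrices may lose positive
semidefiniteness — negative eigenvalues are reported, not clipped. The
activator/suppressor map marks entries where `P` exceeds `R` by more than a
threshold (+1) or vice versa (−1); for two variables `P = R` in closed
form, so the map is identically zero there.

# Kernel PCA and free-energy surfaces

Kernel PCA is run on PCA-reduced features (top PC projections) by default —
the reduction keeps the dominant structure while making kernel evaluation
cheap — or on raw data. The registry holds 13 kernels (linear, polynomial
degree 2 and 3, RBF, Laplacian, sigmoid, cosine, rational quadratic,
multiquadric, inverse multiquadric, chi-square, log, Cauchy) with defaults
`gamma = 1/k`, `coef0 = 1`, `c = 1`, `sigma = 1`. The kernel matrix is
double-centered; modes with non-positive eigenvalues carry no usable
variance (indefinite kernels such as sigmoid can produce them) and are
dropped with a warning. Projections are the centered kernel applied to
coefficient vectors normalized by `1/√λ`, so the linear kernel reproduces
ordinary PCA up to sign.

Free-energy surfaces Boltzmann-invert a 2-D Gaussian kernel density of the
top two projections: `ΔG = −ln(ρ/ρ_max)` in kT (temperature never enters
explicitly), minimum exactly 0 at the density mode. The bandwidth is the
normal-reference (Silverman-type) default per axis multiplied by a user
smoothing factor — a documented choice, since density estimation always
needs one; smoothing broadens basins, which the tests account for by
comparing fitted curvature of a unit Gaussian against `1/(2(σ̂² + h²))`.

# The synthetic-ensemble generators

Fixture residues are idealized 4-atom units on a lattice — chemistry-free,
because only covariance structure reaches the algorithms. The
quasi-harmonic generator draws frames
`X(t) = mean + Σ_k √λ_k ξ_k(t) v_k + ε` with planted orthonormal modes and
isotropic noise, so population eigenvalues and eigenvectors are known
exactly; rigid scrambling applies random rotations/translations per frame
to exercise alignment; the coupled-pair generator plants a shared latent
factor with correlation ρ between two residues' leading motions; the
outlier generator displaces chosen frames by a per-DOF multiple of the
local SD.

Two generator choices deserve explanation. First, the coupled-pair fixture
gives the residues *different* leading amplitudes (1 and 0.6 Å) and noise
levels (0.02/0.03 Å): with exactly equal spectra the pair's covariance is
degenerate and its eigenvectors — hence any mode-coupling weight — are
undefined, mixing arbitrarily between residues regardless of ρ. Real
residues are never exactly degenerate. Second, planted directions are drawn
orthogonal to the pair's rigid-body subspace (restricted per residue), so
the pair-local alignment step cannot convert planted internal motion into
fitted rigid motion and thereby induce spurious inter-residue correlation.
The perfect-coupling calibration fixture instead duplicates one residue's
coordinates *exactly* (a synthetic, spatially overlapping construct), which
is invariant under any rigid transform and therefore scores 100 regardless
of alignment.

What the generators do not emulate: force-field physics, anharmonic basins
(frames are Gaussian), time correlation between frames (frames are i.i.d.,
so the trajectory-quarter labels are bookkeeping only), and chemical
heterogeneity. Passing tests therefore demonstrate the estimators and
algebra, not simulation realism.

# Numerical conventions

* Eigenvector signs: each mode is flipped so its largest-magnitude
  component is positive, making decompositions and serialized outputs
  bit-reproducible; under eigenvalue degeneracy the contract is the
  subspace, not individual vectors.
* Frames are ordered lexicographically by filename (MODEL number within a
  file); the frame index is the time axis. Trajectory quarters are 4 equal
  contiguous blocks with the remainder in the last.
* Coordinates are stored at full precision; 3-decimal rounding applies only
  to PDB serialization, and round-trips are exact at that precision.
* DVP projections are raw dot products, not eigenvalue-normalized.
* Alternate locations other than blank/'A' are dropped on input; insertion
  codes are part of residue identity; hydrogens are identified by element
  symbol with an atom-name fallback.

# Problem sizes used in the test-suite

The suites run planted-mode recoveries at `n = 2000` frames (where the top
eigenvector aligns with truth to |cos| > 0.99 and λ₁ lands within 10%),
coupling calibrations at `n = 400–2000`, the partial-correlation bound on
30 DOF × 500 frames over repeated seeds, and subspace baselines with 2000
Monte-Carlo draws — sizes chosen so sampling error is far from each
assertion's tolerance while the whole suite completes in seconds.

# Known limitations

* mmCIF and binary trajectory formats (DCD/XTC) are out of scope; input is
  standard PDB, optionally compressed.
* The coupling score is conventionally 100 on the diagonal and is undefined
  (scored 0 with a warning) for residues with zero local variance.
* Sparsified models may be indefinite; interpret their negative eigenvalues
  as artifacts of thresholding, not motion.
* Rendering (heat maps, movies, PyMol scripts) is deliberately absent:
  outputs are flat tables meant for downstream plotting.
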