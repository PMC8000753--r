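---
title: "Methods: micro-CT densitometry and FE validation of spiked-scaffold embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micro-CT densitometry and FE validation of spiked-scaffold embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A multi-spiked connecting scaffold replaces the stem of a resurfacing
endoprosthesis with an array of truncated-cone spikes that are press-fit into
periarticular trabecular bone. Whether a linear finite-element (FE) model of
that press-fit can be trusted for design work is decided by comparing its
predicted embedding force–displacement behaviour with bench embedding tests,
using the fraction of variance unexplained (FVU) as the agreement statistic.
The decisive physical effect is *periapical densification*: bone compacts
under the spike apexes as they advance, locally raising density and stiffness,
and a model that ignores it underestimates the embedding force. `scaffembed`
implements the full loop with synthetic data standing in for the physical
specimens: scaffold geometry, micro-CT-like volumes, embedding curves,
densitometry, the FE model with a densified-bone insert, and the FVU
comparison.

# Scaffold geometry

Spikes are truncated cones of height 5 mm, base diameter 0.5 mm, apex
diameter 0.1 mm (the apex tip is not fixed by the prototype; a small nonzero
footprint keeps FE tractions finite), arranged as a central spike plus
concentric rings at a radial pitch of `base_diameter + inter_spike_gap`
= 0.85 mm. Ring *k* holds the largest spike count for which the arc gap
between neighbouring bases stays at or above the 0.35 mm inter-spike gap —
`floor(2*pi*k)` spikes, so 6, 12, 18, ... The number of rings is a free
parameter (the prototype's total spike count is not fixed); the analyses here
use one ring (7 spikes) so the FE domain stays small, which scales the
absolute forces but none of the comparisons, since all validation claims are
directional or relative.

# Synthetic micro-CT volumes

The trabecular phantom thresholds a smoothed Gaussian random field at the
quantile matching the requested marrow/soft fraction φ\*, so the ground-truth
fraction is exact up to ties. Two numerical choices matter:

* **Feature scale.** For a mean-level threshold of a Gaussian field smoothed
  with an isotropic kernel of SD σ voxels, the expected spacing between
  threshold crossings is πσ√2, i.e. a full bone+marrow period of ≈ 8.9 σ.
  The generator therefore sets σ = `correlation_length` / 8.9 (in voxels), so
  the dial is the structural period. At the default 350 µm period and
  φ\* ≈ 0.58 the bone struts come out ≈ 0.15 mm thick, the textbook
  trabecular thickness.
* **Anisotropy.** Periarticular trabeculae align with the dominant load
  direction; the field's axial correlation is stretched by `anisotropy`
  (default 2) relative to the transverse plane. This is the structural
  counterpart of the transversely isotropic elastic constants used in the FE
  model, and it is what makes canal-like pores (which run axially) fit inside
  the bone phase at realistic porosity.

Canals (tubes, default 35 µm radius × 300 µm), lacunae (spheres, 30 µm) and
single-voxel speckles are carved into the bone phase with a one-voxel
clearance shell, so each planted object is its own 26-connected pore
component, disjoint from the marrow space; placement draws from the feasible
set computed by erosion rather than rejection sampling, and the planted
locations are returned as ground truth. The greyscale is two class means
(defaults 180/60) plus Gaussian noise (SD 8); at this contrast Otsu
thresholding recovers the mask essentially exactly, which is intended — the
phantom tests the *chain*, not scanner physics. Beam hardening, ring
artefacts and partial-volume blur are out of scope, so passing tests say
nothing about threshold selection on difficult real scans.

**Densification.** Cylindrical periapical zones (default radius 0.45 mm
≈ 0.9 base diameters, thickness 1 mm) under each apex have soft voxels
flipped to bone, nearest-to-bone first (layer-by-layer over the
6-neighbourhood), which mimics compaction onto the existing network. The
operator accepts either an absolute reduction `delta_phi` or a per-zone
`target_phi`; the pipeline uses targets, because compaction under a spike is
displacement-controlled and the reference quantity is the *achieved* marrow
fraction at each level. Zone fractions hit the target to one-voxel
quantisation; a box ROI inside the zone re-measures them through the full
segmentation chain with sampling noise of a few hundredths (one ROI spans
only a handful of structural periods — the dominant, and honest, error source
of the densitometry stage).

# Densitometry chain

For a region of interest, with its first and last slices discarded against
edge effects: φ = non-bone voxels / total voxels; volumetric density by the
two-phase mixture rule ρ_b = (1−φ)·ρ_T + φ·ρ_w with ρ_T = 1.90 g/cm³
(trabecular tissue, comparable to cortical bone) and ρ_w = 1.00 g/cm³
(marrow/soft tissue ≈ water); longitudinal modulus by the cancellous-bone
power law E2 = 315·ρ_b³ MPa, always evaluated on the unrounded density.
Presentation rounding (ρ_b to 2 decimals, E2 to integer MPa) happens only in
the CSV writer. At φ = 0.582 the chain gives ρ_b = 1.3762 → 1.38 (2 dp) and
E2 = 821 MPa; at φ = 0.491, ρ_b = 1.46 and E2 = 976.5 MPa. Note the
half-unit-in-the-last-place cases: published tables built from unrounded
fractions can print 1.37 or 976 for these two entries; the package reports
what the stated chain produces.

Pore handling follows the standard workflow: inverse segmentation, removal of
single-voxel noise objects (exact component-size rule — the constrained
erosion–dilation equivalent that can never touch a voxel outside the original
pore surface, and is idempotent), then size classification with
`lacuna_max_voxels` = 150 (≈ a 53 µm sphere at 17.5 µm voxels — a chosen,
exposed cut, not a measured one). By default all non-bone voxels count toward
φ, because the mixture rule needs the total soft fraction; the
`exclude_microporosity` flag instead extracts classified canal/lacuna voxels
from the analysis set (both numerator and denominator) for users who want the
stricter reading of "extracted from the volume of interest".

# Force curves and region analysis

Synthetic embedding traces have three regions: a concave quadratic onset
through the origin (spikes entering the intertrabecular space), the linear
elastic load-transfer phase a·x + b (defaults a = 376.49 N/mm,
b = 209.46 N), and a post-yield phase with sawtooth force drops (trabecular
destruction; drop amplitude 30 N and period 0.1 mm are invented dials, the
reference only describes the phenomenon) on a halved mean slope. Regions join
continuously in the noiseless limit; replicate noise is Gaussian (default
15 N, 10 replicates).

Region II is detected as the longest contiguous span whose rolling-window
(0.2 mm) local slope stays within ±15 % of the span's median slope, iterated
to a fixed point, then refined pointwise: a line is fitted to the inner half
of the span and the region extended while residuals stay within 3 robust SDs
(MAD), stopping only on two consecutive violations so a single noise outlier
cannot truncate the region. On noiseless curves this recovers the true
breakpoints to one grid step; with an infinite slope tolerance the detector
degenerates, by construction, to the window-trimmed whole curve. The mean
line is the pointwise mean of linearly interpolated replicates with a sample
SD band (n−1); the region-II fit is ordinary least squares, with R² defined
as 0 (with a warning) for a constant trace.

# Finite-element model

A quarter cylinder of bone (symmetry planes x = 0, y = 0) is meshed with
uniform 8-node hexahedra (2×2×2 Gauss quadrature, stair-step lateral
boundary). The material is transversely isotropic linear elastic with the
longitudinal axis along the spikes: E1 = 608, E2 = 771, G1 = 260, G2 = 269
MPa, ν1 = 0.17, ν2 = 0.15, ultimate compressive strength σ_c = 25 MPa. The
compliance uses S12 = −ν1/E1 and S13 = S23 = −ν2/E2; in the isotropic limit
the stiffness reproduces the Lamé matrix to 1e−9, and a transversely
isotropic uniaxial-stress bar reproduces R = E2·A·ε to 1e−6 relative.

Two deliberate simplifications, both documented departures from a full
contact model:

* **Rigid scaffold, prescribed contact.** The Ti-6Al-4V scaffold modulus
  (116 GPa) is ~150× the bone's, so the spikes are not meshed; each apex
  footprint (the nodes of the apex plane within the spike's section radius at
  the embedding depth — the growing effective contact as the cone advances)
  carries a prescribed axial displacement. This removes the nonlinear
  augmented-Lagrangian contact iterations while preserving the periapical
  stress concentration the analysis is about. Quasi-static, purely axial
  press-fit makes this defensible; frictional sliding and large deformation
  are out of scope.
* **Limit-stress embedding force.** The solution is linear, so it is rescaled
  until the mean over spikes of the per-footprint maximum Huber–von
  Mises–Hencky stress on the periapical contact reaches σ_c; the rescaled
  axial reaction (times 4 for the quarter model) is the embedding force at
  that level. The per-footprint peak is read in the two element layers of
  *bulk bone* directly beneath the contact: σ_c characterises the bulk
  material, and a densified insert is denser — hence stronger — bone, so
  failure onset governs beneath it. Reading the criterion inside the
  stiffened insert instead makes the re-simulated force *fall*, the opposite
  of the physical effect (the stiff layer spreads load, lowers the gradient
  into the bulk, and raises the force at the same limit stress).

The densified insert is a continuous layer (configurable thickness, default
0.5 mm) beneath the apex plane; its E2 comes from the measured densitometry
chain at each level (linearly extrapolated in φ to unswept levels) and E1,
G1, G2 scale by the same ratio with Poisson ratios kept — the reference
modifies "the mechanical properties of the insert" without listing them, and
a single-ratio scaling preserves the anisotropy shape.

Numerics: all elements of a structured mesh are congruent bricks, so one
element stiffness is assembled by index arithmetic into a sparse matrix
solved with a supernodal Cholesky factorisation (the simplicial default is an
order of magnitude slower on 3-D elasticity patterns). Reactions come from
K·u on constrained dofs; every solve checks global force balance to 1e−6
relative. The element kernel is verified against an independently coded
3×3×3-quadrature, finite-difference-gradient oracle on random
parallelepipeds, and by patch tests.

Mesh convergence on the embedding model is reported, not assumed: the
footprint node set is quantised to the grid, so the raw reaction at a fixed
displacement does not decrease monotonically under refinement (the criterion
force partially compensates through its stress normalisation). The
convergence report flags this honestly; default element size 0.1 mm resolves
every footprint in the swept range with at least two elements across.

# Validation loop and FVU

FVU = Σ(y_i − ŷ_i)² / Σ(y_i − ȳ)² on the region-II displacement grid of the
empirical mean line, restricted to the range swept by the FE levels (1.25,
1.5, 2.0, 2.5, 3.0 mm — five levels; the model line is linearly interpolated
between them and never extrapolated). Which sampled points enter the
comparison is a genuine free choice; this one uses all available region-II
information without inventing model values outside the sweep. FVU is 0 for a
perfect model, 1 for the constant-mean model, invariant under a common affine
rescaling of both series, and undefined (an error) for a constant empirical
series.

The pipeline's two-step structure mirrors the experimental logic: the initial
homogeneous model underestimates the embedding force badly (with the scaled
single-ring geometry the model line sits far below the empirical line, so
FVU_initial is large — its absolute value is not comparable to bench values,
which depend on the full-size scaffold and the real curves); adding the
measured densified insert raises every level's force and must strictly reduce
the FVU. The package's validation claims are exactly these directional ones:
`fvu_modified < fvu_initial`, and the reaction at fixed displacement strictly
increases when the insert is added (a consequence of elastic energy
monotonicity in the moduli, so it is a structural invariant, not a tuning
outcome).

The synthetic replication uses one baseline volume per study (the same seed
across levels), matching a single specimen progressively embedded under
micro-CT monitoring and guaranteeing that measured densification grows with
depth. The undisturbed marrow fraction defaults to 0.67 (bone volume fraction
0.33, a typical periarticular value consistent with mild densification
already at the shallowest reported level); the per-level targets 0.582,
0.491, 0.403 at 1.5, 2.0, 2.5 mm are the reference conditions.

# Problem sizes

The shipped analyses use a 160×160×208-voxel specimen at 17.5 µm, a 7-spike
single-ring layout, and a quarter-cylinder FE domain of radius 2 mm and
height 4 mm at 0.1 mm elements (~12.6k hexahedra, ~44k dofs per solve) —
sizes chosen so the whole pipeline runs in about a minute on one core while
every stage still operates above its resolution limits (ROIs span several
structural periods; every footprint spans ≥ 2 elements). The test suite uses
smaller cousins of the same conditions plus one reference 128³ volume for the
segmentation-recovery check.

# Known limitations

* No contact mechanics: penetration-controlled loading replaces frictional
  augmented-Lagrangian contact; lateral spike-flank load transfer enters only
  through the growing footprint radius.
* No plasticity or trabecular failure; region III of the curves is a
  phenomenological sawtooth, and the FE model is valid only up to the limit
  stress it is scaled to.
* The phantom's greyscale is two-class plus noise; real scans need threshold
  calibration the package does not model.
* Absolute embedding forces scale with the chosen ring count and domain; only
  the intra-study comparisons (level-to-level monotonicity, initial vs
  modified FVU) are claims.
* A box ROI samples few structural periods, so per-ROI marrow fractions carry
  sampling noise of a few hundredths; the pipeline pools ROIs across spikes.
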