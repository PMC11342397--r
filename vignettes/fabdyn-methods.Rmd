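---
title: "Methods: antibody conformational-dynamics analysis in fabdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antibody conformational-dynamics analysis in fabdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, numerical choices, and
known limitations behind `fabdyn`. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The descriptor model

An IgG is treated as four chains (two light, two heavy) carrying annotated
domains (VL/CL on light chains; VH/CH1/hinge/CH2/CH3 on heavy chains). All
structural annotation — chain identities, domain residue intervals, glycan
selections, named residue sets, and anchor atoms such as the hinge disulfide
sulfur or the Fc glycosylation asparagines — is configuration, never code.
Residue numbering follows the input topology verbatim, so antibody-specific
numbers (a Cys228, an Asn299) live in the JSON annotation file. Units are
Angstrom, kcal/mol, and degrees throughout; frame indices are 0-based.

### The Fc-attached reference frame

Per frame: origin = Cα centroid of the hinge; z = unit vector from the Fc Cα
centroid (CH2+CH3 of both heavy chains) toward the origin, so z points from
the Fc toward the Fab arms; x = the CH2(HC1)→CH2(HC2) inter-domain axis
orientation, taken **from HC2 toward HC1** and Gram–Schmidt-orthogonalised
against z; y = z × x. Three choices here were genuinely open and are fixed
as follows:

* **Instantaneous frame.** The frame is rebuilt per trajectory frame rather
  than fitted once, because the Fc itself tumbles and deforms; descriptors
  must not inherit Fc motion.
* **Fab1/Fab2 identity** follows annotation order (HC1/LC1 = Fab1). Nothing
  in the geometry distinguishes the arms, so the assignment is a labelling
  convention the user controls through the annotation.
* **θ is the polar angle from z** (not elevation from the equator). Only
  this reading makes the Y/T rule coherent: both arms below 90° means both
  arms on the Fab side of the equator, i.e. a Y.

Degenerate geometries (coincident CH2 centroids, CH2 axis parallel to z,
Fab centroid at the origin) raise errors instead of returning NaN.

### Longitude and its unwrapping

φ is reported in (−180°, 180°]; at the poles (sin θ = 0) it is undefined and
reported as 0 with a flag column rather than NA, so Δφ series never
propagate NaN. `delta_phi()` defaults to unwrapping (jumps > 180° corrected
by ±360° before subtracting φ₀) because cumulative arm rotations of a full
turn or more are physically meaningful and must not alias; the raw circular
difference is available by flag.

### Distances

The Fc-opening descriptor is the distance between the two Fc-glycosylation
residues, by default between their heavy-atom centroids with a Cα–Cα option
(the atom choice is not standardised in the literature, so both are
provided). Glycan-chain separation has two modes — minimum heavy-atom pair
distance (default) and centroid distance — because both conventions appear
in practice; min-atom ≤ centroid holds for every frame and is tested as an
invariant.

## Accelerated-MD reweighting

Boost parameters follow the standard dual-boost recipe: with per-atom
coefficient c_p (default 0.2 kcal/mol/atom) and per-residue coefficient c_d
(default 3.5 kcal/mol/residue), E_thresh,P = ⟨E_pot⟩ + c_p·N_atoms,
α_P = c_p·N_atoms, E_thresh,D = ⟨E_dih⟩ + c_d·N_res, α_D = c_d·N_res/5. The
coefficients are arguments because published protocols vary.

Reweighting multiplies each frame by exp(ΔV/k_BT), approximated by the
Maclaurin series truncated at order 10 (the practical standard: the exact
exponential is noise-dominated at realistic boost magnitudes, low orders
bias the surface). The exact exponential is available as a validation mode.
ΔV defaults to the **total** boost (dihedral + potential), matching the
dual-boost protocol; either component alone can be supplied instead. The
free-energy surface is a weighted 2-D histogram over (θ₁, θ₂) — default
60×60 bins spanning [0°, 180°]², configurable — with PMF = −k_BT ln p
shifted to zero at the occupied minimum, empty bins masked, and no kernel
smoothing (smoothing would silently move minima). Weights are normalised
only at histogram time; only relative weights matter for a PMF.

Minimum-energy frames are those whose angles fall in an occupied bin with
PMF below 0.5 kcal/mol (configurable, must be positive). Every downstream
stage consumes exactly this frame set; the pipeline writes the frame ids so
the propagation is auditable.

## Clustering

The RMSD matrix uses least-squares (Kabsch) superposition per frame pair on
the analysis selection itself (all Cα by default — the superposition
selection equals the analysis selection, since nothing in the protocol
suggests a separate fit region). RMSD is computed from the explicit
superposed residuals rather than the inner-product shortcut: the shortcut
loses about seven digits to cancellation near zero and fails
identical-frame tests.

GROMOS (Daura) clustering repeatedly takes the frame with the most
neighbours within the cutoff (default 6.5 Å) as a medoid, removes it and
its neighbours, and stops at 10 clusters. Two under-specified points are
fixed: ties on neighbour count break toward the lowest frame index, and
frames left when the cluster cap is reached are reported **unassigned**, not
merged into the last cluster. Cluster ids are ordered by decreasing size.

## Interaction operators

* **Contacts**: heavy-atom pairs across two disjoint selections closer than
  4 Å, counted per frame.
* **Hydrogen bonds**: the toolkit-style geometric rule (H···A < 2.5 Å,
  D–H···A > 120°) with donors inferred from covalent H–(N/O/S) pairs in the
  first frame; both parameters are configurable because published
  "H-bond tools" differ. Triplets below 1% frequency over the analysed
  frames are dropped. A topology without hydrogens is an error, not a
  silent empty result.
* **Secondary structure**: 8-state DSSP-style assignment from Kabsch–Sander
  H-bond energies (E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN), bond
  below −0.5 kcal/mol), with amide H taken from the topology when present
  and otherwise inferred along the preceding C=O direction. Covalent
  neighbours (sequence separation < 2) are excluded from bonding.
  Reporting aggregates to the conventional categories helix (H/G/I),
  extended (E/B), turn (T), bend (S), none.
* **SASA**: Shrake–Rupley with a deterministic golden-spiral point set
  (default 960 points, probe 1.4 Å) over a bundled element→radius table;
  unknown elements fall back to 1.70 Å with a warning. Region sums are
  computed for the named residue sets (hinge, FcγRIIIa site, FcRn site),
  which are configuration inputs: the conventions defining them are
  published per antibody numbering and are not hard-coded here.
* **Patches**: an explicitly simplified stand-in for proprietary
  surface-patch tools. Exposed residues (relative SASA ≥ 0.2 against
  Gly-X-Gly reference maxima) of one class (hydrophobic/positive/negative)
  within 8 Å (Cβ, Cα fallback) form a patch; patch area is the sum of
  member SASA. It reproduces the *structure* of a patch report (per-type
  areas) and is validated only against its own graph/area contract, never
  against any commercial tool's numbers.

## Correlation analysis

The DCCM is the scalar normalised covariance C_ij = ⟨Δr_i·Δr_j⟩ /
√(⟨|Δr_i|²⟩⟨|Δr_j|²⟩) of Cα fluctuations after superposing every frame onto
the first analysed frame. The first frame (rather than an iterated mean
structure) is the default reference because it is deterministic and cheap;
the choice only matters at large amplitudes. Zero-variance atoms are masked
with a warning. The block summary averages C over every (chain
label, domain) block pair and tags each pair intra-chain, inter-chain (same
antibody half) or inter-halves; "strong positive" defaults to a mean of 0.5,
a threshold that published correlation maps define only visually, hence
configurable.

## Statistics

The default t-test is pooled-variance Student (Welch by flag). Cohen's d
uses the pooled SD; its confidence interval uses the large-sample normal
form SE = √((n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂))), with a noncentral-t inversion
as an option (the two agree to ~0.02 at n = 400, which the tests check).
Effect-size labels use half-open intervals — negligible below 0.2, small
[0.2, 0.5), medium [0.5, 0.8), large from 0.8 — because "d ~ 0.2/0.5/0.8"
is not a partition. No multiple-testing correction is applied, matching
standard practice in this analysis style; p-values across many descriptors
should be read accordingly.

## The synthetic world

`make_toy_antibody()` builds a Cα-resolution four-chain pseudo-antibody:
static Fc rods (CH2, CH3), a hinge centred at the origin, and rigid Fab
arms placed exactly at the scheduled (θ, φ) with the four-domain centroid at
`arm_length` (default 40 Å, the order of a real Fab arm). Anchor
pseudo-atoms mirror a real system's descriptor anchors. Gaussian positional
noise (seeded) is optional. The construction makes the geometry module's
recovery of the schedules a mathematical identity on noise-free data —
tested to 1e-6 degrees — which is the point: a green geometry test
establishes correct *math*, not realism. The emulated two-form scenario
(θ ≈ (70°, 70°) vs (95°, 70°)) reproduces the Y-vs-T contrast reported for
Fab-glycosylated vs aglycosylated antibody forms.

`simulate_boosted_ensemble()` samples (θ₁, θ₂) from a designed harmonic
surface (default wells at 70°, curvature 0.004 kcal/mol/deg², domain
[40°, 100°]², 300 K) under a configurable boost, by inverse-CDF on a 0.5°
grid with within-cell jitter — no dynamics, because the reweighting math
needs only (sample, ΔV) pairs. One sign convention required care: in
accelerated MD the boost *raises* the potential inside wells, so the
boosted ensemble samples exp(−(PMF + ΔV)/k_BT) and reweighting multiplies
by exp(+ΔV/k_BT). A "flattening" boost is therefore ΔV = c·(max PMF − PMF)
— with c = 1 the boosted ensemble is exactly uniform — not ΔV ∝ PMF, which
would be inconsistent with positive-exponent reweighting. The generator
retains the analytic surface so recovery is assertable: at n = 50,000 the
reweighted PMF matches the design within 0.3 kcal/mol on bins with ≥ 50
samples (sampling noise ≈ 0.05 kcal/mol, order-10 truncation ≈ 0.03
kcal/mol at the well, binning bias ≈ 0.01 kcal/mol).

All-atom fixtures cover what the Cα toy cannot: an ideal α-helix built by
torsion-space chain extension (φ = −57°, ψ = −47°, standard bond geometry),
a hand-designed antiparallel two-strand ladder whose paired residues donate
and accept across strands (idealised — it exercises the bridge/ladder
logic, it is not a physical sheet), parameterised donor–H–acceptor triads,
and one-/two-sphere SASA fixtures with closed-form reference areas.

What the synthetic world does **not** emulate: force-field physics, glycan
conformers, solvent, side chains on the toy antibody, or realistic
correlation structure. Green pipeline tests establish orchestration,
determinism, and descriptor math — not biophysical validity on real
trajectories.

## File formats and scope limits

Trajectory input is DCD (native-endian, single precision) or multi-model
PDB; XTC and AMBER NetCDF are rejected with a clear error because their
compression/HDF backends are not available to a dependency-light R package.
The annotation config is versioned JSON (`fabdyn-annotation/1`); boost logs
are two-column tables or AMBER-style amd.log (ΔV = potential + dihedral
boost per record). Running MD, building or glycosylating structures, and
reproducing any proprietary tool's numbers are out of scope.

## Performance notes

The pipeline caps the RMSD matrix (default 150 frames, evenly subsampled,
logged) and SASA (default 10 frames) on the minimum-energy set; both caps
are parameters, and the full computation is available by raising them. Pure
R is adequate at these scales; nothing in the package needs compiled code
for its tested problem sizes.
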