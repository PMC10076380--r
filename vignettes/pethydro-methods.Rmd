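---
title: "Methods: geometry, pose statistics and impedimetric degradation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, pose statistics and impedimetric degradation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

Thermophilic polyester hydrolases such as PHL7 and LCC hydrolyze amorphous
polyethylene terephthalate (PET) into terephthalic acid (TPA) and ethylene
glycol. Understanding why point mutations around the substrate groove change
activity requires the same few computations over and over: measuring
active-site geometry in product-bound crystal structures, post-processing
docking-pose ensembles of soluble PET analogs, bookkeeping quantum-chemical
interaction energies, and turning impedance spectra of a thinning PET film
into a degradation rate. `pethydro` implements those four stages as tested,
composable functions, plus generators that produce ground-truthed synthetic
inputs for all of them.

What the package deliberately does **not** do: run docking engines or
molecular dynamics, compute electronic-structure energies, refine crystal
structures, or control instruments. Those are upstream tools whose *outputs*
(coordinate files, score tables, component energies, spectra) are the
package's inputs.

## Structure handling

Coordinates are taken as deposited: orthogonal Angstroms, no symmetry
expansion, the asymmetric-unit chains as analysis units. Alternate locations
are resolved to the highest-occupancy conformer, with occupancy ties broken
to the alphabetically first altloc identifier — deterministic and consistent
with common practice. Waters (`HOH`/`WAT`) and hetero groups are retained and
flagged rather than dropped, because which hetero records to exclude (bound
product, cryo additives such as DMSO, ions) is an analysis decision, not a
parsing decision; filtering is left to the caller.

Ligand topologies are reduced to heavy-atom graphs. Hydrogens are stripped
unconditionally: crystal structures rarely resolve them and docking-pose
RMSD conventions are heavy-atom based. A disconnected heavy-atom graph is
rejected as a sign of a multi-molecule record.

## Geometry measurements

**Superposition.** `superpose()` is the closed-form least-squares (Kabsch)
rigid-body alignment via SVD, with the reflection case handled by the sign
of the determinant. Inputs with fewer than three pairs or collinear points
are rejected; the returned RMSD is invariant under rigid motion of either
input (a property test) and cross-checked against an independent fitting
routine.

**Homolog mapping.** Residue numbering differs between homologs (the
active-site tryptophan of PHL7 is W156; its equivalent in *Is*PETase is
W185), so chain comparisons first build a residue correspondence by global
pairwise alignment (BLOSUM62, gap opening 10, extension 0.5) and keep only
match columns — aligned residue pairs, including mismatches, excluding gaps.
Gap-adjacent columns are kept: trimming rules vary between tools, and "no
trimming" is the simplest reproducible choice.

**Chain-averaged RMSD.** `chain_pair_rmsd()` aligns every chain of one
structure against every chain of the other and reports the mean and
*population* SD over chain pairs, matching the convention of quoting a mean
over all asymmetric-unit comparisons. "All-atom C-alpha RMSD" is read as
RMSD over all aligned C-alpha atoms; the reported magnitudes for this family
(0.3–1.4 A between homolog pairs) are typical C-alpha values.

**Ring geometry.** Ring centroids are arithmetic means; normals are
least-squares plane normals (third right singular vector). The interplanar
angle uses `acos(|n_A . n_B|)`, so it lies in [0, 90] degrees and never
depends on the arbitrary sign of a normal. Rings must pass a planarity check
(default 0.1 A RMS from the best plane; loosen deliberately for jittered
synthetic data). For tryptophan the six-membered ring of the indole is the
default stacking reference — the five-membered ring and the full nine-atom
indole are selectable because centroid conventions differ between analysis
tools and the choice shifts centroid distances by a few tenths of an
Angstrom. T-shaped aromatic contacts in these enzymes sit near 5 A centroid
distance and 60–90 degrees; parallel stacks near 3.5 A and 0 degrees.

**Carboxylate rotation.** `out_of_plane_angle()` is the angle between the
carboxylate plane (carboxyl carbon plus both oxygens) and the aromatic ring
plane, folded into [0, 90]. In product complexes of these hydrolases the
proximal carboxylate is rotated roughly 40 degrees out of plane by the
oxyanion-hole interactions.

**Metal shells.** `coordination_shell()` collects O/N atoms within a cutoff
(default 2.8 A, suited to Mg and Na first shells). With exactly six ligands
the fifteen ligand–center–ligand angles are scored against the ideal
octahedral set (each observed angle against the nearer of 90/180 degrees);
RMS deviation below 15 degrees classifies the shell as octahedral. Other
coordination numbers are reported as `"undefined"` rather than force-fit to
a geometry class, and an empty shell is a result, not an error. Site
separations use the bound ion when present, else the centroid of the
ligating carboxylate oxygens.

## Docking-pose statistics

**Symmetry correction.** Chemically equivalent atoms (the two oxygens of a
carboxylate, a para-substituted phenylene flipped by 180 degrees) make naive
RMSD overestimate pose differences. The automorphism group of the heavy-atom
graph — all permutations preserving elements and adjacency — is enumerated by
depth-first backtracking with element/degree/neighborhood pruning (caps: 60
atoms, 1e6 search nodes). `sym_rmsd()` minimizes in-place RMSD over that
group *without re-superposition*: poses share the receptor frame, and
re-fitting would hide genuine placement differences. For TPA the group has
order 16, for benzene 12, for the two-ring docking analog EMT 8; tests pin
these against brute-force enumeration and an independent graph library.
Matching is on element and connectivity only, not bond order — two atoms are
interchangeable for RMSD purposes when the heavy-atom skeleton cannot tell
them apart.

**Clustering.** Following the original analysis chain, the pairwise RMSD
matrix is embedded by treating each pose's row as a feature vector
(`stats::dist` on the rows) and clustered agglomeratively with the
`ward.D2` linkage — distances squared inside the Lance–Williams update,
merge heights reported on the unsquared scale. The tree-cut count `k` is a
parameter (default 5) because the appropriate number is data-dependent; a
sensitivity sweep over k = 3..8 is always written into the pipeline report.
Results are robust to `k` because downstream statistics use the *reference
cluster*, selected as the cluster minimizing the mean distance between each
member's subsite-I ring centroid and the crystallographic TPA phenylene
centroid. This replaces a visual "same site as the crystal ligand"
assessment with a monotone, automatable proxy; the most-populated cluster id
is reported alongside as a cross-check, and ties within 1e-6 A resolve to
the lower cluster id with an explicit flag.

**Energy statistics.** Interface scores follow the Rosetta sign convention
(more negative = stronger predicted binding); the cluster summary averages
the `n_best = 10` best-scoring members, using all members with a flag when
the cluster is smaller. Per-residue binding-energy profiles are means and
sample SDs over cluster members and require a complete common label set —
a residue missing from one pose's map is an error naming the residue, not a
silent NA. Ring-RMSD diversity uses the lowest-total-score member as
reference and symmetry-corrects within each ring subgraph; box-and-whisker
summaries put whiskers at the most extreme values within 1.5 interquartile
ranges of the quartiles.

## Interaction-energy bookkeeping

Quantum-chemical energies are inputs, never computed here. For a fragment X
of the active site,

    E_int(X) = E(active site) - [ E(X) + E(active site without X) ],

in kcal/mol. The decomposition is linear in each component and shifting all
three components by a constant c changes the result by exactly -c — both
properties are tested, the additive case doubling as the zero-interaction
sanity check. Docking binding energies stay in Rosetta energy units and are
never mixed into kcal/mol columns; agreement between the two is assessed by
Spearman rank correlation plus pairwise ordering concordance, which is the
appropriate strength of claim for scores on different scales.

The component energies behind published per-residue interaction values are
generally not deposited, so the shipped tables (`qm_components_synthetic.csv`,
`qm_whole_site_synthetic.csv`) are synthetic constructions consistent with
reported totals; they exercise the bookkeeping, not the electronic structure.

## Impedimetric degradation kinetics

A PET film separating two electrolyte chambers behaves as a blocking
dielectric: a series (solution) resistance `R_s` in series with a parallel
`R_ct || C` element — the simplified Randles circuit, with no Warburg
diffusion element because no faradaic diffusion process is being modeled:

    Z(w) = R_s + R_ct / (1 + i w R_ct C),  w = 2 pi f.

**Fitting.** Each spectrum (41 log-spaced points, 500 Hz–1 MHz) is fitted by
Levenberg–Marquardt least squares jointly over real and imaginary parts.
Residuals are weighted by `1/|Z|` (modulus weighting): |Z| spans several
decades across the band and unweighted fits would be dominated by the
low-frequency points. Positivity is enforced by fitting log-parameters.
Auto-initialization reads the limiting behavior: `R_s` from the
high-frequency real part, `C` from the high-frequency capacitive branch
(`-Im Z ~ 1/(wC)`), `R_ct` from the low-frequency modulus. `R_ct` is capped
at `1e6 * max|Z|`; an effectively ideal capacitor drives the fit to that cap,
which is flagged rather than treated as convergence failure — `C`, the
quantity of interest, is still recovered.

**Thickness.** The film capacitance follows the parallel-plate law
`C = eps0 * eps_r * A / d` with `eps_r = 3.3` for PET. The default
*calibrated* mode anchors to the mechanically measured starting thickness,
`d(t) = d0 * C(t0)/C(t)`: the uncertain exposed electrode area cancels, and
the conversion is invariant under any uniform scaling of the capacitances.
The *absolute* mode (`d = eps0 eps_r A / C`) is provided for completeness
but flagged approximate, because the effective area of a clamped film is not
the coupon area. Defaults: `d0 = 225` um, film 4.3 x 9.1 mm.

**Rate.** The degradation rate is the negated OLS slope of apparent
thickness versus time over a stated window, in um/h, with standard error and
R^2 attached. The window is a *required, logged* argument rather than a
default: analyses of this measurement have used both a 5–10 h and a 10–15 h
window, and silently defaulting would hide a choice that changes the answer
whenever thinning is not perfectly linear. Group comparisons use one-way
ANOVA with Tukey HSD post-hoc tests and stars at 0.05/0.01/0.001; gravimetric
weight losses are normalized to the wild-type mean with first-order error
propagation of the replicate SDs.

## Synthetic generators and what they do (not) show

Each generator writes its ground truth next to the fixture and is
byte-reproducible under a fixed seed; one integer seed drives one stream per
generator call.

* `make_toy_complex()` *inverts* the geometry measurements: the side-chain
  ring is placed in a reference plane and the TPA ring centroid, plane tilt
  and carboxylate rotation are constructed so the measurements return the
  requested values exactly before jitter. This validates the measurement
  code, not crystallography: there is no lattice, no refinement noise model
  beyond isotropic jitter, and no electron density.
* `make_pose_ensemble()` plants clusters of an idealized EMT conformer with
  controlled within/between spreads (defaults: 3 clusters, separation 10 A,
  spread 0.5 A, ring jitters sigma_I = 0.2 A and sigma_II = 1.0 A — the
  wider subsite-II spread mirrors the looser chain-guiding subsite), random
  symmetric relabelings with probability 0.5, and scores correlated with
  distance to the own cluster center. Real docking funnels are not Gaussian
  blobs; passing tests show the statistics machinery recovers planted
  structure, not that any particular enzyme's pose landscape looks like
  this.
* `make_impedance_series()` thins a film linearly at a known rate (default
  20 um/h, the fastest-variant scale) under the Randles model with
  proportional Gaussian spectral noise (default 1%). Electrode drift,
  temperature transients and non-uniform thinning are deliberately outside
  the model; the end-to-end recovery tests therefore demonstrate estimator
  correctness and precision, not instrument realism.

## Numerical choices and degenerate inputs

* Collinearity in superposition and plane fitting is detected via the ratio
  of singular values (threshold 1e-8) and rejected with a named error.
* Quartiles use R's default (type 7) convention.
* A constant thickness series has undefined R^2; it is reported as 0 with an
  explicit flag, and the rate is 0. ANOVA on identical constant groups is
  flagged with `F = NaN` rather than fabricating a statistic.
* Randles fits declare non-convergence as an error carrying the residual;
  `at_bound` flags a capped `R_ct`.
* Tie-breaks are deterministic everywhere (altloc letters, cluster ids) so
  reruns are byte-identical.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
pose ensembles of 18–30 poses (the published analyses cluster the top 50),
impedance series of up to 601 one-minute spectra over 10 h, exhaustive
clustering oracles at n <= 8, and brute-force permutation oracles at <= 7
atoms. These sizes keep every oracle exact while exercising the same code
paths as full-scale inputs; the operations themselves have no size
assumptions beyond the documented automorphism caps.

## Known limitations

* mmCIF reading relies on an upstream parser flagged beta for that format;
  PDB is the primary tested path and generated fixtures use it.
* The automorphism search is exponential in pathological highly symmetric
  graphs; the node cap turns that into a clean error. Ligands of this
  problem domain (tens of atoms, small symmetry groups) are far from the
  cap.
* `chain_pair_rmsd()` assumes homologs align globally; circular permutants
  or heavily domain-swapped pairs would need a different correspondence.
* The Randles model omits double-layer and diffusion elements on purpose;
  spectra from systems where those matter will fit poorly and should be
  modeled elsewhere.
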