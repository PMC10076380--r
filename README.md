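# pethydro

Structure–function analysis of PET-degrading polyester hydrolases.

Enzymes such as the metagenome-derived hydrolase PHL7 depolymerize amorphous
polyethylene terephthalate (PET) into terephthalic acid (TPA) and ethylene
glycol, and single active-site mutations shift their activity and thermal
stability substantially. Characterizing such variants computationally keeps
recombining the same four analyses, which this package implements for
structural biologists and enzyme engineers working on plastic-degrading
hydrolases:

1. **Crystal-structure geometry** — Kabsch superposition and chain-averaged
   C-alpha RMSD between homologs (with sequence-alignment residue mapping),
   aromatic π-stacking geometry (centroid distance *d* and interplanar angle
   θ = arccos |n_A · n_B|), carboxylate out-of-plane rotation, and metal
   coordination shells with octahedral classification.
2. **Docking-pose statistics** — symmetry-corrected ligand RMSD
   (min over the molecular-graph automorphism group of the in-place RMSD,
   no re-superposition), Ward.D2 hierarchical clustering of the pose–pose
   RMSD feature matrix, reference-cluster selection against the crystal
   ligand, interface-score aggregation (Rosetta energy units, lower =
   stronger), per-residue binding-energy profiles, and ring-RMSD diversity
   with 1.5·IQR box-whisker summaries.
3. **Interaction-energy bookkeeping** — the supermolecular decomposition
   E_int(X) = E(site) − [E(X) + E(site∖X)] over externally computed
   quantum-chemical energies, and rank-based trend agreement with docking
   predictions.
4. **Impedimetric degradation kinetics** — per-spectrum fits of the
   simplified Randles circuit Z(ω) = R_s + R_ct/(1 + iωR_ctC), capacitance →
   film thickness via the parallel-plate law (ε_r = 3.3, calibrated to the
   measured starting thickness), windowed linear regression to a thinning
   rate in µm/h, and one-way ANOVA with Tukey post-hoc group comparisons.

Every stage has a synthetic-data generator with serialized ground truth
(`make_toy_complex()`, `make_pose_ensemble()`, `make_impedance_series()`),
so the whole pipeline is testable offline. Standard formats go through
established parsers: PDB/mmCIF via bio3d, SDF via ChemmineR, MOL2 via bio3d.

## Worked example

Cluster a synthetic docking ensemble, pick the cluster whose subsite-I ring
matches the crystal reference, and summarize it; then recover a degradation
rate from synthetic impedance spectra:

```r
library(pethydro)

ens <- make_pose_ensemble(seed = 42)              # 3 planted clusters, 30 poses
M   <- rmsd_matrix(ens$poses)                     # symmetry-corrected, pairwise
cl  <- ward_cluster(feature_distance(M), k = 3)
sel <- select_reference_cluster(cl, ens$poses, ens$reference_ring)
members <- names(cl$assignments)[cl$assignments == sel$selected]
agg <- aggregate_interface_score(ens$poses, members)
head(per_residue_profile(ens$poses, members), 3)

sim <- make_impedance_series(rate = 20, seed = 42)  # 601 spectra, 1% noise
impedance_pipeline(sim$series, window = c(5, 10))
```

Output:

```
selected cluster: 1 | most populated: 1
interface score (10 best): -14.58 +/- 0.21 REU
  residue      mean         sd
1     F63 -2.080222 0.07057265
2    M132 -1.233433 0.07418269
3    W156 -2.765374 0.14145080
<rate_estimate> 20.014 +/- 0.005 um/h over [5, 10] h (n=301, R^2=1.0000)
```

The selected cluster is the one planted at the crystal-reference site (here
also the most populated — reported side by side as a cross-check). The
interface score is the mean ± SD of the 10 best-scoring members; the
per-residue rows are mean ± SD energetic contributions in Rosetta energy
units. The rate estimate recovers the generator's true 20 µm/h thinning
within its standard error, using the 5–10 h regression window, which is a
required, logged argument (see the methods vignette for why).

For multi-stage runs, `run_pipeline(pipeline_config(out_dir))` executes the
geometry, pose, energetics and degradation stages on seeded synthetic
inputs, echoing the resolved configuration and writing per-stage CSV/JSON
reports plus a completion MANIFEST.

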