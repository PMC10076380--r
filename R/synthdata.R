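# Synthetic fixtures with known ground truth for every pipeline stage:
# toy protein/ligand complexes with prescribed ring geometry, docking-pose
# ensembles with known cluster labels and symmetric atom relabelings, and
# impedance series of a dielectric film thinning at a known rate.

# ideal benzene ring (radius 1.39 A) in the xy-plane, centered at origin
benzene_coords <- function(r = 1.39) {
  th <- seq(0, by = pi / 3, length.out = 6)
  cbind(r * cos(th), r * sin(th), 0)
}

# idealized TPA heavy atoms in a local frame: ring C1..C6 in the xy-plane
# centered at the origin (C1 on +x, C4 on -x), carboxylates on C1
# (proximal: C7,O1,O2) and C4 (distal: C8,O3,O4). The proximal carboxylate
# is rotated about the C1-C7 axis (the x-axis) by `carboxylate_angle`.
tpa_coords <- function(carboxylate_angle = 0) {
  ring <- benzene_coords()
  cc <- 1.39 + 1.49   # ring C to carboxyl C
  oo <- 1.25          # carboxyl C to O
  ox <- oo * cos(pi / 3); oy <- oo * sin(pi / 3)
  prox <- rbind(c(cc, 0, 0), c(cc + ox, oy, 0), c(cc + ox, -oy, 0))
  R <- rotation_about_axis(c(1, 0, 0), carboxylate_angle)
  prox[2, ] <- as.numeric(R %*% prox[2, ])
  prox[3, ] <- as.numeric(R %*% prox[3, ])
  dist <- rbind(c(-cc, 0, 0), c(-cc - ox, oy, 0), c(-cc - ox, -oy, 0))
  xyz <- rbind(ring, prox, dist)
  rownames(xyz) <- c(paste0("C", 1:6), "C7", "O1", "O2", "C8", "O3", "O4")
  xyz
}

#' Heavy-atom graph of terephthalic acid
#'
#' Atom order `C1..C6` (phenylene ring), `C7 O1 O2` (proximal
#' carboxylate), `C8 O3 O4` (distal carboxylate). The automorphism group
#' has order 16: ring flip x 180-degree rotation (swapping the two
#' carboxylates) x the two O swaps.
#'
#' @return a [ligand_graph()].
#' @export
tpa_graph <- function() {
  bonds <- rbind(cbind(1:6, c(2:6, 1)),
                 c(1, 7), c(7, 8), c(7, 9),
                 c(4, 10), c(10, 11), c(10, 12))
  ligand_graph("TPA", c(rep("C", 6), "C", "O", "O", "C", "O", "O"), bonds)
}

atoms_df <- function(type, elety, resid, chain, resno, xyz, elesy) {
  data.frame(type = type, elety = elety, resid = resid, chain = chain,
             resno = resno, insert = "", altloc = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
             elesy = elesy, stringsAsFactors = FALSE)
}

#' Toy protein/ligand complex with prescribed stacking geometry
#'
#' Places an aromatic side-chain ring (tryptophan six-membered ring or
#' phenylalanine phenyl ring) in the xy-plane at the origin and a TPA
#' ligand whose phenylene-ring centroid sits `stack_distance` Angstroms
#' away along z with its plane tilted by `stack_angle`; the proximal
#' carboxylate is rotated out of the ligand ring plane by
#' `carboxylate_angle`. Before jitter, [pi_stack_geometry()] and
#' [out_of_plane_angle()] recover the requested values exactly
#' (construction by inverse).
#'
#' @param stack_distance ring-centroid separation, Angstroms (> 0).
#' @param stack_angle interplanar angle, degrees in `[0, 90]`.
#' @param carboxylate_angle proximal carboxylate out-of-plane rotation,
#'   degrees in `[0, 90]`.
#' @param side_chain `"trp"` or `"phe"`.
#' @param resno residue number of the side chain (default 156 for trp,
#'   63 for phe).
#' @param jitter_sd isotropic Gaussian jitter (A per coordinate) applied
#'   to every atom; 0 disables.
#' @param seed RNG seed for the jitter.
#' @param out_dir if given, the complex is written as `complex.pdb` plus
#'   `ground_truth.json`.
#' @return list with `structure` ([pet_structure()]), `ligand`
#'   ([tpa_graph()]), `protein_ring` / `ligand_ring` ([ring_spec()]s),
#'   `truth`.
#' @export
make_toy_complex <- function(stack_distance, stack_angle, carboxylate_angle,
                             side_chain = c("trp", "phe"), resno = NULL,
                             jitter_sd = 0, seed = NULL, out_dir = NULL) {
  side_chain <- match.arg(side_chain)
  if (stack_distance <= 0) stopf("stack_distance must be positive")
  if (stack_angle < 0 || stack_angle > 90) stopf("stack_angle must be in [0, 90]")
  if (carboxylate_angle < 0 || carboxylate_angle > 90)
    stopf("carboxylate_angle must be in [0, 90]")
  resno <- resno %||% if (side_chain == "trp") 156L else 63L

  ring_xyz <- benzene_coords()
  if (side_chain == "trp") {
    resid <- "TRP"; names_ <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  } else {
    resid <- "PHE"; names_ <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  }
  prot <- atoms_df("ATOM", names_, resid, "A", resno, ring_xyz, "C")

  lig_local <- tpa_coords(carboxylate_angle)
  R <- rotation_about_axis(c(1, 0, 0), stack_angle)
  lig_xyz <- t(R %*% t(lig_local))
  lig_xyz <- sweep(lig_xyz, 2, c(0, 0, stack_distance), `+`)
  lig <- atoms_df("HETATM", rownames(lig_local), "TPA", "A", 301L, lig_xyz,
                  substr(rownames(lig_local), 1, 1))

  atoms <- rbind(prot, lig)
  if (jitter_sd > 0) {
    atoms[, c("x", "y", "z")] <- with_seed(seed,
      atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3 * nrow(atoms), 0, jitter_sd), ncol = 3))
  }
  struct <- pet_structure("toy_complex", atoms)
  protein_ring <- ring_spec("A", resno, names_,
                            label = sprintf("%s%d", resid, resno))
  ligand_ring <- tpa_ring("A", 301L)
  truth <- list(stack_distance = stack_distance, stack_angle = stack_angle,
                carboxylate_angle = carboxylate_angle,
                side_chain = side_chain, resno = resno,
                jitter_sd = jitter_sd, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_structure_pdb(struct, file.path(out_dir, "complex.pdb"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  }
  list(structure = struct, ligand = tpa_graph(), protein_ring = protein_ring,
       ligand_ring = ligand_ring, truth = truth)
}

# serialize a pet_structure as standard PDB (so generated fixtures
# exercise the real parser)
write_structure_pdb <- function(struct, path) {
  at <- struct$atoms
  bio3d::write.pdb(file = path,
                   type = at$type,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   elety = at$elety, o = at$o, b = at$b, elesy = at$elesy)
  invisible(path)
}

write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Idealized EMT ligand (two-ring soluble PET analog)
#'
#' Heavy-atom topology and a reference conformer of
#' 1,2-ethylene-mono-terephthalate-mono(2-hydroxyethyl terephthalate):
#' a free terephthalate end (subsite-I ring), an ethylene glycol bridge,
#' and a hydroxyethyl-terminated second terephthalate (subsite-II ring).
#' The conformer is an idealized synthetic geometry, not an experimental
#' one. 29 heavy atoms; automorphism group of order 8 (terminal
#' carboxylate O swap x two ring flips).
#'
#' @return list with `graph` ([ligand_graph()]), `coords` (29 x 3),
#'   `ring_atoms` (`subsite_I`, `subsite_II` index vectors).
#' @export
emt_ligand <- function() {
  ringA <- benzene_coords()                      # atoms 1-6, A1 on +x
  ca <- c(-2.88, 0, 0)                           # 7: terminal carboxyl C on A4
  oa1 <- c(-3.505, 1.0825, 0); oa2 <- c(-3.505, -1.0825, 0)  # 8, 9
  ce1 <- c(2.88, 0, 0)                           # 10: ester carbonyl C on A1
  oe1 <- c(3.505, 1.0825, 0)                     # 11: =O
  oe2 <- c(3.505, -1.0825, 0)                    # 12: ester O
  c9 <- c(4.90, -1.08, 0.20); c10 <- c(5.60, 0.20, 0.30)     # 13, 14: glycol
  oe3 <- c(7.00, 0.20, 0.30)                     # 15: ester O
  ce2 <- c(7.70, 1.40, 0.30); oe4 <- c(7.10, 2.50, 0.30)     # 16, 17
  # ring B centered at (10.54, 1.4, 0.3): B1 (atom 18) on its +x side at
  # (11.93, 1.4, 0.3), B4 (atom 21) at (9.15, 1.4, 0.3) next to ce2
  ringB <- sweep(benzene_coords(), 2, c(10.54, 1.40, 0.30), `+`)  # 18-23
  cb <- c(13.40, 1.40, 0.30)                     # 24: ester carbonyl C on B1
  ob1 <- c(14.00, 2.50, 0.30); ob2 <- c(14.00, 0.30, 0.30)   # 25, 26
  c11 <- c(15.40, 0.30, 0.30); c12 <- c(16.10, 1.50, 0.40)   # 27, 28
  ooh <- c(17.50, 1.50, 0.40)                    # 29
  coords <- rbind(ringA, ca, oa1, oa2, ce1, oe1, oe2, c9, c10, oe3, ce2, oe4,
                  ringB, cb, ob1, ob2, c11, c12, ooh)
  rownames(coords) <- NULL
  elements <- c(rep("C", 6), "C", "O", "O", "C", "O", "O", "C", "C", "O",
                "C", "O", rep("C", 6), "C", "O", "O", "C", "C", "O")
  bonds <- rbind(cbind(1:6, c(2:6, 1)),          # ring A
                 c(4, 7), c(7, 8), c(7, 9),      # terminal carboxylate
                 c(1, 10), c(10, 11), c(10, 12), # ester 1
                 c(12, 13), c(13, 14), c(14, 15),# glycol bridge
                 c(15, 16), c(16, 17), c(16, 21),# ester 2 onto ring B (B4)
                 cbind(18:23, c(19:23, 18)),     # ring B
                 c(18, 24), c(24, 25), c(24, 26),# ester 3 (B1 side)
                 c(26, 27), c(27, 28), c(28, 29))# hydroxyethyl
  list(graph = ligand_graph("EMT", elements, bonds),
       coords = coords,
       ring_atoms = list(subsite_I = 1:6, subsite_II = 18:23))
}

#' Synthetic docking-pose ensemble with known cluster labels
#'
#' Generates an EMT-like pose ensemble at desk scale: `k` cluster centers
#' separated by `between_sep` Angstroms, member poses jittered by
#' `within_spread` per coordinate, extra ring-specific jitter
#' `subsite_spreads` (sigma_I on the subsite-I ring, sigma_II on the
#' subsite-II ring; the wider subsite-II spread emulates the looser
#' chain-guiding subsite). With probability `relabel_prob` a random graph
#' automorphism permutes a pose's atom labels, which leaves the molecule
#' unchanged and exercises symmetry correction. Interface, total and
#' per-residue scores are correlated with the distance to the own cluster
#' center; cluster 1 sits at the crystal reference position.
#'
#' @param k number of clusters.
#' @param n_per_cluster members per cluster (scalar or length-`k`).
#' @param within_spread per-coordinate jitter SD, Angstroms.
#' @param between_sep distance between adjacent cluster centers (> 0).
#' @param relabel_prob probability of a random symmetric relabeling.
#' @param subsite_spreads `c(sigma_I, sigma_II)` ring jitter SDs.
#' @param seed RNG seed.
#' @param out_dir if given, poses + scores + truth are serialized there.
#' @return list with `poses` ([pose_set()]), `reference_ring` (crystal
#'   subsite-I ring coordinates), `truth` (labels, centers, parameters).
#' @export
make_pose_ensemble <- function(k = 3, n_per_cluster = 10, within_spread = 0.5,
                               between_sep = 10, relabel_prob = 0.5,
                               subsite_spreads = c(0.2, 1.0), seed = NULL,
                               out_dir = NULL) {
  if (between_sep <= 0) stopf("between_sep must be positive")
  emt <- emt_ligand()
  sizes <- if (length(n_per_cluster) == 1) rep(n_per_cluster, k) else n_per_cluster
  if (length(sizes) != k) stopf("n_per_cluster must be scalar or length k")
  autos <- automorphisms(emt$graph)
  res_labels <- c("F63", "M132", "W156", "I179", "H209", "L210")
  res_base <- c(-2.1, -1.2, -2.8, -0.9, -1.5, -0.4)
  na <- nrow(emt$coords)

  gen <- with_seed(seed, {
    coords <- list(); labels <- integer(0); relabeled <- logical(0)
    iface <- c(); total <- c(); resE <- NULL
    pid <- 0
    for (cl in seq_len(k)) {
      offset <- c((cl - 1) * between_sep, 0, 0)
      for (m in seq_len(sizes[cl])) {
        pid <- pid + 1
        xyz <- sweep(emt$coords, 2, offset, `+`)
        xyz <- xyz + matrix(stats::rnorm(3 * na, 0, within_spread), ncol = 3)
        iI <- emt$ring_atoms$subsite_I; iII <- emt$ring_atoms$subsite_II
        xyz[iI, ] <- xyz[iI, ] +
          matrix(stats::rnorm(3 * length(iI), 0, subsite_spreads[1]), ncol = 3)
        xyz[iII, ] <- xyz[iII, ] +
          matrix(stats::rnorm(3 * length(iII), 0, subsite_spreads[2]), ncol = 3)
        # draw the relabeling decision and the automorphism unconditionally
        # so the RNG stream (and hence all jitter) is identical across
        # relabel_prob settings under the same seed
        rel <- stats::runif(1) < relabel_prob
        p <- autos[[sample(length(autos), 1)]]
        if (rel) xyz <- xyz[p, , drop = FALSE]
        d <- vec_norm(colMeans(xyz) - (colMeans(emt$coords) + offset))
        coords[[pid]] <- xyz
        labels[pid] <- cl
        relabeled[pid] <- rel
        iface[pid] <- -15 + 2 * d + stats::rnorm(1, 0, 0.2)
        total[pid] <- -320 + 4 * d + stats::rnorm(1, 0, 0.5)
        resE <- rbind(resE, res_base + 0.1 * d + stats::rnorm(6, 0, 0.1))
      }
    }
    list(coords = coords, labels = labels, relabeled = relabeled,
         iface = iface, total = total, resE = resE)
  })
  ids <- sprintf("pose_%03d", seq_along(gen$labels))
  names(gen$coords) <- ids
  colnames(gen$resE) <- res_labels
  rownames(gen$resE) <- ids
  scores <- data.frame(pose_id = ids, total_score = gen$total,
                       interface_score = gen$iface)
  poses <- pose_set(emt$graph, gen$coords, scores, gen$resE, emt$ring_atoms)
  truth <- list(labels = stats::setNames(gen$labels, ids),
                relabeled = stats::setNames(gen$relabeled, ids),
                k = k, sizes = sizes, within_spread = within_spread,
                between_sep = between_sep, relabel_prob = relabel_prob,
                subsite_spreads = subsite_spreads, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pose_set(poses, file.path(out_dir, "poses"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  }
  list(poses = poses,
       reference_ring = emt$coords[emt$ring_atoms$subsite_I, , drop = FALSE],
       truth = truth)
}

#' Synthetic impedance series of an enzymatically thinning PET film
#'
#' Emulates the impedimetric degradation measurement: the film thins
#' linearly, `d(t) = d0 - rate * t`; its capacitance follows the
#' parallel-plate formula `C(t) = eps0 * eps_r * area / d(t)`; each
#' spectrum is the simplified Randles response on 41 log-spaced
#' frequencies between 500 Hz and 1 MHz, one spectrum per minute, with
#' independent Gaussian noise of `noise_frac * |Z|` on the real and
#' imaginary parts. Defaults reproduce the study conditions for the most
#' active variant (20 um/h thinning of a 225 um film).
#'
#' @param rate true thinning rate, um/h (>= 0).
#' @param geom a [film_geometry()] (provides `d0_um`, `epsilon_r`, area).
#' @param circuit baseline circuit: list with `R_s`, `R_ct` (Ohm).
#' @param noise_frac relative spectral noise SD (default 0.01).
#' @param duration_h measurement duration (default 10 h; the film must not
#'   be fully consumed within it).
#' @param cadence_s time between spectra (default 60 s).
#' @param n_freq,f_min,f_max frequency grid (defaults 41 points,
#'   500 Hz to 1 MHz, log-spaced).
#' @param seed RNG seed.
#' @param out_dir if given, writes `impedance.csv` + `ground_truth.json`.
#' @return list with `series` ([impedance_series()]) and `truth`.
#' @export
make_impedance_series <- function(rate = 20, geom = film_geometry(),
                                  circuit = list(R_s = 50, R_ct = 1e9),
                                  noise_frac = 0.01, duration_h = 10,
                                  cadence_s = 60, n_freq = 41, f_min = 500,
                                  f_max = 1e6, seed = NULL, out_dir = NULL) {
  if (rate < 0) stopf("rate must be non-negative")
  t_h <- seq(0, duration_h, by = cadence_s / 3600)
  d_um <- geom$d0_um - rate * t_h
  if (min(d_um) <= 0)
    stopf("film fully consumed within duration (d0 %g um, rate %g um/h, %g h)",
          geom$d0_um, rate, duration_h)
  freqs <- 10^seq(log10(f_min), log10(f_max), length.out = n_freq)
  Z <- with_seed(seed, {
    M <- matrix(0i, length(t_h), n_freq)
    for (i in seq_along(t_h)) {
      p <- randles_params(circuit$R_s, circuit$R_ct,
                          plate_capacitance(geom, d_um[i]))
      z <- randles_impedance(p, freqs)
      if (noise_frac > 0) {
        s <- noise_frac * Mod(z)
        z <- z + complex(real = stats::rnorm(n_freq, 0, s),
                         imaginary = stats::rnorm(n_freq, 0, s))
      }
      M[i, ] <- z
    }
    M
  })
  series <- impedance_series(t_h, freqs, Z, geom)
  truth <- list(rate_um_h = rate, d0_um = geom$d0_um,
                epsilon_r = geom$epsilon_r, area_mm2 = geom$area_mm2,
                R_s = circuit$R_s, R_ct = circuit$R_ct,
                noise_frac = noise_frac, duration_h = duration_h,
                cadence_s = cadence_s, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_impedance(series, file.path(out_dir, "impedance.csv"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  }
  list(series = series, truth = truth)
}
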