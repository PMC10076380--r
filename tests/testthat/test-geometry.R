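random_points <- function(n, seed) {
  withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = 5), ncol = 3))
}

test_that("superposition of identical and rigidly moved copies gives zero RMSD", {
  P <- random_points(40, 1)
  expect_equal(superpose(P, P)$rmsd, 0, tolerance = 1e-10)

  R <- pethydro:::rotation_about_axis(c(0, 0, 1), 90)
  Q <- sweep(P %*% t(R), 2, c(5, 0, 0), `+`)
  sp <- superpose(P, Q)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(P, sp), Q, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-12)
})

test_that("superposition RMSD of jittered copies matches sigma * sqrt(3)", {
  P <- random_points(500, 2)
  Q <- withr::with_seed(3, P + matrix(stats::rnorm(1500, sd = 0.5), ncol = 3))
  expect_equal(superpose(P, Q)$rmsd, 0.5 * sqrt(3), tolerance = 0.05)
})

test_that("superposition RMSD is invariant under rigid motion of either input", {
  P <- random_points(30, 4)
  Q <- withr::with_seed(5, P + matrix(stats::rnorm(90, sd = 0.3), ncol = 3))
  base <- superpose(P, Q)$rmsd
  for (seed in 1:5) {
    ax <- withr::with_seed(seed, stats::rnorm(3))
    R <- pethydro:::rotation_about_axis(ax, withr::with_seed(seed + 10, stats::runif(1, 0, 360)))
    Q2 <- sweep(Q %*% t(R), 2, c(seed, -seed, 2), `+`)
    expect_equal(superpose(P, Q2)$rmsd, base, tolerance = 1e-9)
    P2 <- sweep(P %*% t(R), 2, c(0, seed, 1), `+`)
    expect_equal(superpose(P2, Q)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("superposition agrees with an independent fitting routine", {
  P <- random_points(25, 6)
  Q <- withr::with_seed(7, P + matrix(stats::rnorm(75, sd = 0.4), ncol = 3))
  ours <- superpose(P, Q)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(Q)), as.numeric(t(P)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)  # bio3d rounds to 3 decimals
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(superpose(matrix(1:6, 2), matrix(1:6, 2)), "3 atom pairs")
  line <- cbind(1:5, 2 * (1:5), 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("residue correspondence maps identical and gapped homologs", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  rc <- residue_correspondence(s, s)
  expect_equal(rc$a, seq_len(nchar(s)))
  expect_equal(rc$b, seq_len(nchar(s)))

  # internal 3-residue insertion after position 15: all other columns pair
  ins <- paste0(substr(s, 1, 15), "GGG", substr(s, 16, nchar(s)))
  rc2 <- residue_correspondence(s, ins)
  expect_equal(nrow(rc2), nchar(s))
  expect_equal(rc2$b[rc2$a <= 15], rc2$a[rc2$a <= 15])
  expect_equal(rc2$b[rc2$a >= 16], rc2$a[rc2$a >= 16] + 3)

  expect_error(residue_correspondence("", s), "empty")
})

test_that("chain-averaged C-alpha RMSD covers all chain combinations", {
  toy <- make_toy_complex(5, 60, 30)
  # build helix-like CA-only chains programmatically
  mk_chain <- function(chain, n, jitter = 0, seed = 1) {
    t <- seq_len(n)
    xyz <- cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * t)
    if (jitter > 0)
      xyz <- xyz + withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = jitter), ncol = 3))
    resid <- rep(c("ALA", "GLY", "LEU", "SER", "VAL"), length.out = n)
    data.frame(type = "ATOM", elety = "CA", resid = resid, chain = chain,
               resno = seq_len(n), insert = "", altloc = "",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
               elesy = "C")
  }
  A <- pet_structure("A2", rbind(mk_chain("A", 40), mk_chain("B", 40)))
  B <- pet_structure("B1", mk_chain("A", 40))
  res <- chain_pair_rmsd(A, B)
  expect_equal(res$n_pairs, 2)       # chains {A,B} x {A}
  expect_equal(res$mean, 0, tolerance = 1e-9)
  expect_equal(res$sd, 0, tolerance = 1e-9)

  # identical structure vs itself: 0 +/- 0 regardless of chain count
  self <- chain_pair_rmsd(A, A)
  expect_equal(self$n_pairs, 4)
  expect_equal(self$mean, 0, tolerance = 1e-9)

  # jittered second copy gives a positive mean
  C <- pet_structure("C1", mk_chain("A", 40, jitter = 0.4, seed = 9))
  expect_gt(chain_pair_rmsd(B, C)$mean, 0.2)
})

test_that("ring planes report centroid, normal and planarity", {
  toy <- make_toy_complex(4, 0, 0)
  pl <- ring_plane(toy$structure, toy$protein_ring)
  expect_equal(pl$centroid, c(0, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-9)
  expect_equal(pl$rms, 0, tolerance = 1e-9)

  # equivariance: rotating the structure rotates the normal
  toy30 <- make_toy_complex(4, 30, 0)
  pl30 <- ring_plane(toy30$structure, toy30$ligand_ring)
  expect_equal(pethydro:::interplane_angle(pl30$normal, c(0, 0, 1)), 30,
               tolerance = 1e-6)

  # puckered ring beyond the planarity threshold errors
  at <- toy$structure$atoms
  at$z[at$elety == "CD2"] <- 0.5   # push one ring atom out of plane
  pucker <- pet_structure("pucker", at)
  expect_error(ring_plane(pucker, toy$protein_ring, planarity_tol = 0.1),
               "not planar")
  # and a missing atom is named
  bad <- ring_spec("A", 156, c("CD2", "CE2", "CZ2", "CH2", "CZ3", "XX9"))
  expect_error(ring_plane(toy$structure, bad), "XX9")
})

test_that("pi-stack geometry recovers constructed distance and angle", {
  par <- make_toy_complex(3.5, 0, 0)
  st <- pi_stack_geometry(par$structure, par$protein_ring, par$ligand_ring)
  expect_equal(st$centroid_distance, 3.5, tolerance = 1e-9)
  expect_equal(st$interplanar_angle, 0, tolerance = 1e-6)

  tsh <- make_toy_complex(5.0, 90, 0)
  st2 <- pi_stack_geometry(tsh$structure, tsh$protein_ring, tsh$ligand_ring)
  expect_equal(st2$centroid_distance, 5.0, tolerance = 1e-9)
  expect_equal(st2$interplanar_angle, 90, tolerance = 1e-6)

  # symmetric in its ring arguments
  st3 <- pi_stack_geometry(tsh$structure, tsh$ligand_ring, tsh$protein_ring)
  expect_equal(st3$centroid_distance, st2$centroid_distance)
  expect_equal(st3$interplanar_angle, st2$interplanar_angle)
})

test_that("out-of-plane angle recovers an explicit carboxylate rotation", {
  flat <- make_toy_complex(5, 60, 0)
  expect_equal(out_of_plane_angle(flat$structure, flat$ligand_ring,
                                  c("C7", "O1", "O2")), 0, tolerance = 1e-6)
  rot <- make_toy_complex(5, 60, 25)
  expect_equal(out_of_plane_angle(rot$structure, rot$ligand_ring,
                                  c("C7", "O1", "O2")), 25, tolerance = 0.1)
  # distal carboxylate stays in plane by construction
  expect_equal(out_of_plane_angle(rot$structure, rot$ligand_ring,
                                  c("C8", "O3", "O4")), 0, tolerance = 1e-6)
})

test_that("ligand atom deviations follow the applied transform", {
  toy <- make_toy_complex(5.03, 63.2, 40)
  pairs <- data.frame(a = c("C7", "C8"), b = c("C7", "C8"))
  lig <- list(chain = "A", resno = 301)
  d0 <- ligand_atom_deviation(toy$structure, toy$structure, lig, lig, pairs)
  expect_equal(unname(d0), c(0, 0))

  # ligand translated by 1 A in a copy; protein superposition is identity
  at <- toy$structure$atoms
  sel <- at$resid == "TPA"
  at$x[sel] <- at$x[sel] + 1
  moved <- pet_structure("moved", at)
  ident <- structure(list(rotation = diag(3), translation = c(0, 0, 0)),
                     class = "superposition")
  d1 <- ligand_atom_deviation(toy$structure, moved, lig, lig, pairs,
                              transform = ident)
  expect_equal(unname(d1), c(1, 1), tolerance = 1e-9)
})

octahedron_structure <- function(dist = 2.1, jitter = 0, seed = 1, rot = NULL) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  if (!is.null(rot)) dirs <- dirs %*% t(rot)
  xyz <- dist * dirs
  if (jitter > 0)
    xyz <- xyz + withr::with_seed(seed, matrix(stats::rnorm(18, sd = jitter), ncol = 3))
  atoms <- rbind(
    data.frame(type = "HETATM", elety = "MG", resid = "MG", chain = "A",
               resno = 401L, insert = "", altloc = "", x = 0, y = 0, z = 0,
               o = 1, b = 0, elesy = "Mg"),
    data.frame(type = "HETATM", elety = "O", resid = "HOH", chain = "A",
               resno = 500L + 1:6, insert = "", altloc = "",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
               elesy = "O"))
  pet_structure("octa", atoms)
}

test_that("a perfect octahedron classifies as octahedral with zero angle score", {
  sh <- coordination_shell(octahedron_structure(), "A:401:MG")
  expect_equal(sh$n, 6)
  expect_equal(sh$geometry_class, "octahedral")
  expect_equal(sh$angle_rms, 0, tolerance = 1e-9)
  expect_true(all(sh$ligands$dist <= 2.8))
})

test_that("octahedral classification is stable under rotation and small jitter", {
  for (seed in 1:5) {
    ax <- withr::with_seed(seed, stats::rnorm(3))
    R <- pethydro:::rotation_about_axis(ax, 37 * seed)
    sh <- coordination_shell(octahedron_structure(jitter = 0.05, seed = seed,
                                                  rot = R), "A:401:MG")
    expect_equal(sh$n, 6)
    expect_equal(sh$geometry_class, "octahedral")
  }
})

test_that("non-six-coordinate shells are undefined and empty shells allowed", {
  # square-planar: four ligands only
  sq <- octahedron_structure()
  sq$atoms <- sq$atoms[1:5, ]  # keep Mg + 4 oxygens
  sh4 <- coordination_shell(sq, "A:401:MG")
  expect_equal(sh4$n, 4)
  expect_equal(sh4$geometry_class, "undefined")

  # bare ion: empty shell, not an error
  bare <- octahedron_structure()
  bare$atoms <- bare$atoms[1, , drop = FALSE]
  sh0 <- coordination_shell(bare, "A:401:MG")
  expect_equal(sh0$n, 0)
  expect_equal(sh0$geometry_class, "undefined")
})

test_that("site separation uses ions when present and centroids otherwise", {
  atoms <- rbind(
    data.frame(type = "HETATM", elety = "NA", resid = "NA", chain = "A",
               resno = 402L, insert = "", altloc = "", x = 0, y = 0, z = 0,
               o = 1, b = 0, elesy = "Na"),
    data.frame(type = "HETATM", elety = "MG", resid = "MG", chain = "A",
               resno = 401L, insert = "", altloc = "", x = 0, y = 0, z = 10,
               o = 1, b = 0, elesy = "Mg"),
    data.frame(type = "ATOM", elety = c("OE1", "OE2"), resid = "GLU",
               chain = "A", resno = 148L, insert = "", altloc = "",
               x = c(25, 27), y = 0, z = 0, o = 1, b = 0, elesy = "O"))
  s <- pet_structure("sites", atoms)
  expect_equal(site_separation(s, list("A:402"), list("A:401")), 10)
  expect_equal(site_separation(s, list("A:402"), list("A:402")), 0)
  # no ion in the second site: carboxylate-oxygen centroid at x = 26
  expect_equal(site_separation(s, list("A:402:NA"), list("A:148")), 26)
  expect_error(site_separation(s, list(), list("A:401")), "empty")
})
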