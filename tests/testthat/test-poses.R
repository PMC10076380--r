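chain_cco <- function() ligand_graph("cco", c("C", "C", "O"), rbind(c(1, 2), c(2, 3)))

benzene_graph <- function() {
  ligand_graph("benzene", rep("C", 6), cbind(1:6, c(2:6, 1)))
}

test_that("automorphism groups match brute-force enumeration on small graphs", {
  expect_equal(length(automorphisms(chain_cco())), 1)  # identity only
  expect_equal(length(automorphisms(benzene_graph())), 12)  # dihedral D6

  small <- list(
    chain_cco(),
    benzene_graph(),
    # 2-methyl chain: C(C)(C)-C-O
    ligand_graph("iso", c("C", "C", "C", "C", "O"),
                 rbind(c(1, 2), c(1, 3), c(1, 4), c(4, 5))),
    # cyclopentane with one oxygen substituent
    ligand_graph("cpo", c(rep("C", 5), "O"),
                 rbind(cbind(1:5, c(2:5, 1)), c(1, 6))))
  for (g in small) {
    mine <- automorphisms(g)
    oracle <- brute_force_automorphisms(g)
    expect_equal(length(mine), length(oracle))
    expect_setequal(vapply(mine, paste, "", collapse = ","),
                    vapply(oracle, paste, "", collapse = ","))
  }
})

test_that("TPA and EMT automorphism counts match an independent solver", {
  skip_if_not_installed("igraph")
  count_ref <- function(g) {
    ig <- igraph::graph_from_edgelist(g$bonds, directed = FALSE)
    res <- igraph::count_automorphisms(ig, colors = as.integer(factor(g$elements)))
    as.numeric(res$group_size)
  }
  tpa <- tpa_graph()
  expect_equal(length(automorphisms(tpa)), 16)
  expect_equal(count_ref(tpa), 16)
  emt <- emt_ligand()$graph
  n_emt <- length(automorphisms(emt))
  expect_equal(n_emt, count_ref(emt))
  expect_equal(n_emt, 8)  # terminal O swap x two ring flips
})

test_that("oversized ligands are refused with advice", {
  big <- ligand_graph("big", rep("C", 61), cbind(1:60, 2:61))
  expect_error(automorphisms(big), "partition")
})

test_that("symmetry-corrected RMSD handles relabelings, translations, identity", {
  tpa <- tpa_graph()
  autos <- automorphisms(tpa)
  A <- pethydro:::tpa_coords(30)
  expect_equal(sym_rmsd(A, A, autos), 0)

  # apply a non-identity automorphism: naive RMSD > 0, corrected = 0
  p <- autos[[which(vapply(autos, function(q) any(q != seq_along(q)), TRUE))[1]]]
  B <- A[p, , drop = FALSE]
  expect_gt(sqrt(mean(rowSums((A - B)^2))), 0)
  expect_equal(sym_rmsd(A, B, autos), 0, tolerance = 1e-12)

  # pure translation: exactly the shift magnitude
  expect_equal(sym_rmsd(A, sweep(A, 2, c(3, 0, 0), `+`), autos), 3)

  expect_error(sym_rmsd(A, A[1:6, ], autos), "mismatch")
})

test_that("symmetry-corrected RMSD equals the brute-force minimum and is symmetric", {
  g <- ligand_graph("cpo", c(rep("C", 5), "O"),
                    rbind(cbind(1:5, c(2:5, 1)), c(1, 6)))
  autos <- automorphisms(g)
  for (seed in 1:8) {
    A <- withr::with_seed(seed, matrix(stats::rnorm(18, sd = 2), ncol = 3))
    B <- withr::with_seed(seed + 50, matrix(stats::rnorm(18, sd = 2), ncol = 3))
    mine <- sym_rmsd(A, B, autos)
    expect_equal(mine, brute_force_sym_rmsd(A, B, g), tolerance = 1e-12)
    expect_equal(mine, sym_rmsd(B, A, autos), tolerance = 1e-12)
    # never exceeds the identity-permutation RMSD
    expect_lte(mine, sqrt(mean(rowSums((A - B)^2))) + 1e-12)
  }
})

test_that("RMSD matrices are symmetric with zero diagonal and match construction", {
  # three poses of a rigid TPA translated by a 3-4-5 triangle
  base <- pethydro:::tpa_coords(0)
  coords <- list(p1 = base,
                 p2 = sweep(base, 2, c(3, 0, 0), `+`),
                 p3 = sweep(base, 2, c(3, 4, 0), `+`))
  scores <- data.frame(pose_id = c("p1", "p2", "p3"), total_score = -1,
                       interface_score = -1)
  ps <- pose_set(tpa_graph(), coords, scores)
  M <- rmsd_matrix(ps)
  expect_equal(unclass(M),
               matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3,
                      dimnames = list(names(coords), names(coords))),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unclass(M), t(unclass(M)))
  expect_true(all(diag(M) == 0))
})

test_that("feature distance is the Euclidean distance between RMSD rows", {
  M <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  D <- feature_distance(M)
  expect_equal(D[1, 3], 2 * sqrt(2))   # sqrt((0-2)^2 + (1-1)^2 + (2-0)^2)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_equal(feature_distance(matrix(0, 2, 2))[1, 2], 0)
})

test_that("Ward.D2 clustering separates a 0/1/10/11 line and orders heights", {
  x <- c(0, 1, 10, 11)
  D <- as.matrix(stats::dist(x))
  cl <- ward_cluster(D, 2)
  expect_equal(unname(cl$assignments[1]), unname(cl$assignments[2]))
  expect_equal(unname(cl$assignments[3]), unname(cl$assignments[4]))
  expect_true(cl$assignments[1] != cl$assignments[3])
  expect_true(all(diff(cl$heights) >= -1e-12))  # monotone merges

  # two coincident points merge at height zero
  cl0 <- ward_cluster(as.matrix(stats::dist(c(5, 5))), 1)
  expect_equal(cl0$heights, 0)

  expect_error(ward_cluster(matrix(c(0, NA, NA, 0), 2), 1), "non-finite")
  expect_error(ward_cluster(D, 9), "k must be")
})

test_that("Ward.D2 partitions match exhaustive Ward-objective minimization", {
  for (seed in 1:6) {
    k <- 2 + seed %% 2   # k = 2 or 3
    n <- 7 + seed %% 2   # n = 7 or 8
    centers <- matrix(c(0, 0, 12, 0, 0, 12), ncol = 2, byrow = TRUE)
    pts <- withr::with_seed(seed, {
      lab <- sample(seq_len(k), n, replace = TRUE)
      lab[seq_len(k)] <- seq_len(k)   # every cluster populated
      centers[lab, ] + matrix(stats::rnorm(2 * n, sd = 1.2), ncol = 2)
    })
    D <- as.matrix(stats::dist(pts))
    got <- canon_partition(ward_cluster(D, k)$assignments)
    parts <- partitions_into_k(n, k)
    objs <- vapply(parts, function(p) ward_objective(D, p), 0)
    best <- parts[[which.min(objs)]]
    expect_equal(got, canon_partition(rep(seq_along(best),
                                          times = lengths(best))[order(unlist(best))]))
  }
})

test_that("reference-cluster selection prefers proximity and reports ties", {
  ens <- make_pose_ensemble(k = 3, n_per_cluster = c(6, 10, 8), seed = 21)
  M <- rmsd_matrix(ens$poses)
  cl <- ward_cluster(feature_distance(M), 3)
  sel <- select_reference_cluster(cl, ens$poses, ens$reference_ring)
  # cluster containing the poses generated at the reference site wins
  ref_members <- names(ens$truth$labels)[ens$truth$labels == 1]
  expect_equal(sort(names(cl$assignments)[cl$assignments == sel$selected]),
               sort(ref_members))
  expect_false(sel$tie)
  # when cluster 1 is also most populated, selection = most populated
  ens2 <- make_pose_ensemble(k = 3, n_per_cluster = c(12, 6, 6), seed = 22)
  cl2 <- ward_cluster(feature_distance(rmsd_matrix(ens2$poses)), 3)
  sel2 <- select_reference_cluster(cl2, ens2$poses, ens2$reference_ring)
  expect_equal(sel2$selected, sel2$most_populated)

  # all clusters exactly equidistant -> lowest id with tie flag
  base <- pethydro:::tpa_coords(0)
  coords <- list(a = base, b = sweep(base, 2, c(0, 0, 4), `+`))
  ps <- pose_set(tpa_graph(), coords,
                 data.frame(pose_id = c("a", "b"), total_score = 0,
                            interface_score = 0),
                 ring_atoms = list(subsite_I = 1:6))
  clx <- ward_cluster(feature_distance(rmsd_matrix(ps)), 2)
  ref <- sweep(base[1:6, ], 2, c(0, 0, 2), `+`)  # equidistant from both rings
  selx <- select_reference_cluster(clx, ps, ref)
  expect_true(selx$tie)
  expect_equal(selx$selected, 1)
})

test_that("interface-score aggregation takes the n best and flags small clusters", {
  coords <- lapply(1:3, function(i) pethydro:::tpa_coords(0))
  names(coords) <- c("a", "b", "c")
  ps <- pose_set(tpa_graph(), coords,
                 data.frame(pose_id = c("a", "b", "c"), total_score = 0,
                            interface_score = c(-6, -10, -8)))
  agg <- aggregate_interface_score(ps, c("a", "b", "c"), n_best = 2)
  expect_equal(agg$mean, -9)          # mean of {-10, -8}
  expect_equal(agg$sd, sqrt(2))
  expect_false(agg$used_all)
  # invariant under pose reordering
  agg2 <- aggregate_interface_score(ps, c("c", "a", "b"), n_best = 2)
  expect_equal(agg2$mean, agg$mean)
  # equal scores give zero SD; small cluster is flagged
  ps$scores$interface_score <- rep(-12, 3)
  agg3 <- aggregate_interface_score(ps, c("a", "b"), n_best = 10)
  expect_equal(agg3$mean, -12)
  expect_equal(agg3$sd, 0)
  expect_true(agg3$used_all)
})

test_that("per-residue profiles average energies and enforce a common label set", {
  coords <- lapply(1:2, function(i) pethydro:::tpa_coords(0))
  names(coords) <- c("a", "b")
  E <- matrix(c(-5, -6, -1, -2), 2, dimnames = list(c("a", "b"), c("X210", "F63")))
  ps <- pose_set(tpa_graph(), coords,
                 data.frame(pose_id = c("a", "b"), total_score = 0,
                            interface_score = 0), res_energy = E)
  prof <- per_residue_profile(ps, c("a", "b"))
  expect_equal(prof$residue, c("F63", "X210"))  # ordered by residue number
  x210 <- prof[prof$residue == "X210", ]
  expect_equal(x210$mean, -5.5)
  expect_equal(x210$sd, 0.7071068, tolerance = 1e-6)
  # single pose: means echo values, SD 0
  p1 <- per_residue_profile(ps, "a")
  expect_equal(p1$sd, c(0, 0))
  # a residue missing from one member errors by name
  ps$res_energy["b", "X210"] <- NA
  expect_error(per_residue_profile(ps, c("a", "b")), "X210")
})

test_that("ring-RMSD statistics use the best pose as reference and 1.5 IQR whiskers", {
  ens <- make_pose_ensemble(k = 1, n_per_cluster = 12, within_spread = 0.05,
                            subsite_spreads = c(0.2, 1.0), relabel_prob = 0,
                            seed = 31)
  rr <- ring_rmsd_stats(ens$poses, ens$poses$pose_ids)
  expect_equal(rr$reference,
               ens$poses$scores$pose_id[which.min(ens$poses$scores$total_score)])
  expect_gt(rr$subsite_II$median, rr$subsite_I$median)
  expect_equal(min(rr$subsite_I$values), 0)  # the reference against itself

  # identical members: degenerate box at zero
  base <- pethydro:::tpa_coords(0)
  coords <- list(a = base, b = base, c = base)
  ps <- pose_set(tpa_graph(), coords,
                 data.frame(pose_id = c("a", "b", "c"),
                            total_score = c(-3, -1, -2), interface_score = 0),
                 ring_atoms = list(ring = 1:6))
  rr0 <- ring_rmsd_stats(ps, c("a", "b", "c"))
  expect_equal(rr0$ring$median, 0)
  expect_equal(rr0$ring$upper_whisker, 0)

  # hand-checkable whisker rule
  b <- pethydro:::box_summary(c(0.1, 0.2, 0.3, 0.4, 5.0))
  expect_equal(b$median, 0.3)
  expect_equal(b$q1, 0.2)
  expect_equal(b$q3, 0.4)
  expect_equal(b$upper_whisker, 0.4)   # 5.0 lies beyond Q3 + 1.5 IQR
  expect_equal(b$lower_whisker, 0.1)
  expect_equal(b$outliers, 5.0)

  expect_error(ring_rmsd_stats(ps, c("a", "b"), list(ring = 10:16)),
               "outside ligand")
})
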