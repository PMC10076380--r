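# Docking-pose post-processing: graph-automorphism enumeration,
# symmetry-corrected ligand RMSD in a fixed receptor frame, Ward.D2
# clustering of the RMSD feature matrix, reference-cluster selection, and
# binding-energy / ring-diversity statistics.

#' Docking pose set
#'
#' Poses share one ligand topology and live in a common (receptor) frame,
#' so pose comparisons never re-superpose.
#'
#' @param ligand a [ligand_graph()].
#' @param coords named list of n_atoms x 3 coordinate matrices, atom order
#'   identical to the ligand topology.
#' @param scores data.frame with `pose_id`, `total_score`,
#'   `interface_score` (Rosetta energy units; lower = stronger predicted
#'   binding).
#' @param res_energy optional matrix of per-residue binding energies
#'   (rows = pose ids, columns = residue labels such as `"L210"`).
#' @param ring_atoms optional named list of atom index vectors for the
#'   ligand's aromatic rings (e.g. `subsite_I`, `subsite_II`).
#' @return object of class `pose_set`.
#' @export
pose_set <- function(ligand, coords, scores, res_energy = NULL,
                     ring_atoms = NULL) {
  stopifnot(inherits(ligand, "ligand_graph"))
  ids <- as.character(scores$pose_id)
  if (anyDuplicated(ids)) stopf("duplicate pose ids")
  if (!setequal(names(coords), ids)) stopf("coords and scores disagree on pose ids")
  n <- length(ligand$elements)
  for (pid in ids) {
    xyz <- coords[[pid]]
    if (nrow(xyz) != n) stopf("pose %s: %d atoms, topology has %d", pid, nrow(xyz), n)
    if (!is_finite_matrix(as.matrix(xyz))) stopf("pose %s has non-finite coordinates", pid)
  }
  scores$pose_id <- ids
  structure(list(ligand = ligand, pose_ids = ids, coords = coords[ids],
                 scores = scores, res_energy = res_energy,
                 ring_atoms = ring_atoms),
            class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("<pose_set> %d poses of %s (%d heavy atoms)\n",
              length(x$pose_ids), x$ligand$name, length(x$ligand$elements)))
  invisible(x)
}

#' Graph automorphisms of a ligand
#'
#' Enumerates all permutations of the heavy atoms that preserve both
#' element labels and bond adjacency (the molecular-graph automorphism
#' group), by depth-first backtracking with element/degree/neighborhood
#' pruning. The identity is always included. This group underlies
#' symmetry-corrected RMSD: atoms equivalent by molecular symmetry (e.g.
#' the two carboxylate oxygens of terephthalate, or a phenylene ring
#' flip) are interchangeable labelings of the same molecule.
#'
#' @param graph a [ligand_graph()].
#' @param max_atoms refuse larger graphs (default 60).
#' @param max_nodes abort the search beyond this many search-tree nodes
#'   (default 1e6).
#' @return list of integer permutations `p` (atom `i` maps to `p[i]`).
#' @export
automorphisms <- function(graph, max_atoms = 60, max_nodes = 1e6) {
  n <- length(graph$elements)
  if (n > max_atoms)
    stopf("ligand has %d atoms (limit %d); partition the molecule", n, max_atoms)
  A <- adjacency(graph)
  deg <- rowSums(A)
  # one refinement round: color by element, degree and sorted multiset of
  # neighbor (element, degree) labels
  base <- paste(graph$elements, deg)
  nbhd <- vapply(seq_len(n), function(i) {
    paste(sort(base[A[i, ] == 1]), collapse = "|")
  }, "")
  color <- paste(base, nbhd)
  perms <- list()
  map <- integer(n)
  used <- logical(n)
  nodes <- 0L
  search <- function(i) {
    if (i > n) {
      perms[[length(perms) + 1L]] <<- map
      return(invisible())
    }
    for (cand in which(!used & color == color[i])) {
      nodes <<- nodes + 1L
      if (nodes > max_nodes) stopf("automorphism search exceeded %g nodes", max_nodes)
      prev <- seq_len(i - 1L)
      if (i == 1L || all(A[i, prev] == A[cand, map[prev]])) {
        map[i] <<- cand; used[cand] <<- TRUE
        search(i + 1L)
        used[cand] <<- FALSE
      }
    }
  }
  search(1L)
  perms
}

#' Symmetry-corrected RMSD between two poses
#'
#' Minimum in-place RMSD over all graph automorphisms. No re-superposition
#' is performed: docking poses are compared in the shared receptor frame,
#' as in dedicated docking-pose RMSD tools.
#'
#' @param poseA,poseB n x 3 coordinate matrices (same atom count/order).
#' @param autos automorphism list from [automorphisms()].
#' @return RMSD in Angstroms.
#' @export
sym_rmsd <- function(poseA, poseB, autos) {
  poseA <- as.matrix(poseA); poseB <- as.matrix(poseB)
  if (nrow(poseA) != nrow(poseB)) stopf("atom-count mismatch: %d vs %d",
                                        nrow(poseA), nrow(poseB))
  best <- Inf
  for (p in autos) {
    r <- sqrt(mean(rowSums((poseA - poseB[p, , drop = FALSE])^2)))
    if (r < best) best <- r
  }
  best
}

#' Pairwise symmetry-corrected RMSD matrix
#'
#' @param poses a [pose_set()].
#' @return symmetric matrix (class `rmsd_matrix`) with zero diagonal,
#'   pose ids as dimnames.
#' @export
rmsd_matrix <- function(poses) {
  ids <- poses$pose_ids
  if (length(ids) < 2) stopf("need at least 2 poses")
  autos <- automorphisms(poses$ligand)
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- sym_rmsd(poses$coords[[i]], poses$coords[[j]], autos)
  }
  class(M) <- c("rmsd_matrix", class(M))
  M
}

#' Euclidean feature distance between poses
#'
#' Treats each pose as the feature vector of its RMSDs to every pose (one
#' row of the RMSD matrix) and computes Euclidean distances between those
#' rows via `stats::dist()`. This feature-space embedding is the input to
#' Ward clustering.
#'
#' @param M an [rmsd_matrix()].
#' @return square symmetric distance matrix.
#' @export
feature_distance <- function(M) {
  M <- unclass(M)
  if (!isSymmetric(M, tol = 1e-8)) stopf("RMSD matrix must be symmetric")
  if (!all(is.finite(M))) stopf("non-finite RMSD entries")
  as.matrix(stats::dist(M))
}

#' Ward.D2 hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with the `ward.D2` linkage (distances squared
#' inside the Lance-Williams update, merge heights reported back on the
#' unsquared scale), cut into `k` clusters.
#'
#' @param D square distance matrix (or `dist`).
#' @param k number of clusters, `1 <= k <= n`.
#' @return object of class `cluster_result`: `assignments` (named integer
#'   vector), `heights` (non-decreasing merge heights), `k`, `hclust`.
#' @export
ward_cluster <- function(D, k) {
  Dm <- as.matrix(D)
  if (!all(is.finite(Dm))) stopf("non-finite distances")
  n <- nrow(Dm)
  if (k < 1 || k > n) stopf("k must be in 1..%d", n)
  hc <- stats::hclust(stats::as.dist(Dm), method = "ward.D2")
  assignments <- stats::cutree(hc, k = k)
  structure(list(assignments = assignments, heights = hc$height, k = k,
                 hclust = hc),
            class = "cluster_result")
}

#' Select the reference cluster by crystal-ring proximity
#'
#' The cluster whose members' subsite-I phenylene ring centroids lie, on
#' average, closest to the centroid of the crystallographic reference ring
#' is selected. This replaces a visual assessment of ring placement with a
#' monotone, automatable proxy. The most-populated cluster id is reported
#' alongside as a cross-check. Ties within 1e-6 Angstroms resolve to the
#' lower cluster id and set `tie = TRUE`.
#'
#' @param clusters a [ward_cluster()] result over the poses.
#' @param poses a [pose_set()] with `ring_atoms$subsite_I` set (or pass
#'   `ring_atoms`).
#' @param reference_ring m x 3 coordinates of the crystal ligand's
#'   phenylene ring (>= 5 atoms).
#' @param ring_atoms atom indices of the subsite-I ring within the ligand.
#' @return list with `selected`, `mean_distance` (per cluster),
#'   `most_populated`, `tie`.
#' @export
select_reference_cluster <- function(clusters, poses, reference_ring,
                                     ring_atoms = poses$ring_atoms$subsite_I) {
  if (is.null(ring_atoms)) stopf("subsite-I ring atom indices are required")
  reference_ring <- as.matrix(reference_ring)
  if (nrow(reference_ring) < 5) stopf("reference ring needs >= 5 atoms")
  ref_c <- colMeans(reference_ring)
  asg <- clusters$assignments
  ids <- sort(unique(asg))
  md <- vapply(ids, function(cl) {
    members <- names(asg)[asg == cl]
    mean(vapply(members, function(pid) {
      vec_norm(colMeans(poses$coords[[pid]][ring_atoms, , drop = FALSE]) - ref_c)
    }, 0))
  }, 0)
  names(md) <- ids
  best <- min(md)
  cand <- ids[md <= best + 1e-6]
  sizes <- table(asg)
  list(selected = min(cand), mean_distance = md,
       most_populated = as.integer(names(sizes)[which.max(sizes)]),
       tie = length(cand) > 1)
}

#' Aggregate interface score over the best poses of a cluster
#'
#' Sorts cluster members by interface score ascending (lower = stronger
#' predicted binding, the Rosetta sign convention) and averages the best
#' `n_best`. If the cluster is smaller than `n_best`, all members are used
#' and `used_all` is flagged.
#'
#' @param poses a [pose_set()].
#' @param members pose ids in the cluster.
#' @param n_best how many top poses to average (default 10).
#' @return list with `mean`, `sd` (sample SD), `n_used`, `used_all`.
#' @export
aggregate_interface_score <- function(poses, members, n_best = 10) {
  if (!length(members)) stopf("empty cluster")
  sc <- poses$scores
  s <- sc$interface_score[match(members, sc$pose_id)]
  if (anyNA(s)) stopf("unknown pose id(s): %s",
                      paste(members[is.na(s)], collapse = ","))
  s <- sort(s)
  used <- s[seq_len(min(n_best, length(s)))]
  list(mean = mean(used),
       sd = if (length(used) > 1) stats::sd(used) else 0,
       n_used = length(used), used_all = length(s) < n_best)
}

#' Per-residue binding-energy profile of a cluster
#'
#' Mean and sample SD of each residue's energetic contribution across the
#' cluster members, ordered by residue number. All members must carry a
#' complete energy map over the common residue label set.
#'
#' @param poses a [pose_set()] with `res_energy`.
#' @param members pose ids in the cluster.
#' @return data.frame with `residue`, `mean`, `sd`, ordered by residue
#'   number parsed from the label.
#' @export
per_residue_profile <- function(poses, members) {
  if (is.null(poses$res_energy)) stopf("pose set has no per-residue energies")
  E <- poses$res_energy[members, , drop = FALSE]
  bad <- colnames(E)[colSums(is.na(E)) > 0]
  if (length(bad))
    stopf("residue(s) absent from some pose map: %s", paste(bad, collapse = ","))
  resno <- as.integer(sub("^[A-Za-z]+", "", colnames(E)))
  ord <- order(resno)
  data.frame(residue = colnames(E)[ord],
             mean = colMeans(E)[ord],
             sd = apply(E, 2, function(x) if (length(x) > 1) stats::sd(x) else 0)[ord],
             row.names = NULL)
}

# box-plot summary: quartiles plus whiskers at the extreme observations
# within 1.5 IQR of the quartiles
box_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo <- x[x >= q[1] - 1.5 * iqr]
  hi <- x[x <= q[3] + 1.5 * iqr]
  list(values = x, q1 = q[1], median = q[2], q3 = q[3],
       lower_whisker = min(lo), upper_whisker = max(hi),
       outliers = x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr])
}

#' Ring-RMSD diversity statistics within a cluster
#'
#' Conformational diversity of each aromatic ring across cluster members:
#' the member with the lowest (best) total score is the reference, and
#' every member's ring is compared to it by in-place, symmetry-corrected
#' RMSD restricted to the ring atoms (ring-flip relabelings of the ring
#' subgraph are allowed). Summaries follow box-and-whisker convention with
#' whiskers at the most extreme values within 1.5 interquartile ranges of
#' the quartiles.
#'
#' @param poses a [pose_set()].
#' @param members pose ids in the cluster (>= 2).
#' @param ring_atom_sets named list of atom index vectors, one per subsite
#'   ring; defaults to `poses$ring_atoms`.
#' @return named list (per ring) of box summaries plus `reference` pose id.
#' @export
ring_rmsd_stats <- function(poses, members, ring_atom_sets = poses$ring_atoms) {
  if (length(members) < 2) stopf("need >= 2 cluster members")
  if (is.null(ring_atom_sets) || !length(ring_atom_sets))
    stopf("ring atom sets are required")
  n_atoms <- length(poses$ligand$elements)
  for (idx in ring_atom_sets)
    if (min(idx) < 1 || max(idx) > n_atoms) stopf("ring atoms outside ligand")
  sc <- poses$scores
  ts <- sc$total_score[match(members, sc$pose_id)]
  ref <- members[which.min(ts)]
  out <- lapply(names(ring_atom_sets), function(nm) {
    idx <- ring_atom_sets[[nm]]
    sub <- subgraph_of(poses$ligand, idx)
    autos <- automorphisms(sub)
    vals <- vapply(members, function(pid) {
      sym_rmsd(poses$coords[[pid]][idx, , drop = FALSE],
               poses$coords[[ref]][idx, , drop = FALSE], autos)
    }, 0)
    box_summary(unname(vals))
  })
  names(out) <- names(ring_atom_sets)
  out$reference <- ref
  out
}

# induced subgraph on atom indices idx (as a ligand_graph)
subgraph_of <- function(g, idx) {
  pos <- match(seq_along(g$elements), idx)
  b <- g$bonds
  keep <- b[, 1] %in% idx & b[, 2] %in% idx
  structure(list(name = paste0(g$name, "[sub]"),
                 elements = g$elements[idx],
                 bonds = matrix(cbind(pos[b[keep, 1]], pos[b[keep, 2]]), ncol = 2)),
            class = "ligand_graph")
}
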