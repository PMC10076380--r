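# Structural measurements: rigid-body superposition, homolog residue
# mapping, chain-averaged C-alpha RMSD, aromatic ring geometry,
# carboxylate out-of-plane rotation, ligand atom deviations, and metal
# coordination shells.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired coordinates. The transform maps the mobile set onto the target
#' frame: `aligned = mobile %*% rotation + translation` (row vectors).
#'
#' @param mobile,target n x 3 coordinate matrices (Angstroms).
#' @param pairs optional two-column index matrix pairing `mobile[pairs[,1],]`
#'   with `target[pairs[,2],]`; default pairs rows 1:1.
#' @return object of class `superposition` with `rotation` (3x3,
#'   `det = +1`), `translation`, `rmsd` and `n_pairs`.
#' @export
superpose <- function(mobile, target, pairs = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!is.null(pairs)) {
    mobile <- mobile[pairs[, 1], , drop = FALSE]
    target <- target[pairs[, 2], , drop = FALSE]
  }
  if (nrow(mobile) != nrow(target)) stopf("paired sets differ in size")
  n <- nrow(mobile)
  if (n < 3) stopf("need at least 3 atom pairs, got %d", n)
  if (!is_finite_matrix(mobile) || !is_finite_matrix(target))
    stopf("non-finite coordinates")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  for (X in list(P, Q)) {
    sv <- svd(X)
    if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
      stopf("point set is collinear; superposition is ill-defined")
  }
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  aligned <- P %*% R
  rmsd <- sqrt(mean(rowSums((aligned - Q)^2)))
  structure(list(rotation = R, translation = as.numeric(ct - cm %*% R),
                 rmsd = rmsd, n_pairs = n),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param sp a [superpose()] result.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, sp) {
  sweep(as.matrix(xyz) %*% sp$rotation, 2, sp$translation, `+`)
}

#' Residue correspondence between homologous sequences
#'
#' Global pairwise alignment (BLOSUM62, affine gaps: opening 10,
#' extension 0.5) of one-letter sequences; returns the match columns only
#' (positions aligned residue-to-residue, including mismatches, excluding
#' gaps). Gap-adjacent columns are kept.
#'
#' @param seqA,seqB one-letter amino-acid sequences (single strings).
#' @return data.frame with columns `a`, `b`: 1-based residue positions.
#' @export
residue_correspondence <- function(seqA, seqB) {
  if (!nzchar(seqA) || !nzchar(seqB)) stopf("empty sequence")
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = data_env$BLOSUM62,
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(sa != "-")
  keep <- pa != "-" & sa != "-"
  data.frame(a = ia[keep], b = ib[keep])
}

# protein chains as list(chain -> list(seq, resno, ca (matrix))) using
# residues that carry a CA atom and a standard residue name
protein_chains <- function(struct) {
  at <- struct$atoms
  ca <- at[at$elety == "CA" & !at$is_water & at$resid %in% bio3d::aa.table$aa3, ,
           drop = FALSE]
  if (nrow(ca) == 0) return(list())
  out <- lapply(split(ca, ca$chain), function(d) {
    d <- d[order(d$resno, d$insert), ]
    list(seq = paste(bio3d::aa321(d$resid), collapse = ""),
         resno = d$resno,
         ca = as.matrix(d[, c("x", "y", "z")]))
  })
  out[order(names(out))]
}

#' Chain-averaged C-alpha RMSD between two structures
#'
#' For every (chain of A) x (chain of B) combination the sequences are
#' aligned with [residue_correspondence()], the matched C-alpha pairs
#' superposed with [superpose()], and the per-pair RMSDs averaged. The
#' spread is the population standard deviation over chain pairs, matching
#' the convention of reporting a mean over all asymmetric-unit chain
#' comparisons plus/minus SD.
#'
#' @param structA,structB [pet_structure()] objects.
#' @return list with `mean`, `sd`, `rmsds` (named per chain pair),
#'   `n_pairs`.
#' @export
chain_pair_rmsd <- function(structA, structB) {
  cha <- protein_chains(structA); chb <- protein_chains(structB)
  if (!length(cha) || !length(chb)) stopf("no protein chain with C-alpha atoms")
  rmsds <- c()
  for (na in names(cha)) for (nb in names(chb)) {
    a <- cha[[na]]; b <- chb[[nb]]
    corr <- residue_correspondence(a$seq, b$seq)
    if (nrow(corr) < 3) next
    sp <- superpose(a$ca[corr$a, , drop = FALSE], b$ca[corr$b, , drop = FALSE])
    rmsds[paste0(structA$id, ":", na, "-", structB$id, ":", nb)] <- sp$rmsd
  }
  if (!length(rmsds)) stopf("no alignable chain pairs")
  list(mean = mean(rmsds), sd = pop_sd(rmsds), rmsds = rmsds,
       n_pairs = length(rmsds))
}

#' Specify a planar ring by residue and atom names
#'
#' Helpers for common aromatic rings: [trp_ring()] selects the
#' six-membered, five-membered or full nine-atom indole ring of a
#' tryptophan; [phe_ring()] the phenyl ring; [tpa_ring()] the phenylene
#' ring of a bound terephthalate-like ligand (atom names `C1`-`C6` by
#' default).
#'
#' @param chain,resno residue address in the structure.
#' @param atoms ordered atom names forming the ring (>= 5).
#' @param label free-text label.
#' @return object of class `ring_spec`.
#' @export
ring_spec <- function(chain, resno, atoms, label = NULL) {
  if (length(atoms) < 5) stopf("a ring needs at least 5 atoms")
  structure(list(chain = chain, resno = resno, atoms = atoms,
                 label = label %||% sprintf("%s:%s", chain, resno)),
            class = "ring_spec")
}

#' @rdname ring_spec
#' @param which for tryptophan: which ring to use. The six-membered benzene
#'   ring of the indole is the default for stacking geometry; the
#'   five-membered ring and the full indole are selectable because
#'   centroid conventions differ between analysis tools.
#' @export
trp_ring <- function(chain, resno, which = c("six", "five", "indole")) {
  which <- match.arg(which)
  atoms <- switch(which,
    six = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"),
    five = c("CG", "CD1", "NE1", "CE2", "CD2"),
    indole = c("CG", "CD1", "NE1", "CE2", "CZ2", "CH2", "CZ3", "CE3", "CD2"))
  ring_spec(chain, resno, atoms, label = sprintf("TRP%s(%s)", resno, which))
}

#' @rdname ring_spec
#' @export
phe_ring <- function(chain, resno) {
  ring_spec(chain, resno, c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
            label = sprintf("PHE%s", resno))
}

#' @rdname ring_spec
#' @export
tpa_ring <- function(chain, resno, atoms = paste0("C", 1:6)) {
  ring_spec(chain, resno, atoms, label = sprintf("TPA%s", resno))
}

#' Ring centroid and least-squares plane normal
#'
#' @param struct a [pet_structure()].
#' @param ring a [ring_spec()].
#' @param planarity_tol maximum RMS deviation (Angstroms) of the ring atoms
#'   from their best plane; default 0.1.
#' @return list with `centroid`, `normal` (unit vector, sign arbitrary),
#'   `rms`.
#' @export
ring_plane <- function(struct, ring, planarity_tol = 0.1) {
  xyz <- residue_coords(struct, ring$chain, ring$resno, ring$atoms)
  pl <- lsq_plane(xyz)
  if (pl$rms > planarity_tol)
    stopf("ring %s is not planar: RMS %.3f A exceeds %.3f A", ring$label,
          pl$rms, planarity_tol)
  pl
}

#' Pi-stacking geometry between two rings
#'
#' Centroid-to-centroid distance and interplanar angle
#' `acos(|n_A . n_B|)` folded into `[0, 90]` degrees, so the result never
#' depends on normal orientation. Parallel (face-to-face) stacks give
#' angles near 0, T-shaped (edge-to-face) contacts angles near 90.
#'
#' @inheritParams ring_plane
#' @param ringA,ringB [ring_spec()] objects.
#' @return list with `centroid_distance` (Angstroms) and
#'   `interplanar_angle` (degrees).
#' @export
pi_stack_geometry <- function(struct, ringA, ringB, planarity_tol = 0.1) {
  pa <- ring_plane(struct, ringA, planarity_tol)
  pb <- ring_plane(struct, ringB, planarity_tol)
  list(centroid_distance = vec_norm(pa$centroid - pb$centroid),
       interplanar_angle = interplane_angle(pa$normal, pb$normal))
}

#' Out-of-plane rotation of a substituent group
#'
#' Angle between the least-squares plane of a substituent (typically a
#' carboxylate: carboxyl carbon plus both oxygens) and the aromatic ring
#' plane, folded into `[0, 90]` degrees.
#'
#' @inheritParams ring_plane
#' @param group_chain,group_resno residue address of the group (defaults to
#'   the ring's).
#' @param group_atoms atom names of the substituent plane (>= 3,
#'   non-collinear).
#' @return angle in degrees.
#' @export
out_of_plane_angle <- function(struct, ring, group_atoms,
                               group_chain = ring$chain,
                               group_resno = ring$resno,
                               planarity_tol = 0.1) {
  if (length(group_atoms) < 3) stopf("group needs at least 3 atoms")
  pr <- ring_plane(struct, ring, planarity_tol)
  xyz <- residue_coords(struct, group_chain, group_resno, group_atoms)
  pg <- lsq_plane(xyz)  # errors on collinear atoms
  interplane_angle(pr$normal, pg$normal)
}

#' Ligand atom deviations after protein superposition
#'
#' Applies a protein-derived transform mapping structure B into A's frame,
#' then reports the Euclidean distance between named ligand atom pairs.
#'
#' @param structA,structB [pet_structure()] objects.
#' @param ligA,ligB lists `list(chain=, resno=)` addressing the ligand
#'   residue in each structure.
#' @param atom_pairs data.frame with columns `a`, `b`: atom names in
#'   ligand A and B.
#' @param transform a [superpose()] result mapping B onto A (e.g. from the
#'   best chain pair of [chain_pair_rmsd()]); identity if `NULL`.
#' @return named numeric vector of deviations (Angstroms), named
#'   `"a/b"`.
#' @export
ligand_atom_deviation <- function(structA, structB, ligA, ligB, atom_pairs,
                                  transform = NULL) {
  xa <- residue_coords(structA, ligA$chain, ligA$resno, atom_pairs$a)
  xb <- residue_coords(structB, ligB$chain, ligB$resno, atom_pairs$b)
  if (!is.null(transform)) xb <- apply_transform(xb, transform)
  d <- sqrt(rowSums((xa - xb)^2))
  names(d) <- paste(atom_pairs$a, atom_pairs$b, sep = "/")
  d
}

#' Metal coordination shell
#'
#' Collects all oxygen and nitrogen atoms within `cutoff` of a center atom
#' and classifies the shell geometry. With exactly six ligating atoms the
#' 15 ligand-center-ligand angles are compared to the ideal octahedral set
#' (twelve 90-degree cis and three 180-degree trans angles, each observed
#' angle scored against the nearer ideal); an RMS deviation below 15
#' degrees classifies the shell as `"octahedral"`, otherwise
#' `"distorted"`. Any other ligand count gives class `"undefined"`. An
#' empty shell is returned (not an error) with class `"undefined"`.
#'
#' @param struct a [pet_structure()].
#' @param center selection string `chain:resno:atomname` for the ion.
#' @param cutoff shell radius in Angstroms; default 2.8, appropriate for
#'   Mg or Na first shells.
#' @return object of class `coordination_shell`: `center` (atom row),
#'   `ligands` (data.frame with distances), `n`, `geometry_class`,
#'   `angle_rms` (degrees, `NA` unless n = 6).
#' @export
coordination_shell <- function(struct, center, cutoff = 2.8) {
  ctr <- atom_select(struct, sel = center)
  if (nrow(ctr) != 1) stopf("center selection '%s' matched %d atoms", center, nrow(ctr))
  at <- struct$atoms
  cand <- at[at$elesy %in% c("O", "N"), , drop = FALSE]
  cxyz <- as.numeric(ctr[, c("x", "y", "z")])
  d <- sqrt((cand$x - cxyz[1])^2 + (cand$y - cxyz[2])^2 + (cand$z - cxyz[3])^2)
  keep <- d <= cutoff & d > 1e-6
  lig <- cand[keep, , drop = FALSE]
  lig$dist <- d[keep]
  lig <- lig[order(lig$dist), ]
  n <- nrow(lig)
  angle_rms <- NA_real_
  cls <- "undefined"
  if (n == 6) {
    V <- sweep(as.matrix(lig[, c("x", "y", "z")]), 2, cxyz)
    V <- V / sqrt(rowSums(V^2))
    ang <- c()
    for (i in 1:5) for (j in (i + 1):6)
      ang <- c(ang, rad2deg(acos(max(-1, min(1, sum(V[i, ] * V[j, ]))))))
    dev <- pmin(abs(ang - 90), abs(ang - 180))
    angle_rms <- sqrt(mean(dev^2))
    cls <- if (angle_rms < 15) "octahedral" else "distorted"
  }
  structure(list(center = ctr, ligands = lig, n = n, geometry_class = cls,
                 angle_rms = angle_rms, cutoff = cutoff),
            class = "coordination_shell")
}

#' @export
print.coordination_shell <- function(x, ...) {
  cat(sprintf("<coordination_shell> %s %s:%s: %d ligand(s) within %.2f A, class %s",
              x$center$elety, x$center$chain, x$center$resno, x$n, x$cutoff,
              x$geometry_class))
  if (!is.na(x$angle_rms)) cat(sprintf(" (angle RMS %.1f deg)", x$angle_rms))
  cat("\n")
  invisible(x)
}

# reference point of a metal site: the bound ion if one is present among
# the site's residues, else the centroid of the ligating carboxylate oxygens
site_reference_point <- function(struct, site) {
  metals <- c("Mg", "Na", "Ca", "Zn", "K", "Mn", "Fe")
  rows <- do.call(rbind, lapply(site, function(s) {
    if (is.character(s)) atom_select(struct, sel = s)
    else atom_select(struct, chain = s$chain, resno = s$resno)
  }))
  if (is.null(rows) || nrow(rows) == 0) stopf("empty site selection")
  ion <- rows[rows$elesy %in% metals, , drop = FALSE]
  if (nrow(ion)) return(as.numeric(ion[1, c("x", "y", "z")]))
  carbox <- rows[rows$elety %in% c("OE1", "OE2", "OD1", "OD2"), , drop = FALSE]
  if (nrow(carbox) == 0) carbox <- rows
  colMeans(as.matrix(carbox[, c("x", "y", "z")]))
}

#' Separation between two (metal) sites
#'
#' Each site is a list of selections (strings `"chain:resno"` /
#' `"chain:resno:atom"` or lists `list(chain=, resno=)`). The site
#' reference point is the bound metal ion when present, otherwise the
#' centroid of the ligating carboxylate oxygens of the listed residues.
#'
#' @param struct a [pet_structure()].
#' @param siteA,siteB site selections (non-empty lists).
#' @return distance in Angstroms.
#' @export
site_separation <- function(struct, siteA, siteB) {
  if (!length(siteA) || !length(siteB)) stopf("empty site selection")
  vec_norm(site_reference_point(struct, siteA) -
           site_reference_point(struct, siteB))
}
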