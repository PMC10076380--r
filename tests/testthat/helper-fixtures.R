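# In-code fixtures and independent oracles shared across test files.

# ---- text-format writers -------------------------------------------------

pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, elesy = substr(elety, 1, 1),
                          type = "ATOM", altloc = " ") {
  name4 <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else elety
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name4, altloc, resid, chain, resno, x, y, z, occ, b,
          elesy)
}

write_mini_pdb <- function(path, serial_offset = 0, altloc_demo = FALSE) {
  lines <- c(
    pdb_atom_line(1 + serial_offset, "N", "ALA", "A", 1, 11.104, 6.134, -6.504),
    pdb_atom_line(2 + serial_offset, "CA", "ALA", "A", 1, 11.639, 6.071, -5.147, elesy = "C"),
    pdb_atom_line(3 + serial_offset, "C", "ALA", "A", 1, 12.697, 7.139, -4.899))
  if (altloc_demo) {
    lines <- c(lines,
      pdb_atom_line(4 + serial_offset, "CB", "ALA", "A", 1, 10.5, 5.0, -4.7,
                    occ = 0.6, altloc = "A", elesy = "C"),
      pdb_atom_line(5 + serial_offset, "CB", "ALA", "A", 1, 10.6, 5.1, -4.8,
                    occ = 0.4, altloc = "B", elesy = "C"))
  }
  writeLines(c(lines, "END"), path)
  path
}

write_mini_cif <- function(path) {
  writeLines(c(
    "data_mini", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol", "label_atom_id",
      "label_alt_id", "label_comp_id", "label_asym_id", "label_entity_id",
      "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
      "occupancy", "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")),
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 12.697 7.139 -4.899 1.00 0.00 1 ALA A C 1"),
    path)
  path
}

# minimal V2000 SDF writer (hydrogens included as listed)
write_sdf <- function(path, name, atoms, bonds) {
  n <- nrow(atoms); m <- nrow(bonds)
  lines <- c(name, "  test", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
             sprintf("%10.4f%10.4f%10.4f %-3s 0  0", atoms$x, atoms$y,
                     atoms$z, atoms$el),
             sprintf("%3d%3d%3d  0", bonds[, 1], bonds[, 2],
                     if (ncol(bonds) > 2) bonds[, 3] else rep(1, m)),
             "M  END", "$$$$")
  writeLines(lines, path)
  path
}

hexagon <- function(r = 1.39) {
  th <- seq(0, by = pi / 3, length.out = 6)
  data.frame(x = r * cos(th), y = r * sin(th), z = 0)
}

write_benzene_sdf <- function(path) {
  hx <- hexagon()
  atoms <- rbind(data.frame(el = "C", hx),
                 data.frame(el = "H", hexagon(2.47)))
  bonds <- cbind(c(1:6, 1:6), c(2:6, 1, 7:12), c(2, 1, 2, 1, 2, 1, rep(1, 6)))
  write_sdf(path, "benzene", atoms, bonds)
}

write_tpa_sdf <- function(path) {
  hx <- hexagon()
  atoms <- rbind(
    data.frame(el = "C", hx),                                   # ring 1-6
    data.frame(el = "C", x = 2.88, y = 0, z = 0),               # 7
    data.frame(el = "O", x = 3.5, y = 1.08, z = 0),             # 8
    data.frame(el = "O", x = 3.5, y = -1.08, z = 0),            # 9
    data.frame(el = "C", x = -2.88, y = 0, z = 0),              # 10
    data.frame(el = "O", x = -3.5, y = 1.08, z = 0),            # 11
    data.frame(el = "O", x = -3.5, y = -1.08, z = 0))           # 12
  bonds <- cbind(c(1:6, 1, 7, 7, 4, 10, 10),
                 c(2:6, 1, 7, 8, 9, 10, 11, 12),
                 c(2, 1, 2, 1, 2, 1, 1, 2, 1, 1, 2, 1))
  write_sdf(path, "TPA", atoms, bonds)
}

write_ethanol_sdf <- function(path) {
  atoms <- data.frame(el = c("C", "C", "O"),
                      x = c(0, 1.5, 2.2), y = c(0, 0, 1.2), z = 0)
  write_sdf(path, "ethanol", atoms, cbind(c(1, 2), c(2, 3), c(1, 1)))
}

# ---- independent oracles -------------------------------------------------

# all element- and adjacency-preserving permutations by full enumeration
# (factorial; keep n <= 7)
brute_force_automorphisms <- function(graph) {
  n <- length(graph$elements)
  stopifnot(n <= 7)
  A <- matrix(0L, n, n)
  A[graph$bonds] <- 1L
  A[graph$bonds[, 2:1, drop = FALSE]] <- 1L
  perms <- gtools_permutations(n)
  keep <- apply(perms, 1, function(p) {
    all(graph$elements[p] == graph$elements) && all(A[p, p] == A)
  })
  lapply(which(keep), function(i) perms[i, ])
}

# all permutations of 1..n as a matrix (recursive, no extra packages)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

# brute-force symmetry-corrected RMSD over ALL valid permutations
brute_force_sym_rmsd <- function(A, B, graph) {
  autos <- brute_force_automorphisms(graph)
  min(vapply(autos, function(p) sqrt(mean(rowSums((A - B[p, ]) ^ 2))), 0))
}

# all partitions of 1..n into exactly k non-empty blocks (restricted
# growth strings), as lists of index vectors
partitions_into_k <- function(n, k) {
  out <- list()
  grow <- function(assign, mx) {
    i <- length(assign) + 1
    if (i > n) {
      if (mx == k) out[[length(out) + 1]] <<- split(seq_len(n), assign)
      return(invisible())
    }
    for (b in seq_len(min(mx + 1, k))) grow(c(assign, b), max(mx, b))
  }
  grow(integer(0), 0)
  out
}

# Ward objective of a partition given a distance matrix:
# sum over blocks of sum(d^2 within block) / (2 * block size)
ward_objective <- function(D, blocks) {
  sum(vapply(blocks, function(idx) {
    if (length(idx) < 2) return(0)
    sum(D[idx, idx]^2) / (2 * length(idx))
  }, 0))
}

# canonical form of a set partition for comparison
canon_partition <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))[
    order(vapply(split(seq_along(labels), labels), min, 0))]
}

# one-way ANOVA F statistic from explicit sums of squares
anova_F_by_hand <- function(groups) {
  all_x <- unlist(groups)
  gm <- mean(all_x)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1
  df_w <- length(all_x) - length(groups)
  (ss_between / df_b) / (ss_within / df_w)
}
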