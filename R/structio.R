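#' Normalized macromolecular structure
#'
#' A `pet_structure` is a light container around an atom table in the
#' deposited (asymmetric-unit) coordinate frame. Coordinates are orthogonal
#' Angstroms; no symmetry expansion is performed, so the chains of the
#' asymmetric unit are the analysis units. Waters (residue name `HOH`/`WAT`)
#' and hetero groups are retained but flagged, leaving any filtering to the
#' caller.
#'
#' @param id structure identifier (free text).
#' @param atoms data.frame with columns `type` (`ATOM`/`HETATM`), `elety`
#'   (atom name), `resid` (residue name), `chain`, `resno`, `insert`,
#'   `altloc`, `x`, `y`, `z`, `o` (occupancy), `b` (B-factor), `elesy`
#'   (element symbol).
#' @return object of class `pet_structure`.
#' @export
pet_structure <- function(id, atoms) {
  needed <- c("type", "elety", "resid", "chain", "resno", "insert",
              "altloc", "x", "y", "z", "o", "b", "elesy")
  miss <- setdiff(needed, names(atoms))
  if (length(miss)) stopf("atom table lacks columns: %s", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stopf("empty model: structure '%s' has no atoms", id)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stopf("non-finite coordinates in structure '%s'", id)
  atoms$is_water <- atoms$resid %in% c("HOH", "WAT", "DOD")
  atoms$is_hetero <- atoms$type == "HETATM"
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "pet_structure")
}

#' @export
print.pet_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<pet_structure> %s: %d atoms, %d chain(s) [%s], %d water, %d hetero\n",
              x$id, nrow(x$atoms), length(ch), paste(ch, collapse = ","),
              sum(x$atoms$is_water), sum(x$atoms$is_hetero)))
  invisible(x)
}

# Resolve alternate locations: keep, per (chain, resno, insert, resid, elety),
# the altloc with the highest occupancy; ties break to the alphabetically
# first altloc. Deterministic and matches common practice.
resolve_altloc <- function(atoms) {
  blank <- atoms$altloc %in% c("", " ", NA)
  if (all(blank)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, atoms$elety,
               sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- atoms[idx, ]
    ord <- order(-sub$o, sub$altloc)
    idx[ord[1]]
  }), use.names = FALSE)
  out <- atoms[sort(keep), ]
  out$altloc <- ""
  out
}

#' Read a structure from PDB or mmCIF
#'
#' Parses a coordinate file into a [pet_structure()]. Alternate locations
#' are resolved to the highest-occupancy conformer (ties to the
#' alphabetically first altloc identifier).
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension: `.cif` /
#'   `.mmcif` are mmCIF, anything else PDB).
#' @param id identifier to store; defaults to the file base name.
#' @return a [pet_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  raw <- tryCatch(
    # keep all altlocs (rm.alt = FALSE): resolution by occupancy is ours
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) stopf("cannot parse %s as %s: %s", path, format,
                              conditionMessage(e)))
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) stopf("empty model in %s", path)
  atoms <- data.frame(
    type = at$type,
    elety = at$elety,
    resid = at$resid,
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    elesy = guess_element(at$elesy, at$elety),
    stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms)
  pet_structure(id %||% sub("\\.[^.]*$", "", basename(path)), atoms)
}

# element from the element column when present, else from the atom name
guess_element <- function(elesy, elety) {
  e <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fallback <- toupper(sub("^[0-9]*([A-Za-z]+).*$", "\\1", trimws(elety)))
  fallback <- ifelse(substr(fallback, 1, 2) %in% c("CL", "BR", "MG", "NA", "ZN", "FE", "MN", "CA"),
                     substr(fallback, 1, 2), substr(fallback, 1, 1))
  norm_element(ifelse(e == "", fallback, e))
}

norm_element <- function(e) {
  e <- toupper(trimws(e))
  paste0(substr(e, 1, 1), tolower(substr(e, 2, 10)))
}

#' Select atoms from a structure
#'
#' Selections use the `chain:resno:atomname` syntax (e.g. `"A:156:CD2"`);
#' `resno` and `atomname` may be omitted from the right (`"A:156"`, `"A"`).
#' Alternatively pass `chain` / `resno` / `elety` / `resid` directly.
#'
#' @param struct a [pet_structure()].
#' @param sel selection string, or `NULL` to use the keyword arguments.
#' @param chain,resno,elety,resid optional filters (vectors allowed).
#' @param drop_water drop water molecules first.
#' @return the matching rows of the atom table.
#' @export
atom_select <- function(struct, sel = NULL, chain = NULL, resno = NULL,
                        elety = NULL, resid = NULL, drop_water = FALSE) {
  stopifnot(inherits(struct, "pet_structure"))
  at <- struct$atoms
  if (!is.null(sel)) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) >= 1 && nzchar(parts[1])) chain <- parts[1]
    if (length(parts) >= 2 && nzchar(parts[2])) resno <- as.integer(parts[2])
    if (length(parts) >= 3 && nzchar(parts[3])) elety <- parts[3]
  }
  keep <- rep(TRUE, nrow(at))
  if (drop_water) keep <- keep & !at$is_water
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(elety)) keep <- keep & at$elety %in% elety
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  at[keep, , drop = FALSE]
}

# coordinates (n x 3 matrix, rownames = atom names) for named atoms of one
# residue; errors naming any missing atom
residue_coords <- function(struct, chain, resno, atoms) {
  rows <- atom_select(struct, chain = chain, resno = resno)
  m <- match(atoms, rows$elety)
  if (anyNA(m))
    stopf("atom(s) %s not found in %s:%s", paste(atoms[is.na(m)], collapse = ","),
          chain, resno)
  out <- as.matrix(rows[m, c("x", "y", "z")])
  rownames(out) <- atoms
  out
}

#' Heavy-atom molecular graph of a ligand
#'
#' @param name ligand name.
#' @param elements character vector of element symbols (one per atom).
#' @param bonds two-column integer matrix of bonded atom index pairs.
#' @return object of class `ligand_graph`.
#' @export
ligand_graph <- function(name, elements, bonds) {
  elements <- norm_element(elements)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- length(elements)
  if (n == 0) stopf("ligand '%s' has no atoms", name)
  if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > n))
    stopf("bond indices out of range for ligand '%s'", name)
  g <- structure(list(name = name, elements = elements, bonds = bonds),
                 class = "ligand_graph")
  if (!graph_connected(g))
    stopf("heavy-atom graph of '%s' is disconnected (multi-molecule record?)", name)
  g
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat(sprintf("<ligand_graph> %s: %d heavy atoms (%s), %d bonds\n", x$name,
              length(x$elements),
              paste(names(table(x$elements)), table(x$elements), sep = "", collapse = " "),
              nrow(x$bonds)))
  invisible(x)
}

adjacency <- function(g) {
  n <- length(g$elements)
  A <- matrix(0L, n, n)
  if (nrow(g$bonds)) {
    A[g$bonds] <- 1L
    A[g$bonds[, 2:1, drop = FALSE]] <- 1L
  }
  A
}

graph_connected <- function(g) {
  n <- length(g$elements)
  if (n == 1) return(TRUE)
  A <- adjacency(g)
  seen <- logical(n); seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Read a ligand topology from SDF or MOL2
#'
#' Returns the heavy-atom molecular graph: hydrogens are stripped and
#' element symbols normalized. Crystal-structure and docking-pose RMSDs in
#' this package are heavy-atom based throughout.
#'
#' @param path file path.
#' @param format `"sdf"`, `"mol2"`, or `"auto"` (by extension).
#' @return a [ligand_graph()].
#' @export
read_ligand <- function(path, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  if (format == "sdf") {
    set <- tryCatch(ChemmineR::read.SDFset(path),
                    error = function(e) stopf("cannot parse SDF %s: %s", path,
                                              conditionMessage(e)))
    sdf <- set[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
    name <- ChemmineR::sdfid(sdf)
  } else {
    mol <- tryCatch(bio3d::read.mol2(path),
                    error = function(e) stopf("cannot parse MOL2 %s: %s", path,
                                              conditionMessage(e)))
    elements <- sub("\\..*$", "", mol$atom$elena)
    if (all(is.na(elements)) || is.null(elements))
      elements <- sub("[0-9]*$", "", mol$atom$elena)
    bonds <- cbind(as.integer(mol$bond$origin), as.integer(mol$bond$target))
    name <- mol$name %||% sub("\\.[^.]*$", "", basename(path))
  }
  strip_hydrogens(ligand_graph_raw(name, elements, bonds))
}

# permissive constructor used before hydrogen stripping (H's may dangle)
ligand_graph_raw <- function(name, elements, bonds) {
  structure(list(name = name, elements = norm_element(elements),
                 bonds = matrix(as.integer(bonds), ncol = 2)),
            class = "ligand_graph")
}

strip_hydrogens <- function(g) {
  heavy <- which(g$elements != "H")
  idx <- match(seq_along(g$elements), heavy)
  b <- g$bonds
  b <- b[g$elements[b[, 1]] != "H" & g$elements[b[, 2]] != "H", , drop = FALSE]
  ligand_graph(g$name, g$elements[heavy],
               cbind(idx[b[, 1]], idx[b[, 2]]))
}

#' Read a docking pose set
#'
#' Joins per-pose coordinate files with a score table on `pose_id`. Each
#' pose file must contain exactly the ligand's heavy atoms in topology
#' order (one PDB file per pose named `<pose_id>.pdb`).
#'
#' @param coord_dir directory of `<pose_id>.pdb` files.
#' @param score_path CSV with columns `pose_id`, `total_score`,
#'   `interface_score` and per-residue energy columns prefixed `res_`
#'   (e.g. `res_L210`), energies in Rosetta energy units.
#' @param ligand the [ligand_graph()] the poses instantiate.
#' @return a [pose_set()].
#' @export
read_pose_set <- function(coord_dir, score_path, ligand) {
  scores <- utils::read.csv(score_path, check.names = FALSE)
  if (!all(c("pose_id", "total_score", "interface_score") %in% names(scores)))
    stopf("score table must have pose_id, total_score, interface_score")
  if (anyDuplicated(scores$pose_id))
    stopf("duplicate pose_id in score table: %s",
          paste(unique(scores$pose_id[duplicated(scores$pose_id)]), collapse = ","))
  files <- list.files(coord_dir, pattern = "\\.pdb$")
  file_ids <- sub("\\.pdb$", "", files)
  miss <- setdiff(scores$pose_id, file_ids)
  extra <- setdiff(file_ids, scores$pose_id)
  if (length(miss)) stopf("poses without coordinates: %s", paste(miss, collapse = ","))
  if (length(extra)) stopf("coordinate files without score rows: %s",
                           paste(extra, collapse = ","))
  n_atoms <- length(ligand$elements)
  coords <- lapply(scores$pose_id, function(pid) {
    s <- read_structure(file.path(coord_dir, paste0(pid, ".pdb")), format = "pdb")
    xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
    if (nrow(xyz) != n_atoms)
      stopf("pose %s has %d atoms; ligand topology has %d", pid, nrow(xyz), n_atoms)
    xyz
  })
  names(coords) <- scores$pose_id
  res_cols <- grep("^res_", names(scores), value = TRUE)
  res_energy <- NULL
  if (length(res_cols)) {
    res_energy <- as.matrix(scores[, res_cols, drop = FALSE])
    rownames(res_energy) <- scores$pose_id
    colnames(res_energy) <- sub("^res_", "", res_cols)
  }
  pose_set(ligand, coords,
           scores[, c("pose_id", "total_score", "interface_score")],
           res_energy)
}

#' Write a pose set to disk
#'
#' Inverse of [read_pose_set()]: one PDB per pose plus a score CSV.
#'
#' @param poses a [pose_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, the score CSV path.
#' @export
write_pose_set <- function(poses, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  el <- poses$ligand$elements
  for (pid in poses$pose_ids) {
    xyz <- poses$coords[[pid]]
    bio3d::write.pdb(file = file.path(dir, paste0(pid, ".pdb")),
                     xyz = as.numeric(t(xyz)),
                     type = rep("HETATM", nrow(xyz)),
                     resno = rep(1L, nrow(xyz)),
                     resid = rep("LIG", nrow(xyz)),
                     chain = rep("X", nrow(xyz)),
                     elety = paste0(el, seq_len(nrow(xyz))),
                     elesy = el)
  }
  sc <- poses$scores
  if (!is.null(poses$res_energy)) {
    re <- as.data.frame(poses$res_energy)
    names(re) <- paste0("res_", names(re))
    sc <- cbind(sc, re)
  }
  path <- file.path(dir, "scores.csv")
  utils::write.csv(sc, path, row.names = FALSE)
  invisible(path)
}

#' Time series of impedance spectra
#'
#' @param time_h monotonically increasing time stamps in hours.
#' @param freq_hz frequency grid (Hz), shared by all time points.
#' @param Z complex impedance matrix, `length(time_h)` x `length(freq_hz)`.
#' @param geom optional [film_geometry()] carried with the series.
#' @return object of class `impedance_series`.
#' @export
impedance_series <- function(time_h, freq_hz, Z, geom = NULL) {
  Z <- as.matrix(Z)
  if (any(diff(time_h) <= 0)) stopf("time stamps must be strictly increasing")
  if (nrow(Z) != length(time_h) || ncol(Z) != length(freq_hz))
    stopf("Z must be length(time_h) x length(freq_hz)")
  structure(list(time_h = time_h, freq_hz = freq_hz, Z = Z, geom = geom),
            class = "impedance_series")
}

#' @export
print.impedance_series <- function(x, ...) {
  cat(sprintf("<impedance_series> %d time points over %.2f h, %d frequencies %.3g-%.3g Hz\n",
              length(x$time_h), diff(range(x$time_h)), length(x$freq_hz),
              min(x$freq_hz), max(x$freq_hz)))
  invisible(x)
}

#' Read an impedance time series from CSV
#'
#' Expects long-format columns `time_s`, `freq_hz`, `z_re_ohm`, `z_im_ohm`.
#' The frequency grid must be identical (same values, same order) at every
#' time point and time must be strictly increasing.
#'
#' @param path CSV file path.
#' @return an [impedance_series()] (time converted to hours).
#' @export
read_impedance <- function(path) {
  d <- utils::read.csv(path)
  needed <- c("time_s", "freq_hz", "z_re_ohm", "z_im_ohm")
  miss <- setdiff(needed, names(d))
  if (length(miss)) stopf("impedance CSV lacks columns: %s", paste(miss, collapse = ","))
  times <- unique(d$time_s)
  grids <- split(d$freq_hz, d$time_s)
  ref <- grids[[as.character(times[1])]]
  for (t in times) {
    g <- grids[[as.character(t)]]
    if (length(g) != length(ref) || any(g != ref))
      stopf("inconsistent frequency grid at time %s s", format(t))
  }
  if (any(diff(times) <= 0)) stopf("time stamps not strictly increasing")
  Z <- matrix(complex(real = d$z_re_ohm, imaginary = d$z_im_ohm),
              nrow = length(times), byrow = TRUE)
  impedance_series(times / 3600, ref, Z)
}

#' Write an impedance series to CSV
#'
#' @param series an [impedance_series()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_impedance <- function(series, path) {
  nt <- length(series$time_h); nf <- length(series$freq_hz)
  d <- data.frame(
    time_s = rep(series$time_h * 3600, each = nf),
    freq_hz = rep(series$freq_hz, nt),
    z_re_ohm = as.numeric(t(Re(series$Z))),
    z_im_ohm = as.numeric(t(Im(series$Z))))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Flat result records
#'
#' Report rows carry (measurement, value, uncertainty, units). Floats are
#' serialized with 6 significant digits; [report_write()] followed by
#' [report_read()] reproduces the decimal text bit-identically.
#'
#' @param measurement,value,uncertainty,units vectors (recycled).
#' @return data.frame of class `report_rows`.
#' @export
report_row <- function(measurement, value, uncertainty = NA_real_, units = "") {
  out <- data.frame(measurement = measurement, value = as.numeric(value),
                    uncertainty = as.numeric(uncertainty), units = units,
                    stringsAsFactors = FALSE)
  class(out) <- c("report_rows", "data.frame")
  out
}

fmt_sig6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 6))
}

#' @rdname report_row
#' @param rows a `report_rows` data.frame.
#' @param path output path (`.csv` or `.json` by extension).
#' @export
report_write <- function(rows, path) {
  out <- rows
  out$value <- fmt_sig6(rows$value)
  out$uncertainty <- fmt_sig6(rows$uncertainty)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, dataframe = "rows", pretty = TRUE)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' @rdname report_row
#' @export
report_read <- function(path) {
  if (grepl("\\.json$", path)) {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    d <- utils::read.csv(path, colClasses = c(value = "character",
                                              uncertainty = "character"))
  }
  d$value_text <- as.character(d$value)
  d$uncertainty_text <- as.character(d$uncertainty)
  d$value <- suppressWarnings(as.numeric(d$value))
  d$uncertainty <- suppressWarnings(as.numeric(d$uncertainty))
  d
}
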