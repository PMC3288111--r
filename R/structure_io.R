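#' Atomic structure container
#'
#' A lightweight container for an ordered set of atom records plus the
#' crystallographic metadata needed for symmetry expansion. Atom records are
#' held in a data frame with one row per atom, in file order.
#'
#' @param atoms data.frame with columns `serial`, `name` (atom name),
#'   `elem` (element symbol), `resid` (3-letter residue code), `chain`,
#'   `resno` (integer), `insert` (insertion code, "" if none), `x`, `y`, `z`
#'   (orthogonal coordinates, Angstrom), `occ` (occupancy), `b`
#'   (experimental B-factor, Angstrom^2), `is_hetero` (logical).
#' @param unit_cell numeric length-6 vector `(a, b, c, alpha, beta, gamma)`
#'   with lengths in Angstrom and angles in degrees, or `NULL`.
#' @param space_group Hermann-Mauguin symbol (e.g. `"P 32 2 1"`), or `NULL`.
#' @param provenance free-text source identifier.
#' @return An object of class `enm_structure`.
#' @export
new_structure <- function(atoms, unit_cell = NULL, space_group = NULL,
                          provenance = "") {
  required <- c("serial", "name", "elem", "resid", "chain", "resno",
                "insert", "x", "y", "z", "occ", "b", "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  if (!is.null(unit_cell)) {
    if (length(unit_cell) != 6 || any(unit_cell[1:3] <= 0))
      stop("unit_cell must be (a, b, c, alpha, beta, gamma) with positive lengths")
  }
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 unit_cell = unit_cell,
                 space_group = space_group,
                 provenance = provenance),
            class = "enm_structure")
}

#' @export
print.enm_structure <- function(x, ...) {
  cat("enm_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$insert))),
      "residues\n")
  if (!is.null(x$unit_cell))
    cat("  cell:", paste(signif(x$unit_cell, 6), collapse = " "),
        " space group:", x$space_group %||% "?", "\n")
  if (nzchar(x$provenance)) cat("  source:", x$provenance, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of atoms in a structure
#' @param structure an `enm_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

# Residue identity key used throughout (chain + number + insertion code).
residue_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert,
                                     sep = "|")

#' Read a PDB file
#'
#' Parses a fixed-column PDB file (through \pkg{bio3d}), drops hydrogens and
#' waters, resolves alternate locations, and records unit-cell/space-group
#' metadata from the CRYST1 header. HETATM groups such as the heme and a
#' bound steroid are retained and flagged.
#'
#' @param path PDB file path.
#' @param altloc_policy `"highest_occupancy"` keeps the highest-occupancy
#'   alternate (ties broken by the first listed); `"first"` keeps the first
#'   listed alternate.
#' @param keep_waters keep HOH/WAT records (default `FALSE`).
#' @return An [new_structure()] object.
#' @export
read_structure <- function(path,
                           altloc_policy = c("highest_occupancy", "first"),
                           keep_waters = FALSE) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("cannot read file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("PDB parse error: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  # element: prefer the element column, fall back to the first alphabetic
  # character of the atom name
  elem <- trimws(at$elesy)
  bad <- is.na(elem) | !nzchar(elem)
  if (any(bad))
    elem[bad] <- toupper(substr(gsub("^[0-9]*", "", trimws(at$elety[bad])), 1, 1))
  keep <- toupper(elem) != "H" & toupper(elem) != "D"
  if (!keep_waters) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0) stop("empty structure after filtering: ", path)

  ins <- at$insert
  ins[is.na(ins)] <- ""
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1

  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety), elem = elem,
                      resid = at$resid, chain = at$chain, resno = at$resno,
                      insert = ins, x = at$x, y = at$y, z = at$z,
                      occ = occ, b = ifelse(is.na(at$b), 0, at$b),
                      is_hetero = at$type == "HETATM",
                      stringsAsFactors = FALSE)

  # altloc resolution per (residue, atom name)
  if (any(nzchar(alt))) {
    key <- paste(residue_key(atoms), atoms$name)
    keep_idx <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ix) {
      if (length(ix) == 1) return(ix)
      if (altloc_policy == "first") return(ix[1])
      ix[which.max(atoms$occ[ix])]    # which.max: first of ties
    }), use.names = FALSE)
    atoms <- atoms[sort(keep_idx), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  cryst <- read_cryst1(path)
  new_structure(atoms, unit_cell = cryst$cell, space_group = cryst$sg,
                provenance = path)
}

# CRYST1 header line (bio3d does not expose it)
read_cryst1 <- function(path) {
  lines <- readLines(path, n = 200L, warn = FALSE)
  ln <- lines[startsWith(lines, "CRYST1")]
  if (!length(ln)) return(list(cell = NULL, sg = NULL))
  ln <- ln[1]
  cell <- suppressWarnings(as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                                        substr(ln, 25, 33), substr(ln, 34, 40),
                                        substr(ln, 41, 47), substr(ln, 48, 54))))
  if (any(is.na(cell))) return(list(cell = NULL, sg = NULL))
  sg <- trimws(substr(ln, 56, 66))
  list(cell = cell, sg = if (nzchar(sg)) sg else NULL)
}

#' Write a structure as PDB
#'
#' Fixed-column PDB output (through \pkg{bio3d}); coordinates keep three
#' decimals, so a read/write round trip preserves them exactly. A CRYST1
#' record is emitted when the structure carries a unit cell.
#'
#' @param structure an `enm_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(at$is_hetero, "HETATM", "ATOM"),
                   eleno = at$serial, elety = at$name, resid = at$resid,
                   chain = ifelse(is.na(at$chain), "", at$chain),
                   resno = at$resno, insert = at$insert,
                   o = at$occ, b = at$b, elesy = at$elem)
  if (!is.null(structure$unit_cell)) {
    uc <- structure$unit_cell
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                     uc[1], uc[2], uc[3], uc[4], uc[5], uc[6],
                     structure$space_group %||% "P 1", 1L)
    writeLines(c(cryst, readLines(path, warn = FALSE)), path)
  }
  invisible(path)
}

#' Crystallographic symmetry operators
#'
#' Returns the general-position operators of a space group as fractional
#' rotation matrices and translations. The trigonal group P3(2)21 used for
#' head-to-tail P450 oligomer construction is built in, along with P1;
#' arbitrary operator lists can be passed to [apply_symmetry()] directly.
#'
#' @param space_group Hermann-Mauguin symbol; spaces and subscripts are
#'   ignored when matching (`"P 32 2 1"`, `"P3221"`, ...).
#' @return list of operators, each `list(rot = 3x3 matrix, trans = length-3)`.
#' @export
symmetry_operators <- function(space_group) {
  key <- gsub("[^0-9A-Za-z]", "", toupper(space_group))
  op <- function(rot, trans) list(rot = matrix(rot, 3, 3, byrow = TRUE),
                                  trans = trans)
  if (key == "P1")
    return(list(op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0))))
  if (key == "P3221")
    return(list(
      op(c( 1,  0, 0,   0,  1, 0,  0, 0,  1), c(0, 0, 0)),      # x, y, z
      op(c( 0, -1, 0,   1, -1, 0,  0, 0,  1), c(0, 0, 2 / 3)),  # -y, x-y, z+2/3
      op(c(-1,  1, 0,  -1,  0, 0,  0, 0,  1), c(0, 0, 1 / 3)),  # -x+y, -x, z+1/3
      op(c( 0,  1, 0,   1,  0, 0,  0, 0, -1), c(0, 0, 0)),      # y, x, -z
      op(c( 1, -1, 0,   0, -1, 0,  0, 0, -1), c(0, 0, 1 / 3)),  # x-y, -y, -z+1/3
      op(c(-1,  0, 0,  -1,  1, 0,  0, 0, -1), c(0, 0, 2 / 3))   # -x, -x+y, -z+2/3
    ))
  stop("no built-in operator table for space group '", space_group,
       "'; pass an explicit operator list")
}

#' Invert a symmetry operator
#' @param op operator as returned by [symmetry_operators()].
#' @return the inverse operator (fractional basis).
#' @export
invert_operator <- function(op) {
  rinv <- solve(op$rot)
  list(rot = rinv, trans = as.numeric(-rinv %*% op$trans))
}

# Standard crystallographic orthogonalization matrix (a along x, b in xy).
orthogonalization_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c0 <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c0 * cos(be),
           0, b * sin(ga), c0 * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c0 * v / sin(ga)), 3, 3, byrow = TRUE)
}

#' Expand a structure by crystallographic symmetry
#'
#' Applies fractional-basis symmetry operators (optionally combined with
#' whole lattice translations) to build crystal-packing oligomers such as
#' the head-to-tail chains formed about a 3(2) screw axis. Each generated
#' copy is relabeled with a fresh chain identifier.
#'
#' @param structure an `enm_structure` with a unit cell.
#' @param operators list of operators (see [symmetry_operators()]); defaults
#'   to the table for `structure$space_group`.
#' @param copies integer indices selecting which operators to apply
#'   (default all).
#' @param lattice optional list (parallel to `copies`) of integer length-3
#'   lattice translations added to each operator, for reaching contacting
#'   copies in neighbouring cells.
#' @return a multi-copy `enm_structure`; atom count is `length(copies)`
#'   times the input count.
#' @export
apply_symmetry <- function(structure, operators = NULL, copies = NULL,
                           lattice = NULL) {
  if (is.null(structure$unit_cell))
    stop("symmetry expansion requires a unit cell")
  if (is.null(operators)) {
    if (is.null(structure$space_group))
      stop("no operators given and structure has no space group")
    operators <- symmetry_operators(structure$space_group)
  }
  if (is.null(copies)) copies <- seq_along(operators)
  if (!is.null(lattice) && length(lattice) != length(copies))
    stop("lattice must be parallel to copies")

  M <- orthogonalization_matrix(structure$unit_cell)
  Minv <- solve(M)
  xyz <- t(as.matrix(structure$atoms[, c("x", "y", "z")]))  # 3 x n
  frac <- Minv %*% xyz

  chain_pool <- c(LETTERS, letters, as.character(0:9))
  used <- 0L
  pieces <- vector("list", length(copies))
  for (k in seq_along(copies)) {
    opk <- operators[[copies[k]]]
    tr <- opk$trans + if (is.null(lattice)) c(0, 0, 0) else lattice[[k]]
    newfrac <- opk$rot %*% frac + tr
    newxyz <- t(M %*% newfrac)
    at <- structure$atoms
    at$x <- newxyz[, 1]; at$y <- newxyz[, 2]; at$z <- newxyz[, 3]
    old_chains <- unique(at$chain)
    remap <- chain_pool[used + seq_along(old_chains)]
    used <- used + length(old_chains)
    at$chain <- remap[match(at$chain, old_chains)]
    pieces[[k]] <- at
  }
  out <- do.call(rbind, pieces)
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  new_structure(out, unit_cell = structure$unit_cell,
                space_group = structure$space_group,
                provenance = paste0(structure$provenance, " [sym x",
                                    length(copies), "]"))
}

#' Minimum inter-chain contact distance
#'
#' Brute-force minimum distance between the selected atoms of two chain
#' sets, used to verify head-to-tail contacts in symmetry-expanded
#' oligomers.
#'
#' @param structure an `enm_structure`.
#' @param chains_a,chains_b chain identifier vectors.
#' @param atom_name restrict to one atom name (e.g. `"CA"`); `NULL` = all.
#' @return minimum distance in Angstrom.
#' @export
min_chain_distance <- function(structure, chains_a, chains_b,
                               atom_name = "CA") {
  at <- structure$atoms
  if (!is.null(atom_name)) at <- at[at$name == atom_name, , drop = FALSE]
  A <- as.matrix(at[at$chain %in% chains_a, c("x", "y", "z")])
  B <- as.matrix(at[at$chain %in% chains_b, c("x", "y", "z")])
  if (!nrow(A) || !nrow(B)) stop("empty chain selection")
  min(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)))
}
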