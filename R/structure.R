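#' @importFrom stats rnorm runif sd dist dhyper phyper setNames
#' @importFrom utils read.table write.table write.csv head
NULL

# Standard amino-acid 3-letter codes retained by read_structure()
.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Construct a protein structure object
#'
#' A `rif_structure` is the coordinate substrate for all contact
#' computation: an atom table plus a canonical residue table. Residues are
#' identified by `(chain, resno, insertion code)` — author numbering, never
#' serial index — and ordered ascending by that triple; this order defines
#' all deterministic tie-breaks downstream.
#'
#' @param id free-text structure label.
#' @param atoms data frame with columns `chain`, `resno`, `ins`, `resid`
#'   (3-letter residue name), `elety` (atom name), `elesy` (element),
#'   `x`, `y`, `z` (Angstrom), `o` (occupancy), `alt` (alternate-location
#'   code, `""` if none). Missing `elesy`, `o`, `alt` are filled with
#'   defaults.
#' @return An object of class `rif_structure`: a list with elements `id`,
#'   `atoms` (atom table with an added `res_idx` index into the residue
#'   table) and `residues` (one row per residue: `res_id`, `chain`,
#'   `resno`, `ins`, `resid`).
#' @export
new_structure <- function(id, atoms) {
  stopifnot(is.character(id), length(id) == 1L)
  req <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms")
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  if (is.null(atoms$elesy))
    atoms$elesy <- substr(trimws(atoms$elety), 1L, 1L)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite atom coordinates")
  if (any(atoms$o < 0 | atoms$o > 1))
    stop("occupancy outside [0, 1]")
  key <- paste(atoms$chain, atoms$resno, atoms$ins, sep = "\r")
  ord <- order(atoms$chain, atoms$resno, atoms$ins)
  ukey <- unique(key[ord])
  first <- match(ukey, key)
  residues <- data.frame(
    res_id = make_res_id(atoms$chain[first], atoms$resno[first],
                         atoms$ins[first]),
    chain  = atoms$chain[first],
    resno  = atoms$resno[first],
    ins    = atoms$ins[first],
    resid  = atoms$resid[first],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(residues$res_id))
    stop("residue identifiers (chain, resno, ins) are not unique")
  atoms$res_idx <- match(key, ukey)
  structure(list(id = id, atoms = atoms, residues = residues),
            class = "rif_structure")
}

#' Canonical residue identifier strings
#'
#' @param chain,resno,ins vectors of chain id, author residue number and
#'   insertion code (recycled).
#' @return character vector `"<chain>:<resno><ins>"`.
#' @export
make_res_id <- function(chain, resno, ins = "") {
  ins[is.na(ins)] <- ""
  paste0(chain, ":", resno, ins)
}

#' Residue identifiers of a structure
#'
#' @param s a `rif_structure`.
#' @return character vector of residue ids in canonical
#'   (chain, resno, ins) order.
#' @export
residue_ids <- function(s) {
  stopifnot(inherits(s, "rif_structure"))
  s$residues$res_id
}

#' Number of residues in a structure
#' @param s a `rif_structure`.
#' @return integer count.
#' @export
n_residues <- function(s) nrow(s$residues)

#' Atom coordinates as a matrix
#' @param s a `rif_structure`.
#' @return numeric n_atoms x 3 matrix (Angstrom).
#' @export
atom_xyz <- function(s) {
  stopifnot(inherits(s, "rif_structure"))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' @export
print.rif_structure <- function(x, ...) {
  cat(sprintf("rif_structure '%s': %d residues, %d atoms, %d chain(s)\n",
              x$id, nrow(x$residues), nrow(x$atoms),
              length(unique(x$residues$chain))))
  invisible(x)
}

#' Rigid-body transform
#'
#' Transforms act on column-vector coordinates as `p' = R p + t`.
#'
#' @param rotation 3x3 rotation matrix; must be orthonormal with
#'   determinant +1 to within `tol`.
#' @param translation length-3 numeric translation (Angstrom).
#' @param tol orthonormality tolerance.
#' @return An object of class `rif_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0),
                            tol = 1e-6) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("rotation is not orthonormal (tolerance ", tol, ")")
  if (abs(det(rotation) - 1) > tol)
    stop("rotation determinant is not +1 (improper rotation?)")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite 3-vector")
  structure(list(R = rotation, t = translation), class = "rif_transform")
}

#' Identity transform
#' @return a `rif_transform` leaving coordinates unchanged.
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Invert a rigid transform
#' @param tr a `rif_transform`.
#' @return the inverse `rif_transform` (`R'`, `-R' t`).
#' @export
invert_transform <- function(tr) {
  stopifnot(inherits(tr, "rif_transform"))
  rigid_transform(t(tr$R), -as.numeric(t(tr$R) %*% tr$t))
}

#' Uniform random rotation matrix
#'
#' Draws a rotation uniformly over SO(3) via a random unit quaternion.
#' Uses the current RNG stream (seed it with [set.seed()] or pass seeds to
#' higher-level samplers).
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotation matrix from z-x-z Euler angles
#'
#' @param alpha,beta,gamma angles in radians; the rotation is
#'   `Rz(alpha) %*% Rx(beta) %*% Rz(gamma)`.
#' @return 3x3 rotation matrix.
#' @export
euler_zxz <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), -sin(a), 0,
                             sin(a),  cos(a), 0,
                             0,       0,      1), 3, 3, byrow = TRUE)
  rx <- function(a) matrix(c(1, 0, 0,
                             0, cos(a), -sin(a),
                             0, sin(a),  cos(a)), 3, 3, byrow = TRUE)
  rz(alpha) %*% rx(beta) %*% rz(gamma)
}

#' Apply a rigid transform to a structure
#'
#' Every atom position `p` maps to `R p + t`; pairwise intra-structure
#' distances are preserved (to numerical precision).
#'
#' @param s a `rif_structure`.
#' @param tr a `rif_transform`.
#' @return the transformed `rif_structure`.
#' @export
apply_transform <- function(s, tr) {
  stopifnot(inherits(s, "rif_structure"))
  if (!inherits(tr, "rif_transform"))
    stop("tr must be a rif_transform (see rigid_transform())")
  xyz <- atom_xyz(s) %*% t(tr$R)
  s$atoms$x <- xyz[, 1] + tr$t[1]
  s$atoms$y <- xyz[, 2] + tr$t[2]
  s$atoms$z <- xyz[, 3] + tr$t[3]
  s
}

#' Read a protein structure from a PDB file
#'
#' Parses a PDB file (via bio3d) and applies fixed filtering policies:
#' only the first model of a multi-model file is kept; for atoms with
#' alternate locations, the highest-occupancy altloc wins (ties broken in
#' favour of code `'A'`, then blank); HETATM records and waters are
#' excluded and only standard amino-acid residues are retained. Hydrogens,
#' when present, are kept: the downstream contact rule is deliberately
#' "any atom".
#'
#' @param path PDB file path.
#' @param altloc_policy `"occupancy"` (default, policy above) or `"all"`
#'   (keep every altloc copy).
#' @param het_policy `"exclude"` (default) or `"include"` (retain
#'   non-water HETATM residues as well).
#' @param id structure label; defaults to the file base name.
#' @return a [new_structure()] object.
#' @export
read_structure <- function(path, altloc_policy = c("occupancy", "all"),
                           het_policy = c("exclude", "include"),
                           id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  het_policy <- match.arg(het_policy)
  if (!file.exists(path))
    stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  keep <- at$resid != "HOH" & at$resid != "WAT"
  if (het_policy == "exclude")
    keep <- keep & at$type == "ATOM" & at$resid %in% .standard_aa
  at <- at[keep, , drop = FALSE]
  if (nrow(at) && altloc_policy == "occupancy" && any(at$alt != "")) {
    # within each (residue, atom-name) group keep max occupancy;
    # ties prefer altloc 'A', then blank, then alphabetical
    altrank <- match(at$alt, c("A", ""), nomatch = 3L)
    grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(grp, -at$o, altrank, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(grp[ord]), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  if (nrow(at) == 0L)
    stop("no residues left after filtering: ", path)
  if (is.null(id))
    id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  new_structure(id, data.frame(
    chain = at$chain, resno = at$resno, ins = at$insert,
    resid = at$resid, elety = at$elety, elesy = at$elesy,
    x = at$x, y = at$y, z = at$z, o = at$o, alt = at$alt,
    stringsAsFactors = FALSE))
}

#' Write a structure to a PDB file
#'
#' Standard 80-column fixed-width ATOM records; coordinates are written at
#' PDB precision (1e-3 Angstrom), so a read/write round-trip reproduces
#' residue identifiers exactly and coordinates to that precision.
#'
#' @param s a `rif_structure`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "rif_structure"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot write PDB file, no such directory: ", dir)
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(a$ins == "", NA, a$ins),
                   alt = ifelse(a$alt == "", NA, a$alt),
                   o = a$o, b = rep(0, nrow(a)), elesy = a$elesy,
                   end = TRUE)
  invisible(path)
}
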