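# Interface definition: a receptor residue is in contact when any of its
# atoms lies within `cutoff` (default 3.5 A) of any ligand atom.
# Atom-centre Euclidean distance only; no van der Waals radii and no
# contact typing — the plain distance rule is the operational definition
# used throughout.

# cross squared-distance matrix between two coordinate sets, chunked to
# bound memory on larger structures
.cross_dist2 <- function(a, b, chunk = 4e6) {
  n <- nrow(a); m <- nrow(b)
  if (as.double(n) * m <= chunk) {
    d2 <- matrix(rowSums(a^2), n, m) +
      matrix(rowSums(b^2), n, m, byrow = TRUE) - 2 * tcrossprod(a, b)
    return(pmax(d2, 0))
  }
  NULL
}

# min distance from each row of a to any row of b (chunk-safe)
.min_dist_to <- function(a, b) {
  n <- nrow(a)
  step <- max(1L, floor(4e6 / max(1L, nrow(b))))
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + step - 1L)
    d2 <- .cross_dist2(a[i:j, , drop = FALSE], b)
    out[i:j] <- sqrt(apply(d2, 1L, min))
    i <- j + 1L
  }
  out
}

# shared kernel: residue ids of receptor residues with any atom within
# cutoff of any ligand atom, given raw coordinates
.contact_ids <- function(rxyz, res_idx, res_id, lxyz, cutoff) {
  near <- .min_dist_to(rxyz, lxyz) <= cutoff
  sort_residues(unique(res_id[res_idx[near]]), res_id)
}

# order a subset of residue ids by the canonical order of `universe`
sort_residues <- function(ids, universe) {
  ids[order(match(ids, universe))]
}

#' Receptor residues in contact with a placed ligand
#'
#' A receptor residue is included iff the minimum over its atoms and all
#' ligand atoms of the Euclidean distance is at most `cutoff`. The rule is
#' symmetric in construction: swap the arguments to obtain ligand-side
#' contacts.
#'
#' @param receptor,placed_ligand `rif_structure` objects in a common
#'   coordinate frame.
#' @param cutoff contact distance in Angstrom (default 3.5).
#' @param heavy_only if `TRUE`, hydrogen atoms are ignored on both sides;
#'   the default keeps the literal any-atom rule.
#' @return character vector of receptor residue ids (a contact set), in
#'   canonical residue order.
#' @export
contact_residues <- function(receptor, placed_ligand, cutoff = 3.5,
                             heavy_only = FALSE) {
  stopifnot(inherits(receptor, "rif_structure"),
            inherits(placed_ligand, "rif_structure"))
  if (cutoff <= 0) stop("cutoff must be positive")
  ra <- receptor$atoms
  la <- placed_ligand$atoms
  if (heavy_only) {
    ra <- ra[toupper(trimws(ra$elesy)) != "H", , drop = FALSE]
    la <- la[toupper(trimws(la$elesy)) != "H", , drop = FALSE]
  }
  if (nrow(ra) == 0L || nrow(la) == 0L)
    stop("empty structure in contact computation")
  .contact_ids(as.matrix(ra[, c("x", "y", "z")]), ra$res_idx,
               receptor$residues$res_id,
               as.matrix(la[, c("x", "y", "z")]), cutoff)
}

#' Annotate the true interface of a receptor from its solved complex
#'
#' The ground-truth interface is the set of receptor residues in contact
#' with the cognate ligand chain(s) in the complex frame, under the same
#' any-atom distance rule as [contact_residues()].
#'
#' @inheritParams contact_residues
#' @param cognate_ligand the bound partner, as a `rif_structure` in the
#'   complex coordinate frame.
#' @return An object of class `rif_annotation`: list with `receptor_id`
#'   and `interface_residues` (character vector of residue ids). An empty
#'   interface triggers a warning.
#' @export
annotate_interface <- function(receptor, cognate_ligand, cutoff = 3.5,
                               heavy_only = FALSE) {
  res <- contact_residues(receptor, cognate_ligand, cutoff = cutoff,
                          heavy_only = heavy_only)
  if (length(res) == 0L)
    warning("no interface residues within ", cutoff,
            " A; annotation is empty")
  structure(list(receptor_id = receptor$id, interface_residues = res),
            class = "rif_annotation")
}

#' @export
print.rif_annotation <- function(x, ...) {
  cat(sprintf("rif_annotation '%s': %d interface residue(s)\n",
              x$receptor_id, length(x$interface_residues)))
  invisible(x)
}

#' Construct an interface annotation from residue ids
#'
#' @param receptor_id receptor label.
#' @param interface_residues character vector of residue ids.
#' @return a `rif_annotation`.
#' @export
interface_annotation <- function(receptor_id, interface_residues) {
  structure(list(receptor_id = receptor_id,
                 interface_residues = unique(as.character(interface_residues))),
            class = "rif_annotation")
}

#' Write / read an interface annotation as TSV
#'
#' Columns: chain, seq_number, insertion_code. A `# rifsite annotation v1`
#' header comment records the schema version.
#'
#' @param annotation a `rif_annotation`.
#' @param path file path.
#' @return `write_annotation` returns `path` invisibly; `read_annotation`
#'   returns a `rif_annotation`.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "rif_annotation"))
  parts <- split_res_id(annotation$interface_residues)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rifsite annotation v1",
               paste0("# receptor_id=", annotation$receptor_id),
               "chain\tseq_number\tinsertion_code"), con)
  if (nrow(parts))
    writeLines(paste(parts$chain, parts$resno, parts$ins, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_annotation
#' @param receptor_id label override; defaults to the one recorded in the
#'   file header.
#' @export
read_annotation <- function(path, receptor_id = NULL) {
  lines <- readLines(path)
  if (is.null(receptor_id)) {
    idl <- grep("^# receptor_id=", lines, value = TRUE)
    receptor_id <- if (length(idl)) sub("^# receptor_id=", "", idl[1]) else ""
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    colClasses = c("character", "integer", "character"),
                    na.strings = NULL)
  interface_annotation(receptor_id,
                       make_res_id(tab$chain, tab$seq_number,
                                   tab$insertion_code))
}

# split "<chain>:<resno><ins>" ids back into components
split_res_id <- function(ids) {
  if (length(ids) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      ins = character(), stringsAsFactors = FALSE))
  chain <- sub(":.*$", "", ids)
  rest <- sub("^[^:]*:", "", ids)
  resno <- as.integer(sub("^(-?[0-9]+).*$", "\\1", rest))
  ins <- sub("^-?[0-9]+", "", rest)
  data.frame(chain = chain, resno = resno, ins = ins,
             stringsAsFactors = FALSE)
}
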