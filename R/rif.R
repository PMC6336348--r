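# The core statistic. For receptor residue i and docked pose k let
# I(R_ik) = 1 when residue i is at the pose interface. The Residue
# Interface Frequency is N_i = sum_k I(R_ik), the number of poses in the
# ensemble that contact residue i. Residues are ranked by N_i and the
# top K (default 15) form the predicted binding site. The residues with
# N_i >= 1 are the "sampled" pool used as the population in significance
# testing.

#' Compute a Residue Interface Frequency profile
#'
#' @param contact_sets list of contact sets (character vectors of residue
#'   ids), one per docked pose; see [contacts_for_pose_set()] or
#'   [sample_contact_ensemble()].
#' @param receptor_residues residue-id universe in canonical order,
#'   normally [residue_ids()] of the receptor. Every contact set must be
#'   a subset of it.
#' @param receptor_id optional receptor label stored in the profile.
#' @return An object of class `rif_profile`: list with `receptor_id`,
#'   `counts` (named integer vector N_i over the full universe, zeros
#'   included), `n_poses`, and `sampled_residues` (ids with N_i >= 1).
#' @export
compute_rif <- function(contact_sets, receptor_residues,
                        receptor_id = "receptor") {
  if (length(contact_sets) == 0L)
    stop("RIF profile undefined for an empty contact-set collection")
  all_ids <- unlist(contact_sets, use.names = FALSE)
  bad <- setdiff(unique(all_ids), receptor_residues)
  if (length(bad))
    stop("contact sets contain residues outside the receptor universe: ",
         paste(head(bad, 5L), collapse = ", "))
  counts <- integer(length(receptor_residues))
  names(counts) <- receptor_residues
  if (length(all_ids)) {
    tab <- tabulate(match(all_ids, receptor_residues),
                    nbins = length(receptor_residues))
    counts[] <- tab
  }
  structure(list(receptor_id = receptor_id, counts = counts,
                 n_poses = length(contact_sets),
                 sampled_residues = receptor_residues[counts >= 1L]),
            class = "rif_profile")
}

#' @export
print.rif_profile <- function(x, ...) {
  cat(sprintf(
    "rif_profile '%s': %d poses, %d/%d residues sampled, max N_i = %d\n",
    x$receptor_id, x$n_poses, length(x$sampled_residues),
    length(x$counts), if (length(x$counts)) max(x$counts) else 0L))
  invisible(x)
}

#' Top-ranked residues of a RIF profile
#'
#' Residues are sorted by descending N_i; ties are broken by ascending
#' (chain, seq_number, insertion_code), i.e. the canonical universe
#' order, so rankings are deterministic. Residues never contacted
#' (N_i = 0) are not returned; if fewer than `k` residues were sampled,
#' all sampled residues are returned.
#'
#' @param profile a [compute_rif()] profile.
#' @param k number of residues to return (default 15).
#' @return character vector of residue ids, best first.
#' @export
rank_top_k <- function(profile, k = 15L) {
  stopifnot(inherits(profile, "rif_profile"))
  if (k < 1) stop("k must be >= 1")
  cnt <- profile$counts[profile$counts >= 1L]
  ord <- order(-cnt, match(names(cnt), names(profile$counts)))
  head(names(cnt)[ord], min(k, length(cnt)))
}

#' Filter contact sets by exact interface patch size
#'
#' Retains only the poses whose interface is formed by exactly `size`
#' receptor residues (the production protocol uses the modal patch size,
#' typically 9; see [patch_size_mode()]). Order is preserved.
#'
#' @param contact_sets list of contact sets.
#' @param size required patch size (>= 1).
#' @return the surviving subset of `contact_sets`.
#' @export
filter_patch_size <- function(contact_sets, size = 9L) {
  if (size < 1) stop("size must be >= 1")
  keep <- lengths(contact_sets) == size
  if (!any(keep))
    stop("no contact set has exactly ", size, " residues; inspect the ",
         "patch-size distribution with patch_size_mode()")
  contact_sets[keep]
}

#' Modal interface patch size of an ensemble
#'
#' @param contact_sets non-empty list of contact sets.
#' @return the most frequent patch size; ties resolve to the smallest.
#' @export
patch_size_mode <- function(contact_sets) {
  if (length(contact_sets) == 0L)
    stop("empty contact-set collection")
  sizes <- lengths(contact_sets)
  tab <- table(sizes)
  as.integer(names(tab)[which.max(tab)])  # which.max takes the first =
}                                         # smallest size on ties

#' Pool contact sets across probes and subsample
#'
#' Concatenates the per-probe contact-set collections and draws a uniform
#' sample of `n` sets without replacement (all sets if the pool holds no
#' more than `n`). This mirrors evaluating a consensus over several
#' probes with a fixed ensemble budget.
#'
#' @param contact_set_collections list of per-probe contact-set lists.
#' @param n sample size (default 2000).
#' @param seed RNG seed; identical seed gives an identical sample.
#' @return list of contact sets.
#' @export
pool_and_subsample <- function(contact_set_collections, n = 2000L,
                               seed = NULL) {
  nested <- length(contact_set_collections) > 0L &&
    all(vapply(contact_set_collections, is.list, logical(1)))
  pool <- if (nested)
    do.call(c, c(contact_set_collections, list(use.names = FALSE)))
  else contact_set_collections   # already a single flat collection
  if (is.null(pool) || length(pool) == 0L)
    stop("no contact sets to pool")
  if (length(pool) <= n) return(pool)
  idx <- with_seed(seed, sample.int(length(pool), n))
  pool[idx]
}

#' Serialize a RIF profile as TSV
#'
#' Columns: chain, seq_number, insertion_code, res_name, Ni, rank. The
#' rank column holds the top-K position (1 = best) or NA outside the
#' ranking. A `# rifsite profile v1` comment line records the schema.
#'
#' @param profile a `rif_profile`.
#' @param path output file path.
#' @param residue_table optional residue table (as in
#'   `rif_structure$residues`) supplying res_name; unnamed residues are
#'   written as `UNK`.
#' @param top_k ranking depth recorded in the rank column.
#' @return invisibly, `path`.
#' @export
write_rif_profile <- function(profile, path, residue_table = NULL,
                              top_k = 15L) {
  stopifnot(inherits(profile, "rif_profile"))
  ids <- names(profile$counts)
  parts <- split_res_id(ids)
  resname <- rep("UNK", length(ids))
  if (!is.null(residue_table))
    resname <- residue_table$resid[match(ids, residue_table$res_id)]
  top <- rank_top_k(profile, top_k)
  rk <- match(ids, top)
  df <- data.frame(chain = parts$chain, seq_number = parts$resno,
                   insertion_code = parts$ins, res_name = resname,
                   Ni = as.integer(profile$counts), rank = rk,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rifsite profile v1",
               paste0("# receptor_id=", profile$receptor_id),
               paste0("# n_poses=", profile$n_poses)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a RIF profile written by [write_rif_profile()]
#'
#' @param path profile TSV path.
#' @return a `rif_profile`.
#' @export
read_rif_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, "="), "", hit[1]) else default
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    na.strings = "NA",
                    colClasses = c("character", "integer", "character",
                                   "character", "integer", "integer"))
  ids <- make_res_id(tab$chain, tab$seq_number, tab$insertion_code)
  counts <- setNames(as.integer(tab$Ni), ids)
  structure(list(receptor_id = get_hdr("receptor_id", "receptor"),
                 counts = counts,
                 n_poses = as.integer(get_hdr("n_poses", sum(counts))),
                 sampled_residues = ids[counts >= 1L]),
            class = "rif_profile")
}

#' Write / read contact-set ensembles as TSV
#'
#' Long format, one row per (pose, contacted residue): columns pose_id,
#' chain, seq_number, insertion_code. Poses with empty contact sets are
#' recorded with a single row of empty residue fields so the pose count
#' round-trips.
#'
#' @param contact_sets named list of contact sets.
#' @param path file path.
#' @return `write_contact_sets` returns `path` invisibly;
#'   `read_contact_sets` returns the named list of contact sets.
#' @export
write_contact_sets <- function(contact_sets, path) {
  nm <- names(contact_sets)
  if (is.null(nm)) nm <- sprintf("pose_%d", seq_along(contact_sets))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# rifsite contacts v1",
               "pose_id\tchain\tseq_number\tinsertion_code"), con)
  for (i in seq_along(contact_sets)) {
    ids <- contact_sets[[i]]
    if (length(ids) == 0L) {
      writeLines(paste(nm[i], "", "", "", sep = "\t"), con)
    } else {
      parts <- split_res_id(ids)
      writeLines(paste(nm[i], parts$chain, parts$resno, parts$ins,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_contact_sets
#' @export
read_contact_sets <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "character",
                                   "character"), na.strings = NULL)
  pose <- factor(tab$pose_id, levels = unique(tab$pose_id))
  ids <- ifelse(tab$chain == "", NA_character_,
                make_res_id(tab$chain, as.integer(tab$seq_number),
                            tab$insertion_code))
  out <- lapply(split(ids, pose), function(v) as.character(v[!is.na(v)]))
  out[levels(pose)]
}
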