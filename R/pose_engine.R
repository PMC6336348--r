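# Pose ensembles: a built-in geometric sampler plus an adapter for
# externally generated rigid-body transforms. The sampler is a documented
# surrogate for production docking programs: it draws unbiased touching
# poses (uniform rotation, uniform approach direction, slide-to-contact)
# whose purpose is to exercise the contact/RIF/statistics stack, not to
# model docking energetics.

#' Construct a docked pose
#'
#' @param probe_id probe structure label.
#' @param transform a [rigid_transform()] placing the probe onto the
#'   receptor frame.
#' @param score optional unitless pose score (higher is better).
#' @param rank optional positive integer rank within its pose set.
#' @return an object of class `rif_pose`.
#' @export
docked_pose <- function(probe_id, transform, score = NA_real_,
                        rank = NA_integer_) {
  if (!inherits(transform, "rif_transform"))
    stop("transform must be a rif_transform")
  structure(list(probe_id = probe_id, transform = transform,
                 score = as.numeric(score), rank = as.integer(rank)),
            class = "rif_pose")
}

#' Construct a pose set
#'
#' @param receptor_id receptor label.
#' @param poses list of [docked_pose()] objects.
#' @param generator provenance list (sampler name, seed, parameters).
#' @param max_poses maximum ensemble size (default 2000 poses per probe).
#' @return an object of class `rif_pose_set`.
#' @export
pose_set <- function(receptor_id, poses, generator = list(),
                     max_poses = 2000L) {
  stopifnot(is.list(poses))
  if (length(poses) > max_poses)
    stop("pose set exceeds the configured maximum of ", max_poses)
  ranks <- vapply(poses, function(p) p$rank, integer(1))
  if (any(!is.na(ranks)) && anyDuplicated(ranks[!is.na(ranks)]))
    stop("pose ranks must be unique within a pose set")
  structure(list(receptor_id = receptor_id, poses = poses,
                 generator = generator),
            class = "rif_pose_set")
}

#' @export
print.rif_pose_set <- function(x, ...) {
  cat(sprintf("rif_pose_set on '%s': %d pose(s) [%s]\n", x$receptor_id,
              length(x$poses),
              if (length(x$generator)) x$generator$name else "unknown source"))
  invisible(x)
}

#' @export
length.rif_pose_set <- function(x) length(x$poses)

#' Sample touching rigid-body poses of a probe on a receptor
#'
#' Each pose is drawn by (i) a uniform random rotation of the probe,
#' (ii) a uniform random approach direction through the receptor centroid
#' and (iii) a bisection search for the translation along that direction
#' at which the minimum receptor-probe interatomic distance first falls in
#' `[clash_floor, contact_cutoff]`. Every returned pose therefore has at
#' least one atom pair within `contact_cutoff` and no pair closer than
#' `clash_floor`. Identical inputs and seed yield an identical pose set.
#'
#' When `score_poses = TRUE`, poses are scored with [score_pose()] and
#' ordered by descending score (rank 1 = best), mimicking the ranked
#' output of energy-scored docking programs.
#'
#' @param receptor,probe `rif_structure` objects.
#' @param n_poses number of poses requested (>= 0).
#' @param seed RNG seed for reproducibility.
#' @param clash_floor minimum allowed interatomic distance, Angstrom.
#' @param contact_cutoff contact distance, Angstrom; must exceed
#'   `clash_floor`.
#' @param max_retries direction retries per pose before it is skipped
#'   with a warning.
#' @param score_poses score and rank the ensemble (default `FALSE`).
#' @return a [pose_set()] with provenance in `$generator`.
#' @export
sample_pose_set <- function(receptor, probe, n_poses, seed = NULL,
                            clash_floor = 2.5, contact_cutoff = 3.5,
                            max_retries = 100L, score_poses = FALSE) {
  stopifnot(inherits(receptor, "rif_structure"),
            inherits(probe, "rif_structure"))
  if (n_poses < 0) stop("n_poses must be >= 0")
  if (clash_floor >= contact_cutoff)
    stop("clash_floor must be smaller than contact_cutoff")
  gen <- list(name = "rifsite_touch_sampler", seed = seed,
              clash_floor = clash_floor, contact_cutoff = contact_cutoff,
              max_retries = max_retries)
  if (n_poses == 0L)
    return(pose_set(receptor$id, list(), generator = gen))
  rxyz <- atom_xyz(receptor)
  pxyz <- atom_xyz(probe)
  rcen <- colMeans(rxyz)
  pcen <- colMeans(pxyz)
  pc <- sweep(pxyz, 2, pcen)          # probe centred at origin
  rmax <- sqrt(max(rowSums(sweep(rxyz, 2, rcen)^2)))
  pmax_ <- sqrt(max(rowSums(pc^2)))
  poses <- with_seed(seed, {
    out <- vector("list", n_poses)
    got <- 0L
    for (attempt in seq_len(n_poses)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        R <- random_rotation()
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        rot <- pc %*% t(R)
        fmin <- function(d) min(.min_dist_to(
          sweep(rot, 2, rcen + d * u, "+"), rxyz))
        lo <- 0
        hi <- rmax + pmax_ + contact_cutoff + 1
        fl <- fmin(lo)
        if (fl >= clash_floor) {
          if (fl <= contact_cutoff) { d <- lo; ok <- TRUE }
          # else probe never approaches along this ray; retry
        } else {
          for (it in 1:60) {
            mid <- (lo + hi) / 2
            fm <- fmin(mid)
            if (fm < clash_floor) lo <- mid
            else if (fm > contact_cutoff) hi <- mid
            else { d <- mid; ok <- TRUE; break }
          }
        }
        if (ok) break
      }
      if (!ok) {
        warning("pose sampling: translation search failed after ",
                max_retries, " retries; pose skipped")
        next
      }
      tr <- rigid_transform(R, rcen + d * u - as.numeric(R %*% pcen))
      got <- got + 1L
      out[[got]] <- docked_pose(probe$id, tr)
    }
    if (got == 0L) stop("pose sampler produced zero poses")
    out[seq_len(got)]
  })
  if (score_poses) {
    sc <- vapply(poses, function(p)
      score_pose(receptor, probe, p, clash_floor = clash_floor),
      numeric(1))
    ord <- order(-sc)
    poses <- poses[ord]
    for (i in seq_along(poses)) {
      poses[[i]]$score <- sc[ord[i]]
      poses[[i]]$rank <- i
    }
  } else {
    for (i in seq_along(poses)) poses[[i]]$rank <- i
  }
  pose_set(receptor$id, poses, generator = gen,
           max_poses = max(2000L, n_poses))
}

#' Shape-complementarity surrogate score for a pose
#'
#' `score = #(atom pairs with distance in [clash_floor, shell]) -
#' clash_penalty * #(pairs closer than clash_floor)`; higher is better.
#' A crude stand-in for a docking energy used only to order poses.
#'
#' @inheritParams sample_pose_set
#' @param pose a [docked_pose()].
#' @param shell outer shell distance, Angstrom.
#' @param clash_penalty weight of sub-`clash_floor` pairs.
#' @return numeric score.
#' @export
score_pose <- function(receptor, probe, pose, shell = 4.5,
                       clash_penalty = 5.0, clash_floor = 2.5) {
  stopifnot(inherits(pose, "rif_pose"))
  placed <- apply_transform(probe, pose$transform)
  rxyz <- atom_xyz(receptor)
  lxyz <- atom_xyz(placed)
  n_contact <- 0L; n_clash <- 0L
  step <- max(1L, floor(4e6 / max(1L, nrow(lxyz))))
  i <- 1L
  while (i <= nrow(rxyz)) {
    j <- min(nrow(rxyz), i + step - 1L)
    d2 <- .cross_dist2(rxyz[i:j, , drop = FALSE], lxyz)
    d <- sqrt(d2)
    n_contact <- n_contact + sum(d >= clash_floor & d <= shell)
    n_clash <- n_clash + sum(d < clash_floor)
    i <- j + 1L
  }
  n_contact - clash_penalty * n_clash
}

# Text-serialized rotation matrices are typically rounded; project
# slightly non-orthonormal inputs onto the nearest proper rotation
# (polar decomposition) and reject anything farther off than `tol`.
.nearest_rotation <- function(R, tol = 1e-3, line = NA) {
  dev <- max(abs(crossprod(R) - diag(3)))
  if (dev <= 1e-8 && abs(det(R) - 1) <= 1e-8) return(R)
  if (dev > tol || det(R) <= 0)
    stop("rotation matrix", if (!is.na(line)) paste0(" at line ", line),
         " is not orthonormal (deviation ", signif(dev, 3), ")")
  sv <- svd(R)
  P <- sv$u %*% t(sv$v)
  if (det(P) < 0) P <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  P
}

#' Import externally generated pose transforms
#'
#' Adapter for poses docked outside the package (e.g. converted docking
#' program output). The table is plain text, whitespace-separated, one
#' pose per line; a header line of `matrix` or `euler` selects the
#' dialect:
#' * `matrix`: 9 row-major rotation entries followed by 3 translation
#'   components (Angstrom);
#' * `euler`: 3 z-x-z Euler angles (radians) followed by 3 translations.
#'
#' Record order is preserved as pose rank. Rotation matrices rounded by
#' text serialization are projected onto the nearest proper rotation
#' (polar decomposition); deviations beyond 1e-3 are rejected.
#'
#' @param path transform table file path.
#' @param probe_id probe label attached to every pose.
#' @param receptor_id receptor label for the pose set.
#' @return a [pose_set()].
#' @export
import_pose_transforms <- function(path, probe_id,
                                   receptor_id = "receptor") {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty transform table: ", path)
  dialect <- tolower(trimws(lines[1]))
  if (!dialect %in% c("matrix", "euler"))
    stop("transform table must start with a 'matrix' or 'euler' header line")
  want <- if (dialect == "matrix") 12L else 6L
  rows <- lines[-1]
  poses <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]),
                                                 "[[:space:]]+")[[1]]))
    if (length(vals) != want || anyNA(vals))
      stop("malformed transform record at line ", i + 1L, ": expected ",
           want, " numeric fields")
    tr <- if (dialect == "matrix")
      rigid_transform(.nearest_rotation(matrix(vals[1:9], 3, 3,
                                               byrow = TRUE),
                                        line = i + 1L), vals[10:12])
    else
      rigid_transform(euler_zxz(vals[1], vals[2], vals[3]), vals[4:6])
    poses[[i]] <- docked_pose(probe_id, tr, rank = i)
  }
  pose_set(receptor_id, poses,
           generator = list(name = "imported", source = path,
                            dialect = dialect),
           max_poses = max(2000L, length(poses)))
}

#' Contact sets for every pose of an ensemble
#'
#' Applies each pose transform to the probe and collects the receptor
#' residues in contact (see [contact_residues()]), one contact set per
#' pose.
#'
#' @inheritParams sample_pose_set
#' @param poses a [pose_set()].
#' @param cutoff contact distance, Angstrom.
#' @return named list of contact sets (character vectors of residue ids);
#'   names are `pose_<k>`.
#' @export
contacts_for_pose_set <- function(receptor, probe, poses, cutoff = 3.5) {
  stopifnot(inherits(poses, "rif_pose_set"))
  rxyz <- atom_xyz(receptor)
  res_idx <- receptor$atoms$res_idx
  ids <- receptor$residues$res_id
  pxyz <- atom_xyz(probe)
  out <- lapply(poses$poses, function(p) {
    lxyz <- pxyz %*% t(p$transform$R)
    lxyz <- sweep(lxyz, 2, p$transform$t, "+")
    .contact_ids(rxyz, res_idx, ids, lxyz, cutoff)
  })
  names(out) <- sprintf("pose_%d", seq_along(out))
  out
}
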