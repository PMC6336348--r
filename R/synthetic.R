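# Synthetic fixtures with known statistical structure. Receptors are
# one-pseudo-atom-per-residue shells on a Fibonacci sphere lattice
# (nearest-neighbour spacing ~5 A, the C-alpha scale), the true interface
# is a contiguous surface patch, and pose contact sets are geometric
# patches whose centres favour the interface by a known enrichment
# factor. e = 1 reduces exactly to uniform centre placement (the null);
# e = 0 never centres on the interface. This gives every downstream
# stage a ground truth without any structure download or docking run.

#' Synthetic pose-ensemble model
#'
#' @param n_poses poses per ensemble (default 2000, the production
#'   ensemble budget per probe).
#' @param enrichment relative propensity `e >= 0` of a pose patch
#'   centring on a true-interface residue versus uniform placement: a
#'   centre is drawn from the interface with probability
#'   `e M / (e M + (N - M))`, otherwise uniformly from the non-interface
#'   surface. `e = 1` is the exact uniform null; `e = 0` excludes the
#'   interface.
#' @param patch_sizes integer vector of admissible interface patch
#'   sizes; each pose draws its size uniformly from it (default 5:13,
#'   so 9 is the attainable modal size).
#' @param seed RNG seed used when the model is sampled.
#' @return an object of class `rif_pose_model`.
#' @export
synthetic_pose_model <- function(n_poses = 2000L, enrichment = 1,
                                 patch_sizes = 5:13, seed = NULL) {
  if (enrichment < 0) stop("enrichment must be >= 0")
  if (n_poses < 1) stop("n_poses must be >= 1")
  if (any(patch_sizes < 1)) stop("patch sizes must be >= 1")
  structure(list(n_poses = as.integer(n_poses),
                 enrichment = enrichment,
                 patch_sizes = as.integer(patch_sizes),
                 seed = seed),
            class = "rif_pose_model")
}

# Fibonacci sphere lattice: n quasi-uniform points on the unit sphere
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta),
        z = cos(phi))
}

#' Generate a toy spherical receptor with a known interface patch
#'
#' Residues are single pseudo-atoms on a Fibonacci sphere lattice whose
#' radius is scaled so nearest-neighbour spacing is about 5 A. The
#' annotated interface is the `interface_size` residues nearest a
#' randomly chosen surface point — a geodesically contiguous patch, as a
#' real binding footprint would be.
#'
#' @param n_residues number of residues (>= 1).
#' @param interface_size number of interface residues
#'   (1 <= interface_size <= n_residues).
#' @param seed RNG seed; the generator is a pure function of it.
#' @param id receptor label.
#' @return list with `structure` (a `rif_structure`) and `annotation`
#'   (a `rif_annotation`).
#' @export
make_toy_receptor <- function(n_residues, interface_size, seed = NULL,
                              id = "toy_receptor") {
  if (n_residues < 1) stop("n_residues must be >= 1")
  if (interface_size < 1 || interface_size > n_residues)
    stop("interface_size must lie in [1, n_residues]")
  with_seed(seed, {
    pts <- .fibonacci_sphere(n_residues)
    radius <- 5 * sqrt(n_residues) / 3.81   # lattice nn spacing ~5 A
    xyz <- pts * radius
    atoms <- data.frame(
      chain = "A", resno = seq_len(n_residues), ins = "",
      resid = "ALA", elety = "CA", elesy = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      o = 1, alt = "", stringsAsFactors = FALSE)
    s <- new_structure(id, atoms)
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    near <- order(colSums((t(pts) - v)^2))
    iface <- sort(near[seq_len(interface_size)])
    ann <- interface_annotation(id, s$residues$res_id[iface])
    list(structure = s, annotation = ann)
  })
}

#' Generate a compact random probe blob
#'
#' A Gaussian cloud of single-atom pseudo-residues at roughly 5 A
#' spacing (cloud scale grows as `n_atoms^(1/3)`), usable as a docking
#' probe for the built-in sampler.
#'
#' @param n_atoms number of atoms (>= 1).
#' @param seed RNG seed.
#' @param id probe label.
#' @return a `rif_structure`.
#' @export
make_probe_blob <- function(n_atoms, seed = NULL, id = "probe_blob") {
  if (n_atoms < 1) stop("n_atoms must be >= 1")
  with_seed(seed, {
    sdev <- 2.5 * max(1, n_atoms)^(1 / 3)
    xyz <- matrix(rnorm(3 * n_atoms, sd = sdev), ncol = 3)
    new_structure(id, data.frame(
      chain = "B", resno = seq_len(n_atoms), ins = "",
      resid = "GLY", elety = "CA", elesy = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      o = 1, alt = "", stringsAsFactors = FALSE))
  })
}

#' Sample a synthetic pose-contact ensemble
#'
#' For each pose: draw a patch size `s` from the model's size law; draw
#' a centre residue from the interface with probability
#' `e M / (e M + (N - M))` (uniform within the interface), otherwise
#' uniformly from the non-interface surface; the contact set is the `s`
#' residues nearest the centre in the receptor geometry (centre
#' included). Deterministic under the model seed.
#'
#' @param receptor a `rif_structure` (supplies the geometry and the
#'   surface universe).
#' @param annotation a `rif_annotation`; must be a subset of the
#'   receptor residues.
#' @param model a [synthetic_pose_model()].
#' @param seed optional seed overriding `model$seed`.
#' @return named list of contact sets (`pose_1` ... `pose_n`).
#' @export
sample_contact_ensemble <- function(receptor, annotation, model,
                                    seed = NULL) {
  stopifnot(inherits(receptor, "rif_structure"),
            inherits(annotation, "rif_annotation"),
            inherits(model, "rif_pose_model"))
  ids <- residue_ids(receptor)
  n <- length(ids)
  if (max(model$patch_sizes) > n)
    stop("patch size exceeds the number of surface residues")
  iface_idx <- match(annotation$interface_residues, ids)
  if (anyNA(iface_idx))
    stop("annotation contains residues not in the receptor")
  M <- length(iface_idx)
  e <- model$enrichment
  p_iface <- if (M == n) 1 else e * M / (e * M + (n - M))
  # per-residue neighbour order from the receptor coordinates; residues
  # are single-point here but general structures use residue centroids
  cen <- .residue_centroids(receptor)
  d2 <- as.matrix(dist(cen))^2
  smax <- max(model$patch_sizes)
  nbr <- apply(d2, 2L, function(col) order(col)[seq_len(smax)])
  if (!is.matrix(nbr)) nbr <- matrix(nbr, nrow = 1L)
  if (is.null(seed)) seed <- model$seed
  with_seed(seed, {
    sizes <- model$patch_sizes[sample.int(length(model$patch_sizes),
                                          model$n_poses, replace = TRUE)]
    on_iface <- runif(model$n_poses) < p_iface
    centers <- integer(model$n_poses)
    n_if <- sum(on_iface)
    if (n_if > 0)
      centers[on_iface] <- iface_idx[sample.int(M, n_if, replace = TRUE)]
    if (n_if < model$n_poses) {
      non_iface <- setdiff(seq_len(n), iface_idx)
      centers[!on_iface] <- non_iface[sample.int(length(non_iface),
                                                 model$n_poses - n_if,
                                                 replace = TRUE)]
    }
    out <- lapply(seq_len(model$n_poses), function(k)
      ids[sort(nbr[seq_len(sizes[k]), centers[k]])])
    names(out) <- sprintf("pose_%d", seq_len(model$n_poses))
    out
  })
}

# one centroid per residue, in canonical residue order
.residue_centroids <- function(s) {
  xyz <- atom_xyz(s)
  out <- rowsum(xyz, s$atoms$res_idx)
  out / as.vector(table(factor(s$atoms$res_idx,
                               levels = seq_len(nrow(s$residues)))))
}

#' Generate a synthetic benchmark bundle
#'
#' Independent toy receptors with annotated interfaces and pose-contact
#' ensembles drawn from a shared enrichment model; per-receptor seeds
#' are derived from the master seed, so the bundle is a pure function of
#' `seed`.
#'
#' @param n_receptors number of receptors (>= 1).
#' @param receptor_size_law either a length-2 integer range from which
#'   sizes are drawn uniformly (default `c(120, 200)`) or a function
#'   `f(n)` returning `n` sizes.
#' @param interface_size interface residues per receptor (default 15).
#' @param model a [synthetic_pose_model()].
#' @param seed master RNG seed.
#' @return An object of class `rif_benchmark`: list with `receptors`
#'   (each: `structure`, `annotation`, `contact_sets`, `seed`), `model`
#'   and `seed`.
#' @export
make_benchmark <- function(n_receptors, receptor_size_law = c(120L, 200L),
                           interface_size = 15L,
                           model = synthetic_pose_model(), seed = NULL) {
  if (n_receptors < 1) stop("n_receptors must be >= 1")
  sizes <- if (is.function(receptor_size_law)) {
    with_seed(seed, receptor_size_law(n_receptors))
  } else {
    stopifnot(length(receptor_size_law) == 2L)
    with_seed(seed, sample(receptor_size_law[1]:receptor_size_law[2],
                           n_receptors, replace = TRUE))
  }
  seeds <- derive_seeds(if (is.null(seed)) NULL else seed + 1L,
                        2L * n_receptors)
  receptors <- lapply(seq_len(n_receptors), function(i) {
    toy <- make_toy_receptor(sizes[i], interface_size,
                             seed = seeds[2L * i - 1L],
                             id = sprintf("synth_%03d", i))
    cs <- sample_contact_ensemble(toy$structure, toy$annotation, model,
                                  seed = seeds[2L * i])
    list(structure = toy$structure, annotation = toy$annotation,
         contact_sets = cs, seed = seeds[2L * i - 1L])
  })
  structure(list(receptors = receptors, model = model, seed = seed),
            class = "rif_benchmark")
}

#' @export
print.rif_benchmark <- function(x, ...) {
  cat(sprintf(
    "rif_benchmark: %d receptor(s), %d poses each, enrichment = %g\n",
    length(x$receptors), x$model$n_poses, x$model$enrichment))
  invisible(x)
}

#' Write / read a benchmark bundle directory
#'
#' Layout: `receptor_<i>.pdb`, `annotation_<i>.tsv`,
#' `contacts_<i>.tsv` plus a `manifest.json` recording seeds and model
#' parameters. All files are plain text.
#'
#' @param bundle a `rif_benchmark`.
#' @param dir output directory (created if missing).
#' @return `write_benchmark` returns `dir` invisibly; `read_benchmark`
#'   returns a `rif_benchmark`.
#' @export
write_benchmark <- function(bundle, dir) {
  stopifnot(inherits(bundle, "rif_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(bundle$receptors), function(i) {
    r <- bundle$receptors[[i]]
    pdb <- sprintf("receptor_%03d.pdb", i)
    ann <- sprintf("annotation_%03d.tsv", i)
    cts <- sprintf("contacts_%03d.tsv", i)
    write_structure(r$structure, file.path(dir, pdb))
    write_annotation(r$annotation, file.path(dir, ann))
    write_contact_sets(r$contact_sets, file.path(dir, cts))
    list(id = r$structure$id, pdb = pdb, annotation = ann,
         contacts = cts, seed = r$seed)
  })
  manifest <- list(format = "rifsite benchmark v1",
                   seed = bundle$seed,
                   model = bundle$model[c("n_poses", "enrichment",
                                          "patch_sizes", "seed")],
                   receptors = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf)
  model <- synthetic_pose_model(
    n_poses = manifest$model$n_poses,
    enrichment = manifest$model$enrichment,
    patch_sizes = unlist(manifest$model$patch_sizes),
    seed = manifest$model$seed)
  receptors <- lapply(manifest$receptors, function(e) {
    s <- read_structure(file.path(dir, e$pdb), id = e$id)
    list(structure = s,
         annotation = read_annotation(file.path(dir, e$annotation),
                                      receptor_id = e$id),
         contact_sets = read_contact_sets(file.path(dir, e$contacts)),
         seed = e$seed)
  })
  structure(list(receptors = receptors, model = model,
                 seed = manifest$seed),
            class = "rif_benchmark")
}
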