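# End-to-end orchestration. All defaults match the production protocol:
# 2000 poses per probe, top-15 ranking, 200 resampling draws, p < 0.05
# and Z > 1.97 thresholds. Every run logs its seeds and parameters and
# is fully reproducible from them.

.log_msg <- function(verbose, ...) {
  if (verbose)
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(...))
}

.as_structure <- function(x, id = NULL) {
  if (inherits(x, "rif_structure")) x
  else read_structure(x, id = id)
}

#' Predict a binding site for one receptor
#'
#' Runs the full prediction pipeline: obtain pose ensembles for each
#' probe (built-in sampler, or an imported transform table), compute
#' per-pose contact sets, optionally filter to a fixed interface patch
#' size, optionally pool-and-subsample across probes, build the RIF
#' profile and rank the top K residues. When an interface annotation (or
#' a cognate ligand structure) is supplied, prediction significance and
#' set metrics are computed as well.
#'
#' Writes `profile.tsv`, `top_residues.tsv` and (given an annotation)
#' `significance.json` under `out_dir` when it is non-NULL.
#'
#' @param receptor `rif_structure` or PDB path.
#' @param probes list of `rif_structure`s or PDB paths (sampler mode).
#' @param pose_tables named list mapping probe ids to transform-table
#'   paths (import mode, see [import_pose_transforms()]); `probes` must
#'   then supply the matching probe structures.
#' @param annotation optional `rif_annotation` or annotation TSV path.
#' @param cognate optional cognate-ligand `rif_structure` or PDB path;
#'   used to derive the annotation when none is given.
#' @param n_poses poses sampled per probe (default 2000).
#' @param top_k prediction size (default 15).
#' @param patch_size optional exact patch-size filter (the production
#'   choice is 9); `NULL` disables filtering.
#' @param subsample_n optional pooled-ensemble budget; `NULL` keeps all
#'   poses.
#' @param sig_mode hypergeometric criterion, `"pmf"` or `"upper_tail"`.
#' @param reps resampling draws for the Z-criterion (default 200).
#' @param seed master seed; probe-level and subsampling seeds are
#'   derived from it.
#' @param cutoff contact distance, Angstrom.
#' @param out_dir output directory or `NULL` for no files.
#' @param verbose log progress messages.
#' @return invisibly, a list with `profile`, `top_residues`,
#'   `significance` (or NULL), `metrics` (or NULL), `contact_sets`, and
#'   `config`.
#' @export
run_predict <- function(receptor, probes = NULL, pose_tables = NULL,
                        annotation = NULL, cognate = NULL,
                        n_poses = 2000L, top_k = 15L, patch_size = NULL,
                        subsample_n = NULL,
                        sig_mode = c("pmf", "upper_tail"), reps = 200L,
                        seed = NULL, cutoff = 3.5, out_dir = NULL,
                        verbose = FALSE) {
  sig_mode <- match.arg(sig_mode)
  receptor <- .as_structure(receptor)
  if (is.null(probes) && is.null(pose_tables))
    stop("run_predict needs at least one probe structure or pose table")
  if (!is.null(probes) && !is.list(probes)) probes <- list(probes)
  probes <- lapply(probes, .as_structure)
  probe_ids <- vapply(probes, function(p) p$id, character(1))
  seeds <- derive_seeds(seed, max(1L, length(probes)) + 1L)
  .log_msg(verbose, "predict: receptor '%s' (%d residues), seed %s",
           receptor$id, n_residues(receptor),
           if (is.null(seed)) "none" else seed)
  per_probe <- list()
  if (!is.null(pose_tables)) {
    if (is.null(names(pose_tables)) || any(!nzchar(names(pose_tables))))
      stop("pose_tables must be a named list (names = probe ids)")
    for (pid in names(pose_tables)) {
      hit <- match(pid, probe_ids)
      if (is.na(hit))
        stop("no probe structure supplied for pose table '", pid, "'")
      probe <- probes[[hit]]
      ps <- import_pose_transforms(pose_tables[[pid]], probe_id = pid,
                                   receptor_id = receptor$id)
      per_probe[[pid]] <- contacts_for_pose_set(receptor, probe, ps,
                                                cutoff = cutoff)
      .log_msg(verbose, "imported %d poses for probe '%s'",
               length(ps), pid)
    }
  } else {
    for (i in seq_along(probes)) {
      ps <- sample_pose_set(receptor, probes[[i]], n_poses,
                            seed = seeds[i], contact_cutoff = cutoff)
      per_probe[[probe_ids[i]]] <-
        contacts_for_pose_set(receptor, probes[[i]], ps, cutoff = cutoff)
      .log_msg(verbose, "sampled %d poses for probe '%s' (seed %d)",
               length(ps), probe_ids[i], seeds[i])
    }
  }
  contact_sets <- pool_and_subsample(
    per_probe, n = if (is.null(subsample_n)) .Machine$integer.max
    else subsample_n,
    seed = seeds[length(seeds)])
  if (!is.null(patch_size))
    contact_sets <- filter_patch_size(contact_sets, patch_size)
  profile <- compute_rif(contact_sets, residue_ids(receptor),
                         receptor_id = receptor$id)
  top <- rank_top_k(profile, top_k)
  if (is.null(annotation) && !is.null(cognate))
    annotation <- annotate_interface(receptor, .as_structure(cognate),
                                     cutoff = cutoff)
  if (is.character(annotation))
    annotation <- read_annotation(annotation, receptor_id = receptor$id)
  sig <- metrics <- NULL
  if (!is.null(annotation)) {
    sig <- significance_from_profile(profile, annotation, K = top_k,
                                     mode = sig_mode, reps = reps,
                                     seed = seeds[length(seeds)])
    metrics <- precision_recall_f(top, annotation)
  }
  config <- list(command = "predict", receptor = receptor$id,
                 probes = probe_ids, n_poses = n_poses, top_k = top_k,
                 patch_size = patch_size, subsample_n = subsample_n,
                 sig_mode = sig_mode, reps = reps, seed = seed,
                 cutoff = cutoff)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_rif_profile(profile, file.path(out_dir, "profile.tsv"),
                      residue_table = receptor$residues, top_k = top_k)
    parts <- split_res_id(top)
    con <- file(file.path(out_dir, "top_residues.tsv"), "w")
    writeLines(c("# rifsite top-k v1",
                 "rank\tchain\tseq_number\tinsertion_code\tNi"), con)
    if (length(top))
      writeLines(paste(seq_along(top), parts$chain, parts$resno,
                       parts$ins, profile$counts[top], sep = "\t"), con)
    close(con)
    if (!is.null(sig))
      jsonlite::write_json(
        c(unclass(sig), list(config = config)),
        file.path(out_dir, "significance.json"),
        auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
    .log_msg(verbose, "wrote outputs to %s", out_dir)
  }
  invisible(list(profile = profile, top_residues = top,
                 significance = sig, metrics = metrics,
                 contact_sets = contact_sets, config = config))
}

#' Evaluate an existing RIF profile against an annotation
#'
#' @param profile `rif_profile` or profile TSV path.
#' @param annotation `rif_annotation` or annotation TSV path.
#' @inheritParams run_predict
#' @param roc_universe universe for the ROC sweep, see [roc_auc()].
#' @return invisibly, list with `significance`, `metrics`, `roc`.
#' @export
run_evaluate <- function(profile, annotation, top_k = 15L,
                         sig_mode = c("pmf", "upper_tail"), reps = 200L,
                         seed = NULL,
                         roc_universe = c("all_residues", "sampled_only"),
                         out_dir = NULL, verbose = FALSE) {
  sig_mode <- match.arg(sig_mode)
  roc_universe <- match.arg(roc_universe)
  if (is.character(profile)) profile <- read_rif_profile(profile)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  sig <- significance_from_profile(profile, annotation, K = top_k,
                                   mode = sig_mode, reps = reps,
                                   seed = seed)
  top <- rank_top_k(profile, top_k)
  metrics <- precision_recall_f(top, annotation)
  roc <- tryCatch(roc_auc(profile, annotation, universe = roc_universe),
                  error = function(e) NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- list(significance = unclass(sig),
                metrics = unclass(metrics)[c("true_positives",
                                             "false_positives",
                                             "false_negatives",
                                             "precision", "recall",
                                             "f_score")],
                auc = if (!is.null(roc)) roc$auc else NULL)
    jsonlite::write_json(out, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
    if (!is.null(roc))
      write.csv(roc$roc_points, file.path(out_dir, "roc_points.csv"),
                row.names = FALSE)
    .log_msg(verbose, "wrote evaluation to %s", out_dir)
  }
  invisible(list(significance = sig, metrics = metrics, roc = roc))
}

#' Generate and persist a synthetic benchmark
#'
#' @inheritParams make_benchmark
#' @param out_dir bundle directory to write (see [write_benchmark()]);
#'   `NULL` keeps the bundle in memory only.
#' @param verbose log progress.
#' @return invisibly, the `rif_benchmark` bundle.
#' @export
run_simulate <- function(n_receptors, receptor_size_law = c(120L, 200L),
                         interface_size = 15L,
                         model = synthetic_pose_model(), seed = NULL,
                         out_dir = NULL, verbose = FALSE) {
  bundle <- make_benchmark(n_receptors, receptor_size_law,
                           interface_size, model, seed = seed)
  .log_msg(verbose, "simulated %d receptors (enrichment %g, seed %s)",
           n_receptors, model$enrichment,
           if (is.null(seed)) "none" else seed)
  if (!is.null(out_dir)) {
    write_benchmark(bundle, out_dir)
    .log_msg(verbose, "wrote bundle to %s", out_dir)
  }
  invisible(bundle)
}

#' Benchmark the predictor over a bundle of receptors
#'
#' For every receptor: build the RIF profile from its contact-set
#' ensemble (optionally subsampled), rank the top K residues, and assess
#' significance under both the hypergeometric and resampling criteria
#' plus precision/recall/F. The summary reports % significance under
#' both criteria, the pooled ROC/AUC over all receptors' per-residue
#' (score, label) pairs, and the mean F-score. With `n_draws > 1` the
#' subsampling is repeated and % significance is reported as mean +/- sd
#' over draws.
#'
#' @param bundle a `rif_benchmark` or a bundle directory path.
#' @inheritParams run_predict
#' @param n_draws repeated-subsample replicates (default 1).
#' @return invisibly, a list with `per_receptor` (data frame),
#'   `summary` (list) and `roc` (pooled ROC, or NULL).
#' @export
run_benchmark <- function(bundle, top_k = 15L, patch_size = NULL,
                          subsample_n = NULL, n_draws = 1L,
                          sig_mode = c("pmf", "upper_tail"),
                          reps = 200L, seed = NULL, out_dir = NULL,
                          verbose = FALSE) {
  sig_mode <- match.arg(sig_mode)
  if (is.character(bundle)) bundle <- read_benchmark(bundle)
  stopifnot(inherits(bundle, "rif_benchmark"))
  n_rec <- length(bundle$receptors)
  if (n_rec == 0L) stop("empty benchmark bundle")
  draw_seeds <- derive_seeds(seed, n_draws)
  eval_one_draw <- function(draw_seed) {
    rec_seeds <- derive_seeds(draw_seed, n_rec)
    rows <- vector("list", n_rec)
    pooled_scores <- list(); pooled_labels <- list()
    for (i in seq_len(n_rec)) {
      r <- bundle$receptors[[i]]
      cs <- r$contact_sets
      if (!is.null(subsample_n))
        cs <- pool_and_subsample(cs, n = subsample_n,
                                 seed = rec_seeds[i])
      if (!is.null(patch_size))
        cs <- filter_patch_size(cs, patch_size)
      prof <- compute_rif(cs, residue_ids(r$structure),
                          receptor_id = r$structure$id)
      sig <- significance_from_profile(prof, r$annotation, K = top_k,
                                       mode = sig_mode, reps = reps,
                                       seed = rec_seeds[i])
      met <- precision_recall_f(rank_top_k(prof, top_k), r$annotation)
      rows[[i]] <- data.frame(
        receptor_id = r$structure$id, x = sig$x, K = sig$K, M = sig$M,
        N = sig$N, p_value = sig$p_value, mode = sig$mode,
        mu = sig$mu, sigma = sig$sigma, z = sig$z,
        significant_p = isTRUE(sig$significant_p),
        significant_z = isTRUE(sig$significant_z),
        f_score = met$f_score, stringsAsFactors = FALSE)
      pooled_scores[[i]] <- as.numeric(prof$counts)
      pooled_labels[[i]] <-
        names(prof$counts) %in% r$annotation$interface_residues
    }
    per_receptor <- do.call(rbind, rows)
    roc <- tryCatch(roc_curve(unlist(pooled_scores),
                              unlist(pooled_labels)),
                    error = function(e) NULL)
    list(per_receptor = per_receptor, roc = roc)
  }
  draws <- lapply(draw_seeds, eval_one_draw)
  first <- draws[[1L]]
  pct_p <- vapply(draws, function(d)
    100 * mean(d$per_receptor$significant_p), numeric(1))
  pct_z <- vapply(draws, function(d)
    100 * mean(d$per_receptor$significant_z), numeric(1))
  meanF <- vapply(draws, function(d)
    mean(d$per_receptor$f_score), numeric(1))
  summary <- list(
    n_receptors = n_rec, n_draws = as.integer(n_draws),
    sig_mode = sig_mode,
    percent_significant_p = mean(pct_p),
    percent_significant_p_sd = if (n_draws > 1) sd(pct_p) else NA_real_,
    percent_significant_z = mean(pct_z),
    percent_significant_z_sd = if (n_draws > 1) sd(pct_z) else NA_real_,
    mean_f_score = mean(meanF),
    pooled_auc = if (!is.null(first$roc)) first$roc$auc else NA_real_,
    seed = seed)
  .log_msg(verbose,
           "benchmark: %d receptors, %%sig(p)=%.1f, %%sig(z)=%.1f, AUC=%.3f",
           n_rec, summary$percent_significant_p,
           summary$percent_significant_z, summary$pooled_auc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(out_dir, "per_receptor.tsv"), "w")
    writeLines("# rifsite benchmark per-receptor v1", con)
    suppressWarnings(write.table(first$per_receptor, con, sep = "\t",
                                 quote = FALSE, row.names = FALSE))
    close(con)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
    if (!is.null(first$roc))
      write.csv(first$roc$roc_points,
                file.path(out_dir, "roc_points.csv"), row.names = FALSE)
  }
  invisible(list(per_receptor = first$per_receptor, summary = summary,
                 roc = first$roc))
}
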