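# Chance model for a top-K prediction. With N sampled residues of which
# M lie on the annotated interface, the number X of interface residues in
# a uniformly random K-subset is hypergeometric:
#   P(X = x) = C(M, x) C(N - M, K - x) / C(N, K).
# Two criteria are supported: the point-mass test P(X = x) < 0.05 (the
# historical form) and the upper-tail test P(X >= x) < 0.05 (the
# statistically sound form, recommended). An empirical alternative draws
# K residues from the sampled pool `reps` times and flags predictions
# with Z = (x - mu) / sigma > 1.97.

.check_hyper_counts <- function(N, M, K) {
  v <- c(N = N, M = M, K = K)
  if (any(v < 0) || any(v != floor(v)))
    stop("N, M, K must be non-negative integers")
  if (M > N) stop("M (interface residues) cannot exceed N (pool size)")
  if (K > N) stop("K (prediction size) cannot exceed N (pool size)")
}

#' Hypergeometric probability mass
#'
#' `P(X = x)` for `x` interface residues in a uniform draw of `K` from a
#' pool of `N` residues containing `M` interface residues. Computed in
#' log space for stability; values of `x` outside the support return 0.
#'
#' @param x observed count of interface residues among the top K.
#' @param N sampled-residue pool size.
#' @param M interface residues in the pool.
#' @param K prediction (draw) size.
#' @return probability in `[0, 1]`.
#' @export
hypergeom_pmf <- function(x, N, M, K) {
  .check_hyper_counts(N, M, K)
  if (length(x) != 1L || x != floor(x)) stop("x must be a single integer")
  if (x < max(0, K + M - N) || x > min(K, M)) return(0)
  dhyper(x, m = M, n = N - M, k = K)
}

#' Significance of a top-K prediction against the hypergeometric null
#'
#' @inheritParams hypergeom_pmf
#' @param mode `"pmf"` tests the point mass `P(X = x)` (historical
#'   definition; note it can flag an atypically *low* overlap as
#'   significant when the null distribution is spread out);
#'   `"upper_tail"` tests `P(X >= x)` and is recommended.
#' @param alpha significance level (default 0.05).
#' @return An object of class `rif_significance`: list with `x`, `K`,
#'   `M`, `N`, `p_value`, `mode`, `significant_p`, plus `mu`, `sigma`,
#'   `z`, `significant_z` fields (NA here; populated by
#'   [empirical_z()] / [significance_from_profile()]).
#' @export
significance_test <- function(x, N, M, K = 15L,
                              mode = c("pmf", "upper_tail"),
                              alpha = 0.05) {
  mode <- match.arg(mode)
  .check_hyper_counts(N, M, K)
  if (x < 0 || x > min(K, M))
    stop("x must lie in [0, min(K, M)]")
  p <- if (mode == "pmf") hypergeom_pmf(x, N, M, K)
  else phyper(x - 1, m = M, n = N - M, k = K, lower.tail = FALSE)
  structure(list(x = as.integer(x), K = as.integer(K), M = as.integer(M),
                 N = as.integer(N), p_value = p, mode = mode,
                 significant_p = p < alpha,
                 mu = NA_real_, sigma = NA_real_, z = NA_real_,
                 significant_z = NA),
            class = "rif_significance")
}

#' @export
print.rif_significance <- function(x, ...) {
  cat(sprintf(
    "rif_significance: x=%d of K=%d (M=%d, N=%d); p=%.4g [%s]%s\n",
    x$x, x$K, x$M, x$N, x$p_value, x$mode,
    if (isTRUE(x$significant_p)) " *" else ""))
  if (!is.na(x$z))
    cat(sprintf("  resampling null: mu=%.3f sigma=%.3f Z=%.3f%s\n",
                x$mu, x$sigma, x$z,
                if (isTRUE(x$significant_z)) " *" else ""))
  invisible(x)
}

#' Empirical resampling Z-score for a top-K prediction
#'
#' Draws `K` residues uniformly without replacement from the sampled
#' pool of the profile `reps` times; `mu` and `sigma` are the mean and
#' standard deviation of the interface-residue counts over the draws and
#' `Z = (x - mu) / sigma`, where `x` is the observed interface overlap of
#' the top-K prediction. Predictions with `Z > z_threshold` (default
#' 1.97) are flagged significant.
#'
#' @param profile a [compute_rif()] profile with at least `K` sampled
#'   residues.
#' @param annotation a `rif_annotation` with the true interface.
#' @param K prediction size (default 15).
#' @param reps number of random draws (default 200).
#' @param seed RNG seed.
#' @param z_threshold significance threshold on Z.
#' @return a `rif_significance` with the resampling fields populated
#'   (`p_value`/`significant_p` are NA; combine with
#'   [significance_from_profile()] for both criteria).
#' @export
empirical_z <- function(profile, annotation, K = 15L, reps = 200L,
                        seed = NULL, z_threshold = 1.97) {
  stopifnot(inherits(profile, "rif_profile"),
            inherits(annotation, "rif_annotation"))
  if (length(annotation$interface_residues) == 0L)
    stop("empty interface annotation")
  pool <- profile$sampled_residues
  if (length(pool) < K)
    stop("sampled-residue pool (", length(pool),
         ") is smaller than K = ", K)
  iface <- annotation$interface_residues
  x <- length(intersect(rank_top_k(profile, K), iface))
  is_iface <- pool %in% iface
  draws <- with_seed(seed, vapply(seq_len(reps), function(i)
    sum(is_iface[sample.int(length(pool), K)]), numeric(1)))
  mu <- mean(draws)
  sigma <- sd(draws)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate resampling null: every draw yields the same ",
         "overlap (sigma = 0); the Z-criterion is undefined here")
  z <- (x - mu) / sigma
  structure(list(x = as.integer(x), K = as.integer(K),
                 M = sum(is_iface), N = length(pool),
                 p_value = NA_real_, mode = "resampling",
                 significant_p = NA,
                 mu = mu, sigma = sigma, z = z,
                 significant_z = z > z_threshold),
            class = "rif_significance")
}

#' Full significance assessment of a RIF prediction
#'
#' Convenience wrapper: takes the top-K prediction of a profile, counts
#' its overlap `x` with the annotated interface, and populates both the
#' hypergeometric p-value and (when `reps > 0`) the resampling Z-score
#' in a single `rif_significance` result.
#'
#' @inheritParams empirical_z
#' @param mode hypergeometric criterion, see [significance_test()].
#' @param n_definition population used as N: `"sampled"` (default; the
#'   residues with N_i >= 1, matching the method's definition) or
#'   `"all"` (every receptor residue, for sensitivity analysis). `M` is
#'   the number of annotated interface residues inside that population.
#' @param universe full residue universe; required for
#'   `n_definition = "all"` (defaults to the profile's count names).
#' @return a `rif_significance`.
#' @export
significance_from_profile <- function(profile, annotation, K = 15L,
                                      mode = c("pmf", "upper_tail"),
                                      reps = 200L, seed = NULL,
                                      n_definition = c("sampled", "all"),
                                      universe = NULL,
                                      z_threshold = 1.97) {
  mode <- match.arg(mode)
  n_definition <- match.arg(n_definition)
  stopifnot(inherits(profile, "rif_profile"),
            inherits(annotation, "rif_annotation"))
  if (length(annotation$interface_residues) == 0L)
    stop("empty interface annotation")
  if (is.null(universe)) universe <- names(profile$counts)
  pop <- if (n_definition == "sampled") profile$sampled_residues
  else universe
  iface <- annotation$interface_residues
  top <- rank_top_k(profile, K)
  x <- length(intersect(top, iface))
  N <- length(pop)
  M <- length(intersect(iface, pop))
  Keff <- length(top)   # < K only when fewer residues were sampled
  res <- significance_test(x, N = N, M = M, K = Keff, mode = mode)
  if (reps > 0 && length(profile$sampled_residues) >= Keff) {
    zres <- tryCatch(
      empirical_z(profile, annotation, K = Keff, reps = reps,
                  seed = seed, z_threshold = z_threshold),
      error = function(e) e)
    if (!inherits(zres, "error")) {
      res$mu <- zres$mu; res$sigma <- zres$sigma; res$z <- zres$z
      res$significant_z <- zres$significant_z
    } else {
      attr(res, "z_error") <- conditionMessage(zres)
    }
  }
  res
}

#' Dataset-level percent significance
#'
#' `100 x (number of receptors flagged significant) / (total receptors)`
#' under the chosen criterion.
#'
#' @param results non-empty list of `rif_significance` objects.
#' @param criterion `"p"` (hypergeometric flag) or `"z"` (resampling
#'   flag).
#' @return percentage in `[0, 100]`.
#' @export
percent_significance <- function(results, criterion = c("p", "z")) {
  criterion <- match.arg(criterion)
  if (length(results) == 0L) stop("no significance results")
  flags <- vapply(results, function(r) {
    f <- if (criterion == "p") r$significant_p else r$significant_z
    isTRUE(f)
  }, logical(1))
  100 * sum(flags) / length(flags)
}

#' Expected overlap of two random top-K draws
#'
#' Monte-Carlo estimate of `E|A intersect B|` where A and B are
#' independent uniform K-subsets of an N-residue pool — the chance
#' baseline for comparing predictions from two independent docking
#' programs. The closed-form expectation `K^2 / N` is reported alongside.
#'
#' @param pool_size pool size N.
#' @param draw_size draw size K (default 15); must not exceed N.
#' @param reps number of Monte-Carlo draw pairs (default 200).
#' @param seed RNG seed.
#' @return list with `mc_mean` (Monte-Carlo estimate), `analytic`
#'   (`K^2/N`), `mc_sd` (sd of overlap across replicates), `reps`.
#' @export
expected_random_overlap <- function(pool_size, draw_size = 15L,
                                    reps = 200L, seed = NULL) {
  if (draw_size > pool_size)
    stop("draw_size cannot exceed pool_size")
  if (reps < 1) stop("reps must be >= 1")
  overlaps <- with_seed(seed, vapply(seq_len(reps), function(i) {
    a <- sample.int(pool_size, draw_size)
    b <- sample.int(pool_size, draw_size)
    sum(a %in% b)
  }, numeric(1)))
  list(mc_mean = mean(overlaps),
       analytic = draw_size^2 / pool_size,
       mc_sd = sd(overlaps),
       reps = as.integer(reps))
}
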