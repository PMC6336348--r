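# Residue-level prediction quality: precision / recall / F against the
# annotated interface for a fixed prediction set, and threshold-free
# ROC / AUC over the RIF score.

#' Precision, recall and F-score of a predicted residue set
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F = 2 * precision * recall / (precision + recall)`. An empty
#' prediction has precision 0 and F 0 by convention.
#'
#' @param predicted character vector of predicted residue ids (typically
#'   [rank_top_k()] output).
#' @param annotation a `rif_annotation` with a non-empty interface.
#' @return An object of class `rif_metrics`: list with
#'   `true_positives`, `false_positives`, `false_negatives`,
#'   `precision`, `recall`, `f_score`.
#' @export
precision_recall_f <- function(predicted, annotation) {
  stopifnot(inherits(annotation, "rif_annotation"))
  iface <- annotation$interface_residues
  if (length(iface) == 0L) stop("empty interface annotation")
  predicted <- unique(as.character(predicted))
  tp <- length(intersect(predicted, iface))
  fp <- length(predicted) - tp
  fn <- length(iface) - tp
  precision <- if (length(predicted)) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(true_positives = tp, false_positives = fp,
                 false_negatives = fn, precision = precision,
                 recall = recall, f_score = f),
            class = "rif_metrics")
}

#' @export
print.rif_metrics <- function(x, ...) {
  cat(sprintf(
    "rif_metrics: TP=%d FP=%d FN=%d | precision=%.3f recall=%.3f F=%.3f\n",
    x$true_positives, x$false_positives, x$false_negatives,
    x$precision, x$recall, x$f_score))
  if (!is.null(x$auc)) cat(sprintf("  AUC = %.4f\n", x$auc))
  invisible(x)
}

#' ROC curve and AUC from scores and labels
#'
#' Threshold sweep over the distinct score values, descending; tied
#' scores advance TP and FP jointly, which with trapezoidal integration
#' makes the AUC equal to the normalized Mann-Whitney statistic
#' (concordant pairs plus half the ties).
#'
#' @param scores numeric vector of per-residue scores.
#' @param labels logical vector, `TRUE` for interface residues.
#' @return list with `roc_points` (data frame `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: need at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # one ROC vertex after each distinct score value
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' ROC/AUC of a RIF profile against an interface annotation
#'
#' Residues are scored by N_i and labelled by interface membership. With
#' `universe = "all_residues"` every receptor residue enters the sweep
#' (never-contacted residues score 0); with `"sampled_only"` the sweep is
#' restricted to residues with N_i >= 1.
#'
#' @param profile a [compute_rif()] profile.
#' @param annotation a `rif_annotation`.
#' @param universe `"all_residues"` (default) or `"sampled_only"`.
#' @return a `rif_metrics` object with `roc_points` and `auc` set (the
#'   set-metric fields are NA; they apply to a fixed top-K cut, see
#'   [precision_recall_f()]).
#' @export
roc_auc <- function(profile, annotation,
                    universe = c("all_residues", "sampled_only")) {
  universe <- match.arg(universe)
  stopifnot(inherits(profile, "rif_profile"),
            inherits(annotation, "rif_annotation"))
  iface <- annotation$interface_residues
  if (length(iface) == 0L) stop("empty interface annotation")
  counts <- profile$counts
  if (universe == "sampled_only")
    counts <- counts[profile$sampled_residues]
  rc <- roc_curve(as.numeric(counts), names(counts) %in% iface)
  structure(list(true_positives = NA_integer_,
                 false_positives = NA_integer_,
                 false_negatives = NA_integer_,
                 precision = NA_real_, recall = NA_real_,
                 f_score = NA_real_,
                 roc_points = rc$roc_points, auc = rc$auc),
            class = "rif_metrics")
}
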