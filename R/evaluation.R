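#' Confusion counts and rates
#'
#' Tallies true/false positives and negatives of a boolean prediction
#' against boolean labels and derives the true positive rate
#' TPR = TP / (TP + FN) (sensitivity) and false positive rate
#' FPR = FP / (FP + TN) (1 - specificity).  A rate whose denominator is 0
#' is reported as `NA` (missing), never 0.
#'
#' @param labels logical vector of true classes.
#' @param predictions logical vector of predicted classes, same length.
#' @return list with `TP`, `FP`, `TN`, `FN`, `TPR`, `FPR`.
#' @export
confusion_rates <- function(labels, predictions) {
  labels <- as.logical(labels); predictions <- as.logical(predictions)
  if (length(labels) != length(predictions)) {
    stopf("labels (%d) and predictions (%d) differ in length",
          length(labels), length(predictions))
  }
  if (!length(labels)) stopf("empty label vector")
  if (anyNA(labels) || anyNA(predictions)) stopf("NA in labels or predictions")
  tp <- sum(labels & predictions)
  fp <- sum(!labels & predictions)
  tn <- sum(!labels & !predictions)
  fn <- sum(labels & !predictions)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
}

# How a feature value is turned into a positive call at a cutoff c.
apply_cutoff <- function(values, cutoff, orientation) {
  switch(orientation,
         greater = values > cutoff,
         less = values < cutoff,
         leq = values <= cutoff,
         geq = values >= cutoff,
         stopf("unknown orientation '%s'", orientation))
}

#' ROC sweep of a feature over a cutoff grid
#'
#' Classifies items at every cutoff of a grid, records (TPR, FPR), and
#' summarizes the curve by the trapezoid AUC (points sorted by FPR,
#' anchored at (0,0) and (1,1)) and the Youden point: the cutoff
#' maximizing TPR - FPR, the point furthest from the chance diagonal.
#' Ties on TPR - FPR are broken toward the more stringent cutoff (the one
#' calling fewer items positive).
#'
#' @param values numeric feature values (`Inf` allowed, e.g. junction
#'   distances beyond the reporting range).
#' @param labels logical vector, `TRUE` for positives.
#' @param cutoffs numeric grid of cutoffs; defaults to the sorted unique
#'   values.
#' @param orientation how values are compared to a cutoff: `"greater"`
#'   (positive if value > cutoff; SVM score, conservation rank), `"less"`
#'   (distance features), `"leq"` (junction distance), or `"geq"`.
#' @return object of class `roc_curve`: list with `points` (data frame of
#'   cutoff, TPR, FPR), `auc`, `youden_cutoff`, `youden_j`, `orientation`.
#' @export
roc_sweep <- function(values, labels,
                      cutoffs = NULL,
                      orientation = c("greater", "less", "leq", "geq")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (length(values) != length(labels)) stopf("values and labels differ in length")
  if (!any(labels) || all(labels)) {
    stopf("ROC needs at least one positive and one negative label")
  }
  if (is.null(cutoffs)) cutoffs <- sort(unique(values[is.finite(values)]))
  if (!length(cutoffs)) stopf("empty cutoff grid")
  pts <- vapply(cutoffs, function(ct) {
    cr <- confusion_rates(labels, apply_cutoff(values, ct, orientation))
    c(cr$TPR, cr$FPR)
  }, numeric(2))
  points <- data.frame(cutoff = cutoffs, TPR = pts[1L, ], FPR = pts[2L, ])

  fp <- c(0, points$FPR, 1)
  tp <- c(0, points$TPR, 1)
  o <- order(fp, tp)
  fp <- fp[o]; tp <- tp[o]
  auc <- sum(diff(fp) * (tp[-1L] + tp[-length(tp)]) / 2)

  j <- points$TPR - points$FPR
  best <- which(j == max(j))
  # more stringent = fewer positive calls: larger cutoff for > / >=,
  # smaller cutoff for < / <=
  stringent <- if (orientation %in% c("greater", "geq")) which.max(cutoffs[best])
               else which.min(cutoffs[best])
  structure(
    list(points = points, auc = auc,
         youden_cutoff = cutoffs[best[stringent]],
         youden_j = max(j),
         orientation = orientation),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d cutoffs (%s), AUC = %.3f\n",
              nrow(x$points), x$orientation, x$auc))
  cat(sprintf("  Youden cutoff %.4g (TPR - FPR = %.3f)\n",
              x$youden_cutoff, x$youden_j))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  o <- order(x$points$FPR, x$points$TPR)
  graphics::plot(c(0, x$points$FPR[o], 1), c(0, x$points$TPR[o], 1),
                 type = "l", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2)
  at <- which(x$points$cutoff == x$youden_cutoff)
  graphics::points(x$points$FPR[at], x$points$TPR[at], pch = 1, cex = 1.6)
  invisible(x)
}

#' Export an ROC curve as TSV
#'
#' @param x a `roc_curve`.
#' @param path output path (columns cutoff, TPR, FPR).
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(x, path) {
  stopifnot(inherits(x, "roc_curve"))
  utils::write.table(x$points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Wilcoxon rank-sum comparison of two feature distributions
#'
#' Two-sided rank-sum (Mann-Whitney) test used to compare the feature
#' distribution of native insertion sites against all C/S/T sites.  Exact
#' enumeration is used for small untied samples, the tie-corrected normal
#' approximation otherwise (base R `wilcox.test` conventions).
#'
#' @param x,y numeric samples.
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))$p.value
}

#' Chi-squared enrichment test on a contingency table
#'
#' Pearson chi-squared test (no continuity correction) with
#' (r - 1)(c - 1) degrees of freedom, used for category-by-class
#' enrichment such as secondary-structure bin composition of native versus
#' decoy sites.
#'
#' @param table matrix of non-negative observed counts, at least 2 x 2.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chisq_enrichment <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stopf("contingency table must be at least 2 x 2")
  if (any(table < 0) || anyNA(table)) stopf("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stopf("zero row or column marginal; expected counts undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
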