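#' @include AllGenerics.R
NULL

.checkTwoClass <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  if (!any(labels) || all(labels))
    stop("both classes are required for a ROC analysis")
  labels
}

#' Empirical ROC curve with trapezoidal AUC
#'
#' Higher score = more case-like (direction fixed). Thresholds sweep the
#' distinct observed scores from high to low; tied scores are grouped into a
#' single vertex, so ties contribute diagonal segments and receive exactly
#' half credit. With that convention the trapezoidal area equals the
#' Mann-Whitney pair-counting AUC ([aucMannWhitney()]) identically, which
#' serves as the test oracle.
#'
#' @param scores numeric.
#' @param labels logical, `TRUE` = case.
#' @return a [RocCurve-class].
#' @examples
#' auc(rocCurve(c(3, 4, 5, 0, 1, 2), rep(c(TRUE, FALSE), each = 3)))  # 1
#' @export
rocCurve <- function(scores, labels) {
  labels <- .checkTwoClass(scores, labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores[labels] >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(scores[!labels] >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos))
  a <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  new("RocCurve", points = pts, auc = a,
      nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' Mann-Whitney AUC by direct pair enumeration
#'
#' The probability that a random case outscores a random control, ties at
#' half credit: `(#(case > control) + 0.5 #(case = control)) / (nPos nNeg)`.
#' Computed by brute-force enumeration of all case-control pairs; intended
#' as the independent cross-check for [rocCurve()].
#'
#' @inheritParams rocCurve
#' @return numeric(1) in `[0,1]`.
#' @export
aucMannWhitney <- function(scores, labels) {
  labels <- .checkTwoClass(scores, labels)
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}

#' Export a ROC curve as delimited text plus a JSON summary
#'
#' @param x a [RocCurve-class].
#' @param pointsPath TSV output (`threshold`, `fpr`, `tpr`).
#' @param summaryPath JSON output (`auc`, `n_pos`, `n_neg`).
#' @return invisibly, the written paths.
#' @export
writeRocCurve <- function(x, pointsPath, summaryPath = NULL) {
  stopifnot(is(x, "RocCurve"))
  utils::write.table(x@points, pointsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(summaryPath))
    jsonlite::write_json(list(auc = x@auc, n_pos = x@nPos, n_neg = x@nNeg),
                         summaryPath, auto_unbox = TRUE, digits = NA)
  invisible(c(pointsPath, summaryPath))
}
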