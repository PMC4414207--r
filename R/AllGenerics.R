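#' @include AllClasses.R
NULL

#' Accessors for plasmaLncDx classes
#'
#' Small accessor family: platform tag and sample metadata of a
#' [PlasmaExperiment-class]; panel, thresholds, weights, cutoff and score
#' maximum of a [RiskModel-class]; counts and derived diagnostics of a
#' [ConfusionTable-class]; area under the curve of a [RocCurve-class].
#'
#' @param x an object of the documented class.
#' @return `platformType`: `"array"` or `"qpcr"`. `sampleRecords`: a
#'   data.frame with a `sample_id` column plus the study annotation.
#'   `panelMarkers`, `positivityThresholds`, `riskWeights`, `cutoff`,
#'   `scoreMax`: the corresponding model components. `counts`: named integer
#'   vector `tp`, `fp`, `fn`, `tn`. `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`: proportions in `[0,1]`, `NA` if the denominator is
#'   zero. `auc`: numeric in `[0,1]`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("platformType", function(x) standardGeneric("platformType"))
#' @rdname accessors
#' @export
setGeneric("sampleRecords", function(x) standardGeneric("sampleRecords"))
#' @rdname accessors
#' @export
setGeneric("panelMarkers", function(x) standardGeneric("panelMarkers"))
#' @rdname accessors
#' @export
setGeneric("positivityThresholds",
           function(x) standardGeneric("positivityThresholds"))
#' @rdname accessors
#' @export
setGeneric("riskWeights", function(x) standardGeneric("riskWeights"))
#' @rdname accessors
#' @export
setGeneric("cutoff", function(x) standardGeneric("cutoff"))
#' @rdname accessors
#' @export
setGeneric("scoreMax", function(x) standardGeneric("scoreMax"))
#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname accessors
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
#' @rdname accessors
#' @export
setGeneric("ppv", function(x) standardGeneric("ppv"))
#' @rdname accessors
#' @export
setGeneric("npv", function(x) standardGeneric("npv"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
setMethod("platformType", "PlasmaExperiment",
          function(x) metadata(x)$platform)

#' @rdname accessors
setMethod("sampleRecords", "PlasmaExperiment", function(x) {
  cd <- as.data.frame(colData(x))
  ids <- colnames(x)
  if (is.null(ids)) ids <- character(0)
  data.frame(sample_id = ids, cd, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("panelMarkers", "RiskModel", function(x) x@markers)
#' @rdname accessors
setMethod("positivityThresholds", "RiskModel", function(x) x@thresholds)
#' @rdname accessors
setMethod("riskWeights", "RiskModel", function(x) x@weights)
#' @rdname accessors
setMethod("cutoff", "RiskModel", function(x) x@cutoff)
#' @rdname accessors
setMethod("scoreMax", "RiskModel", function(x) sum(x@weights))
#' @rdname accessors
setMethod("panelMarkers", "StudyReport", function(x) x@panel)

.ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' @rdname accessors
setMethod("counts", "ConfusionTable",
          function(x) c(tp = x@tp, fp = x@fp, fn = x@fn, tn = x@tn))
#' @rdname accessors
setMethod("sensitivity", "ConfusionTable",
          function(x) .ratio(x@tp, x@tp + x@fn))
#' @rdname accessors
setMethod("specificity", "ConfusionTable",
          function(x) .ratio(x@tn, x@tn + x@fp))
#' @rdname accessors
setMethod("ppv", "ConfusionTable", function(x) .ratio(x@tp, x@tp + x@fp))
#' @rdname accessors
setMethod("npv", "ConfusionTable", function(x) .ratio(x@tn, x@tn + x@fn))
#' @rdname accessors
setMethod("accuracy", "ConfusionTable",
          function(x) .ratio(x@tp + x@tn, x@tp + x@fp + x@fn + x@tn))
#' @rdname accessors
setMethod("auc", "RocCurve", function(x) x@auc)

#' Coordinates of a ROC curve
#'
#' @param x a [RocCurve-class].
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocPoints <- function(x) {
  stopifnot(is(x, "RocCurve"))
  x@points
}

setMethod("show", "PlasmaExperiment", function(object) {
  cd <- colData(object)
  cat("PlasmaExperiment (", metadata(object)$platform, "): ",
      nrow(object), " transcripts x ", ncol(object), " samples\n", sep = "")
  if (ncol(object)) {
    tab <- table(group = as.character(cd$group),
                 phase = as.character(cd$phase))
    print(tab)
  }
  invisible(NULL)
})

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel:", length(object@markers), "marker(s), cutoff",
      format(object@cutoff, digits = 4), "of score range [0,",
      format(sum(object@weights), digits = 4), "]\n")
  print(data.frame(marker = object@markers,
                   threshold = unname(object@thresholds),
                   weight = unname(object@weights)))
  invisible(NULL)
})

setMethod("show", "ConfusionTable", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(truth = c("case", "control"),
                              predicted = c("high", "low")))
  print(m)
  cat(sprintf(
    "sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f  accuracy %.3f\n",
    sensitivity(object), specificity(object), ppv(object), npv(object),
    accuracy(object)))
  invisible(NULL)
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: AUC %.4f (%d cases vs %d controls, %d vertices)\n",
              object@auc, object@nPos, object@nNeg, nrow(object@points)))
  invisible(NULL)
})

setMethod("show", "StudyReport", function(object) {
  cat("StudyReport\n  panel:", paste(object@panel, collapse = ", "), "\n")
  sc <- object@stages$screening
  if (!is.null(sc))
    cat(sprintf("  screening funnel: %d deregulated -> %d intersection -> %d candidates\n",
                sc$n_deregulated, sc$n_intersection, sc$n_candidates))
  for (ph in c("training", "validation")) {
    st <- object@stages[[ph]]
    if (is.null(st)) next
    cat(sprintf("  %s: sens %.3f spec %.3f PPV %.3f NPV %.3f AUC %.3f\n",
                ph, sensitivity(st$confusion), specificity(st$confusion),
                ppv(st$confusion), npv(st$confusion), auc(st$roc)))
  }
  db <- object@stages$double_blind
  if (!is.null(db))
    cat(sprintf("  double-blind accuracy: %.3f\n", accuracy(db$confusion)))
  mv <- object@stages$metastasis$validation
  if (!is.null(mv))
    cat(sprintf("  metastasis validation: sens %.3f spec %.3f AUC %.3f\n",
                sensitivity(mv$confusion), specificity(mv$confusion),
                auc(mv$roc)))
  as <- object@stages$postop$association
  if (!is.null(as))
    cat(sprintf("  post-op rise vs metastasis: Fisher p = %.3g\n",
                as$fisher_p))
  invisible(NULL)
})
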