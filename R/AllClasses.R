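#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

.GROUPS     <- c("HCC", "CH", "control")
.TIMEPOINTS <- c("pre_op", "post_op", "none")
.METASTASIS <- c("yes", "no", "unknown")
.PHASES     <- c("screening", "training", "validation", "double_blind")
.PLATFORMS  <- c("array", "qpcr")

#' PlasmaExperiment: plasma expression matrix with study metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' transcripts-by-samples expression matrix together with the per-sample
#' study annotation a multiphase case-control design needs. The single assay
#' (`"exprs"`) stores log2 intensities for the `"array"` platform or strictly
#' positive linear-scale relative levels for the `"qpcr"` platform; the
#' platform tag lives in `metadata(x)$platform`.
#'
#' Required `colData` columns:
#' \describe{
#'   \item{patient_id}{patient identifier linking paired samples}
#'   \item{group}{`"HCC"`, `"CH"` (chronic hepatitis) or `"control"`}
#'   \item{timepoint}{`"pre_op"`, `"post_op"`, or `"none"` for non-patients}
#'   \item{metastasis}{`"yes"`, `"no"`, or `"unknown"`}
#'   \item{phase}{`"screening"`, `"training"`, `"validation"`, `"double_blind"`}
#' }
#'
#' Validity enforces: finite values, unique transcript and sample identifiers,
#' non-patient samples carrying `timepoint = "none"` and
#' `metastasis = "unknown"`, every post-operative sample having a
#' pre-operative mate from the same patient, and positivity of qPCR levels.
#'
#' @seealso [PlasmaExperiment()], [generateCohort()]
#' @export
setClass("PlasmaExperiment", contains = "SummarizedExperiment")

setValidity("PlasmaExperiment", function(object) {
  msg <- character()
  plat <- metadata(object)$platform
  if (is.null(plat) || length(plat) != 1L || !plat %in% .PLATFORMS)
    msg <- c(msg, "metadata(x)$platform must be 'array' or 'qpcr'")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is missing")
  cd <- colData(object)
  need <- c("patient_id", "group", "timepoint", "metastasis", "phase")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample identifiers")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated transcript identifiers")
  bad <- function(x, lv) any(!as.character(x) %in% lv)
  if (bad(cd$group, .GROUPS))          msg <- c(msg, "invalid group value")
  if (bad(cd$timepoint, .TIMEPOINTS))  msg <- c(msg, "invalid timepoint value")
  if (bad(cd$metastasis, .METASTASIS)) msg <- c(msg, "invalid metastasis value")
  if (bad(cd$phase, .PHASES))          msg <- c(msg, "invalid phase value")
  nonpat <- as.character(cd$group) %in% c("CH", "control")
  if (any(nonpat & (cd$timepoint != "none" | cd$metastasis != "unknown")))
    msg <- c(msg,
      "CH/control samples must have timepoint 'none' and metastasis 'unknown'")
  post <- as.character(cd$timepoint) == "post_op"
  if (any(post)) {
    prePat <- cd$patient_id[as.character(cd$timepoint) == "pre_op"]
    orphan <- setdiff(cd$patient_id[post], prePat)
    if (length(orphan))
      msg <- c(msg, paste0("post_op sample(s) without a pre_op mate: ",
                           paste(orphan, collapse = ", ")))
  }
  if (ncol(object) && nrow(object)) {
    v <- assay(object, "exprs")
    if (!all(is.finite(v)))
      msg <- c(msg, "expression values must be finite")
    else if (identical(plat, "qpcr") && any(v <= 0))
      msg <- c(msg, "qPCR relative levels must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PlasmaExperiment
#'
#' @param values numeric matrix, transcripts in rows (rownames = transcript
#'   ids), samples in columns (colnames = sample ids).
#' @param records data.frame of sample metadata with columns `sample_id`,
#'   `patient_id`, `group`, `timepoint`, `metastasis`, `phase`; rows are
#'   matched to the matrix columns by `sample_id`.
#' @param platform `"array"` (log2 intensities) or `"qpcr"` (linear relative
#'   levels).
#' @return A [PlasmaExperiment-class] object.
#' @examples
#' m <- matrix(2^rnorm(12), 3, 4,
#'             dimnames = list(paste0("lnc", 1:3), paste0("s", 1:4)))
#' rec <- data.frame(sample_id = paste0("s", 1:4),
#'                   patient_id = c("p1", "p1", "c1", "c2"),
#'                   group = c("HCC", "HCC", "control", "control"),
#'                   timepoint = c("pre_op", "post_op", "none", "none"),
#'                   metastasis = c("no", "no", "unknown", "unknown"),
#'                   phase = "training")
#' pe <- PlasmaExperiment(m, rec, "qpcr")
#' @export
PlasmaExperiment <- function(values, records,
                             platform = c("qpcr", "array")) {
  platform <- match.arg(platform)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!"sample_id" %in% colnames(records))
    stop("records must contain a 'sample_id' column")
  if (ncol(values)) {
    idx <- match(colnames(values), records$sample_id)
    if (anyNA(idx))
      stop("sample(s) missing from records: ",
           paste(colnames(values)[is.na(idx)], collapse = ", "))
    records <- records[idx, , drop = FALSE]
  }
  cd <- DataFrame(records[setdiff(colnames(records), "sample_id")],
                  row.names = colnames(values))
  se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
  metadata(se)$platform <- platform
  new("PlasmaExperiment", se)
}

#' RiskModel: an indicator-based risk score function
#'
#' The diagnostic model: for each panel marker a positivity threshold derived
#' from the control expression distribution and a non-negative weight. A
#' sample's risk score is the weighted count of markers whose level exceeds
#' their threshold; samples scoring above the global `cutoff` are called
#' high risk. `scoreMax(x)` (the sum of weights) bounds every attainable
#' score, so printed score ranges read `0 -- cutoff` and `cutoff -- scoreMax`.
#'
#' @slot markers character vector of panel transcript ids.
#' @slot thresholds named numeric, per-marker positivity thresholds on the
#'   linear expression scale.
#' @slot weights named numeric, per-marker non-negative score contributions.
#' @slot cutoff numeric(1), global score cutoff in `[0, scoreMax]`.
#' @slot provenance list of fitting metadata (percentile, weight and cutoff
#'   methods, fallbacks, seed).
#' @seealso [fitRiskModel()], [riskScore()], [chooseCutoff()]
#' @export
setClass("RiskModel",
  representation(markers = "character", thresholds = "numeric",
                 weights = "numeric", cutoff = "numeric",
                 provenance = "list"))

setValidity("RiskModel", function(object) {
  msg <- character()
  m <- object@markers
  if (!length(m)) msg <- c(msg, "empty marker panel")
  if (!identical(names(object@thresholds), m) ||
      !identical(names(object@weights), m))
    msg <- c(msg, "thresholds and weights must be named by the panel markers")
  if (any(!is.finite(object@thresholds)))
    msg <- c(msg, "non-finite positivity threshold")
  if (any(object@weights < 0)) msg <- c(msg, "negative weight")
  if (length(object@cutoff) != 1L || is.na(object@cutoff) ||
      object@cutoff < 0 || object@cutoff > sum(object@weights) + 1e-9)
    msg <- c(msg, "cutoff must lie in [0, sum of weights]")
  if (length(msg)) msg else TRUE
})

#' ConfusionTable: 2x2 classification counts with derived diagnostics
#'
#' Counts of true/false positives/negatives plus accessor-computed
#' sensitivity, specificity, positive and negative predictive value and
#' accuracy. A metric whose denominator is zero is reported as `NA` (the
#' counts are retained, so the degenerate case stays inspectable).
#'
#' @slot tp,fp,fn,tn integer counts.
#' @seealso [confusionMetrics()]
#' @export
setClass("ConfusionTable",
  representation(tp = "integer", fp = "integer",
                 fn = "integer", tn = "integer"))

setValidity("ConfusionTable", function(object) {
  n <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(n) != 4L || anyNA(n) || any(n < 0L)) "counts must be non-negative"
  else TRUE
})

#' RocCurve: a receiver operating characteristic curve
#'
#' Vertices of the empirical ROC curve (one per distinct score threshold;
#' tied scores are grouped into a single diagonal segment, i.e. half credit)
#' with the trapezoidal area under the curve. Higher scores are treated as
#' more case-like. The point list always begins at (0,0) and ends at (1,1),
#' and the trapezoidal area equals the Mann-Whitney pair-counting AUC.
#'
#' @slot points data.frame with columns `threshold`, `fpr`, `tpr`.
#' @slot auc numeric(1) in `[0,1]`.
#' @slot nPos,nNeg integer class sizes.
#' @seealso [rocCurve()], [aucMannWhitney()]
#' @export
setClass("RocCurve",
  representation(points = "data.frame", auc = "numeric",
                 nPos = "integer", nNeg = "integer"))

setValidity("RocCurve", function(object) {
  p <- object@points
  msg <- character()
  if (!all(c("threshold", "fpr", "tpr") %in% colnames(p)))
    return("points must have columns threshold, fpr, tpr")
  if (is.unsorted(p$fpr) || is.unsorted(p$tpr))
    msg <- c(msg, "fpr and tpr must be non-decreasing")
  if (abs(p$fpr[1]) > 1e-12 || abs(p$tpr[1]) > 1e-12 ||
      abs(p$fpr[nrow(p)] - 1) > 1e-12 || abs(p$tpr[nrow(p)] - 1) > 1e-12)
    msg <- c(msg, "curve must run from (0,0) to (1,1)")
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    msg <- c(msg, "auc outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' StudyReport: results of a full multiphase study run
#'
#' Container returned by [runStudy()]: the final marker panel, the fitted
#' diagnostic and (when applicable) metastasis [RiskModel-class] objects, and
#' a named list of per-stage results (screening funnel counts, per-phase
#' confusion tables and ROC curves, double-blind accuracy, post-operative
#' dynamics and the secondary-increase/metastasis association).
#'
#' @slot panel character, final diagnostic panel markers.
#' @slot diagnosisModel the frozen diagnostic [RiskModel-class].
#' @slot metastasisModel the metastasis [RiskModel-class], or `NULL`.
#' @slot stages named list of stage results.
#' @slot provenance list: configuration echo, seed, package version.
#' @export
setClass("StudyReport",
  representation(panel = "character", diagnosisModel = "RiskModel",
                 metastasisModel = "ANY", stages = "list",
                 provenance = "list"))
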