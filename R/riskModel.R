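#' @include AllGenerics.R screening.R
NULL

# Accept either a PlasmaExperiment or a plain linear-scale matrix and
# return the marker-by-sample linear level matrix.
.linearLevels <- function(x, markers) {
  v <- if (is(x, "PlasmaExperiment")) {
    m <- assay(x, "exprs")
    if (identical(platformType(x), "array")) 2^m else m
  } else as.matrix(x)
  missing <- setdiff(markers, rownames(v))
  if (length(missing))
    stop("marker(s) absent: ", paste(missing, collapse = ", "))
  v[markers, , drop = FALSE]
}

#' Per-marker positivity thresholds from control samples
#'
#' A marker counts as "positive" in a sample when its level exceeds a
#' threshold placed at an upper percentile of the control expression
#' distribution (default the 95th). Quantiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7); this convention is
#' fixed so thresholds are reproducible across ecosystems.
#'
#' @param controls control-sample expression: a [PlasmaExperiment-class]
#'   already subset to controls, or a markers-by-samples matrix of linear
#'   levels.
#' @param markers character vector of panel transcript ids.
#' @param percentile control percentile in (50, 100).
#' @return named numeric vector of thresholds (linear scale).
#' @examples
#' fitThresholds(matrix(1:100, 1, dimnames = list("m", NULL)), "m")
#' # 95.05: the interpolated 95th percentile of 1..100
#' @export
fitThresholds <- function(controls, markers, percentile = 95) {
  if (length(percentile) != 1 || percentile <= 50 || percentile >= 100)
    stop("configuration error: percentile must lie in (50, 100)")
  v <- .linearLevels(controls, markers)
  if (ncol(v) < 5)
    stop("at least 5 control samples are required")
  thr <- apply(v, 1, stats::quantile, probs = percentile / 100,
               names = FALSE, type = 7)
  names(thr) <- markers
  thr
}

#' Per-marker score weights
#'
#' Weights the positivity indicator of each marker contributes to the risk
#' score. `"logistic"` fits, per marker, a univariate logistic regression of
#' case status on the positivity indicator and uses the coefficient, floored
#' at zero so the score stays monotone in positivity (floored markers are
#' reported in the attribute `floored`); under complete separation (a zero
#' cell in the indicator-by-class table, where the coefficient diverges) the
#' marker falls back to the `"log2fc"` weight with a warning. `"log2fc"`
#' uses the absolute mean log2 fold between classes; `"unit"` gives every
#' marker weight 1, making the score the count of positive markers.
#'
#' @param x training expression (see [fitThresholds()] for accepted forms).
#' @param labels logical per sample, `TRUE` for cases; must contain both
#'   classes.
#' @param thresholds named per-marker positivity thresholds.
#' @param method `"logistic"` (default), `"log2fc"` or `"unit"`.
#' @return named non-negative numeric weights with attributes `floored` and
#'   `fallback` listing affected markers.
#' @export
fitWeights <- function(x, labels, thresholds,
                       method = c("logistic", "log2fc", "unit")) {
  method <- match.arg(method)
  markers <- names(thresholds)
  v <- .linearLevels(x, markers)
  labels <- as.logical(labels)
  if (length(labels) != ncol(v)) stop("labels must match the samples")
  if (!any(labels) || all(labels))
    stop("training data must contain both classes")
  log2fc <- abs(rowMeans(log2(v[, labels, drop = FALSE])) -
                rowMeans(log2(v[, !labels, drop = FALSE])))
  floored <- character(); fallback <- character()
  w <- switch(method,
    unit = rep(1, length(markers)),
    log2fc = unname(log2fc),
    logistic = vapply(seq_along(markers), function(k) {
      ind <- v[k, ] > thresholds[k]
      tab <- table(factor(ind, c(FALSE, TRUE)),
                   factor(labels, c(FALSE, TRUE)))
      if (!any(ind) || all(ind)) {
        # indicator constant: carries no information
        floored <<- c(floored, markers[k])
        return(0)
      }
      if (any(tab == 0)) {
        # (quasi-)separation: the logistic MLE diverges
        warning("complete separation for marker ", markers[k],
                "; falling back to log2fc weight")
        fallback <<- c(fallback, markers[k])
        return(log2fc[k])
      }
      co <- stats::coef(stats::glm(labels ~ ind,
                                   family = stats::binomial()))[["indTRUE"]]
      if (co < 0) {
        floored <<- c(floored, markers[k])
        0
      } else co
    }, numeric(1)))
  names(w) <- markers
  attr(w, "floored") <- floored
  attr(w, "fallback") <- fallback
  w
}

#' Risk score of samples under a model
#'
#' `score = sum over markers of weight * 1[level > threshold]`. Scores are
#' therefore piecewise constant, monotone non-decreasing in every marker's
#' level, and bounded by `[0, scoreMax(model)]`.
#'
#' @param x expression of the scored samples (a [PlasmaExperiment-class] or
#'   a markers-by-samples matrix of linear levels; a named vector is treated
#'   as a single sample). All panel markers must be present.
#' @param model a [RiskModel-class].
#' @return named numeric vector of scores, one per sample.
#' @export
riskScore <- function(x, model) {
  stopifnot(is(model, "RiskModel"))
  if (is.numeric(x) && !is.matrix(x) && !is(x, "PlasmaExperiment")) {
    if (is.null(names(x))) stop("sample level vector must be named")
    x <- matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
  }
  v <- .linearLevels(x, model@markers)
  ind <- v > model@thresholds   # thresholds recycle down rows (markers)
  sc <- as.numeric(crossprod(ind, model@weights))
  names(sc) <- colnames(v)
  sc
}

#' Choose the global score cutoff
#'
#' `"youden"` maximises sensitivity + specificity over the midpoints between
#' adjacent distinct observed scores (classification is `score > cutoff`,
#' so midpoints are the only informative candidates); ties are broken toward
#' the smallest such cutoff. With fewer than two distinct scores the single
#' observed value is returned (every sample low risk). `"midpoint"` ignores
#' the data and returns `scoreMax / 2` — half the attainable score range, an
#' option motivated by published panels whose cutoff is exactly half the
#' weight sum.
#'
#' @param scores numeric sample scores (ignored by `"midpoint"`).
#' @param labels logical, `TRUE` = case; both classes required for
#'   `"youden"`.
#' @param method `"youden"` or `"midpoint"`.
#' @param scoreMax attainable score maximum, required for `"midpoint"`.
#' @return numeric(1) cutoff.
#' @export
chooseCutoff <- function(scores, labels = NULL,
                         method = c("youden", "midpoint"),
                         scoreMax = NULL) {
  method <- match.arg(method)
  if (method == "midpoint") {
    if (is.null(scoreMax)) stop("midpoint method needs scoreMax")
    return(scoreMax / 2)
  }
  labels <- as.logical(labels)
  if (length(labels) != length(scores))
    stop("scores and labels must have equal length")
  if (!any(labels) || all(labels))
    stop("both classes are required to optimise a cutoff")
  s <- sort(unique(scores))
  if (length(s) < 2) return(s)
  cand <- (s[-1] + s[-length(s)]) / 2
  youden <- vapply(cand, function(cut) {
    hi <- scores > cut
    mean(hi[labels]) + mean(!hi[!labels])
  }, numeric(1))
  # ties (within numerical noise) break toward the smallest cutoff
  min(cand[youden >= max(youden) - 1e-9])
}

#' Classify scores against a cutoff
#'
#' A sample is called high risk strictly above the cutoff; a score exactly
#' equal to the cutoff is low risk (published score bins are ambiguous at
#' the shared boundary, so the rule is fixed here and documented).
#'
#' @param scores numeric.
#' @param cutoff numeric(1).
#' @return character vector `"high"`/`"low"`.
#' @export
classifyScores <- function(scores, cutoff) {
  ifelse(scores > cutoff, "high", "low")
}

#' Confusion table of predicted vs true class
#'
#' @param predicted `"high"`/`"low"` calls (or logical, `TRUE` = high).
#' @param truth logical (or `"case"`-like factor), `TRUE` = case.
#' @return a [ConfusionTable-class].
#' @examples
#' ct <- confusionMetrics(rep(c("high", "low"), c(19, 21)),
#'                        rep(c(TRUE, FALSE), c(20, 20)))
#' ppv(ct); npv(ct)
#' @export
confusionMetrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  hi <- if (is.logical(predicted)) predicted else predicted == "high"
  tr <- as.logical(truth)
  if (anyNA(hi) || anyNA(tr)) stop("missing values in predictions or truth")
  new("ConfusionTable",
      tp = sum(hi & tr), fp = sum(hi & !tr),
      fn = sum(!hi & tr), tn = sum(!hi & !tr))
}

#' Fit a complete risk score model on a training phase
#'
#' Convenience wrapper tying the pieces together: positivity thresholds from
#' the control samples of the training phase, weights from the training
#' cases vs controls, scores, and the global cutoff.
#'
#' @param x a qPCR-platform [PlasmaExperiment-class].
#' @param markers panel transcript ids.
#' @param percentile control percentile for [fitThresholds()].
#' @param weightMethod see [fitWeights()].
#' @param cutoffMethod see [chooseCutoff()].
#' @param case,control logical sample selections for the two classes
#'   (defaults: training-phase pre-operative HCC vs training-phase
#'   controls).
#' @return a [RiskModel-class] with fitting provenance.
#' @export
fitRiskModel <- function(x, markers, percentile = 95,
                         weightMethod = c("logistic", "log2fc", "unit"),
                         cutoffMethod = c("youden", "midpoint"),
                         case = NULL, control = NULL) {
  stopifnot(is(x, "PlasmaExperiment"))
  weightMethod <- match.arg(weightMethod)
  cutoffMethod <- match.arg(cutoffMethod)
  if (is.null(case))
    case <- selectSamples(x, group = "HCC", timepoint = "pre_op",
                          phase = "training")
  if (is.null(control))
    control <- selectSamples(x, group = "control", phase = "training")
  if (!any(case) || !any(control))
    stop("phase error: training phase must contain both classes")
  thr <- fitThresholds(x[, control, drop = FALSE], markers, percentile)
  both <- case | control
  labels <- case[both]
  w <- fitWeights(x[, both, drop = FALSE], labels, thr,
                  method = weightMethod)
  scores <- riskScore(x[, both, drop = FALSE],
                      new("RiskModel", markers = markers, thresholds = thr,
                          weights = as.numeric(w) |>
                            stats::setNames(markers),
                          cutoff = 0, provenance = list()))
  cut <- chooseCutoff(scores, labels, method = cutoffMethod,
                      scoreMax = sum(w))
  new("RiskModel", markers = markers, thresholds = thr,
      weights = stats::setNames(as.numeric(w), markers), cutoff = cut,
      provenance = list(percentile = percentile,
                        weight_method = weightMethod,
                        cutoff_method = cutoffMethod,
                        floored = attr(w, "floored"),
                        fallback = attr(w, "fallback"),
                        n_case = sum(case), n_control = sum(control)))
}

#' Serialise / restore a RiskModel as JSON
#'
#' @param model a [RiskModel-class].
#' @param path file path.
#' @return `writeRiskModel` the path, invisibly; `readRiskModel` the model.
#' @export
writeRiskModel <- function(model, path) {
  stopifnot(is(model, "RiskModel"))
  obj <- list(markers = model@markers,
              thresholds = as.list(model@thresholds),
              weights = as.list(model@weights),
              cutoff = model@cutoff,
              provenance = model@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeRiskModel
#' @export
readRiskModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  markers <- as.character(obj$markers)
  new("RiskModel", markers = markers,
      thresholds = stats::setNames(as.numeric(obj$thresholds[markers]),
                                   markers),
      weights = stats::setNames(as.numeric(obj$weights[markers]), markers),
      cutoff = as.numeric(obj$cutoff),
      provenance = as.list(obj$provenance))
}
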