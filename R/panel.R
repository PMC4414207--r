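#' @include screening.R
NULL

#' Training-set qPCR panel filter
#'
#' Reduces the screened candidate list to the final marker panel using the
#' training phase: per candidate, a two-sample Student t test of
#' pre-operative case vs control samples on log2-transformed relative
#' levels, and a mean fold change computed (by default) as the ratio of
#' geometric means, i.e. `2^(difference of log2 means)`. A candidate is
#' retained iff `mean_fold > foldThreshold` and `p_value < pThreshold`.
#'
#' @param x a qPCR-platform [PlasmaExperiment-class].
#' @param candidates character vector of candidate transcript ids.
#' @param foldThreshold minimum (exclusive) case/control mean fold.
#' @param pThreshold maximum (exclusive) p value.
#' @param foldType `"geometric"` (default, matches log-scale analysis) or
#'   `"arithmetic"` (ratio of linear-scale means).
#' @param phase study phase supplying the samples (default `"training"`).
#' @return data.frame with one row per candidate: `transcript_id`,
#'   `mean_fold`, `p_value`, `retained`.
#' @export
trainingFilter <- function(x, candidates, foldThreshold = 2,
                           pThreshold = 0.05,
                           foldType = c("geometric", "arithmetic"),
                           phase = "training") {
  stopifnot(is(x, "PlasmaExperiment"))
  foldType <- match.arg(foldType)
  if (!identical(platformType(x), "qpcr"))
    stop("trainingFilter expects qPCR-platform data")
  missing <- setdiff(candidates, rownames(x))
  if (length(missing))
    stop("candidate(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  case <- selectSamples(x, group = "HCC", timepoint = "pre_op",
                        phase = phase)
  ctrl <- selectSamples(x, group = "control", phase = phase)
  if (!any(case) || !any(ctrl))
    stop("phase error: no ", phase, "-phase case/control samples")
  sub <- x[candidates, , drop = FALSE]
  res <- differentialTest(sub, case, ctrl, paired = FALSE)
  fold <- if (foldType == "geometric") {
    2^res$log2_fold
  } else {
    lin <- assay(sub, "exprs")
    rowMeans(lin[, case, drop = FALSE]) /
      rowMeans(lin[, ctrl, drop = FALSE])
  }
  data.frame(transcript_id = res$transcript_id, mean_fold = fold,
             p_value = res$p_value,
             retained = fold > foldThreshold & res$p_value < pThreshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
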