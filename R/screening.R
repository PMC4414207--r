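#' @include AllClasses.R
NULL

#' Select samples of a PlasmaExperiment by metadata
#'
#' @param x a [PlasmaExperiment-class].
#' @param ... metadata filters, e.g. `group = "HCC"`, `timepoint = "pre_op"`,
#'   `phase = c("training", "validation")`. A filter matches when the
#'   sample's value is among those given; filters combine with AND.
#' @return logical vector over the samples (columns) of `x`.
#' @export
selectSamples <- function(x, ...) {
  stopifnot(is(x, "PlasmaExperiment"))
  crit <- list(...)
  keep <- rep(TRUE, ncol(x))
  cd <- colData(x)
  for (nm in names(crit)) {
    if (!nm %in% colnames(cd)) stop("unknown metadata column: ", nm)
    keep <- keep & as.character(cd[[nm]]) %in% as.character(crit[[nm]])
  }
  keep
}

# Expression on the log2 scale regardless of platform.
.log2Values <- function(x) {
  v <- assay(x, "exprs")
  if (identical(platformType(x), "qpcr")) log2(v) else v
}

# Vectorised one-sample t on the rows of a matrix of differences.
.pairedT <- function(d) {
  n <- ncol(d)
  m <- rowMeans(d)
  s2 <- rowSums((d - m)^2) / (n - 1)
  se <- sqrt(s2 / n)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(m / se), df = n - 1),
              ifelse(abs(m) > 0, 0, 1))
  list(mean = m, p = p)
}

# Vectorised two-sample t (Student or Welch) on rows.
.twoSampleT <- function(a, b, varEqual = TRUE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (varEqual) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    df[!is.finite(df)] <- na + nb - 2
  }
  diff <- ma - mb
  p <- ifelse(se > 0, 2 * stats::pt(-abs(diff / se), df = df),
              ifelse(abs(diff) > 0, 0, 1))
  list(meanA = ma, meanB = mb, diff = diff, p = p)
}

#' Per-transcript differential expression test
#'
#' Compares two sample selections transcript by transcript on the log2
#' scale: an unpaired two-sample Student t test (Welch optional) or, for
#' pre/post-operative designs, a paired t test on per-patient log2
#' differences with pairs matched by `patient_id`. Fold change is
#' `2^|difference of log2 means|`, so it is the ratio of geometric means on
#' the linear scale.
#'
#' @param x a [PlasmaExperiment-class].
#' @param groupA,groupB logical sample selections (see [selectSamples()]);
#'   group A is conventionally the case / pre-operative group.
#' @param paired match samples one-to-one by patient id and test the paired
#'   differences.
#' @param varEqual pooled-variance Student t (default) or Welch when `FALSE`.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `mean_a`, `mean_b` (log2 means), `log2_fold` (`mean_a - mean_b`),
#'   `fold` (`2^|log2_fold|`, so always >= 1), `direction`
#'   (`"up"`/`"down"`/`"none"` from the sign of `log2_fold`), `p_value`,
#'   `paired`.
#' @export
differentialTest <- function(x, groupA, groupB, paired = FALSE,
                             varEqual = TRUE) {
  stopifnot(is(x, "PlasmaExperiment"))
  v <- .log2Values(x)
  a <- v[, groupA, drop = FALSE]
  b <- v[, groupB, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("insufficient replication: each group needs at least 2 samples")
  if (paired) {
    pidA <- colData(x)$patient_id[groupA]
    pidB <- colData(x)$patient_id[groupB]
    orphans <- c(setdiff(pidA, pidB), setdiff(pidB, pidA))
    if (length(orphans) || anyDuplicated(pidA) || anyDuplicated(pidB))
      stop("pairing error: unmatched or duplicated patients: ",
           paste(unique(c(orphans, pidA[duplicated(pidA)],
                          pidB[duplicated(pidB)])), collapse = ", "))
    b <- b[, match(pidA, pidB), drop = FALSE]
    tt <- .pairedT(a - b)
    res <- data.frame(transcript_id = rownames(v),
                      mean_a = rowMeans(a), mean_b = rowMeans(b),
                      log2_fold = tt$mean, p_value = tt$p,
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    tt <- .twoSampleT(a, b, varEqual = varEqual)
    res <- data.frame(transcript_id = rownames(v),
                      mean_a = tt$meanA, mean_b = tt$meanB,
                      log2_fold = tt$diff, p_value = tt$p,
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  res$fold <- 2^abs(res$log2_fold)
  res$direction <- ifelse(res$log2_fold > 0, "up",
                          ifelse(res$log2_fold < 0, "down", "none"))
  res$paired <- rep(paired, nrow(res))
  res[, c("transcript_id", "mean_a", "mean_b", "log2_fold", "fold",
          "direction", "p_value", "paired")]
}

#' Screening filter thresholds
#'
#' @param pThreshold p-value ceiling for calling a transcript deregulated.
#' @param minFold minimum linear fold change.
#' @param minSignal minimum case-group mean log2 intensity ("high signal").
#' @return classed list used by [selectDeregulated()] and
#'   [filterCandidates()].
#' @export
filterSpec <- function(pThreshold = 0.05, minFold = 2, minSignal = 5) {
  if (pThreshold <= 0 || pThreshold > 1)
    stop("pThreshold must lie in (0, 1]")
  if (minFold <= 0) stop("minFold must be positive")
  structure(list(pThreshold = pThreshold, minFold = minFold,
                 minSignal = minSignal), class = "FilterSpec")
}

#' Split differential results into up- and down-regulated sets
#'
#' @param results a [differentialTest()] table.
#' @param spec a [filterSpec()] (only `pThreshold` is used here).
#' @return list with character vectors `up` and `down` (disjoint).
#' @export
selectDeregulated <- function(results, spec = filterSpec()) {
  if (!nrow(results)) stop("empty differential results")
  sig <- results$p_value <= spec$pThreshold
  list(up = results$transcript_id[sig & results$direction == "up"],
       down = results$transcript_id[sig & results$direction == "down"])
}

#' Intersect candidate transcript sets
#'
#' The screening funnel's merge step: transcripts elevated in case plasma
#' that also fall after tumour resection.
#'
#' @param upInCase,downPostOp character vectors of transcript ids.
#' @return sorted character vector, the exact set intersection.
#' @export
intersectCandidates <- function(upInCase, downPostOp) {
  sort(intersect(unique(upInCase), unique(downPostOp)))
}

#' Intensity / fold candidate filter
#'
#' Retains candidates whose case-group mean log2 intensity (`mean_a`) is at
#' least `minSignal` and whose fold change is at least `minFold` in *every*
#' supplied comparison.
#'
#' @param candidates character vector of transcript ids.
#' @param comparisons named list of [differentialTest()] tables.
#' @param spec a [filterSpec()].
#' @return sorted character vector of surviving candidates.
#' @export
filterCandidates <- function(candidates, comparisons, spec = filterSpec()) {
  if (!is.list(comparisons) || !length(comparisons))
    stop("comparisons must be a non-empty list of differential tables")
  keep <- rep(TRUE, length(candidates))
  for (nm in seq_along(comparisons)) {
    res <- comparisons[[nm]]
    idx <- match(candidates, res$transcript_id)
    if (anyNA(idx))
      stop("candidate(s) missing from comparison ",
           if (!is.null(names(comparisons))) names(comparisons)[nm] else nm,
           ": ", paste(candidates[is.na(idx)], collapse = ", "))
    keep <- keep & res$mean_a[idx] >= spec$minSignal &
      res$fold[idx] >= spec$minFold
  }
  sort(candidates[keep])
}

#' Volcano coordinates for a differential table
#'
#' @param results a [differentialTest()] table.
#' @param cap ceiling for `-log10(p)` when p underflows to zero.
#' @return data.frame `transcript_id`, `log2_fold`, `neg_log10_p`.
#' @export
volcanoTable <- function(results, cap = 300) {
  data.frame(transcript_id = results$transcript_id,
             log2_fold = results$log2_fold,
             neg_log10_p = pmin(-log10(pmax(results$p_value, 10^-cap)), cap),
             stringsAsFactors = FALSE)
}

#' Hierarchical ordering of transcripts for report output
#'
#' Average-linkage clustering on Euclidean distance between standardised
#' rows; a tabular stand-in for the usual clustered heatmap.
#'
#' @param x a [PlasmaExperiment-class] (typically subset to candidates).
#' @return character vector of transcript ids in dendrogram order.
#' @export
clusterOrder <- function(x) {
  v <- .log2Values(x)
  if (nrow(v) < 3) return(rownames(v))
  s <- (v - rowMeans(v)) / pmax(apply(v, 1, stats::sd), .Machine$double.eps)
  hc <- stats::hclust(stats::dist(s), method = "average")
  rownames(v)[hc$order]
}
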