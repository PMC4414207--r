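#' @include AllClasses.R
NULL

# Evaluate expr with a locally seeded RNG, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Default multiphase group sizes
#'
#' The study design the generator replicates by default: a small paired
#' screening set (3 HCC patients, each sampled pre- and post-operation, plus
#' 3 controls), a 20 vs 20 training set, a 147 vs 180 validation set and a
#' 50 vs 50 double-blind set. Every HCC patient outside screening is also
#' sampled post-operatively, so paired dynamics are available study-wide.
#'
#' @return data.frame with columns `group`, `phase`, `n` (patients).
#' @export
defaultGroupSizes <- function() {
  data.frame(
    group = c("HCC", "control", "HCC", "control", "HCC", "control",
              "HCC", "control"),
    phase = c("screening", "screening", "training", "training",
              "validation", "validation", "double_blind", "double_blind"),
    n = c(3L, 3L, 20L, 20L, 147L, 180L, 50L, 50L),
    stringsAsFactors = FALSE)
}

#' Configure a synthetic plasma cohort
#'
#' Describes the statistical structure of a simulated circulating-lncRNA
#' study. Expression is generated on the log2 scale: every transcript gets a
#' background mean drawn from `N(baselineMean, baselineSd^2)`, each
#' measurement adds `N(0, noiseSd^2)` noise, and the first `nMarkers`
#' transcripts are "true biomarkers" carrying the configured mean offsets:
#' `caseEffect` log2 units up in pre-operative HCC plasma, `resectionEffect`
#' down again after tumour resection, and `metastasisEffect` further up in
#' metastatic patients for the metastasis-linked subset (by default the last
#' `ceiling(nMarkers * 2/3)` markers, mirroring a 3-marker panel of which 2
#' track metastasis). A fraction `secondaryRiseFraction` of metastatic
#' patients instead *rise* by `riseEffect` log2 units post-operatively
#' (`nonMetRiseFraction` allows the same leak among non-metastatic patients).
#'
#' @param nTranscripts total transcripts simulated.
#' @param nMarkers planted true biomarkers (first `nMarkers` transcripts).
#' @param groupSizes data.frame (`group`, `phase`, `n`) of patient counts per
#'   study cell; see [defaultGroupSizes()].
#' @param caseEffect log2 fold elevation of markers in pre-op HCC vs control.
#' @param resectionEffect log2 fold reduction post-op vs pre-op.
#' @param metastasisEffect extra log2 elevation of the metastasis-linked
#'   marker subset in metastatic patients.
#' @param secondaryRiseFraction fraction of metastatic patients whose
#'   post-op marker levels rise above pre-op.
#' @param nonMetRiseFraction same leak among non-metastatic patients.
#' @param riseEffect log2 magnitude of the secondary rise.
#' @param metFraction fraction of HCC patients (per phase cell, rounded to a
#'   fixed count as in a designed case-control split) that are metastatic.
#' @param noiseSd log2-scale measurement noise standard deviation.
#' @param baselineMean,baselineSd log2-scale background distribution.
#' @param seed integer RNG seed; generation is a pure function of the
#'   configuration.
#' @return A `CohortConfig` (validated list).
#' @examples
#' cfg <- cohortConfig(nTranscripts = 50, seed = 1)
#' pe <- generateCohort(cfg)
#' @export
cohortConfig <- function(nTranscripts = 2000L, nMarkers = 3L,
                         groupSizes = defaultGroupSizes(),
                         caseEffect = 2, resectionEffect = 2,
                         metastasisEffect = 1.5,
                         secondaryRiseFraction = 0.8,
                         nonMetRiseFraction = 0, riseEffect = 1,
                         metFraction = 0.5, noiseSd = 0.5,
                         baselineMean = 6, baselineSd = 1.5, seed = 1L) {
  cfg <- list(nTranscripts = as.integer(nTranscripts),
              nMarkers = as.integer(nMarkers), groupSizes = groupSizes,
              caseEffect = caseEffect, resectionEffect = resectionEffect,
              metastasisEffect = metastasisEffect,
              secondaryRiseFraction = secondaryRiseFraction,
              nonMetRiseFraction = nonMetRiseFraction,
              riseEffect = riseEffect, metFraction = metFraction,
              noiseSd = noiseSd, baselineMean = baselineMean,
              baselineSd = baselineSd, seed = as.integer(seed))
  counts <- c(cfg$nTranscripts, cfg$nMarkers)
  fracs <- c(cfg$secondaryRiseFraction, cfg$nonMetRiseFraction,
             cfg$metFraction)
  if (anyNA(counts) || any(counts < 0))
    stop("transcript and marker counts must be non-negative")
  if (cfg$nMarkers > cfg$nTranscripts)
    stop("nMarkers cannot exceed nTranscripts")
  if (any(fracs < 0) || any(fracs > 1))
    stop("fractions must lie in [0, 1]")
  if (cfg$noiseSd < 0 || cfg$baselineSd < 0)
    stop("standard deviations must be non-negative")
  if (!all(c("group", "phase", "n") %in% colnames(groupSizes)))
    stop("groupSizes needs columns group, phase, n")
  if (any(!groupSizes$group %in% .GROUPS) ||
      any(!groupSizes$phase %in% .PHASES))
    stop("groupSizes contains an unknown group or phase")
  if (any(groupSizes$n < 0)) stop("group sizes must be non-negative")
  if (is.na(cfg$seed)) stop("seed is mandatory")
  structure(cfg, class = "CohortConfig")
}

#' Transcript ids and planted-marker bookkeeping for a configuration
#'
#' The first `nMarkers` transcripts are the planted biomarkers; the
#' metastasis-linked subset is the last `ceiling(nMarkers * 2/3)` of them.
#'
#' @param config a [cohortConfig()].
#' @return list with `transcripts`, `markers`, `metMarkers` character
#'   vectors.
#' @export
plantedMarkers <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  ids <- sprintf("lnc%04d", seq_len(config$nTranscripts))
  markers <- ids[seq_len(config$nMarkers)]
  nMet <- ceiling(config$nMarkers * 2 / 3)
  metMarkers <- if (nMet > 0) markers[seq.int(config$nMarkers - nMet + 1,
                                              config$nMarkers)]
                else character()
  list(transcripts = ids, markers = markers, metMarkers = metMarkers)
}

# Build the per-sample metadata for the phases covered by a platform.
.buildRecords <- function(config, phases) {
  gs <- config$groupSizes
  gs <- gs[gs$phase %in% phases & gs$n > 0, , drop = FALSE]
  recs <- list()
  pid <- 0L
  for (i in seq_len(nrow(gs))) {
    g <- gs$group[i]; ph <- gs$phase[i]; n <- gs$n[i]
    ids <- sprintf("%s_%s_%03d", substr(ph, 1, 4), tolower(g), seq_len(n))
    pid <- pid + n
    if (g == "HCC") {
      # screening patients emulate the discovery set of fully resected
      # tumours: metastasis status unknown, no secondary rise
      if (ph == "screening") {
        met <- rep("unknown", n)
      } else {
        nMet <- round(config$metFraction * n)
        met <- rep("no", n)
        if (nMet > 0) met[sample.int(n, nMet)] <- "yes"
      }
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = c(paste0(ids, "_pre"), paste0(ids, "_post")),
        patient_id = rep(ids, 2L), group = "HCC",
        timepoint = rep(c("pre_op", "post_op"), each = n),
        metastasis = rep(met, 2L), phase = ph, stringsAsFactors = FALSE)
    } else {
      recs[[length(recs) + 1L]] <- data.frame(
        sample_id = ids, patient_id = ids, group = g, timepoint = "none",
        metastasis = "unknown", phase = ph, stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(sample_id = character(), patient_id = character(),
                      group = character(), timepoint = character(),
                      metastasis = character(), phase = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Generate a synthetic plasma cohort
#'
#' Draws a [PlasmaExperiment-class] from a [cohortConfig()]. The `"array"`
#' platform covers the screening phase and emits log2 intensities; the
#' `"qpcr"` platform covers every other configured phase and emits linear
#' relative levels (`2^log2`). Generation is deterministic given the
#' configuration seed (the two platforms use disjoint seed streams), and the
#' caller's RNG state is left untouched.
#'
#' Mean structure on the log2 scale, relative to a per-transcript baseline:
#' planted markers gain `caseEffect` in pre-operative HCC samples (plus
#' `metastasisEffect` for the metastasis-linked subset in metastatic
#' patients); post-operative samples of "resolving" patients drop by
#' `resectionEffect` from their pre-op mean, while "secondary-rise" patients
#' (a `secondaryRiseFraction` of the metastatic, `nonMetRiseFraction` of the
#' rest) gain `riseEffect` instead. Chronic-hepatitis and control samples
#' sit at baseline for every transcript.
#'
#' @param config a [cohortConfig()].
#' @param platform `"qpcr"` (default) or `"array"`.
#' @return A [PlasmaExperiment-class].
#' @export
generateCohort <- function(config, platform = c("qpcr", "array")) {
  stopifnot(inherits(config, "CohortConfig"))
  platform <- match.arg(platform)
  ids <- plantedMarkers(config)
  phases <- if (platform == "array") "screening" else setdiff(.PHASES,
                                                              "screening")
  # distinct substreams so the two platforms are independent draws
  streamSeed <- config$seed + if (platform == "array") 1000003L else 0L
  withSeed(streamSeed, {
    records <- .buildRecords(config, phases)
    n <- nrow(records)
    baseline <- stats::rnorm(config$nTranscripts, config$baselineMean,
                             config$baselineSd)
    mu <- matrix(rep(baseline, times = n), config$nTranscripts, n)
    dimnames(mu) <- list(ids$transcripts, records$sample_id)
    if (n) {
      hccPat <- unique(records$patient_id[records$group == "HCC"])
      metPat <- unique(records$patient_id[records$metastasis == "yes"])
      unknownPat <- unique(records$patient_id[records$metastasis ==
                                                "unknown"])
      riser <- vapply(hccPat, function(p) {
        fr <- if (p %in% unknownPat) 0
              else if (p %in% metPat) config$secondaryRiseFraction
              else config$nonMetRiseFraction
        stats::runif(1) < fr
      }, logical(1))
      names(riser) <- hccPat
      isPre <- records$group == "HCC" & records$timepoint == "pre_op"
      isPost <- records$group == "HCC" & records$timepoint == "post_op"
      mk <- ids$markers
      mu[mk, isPre | isPost] <- mu[mk, isPre | isPost] + config$caseEffect
      isMet <- records$metastasis == "yes"
      if (length(ids$metMarkers) && any(isMet))
        mu[ids$metMarkers, isMet] <- mu[ids$metMarkers, isMet] +
          config$metastasisEffect
      if (any(isPost)) {
        postRise <- riser[records$patient_id[isPost]]
        shift <- ifelse(postRise, config$riseEffect, -config$resectionEffect)
        mu[mk, isPost] <- sweep(mu[mk, isPost, drop = FALSE], 2, shift, "+")
      }
      vals <- mu + matrix(stats::rnorm(length(mu), 0, config$noiseSd),
                          nrow(mu), ncol(mu))
    } else {
      vals <- mu
    }
    if (platform == "qpcr") vals <- 2^vals
    PlasmaExperiment(vals, records, platform)
  })
}

#' Write / read a cohort as delimited text
#'
#' The expression matrix is written with transcript ids in the first column
#' (`transcript_id`) and one column per sample; the metadata table has
#' columns `sample_id`, `patient_id`, `group`, `timepoint`, `metastasis`,
#' `phase`. Tab- or comma-separation is inferred from the file extension
#' (`.tsv`/`.txt` vs `.csv`). The pair round-trips losslessly through
#' [readCohort()].
#'
#' @param x a [PlasmaExperiment-class].
#' @param matrixPath,metadataPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeCohort <- function(x, matrixPath, metadataPath) {
  stopifnot(is(x, "PlasmaExperiment"))
  sepFor <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) ","
                        else "\t"
  m <- assay(x, "exprs")
  df <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  tryCatch({
    utils::write.table(df, matrixPath, sep = sepFor(matrixPath),
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sampleRecords(x), metadataPath,
                       sep = sepFor(metadataPath), quote = FALSE,
                       row.names = FALSE)
  }, error = function(e) stop("failed to write cohort files: ",
                              conditionMessage(e)))
  invisible(c(matrixPath, metadataPath))
}

#' @rdname writeCohort
#' @param platform platform tag to attach on reading.
#' @export
readCohort <- function(matrixPath, metadataPath,
                       platform = c("qpcr", "array")) {
  platform <- match.arg(platform)
  PlasmaExperiment(readExpressionMatrix(matrixPath),
                   readSampleMetadata(metadataPath), platform)
}
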