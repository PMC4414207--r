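#' @include cohort.R panel.R riskModel.R roc.R postop.R
NULL

.readDelim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (!ncol(df)) stop("empty input file: ", path)
  df
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row, transcript ids in the first column and one numeric
#' column per sample. Duplicated transcript or sample ids and non-numeric
#' values are rejected with the offending rows named.
#'
#' @param path CSV or TSV file.
#' @return numeric matrix, transcripts x samples.
#' @export
readExpressionMatrix <- function(path) {
  df <- .readDelim(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated transcript id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1]))
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(colnames(df)[-1][duplicated(colnames(df)[-1])]),
               collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)
    stop("non-numeric or missing value(s) in ", path, " at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  rownames(m) <- ids
  m
}

#' Read sample metadata from delimited text
#'
#' Requires columns `sample_id`, `patient_id`, `group`, `timepoint`,
#' `metastasis`, `phase` (extra columns are preserved); validates category
#' levels, duplicate sample ids, and that every post-operative sample has
#' its pre-operative mate.
#'
#' @param path CSV or TSV file.
#' @return data.frame of sample records.
#' @export
readSampleMetadata <- function(path) {
  df <- .readDelim(path)
  need <- c("sample_id", "patient_id", "group", "timepoint", "metastasis",
            "phase")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  checkLv <- function(col, lv) {
    bad <- which(!df[[col]] %in% lv)
    if (length(bad))
      stop("invalid ", col, " value(s) in ", path, " at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  checkLv("group", .GROUPS); checkLv("timepoint", .TIMEPOINTS)
  checkLv("metastasis", .METASTASIS); checkLv("phase", .PHASES)
  post <- df$timepoint == "post_op"
  orphan <- setdiff(df$patient_id[post],
                    df$patient_id[df$timepoint == "pre_op"])
  if (length(orphan))
    stop("post_op sample(s) without a pre_op mate in ", path, ": ",
         paste(orphan, collapse = ", "))
  df
}

#' Configure a multiphase study run
#'
#' Exactly one input route: simulated (a [cohortConfig()]) or files
#' (qPCR matrix + metadata, optional array matrix + metadata for the
#' screening stage). The remaining fields tune the analysis stages.
#'
#' @param cohort a [cohortConfig()] for simulation, or `NULL`.
#' @param qpcrMatrix,qpcrMetadata,arrayMatrix,arrayMetadata input file
#'   paths (file route).
#' @param screen a [filterSpec()] for the screening funnel.
#' @param candidates transcript ids entering the training filter; `NULL`
#'   derives them from the screening stage (or uses all transcripts when no
#'   array data is supplied).
#' @param applyTrainingFilter set `FALSE` to take `candidates` as the panel
#'   directly (e.g. for null calibration of the score itself).
#' @param foldThreshold,pThreshold training-filter thresholds.
#' @param percentile,weightMethod,cutoffMethod risk-model options (see
#'   [fitRiskModel()]).
#' @param metTrain,metValid metastasis-stage design: `c(cases, controls)`
#'   patient counts for the metastasis training and validation splits.
#' @param minMarkers patient-level secondary-rise flag threshold (see
#'   [metastasisAssociation()]).
#' @param riseMargin see [pairedChanges()].
#' @param seed integer seed for the run's own randomness (metastasis-split
#'   sampling; also the cohort seed fallback).
#' @return classed list (`StudyConfig`).
#' @export
studyConfig <- function(cohort = NULL, qpcrMatrix = NULL,
                        qpcrMetadata = NULL, arrayMatrix = NULL,
                        arrayMetadata = NULL, screen = filterSpec(),
                        candidates = NULL, applyTrainingFilter = TRUE,
                        foldThreshold = 2, pThreshold = 0.05,
                        percentile = 95, weightMethod = "logistic",
                        cutoffMethod = "youden",
                        metTrain = c(20L, 20L), metValid = c(79L, 78L),
                        minMarkers = 2, riseMargin = 0, seed = 1L) {
  simulated <- !is.null(cohort)
  files <- !is.null(qpcrMatrix)
  if (simulated == files)
    stop("exactly one of a cohort configuration or input files is required")
  if (files && is.null(qpcrMetadata))
    stop("qpcrMetadata is required with qpcrMatrix")
  structure(list(cohort = cohort, qpcrMatrix = qpcrMatrix,
                 qpcrMetadata = qpcrMetadata, arrayMatrix = arrayMatrix,
                 arrayMetadata = arrayMetadata, screen = screen,
                 candidates = candidates,
                 applyTrainingFilter = applyTrainingFilter,
                 foldThreshold = foldThreshold, pThreshold = pThreshold,
                 percentile = percentile, weightMethod = weightMethod,
                 cutoffMethod = cutoffMethod, metTrain = metTrain,
                 metValid = metValid, minMarkers = minMarkers,
                 riseMargin = riseMargin, seed = as.integer(seed)),
            class = "StudyConfig")
}

.requirePhase <- function(x, group, phase) {
  if (!any(selectSamples(x, group = group, phase = phase)))
    stop("configuration error: no samples for (", group, ", ", phase, ")")
}

#' Evaluate a frozen risk model on new samples
#'
#' Applies a fitted [RiskModel-class] without any refitting: thresholds,
#' weights and the global cutoff all stay as trained. Refusing to refit is
#' the point — validation and double-blind estimates are only honest for a
#' frozen model.
#'
#' @param model a fitted [RiskModel-class].
#' @param x a [PlasmaExperiment-class] holding the evaluation samples.
#' @param truth logical per evaluated sample, `TRUE` = case.
#' @param samples logical selection of the columns of `x` to evaluate
#'   (default: all).
#' @param refit must remain `FALSE`; `TRUE` is refused.
#' @return list: `confusion` ([ConfusionTable-class]), `roc`
#'   ([RocCurve-class]), `scores` (named numeric), `predicted`.
#' @export
evaluateFrozen <- function(model, x, truth, samples = NULL, refit = FALSE) {
  if (isTRUE(refit))
    stop("refusing to refit: evaluation requires a frozen model")
  stopifnot(is(model, "RiskModel"), is(x, "PlasmaExperiment"))
  if (is.null(samples)) samples <- rep(TRUE, ncol(x))
  sub <- x[, samples, drop = FALSE]
  truth <- as.logical(truth)
  if (length(truth) != ncol(sub))
    stop("truth must match the evaluated samples")
  scores <- riskScore(sub, model)
  predicted <- classifyScores(scores, cutoff(model))
  list(confusion = confusionMetrics(predicted, truth),
       roc = rocCurve(scores, truth), scores = scores,
       predicted = predicted)
}

# Draw the metastasis training/validation patient splits (pre-op samples).
.metSplits <- function(records, metTrain, metValid) {
  hcc <- records[records$group == "HCC" & records$timepoint == "pre_op" &
                   records$phase != "screening" &
                   records$metastasis %in% c("yes", "no"), ]
  met <- hcc$patient_id[hcc$metastasis == "yes"]
  non <- hcc$patient_id[hcc$metastasis == "no"]
  nTr <- c(min(metTrain[1], length(met)), min(metTrain[2], length(non)))
  trainPat <- c(sample(met, nTr[1]), sample(non, nTr[2]))
  metLeft <- setdiff(met, trainPat); nonLeft <- setdiff(non, trainPat)
  validPat <- c(sample(metLeft, min(metValid[1], length(metLeft))),
                sample(nonLeft, min(metValid[2], length(nonLeft))))
  list(train = trainPat, valid = validPat)
}

#' Run the full multiphase study
#'
#' Executes the study end to end: microarray screening (when array data is
#' present) reduces the transcriptome to candidates via the
#' up-in-case/down-post-operation intersection and the intensity/fold
#' filter; the qPCR training filter reduces candidates to the final panel;
#' a risk score model is fitted on the training phase and then applied
#' *frozen* to the validation and double-blind phases; a second risk model
#' for metastasis is trained on a metastatic/non-metastatic patient split
#' (markers: panel members differentially expressed by metastasis status)
#' and validated on the held-out split; finally paired pre/post-operative
#' dynamics are computed and secondary rises are tested for association
#' with metastasis. The run is a pure function of (inputs, configuration,
#' seed).
#'
#' @param config a [studyConfig()].
#' @return a [StudyReport-class].
#' @export
runStudy <- function(config) {
  stopifnot(inherits(config, "StudyConfig"))
  if (!is.null(config$cohort)) {
    qpcr <- generateCohort(config$cohort, platform = "qpcr")
    gs <- config$cohort$groupSizes
    hasScreen <- any(gs$phase == "screening" & gs$n > 0)
    array <- if (hasScreen) generateCohort(config$cohort,
                                           platform = "array") else NULL
  } else {
    qpcr <- readCohort(config$qpcrMatrix, config$qpcrMetadata, "qpcr")
    array <- if (!is.null(config$arrayMatrix))
      readCohort(config$arrayMatrix, config$arrayMetadata, "array")
      else NULL
  }
  .requirePhase(qpcr, "HCC", "training")
  .requirePhase(qpcr, "control", "training")
  stages <- list()

  # --- screening funnel (array data) ---
  candidates <- config$candidates
  if (!is.null(array)) {
    caseSel <- selectSamples(array, group = "HCC", timepoint = "pre_op",
                             phase = "screening")
    ctrlSel <- selectSamples(array, group = "control", phase = "screening")
    postSel <- selectSamples(array, group = "HCC", timepoint = "post_op",
                             phase = "screening")
    diffCase <- differentialTest(array, caseSel, ctrlSel, paired = FALSE)
    diffPost <- differentialTest(array, caseSel, postSel, paired = TRUE)
    upCase <- selectDeregulated(diffCase, config$screen)
    downPost <- selectDeregulated(diffPost, config$screen)  # up pre vs post
    inter <- intersectCandidates(upCase$up, downPost$up)
    screened <- filterCandidates(inter,
                                 list(case_vs_control = diffCase,
                                      pre_vs_post = diffPost),
                                 config$screen)
    stages$screening <- list(
      n_deregulated = length(upCase$up) + length(upCase$down),
      n_up_in_case = length(upCase$up),
      n_down_post_op = length(downPost$up),
      n_intersection = length(inter), n_candidates = length(screened),
      candidates = screened)
    if (is.null(candidates)) candidates <- screened
    if (!length(candidates))
      stop("screening produced no candidate transcripts")
  }
  if (is.null(candidates)) candidates <- rownames(qpcr)

  # --- training-set panel filter (qPCR) ---
  if (isTRUE(config$applyTrainingFilter)) {
    decisions <- trainingFilter(qpcr, candidates,
                                foldThreshold = config$foldThreshold,
                                pThreshold = config$pThreshold)
    panel <- decisions$transcript_id[decisions$retained]
    stages$panel <- list(decisions = decisions)
  } else {
    panel <- candidates
  }
  if (!length(panel))
    stop("no markers survived the training filter; cannot fit a model")

  # --- diagnostic risk model, frozen evaluation ---
  model <- fitRiskModel(qpcr, panel, percentile = config$percentile,
                        weightMethod = config$weightMethod,
                        cutoffMethod = config$cutoffMethod)
  phaseEval <- function(phase) {
    case <- selectSamples(qpcr, group = "HCC", timepoint = "pre_op",
                          phase = phase)
    ctrl <- selectSamples(qpcr, group = "control", phase = phase)
    sel <- case | ctrl
    evaluateFrozen(model, qpcr, truth = case[sel], samples = sel)
  }
  stages$training <- phaseEval("training")
  for (ph in c("validation", "double_blind")) {
    ok <- any(selectSamples(qpcr, group = "HCC", phase = ph)) &&
      any(selectSamples(qpcr, group = "control", phase = ph))
    if (ok) stages[[ph]] <- phaseEval(ph)
  }

  # --- metastasis risk model on held-out patient splits ---
  records <- sampleRecords(qpcr)
  metModel <- NULL
  statusKnown <- records$group == "HCC" & records$timepoint == "pre_op" &
    records$metastasis %in% c("yes", "no") & records$phase != "screening"
  if (sum(records$metastasis[statusKnown] == "yes") >= 5 &&
      sum(records$metastasis[statusKnown] == "no") >= 5) {
    metDiff <- differentialTest(
      qpcr[panel, , drop = FALSE],
      statusKnown & records$metastasis == "yes",
      statusKnown & records$metastasis == "no")
    metMarkers <- metDiff$transcript_id[metDiff$p_value < 0.05 &
                                          metDiff$direction == "up"]
    if (length(metMarkers)) {
      splits <- withSeed(config$seed + 77L,
                         .metSplits(records, config$metTrain,
                                    config$metValid))
      preSel <- records$group == "HCC" & records$timepoint == "pre_op"
      trSel <- preSel & records$patient_id %in% splits$train
      vaSel <- preSel & records$patient_id %in% splits$valid
      trCase <- trSel & records$metastasis == "yes"
      trCtrl <- trSel & records$metastasis == "no"
      metModel <- fitRiskModel(qpcr, metMarkers,
                               percentile = config$percentile,
                               weightMethod = config$weightMethod,
                               cutoffMethod = config$cutoffMethod,
                               case = trCase, control = trCtrl)
      metStage <- list(markers = metMarkers,
                       training = evaluateFrozen(
                         metModel, qpcr,
                         truth = (records$metastasis == "yes")[trSel],
                         samples = trSel))
      if (any(vaSel))
        metStage$validation <- evaluateFrozen(
          metModel, qpcr,
          truth = (records$metastasis == "yes")[vaSel], samples = vaSel)
      stages$metastasis <- metStage
    }
  }

  # --- post-operative dynamics ---
  if (any(records$timepoint == "post_op")) {
    dyn <- pairedChanges(qpcr, panel, riseMargin = config$riseMargin)
    po <- list(changes = dyn$changes, tests = dyn$tests)
    if (any(records$metastasis %in% c("yes", "no")))
      po$association <- metastasisAssociation(dyn$changes, records,
                                              minMarkers = config$minMarkers)
    stages$postop <- po
  }

  new("StudyReport", panel = panel, diagnosisModel = model,
      metastasisModel = metModel, stages = stages,
      provenance = list(seed = config$seed,
                        weight_method = config$weightMethod,
                        cutoff_method = config$cutoffMethod,
                        percentile = config$percentile,
                        package_version =
                          as.character(utils::packageVersion("plasmaLncDx"))))
}

#' Write a StudyReport to a directory
#'
#' Emits plain-text artefacts: `report.json` (panel, per-phase metrics,
#' provenance), `risk_model.json` / `metastasis_model.json` (frozen
#' models), `postop_changes.tsv` and per-phase `roc_<phase>.tsv` files.
#'
#' @param report a [StudyReport-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeStudyReport <- function(report, dir) {
  stopifnot(is(report, "StudyReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  confAsList <- function(ct) {
    c(as.list(counts(ct)),
      list(sensitivity = sensitivity(ct), specificity = specificity(ct),
           ppv = ppv(ct), npv = npv(ct), accuracy = accuracy(ct)))
  }
  out <- list(panel = report@panel, provenance = report@provenance)
  for (ph in intersect(c("training", "validation", "double_blind"),
                       names(report@stages))) {
    st <- report@stages[[ph]]
    out[[ph]] <- list(confusion = confAsList(st$confusion),
                      auc = auc(st$roc))
    writeRocCurve(st$roc, file.path(dir, paste0("roc_", ph, ".tsv")))
  }
  ms <- report@stages$metastasis
  if (!is.null(ms)) {
    out$metastasis <- list(markers = ms$markers,
                           training = list(
                             confusion = confAsList(ms$training$confusion),
                             auc = auc(ms$training$roc)))
    if (!is.null(ms$validation))
      out$metastasis$validation <- list(
        confusion = confAsList(ms$validation$confusion),
        auc = auc(ms$validation$roc))
  }
  po <- report@stages$postop
  if (!is.null(po)) {
    utils::write.table(po$changes, file.path(dir, "postop_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(po$association))
      out$postop_association <- list(
        table = as.vector(po$association$table),
        chisq_p = po$association$chisq_p,
        fisher_p = po$association$fisher_p)
  }
  sc <- report@stages$screening
  if (!is.null(sc)) out$screening <- sc
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeRiskModel(report@diagnosisModel, file.path(dir, "risk_model.json"))
  if (!is.null(report@metastasisModel))
    writeRiskModel(report@metastasisModel,
                   file.path(dir, "metastasis_model.json"))
  invisible(dir)
}
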