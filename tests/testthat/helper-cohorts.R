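# Shared fixtures, built in code.

# A small qPCR-only design: no screening, reduced validation/blind cells.
smallSizes <- function(train = 20L, valid = 30L, blind = 15L) {
  data.frame(group = rep(c("HCC", "control"), 3),
             phase = rep(c("training", "validation", "double_blind"),
                         each = 2),
             n = c(train, train, valid, valid, blind, blind),
             stringsAsFactors = FALSE)
}

smallConfig <- function(seed = 1L, nTranscripts = 13L, ...) {
  cohortConfig(nTranscripts = nTranscripts, nMarkers = 3L,
               groupSizes = smallSizes(), seed = seed, ...)
}

# Paper-sized qPCR phases (training 20/20, validation 147/180, blind 50/50)
# over the 13 screened candidates, 3 of them planted.
paperPhaseConfig <- function(seed, caseEffect = 2, noiseSd = 0.5, ...) {
  gs <- defaultGroupSizes()
  cohortConfig(nTranscripts = 13L, nMarkers = 3L,
               groupSizes = gs[gs$phase != "screening", ],
               caseEffect = caseEffect, noiseSd = noiseSd, seed = seed, ...)
}

# A hand-built PlasmaExperiment from explicit values.
toyExperiment <- function(values, group, timepoint = NULL, patient = NULL,
                          phase = "training", platform = "qpcr",
                          metastasis = NULL) {
  n <- ncol(values)
  if (is.null(timepoint)) timepoint <- ifelse(group == "HCC", "pre_op",
                                              "none")
  if (is.null(patient)) patient <- paste0("p", seq_len(n))
  if (is.null(metastasis)) metastasis <- ifelse(group == "HCC", "no",
                                                "unknown")
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(n))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("t", seq_len(nrow(values)))
  rec <- data.frame(sample_id = colnames(values), patient_id = patient,
                    group = group, timepoint = timepoint,
                    metastasis = metastasis, phase = phase,
                    stringsAsFactors = FALSE)
  PlasmaExperiment(values, rec, platform)
}

# Risk model with explicit components (bypasses fitting).
toyModel <- function(markers, thresholds, weights, cutoff) {
  new("RiskModel", markers = markers,
      thresholds = stats::setNames(thresholds, markers),
      weights = stats::setNames(weights, markers), cutoff = cutoff,
      provenance = list())
}
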