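#' @include screening.R
NULL

#' Paired pre/post-operative marker changes
#'
#' For every HCC patient with both a pre- and a post-operative sample,
#' computes each panel marker's log2 change (`log2(post/pre)`) and flags a
#' *secondary increase* when the change exceeds `riseMargin` (default 0:
#' any rise counts; a positive margin makes the flag robust to measurement
#' noise). Alongside the per-patient records, a paired t test of post vs
#' pre log2 levels is reported per marker. Zero-variance differences are
#' handled explicitly: an identically zero change gives p = 1, an exactly
#' constant non-zero change gives p = 0 (below any reportable floor).
#'
#' @param x a [PlasmaExperiment-class].
#' @param markers panel transcript ids.
#' @param riseMargin log2 margin a post/pre change must exceed to be
#'   flagged.
#' @return list with `changes` (data.frame: `patient_id`, `transcript_id`,
#'   `pre_level`, `post_level`, `log2_change`, `secondary_increase`) and
#'   `tests` (data.frame: `transcript_id`, `mean_log2_change`, `p_value`,
#'   `n_pairs`).
#' @export
pairedChanges <- function(x, markers, riseMargin = 0) {
  stopifnot(is(x, "PlasmaExperiment"))
  missing <- setdiff(markers, rownames(x))
  if (length(missing))
    stop("marker(s) absent: ", paste(missing, collapse = ", "))
  cd <- colData(x)
  pre <- which(cd$group == "HCC" & cd$timepoint == "pre_op")
  post <- which(cd$group == "HCC" & cd$timepoint == "post_op")
  prePid <- cd$patient_id[pre]; postPid <- cd$patient_id[post]
  orphans <- c(setdiff(prePid, postPid), setdiff(postPid, prePid))
  if (length(orphans))
    stop("pairing error: patients without both timepoints: ",
         paste(unique(orphans), collapse = ", "))
  if (!length(pre)) stop("no paired pre/post-operative samples")
  post <- post[match(prePid, postPid)]
  lv <- .linearLevels(x, markers)
  preM <- lv[, pre, drop = FALSE]; postM <- lv[, post, drop = FALSE]
  d <- log2(postM) - log2(preM)
  changes <- data.frame(
    patient_id = rep(prePid, each = length(markers)),
    transcript_id = rep(markers, times = length(pre)),
    pre_level = as.numeric(preM), post_level = as.numeric(postM),
    log2_change = as.numeric(d),
    secondary_increase = as.numeric(d) > riseMargin,
    stringsAsFactors = FALSE)
  tt <- if (ncol(d) >= 2) .pairedT(d)
        else list(mean = rowMeans(d), p = rep(NA_real_, nrow(d)))
  tests <- data.frame(transcript_id = markers, mean_log2_change = tt$mean,
                      p_value = tt$p, n_pairs = length(pre),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(changes = changes, tests = tests)
}

#' Association between post-operative rises and metastasis
#'
#' Aggregates marker-level secondary-increase flags to the patient level (a
#' patient is a *riser* when at least `minMarkers` panel markers rose) and
#' tests the 2x2 contingency of riser status against known metastasis
#' status with both the Pearson chi-square test (no continuity correction)
#' and Fisher's exact test; Fisher is the authoritative p value for the
#' small cell counts typical here. A per-patient concordance listing (the
#' tabular equivalent of the usual radar display) is returned alongside.
#'
#' @param changes the `changes` data.frame from [pairedChanges()].
#' @param records sample metadata carrying `patient_id` and `metastasis`
#'   (e.g. [sampleRecords()] output), or a [PlasmaExperiment-class].
#' @param minMarkers markers that must rise for a patient-level flag
#'   (default 2, i.e. 2 of a 3-marker panel).
#' @return list: `table` (2x2 riser-by-metastasis contingency), `chisq_p`,
#'   `fisher_p`, `patients` (data.frame `patient_id`, `n_risen`, `riser`,
#'   `metastasis`), `n_excluded` (patients with unknown status).
#' @export
metastasisAssociation <- function(changes, records, minMarkers = 2) {
  if (is(records, "PlasmaExperiment")) records <- sampleRecords(records)
  status <- unique(records[records$patient_id %in% changes$patient_id,
                           c("patient_id", "metastasis")])
  if (anyDuplicated(status$patient_id))
    stop("inconsistent metastasis status within a patient")
  nRisen <- tapply(changes$secondary_increase, changes$patient_id, sum)
  pat <- data.frame(patient_id = names(nRisen),
                    n_risen = as.integer(nRisen),
                    riser = as.integer(nRisen) >= minMarkers,
                    stringsAsFactors = FALSE, row.names = NULL)
  pat$metastasis <- status$metastasis[match(pat$patient_id,
                                            status$patient_id)]
  known <- pat$metastasis %in% c("yes", "no")
  if (!any(known))
    stop("metastasis status unknown for every paired patient")
  k <- pat[known, , drop = FALSE]
  tab <- table(riser = factor(k$riser, c(TRUE, FALSE)),
               metastasis = factor(k$metastasis, c("yes", "no")))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  fis <- stats::fisher.test(tab)
  list(table = tab, chisq_p = unname(chi$p.value),
       fisher_p = unname(fis$p.value),
       patients = pat[order(-pat$n_risen, pat$patient_id), ],
       n_excluded = sum(!known))
}
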