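#' @include AllClasses.R AllGenerics.R
NULL

## Matching rule: a call matches a truth event when it is in the same trial
## and gene, has the same type (DEL vs DUP), and overlaps at least one truth
## exon. Events on these panels are exon-granular, so exon-range overlap is
## the natural unit; a reciprocal-overlap fraction can be layered on top.
.matches <- function(call, ev, minReciprocal = 0) {
  if (call$gene != ev$gene || call$type != ev$type) return(FALSE)
  ov <- min(call$last_exon, ev$last_exon) - max(call$first_exon, ev$first_exon) + 1L
  if (ov < 1L) return(FALSE)
  if (minReciprocal > 0) {
    spanC <- call$last_exon - call$first_exon + 1L
    spanE <- ev$last_exon - ev$first_exon + 1L
    if (ov / spanC < minReciprocal || ov / spanE < minReciprocal) return(FALSE)
  }
  TRUE
}

#' Match calls against a truth table
#'
#' Annotates each truth event with whether it was detected (a call in the
#' same trial with the same gene and type overlapping at least one truth
#' exon) and each call with whether it is a true positive.
#'
#' @param calls calls data.frame (\code{specimen_id} is the trial id,
#'   \code{gene}, \code{type}, \code{first_exon}, \code{last_exon}).
#' @param truth truth data.frame with the same columns (e.g. from
#'   \code{\link{spikeCnvs}}).
#' @param minReciprocal optional reciprocal exon-overlap fraction required
#'   for a match (default 0: one shared exon suffices).
#' @return list: \code{truth} with a \code{detected} column, \code{calls}
#'   with a \code{true_positive} column.
#' @export
matchCalls <- function(calls, truth, minReciprocal = 0) {
  truth$detected <- vapply(seq_len(nrow(truth)), function(i) {
    cs <- calls[calls$specimen_id == truth$specimen_id[i], , drop = FALSE]
    any(vapply(seq_len(nrow(cs)), function(j)
      .matches(cs[j, ], truth[i, ], minReciprocal), NA))
  }, NA)
  calls$true_positive <- vapply(seq_len(nrow(calls)), function(j) {
    ev <- truth[truth$specimen_id == calls$specimen_id[j], , drop = FALSE]
    any(vapply(seq_len(nrow(ev)), function(i)
      .matches(calls[j, ], ev[i, ], minReciprocal), NA))
  }, NA)
  if (nrow(calls) == 0) calls$true_positive <- logical(0)
  if (nrow(truth) == 0) truth$detected <- logical(0)
  list(truth = truth, calls = calls)
}

#' CNV detection sensitivity over positive trials
#'
#' Fraction of truth events detected, one event per positive trial
#' (\code{detected positive trials / positive trials}).
#'
#' @param calls,truth see \code{\link{matchCalls}}.
#' @param minReciprocal see \code{\link{matchCalls}}.
#' @return proportion in [0, 1]; NA (with a message) when there are no
#'   positive trials.
#' @export
cnvSensitivity <- function(calls, truth, minReciprocal = 0) {
  if (nrow(truth) == 0) {
    message("no positive trials: sensitivity undefined")
    return(NA_real_)
  }
  m <- matchCalls(calls, truth, minReciprocal)
  mean(m$truth$detected)
}

#' Trial-level specificity
#'
#' A false-positive trial is any trial containing at least one call that
#' matches no truth event of that trial; specificity is
#' \code{(trials - FP trials) / trials}. The denominator is the full set of
#' trials scored (positive trials included), following the trial-level
#' convention of clinical assay validation.
#'
#' @param calls,truth see \code{\link{matchCalls}}.
#' @param trialIds character vector of all scored trial ids (trials without
#'   calls must be present here).
#' @param minReciprocal see \code{\link{matchCalls}}.
#' @return proportion in [0, 1].
#' @export
cnvTrialSpecificity <- function(calls, truth, trialIds, minReciprocal = 0) {
  m <- matchCalls(calls, truth, minReciprocal)
  fpTrials <- unique(m$calls$specimen_id[!m$calls$true_positive])
  (length(trialIds) - sum(trialIds %in% fpTrials)) / length(trialIds)
}

## Canonical comparison of two call sets under the matching rule.
.sameCallSet <- function(a, b, minReciprocal = 0) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (nrow(a) == 0) return(TRUE)
  used <- logical(nrow(b))
  for (i in seq_len(nrow(a))) {
    hit <- FALSE
    for (j in which(!used)) {
      if (.matches(a[i, ], b[j, ], minReciprocal)) { used[j] <- TRUE; hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

#' Inter-assay precision from replicated call sets
#'
#' A specimen is concordant when all of its replicate trials yield identical
#' call sets under the gene + type + overlap matching rule (empty call sets
#' are concordant negatives). Precision is concordant / replicated
#' specimens.
#'
#' @param calls calls data.frame over all replicate trials.
#' @param replicates data.frame mapping \code{trial_id} to \code{specimen_id}
#'   (one row per replicate trial; specimens with >= 2 rows are evaluated).
#' @param minReciprocal see \code{\link{matchCalls}}.
#' @return list: \code{precision}, \code{concordant}, \code{replicated},
#'   \code{discordant_specimens}.
#' @export
interAssayPrecision <- function(calls, replicates, minReciprocal = 0) {
  counts <- table(replicates$specimen_id)
  specs <- names(counts)[counts >= 2]
  conc <- vapply(specs, function(sp) {
    tr <- replicates$trial_id[replicates$specimen_id == sp]
    ## type must agree exactly across replicates, so compare both directions
    sets <- lapply(tr, function(t) calls[calls$specimen_id == t, , drop = FALSE])
    for (i in seq_along(sets)[-1])
      if (!.sameCallSet(sets[[1]], sets[[i]], minReciprocal) ||
          !.sameCallSet(sets[[i]], sets[[1]], minReciprocal)) return(FALSE)
    TRUE
  }, NA)
  list(precision = mean(conc), concordant = sum(conc),
       replicated = length(specs),
       discordant_specimens = specs[!conc])
}

#' Validation summary from confusion counts
#'
#' Computes the headline validation rates directly from trial-level
#' confusion counts: sensitivity (detected / positive trials), trial-level
#' specificity ((trials - FP trials) / trials), inter-assay precision
#' (concordant / replicated specimens), and - when the orthogonal
#' confirmation outcome of the false-positive trials is known - the
#' post-confirmation specificity, counting refuted flags as not reported.
#'
#' @param nTrials total scored trials.
#' @param positiveTrials trials of known CNV-positive specimens.
#' @param detectedPositiveTrials positive trials with the event called.
#' @param fpTrials trials containing at least one false-positive call.
#' @param nReplicated specimens with replicate trials.
#' @param discordant replicated specimens with discordant call sets.
#' @param refutedFpTrials FP trials refuted by confirmation (NA: no
#'   confirmation performed).
#' @return a \code{cnvValidationResult} list (rates as proportions; a print
#'   method shows them as percentages).
#' @examples
#' validationSummary(nTrials = 457, positiveTrials = 42,
#'                   detectedPositiveTrials = 42, fpTrials = 9,
#'                   nReplicated = 94, discordant = 4, refutedFpTrials = 9)
#' @export
validationSummary <- function(nTrials, positiveTrials, detectedPositiveTrials,
                              fpTrials, nReplicated = NA, discordant = NA,
                              refutedFpTrials = NA) {
  if (detectedPositiveTrials > positiveTrials)
    .inputError("detected cannot exceed positive trials")
  res <- list(
    n_trials = nTrials, n_positive_trials = positiveTrials,
    detected_positive_trials = detectedPositiveTrials,
    false_positive_trials = fpTrials,
    n_replicated_specimens = nReplicated, discordant_specimens = discordant,
    sensitivity = if (positiveTrials > 0)
      detectedPositiveTrials / positiveTrials else NA_real_,
    specificity = (nTrials - fpTrials) / nTrials,
    inter_assay_precision = if (!is.na(nReplicated))
      (nReplicated - discordant) / nReplicated else NA_real_,
    post_confirmation_specificity = if (!is.na(refutedFpTrials))
      confirmationAdjustedSpecificity(nTrials, fpTrials, refutedFpTrials)
    else NA_real_)
  structure(res, class = "cnvValidationResult")
}

#' @export
print.cnvValidationResult <- function(x, ...) {
  cat("CNV validation summary\n")
  cat("  sensitivity:          ", formatPercent(x$sensitivity, 0), " (",
      x$detected_positive_trials, "/", x$n_positive_trials, " positive trials)\n",
      sep = "")
  cat("  specificity:          ", formatPercent(x$specificity), " (",
      x$n_trials - x$false_positive_trials, "/", x$n_trials, " trials)\n",
      sep = "")
  if (!is.na(x$inter_assay_precision))
    cat("  inter-assay precision:", formatPercent(x$inter_assay_precision),
        sprintf(" (%d/%d specimens)\n",
                x$n_replicated_specimens - x$discordant_specimens,
                x$n_replicated_specimens))
  if (!is.na(x$post_confirmation_specificity))
    cat("  post-confirmation specificity:",
        formatPercent(x$post_confirmation_specificity, 0), "\n")
  invisible(x)
}

#' Confirmation-adjusted specificity
#'
#' Specificity recomputed after orthogonal confirmation, counting refuted
#' false-positive trials as not reported:
#' \code{(nTrials - (fpTrials - refuted)) / nTrials}.
#'
#' @param nTrials total scored trials.
#' @param fpTrials false-positive trials before confirmation.
#' @param refutedFpTrials FP trials refuted by the confirmatory method.
#' @return proportion in [0, 1].
#' @export
confirmationAdjustedSpecificity <- function(nTrials, fpTrials,
                                            refutedFpTrials) {
  if (is.na(refutedFpTrials))
    .inputError("confirmation status unresolved; adjudicate pending calls first")
  if (refutedFpTrials > fpTrials)
    .inputError("cannot refute more FP trials than exist")
  (nTrials - (fpTrials - refutedFpTrials)) / nTrials
}

#' Summarize a clinical cohort variant table
#'
#' Totals the per-variant detection counts by gene (with integer percentage
#' shares of all variants) and by variant type, and reports the
#' patient-level positive rate.
#'
#' @param records variant records (see \code{\link{cohortVariantTable}}).
#' @param nPatients cohort size.
#' @param patientsWithFinding patients with at least one reportable variant.
#' @return list: \code{by_gene} (gene, n, pct), \code{by_type} (named
#'   counts), \code{total_variants}, \code{positive_rate} (proportion).
#' @export
summarizeCohort <- function(records, nPatients, patientsWithFinding) {
  byGene <- stats::aggregate(n_detected ~ gene, records, sum)
  byGene <- byGene[order(-byGene$n_detected, byGene$gene), ]
  total <- sum(records$n_detected)
  byGene$pct <- as.integer(round(100 * byGene$n_detected / total))
  names(byGene)[2] <- "n"
  byType <- tapply(records$n_detected, records$type, sum)
  list(by_gene = `rownames<-`(byGene, NULL),
       by_type = byType[order(-byType)],
       total_variants = total,
       positive_rate = patientsWithFinding / nPatients)
}
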