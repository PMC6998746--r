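#' @include AllClasses.R AllGenerics.R simulate.R train.R score.R metrics.R
NULL

#' Train a model on a simulated null cohort
#'
#' Convenience harness for the simulation validation studies: simulates a
#' CNV-free training cohort under the default generator and fits a
#' \linkS4class{CnvModel}.
#'
#' @param panel a \linkS4class{CnvPanel} with groups.
#' @param nSpecimens training cohort size (default 300).
#' @param seed simulation seed.
#' @param meanDepth mean coverage (default 380).
#' @param targetSpecificity cutoff calibration target (default 0.98).
#' @param nComponents principal components (default 5).
#' @param ... further arguments to \code{\link{simConfig}}.
#' @return a \linkS4class{CnvModel}.
#' @export
trainNullModel <- function(panel, nSpecimens = 300, seed, meanDepth = 380,
                           targetSpecificity = 0.98, nComponents = 5, ...) {
  cfg <- simConfig(nSpecimens = nSpecimens, meanDepth = meanDepth,
                   seed = seed, ...)
  dm <- simulateDepth(cfg, panel, prefix = "train")
  trainModel(dm, panel, nComponents = nComponents,
             targetSpecificity = targetSpecificity)
}

## Expand an event table to one row per replicate trial.
.expandTrials <- function(events) {
  rows <- rep(seq_len(nrow(events)), events$replications)
  repNo <- unlist(lapply(events$replications, seq_len))
  out <- events[rows, c("specimen_id", "gene", "first_exon", "last_exon",
                        "copy_state")]
  out$source_specimen <- out$specimen_id
  out$replicate <- repNo
  rownames(out) <- NULL
  out
}

#' Simulated sensitivity study
#'
#' Spikes the CNV-positive truth set (each event replicated per its
#' replication count, 42 positive trials under the packaged set) into one
#' simulated batch, fills the batch with CNV-free specimens, calls CNVs with
#' the trained model and tallies detected positive trials under the
#' gene + type + overlap matching rule.
#'
#' @param panel a \linkS4class{CnvPanel}.
#' @param model a \linkS4class{CnvModel} trained on the same panel.
#' @param seed simulation seed for the batch and the spike-in.
#' @param events event table (default \code{\link{validationCnvEvents}()}).
#' @param batchSize batch size (default 92).
#' @param meanDepth mean coverage (default 380).
#' @return list: \code{detected}, \code{positives}, \code{sensitivity},
#'   \code{missed} (truth rows not detected), \code{calls}, \code{truth}.
#' @export
runSensitivityStudy <- function(panel, model, seed,
                                events = validationCnvEvents(),
                                batchSize = 92, meanDepth = 380) {
  trials <- .expandTrials(events)
  if (nrow(trials) > batchSize)
    .inputError("more positive trials (", nrow(trials),
                ") than batch slots (", batchSize, ")")
  cfg <- simConfig(nSpecimens = batchSize, batchSize = batchSize,
                   meanDepth = meanDepth, seed = seed)
  dm <- simulateDepth(cfg, panel, prefix = "trial")
  trials$specimen_id <- specimenIds(dm)[seq_len(nrow(trials))]
  sp <- spikeCnvs(dm, trials, panel, seed = seed + 1L)
  res <- callCnvs(sp$matrix, panel, model)
  m <- matchCalls(res$calls, sp$truth)
  m$truth$source_specimen <- trials$source_specimen
  m$truth$n_exons <- m$truth$last_exon - m$truth$first_exon + 1L
  list(detected = sum(m$truth$detected), positives = nrow(m$truth),
       sensitivity = mean(m$truth$detected),
       missed = m$truth[!m$truth$detected, , drop = FALSE],
       calls = m$calls, truth = m$truth)
}

#' Simulated trial-level specificity study
#'
#' Simulates CNV-negative trials in batches, calls them against the trained
#' model and reports the fraction of trials without any call.
#'
#' @param panel a \linkS4class{CnvPanel}.
#' @param model a \linkS4class{CnvModel}.
#' @param seed base simulation seed (one derived seed per batch).
#' @param nTrials total null trials (default 457).
#' @param batchSize batch size (default 92).
#' @param meanDepth mean coverage (default 380).
#' @return list: \code{specificity}, \code{fpTrials}, \code{nTrials},
#'   \code{fpCalls} (the false calls).
#' @export
runSpecificityStudy <- function(panel, model, seed, nTrials = 457,
                                batchSize = 92, meanDepth = 380) {
  done <- 0L; fp <- 0L; fpCalls <- list()
  b <- 0L
  while (done < nTrials) {
    b <- b + 1L
    n <- min(batchSize, nTrials - done)
    cfg <- simConfig(nSpecimens = n, batchSize = n, meanDepth = meanDepth,
                     seed = seed + 1000L * b)
    dm <- simulateDepth(cfg, panel, prefix = sprintf("b%02d_", b))
    res <- callCnvs(dm, panel, model)
    flagged <- unique(res$calls$specimen_id)
    fp <- fp + length(flagged)
    if (nrow(res$calls)) fpCalls[[b]] <- res$calls
    done <- done + n
  }
  list(specificity = (nTrials - fp) / nTrials, fpTrials = fp,
       nTrials = nTrials,
       fpCalls = if (length(fpCalls)) do.call(rbind, fpCalls)
                 else .emptyCalls())
}

#' Simulated inter-assay precision study
#'
#' Simulates a replication cohort (default 94 specimens of which 9 carry
#' events), re-draws every specimen's counts under the same noise law for
#' each replicate trial, calls each replicate and reports the fraction of
#' specimens whose replicate call sets are identical under the
#' gene + type + overlap matching rule.
#'
#' @param panel a \linkS4class{CnvPanel}.
#' @param model a \linkS4class{CnvModel}.
#' @param seed base simulation seed.
#' @param events events carried by the positive specimens (default: the
#'   first 9 of \code{\link{validationCnvEvents}()}, the precision-cohort
#'   positives).
#' @param nSpecimens cohort size (default 94).
#' @param nReplicates replicate draws per specimen (default 3).
#' @param meanDepth mean coverage (default 380).
#' @return list: \code{precision}, \code{concordant}, \code{replicated},
#'   \code{discordant} (specimen ids), \code{calls}, \code{replicates}.
#' @export
runPrecisionStudy <- function(panel, model, seed,
                              events = validationCnvEvents()[1:9, ],
                              nSpecimens = 94, nReplicates = 3,
                              meanDepth = 380) {
  if (nrow(events) > nSpecimens)
    .inputError("more event specimens than cohort slots")
  cfg <- simConfig(nSpecimens = nSpecimens, batchSize = nSpecimens,
                   meanDepth = meanDepth, seed = seed)
  dm <- simulateDepth(cfg, panel, prefix = "p")
  spike <- events
  spike$specimen_id <- specimenIds(dm)[seq_len(nrow(events))]
  sp <- spikeCnvs(dm, spike, panel, seed = seed + 1L)
  calls <- NULL; repmap <- NULL
  for (r in seq_len(nReplicates)) {
    repDm <- redrawDepth(sp$matrix, seed = seed + 10L * r,
                         suffix = sprintf("_r%d", r))
    rc <- callCnvs(repDm, panel, model)$calls
    calls <- rbind(calls, rc)
    repmap <- rbind(repmap,
                    data.frame(specimen_id = specimenIds(dm),
                               trial_id = specimenIds(repDm)))
  }
  pr <- interAssayPrecision(calls, repmap)
  list(precision = pr$precision, concordant = pr$concordant,
       replicated = pr$replicated, discordant = pr$discordant_specimens,
       calls = calls, replicates = repmap)
}
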