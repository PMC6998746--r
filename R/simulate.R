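#' @include AllClasses.R AllGenerics.R coverage.R
NULL

#' Simulation configuration for synthetic coverage
#'
#' Bundles the generative parameters of the coverage simulator. Depth of bin
#' b in specimen s is drawn as
#' \deqn{NB(mean = D \cdot d_s \cdot e_b \cdot exp(\sum_k u_{sk} v_{bk}) \cdot c_{sb},\ size = 1/dispersion)}
#' with \eqn{d_s} a lognormal specimen size factor, \eqn{e_b} a lognormal
#' capture-efficiency profile fixed per panel and seed, \eqn{u, v} low-rank
#' technical (batch/library) factors, and \eqn{c} the copy ratio (1
#' everywhere until events are spiked in).
#'
#' @param nSpecimens number of specimens (>= 2).
#' @param batchSize specimens per batch (default 92, a typical clinical run).
#' @param meanDepth grand mean depth (default 380, a typical validated
#'   median coverage for this assay class).
#' @param specimenSdLog log-sd of the specimen size factors (default 0.15).
#' @param efficiencySdLog log-sd of per-bin capture efficiency (default 0.3).
#' @param nTechnicalFactors rank of the systematic technical term (default 2).
#' @param technicalSd log-scale sd of the technical loadings (default 0.05).
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2; default 0.002, i.e. ~7 percent bin CV at 380x;
#'   0 gives Poisson noise).
#' @param seed integer RNG seed (mandatory; no wall-clock seeding).
#' @return a \code{SimulationConfig} list.
#' @export
simConfig <- function(nSpecimens, batchSize = 92, meanDepth = 380,
                      specimenSdLog = 0.15, efficiencySdLog = 0.3,
                      nTechnicalFactors = 2, technicalSd = 0.05,
                      dispersion = 0.002, seed) {
  if (missing(seed)) .inputError("simConfig: a seed is required")
  if (nSpecimens < 2) .inputError("nSpecimens must be >= 2")
  if (meanDepth <= 0) .inputError("meanDepth must be > 0")
  if (any(c(specimenSdLog, efficiencySdLog, technicalSd, dispersion) < 0))
    .inputError("variance parameters must be >= 0")
  structure(list(
    nSpecimens = as.integer(nSpecimens), batchSize = as.integer(batchSize),
    meanDepth = meanDepth, specimenSdLog = specimenSdLog,
    efficiencySdLog = efficiencySdLog,
    nTechnicalFactors = as.integer(nTechnicalFactors),
    technicalSd = technicalSd, dispersion = dispersion,
    seed = as.integer(seed)), class = "SimulationConfig")
}

.rdepth <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion > 0) matrix(stats::rnbinom(n, mu = mu, size = 1 / dispersion),
                             nrow = nrow(mu))
  else matrix(stats::rpois(n, lambda = mu), nrow = nrow(mu))
}

#' Simulate a CNV-free coverage matrix
#'
#' Draws a bin x specimen depth matrix under the model described in
#' \code{\link{simConfig}}; deterministic given (config, panel). The
#' capture-efficiency profile is drawn first from the seed, so it is fixed
#' per panel per seed across configs of different cohort sizes. The latent
#' mean matrix is kept in the \code{"mu"} assay so that events can be spiked
#' and replicate trials re-drawn under the identical noise law.
#'
#' @param config a \code{\link{simConfig}}.
#' @param panel a binned \linkS4class{CnvPanel}.
#' @param prefix specimen id prefix (default \code{"spec"}).
#' @return a \linkS4class{DepthMatrix} with assays \code{depth} and
#'   \code{mu}, batch labels in blocks of \code{batchSize}.
#' @export
simulateDepth <- function(config, panel, prefix = "spec") {
  stopifnot(inherits(config, "SimulationConfig"), is(panel, "CnvPanel"))
  bins <- binTargets(panel)
  if (length(bins) == 0) .inputError("panel has no bins; run makeBins")
  B <- length(bins); N <- config$nSpecimens
  K <- config$nTechnicalFactors
  ## The capture-efficiency profile and the technical loading directions are
  ## systematic properties of the capture design (bait efficiency, GC
  ## response), stable across runs of the same panel - which is what makes
  ## per-group dispersions trained on one cohort, and a training-fixed PCA
  ## basis, applicable to later batches. Draw both from a panel-derived
  ## seed; specimen factors, technical scores and counting noise remain
  ## governed by the config seed.
  set.seed(as.integer(as.numeric(sub(":.*", "", panelFingerprint(panel))) %%
                        2147483647))
  e <- stats::rlnorm(B, 0, config$efficiencySdLog)
  v <- if (K > 0) matrix(stats::rnorm(B * K, 0, config$technicalSd), B, K)
       else matrix(0, B, 0)
  set.seed(config$seed)
  d <- stats::rlnorm(N, 0, config$specimenSdLog)
  logTech <- if (K > 0) {
    u <- matrix(stats::rnorm(N * K), N, K)
    v %*% t(u)
  } else matrix(0, B, N)
  mu <- config$meanDepth * (e %o% d) * exp(logTech)
  depth <- .rdepth(mu, config$dispersion)
  nb <- ceiling(N / config$batchSize)
  batch <- sprintf("batch%02d", rep(seq_len(nb), each = config$batchSize))[seq_len(N)]
  DepthMatrix(depth, targetIds = S4Vectors::mcols(bins)$target_id,
              specimenIds = sprintf("%s%03d", prefix, seq_len(N)),
              batch = batch, mu = mu, config = list(sim = unclass(config)))
}

.copyRatio <- function(state) {
  r <- c(het_del = 0.5, hom_del = 0, dup = 1.5)[state]
  if (anyNA(r)) .inputError("unknown copy_state: ",
                            paste(state[is.na(r)], collapse = ", "))
  unname(r)
}

## bins (row indices into dm) of an event; unmasked only
.eventBins <- function(dm, panel, gene, firstExon, lastExon) {
  bins <- binTargets(panel)
  mc <- S4Vectors::mcols(bins)
  hit <- mc$gene == gene & !mc$masked
  if (!any(mc$gene == gene)) .inputError("event names unknown gene: ", gene)
  if (!identical(firstExon, "*")) {
    fe <- as.integer(firstExon); le <- as.integer(lastExon)
    hit <- hit & mc$exon_index >= fe & mc$exon_index <= le
  }
  ids <- mc$target_id[hit]
  idx <- match(ids, rownames(depthValues(dm)))
  if (length(idx) == 0 || anyNA(idx))
    .inputError("event on ", gene, " exons ", firstExon, "-", lastExon,
                " covers no unmasked bin present in the matrix")
  idx
}

#' Spike CNV events into a simulated matrix
#'
#' Multiplies the latent means over each event's unmasked bins by the copy
#' ratio (0.5 het del, 0 hom del, 1.5 dup) and re-draws those bins under the
#' same noise law; all other bins are untouched bit-exactly. Events whose
#' exon range contains masked exons (e.g. a whole-gene deletion over a
#' pseudogene-masked region) are spiked on their unmasked bins only, which is
#' also what the assay can see; an event with no unmasked bin is an error.
#'
#' @param x a simulated \linkS4class{DepthMatrix} (must carry the \code{mu}
#'   assay).
#' @param events data.frame with columns \code{specimen_id}, \code{gene},
#'   \code{first_exon}, \code{last_exon} (\code{"*"} for whole gene) and
#'   \code{copy_state}; see \code{\link{readCnvEvents}}.
#' @param panel the \linkS4class{CnvPanel} the matrix was simulated from.
#' @param seed RNG seed for the re-draw.
#' @return list with the spiked \code{matrix} and a \code{truth} data.frame
#'   (specimen, gene, type, ratio, exon span, genomic span, bin ids).
#' @export
spikeCnvs <- function(x, events, panel, seed) {
  stopifnot(is(x, "DepthMatrix"))
  if (!"mu" %in% SummarizedExperiment::assayNames(x))
    .inputError("matrix lacks latent means; only simulated matrices can be spiked")
  if (missing(seed)) .inputError("spikeCnvs: a seed is required")
  dispersion <- metadata(x)$sim$dispersion %||% 0
  depth <- assay(x, "depth"); mu <- assay(x, "mu")
  truth <- list()
  if (nrow(events) > 0) {
    set.seed(as.integer(seed))
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      j <- match(ev$specimen_id, colnames(depth))
      if (is.na(j)) .inputError("event names unknown specimen: ", ev$specimen_id)
      rows <- .eventBins(x, panel, ev$gene, ev$first_exon, ev$last_exon)
      ratio <- .copyRatio(as.character(ev$copy_state))
      mu[rows, j] <- mu[rows, j] * ratio
      depth[rows, j] <- as.numeric(.rdepth(mu[rows, j, drop = FALSE], dispersion))
      bins <- binTargets(panel)
      sel <- match(rownames(depth)[rows], S4Vectors::mcols(bins)$target_id)
      truth[[i]] <- data.frame(
        specimen_id = ev$specimen_id, gene = ev$gene,
        type = if (ratio < 1) "DEL" else "DUP", ratio = ratio,
        first_exon = min(S4Vectors::mcols(bins)$exon_index[sel]),
        last_exon = max(S4Vectors::mcols(bins)$exon_index[sel]),
        chrom = as.character(seqnames(bins))[sel[1]],
        start = min(start(bins)[sel]) - 1L, end = max(end(bins)[sel]),
        bins = paste(rownames(depth)[rows], collapse = ","))
    }
  }
  SummarizedExperiment::assay(x, "depth") <- depth
  SummarizedExperiment::assay(x, "mu") <- mu
  list(matrix = x,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(specimen_id = character(), gene = character(),
                    type = character(), ratio = numeric(),
                    first_exon = integer(), last_exon = integer(),
                    chrom = character(), start = integer(), end = integer(),
                    bins = character()))
}

#' Re-draw a simulated matrix with fresh noise
#'
#' Resamples every bin from the stored latent means under the same noise law,
#' modeling an independent sequencing trial of the same specimens (replicate
#' runs share library biology through \code{mu} but not counting noise).
#'
#' @param x a simulated \linkS4class{DepthMatrix} with a \code{mu} assay.
#' @param seed RNG seed.
#' @param suffix appended to specimen ids (e.g. \code{"_r2"}); default none.
#' @return a \linkS4class{DepthMatrix}.
#' @export
redrawDepth <- function(x, seed, suffix = "") {
  stopifnot(is(x, "DepthMatrix"))
  if (!"mu" %in% SummarizedExperiment::assayNames(x))
    .inputError("matrix lacks latent means; cannot re-draw")
  dispersion <- metadata(x)$sim$dispersion %||% 0
  mu <- assay(x, "mu")
  set.seed(as.integer(seed))
  depth <- .rdepth(mu, dispersion)
  DepthMatrix(depth, targetIds = rownames(mu),
              specimenIds = paste0(colnames(mu), suffix),
              batch = batchLabels(x), qcPass = qcPass(x), mu = mu,
              config = metadata(x))
}

#' Read a CNV event table
#'
#' TSV with columns \code{specimen_id}, \code{gene}, \code{first_exon},
#' \code{last_exon} (\code{"*"} for a whole-gene event), \code{copy_state}
#' (\code{het_del}, \code{hom_del}, \code{dup}) and \code{replications};
#' an optional \code{note} column is carried along.
#'
#' @param path TSV path.
#' @return data.frame of events.
#' @export
readCnvEvents <- function(path) {
  if (!file.exists(path)) .inputError("event table not found: ", path)
  ev <- .readTsv(path)
  need <- c("specimen_id", "gene", "first_exon", "last_exon", "copy_state")
  if (!all(need %in% colnames(ev)))
    .inputError("event table must have columns: ", paste(need, collapse = ", "))
  ev$first_exon <- as.character(ev$first_exon)
  ev$last_exon <- as.character(ev$last_exon)
  if (is.null(ev$replications)) ev$replications <- 1L
  ev$replications <- as.integer(ev$replications)
  ev
}

#' The packaged CNV-positive validation truth set
#'
#' The 18 CNV-positive specimens (S1-S18) used in the assay validation
#' study, with gene, exon span, del/dup state and per-specimen replication
#' counts (42 positive trials in total). The S12 whole-gene PMS2 deletion is
#' annotated: its exon 11-15 portion falls in the pseudogene mask and was not
#' assayed by sequencing.
#'
#' @return data.frame of 18 events.
#' @examples
#' ev <- validationCnvEvents()
#' nrow(ev); sum(ev$replications)
#' @export
validationCnvEvents <- function() {
  readCnvEvents(system.file("extdata", "validation_cnv_events.tsv",
                            package = "panelCNV"))
}

#' The packaged clinical-cohort variant summary
#'
#' The 53 pathogenic/likely pathogenic variants reported from the assay's
#' first 500 consecutive clinical specimens: gene, variant label, type
#' (SNV/INS/DEL/CNV), classification (P/LP) and per-variant detection count.
#'
#' @return data.frame of variant records.
#' @export
cohortVariantTable <- function() {
  v <- .readTsv(system.file("extdata", "cohort_variants.tsv",
                            package = "panelCNV"))
  v$n_detected <- as.integer(v$n_detected)
  v
}
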