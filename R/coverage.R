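#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a DepthMatrix
#'
#' @param depth numeric matrix of mean per-base read depth, bins x specimens.
#' @param targetIds row (bin) ids; default rownames of \code{depth}.
#' @param specimenIds column ids; default colnames of \code{depth}.
#' @param batch per-specimen batch labels (default one \code{"default"} batch).
#' @param qcPass per-specimen QC state (default all pass).
#' @param mu optional latent mean matrix (simulator provenance).
#' @param config optional list stored in \code{metadata()}.
#' @return a \linkS4class{DepthMatrix}.
#' @export
DepthMatrix <- function(depth, targetIds = rownames(depth),
                        specimenIds = colnames(depth),
                        batch = rep("default", ncol(depth)),
                        qcPass = rep(TRUE, ncol(depth)),
                        mu = NULL, config = list()) {
  depth <- as.matrix(depth)
  if (is.null(targetIds)) targetIds <- sprintf("bin%04d", seq_len(nrow(depth)))
  if (is.null(specimenIds)) specimenIds <- sprintf("spec%03d", seq_len(ncol(depth)))
  dimnames(depth) <- list(targetIds, specimenIds)
  assays <- list(depth = depth)
  if (!is.null(mu)) {
    dimnames(mu) <- dimnames(depth)
    assays$mu <- mu
  }
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(target_id = targetIds),
    colData = DataFrame(specimen_id = specimenIds, batch = batch,
                        qc_pass = qcPass, row.names = specimenIds))
  out <- new("DepthMatrix", se)
  metadata(out) <- config
  validObject(out)
  out
}

#' Read / write a target x specimen depth matrix as TSV
#'
#' The TSV has a header row of specimen ids with \code{target_id} as the
#' first column. An optional comment line \code{"#batch<TAB>b1<TAB>b2..."}
#' immediately above the header assigns one batch label per specimen column;
#' without it every specimen goes to batch \code{"default"}.
#'
#' @param path file path.
#' @return \code{readDepthMatrix}: a \linkS4class{DepthMatrix}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("target_id\ts1\ts2", "binA\t10\t20", "binB\t30\t40"), tsv)
#' depthValues(readDepthMatrix(tsv))
#' @export
readDepthMatrix <- function(path) {
  if (!file.exists(path)) .inputError("depth matrix not found: ", path)
  raw <- readLines(path)
  batchLine <- grep("^#batch\t", raw, value = TRUE)
  body <- raw[!startsWith(raw, "#")]
  if (length(body) < 2) .inputError("depth matrix must have a header and data rows")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  specimens <- header[-1]
  if (anyDuplicated(specimens))
    .inputError("duplicated specimen column: ",
                specimens[duplicated(specimens)][1])
  cells <- strsplit(body[-1], "\t", fixed = TRUE)
  if (any(lengths(cells) != length(header)))
    .inputError("ragged row in depth matrix at data line ",
                which(lengths(cells) != length(header))[1])
  ids <- vapply(cells, `[[`, "", 1)
  if (anyDuplicated(ids))
    .inputError("duplicate target id: ", ids[duplicated(ids)][1])
  vals <- suppressWarnings(
    vapply(cells, function(r) as.numeric(r[-1]), numeric(length(specimens))))
  vals <- matrix(vals, ncol = length(specimens), byrow = TRUE,
                 dimnames = list(ids, specimens))
  if (anyNA(vals)) {
    ij <- which(is.na(vals), arr.ind = TRUE)[1, ]
    .inputError("non-numeric cell at target ", ids[ij[1]],
                ", specimen ", specimens[ij[2]])
  }
  batch <- rep("default", length(specimens))
  if (length(batchLine)) {
    bl <- strsplit(batchLine[1], "\t", fixed = TRUE)[[1]][-1]
    if (length(bl) != length(specimens))
      .inputError("#batch line has ", length(bl), " labels for ",
                  length(specimens), " specimens")
    batch <- bl
  }
  DepthMatrix(vals, batch = batch)
}

#' @rdname readDepthMatrix
#' @param x a \linkS4class{DepthMatrix}.
#' @return \code{writeDepthMatrix}: the path, invisibly.
#' @export
writeDepthMatrix <- function(x, path) {
  stopifnot(is(x, "DepthMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#batch", batchLabels(x)), collapse = "\t"), con)
  writeLines(paste(c("target_id", specimenIds(x)), collapse = "\t"), con)
  v <- depthValues(x)
  writeLines(paste(rownames(v), apply(v, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Aggregate per-base depth records into bin means
#'
#' Builds the bin x specimen depth matrix from a per-base depth table
#' (samtools-depth dialect: \code{chrom}, 1-based \code{pos}, then one depth
#' column per specimen, with a header naming the specimens). Each bin's value
#' is the mean depth over all its bases; bases absent from the table count as
#' depth 0. Records on chromosomes not in the panel are skipped (a count is
#' reported via \code{message}).
#'
#' @param records data.frame of per-base records, or a path to such a TSV.
#' @param panel a binned \linkS4class{CnvPanel}.
#' @param batch optional per-specimen batch labels.
#' @return a \linkS4class{DepthMatrix} over the panel's bins.
#' @export
aggregatePerBase <- function(records, panel, batch = NULL) {
  stopifnot(is(panel, "CnvPanel"))
  if (is.character(records)) records <- .readTsv(records)
  if (ncol(records) < 3) .inputError("per-base table needs chrom, pos, depth columns")
  bins <- binTargets(panel)
  if (length(bins) == 0) .inputError("panel has no bins; run makeBins")
  specimens <- colnames(records)[-(1:2)]
  chrom <- as.character(records[[1]])
  pos <- as.integer(records[[2]])
  known <- chrom %in% unique(as.character(seqnames(bins)))
  if (any(!known))
    message("aggregatePerBase: skipped ", sum(!known),
            " record(s) on chromosomes not in the panel")
  gr <- GRanges(chrom[known], IRanges(pos[known], width = 1L))
  hits <- GenomicRanges::findOverlaps(gr, bins)
  vals <- matrix(0, nrow = length(bins), ncol = length(specimens),
                 dimnames = list(S4Vectors::mcols(bins)$target_id, specimens))
  binIdx <- S4Vectors::subjectHits(hits)
  recIdx <- which(known)[S4Vectors::queryHits(hits)]
  for (j in seq_along(specimens)) {
    d <- as.numeric(records[[j + 2]])[recIdx]
    sums <- tapply(d, binIdx, sum)
    vals[as.integer(names(sums)), j] <- as.numeric(sums)
  }
  vals <- vals / width(bins)  # absent bases contribute 0 to the mean
  DepthMatrix(vals, batch = batch %||% rep("default", length(specimens)))
}

#' Coverage QC for specimens
#'
#' Marks a specimen as QC-fail when the fraction of unmasked bins with depth
#' at or above \code{minDepth} falls below \code{targetFraction} (the clinical
#' rule is 20x over the full region of interest, approximated per bin at
#' matrix level). Failed specimens are excluded from the batch medians used
#' as mu downstream, but still receive scores.
#'
#' @param x a \linkS4class{DepthMatrix}.
#' @param panel optional \linkS4class{CnvPanel}; when given, masked bins are
#'   ignored by the QC rule.
#' @param minDepth minimum acceptable bin depth (default 20).
#' @param targetFraction required fraction of bins at or above
#'   \code{minDepth} (default 1.0).
#' @return the matrix with \code{qc_pass} updated.
#' @export
qcMatrix <- function(x, panel = NULL, minDepth = 20, targetFraction = 1.0) {
  stopifnot(is(x, "DepthMatrix"))
  v <- depthValues(x)
  if (!is.null(panel)) {
    bins <- binTargets(panel)
    keep <- S4Vectors::mcols(bins)$target_id[!S4Vectors::mcols(bins)$masked]
    v <- v[rownames(v) %in% keep, , drop = FALSE]
  }
  frac <- colMeans(v >= minDepth)
  colData(x)$qc_pass <- frac >= targetFraction
  x
}
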