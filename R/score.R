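#' @include AllClasses.R AllGenerics.R normalize.R
NULL

#' Batch medians of X (mu)
#'
#' Per target group and batch, the median X across the batch's QC-passing,
#' scorable specimens - the robust per-batch reference against which Z is
#' measured. The median moves by well under a percent when a single specimen
#' in a typical batch of 92 carries a heterozygous event, which is what makes
#' a batch-internal reference safe.
#'
#' @param x a \linkS4class{NormalizedMatrix} at stage \code{"X"}.
#' @param minBatch minimum QC-passing specimens a batch must have (default 3).
#' @return numeric matrix, groups x batches.
#' @export
batchMu <- function(x, minBatch = 3) {
  stopifnot(is(x, "NormalizedMatrix"))
  if (x@stage != "X") .inputError("batchMu expects stage X, got ", x@stage)
  si <- x@specimenInfo
  batches <- unique(si$batch)
  use <- si$qc_pass & si$scorable
  mu <- vapply(batches, function(b) {
    j <- which(si$batch == b & use)
    if (length(j) < minBatch)
      .inputError("batch ", b, " has only ", length(j),
                  " usable specimen(s) (< ", minBatch,
                  "); pool it with another batch")
    apply(x@values[, j, drop = FALSE], 1, stats::median)
  }, numeric(nrow(x@values)))
  mu <- matrix(mu, nrow = nrow(x@values),
               dimnames = list(rownames(x@values), batches))
  mu
}

#' Z score
#'
#' \code{Z = (X - mu) / sigma} per group and specimen, with mu the group's
#' batch median and sigma the trained per-group dispersion. Groups with
#' sigma 0 (or missing) are unscorable: their Z is NA and a warning names
#' how many were excluded.
#'
#' @param x a \linkS4class{NormalizedMatrix} at stage \code{"X"}.
#' @param mu groups x batches matrix from \code{\link{batchMu}}.
#' @param sigma named per-group sigma (see \code{\link{fitSigma}}).
#' @return list with \code{Z} (matrix) and \code{mu} expanded to
#'   groups x specimens.
#' @export
zScore <- function(x, mu, sigma) {
  stopifnot(is(x, "NormalizedMatrix"))
  if (x@stage != "X") .inputError("zScore expects stage X, got ", x@stage)
  sigma <- sigma[rownames(x@values)]
  if (anyNA(sigma)) .inputError("sigma is missing for some groups")
  bad <- sigma <= 0
  if (any(bad))
    warning(sum(bad), " group(s) with sigma = 0 are unscorable and excluded")
  muS <- mu[, x@specimenInfo$batch, drop = FALSE]
  dimnames(muS) <- dimnames(x@values)
  Z <- (x@values - muS) / ifelse(bad, NA_real_, sigma)
  list(Z = Z, mu = muS)
}

#' Noise-adjusted Z score (Z.adj)
#'
#' Divides each Z by the sample standard deviation (n - 1 denominator) of the
#' same specimen's Z over the \emph{other} groups of the same level. A
#' specimen whose coverage is globally noisy has all its |Z| inflated by a
#' common factor; that factor cancels here, so Z.adj extracts putative CNV
#' signal from noisy read-depth. Cells whose peer standard deviation is zero
#' (or with fewer than 3 scored groups in the level) are NA and never flag.
#'
#' @param Z Z matrix (groups x specimens).
#' @param levels per-group level vector aligned with the rows of \code{Z}.
#' @return Z.adj matrix.
#' @export
zAdj <- function(Z, levels) {
  stopifnot(nrow(Z) == length(levels))
  out <- matrix(NA_real_, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  for (lv in unique(levels)) {
    r <- which(levels == lv)
    z <- Z[r, , drop = FALSE]
    ok <- !is.na(z)
    cnt <- colSums(ok)
    if (nrow(z) <= 64) {
      ## small level: exact two-pass leave-one-out sd (immune to the
      ## cancellation a shared-sums shortcut suffers with near-tied peers)
      sdO <- z * NA_real_
      for (g in seq_len(nrow(z))) {
        zz <- z[-g, , drop = FALSE]
        m <- colMeans(zz, na.rm = TRUE)
        nn <- colSums(!is.na(zz))
        sdO[g, ] <- sqrt(colSums(sweep(zz, 2, m)^2, na.rm = TRUE) /
                           pmax(nn - 1L, 1L))
      }
      nOth <- rep(cnt, each = nrow(z)) - 1L
    } else {
      ## large level: leave-one-out variance from shared sums, centered at
      ## the level median so the identity stays well-conditioned
      ctr <- apply(z, 2, stats::median, na.rm = TRUE)
      ctr[is.na(ctr)] <- 0
      zc <- sweep(z, 2, ctr)
      s1 <- colSums(ifelse(ok, zc, 0))
      s2 <- colSums(ifelse(ok, zc^2, 0))
      nOth <- rep(cnt, each = nrow(z)) - 1L     # peers of each cell
      sumO <- rep(s1, each = nrow(z)) - ifelse(ok, zc, 0)
      sqO <- rep(s2, each = nrow(z)) - ifelse(ok, zc^2, 0)
      varO <- (sqO - sumO^2 / nOth) / (nOth - 1L)
      sdO <- sqrt(pmax(varO, 0))
    }
    adj <- ifelse(ok & nOth >= 2 & sdO > .Machine$double.eps^0.5,
                  z / sdO, NA_real_)
    out[r, ] <- adj
  }
  out
}

#' Flag target groups over the cutoffs
#'
#' A group is flagged when |Z| exceeds the level's Z cutoff and/or |Z.adj|
#' exceeds the level's Z.adj cutoff (rule \code{"either"}, the default;
#' \code{"both"} requires both). Flagging is two-sided - the sign separates
#' deletions from duplications downstream - and NA scores never flag.
#'
#' @param Z,Zadj score matrices.
#' @param zCut,zadjCut named per-level cutoffs (> 0).
#' @param levels per-group level vector aligned with the rows.
#' @param rule \code{"either"} or \code{"both"}.
#' @return list with logical \code{flags} and character \code{source}
#'   (\code{"Z"}, \code{"Zadj"}, \code{"both"}, \code{"none"}) matrices.
#' @export
flagGroups <- function(Z, Zadj, zCut, zadjCut, levels,
                       rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (any(c(zCut, zadjCut) <= 0, na.rm = TRUE))
    .inputError("cutoffs must be positive")
  zc <- zCut[levels]; ac <- zadjCut[levels]
  hitZ <- !is.na(Z) & abs(Z) > zc
  hitA <- !is.na(Zadj) & abs(Zadj) > ac
  flags <- if (rule == "either") hitZ | hitA else hitZ & hitA
  src <- matrix("none", nrow(Z), ncol(Z), dimnames = dimnames(Z))
  src[hitZ & !hitA] <- "Z"
  src[!hitZ & hitA] <- "Zadj"
  src[hitZ & hitA] <- "both"
  if (rule == "both") src[!flags] <- "none"
  list(flags = flags, source = src)
}

## Calls table skeleton (also the empty-result contract)
.emptyCalls <- function() {
  data.frame(specimen_id = character(), gene = character(),
             chrom = character(), start = integer(), end = integer(),
             first_exon = integer(), last_exon = integer(),
             type = character(), best_group_id = character(),
             max_abs_Z = numeric(), mean_X_ratio = numeric(),
             flag_source = character(), status = character())
}

#' Merge flagged groups into CNV calls
#'
#' Per specimen and gene, every flagged group is projected onto its member
#' bins; maximal runs of contiguous flagged bins (in the gene's unmasked bin
#' order) become one call. The call type is DEL when the run's mean copy
#' ratio X/mu (depth relative to the batch reference) is below 1, DUP
#' otherwise; the best group is the flagged group overlapping
#' the run with the largest |Z|. New calls carry status
#' \code{"flagged_pending_confirmation"}: confirmation by an orthogonal
#' method is an external annotation (\code{\link{setCallStatus}}), never
#' automatic.
#'
#' @param scores a \linkS4class{ScoreMatrix}.
#' @param panel the \linkS4class{CnvPanel}.
#' @param x the stage-\code{"X"} \linkS4class{NormalizedMatrix} the scores
#'   came from.
#' @return data.frame of calls (possibly 0 rows).
#' @export
mergeCalls <- function(scores, panel, x) {
  stopifnot(is(scores, "ScoreMatrix"), is(panel, "CnvPanel"),
            is(x, "NormalizedMatrix"))
  gs <- panelGroups(panel)
  bins <- binTargets(panel, includeMasked = FALSE)
  bmc <- S4Vectors::mcols(bins)
  calls <- list()
  flagged <- which(colSums(scores@flags, na.rm = TRUE) > 0)
  for (j in flagged) {
    sid <- scores@specimenInfo$specimen_id[j]
    fg <- which(scores@flags[, j])
    for (g in unique(gs$gene[fg])) {
      gBins <- which(bmc$gene == g)           # gene's bins, genomic order
      gBinIds <- bmc$target_id[gBins]
      fgg <- fg[gs$gene[fg] == g]
      hit <- gBinIds %in% unique(unlist(gs$members[fgg]))
      runs <- split(seq_along(gBinIds)[hit], cumsum(!hit)[hit])
      for (run in runs) {
        ids <- gBinIds[run]
        sel <- gBins[run]
        sbRows <- match(paste0("sb:", ids), rownames(x@values))
        ## copy ratio relative to the batch reference: X carries a per-group
        ## systematic profile, so raw X ~ 1 is not the 2-copy baseline - X/mu is
        meanX <- mean(x@values[sbRows, j] / scores@mu[sbRows, j], na.rm = TRUE)
        ## flagged groups of this gene overlapping the run
        ov <- fgg[vapply(gs$members[fgg],
                         function(m) any(m %in% ids), NA)]
        zOv <- abs(scores@Z[ov, j])
        best <- if (all(is.na(zOv))) ov[1] else ov[which.max(zOv)]
        calls[[length(calls) + 1L]] <- data.frame(
          specimen_id = sid, gene = g,
          chrom = as.character(seqnames(bins))[sel[1]],
          start = min(start(bins)[sel]) - 1L, end = max(end(bins)[sel]),
          first_exon = min(bmc$exon_index[sel]),
          last_exon = max(bmc$exon_index[sel]),
          type = if (!is.na(meanX) && meanX < 1) "DEL" else "DUP",
          best_group_id = gs$group_id[best],
          max_abs_Z = if (all(is.na(zOv))) NA_real_ else max(zOv, na.rm = TRUE),
          mean_X_ratio = meanX,
          flag_source = scores@flagSource[best, j],
          status = "flagged_pending_confirmation")
      }
    }
  }
  if (length(calls)) do.call(rbind, calls) else .emptyCalls()
}

#' Score a batch and call CNVs against a trained model
#'
#' The production entry point: normalizes the depth matrix with the model's
#' principal-component basis, computes batch medians, Z and Z.adj, flags
#' groups over the trained cutoffs and merges flags into calls. The panel
#' fingerprint must match the one the model was trained on.
#'
#' @param x a \linkS4class{DepthMatrix} (bins x specimens) of one or more
#'   batches.
#' @param panel the \linkS4class{CnvPanel}.
#' @param model a \linkS4class{CnvModel}.
#' @param rule flag combination rule, \code{"either"} (default) or
#'   \code{"both"}.
#' @param minBatch minimum usable specimens per batch (default 3).
#' @return list: \code{calls} (data.frame), \code{scores}
#'   (\linkS4class{ScoreMatrix}), \code{X} (\linkS4class{NormalizedMatrix}).
#' @export
callCnvs <- function(x, panel, model, rule = "either", minBatch = 3) {
  stopifnot(is(x, "DepthMatrix"), is(panel, "CnvPanel"), is(model, "CnvModel"))
  if (!identical(panelFingerprint(panel), model@panelFingerprint))
    .inputError("panel fingerprint does not match the trained model")
  X <- normalizeDepth(x, panel, model)
  mu <- batchMu(X, minBatch = minBatch)
  zs <- suppressWarnings(zScore(X, mu, model@sigma))
  za <- zAdj(zs$Z, X@groupInfo$level)
  fl <- flagGroups(zs$Z, za, model@zCut, model@zadjCut, X@groupInfo$level,
                   rule = rule)
  scores <- new("ScoreMatrix", Z = zs$Z, Zadj = za, mu = zs$mu,
                flags = fl$flags, flagSource = fl$source,
                groupInfo = X@groupInfo, specimenInfo = X@specimenInfo)
  list(calls = mergeCalls(scores, panel, X), scores = scores, X = X)
}

#' Annotate call confirmation status
#'
#' Records the outcome of orthogonal confirmation (e.g. array CGH reflex
#' testing of every flagged specimen) on a calls table.
#'
#' @param calls calls data.frame from \code{\link{mergeCalls}}.
#' @param index row index (or logical vector) of the call(s) to annotate.
#' @param status \code{"confirmed"} or \code{"refuted"}.
#' @return the updated calls data.frame.
#' @export
setCallStatus <- function(calls, index, status = c("confirmed", "refuted")) {
  status <- match.arg(status)
  calls$status[index] <- status
  calls
}

#' Write calls as TSV / VCF
#'
#' \code{writeCallsTsv} writes the full calls table. \code{writeCallsVcf}
#' writes a minimal VCF 4.2 with symbolic ALT (\code{<DEL>}/\code{<DUP>}),
#' INFO keys SVTYPE, END, ZMAX, XRATIO and one sample column per specimen
#' (GT 0/1 for flagged events).
#'
#' @param calls calls data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCallsTsv <- function(calls, path) {
  .writeTsv(calls, path)
  invisible(path)
}

#' @rdname writeCallsTsv
#' @export
writeCallsVcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panelCNV",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=DUP,Description=\"Duplication\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=ZMAX,Number=1,Type=Float,Description=\"Max |Z| of flagged groups\">",
           "##INFO=<ID=XRATIO,Number=1,Type=Float,Description=\"Mean normalized depth ratio\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "SAMPLE"), collapse = "\t"))
  rows <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    rows[i] <- paste(
      cl$chrom, cl$start + 1L,
      sprintf("%s_%s_%d", cl$specimen_id, cl$gene, i), "N",
      sprintf("<%s>", cl$type), ".", "PASS",
      sprintf("SVTYPE=%s;END=%d;ZMAX=%.3f;XRATIO=%.3f;GENE=%s",
              cl$type, cl$end, cl$max_abs_Z, cl$mean_X_ratio, cl$gene),
      "GT", "0/1", sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
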