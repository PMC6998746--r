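#' @include AllClasses.R AllGenerics.R
#' @importFrom Matrix sparseMatrix
NULL

.newNorm <- function(stage, values, groupInfo, specimenInfo) {
  new("NormalizedMatrix", stage = stage, values = values,
      groupInfo = groupInfo, specimenInfo = specimenInfo)
}

.singleBinRows <- function(nm) which(nm@groupInfo$level == "single_bin")

#' Aggregate bin depth to target-group depth
#'
#' The value of a group is the length-weighted mean of its member bins'
#' depths, i.e. the per-base mean depth over the whole group. Each target
#' group is carried independently from here on.
#'
#' @param x a \linkS4class{DepthMatrix} over the panel's bins.
#' @param panel a \linkS4class{CnvPanel} with groups.
#' @return a \linkS4class{NormalizedMatrix} at stage \code{"RD"}
#'   (groups x specimens).
#' @export
groupDepth <- function(x, panel) {
  stopifnot(is(x, "DepthMatrix"), is(panel, "CnvPanel"))
  gs <- panelGroups(panel)
  if (nrow(gs) == 0) .inputError("panel has no groups; run makeTargetGroups")
  bins <- binTargets(panel)
  binIds <- S4Vectors::mcols(bins)$target_id
  v <- depthValues(x)
  idx <- match(binIds, rownames(v))
  if (anyNA(idx))
    .inputError("depth matrix is missing panel bin(s), e.g. ",
                binIds[is.na(idx)][1])
  v <- v[idx, , drop = FALSE]
  w <- width(bins)
  memb <- gs$members
  gi <- rep(seq_along(memb), lengths(memb))
  bi <- match(unlist(memb), binIds)
  W <- Matrix::sparseMatrix(i = gi, j = bi, x = w[bi],
                            dims = c(nrow(gs), length(binIds)))
  W <- W / Matrix::rowSums(W)
  vals <- as.matrix(W %*% v)
  dimnames(vals) <- list(gs$group_id, colnames(v))
  ginfo <- DataFrame(group_id = gs$group_id, gene = gs$gene, level = gs$level,
                     n_bins = lengths(memb),
                     length = as.integer(gs$end - gs$start))
  sinfo <- DataFrame(specimen_id = specimenIds(x), batch = batchLabels(x),
                     qc_pass = qcPass(x), scorable = TRUE)
  .newNorm("RD", vals, ginfo, sinfo)
}

#' Relative read depth (RDr)
#'
#' Divides every group value by the specimen's mean depth over the unmasked
#' single-bin groups, removing specimen-level sequencing yield. The same
#' per-specimen denominator is reused for every group level so that all
#' levels share one scale. Specimens with zero mean depth are marked
#' unscorable.
#'
#' @param x a \linkS4class{NormalizedMatrix} at stage \code{"RD"}.
#' @return a \linkS4class{NormalizedMatrix} at stage \code{"RDr"}.
#' @export
computeRdr <- function(x) {
  stopifnot(is(x, "NormalizedMatrix"))
  if (x@stage != "RD") .inputError("computeRdr expects stage RD, got ", x@stage)
  sb <- .singleBinRows(x)
  denom <- colMeans(x@values[sb, , drop = FALSE])
  sinfo <- x@specimenInfo
  sinfo$scorable <- sinfo$scorable & denom > 0
  vals <- sweep(x@values, 2, ifelse(denom > 0, denom, NA_real_), "/")
  .newNorm("RDr", vals, x@groupInfo, sinfo)
}

#' Fit the principal-component basis on training RDr
#'
#' PCA with specimens as observations and groups as variables, on
#' specimen-centered RDr. The basis holds the per-group training means and
#' the top loading vectors; it is fitted once on the training cohort and then
#' applied unchanged to production batches, because the dispersions and
#' cutoffs calibrated downstream presuppose the same normalization.
#'
#' @param x a \linkS4class{NormalizedMatrix} at stage \code{"RDr"}.
#' @param nComponents number of components to remove (default 5);
#'   0 makes \code{\link{applyPca}} the identity.
#' @param varCap retain at most the components needed to explain this
#'   fraction of training variance (default 0.9).
#' @return a \code{cnvPcaBasis} list: \code{center}, \code{rotation},
#'   \code{sdev}, \code{nComponents}, \code{groups}.
#' @export
fitPca <- function(x, nComponents = 5, varCap = 0.9) {
  stopifnot(is(x, "NormalizedMatrix"))
  if (x@stage != "RDr") .inputError("fitPca expects stage RDr, got ", x@stage)
  M <- t(x@values[, x@specimenInfo$scorable, drop = FALSE])  # specimens x groups
  n <- nrow(M); p <- ncol(M)
  if (nComponents >= min(n, p))
    .inputError("nComponents must be < min(specimens, groups) = ", min(n, p))
  if (n < nComponents + 2)
    .inputError("need at least nComponents + 2 training specimens")
  ctr <- colMeans(M)
  k <- as.integer(nComponents)
  if (k == 0) {
    basis <- list(center = ctr, rotation = matrix(0, p, 0), sdev = numeric(),
                  nComponents = 0L, groups = rownames(x@values))
  } else {
    sv <- svd(sweep(M, 2, ctr), nu = 0, nv = min(k, n - 1))
    sdev <- sv$d / sqrt(n - 1)
    cumvar <- cumsum(sdev^2) / sum(sdev^2)
    kEff <- min(k, which(cumvar >= varCap)[1], na.rm = TRUE)
    basis <- list(center = ctr,
                  rotation = sv$v[, seq_len(kEff), drop = FALSE],
                  sdev = sdev[seq_len(kEff)], nComponents = as.integer(kEff),
                  groups = rownames(x@values))
  }
  structure(basis, class = "cnvPcaBasis")
}

#' Principal-component denoising (RDrp)
#'
#' Removes the basis-spanned component of (RDr - training mean) from each
#' specimen and re-adds the mean:
#' \code{RDrp = m + (I - Q Q') (RDr - m)}, where Q orthonormally spans the
#' fitted loading vectors together with the direction of the training mean
#' profile itself. Systematic technical variation captured by the top
#' components (capture efficiency drift, batch effects) is cancelled, while
#' sparse CNV signal - nearly orthogonal to those dense components -
#' survives in the residual. Including the mean direction makes the stage
#' exact for per-specimen scale deviations: a large CNV inflates or
#' depresses the specimen's mean-based RDr denominator, and the resulting
#' global deviation is proportional to the mean profile; projecting it out
#' here (rather than leaving a partial, basis-filtered remnant) prevents
#' spurious whole-gene signal in specimens carrying genuine large events.
#' For the same reason the component scores of each specimen are estimated
#' robustly, from the groups not grossly copy-shifted against the training
#' profile, so that a genuine large event cannot imprint a dense ghost of
#' itself on unrelated genes through the subtraction. With an empty basis
#' this is the exact identity.
#'
#' @param x a \linkS4class{NormalizedMatrix} at stage \code{"RDr"}.
#' @param basis a \code{cnvPcaBasis} from \code{\link{fitPca}}.
#' @return a \linkS4class{NormalizedMatrix} at stage \code{"RDrp"}.
#' @export
applyPca <- function(x, basis) {
  stopifnot(is(x, "NormalizedMatrix"), inherits(basis, "cnvPcaBasis"))
  if (x@stage != "RDr") .inputError("applyPca expects stage RDr, got ", x@stage)
  if (!identical(basis$groups, rownames(x@values)))
    .inputError("basis groups do not match matrix groups")
  if (basis$nComponents == 0)
    return(.newNorm("RDrp", x@values, x@groupInfo, x@specimenInfo))
  R <- sweep(x@values, 1, basis$center)        # groups x specimens, centered
  mhat <- basis$center / sqrt(sum(basis$center^2))
  Q <- qr.Q(qr(cbind(mhat, basis$rotation)))   # + scale-deviation direction
  ## Robust component scores: a large CNV is a sparse vector with nonzero
  ## inner products against every dense component; plain projection lets
  ## the event bins drag the specimen's scores and then subtracts a
  ## deterministic dense "ghost" over unrelated genes. Estimate the scores
  ## only from groups that are not grossly copy-shifted against the
  ## training profile (deviation <= 25 percent, half way to a heterozygous
  ## change), then remove the fitted component everywhere.
  ok <- basis$center > 0 &
    abs(sweep(x@values, 1, ifelse(basis$center > 0, basis$center, 1), "/") - 1) <= 0.25
  coef <- t(Q) %*% R                           # full-LS fallback
  minKeep <- 10L * ncol(Q)
  for (j in seq_len(ncol(R))) {
    keep <- ok[, j]
    if (sum(keep) >= minKeep && sum(keep) < nrow(R)) {
      Qk <- Q[keep, , drop = FALSE]
      fit <- tryCatch(solve(crossprod(Qk), crossprod(Qk, R[keep, j])),
                      error = function(e) NULL)
      if (!is.null(fit)) coef[, j] <- fit
    }
  }
  resid <- R - Q %*% coef
  vals <- sweep(resid, 1, basis$center, "+")
  dimnames(vals) <- dimnames(x@values)
  .newNorm("RDrp", vals, x@groupInfo, x@specimenInfo)
}

#' Median scaling (X)
#'
#' Divides each specimen's RDrp by its median over the unmasked single-bin
#' groups, yielding the normalized target representation X - a copy-ratio
#' like quantity centered at 1 for two copies. The median (not the mean) is
#' used so that a real CNV barely moves the denominator.
#'
#' Even a median is not fully event-proof: a whole-gene duplication moves
#' several percent of a specimen's bins far upward, which shifts the median
#' of the widely spread per-bin values by a percent or two and biases every
#' other group's X in the opposite direction - enough to graze tight
#' whole-gene cutoffs. When the matrix has at least \code{minProfile}
#' specimens, the denominator is therefore a two-pass robust median: bins
#' whose ratio to the cohort's per-bin median profile deviates by more than
#' \code{outlierDev} (copy-shifted in that specimen) are excluded from that
#' specimen's median. With no exclusions - every event-free specimen - this
#' is exactly the plain median. Specimens with a nonpositive median are
#' marked unscorable.
#'
#' @param x a \linkS4class{NormalizedMatrix} at stage \code{"RDrp"}.
#' @param outlierDev relative deviation from the cohort profile beyond which
#'   a bin is excluded from its specimen's denominator (default 0.25, half
#'   way to a heterozygous copy change).
#' @param minProfile minimum specimens needed to estimate the cohort profile
#'   (default 10; below it the plain median is used).
#' @return a \linkS4class{NormalizedMatrix} at stage \code{"X"}.
#' @export
medianNormalize <- function(x, outlierDev = 0.25, minProfile = 10) {
  stopifnot(is(x, "NormalizedMatrix"))
  if (x@stage != "RDrp")
    .inputError("medianNormalize expects stage RDrp, got ", x@stage)
  sb <- .singleBinRows(x)
  V <- x@values[sb, , drop = FALSE]
  denom <- apply(V, 2, stats::median)
  if (ncol(V) >= minProfile) {
    prof <- apply(V, 1, stats::median)
    usable <- prof > 0
    for (j in seq_len(ncol(V))) {
      keep <- usable & abs(V[, j] / ifelse(usable, prof, 1) - 1) <= outlierDev
      if (sum(keep) >= length(sb) / 2)
        denom[j] <- stats::median(V[keep, j])
    }
  }
  sinfo <- x@specimenInfo
  sinfo$scorable <- sinfo$scorable & !is.na(denom) & denom > 0
  vals <- sweep(x@values, 2, ifelse(!is.na(denom) & denom > 0, denom, NA_real_),
                "/")
  .newNorm("X", vals, x@groupInfo, sinfo)
}

#' Run the full normalization chain
#'
#' Convenience wrapper: group depth, RDr, principal-component denoising
#' (with the given basis, or none), median scaling.
#'
#' @param x a \linkS4class{DepthMatrix}.
#' @param panel a \linkS4class{CnvPanel} with groups.
#' @param basis a \code{cnvPcaBasis}, a \linkS4class{CnvModel} (its basis is
#'   used), or NULL for no denoising.
#' @return a \linkS4class{NormalizedMatrix} at stage \code{"X"}.
#' @export
normalizeDepth <- function(x, panel, basis = NULL) {
  rdr <- computeRdr(groupDepth(x, panel))
  if (is(basis, "CnvModel"))
    basis <- structure(list(center = basis@center, rotation = basis@rotation,
                            sdev = basis@sdev,
                            nComponents = ncol(basis@rotation),
                            groups = names(basis@center)),
                       class = "cnvPcaBasis")
  if (is.null(basis))
    basis <- structure(list(center = stats::setNames(rowMeans(rdr@values),
                                                     rownames(rdr@values)),
                            rotation = matrix(0, nrow(rdr@values), 0),
                            sdev = numeric(), nComponents = 0L,
                            groups = rownames(rdr@values)),
                       class = "cnvPcaBasis")
  medianNormalize(applyPca(rdr, basis))
}

#' Write a staged matrix as TSV (audit trail)
#'
#' Same layout as the depth matrix TSV: \code{group_id} first column, one
#' column per specimen, \code{#batch} comment line.
#'
#' @param x a \linkS4class{NormalizedMatrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeNormalizedTsv <- function(x, path) {
  stopifnot(is(x, "NormalizedMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#batch", x@specimenInfo$batch), collapse = "\t"), con)
  writeLines(paste(c("group_id", x@specimenInfo$specimen_id), collapse = "\t"),
             con)
  writeLines(paste(rownames(x@values),
                   apply(x@values, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}
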