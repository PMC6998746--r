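#' @include AllClasses.R AllGenerics.R normalize.R score.R
NULL

#' Per-group dispersion sigma from a training cohort
#'
#' \code{sigma(g) = madScale * median_s |X(s,g) - median_s X(s,g)|} over the
#' QC-passing, scorable training specimens. The 1.4826 scale makes the MAD
#' consistent for a normal distribution, so Z is interpretable in approximate
#' standard-normal units (set \code{madScale = 1} for the raw MAD). Groups
#' with sigma 0 (constant columns) are unscorable.
#'
#' @param x a training \linkS4class{NormalizedMatrix} at stage \code{"X"}.
#' @param madScale MAD scale constant (default 1.4826).
#' @return named per-group sigma vector.
#' @export
fitSigma <- function(x, madScale = 1.4826) {
  stopifnot(is(x, "NormalizedMatrix"))
  if (x@stage != "X") .inputError("fitSigma expects stage X, got ", x@stage)
  use <- x@specimenInfo$qc_pass & x@specimenInfo$scorable
  if (sum(use) < 30)
    warning("only ", sum(use), " usable training specimens; ",
            "sigma estimates will be unstable (>= 30 recommended)")
  v <- x@values[, use, drop = FALSE]
  sig <- apply(v, 1, stats::mad, constant = madScale)
  stats::setNames(sig, rownames(x@values))
}

.subsetSpecimens <- function(x, idx) {
  .newNorm(x@stage, x@values[, idx, drop = FALSE], x@groupInfo,
           x@specimenInfo[idx, ])
}

## Held-out normalized matrices under leave-one-batch-out fitting: each batch
## is put through an RDr -> X chain whose PCA basis was fitted on the other
## batches, so scores computed on these matrices are out-of-sample with
## respect to the normalization - in-sample replay puts the cutoff quantiles
## slightly inside the true tails (everything is fit on the same specimens)
## and the union over levels and statistics amplifies that into a real
## specificity loss.
.loboFoldX <- function(rdr, nComponents, minBatch = 3) {
  si <- rdr@specimenInfo
  batches <- unique(si$batch)
  usable <- si$qc_pass & si$scorable
  if (length(batches) < 2) return(NULL)
  folds <- list()
  for (b in batches) {
    te <- which(si$batch == b & usable)
    tr <- which(si$batch != b & usable)
    if (length(te) < minBatch || length(tr) < max(10, nComponents + 2))
      return(NULL)
    basisB <- fitPca(.subsetSpecimens(rdr, tr), nComponents = nComponents)
    folds[[b]] <- medianNormalize(applyPca(.subsetSpecimens(rdr, te), basisB))
  }
  folds
}

## Per-specimen, per-level maxima of |Z| and |Z.adj| over the held-out folds,
## scored with the sigma the model will actually ship - so the calibration
## is self-consistent with any robust sigma refit.
.loboMaxStats <- function(folds, sigma, minBatch = 3) {
  if (is.null(folds)) return(NULL)
  MZ <- NULL; MA <- NULL
  lvls <- NULL
  for (Xte in folds) {
    rs <- .replayMaxStats(Xte, sigma, minBatch = minBatch)
    MZ <- rbind(MZ, rs$MZ); MA <- rbind(MA, rs$MA)
    lvls <- rs$levels
  }
  rownames(MZ) <- rownames(MA) <- NULL
  list(MZ = MZ, MA = MA, levels = lvls)
}

## Per-specimen, per-level maxima of |Z| and |Z.adj| on a cohort replay.
.replayMaxStats <- function(x, sigma, minBatch = 3) {
  mu <- batchMu(x, minBatch = minBatch)
  zs <- suppressWarnings(zScore(x, mu, sigma))
  za <- zAdj(zs$Z, x@groupInfo$level)
  lvls <- intersect(GROUP_LEVELS, unique(x@groupInfo$level))
  use <- which(x@specimenInfo$qc_pass & x@specimenInfo$scorable)
  mx <- function(m, lv) {
    r <- which(x@groupInfo$level == lv)
    a <- abs(m[r, use, drop = FALSE])
    out <- apply(a, 2, function(col)
      if (all(is.na(col))) 0 else max(col, na.rm = TRUE))
    out
  }
  list(MZ = vapply(lvls, function(lv) mx(zs$Z, lv), numeric(length(use))),
       MA = vapply(lvls, function(lv) mx(za, lv), numeric(length(use))),
       levels = lvls, Z = zs$Z, Zadj = za, use = use)
}

#' Calibrate per-level flagging cutoffs
#'
#' Sets the |Z| and |Z.adj| cutoff per group level to the (1 - alpha)
#' quantile of the per-specimen maximum statistic over the cohort's
#' batch-wise replay, with alpha solved by bisection so that the replayed
#' fraction of specimens carrying at least one flag does not exceed
#' \code{1 - targetSpecificity}. The flag-rate constraint is specimen-level
#' (family-wise over all groups) because assay specificity is tallied per
#' trial, not per target. Cutoffs are per level since the null maximum grows
#' with the number of groups in a level.
#'
#' Each statistic is a maximum over many groups, so its null distribution is
#' close to an extreme-value (Gumbel) law; the quantile function used for
#' the cutoffs is a Gumbel fitted to the replay maxima by moments. Fitting
#' the whole sample instead of reading the one or two largest order
#' statistics keeps the tail estimate stable at training sizes of a few
#' hundred specimens, where an empirical 99.7th percentile is noise. The
#' union flag rate is still evaluated empirically, so correlation between
#' levels and between the two statistics is respected.
#' \code{targetSpecificity = 1} drives alpha to 0: cutoffs sit just above
#' every observed null score and the replay flags nothing (a warning notes
#' the saturation).
#'
#' @param x a training \linkS4class{NormalizedMatrix} at stage \code{"X"}
#'   (assumed CNV-free or pre-cleaned).
#' @param sigma per-group sigma from \code{\link{fitSigma}}.
#' @param targetSpecificity target fraction of event-free specimens with no
#'   flag (default 0.98).
#' @param minBatch minimum usable specimens per batch (default 3).
#' @param maxStats optional precomputed per-specimen max-statistics (as from
#'   the leave-one-batch-out scoring \code{\link{trainModel}} performs);
#'   default: in-sample replay of \code{x}.
#' @return list: named \code{zCut} and \code{zadjCut} per level, solved
#'   \code{alpha}, replayed \code{flagRate}.
#' @export
calibrateCutoffs <- function(x, sigma, targetSpecificity = 0.98, minBatch = 3,
                             maxStats = NULL) {
  if (targetSpecificity < 0 || targetSpecificity > 1)
    .inputError("targetSpecificity must be in [0, 1]")
  rs <- maxStats %||% .replayMaxStats(x, sigma, minBatch = minBatch)
  budget <- 1 - targetSpecificity
  ## Gumbel quantile function fitted by moments to each family's maxima
  gumbelQ <- function(M) {
    beta <- stats::sd(M) * sqrt(6) / pi
    mu <- mean(M) - 0.5772156649 * beta
    function(alpha) if (alpha <= 0) Inf else mu - beta * log(-log(1 - alpha))
  }
  qZ <- apply(rs$MZ, 2, gumbelQ)
  qA <- apply(rs$MA, 2, gumbelQ)
  cutsAt <- function(alpha) list(
    z = vapply(qZ, function(f) f(alpha), 0),
    a = vapply(qA, function(f) f(alpha), 0))
  rateAt <- function(cuts) {
    hit <- sweep(rs$MZ, 2, cuts$z, ">") | sweep(rs$MA, 2, cuts$a, ">")
    mean(rowSums(hit) > 0)
  }
  lo <- 0; hi <- 0.5
  if (budget <= 0) {
    alpha <- 0
  } else if (rateAt(cutsAt(hi)) <= budget) {
    alpha <- hi
  } else {
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (rateAt(cutsAt(mid)) <= budget) lo <- mid else hi <- mid
    }
    alpha <- lo
  }
  cuts <- cutsAt(alpha)
  if (alpha == 0) {
    warning("target specificity saturates the null quantiles; ",
            "cutoffs set just above the maximum observed scores")
    cuts$z <- apply(rs$MZ, 2, max) + 1e-6
    cuts$a <- apply(rs$MA, 2, max) + 1e-6
  }
  list(zCut = stats::setNames(cuts$z, rs$levels),
       zadjCut = stats::setNames(cuts$a, rs$levels),
       alpha = alpha, flagRate = rateAt(cuts))
}

#' Train a CNV flagging model
#'
#' Full training pipeline on a (presumed CNV-free) cohort: group-level depth,
#' RDr, principal-component basis, X, per-group sigma, and per-level cutoffs
#' calibrated to the target specimen-level specificity. When the cohort has
#' two or more batches the cutoff quantiles come from leave-one-batch-out
#' scoring (each batch scored with a basis and sigma fitted on the others),
#' so they estimate the out-of-sample null tails rather than an in-sample
#' replay. With
#' \code{robust = TRUE} (default) specimens flagged in a first replay are
#' excluded from a sigma refit - clinical training cohorts carry real CNVs
#' at a low rate, which would otherwise inflate sigma - while the cutoffs are
#' always recalibrated on the full QC-passing cohort with the final sigma, so
#' the specificity calibration is not biased by dropping extremes.
#'
#' @param x a training \linkS4class{DepthMatrix}.
#' @param panel a \linkS4class{CnvPanel} with groups.
#' @param nComponents principal components to remove (default 5; capped at
#'   the number explaining 90 percent of training variance).
#' @param targetSpecificity see \code{\link{calibrateCutoffs}} (default 0.98).
#' @param madScale MAD scale constant (default 1.4826).
#' @param robust drop first-pass flagged specimens from the sigma refit
#'   (default TRUE).
#' @param minBatch minimum usable specimens per batch (default 3).
#' @return a \linkS4class{CnvModel}.
#' @export
trainModel <- function(x, panel, nComponents = 5, targetSpecificity = 0.98,
                       madScale = 1.4826, robust = TRUE, minBatch = 3) {
  stopifnot(is(x, "DepthMatrix"), is(panel, "CnvPanel"))
  rdr <- computeRdr(groupDepth(x, panel))
  basis <- fitPca(rdr, nComponents = nComponents)
  X <- medianNormalize(applyPca(rdr, basis))
  sigma <- fitSigma(X, madScale = madScale)
  folds <- .loboFoldX(rdr, nComponents, minBatch = minBatch)
  dropped <- character()
  if (robust) {
    cal0 <- calibrateCutoffs(X, sigma, targetSpecificity, minBatch = minBatch,
                             maxStats = .loboMaxStats(folds, sigma, minBatch))
    rs <- .replayMaxStats(X, sigma, minBatch = minBatch)
    hit <- sweep(rs$MZ, 2, cal0$zCut[rs$levels], ">") |
      sweep(rs$MA, 2, cal0$zadjCut[rs$levels], ">")
    flagged <- rs$use[rowSums(hit) > 0]
    keep <- setdiff(which(X@specimenInfo$qc_pass & X@specimenInfo$scorable),
                    flagged)
    if (length(flagged) && length(keep) >= max(10, basis$nComponents + 2)) {
      dropped <- X@specimenInfo$specimen_id[flagged]
      sigma <- suppressWarnings(
        fitSigma(.subsetSpecimens(X, keep), madScale = madScale))
    }
  }
  ## cutoffs are always calibrated with the sigma the model ships, on the
  ## held-out folds, so the robust refit cannot bias the flag rate
  cal <- calibrateCutoffs(X, sigma, targetSpecificity, minBatch = minBatch,
                          maxStats = .loboMaxStats(folds, sigma, minBatch))
  new("CnvModel",
      panelFingerprint = panelFingerprint(panel),
      center = stats::setNames(basis$center, rownames(X@values)),
      rotation = basis$rotation, sdev = basis$sdev, sigma = sigma,
      zCut = cal$zCut, zadjCut = cal$zadjCut,
      nTraining = ncol(X@values),
      targetSpecificity = targetSpecificity, madScale = madScale,
      config = list(alpha = cal$alpha, replay_flag_rate = cal$flagRate,
                    lobo_calibration = !is.null(folds),
                    robust = robust, dropped_specimens = dropped,
                    n_components = basis$nComponents))
}

#' Save / load a trained model as JSON
#'
#' Lossless round-trip (full-precision numbers); loading verifies the panel
#' fingerprint when a panel is supplied and refuses a mismatch.
#'
#' @param model a \linkS4class{CnvModel}.
#' @param path JSON path.
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: the
#'   restored \linkS4class{CnvModel}.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CnvModel"))
  obj <- list(
    format = "panelCNV-model-1",
    panel_fingerprint = model@panelFingerprint,
    groups = names(model@center),
    center = unname(model@center),
    rotation = as.numeric(model@rotation),
    rotation_dim = dim(model@rotation),
    sdev = model@sdev,
    sigma = unname(model@sigma),
    z_cut = as.list(model@zCut),
    zadj_cut = as.list(model@zadjCut),
    n_training = model@nTraining,
    target_specificity = model@targetSpecificity,
    mad_scale = model@madScale,
    config = model@config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @param panel optional \linkS4class{CnvPanel}; when given, its fingerprint
#'   must match the model's.
#' @export
loadModel <- function(path, panel = NULL) {
  if (!file.exists(path)) .inputError("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "panelCNV-model-1"))
    .inputError("not a panelCNV model file: ", path)
  model <- new("CnvModel",
    panelFingerprint = obj$panel_fingerprint,
    center = stats::setNames(obj$center, obj$groups),
    rotation = matrix(obj$rotation, obj$rotation_dim[1], obj$rotation_dim[2]),
    sdev = as.numeric(obj$sdev),
    sigma = stats::setNames(obj$sigma, obj$groups),
    zCut = unlist(obj$z_cut), zadjCut = unlist(obj$zadj_cut),
    nTraining = as.integer(obj$n_training),
    targetSpecificity = obj$target_specificity,
    madScale = obj$mad_scale,
    config = lapply(obj$config, function(x)
      if (length(x) == 0) character() else x))
  if (!is.null(panel) &&
      !identical(panelFingerprint(panel), model@panelFingerprint))
    .inputError("panel fingerprint does not match the model (different ",
                "capture design or bin/group layout)")
  model
}
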