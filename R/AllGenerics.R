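#' @include AllClasses.R
NULL

#' @export
setGeneric("panelName", function(x) standardGeneric("panelName"))
#' @export
setGeneric("panelTargets", function(x, ...) standardGeneric("panelTargets"))
#' @export
setGeneric("panelGroups", function(x) standardGeneric("panelGroups"))
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))
#' @export
setGeneric("binTargets", function(x, ...) standardGeneric("binTargets"))
#' @export
setGeneric("depthValues", function(x) standardGeneric("depthValues"))
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))
#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))
#' @export
setGeneric("normStage", function(x) standardGeneric("normStage"))
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))
#' @export
setGeneric("groupInfo", function(x) standardGeneric("groupInfo"))
#' @export
setGeneric("specimenInfo", function(x) standardGeneric("specimenInfo"))
#' @export
setGeneric("sigmaValues", function(x) standardGeneric("sigmaValues"))
#' @export
setGeneric("cutoffValues", function(x) standardGeneric("cutoffValues"))
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))
#' @export
setGeneric("zadjValues", function(x) standardGeneric("zadjValues"))
#' @export
setGeneric("flagValues", function(x) standardGeneric("flagValues"))

## ---- CnvPanel accessors ----

#' @describeIn CnvPanel panel name
#' @param x a CnvPanel
#' @export
setMethod("panelName", "CnvPanel", function(x) x@name)

#' @describeIn CnvPanel all targets as GRanges (exons, bins, promoters)
#' @param kind optionally restrict to one target kind
#' @param ... unused
#' @export
setMethod("panelTargets", "CnvPanel", function(x, kind = NULL, ...) {
  gr <- x@targets
  if (!is.null(kind)) gr <- gr[S4Vectors::mcols(gr)$kind %in% kind]
  gr
})

#' @describeIn CnvPanel target-group table
#' @export
setMethod("panelGroups", "CnvPanel", function(x) x@groups)

#' @describeIn CnvPanel gene names, in genomic order of first target
#' @export
setMethod("panelGenes", "CnvPanel", function(x) {
  unique(S4Vectors::mcols(x@targets)$gene)
})

#' @describeIn CnvPanel bin targets in genomic order
#' @param includeMasked keep masked bins (default TRUE)
#' @export
setMethod("binTargets", "CnvPanel", function(x, includeMasked = TRUE, ...) {
  gr <- panelTargets(x, kind = "bin")
  if (!includeMasked) gr <- gr[!S4Vectors::mcols(gr)$masked]
  gr
})

setMethod("show", "CnvPanel", function(object) {
  tg <- S4Vectors::mcols(object@targets)
  cat("CnvPanel:", object@name, "\n")
  cat(" ", length(panelGenes(object)), "genes;",
      sum(tg$kind == "exon"), "exons;",
      sum(tg$kind == "bin"), "bins (",
      sum(tg$kind == "bin" & tg$masked), "masked ); bin size",
      object@binSize, "\n")
  if (nrow(object@groups))
    cat("  groups:", paste(sprintf("%s=%d", names(table(object@groups$level)),
                                   table(object@groups$level)), collapse = ", "), "\n")
  else cat("  groups: none (run makeTargetGroups)\n")
})

## ---- DepthMatrix accessors ----

#' @describeIn DepthMatrix the depth assay matrix (bins x specimens)
#' @param x a DepthMatrix
#' @export
setMethod("depthValues", "DepthMatrix", function(x) assay(x, "depth"))

#' @describeIn DepthMatrix per-specimen batch labels
#' @export
setMethod("batchLabels", "DepthMatrix", function(x) colData(x)$batch)

#' @describeIn DepthMatrix per-specimen QC state
#' @export
setMethod("qcPass", "DepthMatrix", function(x) colData(x)$qc_pass)

#' @describeIn DepthMatrix specimen ids
#' @export
setMethod("specimenIds", "DepthMatrix", function(x) colData(x)$specimen_id)

setMethod("show", "DepthMatrix", function(object) {
  cat("DepthMatrix:", nrow(object), "bins x", ncol(object), "specimens;",
      length(unique(batchLabels(object))), "batch(es);",
      sum(!qcPass(object)), "QC-fail\n")
  cat("  mean depth:", round(mean(depthValues(object)), 1), "\n")
})

## ---- NormalizedMatrix accessors ----

#' @describeIn NormalizedMatrix normalization stage
#' @param x a NormalizedMatrix
#' @export
setMethod("normStage", "NormalizedMatrix", function(x) x@stage)

#' @describeIn NormalizedMatrix value matrix (groups x specimens)
#' @export
setMethod("normValues", "NormalizedMatrix", function(x) x@values)

#' @describeIn NormalizedMatrix group annotation
#' @export
setMethod("groupInfo", "NormalizedMatrix", function(x) x@groupInfo)

#' @describeIn NormalizedMatrix specimen annotation
#' @export
setMethod("specimenInfo", "NormalizedMatrix", function(x) x@specimenInfo)

setMethod("show", "NormalizedMatrix", function(object) {
  cat("NormalizedMatrix [stage ", object@stage, "]: ",
      nrow(object@values), " groups x ", ncol(object@values), " specimens\n",
      sep = "")
})

## ---- CnvModel accessors ----

#' @describeIn CnvModel per-group sigma (scaled MAD of X)
#' @param x a CnvModel
#' @export
setMethod("sigmaValues", "CnvModel", function(x) x@sigma)

#' @describeIn CnvModel per-level cutoffs as a data.frame
#' @export
setMethod("cutoffValues", "CnvModel", function(x) {
  data.frame(level = names(x@zCut), z_cut = unname(x@zCut),
             zadj_cut = unname(x@zadjCut[names(x@zCut)]))
})

setMethod("show", "CnvModel", function(object) {
  cat("CnvModel: trained on", object@nTraining, "specimens;",
      ncol(object@rotation), "principal component(s)\n")
  cat("  target specificity:", object@targetSpecificity,
      "; unscorable groups:", sum(object@sigma == 0), "\n")
  print(cutoffValues(object), row.names = FALSE)
})

## ---- ScoreMatrix accessors ----

#' @describeIn ScoreMatrix Z score matrix
#' @param x a ScoreMatrix
#' @export
setMethod("zValues", "ScoreMatrix", function(x) x@Z)

#' @describeIn ScoreMatrix Z.adj score matrix
#' @export
setMethod("zadjValues", "ScoreMatrix", function(x) x@Zadj)

#' @describeIn ScoreMatrix logical flag matrix
#' @export
setMethod("flagValues", "ScoreMatrix", function(x) x@flags)

#' @describeIn ScoreMatrix group annotation
#' @export
setMethod("groupInfo", "ScoreMatrix", function(x) x@groupInfo)

#' @describeIn ScoreMatrix specimen annotation
#' @export
setMethod("specimenInfo", "ScoreMatrix", function(x) x@specimenInfo)

setMethod("show", "ScoreMatrix", function(object) {
  nf <- sum(object@flags, na.rm = TRUE)
  cat("ScoreMatrix:", nrow(object@Z), "groups x", ncol(object@Z),
      "specimens;", nf, "flagged cell(s) in",
      sum(colSums(object@flags, na.rm = TRUE) > 0), "specimen(s)\n")
})
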