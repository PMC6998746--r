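#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges CharacterList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames colData colData<- rowData
NULL

## Group hierarchy levels, ordered from finest to coarsest.
GROUP_LEVELS <- c("single_bin", "exon", "multi_exon_window", "whole_gene")

#' CnvPanel: a capture panel as genes, exons, bins and target groups
#'
#' Holds the coordinate backbone of the analysis: exon (and promoter/intronic)
#' targets of a capture design as a \linkS4class{GRanges}, the ~200 bp bins
#' derived from them, and the hierarchical target groups (single bin, exon,
#' multi-exon window, whole gene) that are scored jointly. All coordinates are
#' 0-based half-open internally (BED convention); \code{GRanges} display is
#' 1-based formatting only.
#'
#' @slot name panel name.
#' @slot targets \code{GRanges} of exon/bin/promoter/intronic targets with
#'   metadata columns \code{target_id}, \code{gene}, \code{kind},
#'   \code{exon_index}, \code{parent_id} (for bins) and \code{masked}.
#' @slot groups \code{DataFrame} of target groups: \code{group_id},
#'   \code{gene}, \code{level}, \code{chrom}, \code{start}, \code{end},
#'   \code{first_exon}, \code{last_exon} and \code{members}
#'   (a \code{CharacterList} of bin target ids, contiguous in genomic order).
#' @slot binSize requested bin size in bp (\code{NA} before binning).
#'
#' @export
setClass("CnvPanel",
  representation(name = "character", targets = "GRanges",
                 groups = "DataFrame", binSize = "numeric"))

setValidity("CnvPanel", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object@targets)
  need <- c("target_id", "gene", "kind", "exon_index", "parent_id", "masked")
  if (!all(need %in% colnames(mc)))
    msg <- c(msg, paste("targets must carry mcols:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(mc$target_id)) msg <- c(msg, "duplicate target ids")
    if (!all(mc$kind %in% c("exon", "bin", "promoter", "intronic")))
      msg <- c(msg, "unknown target kind")
  }
  if (nrow(object@groups) > 0) {
    if (anyDuplicated(object@groups$group_id)) msg <- c(msg, "duplicate group ids")
    if (!all(object@groups$level %in% GROUP_LEVELS)) msg <- c(msg, "unknown group level")
  }
  if (length(msg)) msg else TRUE
})

#' DepthMatrix: per-bin, per-specimen read depth
#'
#' A \linkS4class{SummarizedExperiment} whose \code{"depth"} assay holds the
#' mean per-base read depth of each bin (rows) in each specimen (columns).
#' \code{colData} carries \code{specimen_id}, \code{batch} and \code{qc_pass};
#' simulated matrices additionally keep their latent negative-binomial means in
#' a \code{"mu"} assay so that CNV spike-in and replicate re-draws can resample
#' from the same noise law.
#'
#' @export
setClass("DepthMatrix", contains = "SummarizedExperiment")

setValidity("DepthMatrix", function(object) {
  msg <- character()
  if (!"depth" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "missing 'depth' assay")
  else if (any(assay(object, "depth") < 0, na.rm = TRUE))
    msg <- c(msg, "depth values must be >= 0")
  cd <- colData(object)
  if (!all(c("specimen_id", "batch", "qc_pass") %in% colnames(cd)))
    msg <- c(msg, "colData must carry specimen_id, batch, qc_pass")
  else if (any(is.na(cd$batch)) || any(!nzchar(cd$batch)))
    msg <- c(msg, "batch labels must be nonempty")
  if (!"target_id" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must carry target_id")
  if (length(msg)) msg else TRUE
})

#' NormalizedMatrix: staged group-level coverage values
#'
#' Values per target group (rows) per specimen (columns) at one stage of the
#' normalization chain: \code{RD} (length-weighted group read depth),
#' \code{RDr} (relative depth: RD over the specimen's mean single-bin depth),
#' \code{RDrp} (RDr after principal-component denoising) or \code{X}
#' (RDrp over the specimen's median single-bin RDrp).
#'
#' @slot stage one of \code{"RD"}, \code{"RDr"}, \code{"RDrp"}, \code{"X"}.
#' @slot values numeric matrix, groups x specimens.
#' @slot groupInfo \code{DataFrame}: \code{group_id}, \code{gene},
#'   \code{level}, \code{n_bins}, \code{length}.
#' @slot specimenInfo \code{DataFrame}: \code{specimen_id}, \code{batch},
#'   \code{qc_pass}, \code{scorable}.
#'
#' @export
setClass("NormalizedMatrix",
  representation(stage = "character", values = "matrix",
                 groupInfo = "DataFrame", specimenInfo = "DataFrame"))

setValidity("NormalizedMatrix", function(object) {
  msg <- character()
  if (!object@stage %in% c("RD", "RDr", "RDrp", "X"))
    msg <- c(msg, "stage must be RD, RDr, RDrp or X")
  if (nrow(object@values) != nrow(object@groupInfo))
    msg <- c(msg, "row count does not match groupInfo")
  if (ncol(object@values) != nrow(object@specimenInfo))
    msg <- c(msg, "column count does not match specimenInfo")
  if (length(msg)) msg else TRUE
})

#' CnvModel: trained normalization basis, dispersions and cutoffs
#'
#' Everything learned from a training cohort that production batches are scored
#' against: the principal-component basis fitted on training RDr, the per-group
#' robust dispersion sigma (scaled median absolute deviation of X) and the
#' per-level flagging cutoffs for |Z| and |Z.adj| calibrated to a target
#' specimen-level specificity. A fingerprint of the panel geometry guards
#' against applying a model to a different capture design.
#'
#' @slot panelFingerprint fingerprint of the panel the model was trained on.
#' @slot center per-group training mean of RDr (PCA center).
#' @slot rotation loading matrix (groups x components), possibly 0 columns.
#' @slot sdev standard deviations of the retained components.
#' @slot sigma named per-group dispersion of X; 0 marks unscorable groups.
#' @slot zCut,zadjCut named per-level cutoffs on |Z| and |Z.adj|.
#' @slot nTraining number of training specimens.
#' @slot targetSpecificity specimen-level specificity the cutoffs target.
#' @slot madScale MAD scale factor (1.4826 for normal consistency).
#' @slot config miscellaneous provenance (seed, alpha, flag rule, ...).
#'
#' @export
setClass("CnvModel",
  representation(panelFingerprint = "character", center = "numeric",
                 rotation = "matrix", sdev = "numeric", sigma = "numeric",
                 zCut = "numeric", zadjCut = "numeric", nTraining = "integer",
                 targetSpecificity = "numeric", madScale = "numeric",
                 config = "list"))

setValidity("CnvModel", function(object) {
  msg <- character()
  if (any(object@sigma < 0, na.rm = TRUE)) msg <- c(msg, "sigma must be >= 0")
  if (any(c(object@zCut, object@zadjCut) <= 0, na.rm = TRUE))
    msg <- c(msg, "cutoffs must be > 0")
  if (object@targetSpecificity < 0 || object@targetSpecificity > 1)
    msg <- c(msg, "targetSpecificity must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ScoreMatrix: Z and Z.adj scores with flags
#'
#' Per-group, per-specimen scores of one batch run: \code{Z = (X - mu) / sigma}
#' with \code{mu} the batch median of X and \code{sigma} the trained
#' dispersion, and \code{Z.adj}, the Z score divided by the standard deviation
#' of the specimen's Z over the other groups of the same level. \code{flags}
#' marks groups exceeding the trained cutoffs; \code{flagSource} records which
#' statistic fired (\code{"Z"}, \code{"Zadj"}, \code{"both"}, \code{"none"}).
#'
#' @export
setClass("ScoreMatrix",
  representation(Z = "matrix", Zadj = "matrix", mu = "matrix",
                 flags = "matrix", flagSource = "matrix",
                 groupInfo = "DataFrame", specimenInfo = "DataFrame"))

setValidity("ScoreMatrix", function(object) {
  d <- dim(object@Z)
  ok <- identical(d, dim(object@Zadj)) && identical(d, dim(object@mu)) &&
    identical(d, dim(object@flags)) && identical(d, dim(object@flagSource))
  if (!ok) return("score matrices must share dimensions")
  if (nrow(object@Z) != nrow(object@groupInfo) ||
      ncol(object@Z) != nrow(object@specimenInfo))
    return("dimensions do not match group/specimen info")
  TRUE
})
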