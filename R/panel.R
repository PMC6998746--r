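#' @include AllClasses.R AllGenerics.R
NULL

#' Load a capture panel from a BED file
#'
#' Reads a BED4+ interval file describing the exon (and optionally promoter or
#' intronic) targets of a capture design. The name field is expected to be
#' \code{"GENE|exNN"}, \code{"GENE|promoter"} or \code{"GENE|intronic"},
#' optionally suffixed with \code{"|masked"}. BED coordinates are 0-based
#' half-open; they are held in a \code{GRanges} (1-based display is formatting
#' only) and written back out 0-based. Targets are stably sorted by
#' (chrom, start). Lines starting with \code{#} are ignored.
#'
#' @param path path to the BED file.
#' @param geneColumn 1-based index of the column carrying the
#'   \code{"GENE|exNN"} label (default 4, the BED name field).
#' @param name panel name (default: file base name).
#' @return a \linkS4class{CnvPanel} with exon-level targets and no bins or
#'   groups yet (see \code{\link{makeBins}}, \code{\link{makeTargetGroups}}).
#' @examples
#' bed <- system.file("extdata", "demo_panel_synthetic.bed", package = "panelCNV")
#' panel <- loadPanelBed(bed)
#' length(panelGenes(panel))
#' @export
loadPanelBed <- function(path, geneColumn = 4, name = NULL) {
  if (!file.exists(path)) .inputError("panel BED not found: ", path)
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) .inputError("panel BED has no interval lines: ", path)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < geneColumn))
    .inputError("malformed BED line ", keep[which(nf < geneColumn)[1]],
                ": fewer than ", geneColumn, " columns")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    .inputError("malformed BED line ", keep[bad[1]], ": non-numeric coordinates")
  bad <- which(end <= start)
  if (length(bad))
    .inputError("malformed BED line ", keep[bad[1]], ": end must be > start")
  label <- vapply(fields, `[[`, "", geneColumn)
  parts <- strsplit(label, "|", fixed = TRUE)
  gene <- vapply(parts, `[[`, "", 1)
  anno <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "ex1", "")
  masked <- vapply(parts, function(p) "masked" %in% p[-1], NA)
  kind <- ifelse(anno == "promoter", "promoter",
                 ifelse(anno == "intronic", "intronic", "exon"))
  exon_index <- ifelse(kind == "exon",
                       suppressWarnings(as.integer(sub("^ex", "", anno))), NA_integer_)
  if (any(kind == "exon" & is.na(exon_index)))
    .inputError("malformed BED line ",
                keep[which(kind == "exon" & is.na(exon_index))[1]],
                ": cannot parse exon label '",
                anno[which(kind == "exon" & is.na(exon_index))[1]], "'")
  ord <- order(chrom, start)  # stable
  gr <- GRanges(chrom[ord], IRanges(start[ord] + 1L, end[ord]))
  S4Vectors::mcols(gr) <- DataFrame(
    target_id = ifelse(kind[ord] == "exon",
                       sprintf("%s_ex%d", gene[ord], exon_index[ord]),
                       paste0(gene[ord], "_", kind[ord])),
    gene = gene[ord], kind = kind[ord], exon_index = exon_index[ord],
    parent_id = NA_character_, masked = masked[ord])
  ## overlapping exons within a gene are a design error
  ex <- gr[S4Vectors::mcols(gr)$kind == "exon"]
  for (g in unique(S4Vectors::mcols(ex)$gene)) {
    sub <- ex[S4Vectors::mcols(ex)$gene == g]
    hits <- GenomicRanges::findOverlaps(sub, drop.self = TRUE)
    if (length(hits)) .inputError("overlapping exons within gene ", g)
  }
  if (anyDuplicated(S4Vectors::mcols(gr)$target_id))
    .inputError("duplicate target labels in BED (gene/exon combination repeated)")
  new("CnvPanel", name = name %||% sub("\\.bed$", "", basename(path)),
      targets = gr, groups = DataFrame(), binSize = NA_real_)
}

#' Partition exon targets into nonoverlapping bins
#'
#' Each exon of length L is split into \code{ceiling(L / binSize)} contiguous,
#' nonoverlapping bins of near-equal length (all within one base of each
#' other); the bins tile the exon exactly. Exons no longer than
#' \code{binSize} yield a single bin. Bins inherit the parent exon's mask
#' state. Existing bins (and groups) are rebuilt.
#'
#' @param panel a \linkS4class{CnvPanel}.
#' @param binSize target bin length in bp (default 200, minimum 50).
#' @return the panel with bin targets added.
#' @export
makeBins <- function(panel, binSize = 200) {
  stopifnot(is(panel, "CnvPanel"))
  if (binSize < 50) .inputError("binSize must be >= 50")
  gr <- panel@targets
  gr <- gr[S4Vectors::mcols(gr)$kind != "bin"]  # rebuild from scratch
  ex <- gr[S4Vectors::mcols(gr)$kind == "exon"]
  nb <- as.integer(ceiling(width(ex) / binSize))
  base <- width(ex) %/% nb
  rem <- width(ex) %% nb
  exIdx <- rep(seq_along(ex), nb)
  binNo <- sequence(nb)
  lens <- ifelse(binNo <= rem[exIdx], base[exIdx] + 1L, base[exIdx])
  off <- unlist(lapply(split(lens, factor(exIdx, levels = unique(exIdx))),
                       function(l) cumsum(c(0L, l[-length(l)]))),
                use.names = FALSE)
  emc <- S4Vectors::mcols(ex)
  bingr <- GRanges(as.character(seqnames(ex))[exIdx],
                   IRanges(start(ex)[exIdx] + off, width = lens))
  S4Vectors::mcols(bingr) <- DataFrame(
    target_id = sprintf("%s_b%02d", emc$target_id[exIdx], binNo),
    gene = emc$gene[exIdx], kind = "bin", exon_index = emc$exon_index[exIdx],
    parent_id = emc$target_id[exIdx], masked = emc$masked[exIdx])
  allt <- suppressWarnings(c(gr, bingr))
  ord <- order(as.character(seqnames(allt)), start(allt),
               S4Vectors::mcols(allt)$kind != "exon")  # exon before its bins
  panel@targets <- allt[ord]
  panel@binSize <- binSize
  if (nrow(panel@groups) > 0) panel <- makeTargetGroups(panel)
  validObject(panel)
  panel
}

#' Build the hierarchical target groups
#'
#' Per gene, groups are created at four levels from the unmasked bins:
#' every single bin; every exon (its bins joined); sliding multi-exon windows
#' of each size in \code{windowSizes} (step one exon, within runs of
#' consecutive unmasked exons); and the whole gene (all unmasked bins).
#' Groups that would contain only masked bins are dropped; promoter and
#' intronic targets are not grouped. Larger groups average depth over more
#' bases and so amplify the signal of large events (multi-exon and whole-gene
#' deletions/duplications) relative to bin-level noise.
#'
#' @param panel a \linkS4class{CnvPanel} with bins (see \code{\link{makeBins}}).
#' @param windowSizes multi-exon window sizes (default \code{c(2, 4, 8)}).
#' @param includeWholeGene add a whole-gene group per gene (default TRUE).
#' @return the panel with the group table populated.
#' @export
makeTargetGroups <- function(panel, windowSizes = c(2, 4, 8),
                             includeWholeGene = TRUE) {
  stopifnot(is(panel, "CnvPanel"))
  bins <- binTargets(panel, includeMasked = FALSE)
  if (length(bins) == 0) .inputError("no unmasked bins; run makeBins first")
  mc <- S4Vectors::mcols(bins)
  rows <- list()
  addGroup <- function(gid, gene, level, idx, first_ex, last_ex) {
    sub <- bins[idx]
    rows[[length(rows) + 1L]] <<- list(
      group_id = gid, gene = gene, level = level,
      chrom = as.character(seqnames(sub))[1],
      start = min(start(sub)) - 1L, end = max(end(sub)),
      first_exon = first_ex, last_exon = last_ex,
      members = list(mc$target_id[idx]))
  }
  for (g in unique(mc$gene)) {
    gi <- which(mc$gene == g)
    ex_of <- mc$exon_index[gi]
    exons <- sort(unique(ex_of))
    for (i in gi)
      addGroup(paste0("sb:", mc$target_id[i]), g, "single_bin", i,
               mc$exon_index[i], mc$exon_index[i])
    for (e in exons)
      addGroup(sprintf("ex:%s_ex%d", g, e), g, "exon", gi[ex_of == e], e, e)
    ## multi-exon windows slide within runs of consecutive unmasked exons
    runs <- split(exons, cumsum(c(1L, diff(exons) != 1L)))
    for (w in windowSizes) {
      for (run in runs) {
        if (length(run) < w) next
        for (s in seq_len(length(run) - w + 1L)) {
          win <- run[s:(s + w - 1L)]
          addGroup(sprintf("w%d:%s_ex%d-%d", w, g, win[1], win[w]), g,
                   "multi_exon_window", gi[ex_of %in% win], win[1], win[w])
        }
      }
    }
    if (includeWholeGene)
      addGroup(paste0("wg:", g), g, "whole_gene", gi, min(exons), max(exons))
  }
  df <- DataFrame(
    group_id = vapply(rows, `[[`, "", "group_id"),
    gene = vapply(rows, `[[`, "", "gene"),
    level = vapply(rows, `[[`, "", "level"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), 0L),
    end = vapply(rows, function(r) as.integer(r$end), 0L),
    first_exon = vapply(rows, function(r) as.integer(r$first_exon), 0L),
    last_exon = vapply(rows, function(r) as.integer(r$last_exon), 0L),
    members = CharacterList(lapply(rows, function(r) r$members[[1]])))
  panel@groups <- df
  validObject(panel)
  panel
}

#' Default pseudogene mask
#'
#' Regions excluded from copy number analysis because highly homologous
#' pseudogene sequence makes their read depth uninterpretable: PMS2 (PMS2CL)
#' and CHEK2 exons 11-15.
#'
#' @return named list of \code{c(first_exon, last_exon)} ranges.
#' @export
defaultMaskRegions <- function() {
  list(PMS2 = c(11L, 15L), CHEK2 = c(11L, 15L))
}

#' Mask exon ranges from copy number analysis
#'
#' Marks the exons (and their bins) of the named genes as masked; masked
#' targets never contribute to normalization statistics, groups or flags.
#' Groups are rebuilt if already present. Applying the same mask twice is a
#' no-op.
#'
#' @param panel a \linkS4class{CnvPanel}.
#' @param maskRegions named list: gene -> \code{c(first_exon, last_exon)}, or
#'   \code{"*"} to mask the whole gene. An empty list leaves the panel
#'   unchanged.
#' @return the masked panel.
#' @export
applyMask <- function(panel, maskRegions = defaultMaskRegions()) {
  stopifnot(is(panel, "CnvPanel"))
  if (length(maskRegions) == 0) return(panel)
  mc <- S4Vectors::mcols(panel@targets)
  for (g in names(maskRegions)) {
    hit <- mc$gene == g & mc$kind %in% c("exon", "bin")
    if (!any(hit)) .inputError("mask names unknown gene: ", g)
    rg <- maskRegions[[g]]
    if (identical(rg, "*")) {
      mc$masked[hit] <- TRUE
    } else {
      if (length(rg) != 2 || any(is.na(rg)))
        .inputError("mask range for ", g, " must be c(first, last) or \"*\"")
      mc$masked[hit & mc$exon_index >= rg[1] & mc$exon_index <= rg[2]] <- TRUE
    }
  }
  S4Vectors::mcols(panel@targets) <- mc
  if (nrow(panel@groups) > 0) panel <- makeTargetGroups(panel)
  panel
}

#' Fingerprint of the panel geometry
#'
#' A stable hash over bin coordinates, mask state and group membership, used
#' to refuse applying a trained model to a different capture design.
#'
#' @param panel a \linkS4class{CnvPanel}.
#' @return character fingerprint.
#' @export
panelFingerprint <- function(panel) {
  bins <- binTargets(panel)
  mc <- S4Vectors::mcols(bins)
  gs <- panel@groups
  .polyHash(c(
    sprintf("%s:%s:%d:%d:%d", mc$target_id, as.character(seqnames(bins)),
            start(bins), end(bins), as.integer(mc$masked)),
    if (nrow(gs)) sprintf("%s=%s", gs$group_id,
                          vapply(gs$members, paste, "", collapse = ","))))
}

#' Write / read a panel as JSON
#'
#' Serializes targets and groups for reproducibility; \code{readPanelJson}
#' restores an identical panel.
#'
#' @param panel a \linkS4class{CnvPanel}.
#' @param path output (input) file path.
#' @return \code{writePanelJson}: the path, invisibly. \code{readPanelJson}:
#'   the restored \linkS4class{CnvPanel}.
#' @export
writePanelJson <- function(panel, path) {
  gr <- panel@targets
  mc <- S4Vectors::mcols(gr)
  obj <- list(
    name = panel@name, bin_size = panel@binSize,
    targets = data.frame(
      target_id = mc$target_id, gene = mc$gene, kind = mc$kind,
      exon_index = mc$exon_index, parent_id = mc$parent_id,
      masked = mc$masked, chrom = as.character(seqnames(gr)),
      start = start(gr) - 1L, end = end(gr)),
    groups = if (nrow(panel@groups)) {
      gdf <- as.data.frame(panel@groups[, setdiff(colnames(panel@groups), "members")])
      gdf$members <- vapply(panel@groups$members, paste, "", collapse = ",")
      gdf
    })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writePanelJson
#' @export
readPanelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  t <- obj$targets
  gr <- GRanges(t$chrom, IRanges(t$start + 1L, t$end))
  S4Vectors::mcols(gr) <- DataFrame(
    target_id = t$target_id, gene = t$gene, kind = t$kind,
    exon_index = as.integer(t$exon_index), parent_id = as.character(t$parent_id),
    masked = t$masked)
  groups <- DataFrame()
  if (!is.null(obj$groups) && length(obj$groups)) {
    g <- obj$groups
    groups <- DataFrame(
      group_id = g$group_id, gene = g$gene, level = g$level, chrom = g$chrom,
      start = as.integer(g$start), end = as.integer(g$end),
      first_exon = as.integer(g$first_exon), last_exon = as.integer(g$last_exon),
      members = CharacterList(strsplit(g$members, ",", fixed = TRUE)))
  }
  new("CnvPanel", name = obj$name, targets = gr, groups = groups,
      binSize = obj$bin_size %||% NA_real_)
}

#' The packaged 34-gene demonstration panel
#'
#' Loads the synthetic-coordinate demonstration panel shipped with the
#' package (34 hereditary-cancer genes; gene list mirrors a clinical
#' inherited-cancer capture design, coordinates are synthetic), bins it,
#' applies the default pseudogene mask and builds target groups.
#'
#' @param binSize bin size in bp (default 200).
#' @param mask mask regions (default \code{\link{defaultMaskRegions}()});
#'   \code{NULL} for no mask.
#' @param windowSizes multi-exon window sizes (default \code{c(2, 4, 8)}).
#' @return a ready-to-use \linkS4class{CnvPanel}.
#' @export
demoPanel <- function(binSize = 200, mask = defaultMaskRegions(),
                      windowSizes = c(2, 4, 8)) {
  bed <- system.file("extdata", "demo_panel_synthetic.bed", package = "panelCNV")
  panel <- loadPanelBed(bed, name = "demo34")
  panel <- makeBins(panel, binSize = binSize)
  if (length(mask)) panel <- applyMask(panel, mask)
  makeTargetGroups(panel, windowSizes = windowSizes)
}
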