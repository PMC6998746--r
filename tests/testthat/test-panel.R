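test_that("BED parsing builds sorted exon targets with correct lengths", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr17\t100\t600\tBRCA1|ex1", bed)
  p <- loadPanelBed(bed)
  ex <- panelTargets(p, kind = "exon")
  expect_length(ex, 1)
  expect_equal(GenomicRanges::width(ex), 500)
  expect_equal(S4Vectors::mcols(ex)$gene, "BRCA1")

  # out-of-order input is sorted by (chrom, start)
  writeLines(c("chr2\t500\t700\tG|ex2", "chr1\t900\t950\tH|ex1",
               "chr2\t100\t300\tG|ex1"), bed)
  p2 <- loadPanelBed(bed)
  ex2 <- panelTargets(p2, kind = "exon")
  expect_equal(as.character(GenomicRanges::seqnames(ex2)),
               c("chr1", "chr2", "chr2"))
  expect_equal(GenomicRanges::start(ex2) - 1L, c(900L, 100L, 500L))
})

test_that("malformed and overlapping BED inputs fail with line context", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tG|ex1", "chr1\txx\t300\tG|ex2"), bed)
  expect_error(loadPanelBed(bed), "line 2")
  writeLines(c("chr1\t100\t200\tG|ex1", "chr1\t150\t300\tG|ex2"), bed)
  expect_error(loadPanelBed(bed), "overlapping")
  writeLines("chr1\t200\t100\tG|ex1", bed)
  expect_error(loadPanelBed(bed), "end must be > start")
})

test_that("the shipped demonstration panel has the 34-gene design", {
  p <- getDemoPanel()
  expect_length(panelGenes(p), 34)
  expect_true(all(c("BRCA1", "BRCA2", "PMS2", "CHEK2", "EPCAM") %in%
                    panelGenes(p)))
  # pseudogene mask: PMS2/CHEK2 exons 11-15 carry no groups
  gs <- panelGroups(p)
  for (g in c("PMS2", "CHEK2")) {
    expect_equal(max(gs$last_exon[gs$gene == g]), 10L)
    wg <- gs[gs$gene == g & gs$level == "whole_gene", ]
    expect_equal(c(wg$first_exon, wg$last_exon), c(1L, 10L))
  }
})

test_that("binning tiles every exon exactly with near-equal bins", {
  p <- tinyPanel()
  bins <- binTargets(p)
  mc <- S4Vectors::mcols(bins)
  # forced arithmetic: 500 bp at bin size 200 -> 3 bins of 167/167/166
  b1 <- bins[mc$parent_id %in% "GA_ex1"]
  expect_equal(sort(GenomicRanges::width(b1), decreasing = TRUE),
               c(167, 167, 166))
  # 120 bp -> single bin; 400 bp -> two bins of exactly 200
  expect_equal(GenomicRanges::width(bins[mc$parent_id %in% "GA_ex2"]), 120)
  expect_equal(GenomicRanges::width(bins[mc$parent_id %in% "GA_ex3"]),
               c(200, 200))
  # tiling conservation on every exon of the demo panel
  dp <- getDemoPanel()
  dbins <- binTargets(dp)
  perExon <- tapply(GenomicRanges::width(dbins),
                    S4Vectors::mcols(dbins)$parent_id, sum)
  ex <- panelTargets(dp, kind = "exon")
  expect_equal(as.vector(perExon[S4Vectors::mcols(ex)$target_id]),
               GenomicRanges::width(ex))
  # bins within an exon are disjoint and cover it
  ir <- GenomicRanges::ranges(dbins)
  byExon <- split(ir, S4Vectors::mcols(dbins)$parent_id)
  ov <- vapply(byExon, function(x) sum(GenomicRanges::width(
    IRanges::reduce(x))), 0)
  expect_equal(unname(ov[S4Vectors::mcols(ex)$target_id]),
               GenomicRanges::width(ex))
  expect_error(makeBins(p, binSize = 10), "binSize")
})

test_that("group construction enumerates the hierarchy per gene", {
  p <- tinyPanel(windowSizes = 2)
  gs <- panelGroups(p)
  ga <- gs[gs$gene == "GA", ]
  # 5 exons, window size 2: 5 exon groups + 4 windows + 1 whole gene
  expect_equal(sum(ga$level == "exon"), 5)
  expect_equal(sum(ga$level == "multi_exon_window"), 4)
  expect_equal(sum(ga$level == "whole_gene"), 1)
  expect_equal(sum(ga$level == "single_bin"),
               sum(S4Vectors::mcols(binTargets(p))$gene == "GA"))
  # degenerate single-exon single-bin gene: both levels retained, ids distinct
  gc <- gs[gs$gene == "GC", ]
  expect_setequal(gc$level, c("single_bin", "exon", "whole_gene"))
  expect_equal(anyDuplicated(gc$group_id), 0L)
  expect_equal(length(unique(gc$start)), 1L)
  # group closure: whole-gene groups cover exactly the unmasked bins
  covered <- sort(unique(unlist(gs$members[gs$level == "whole_gene"])))
  unmasked <- sort(S4Vectors::mcols(binTargets(p, includeMasked = FALSE))$target_id)
  expect_equal(covered, unmasked)
})

test_that("masking is idempotent, honored by groups, and validated", {
  p <- tinyPanel()
  m1 <- applyMask(p, list(GA = c(4, 5)))
  m2 <- applyMask(m1, list(GA = c(4, 5)))
  expect_equal(panelGroups(m1), panelGroups(m2))
  expect_equal(panelFingerprint(m1), panelFingerprint(m2))
  # no group spans a masked bin
  gs <- panelGroups(m1)
  maskedIds <- S4Vectors::mcols(binTargets(m1))$target_id[
    S4Vectors::mcols(binTargets(m1))$masked]
  expect_false(any(unlist(gs$members) %in% maskedIds))
  expect_equal(max(gs$last_exon[gs$gene == "GA"]), 3L)
  # empty mask is the identity; whole-gene mask removes the gene's groups
  expect_equal(panelGroups(applyMask(p, list())), panelGroups(p))
  whole <- applyMask(p, list(GC = "*"))
  expect_false("GC" %in% panelGroups(whole)$gene)
  expect_error(applyMask(p, list(NOPE = c(1, 2))), "unknown gene")
})

test_that("masking interior exons keeps windows within unmasked runs", {
  p <- tinyPanel(windowSizes = 2)
  m <- applyMask(p, list(GA = c(3, 3)))
  gs <- panelGroups(m)
  win <- gs[gs$gene == "GA" & gs$level == "multi_exon_window", ]
  # runs are {1,2} and {4,5}: windows 1-2 and 4-5 only
  expect_setequal(paste(win$first_exon, win$last_exon),
                  c("1 2", "4 5"))
})

test_that("panel JSON round-trips losslessly", {
  p <- tinyPanel()
  f <- tempfile(fileext = ".json")
  writePanelJson(p, f)
  q <- readPanelJson(f)
  expect_equal(panelFingerprint(p), panelFingerprint(q))
  expect_equal(panelGroups(p)$group_id, panelGroups(q)$group_id)
  expect_equal(S4Vectors::mcols(panelTargets(p))$target_id,
               S4Vectors::mcols(panelTargets(q))$target_id)
})
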