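# Shared fixtures, built in code. Heavy objects (demo panel, trained null
# model) are cached per test session.

.cache <- new.env(parent = emptyenv())

# A small 3-gene panel: GA has 5 exons incl. a 500 bp one (multi-bin),
# GB 2 exons, GC a single 1-bin exon (degenerate gene).
tinyBedLines <- function() {
  c("# tiny test panel",
    "chr1\t1000\t1500\tGA|ex1",     # 500 bp -> 3 bins of 167/167/166
    "chr1\t2000\t2120\tGA|ex2",     # 120 bp -> 1 bin
    "chr1\t3000\t3400\tGA|ex3",     # 400 bp -> 2 bins of 200
    "chr1\t4000\t4180\tGA|ex4",
    "chr1\t5000\t5210\tGA|ex5",
    "chr2\t1000\t1250\tGB|ex1",
    "chr2\t2000\t2220\tGB|ex2",
    "chr3\t500\t680\tGC|ex1")
}

tinyPanel <- function(windowSizes = c(2, 4), binSize = 200) {
  bed <- tempfile(fileext = ".bed")
  writeLines(tinyBedLines(), bed)
  panel <- loadPanelBed(bed, name = "tiny")
  panel <- makeBins(panel, binSize = binSize)
  makeTargetGroups(panel, windowSizes = windowSizes)
}

getDemoPanel <- function() {
  if (is.null(.cache$panel)) .cache$panel <- demoPanel()
  .cache$panel
}

# Null model trained once on 300 simulated specimens (the validation-study
# conditions); reused by the acceptance tests.
getDemoModel <- function() {
  if (is.null(.cache$model)) {
    dm <- simulateDepth(simConfig(nSpecimens = 300, seed = 101),
                        getDemoPanel(), prefix = "train")
    .cache$model <- trainModel(dm, getDemoPanel())
  }
  .cache$model
}

# Brute-force transcription of the score formulas, kept deliberately naive
# and independent of the package implementation.
oracleZ <- function(X, sigma) {
  mu <- apply(X, 1, median)
  sweep(sweep(X, 1, mu), 1, sigma, "/")
}
oracleZadj <- function(Z, levels) {
  out <- Z * NA
  for (s in seq_len(ncol(Z))) {
    for (g in seq_len(nrow(Z))) {
      peers <- setdiff(which(levels == levels[g]), g)
      sdv <- sd(Z[peers, s])
      out[g, s] <- if (isTRUE(sdv > 1e-12)) Z[g, s] / sdv else NA_real_
    }
  }
  out
}

# X oracle with no denoising: relative depth over single-bin mean, divided
# by the per-specimen median (all groups single-bin here).
oracleX <- function(raw) {
  rdr <- sweep(raw, 2, colMeans(raw), "/")
  sweep(rdr, 2, apply(rdr, 2, median), "/")
}

# Build a NormalizedMatrix directly from a plain matrix (test convenience).
makeNorm <- function(values, stage = "X",
                     levels = rep("single_bin", nrow(values)),
                     batch = rep("b1", ncol(values)),
                     genes = rep("G", nrow(values))) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  panelCNV:::.newNorm(stage, values,
    S4Vectors::DataFrame(group_id = rownames(values), gene = genes,
                         level = levels, n_bins = 1L, length = 200L),
    S4Vectors::DataFrame(specimen_id = colnames(values), batch = batch,
                         qc_pass = TRUE, scorable = TRUE))
}

# Model for the specificity/precision studies, trained on a 1,288-specimen
# null cohort (14 batches of 92): per-group dispersions and cutoffs come
# from a cohort of about 1,300, mirroring the assay's training design,
# which keeps the far-tail cutoff calibration stable.
getCalibrationModel <- function() {
  if (is.null(.cache$bigModel)) {
    dm <- simulateDepth(simConfig(nSpecimens = 1288, seed = 202),
                        getDemoPanel(), prefix = "train")
    .cache$bigModel <- trainModel(dm, getDemoPanel())
  }
  .cache$bigModel
}
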