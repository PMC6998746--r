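test_that("simulation is deterministic given (config, panel)", {
  p <- tinyPanel()
  cfg <- simConfig(nSpecimens = 5, seed = 7)
  a <- simulateDepth(cfg, p)
  b <- simulateDepth(cfg, p)
  expect_identical(depthValues(a), depthValues(b))
  expect_identical(SummarizedExperiment::assay(a, "mu"),
                   SummarizedExperiment::assay(b, "mu"))
  # a different seed changes the draw
  c <- simulateDepth(simConfig(nSpecimens = 5, seed = 8), p)
  expect_false(identical(depthValues(a), depthValues(c)))
})

test_that("mean depth is recovered when variance sources vanish", {
  p <- getDemoPanel()
  cfg <- simConfig(nSpecimens = 92, meanDepth = 380, specimenSdLog = 0,
                   efficiencySdLog = 0, nTechnicalFactors = 0,
                   dispersion = 0, seed = 11)
  dm <- simulateDepth(cfg, p)
  expect_lt(abs(mean(depthValues(dm)) / 380 - 1), 0.01)
  # with zero technical rank, depth columns are independent given size
  # factors: correlation between two specimens' bin depths stays near 0
  cfg2 <- simConfig(nSpecimens = 4, meanDepth = 380, specimenSdLog = 0,
                    efficiencySdLog = 0, nTechnicalFactors = 0,
                    dispersion = 0.002, seed = 12)
  v <- depthValues(simulateDepth(cfg2, p))
  cors <- cor(v)[upper.tri(diag(4))]
  expect_lt(max(abs(cors)), 0.15)
})

test_that("spiked events scale depth by the copy ratio and only there", {
  p <- getDemoPanel()
  dm <- simulateDepth(simConfig(nSpecimens = 6, seed = 21), p)
  ev <- data.frame(specimen_id = c("spec001", "spec002"),
                   gene = c("BRCA1", "BRCA1"),
                   first_exon = c("9", "*"), last_exon = c("12", "*"),
                   copy_state = c("het_del", "dup"))
  sp <- spikeCnvs(dm, ev, p, seed = 22)
  expect_equal(nrow(sp$truth), 2)
  expect_equal(sp$truth$type, c("DEL", "DUP"))
  evBins1 <- strsplit(sp$truth$bins[1], ",")[[1]]
  evBins2 <- strsplit(sp$truth$bins[2], ",")[[1]]
  pre <- depthValues(dm); post <- depthValues(sp$matrix)
  # ratio recovery within sampling error
  expect_equal(mean(post[evBins1, "spec001"]) / mean(pre[evBins1, "spec001"]),
               0.5, tolerance = 0.05)
  expect_equal(mean(post[evBins2, "spec002"]) / mean(pre[evBins2, "spec002"]),
               1.5, tolerance = 0.05)
  # non-event cells are bit-exact
  untouched <- post
  untouched[evBins1, "spec001"] <- pre[evBins1, "spec001"]
  untouched[evBins2, "spec002"] <- pre[evBins2, "spec002"]
  expect_identical(untouched, pre)
  # empty event list is the identity
  sp0 <- spikeCnvs(dm, ev[0, ], p, seed = 23)
  expect_identical(depthValues(sp0$matrix), pre)
  expect_equal(nrow(sp0$truth), 0)
})

test_that("events restricted to masked regions are rejected", {
  p <- getDemoPanel()
  dm <- simulateDepth(simConfig(nSpecimens = 3, seed = 31), p)
  evBad <- data.frame(specimen_id = "spec001", gene = "PMS2",
                      first_exon = "12", last_exon = "14",
                      copy_state = "het_del")
  expect_error(spikeCnvs(dm, evBad, p, seed = 32), "no unmasked bin")
  # a whole-gene event over a partially masked gene spikes the visible part
  evWhole <- data.frame(specimen_id = "spec001", gene = "PMS2",
                        first_exon = "*", last_exon = "*",
                        copy_state = "het_del")
  sp <- spikeCnvs(dm, evWhole, p, seed = 33)
  expect_equal(sp$truth$last_exon, 10L)
})

test_that("replicate re-draws share latent means but not noise", {
  p <- tinyPanel()
  dm <- simulateDepth(simConfig(nSpecimens = 4, seed = 41), p)
  r1 <- redrawDepth(dm, seed = 42, suffix = "_r1")
  r1b <- redrawDepth(dm, seed = 42, suffix = "_r1")
  r2 <- redrawDepth(dm, seed = 43, suffix = "_r2")
  expect_identical(depthValues(r1), depthValues(r1b))
  expect_false(identical(unname(depthValues(r1)), unname(depthValues(r2))))
  expect_identical(unname(SummarizedExperiment::assay(r1, "mu")),
                   unname(SummarizedExperiment::assay(dm, "mu")))
  expect_equal(specimenIds(r1), paste0(specimenIds(dm), "_r1"))
})

test_that("the packaged CNV-positive truth set matches the validation design", {
  ev <- validationCnvEvents()
  expect_equal(nrow(ev), 18)                      # 18 positive specimens
  expect_equal(sum(ev$replications), 42)          # 42 positive trials
  single <- ev$first_exon != "*" & ev$first_exon == ev$last_exon
  expect_equal(sum(single), 3)                    # 3 single-exon events
  expect_true(all(ev$copy_state %in% c("het_del", "dup")))
  expect_equal(sum(ev$gene == "BRCA1"), 9)
  # every event maps onto unmasked bins of the demo panel
  p <- getDemoPanel()
  dm <- simulateDepth(simConfig(nSpecimens = 18, seed = 51), p)
  ev$specimen_id <- specimenIds(dm)
  sp <- spikeCnvs(dm, ev, p, seed = 52)
  expect_equal(nrow(sp$truth), 18)
})

test_that("the packaged cohort variant table matches the clinical summary", {
  v <- cohortVariantTable()
  expect_equal(sum(v$n_detected), 53)
  expect_equal(sum(v$n_detected[v$type == "CNV"]), 2)
  expect_equal(v$n_detected[v$gene == "MUTYH" &
                              grepl("1187G>A", v$variant)], 6)
  expect_equal(sort(unique(v$classification)), c("LP", "P"))
})
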