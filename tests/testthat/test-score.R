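test_that("batch mu is the per-batch median over usable specimens", {
  X <- makeNorm(matrix(c(0.9, 1.0, 1.1), 1, 3))
  expect_equal(unname(batchMu(X)[1, 1]), 1.0)
  # all specimens identical -> mu equals the common value
  Xc <- makeNorm(matrix(2, 2, 4))
  expect_true(all(batchMu(Xc) == 2))
  # QC-fail specimens are excluded from mu but still scored
  Xq <- makeNorm(matrix(c(1, 1, 1, 9), 1, 4))
  Xq@specimenInfo$qc_pass[4] <- FALSE
  expect_equal(unname(batchMu(Xq)[1, 1]), 1)
  zq <- zScore(Xq, batchMu(Xq), c(g01 = 0.1))
  expect_equal(unname(zq$Z[1, 4]), 80)
  # undersized batches are refused with pooling advice
  Xs <- makeNorm(matrix(1, 1, 2))
  expect_error(batchMu(Xs), "pool")
  # robustness: one het-del among 92 moves mu by well under 0.6 percent
  vals <- matrix(rep(1, 92), 1)
  vals[1, 1] <- 0.5
  shift <- abs(batchMu(makeNorm(vals))[1, 1] - 1)
  expect_lt(shift, 0.006)
})

test_that("Z score arithmetic and unscorable groups behave as specified", {
  X <- makeNorm(matrix(c(1.0, 1.05, 0.5), 1, 3))
  mu <- matrix(1, 1, 1, dimnames = list("g01", "b1"))
  z <- zScore(X, mu, c(g01 = 0.05))
  expect_equal(unname(z$Z[1, ]), c(0, 1, -10))   # X=mu; X=mu+sigma; het-del
  # sigma = 0 groups are excluded with a warning
  X2 <- makeNorm(matrix(1, 2, 3))
  mu2 <- matrix(1, 2, 1, dimnames = list(c("g01", "g02"), "b1"))
  expect_warning(z2 <- zScore(X2, mu2, c(g01 = 0.1, g02 = 0)), "unscorable")
  expect_true(all(is.na(z2$Z[2, ])))
  expect_false(anyNA(z2$Z[1, ]))
})

test_that("Z.adj divides by the peer standard deviation and cancels scale", {
  # forced arithmetic: Z = 6 against peers with sd 2
  Z <- matrix(c(6, 2, -2, 2, -2), 5, 1)
  za <- zAdj(Z, rep("single_bin", 5))
  expect_equal(unname(za[1, 1]), 6 / sd(c(2, -2, 2, -2)))
  # a uniformly noisy specimen (all Z tripled) has identical Z.adj
  expect_equal(zAdj(3 * Z, rep("single_bin", 5)), zAdj(Z, rep("single_bin", 5)))
  # constant Z row: peer sd 0 -> undefined everywhere
  expect_true(all(is.na(zAdj(matrix(1, 4, 1), rep("single_bin", 4)))))
  # levels are segregated: peers never cross levels
  Z2 <- rbind(matrix(rnorm(8, sd = 1), 4), matrix(100, 2, 2))
  lv <- c(rep("single_bin", 4), rep("whole_gene", 2))
  za2 <- zAdj(Z2, lv)
  expect_equal(unname(za2[1:4, ]),
               unname(zAdj(Z2[1:4, , drop = FALSE], rep("single_bin", 4))))
})

test_that("Z and Z.adj match a brute-force oracle on random matrices", {
  set.seed(99)
  for (rep in 1:5) {
    vals <- matrix(rnorm(54, 1, 0.1), 6, 9)          # 9 groups x 6... transposed below
    X <- makeNorm(t(vals), levels = rep(c("single_bin", "exon", "whole_gene"),
                                        each = 3))
    sigma <- setNames(runif(9, 0.02, 0.2), rownames(normValues(X)))
    z <- zScore(X, batchMu(X), sigma)
    expect_equal(z$Z, oracleZ(normValues(X), sigma), tolerance = 1e-12)
    za <- zAdj(z$Z, groupInfo(X)$level)
    expect_equal(za, oracleZadj(z$Z, groupInfo(X)$level), tolerance = 1e-12)
    # median-zero invariant: per group, the batch median of Z is exactly 0
    expect_equal(unname(apply(z$Z, 1, median)), rep(0, 9))
  }
})

test_that("flag rule implements two-sided and/or with provenance", {
  Z <- matrix(c(-10, 2, 0), 3, 1)
  A <- matrix(c(0, 5, 0), 3, 1)
  lv <- rep("single_bin", 3)
  cut <- c(single_bin = 3.5)
  fl <- flagGroups(Z, A, cut, cut, lv)
  expect_equal(unname(fl$flags[, 1]), c(TRUE, TRUE, FALSE))
  expect_equal(unname(fl$source[, 1]), c("Z", "Zadj", "none"))
  # rule "both" needs both statistics over the line
  flb <- flagGroups(Z, A, cut, cut, lv, rule = "both")
  expect_false(any(flb$flags))
  # monotonicity: lowering a cutoff never removes a flag
  fl2 <- flagGroups(Z, A, c(single_bin = 1.5), c(single_bin = 1.5), lv)
  expect_true(all(fl$flags <= fl2$flags))
  expect_error(flagGroups(Z, A, c(single_bin = -1), cut, lv), "positive")
})

test_that("flagged groups merge into contiguity-respecting typed calls", {
  p <- getDemoPanel()
  model <- getDemoModel()
  dm <- simulateDepth(simConfig(nSpecimens = 8, seed = 81), p)
  ev <- data.frame(specimen_id = c("spec001", "spec002", "spec002"),
                   gene = c("BRCA1", "MLH1", "MLH1"),
                   first_exon = c("9", "2", "8"), last_exon = c("12", "3", "9"),
                   copy_state = c("het_del", "het_del", "het_del"))
  sp <- spikeCnvs(dm, ev, p, seed = 82)
  res <- callCnvs(sp$matrix, p, model)
  c1 <- res$calls[res$calls$specimen_id == "spec001" &
                    res$calls$gene == "BRCA1", ]
  expect_equal(nrow(c1), 1)        # one merged call, not one per group
  expect_equal(c1$type, "DEL")
  expect_true(c1$first_exon <= 9 && c1$last_exon >= 12)
  expect_lt(c1$mean_X_ratio, 1)
  expect_equal(c1$status, "flagged_pending_confirmation")
  # two events separated by unflagged exons yield separate calls
  c2 <- res$calls[res$calls$specimen_id == "spec002" &
                    res$calls$gene == "MLH1", ]
  expect_equal(nrow(c2), 2)
  # no flags -> empty calls with the standard schema
  null8 <- callCnvs(simulateDepth(
    simConfig(nSpecimens = 8, seed = 83), p), p, model)
  expect_true(nrow(null8$calls) <= 1)  # at most a stray false flag
  expect_true(all(c("specimen_id", "gene", "type", "max_abs_Z",
                    "mean_X_ratio", "status") %in% colnames(null8$calls)))
})

test_that("calls export to TSV and VCF", {
  p <- getDemoPanel()
  model <- getDemoModel()
  dm <- simulateDepth(simConfig(nSpecimens = 6, seed = 91), p)
  ev <- data.frame(specimen_id = "spec001", gene = "BRCA2",
                   first_exon = "*", last_exon = "*", copy_state = "dup")
  sp <- spikeCnvs(dm, ev, p, seed = 92)
  calls <- callCnvs(sp$matrix, p, model)$calls
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  writeCallsTsv(calls, tsv)
  back <- read.delim(tsv)
  expect_equal(back$gene, calls$gene)
  writeCallsVcf(calls, vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, nrow(calls))
  expect_true(all(grepl("SVTYPE=(DEL|DUP);END=\\d+;ZMAX=", body)))
  # confirmation status is an external annotation
  calls2 <- setCallStatus(calls, 1, "refuted")
  expect_equal(calls2$status[1], "refuted")
})

test_that("fingerprint mismatch refuses scoring", {
  model <- getDemoModel()
  other <- tinyPanel()
  dm <- simulateDepth(simConfig(nSpecimens = 5, seed = 95), other)
  expect_error(callCnvs(dm, other, model), "fingerprint")
})
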