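test_that("group depth is the length-weighted mean of member bins", {
  p <- tinyPanel()
  bins <- binTargets(p)
  ids <- S4Vectors::mcols(bins)$target_id
  v <- matrix(100, length(ids), 1, dimnames = list(ids, "s1"))
  # GA|ex3 has two 200 bp bins; set them to 100 and 400: exon mean 250
  ex3 <- ids[S4Vectors::mcols(bins)$parent_id %in% "GA_ex3"]
  v[ex3, 1] <- c(100, 400)
  rd <- groupDepth(DepthMatrix(v), p)
  expect_equal(normStage(rd), "RD")
  expect_equal(unname(normValues(rd)["ex:GA_ex3", 1]), 250)
  # single-bin groups equal their bin depth
  expect_equal(unname(normValues(rd)[paste0("sb:", ex3[2]), 1]), 400)
  # a gene with uniform depth d has whole-gene value d
  expect_equal(unname(normValues(rd)["wg:GB", 1]), 100)
  # weighted-mean worked example: len 200 @ 100 with len 100 @ 400 -> 200
  expect_equal((200 * 100 + 100 * 400) / 300, 200)
})

test_that("RDr divides by the specimen mean over single-bin groups", {
  m <- matrix(c(100, 300, 200), 3, 1)
  rd <- makeNorm(m, stage = "RD")
  rdr <- computeRdr(rd)
  expect_equal(unname(normValues(rdr))[, 1], c(0.5, 1.5, 1.0))
  # constant specimen -> all 1; doubling depths leaves RDr unchanged
  rd2 <- makeNorm(cbind(rep(7, 3), 2 * m), stage = "RD")
  rdr2 <- computeRdr(rd2)
  expect_equal(unname(normValues(rdr2))[, 1], rep(1, 3))
  expect_equal(normValues(rdr2)[, 2], normValues(rdr)[, 1],
               ignore_attr = TRUE)
  # per-specimen mean of RDr over single-bin groups is exactly 1
  set.seed(1)
  rdr3 <- computeRdr(makeNorm(matrix(rexp(60, 1 / 300), 10, 6), stage = "RD"))
  expect_equal(unname(colMeans(normValues(rdr3))), rep(1, 6),
               tolerance = 1e-9)
  # zero-depth specimen becomes unscorable
  rd0 <- makeNorm(cbind(m, 0), stage = "RD")
  expect_equal(unname(specimenInfo(computeRdr(rd0))$scorable), c(TRUE, FALSE))
})

test_that("PCA basis captures planted structure and is orthonormal", {
  set.seed(42)
  G <- 40; S <- 30
  ctr <- runif(G, 0.8, 1.2)
  v1 <- rnorm(G); v1 <- v1 / sqrt(sum(v1^2))
  scores <- rnorm(S, sd = 0.2)
  vals <- sapply(seq_len(S), function(s)
    ctr + scores[s] * v1 + rnorm(G, sd = 1e-4))
  rdr <- makeNorm(vals, stage = "RDr")
  b <- fitPca(rdr, nComponents = 1)
  expect_equal(b$nComponents, 1L)
  expect_gt(b$sdev[1]^2 / (b$sdev[1]^2 + 1e-8 * G), 0.99)
  expect_equal(abs(sum(b$rotation[, 1] * v1)), 1, tolerance = 1e-4)
  b3 <- fitPca(rdr, nComponents = 3, varCap = 2)  # no cap
  expect_equal(crossprod(b3$rotation), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # the 90 percent variance cap trims needless components
  expect_equal(fitPca(rdr, nComponents = 3)$nComponents, 1L)
  expect_error(fitPca(rdr, nComponents = 40), "nComponents")
})

test_that("denoising removes exactly the basis-spanned component", {
  set.seed(43)
  G <- 25; S <- 12
  # sd 0.05: all cells within the robust-score inlier band, so the stage
  # coincides with the plain least-squares projection the oracle computes
  vals <- matrix(rnorm(G * S, 1, 0.05), G, S)
  rdr <- makeNorm(vals, stage = "RDr")
  # identity at k = 0
  b0 <- fitPca(rdr, nComponents = 0)
  expect_identical(normValues(applyPca(rdr, b0)), normValues(rdr))
  # a specimen lying exactly on mean + component 1 collapses to the mean
  b1 <- fitPca(rdr, nComponents = 1, varCap = 2)
  probe <- makeNorm(cbind(on_comp = b1$center + 0.3 * b1$rotation[, 1]),
                    stage = "RDr")
  probe@groupInfo$group_id <- rdr@groupInfo$group_id
  rownames(probe@values) <- rownames(rdr@values)
  out <- applyPca(probe, b1)
  expect_equal(unname(out@values[, 1]), unname(b1$center), tolerance = 1e-10)
  # projection oracle on arbitrary data: residual after removing the
  # span of the loadings plus the training-mean (scale) direction
  Q <- qr.Q(qr(cbind(b1$center / sqrt(sum(b1$center^2)), b1$rotation)))
  R <- sweep(vals, 1, b1$center)
  oracle <- sweep(R - Q %*% (t(Q) %*% R), 1, b1$center, "+")
  expect_equal(unname(normValues(applyPca(rdr, b1))), oracle,
               tolerance = 1e-12)
  # a pure scale deviation is annihilated exactly: a specimen at c * mean
  # returns the mean row, for any c
  probe2 <- makeNorm(cbind(scaled = 1.07 * b1$center), stage = "RDr")
  probe2@groupInfo$group_id <- rdr@groupInfo$group_id
  rownames(probe2@values) <- rownames(rdr@values)
  expect_equal(unname(applyPca(probe2, b1)@values[, 1]), unname(b1$center),
               tolerance = 1e-10)
})

test_that("a large event cannot imprint a ghost on other genes", {
  # rank-1 structured data; one specimen carries a dense 'event' block.
  # With robust component scores, groups outside the block keep the same
  # denoised values the specimen would have had without the event.
  set.seed(47)
  G <- 60; S <- 20
  ctr <- runif(G, 0.9, 1.1)
  v1 <- rnorm(G); v1 <- v1 / sqrt(sum(v1^2))
  vals <- sapply(seq_len(S), function(s)
    ctr + rnorm(1, sd = 0.1) * v1 + rnorm(G, sd = 0.01))
  rdr <- makeNorm(vals, stage = "RDr")
  b <- fitPca(rdr, nComponents = 1, varCap = 2)
  spiked <- vals
  block <- 1:12
  spiked[block, 3] <- spiked[block, 3] * 0.5   # het-del-like block
  rdrS <- makeNorm(spiked, stage = "RDr")
  rdrS@groupInfo$group_id <- rdr@groupInfo$group_id
  rownames(rdrS@values) <- rownames(rdr@values)
  clean <- applyPca(rdr, b)
  dirty <- applyPca(rdrS, b)
  # off-block values agree to coefficient-estimation noise (~0.1%) ...
  expect_equal(normValues(dirty)[-block, 3], normValues(clean)[-block, 3],
               tolerance = 0.005)
  # ... whereas a plain full-LS projection would leave a ~10% ghost
  Q <- qr.Q(qr(cbind(b$center / sqrt(sum(b$center^2)), b$rotation)))
  R <- sweep(spiked, 1, b$center)
  naive <- sweep(R - Q %*% (t(Q) %*% R), 1, b$center, "+")
  ghostNaive <- max(abs(naive[-block, 3] - normValues(clean)[-block, 3]))
  ghostRobust <- max(abs(normValues(dirty)[-block, 3] -
                           normValues(clean)[-block, 3]))
  expect_gt(ghostNaive, 20 * ghostRobust)
  # and the event itself survives in the residual
  expect_equal(mean(normValues(dirty)[block, 3] /
                      normValues(clean)[block, 3]), 0.5, tolerance = 0.02)
})

test_that("sparse CNV signal survives removal of a dense technical factor", {
  p <- getDemoPanel()
  model0 <- getDemoModel()
  dm <- simulateDepth(simConfig(nSpecimens = 10, seed = 61), p)
  ev <- data.frame(specimen_id = "spec001", gene = "BRCA1",
                   first_exon = "9", last_exon = "12",
                   copy_state = "het_del")
  sp <- spikeCnvs(dm, ev, p, seed = 62)
  X <- normalizeDepth(sp$matrix, p, model0)
  evBins <- strsplit(sp$truth$bins, ",")[[1]]
  rows <- match(paste0("sb:", evBins), rownames(normValues(X)))
  ## compare the event specimen to the cohort at those bins: ratio near 0.5
  ratio <- mean(normValues(X)[rows, 1]) /
    mean(apply(normValues(X)[rows, -1, drop = FALSE], 1, median))
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("median scaling yields per-specimen median 1 and scale invariance", {
  set.seed(44)
  raw <- matrix(rexp(35, 1 / 300), 7, 5)
  # brute-force oracle: the whole chain at k = 0 on a random 7x5 matrix
  rd <- makeNorm(raw, stage = "RD")
  X <- medianNormalize(applyPca(computeRdr(rd), fitPca(computeRdr(rd), 0)))
  expect_equal(unname(normValues(X)), unname(oracleX(raw)), tolerance = 1e-12)
  expect_equal(unname(apply(normValues(X), 2, median)), rep(1, 5),
               tolerance = 1e-9)
  # scale invariance: scaling a specimen's raw depths leaves X unchanged
  raw2 <- raw
  raw2[, 3] <- raw2[, 3] * 17.3
  X2 <- medianNormalize(applyPca(computeRdr(makeNorm(raw2, stage = "RD")),
                                 fitPca(computeRdr(rd), 0)))
  expect_equal(normValues(X2), normValues(X), tolerance = 1e-12)
  # constant RDrp row scales to 1; even group counts use the midpoint median
  cst <- makeNorm(matrix(3, 4, 2), stage = "RDrp")
  expect_true(all(normValues(medianNormalize(cst)) == 1))
  ev <- makeNorm(matrix(c(1, 2, 1, 3), 2, 2), stage = "RDrp")
  expect_equal(unname(normValues(medianNormalize(ev))[, 1]),
               c(1, 2) / 1.5)
})

test_that("on null simulation X concentrates near 1", {
  p <- getDemoPanel()
  # flat capture efficiency: X itself sits near 1
  dm <- simulateDepth(simConfig(nSpecimens = 60, efficiencySdLog = 0,
                                nTechnicalFactors = 0, seed = 71), p)
  X <- normalizeDepth(dm, p)
  sb <- groupInfo(X)$level == "single_bin"
  expect_lt(mean(abs(normValues(X)[sb, ] - 1) > 0.3), 0.01)
  # default efficiency profile: X concentrates around the per-group profile
  dm2 <- simulateDepth(simConfig(nSpecimens = 60, seed = 72), p)
  X2 <- normalizeDepth(dm2, p)
  dev <- abs(normValues(X2)[sb, ] /
               apply(normValues(X2)[sb, ], 1, median) - 1)
  expect_lt(mean(dev > 0.3), 0.01)
})
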