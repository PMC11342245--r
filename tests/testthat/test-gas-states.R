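mkGasSE <- function(mats) {
  se <- SummarizedExperiment::SummarizedExperiment(assays = mats)
  S4Vectors::metadata(se)$normalized <- "quantile"
  se
}

test_that("GAS is active components minus H3K27me3, cell-wise", {
  one <- function(x) matrix(x, 1, 1)
  se <- mkGasSE(list(H3K4me3 = one(0.8), H3K27ac = one(0.6),
                     Pol2 = one(0.5), DHS = one(0.7),
                     H3K27me3 = one(0.2)))
  expect_equal(SummarizedExperiment::assay(computeGAS(se), "GAS")[1, 1],
               2.4)
  z <- mkGasSE(list(H3K4me3 = one(0), H3K27ac = one(0), Pol2 = one(0),
                    DHS = one(0), H3K27me3 = one(0)))
  expect_equal(SummarizedExperiment::assay(computeGAS(z), "GAS")[1, 1], 0)
  ## random matrices against an element-wise loop oracle
  set.seed(8)
  mats <- lapply(1:5, function(i) matrix(runif(35), 5, 7))
  names(mats) <- c("H3K4me3", "H3K27ac", "Pol2", "DHS", "H3K27me3")
  gas <- SummarizedExperiment::assay(computeGAS(mkGasSE(mats)), "GAS")
  oracle <- matrix(0, 5, 7)
  for (i in 1:5) for (j in 1:7)
    oracle[i, j] <- mats$H3K4me3[i, j] + mats$H3K27ac[i, j] +
      mats$Pol2[i, j] + mats$DHS[i, j] - mats$H3K27me3[i, j]
  expect_equal(unname(gas), oracle)
  ## missing mark named in the error
  expect_error(computeGAS(mkGasSE(mats[-3])), "Pol2")
})

test_that("promoter states follow peak presence with half-open overlap", {
  prom <- gr("chr1", 1001, 5000, gene_id = "g1")
  k4 <- gr("chr1", 4000, 6000)
  k27 <- gr("chr1", 500, 1200)
  expect_equal(classifyPromoterState(k4, k27, prom), "bivalent")
  expect_equal(classifyPromoterState(k4, GenomicRanges::GRanges(), prom),
               "active")
  expect_equal(classifyPromoterState(GenomicRanges::GRanges(), k27, prom),
               "repressive")
  expect_equal(classifyPromoterState(GenomicRanges::GRanges(),
                                     GenomicRanges::GRanges(), prom),
               "none")
  ## a peak ending exactly at the promoter start half-open boundary:
  ## BED [0,1000) next to promoter [1000, ...) -> no overlap
  peakBefore <- gr("chr1", 1, 1000)
  expect_equal(classifyPromoterState(peakBefore,
                                     GenomicRanges::GRanges(), prom),
               "none")
})

test_that("transition tables conserve genes and find BTA genes", {
  states <- rbind(g1 = c("bivalent", "active", "active"),
                  g2 = c("active", "active", "active"),
                  g3 = c("bivalent", "bivalent", "repressive"),
                  g4 = c("none", "none", "none"))
  colnames(states) <- c("s1", "s2", "s3")
  tr <- stateTransitions(states)
  expect_equal(tr$bta$s2, "g1")
  expect_equal(tr$bta$s3, character(0))
  expect_equal(tr$btr$s3, "g3")
  ## counts conserved: each 4x4 table sums to the number of genes
  expect_true(all(apply(tr$counts, 3, sum) == nrow(states)))
  ## an always-active gene is never BTA
  expect_false("g2" %in% unlist(tr$bta))
})

test_that("noise-free simulation reproduces planted states exactly", {
  b <- smallNoiseFreeBundle()
  stages <- b$config$stages
  states <- promoterStates(b$peaks$H3K4me3, b$peaks$H3K27me3,
                           b$promoters, stages)
  expect_equal(unname(states), unname(b$truth$states))
  ## transition counts equal those derived independently from truth
  tr <- stateTransitions(states)
  for (s in 2:length(stages)) {
    oracle <- table(
      factor(b$truth$states[, s - 1],
             c("bivalent", "active", "repressive", "none")),
      factor(b$truth$states[, s],
             c("bivalent", "active", "repressive", "none")))
    expect_equal(unname(tr$counts[, , s - 1]), unname(unclass(oracle)))
  }
})

test_that("methylation handoff flags high-K27-then-high-5mC genes", {
  set.seed(40)
  k27 <- rbind(gHand = c(9, 9, 0.6, 0.6, 0.6),
               gNo = rep(0.8, 5),
               gK27only = rep(9, 5))
  k27 <- rbind(k27, matrix(runif(100, 0.5, 1.5), 20, 5))
  rownames(k27)[4:23] <- paste0("bg", 1:20)
  colnames(k27) <- paste0("s", 1:5)
  mC <- matrix(0.1, nrow(k27), 5, dimnames = dimnames(k27))
  mC["gHand", 4:5] <- 0.8
  out <- methylationHandoff(k27, mC)
  expect_true(out$handoff[out$gene_id == "gHand"])
  expect_equal(out$s1[out$gene_id == "gHand"], 1L)
  expect_equal(out$s2[out$gene_id == "gHand"], 4L)
  ## constant low methylation is never flagged
  expect_false(any(out$handoff[out$gene_id != "gHand"]))
  mC["gNo", 1] <- 1.2
  expect_error(methylationHandoff(k27, mC), "\\[0, 1\\]")
})

test_that("planted methylation handoffs are recovered at default noise", {
  b <- sharedBundle()
  promSE <- quantifySignals(
    Filter(function(t) markName(t) == "H3K27me3", b$tracks),
    b$annotation, b$config$stages, region = "promoter")
  ho <- methylationHandoff(SummarizedExperiment::assay(promSE, "H3K27me3"),
                           b$methylation)
  recall <- mean(b$truth$handoff$gene_id %in% ho$gene_id[ho$handoff])
  expect_gte(recall, 0.9)
})

test_that("cumulative activation curves, folds and permutation p", {
  ## 70 genes, 10 activating at each of 7 stages: uniform reference
  gas <- matrix(-1, 70, 7,
                dimnames = list(sprintf("g%02d", 1:70), paste0("s", 1:7)))
  for (s in 1:7) {
    rows <- ((s - 1) * 10 + 1):(s * 10)
    gas[rows, s:7] <- 20
  }
  early <- rownames(gas)[1:10]     # all active from stage 1
  res <- cumulativeActivation(gas, list(early = early, all = rownames(gas)),
                              activeThreshold = 10, nPerm = 2000)
  ## set identical to the reference has fold 1
  expect_equal(unname(res$fold["all"]), 1)
  ## all-at-stage-1 set against a uniform 7-stage reference: fold 7
  expect_equal(unname(res$fold["early"]), 7)
  expect_lt(res$p[["early"]], 0.01)
  ## curves are monotone and bounded by 1
  expect_true(all(diff(t(res$curves)) >= 0))
  expect_true(all(res$curves <= 1))
  expect_error(cumulativeActivation(gas, list(bad = character(0))),
               "empty")
})

test_that("planted early-activating sets show the expected fold", {
  b <- sharedBundle()
  stages <- b$config$stages
  gt <- Filter(function(t) markName(t) %in%
               c("H3K4me3", "H3K27ac", "Pol2", "DHS", "H3K27me3"),
               b$tracks)
  promN <- normalizeStages(
    quantifySignals(gt, b$annotation, stages, "promoter"))
  bodyN <- normalizeStages(
    quantifySignals(gt, b$annotation, stages, "body"))
  gas <- computeGAS(promN, bodyN)
  tg <- b$truth$genes
  earlySet <- tg$gene_id[tg$class == "specific" & tg$specificStage == 1]
  res <- cumulativeActivation(gas, list(early = earlySet), nPerm = 1000)
  ## the planted early set activates in full at stage 1 while only a
  ## minority of the reference does: the fold is large and significant
  expect_gt(unname(res$fold["early"]), 3)
  expect_lt(res$p[["early"]], 0.01)
  ## the set curve reaches (close to) 1 at stage 1 by construction
  expect_gt(res$curves["early", 1], 0.95)
})
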