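## a toy locus: one gene with promoter, candidate elements, loops
toyEnhancerSetup <- function() {
  genes <- gr("chr1", 1e6 + 1, 1e6 + 20000, strand = "+",
              gene_id = "gene1")
  GenomeInfoDb::seqlengths(genes) <- c(chr1 = 2e7)
  proms <- promoterOf(genes)
  list(genes = genes, proms = proms)
}

test_that("enhancers need all three marks, no promoter, and a loop", {
  s <- toyEnhancerSetup()
  k27 <- gr("chr1", c(1100001, 1300001), c(1105000, 1304000))
  ctcf <- gr("chr1", c(1102001, 1301001), c(1102400, 1301400))
  dhs <- gr("chr1", c(1102001, 1301001), c(1102400, 1301400))
  loops <- LoopSet(gr("chr1", 1100001, 1108000),
                   gr("chr1", 998001, 1002000))   # to the promoter
  calls <- callEnhancers(k27, ctcf, dhs, s$proms, s$genes, loops)
  ## only the looped element is called, with the target recorded
  expect_equal(length(calls), 1L)
  expect_equal(GenomicRanges::start(calls), 1100001L)
  expect_equal(unlist(S4Vectors::mcols(calls)$targets), "gene1")
  ## an element overlapping the promoter is never called
  k27b <- c(k27, gr("chr1", 999001, 1003000))
  ctcfb <- c(ctcf, gr("chr1", 999500, 1000500))
  dhsb <- c(dhs, gr("chr1", 999500, 1000500))
  loopsb <- LoopSet(gr("chr1", c(1100001, 999001), c(1108000, 1003000)),
                    gr("chr1", c(998001, 998001), c(1002000, 1002000)))
  callsb <- callEnhancers(k27b, ctcfb, dhsb, s$proms, s$genes, loopsb)
  expect_false(any(GenomicRanges::countOverlaps(callsb, s$proms) > 0))
  ## a target 3.5 Mb away is beyond the window
  k27far <- gr("chr1", 4600001, 4605000)
  ctcff <- gr("chr1", 4601001, 4601400)
  loopsf <- LoopSet(gr("chr1", 4600001, 4608000),
                    gr("chr1", 998001, 1002000))
  callsf <- callEnhancers(k27far, ctcff, ctcff, s$proms, s$genes, loopsf)
  expect_equal(length(callsf), 0L)
  expect_error(callEnhancers(NULL, ctcf, dhs, s$proms, s$genes, loops),
               "missing mark")
  expect_warning(
    empty <- callEnhancers(k27, ctcf, dhs, s$proms, s$genes,
                           LoopSet(GenomicRanges::GRanges(),
                                   GenomicRanges::GRanges())),
    "no loops")
  expect_equal(length(empty), 0L)
})

test_that("SE/TE split is a pure merged-length rule at 8 kb", {
  calls <- gr("chr1", c(1, 20001, 50001), c(8000, 28000 - 1, 57999))
  out <- classifySeTe(calls)
  expect_equal(S4Vectors::mcols(out)$class, c("SE", "TE", "TE"))
  expect_equal(GenomicRanges::width(calls), c(8000L, 7999L, 7999L))
  ## book-ended 5 kb + 4 kb merge into one 9 kb SE before classification
  pieces <- gr("chr1", c(100001, 105001), c(105000, 109000))
  merged <- GenomicRanges::reduce(pieces, min.gapwidth = 1L)
  expect_equal(GenomicRanges::width(merged), 9000L)
  expect_equal(S4Vectors::mcols(classifySeTe(merged))$class, "SE")
})

test_that("stage partition separates specific from common lineages", {
  common <- gr("chr1", 100001, 110000)
  only1 <- gr("chr1", 500001, 504000)
  only3 <- gr("chr1", 900001, 905000)
  calls <- list(s1 = c(common, only1), s2 = common,
                s3 = c(common, only3))
  part <- stagePartition(calls)
  expect_equal(part$nCommon, 1L)
  expect_equal(part$nSpecific, 2L)
  ## planted mixture recovered on the simulated bundle
  b <- sharedBundle()
  stages <- b$config$stages
  callsByStage <- lapply(stages, function(st) {
    enh <- b$truth$enhancers
    act <- vapply(strsplit(enh$activeStages, ","), function(z)
      match(st, stages) %in% as.integer(z), logical(1))
    gr(enh$chrom[act], enh$start[act], enh$end[act])
  })
  names(callsByStage) <- stages
  part2 <- stagePartition(callsByStage)
  truthCommon <- sum(b$truth$enhancers$common)
  truthSpecific <- sum(!b$truth$enhancers$common)
  expect_equal(part2$nCommon, truthCommon)
  expect_gte(part2$nSpecific / truthSpecific, 0.95)
})

test_that("target-count bins and odds ratios are computed per class", {
  calls <- gr("chr1", seq(1, by = 20000, length.out = 6),
              width = c(9000, 9000, 9000, 4000, 4000, 4000))
  S4Vectors::mcols(calls)$class <- rep(c("SE", "TE"), each = 3)
  S4Vectors::mcols(calls)$nTargets <- c(20, 18, 1, 1, 1, 2)
  res <- targetCountDistribution(calls)
  expect_equal(unname(res$histogram["SE", "15-30"]), 2)
  expect_equal(res$fractionSingleTarget, 3 / 6)
  or1530 <- res$oddsRatios[res$oddsRatios$bin == "15-30", ]
  expect_gt(or1530$oddsRatio, 1)
  allOne <- calls
  S4Vectors::mcols(allOne)$nTargets <- 1
  resAll <- targetCountDistribution(allOne)
  expect_equal(sum(resAll$histogram[, "1"]), 6)
  expect_equal(resAll$fractionSingleTarget, 1)
})

test_that("correlated-element selection applies the one-sided r rule", {
  stages <- paste0("s", 1:7)
  traj <- seq(1, 7)
  scores <- rbind(e1 = traj, e2 = rev(traj), e3 = rep(2, 7))
  colnames(scores) <- stages
  expr <- rbind(gA = 3 * traj + 2, gB = traj^1.5)
  colnames(expr) <- stages
  sel <- selectCorrelatedElements(scores, expr,
                                  list(c("gA"), c("gA"), c("gA")))
  ## affine transform of the trajectory gives r = 1 and is kept
  expect_true("e1" %in% sel$element)
  expect_equal(sel$r[sel$element == "e1"], 1)
  ## anti-correlated element dropped under one-sided r >= 0.8
  expect_false("e2" %in% sel$element)
  ## constant trajectory skipped with a note
  expect_message(
    selectCorrelatedElements(scores["e3", , drop = FALSE], expr,
                             list("gA")), "constant")
  ## invariant to a global affine rescaling of expression
  sel2 <- selectCorrelatedElements(scores, 5 * expr + 3,
                                   list("gA", "gA", "gA"))
  expect_equal(as.data.frame(sel)[c("element", "r")],
               as.data.frame(sel2)[c("element", "r")])
  expect_error(selectCorrelatedElements(scores[, 1:3], expr[, 1:3],
                                        list("gA", "gA", "gA")),
               "4 stages")
})

test_that("element clustering separates planted modules deterministically", {
  stages <- paste0("s", 1:7)
  up <- seq(0, 3, length.out = 7)
  g1 <- t(replicate(6, up + rnorm(7, sd = 0.05)))
  g2 <- t(replicate(6, rev(up) + rnorm(7, sd = 0.05)))
  set.seed(19)
  scores <- rbind(g1, g2)
  rownames(scores) <- sprintf("e%02d", 1:12)
  colnames(scores) <- stages
  lab <- clusterElements(scores, k = 2)
  expect_equal(length(unique(lab[1:6])), 1L)
  expect_equal(length(unique(lab[7:12])), 1L)
  expect_false(lab[1] == lab[7])
  ## permuted input order yields the identical partition
  perm <- sample(12)
  lab2 <- clusterElements(scores[perm, ], k = 2)
  expect_equal(lab2[names(lab)], lab)
  ## planted five-module recovery with silhouette-chosen k
  set.seed(20)
  protos <- matrix(rnorm(5 * 7, sd = 2), 5, 7)
  big <- do.call(rbind, lapply(1:5, function(m)
    t(replicate(12, protos[m, ] + rnorm(7, sd = 0.15)))))
  rownames(big) <- sprintf("x%02d", 1:60)
  colnames(big) <- stages
  labBig <- clusterElements(big)
  truthLab <- rep(1:5, each = 12)
  expect_gte(mclust::adjustedRandIndex(labBig, truthLab), 0.8)
  expect_error(clusterElements(big[1, , drop = FALSE]), "two elements")
})

test_that("element active scores combine the three marks over stages", {
  el <- gr("chr1", 101, 300)
  stages <- c("s1", "s2")
  tr <- function(mark, vals) lapply(stages, function(st)
    mkTrack(vals[[st]], mark = mark, stage = st))
  tracksByMark <- list(
    H3K27ac = setNames(tr("H3K27ac", list(s1 = rep(4, 10),
                                          s2 = rep(1, 10))), stages),
    DHS = setNames(tr("DHS", list(s1 = rep(2, 10),
                                  s2 = rep(1, 10))), stages),
    H3K27me3 = setNames(tr("H3K27me3", list(s1 = rep(1, 10),
                                            s2 = rep(5, 10))), stages))
  sc <- elementActiveScore(el, tracksByMark, stages)
  expect_equal(unname(sc), matrix(c(4 + 2 - 1, 1 + 1 - 5), 1, 2))
})
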