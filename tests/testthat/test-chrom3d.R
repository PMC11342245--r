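twoBlock <- function(n = 60, hi = 5, lo = 1) {
  m <- matrix(lo, n, n)
  m[1:(n / 2), 1:(n / 2)] <- hi
  m[(n / 2 + 1):n, (n / 2 + 1):n] <- hi
  ContactMatrix(m, 40000)
}

test_that("eigenvector sign partitions a two-block checkerboard", {
  ## 20-bin checkerboard: alternating 4-bin A/B blocks with plaid counts
  n <- 20
  lab <- rep(rep(c(1, -1), each = 4), length.out = n)
  d <- abs(outer(1:n, 1:n, "-"))
  mu <- 50 * pmax(d, 1)^-0.8 * (1 + 0.4 * outer(lab, lab))
  cm <- ContactMatrix(mu, 40000)
  prof <- callCompartments(cm, orient = as.numeric(lab == 1),
                           targetBinSize = NA, balance = FALSE)
  got <- ifelse(compartmentLabels(prof) == "A", 1, -1)
  expect_equal(got, lab)
  ## oracle: direct eigen-decomposition of the O/E correlation matrix
  oe <- oeMatrix(cm)
  e1 <- eigen(cor(oe), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sign(e1)), abs(sign(eigenvector(prof))))
  expect_true(all(sign(e1) == sign(eigenvector(prof))) ||
              all(sign(e1) == -sign(eigenvector(prof))))
})

test_that("flat or degenerate matrices are flagged or rejected", {
  flat <- ContactMatrix(matrix(1, 20, 20), 40000)
  expect_error(callCompartments(flat, targetBinSize = NA,
                                balance = FALSE), "zero-variance|10 informative")
  tiny <- ContactMatrix(matrix(1, 4, 4), 40000)
  expect_error(callCompartments(tiny, targetBinSize = NA), "10")
})

test_that("compartment switch fractions compare label tracks", {
  mk <- function(lab) new("CompartmentProfile", stage = "s", chrom = "c",
                          binSize = 400000L,
                          eigen = ifelse(lab == "A", 1, -1),
                          labels = lab, orientation = "oriented")
  a <- mk(rep(c("A", "B"), 10))
  expect_equal(compartmentSwitches(a, a)$fracSwitched, 0)
  b <- mk(rep(c("B", "A"), 10))
  expect_equal(compartmentSwitches(a, b)$fracSwitched, 1)
  expect_error(compartmentSwitches(a, mk(rep("A", 5))), "binning")
})

test_that("insulation minima sit at domain starts", {
  cm <- twoBlock()
  ins <- insulationScore(cm, 5)
  b <- boundariesFromInsulation(ins, 0.2, span = 5)
  expect_equal(b, 31L)
  ## uniform matrix: no boundaries
  insFlat <- insulationScore(ContactMatrix(matrix(2, 60, 60), 40000), 5)
  expect_equal(length(boundariesFromInsulation(insFlat, 0.2, 5)), 0L)
  expect_error(insulationScore(cm, 1), "window")
  expect_error(insulationScore(ContactMatrix(matrix(1, 6, 6), 1000), 5),
               "window larger")
  ## brute-force oracle for the score definition
  m <- as.matrix(contactCounts(cm))
  w <- 5
  raw <- rep(NA_real_, 60)
  for (i in (w + 1):(60 - w + 1))
    raw[i] <- mean(m[(i - w):(i - 1), i:(i + w - 1)])
  expect_equal(ins, log2(raw / mean(raw, na.rm = TRUE)))
})

test_that("TAD change taxonomy labels canonical cases", {
  bs <- 40000L
  t1 <- TADSet(c(31, 61), 100, bs)            # domains 1-30,31-60,61-100
  tSplit <- TADSet(c(31, 45, 61), 100, bs)
  df <- classifyTadChanges(t1, tSplit)
  expect_equal(df$type, c("stable", "split", "stable"))
  ## merge is the inverse on swapped inputs
  df2 <- classifyTadChanges(tSplit, t1)
  expect_equal(df2$type[2:3], c("merge", "merge"))
  tShift <- TADSet(c(31, 64), 100, bs)
  expect_equal(classifyTadChanges(t1, tShift)$type[2], "shift")
  expect_equal(classifyTadChanges(t1, tShift)$offset[2], 3)
  ## identical boundaries with doubled intra-domain contact; the boosted
  ## domain is small relative to the chromosome so the distance
  ## expectation stays put
  tS <- TADSet(c(31, 46), 100, bs)
  base <- matrix(1, 100, 100)
  base[31:45, 31:45] <- 4
  cm1 <- ContactMatrix(base, bs)
  boosted <- base; boosted[31:45, 31:45] <- 12
  cm2 <- ContactMatrix(boosted, bs)
  df3 <- classifyTadChanges(tS, tS, cm1, cm2)
  expect_equal(df3$type[2], "strength_change")
  expect_error(classifyTadChanges(t1, TADSet(integer(0), 1, bs)), ".")
})

test_that("boundary-gene distances match a brute-force scan", {
  set.seed(10)
  tads <- TADSet(c(26, 51, 80), 100, 40000L, chrom = "chr1")
  genes <- gr("chr1", sort(sample(3.9e6, 30)), width = 1000,
              strand = "+", gene_id = sprintf("g%02d", 1:30))
  d <- boundaryGeneDistance(genes, tads)
  pos <- (boundaries(tads) - 1) * 40000
  for (i in 1:30) {
    tss0 <- GenomicRanges::start(genes)[i] - 1
    expect_equal(abs(d$distance[i]), min(abs(tss0 - pos)))
  }
  ## TSS exactly on a boundary
  g0 <- gr("chr1", 25 * 40000 + 1, 25 * 40000 + 500, strand = "+",
           gene_id = "gb")
  expect_equal(boundaryGeneDistance(g0, tads)$distance, 0)
  ## the 80-kb window is inclusive at 80000 and excludes 80001
  gIn <- gr("chr1", 25 * 40000 + 80001, 25 * 40000 + 80500,
            strand = "+", gene_id = "gIn")
  gOut <- gr("chr1", 25 * 40000 + 80002, 25 * 40000 + 80500,
             strand = "+", gene_id = "gOut")
  dyn <- 25 * 40000
  expect_equal(dTADBAG(gIn, dyn, "chr1"), "gIn")
  expect_equal(length(dTADBAG(gOut, dyn, "chr1")), 0L)
})

test_that("boundary metaplots average aligned windows", {
  v <- rep(0, 100); v[c(21, 61)] <- 10   # delta at two boundary bins
  tr <- mkTrack(v, bin = 1000L, mark = "CTCF")
  mp <- boundaryMetaplot(tr, c(20000, 60000), "chr1", 5000)
  expect_equal(mp$mean[mp$offset == 0], 10)
  expect_true(all(mp$mean[mp$offset != 0] == 0))
  flat <- boundaryMetaplot(mkTrack(rep(3, 100), bin = 1000L),
                           c(20000, 60000), "chr1", 5000)
  expect_true(all(flat$mean == 3))
  ## naive loop oracle on a random case with edge clipping
  set.seed(13)
  v2 <- runif(50)
  tr2 <- mkTrack(v2, bin = 1000L)
  bps <- c(1000, 25000, 48000)
  mp2 <- boundaryMetaplot(tr2, bps, "chr1", 3000)
  for (k in seq_len(nrow(mp2))) {
    idx <- bps / 1000 + 1 + mp2$offset[k] / 1000
    idx <- idx[idx >= 1 & idx <= 50]
    expect_equal(mp2$mean[k], mean(v2[idx]))
    expect_equal(mp2$n[k], length(idx))
  }
  expect_error(boundaryMetaplot(tr2, numeric(0), "chr1", 3000),
               "no boundaries")
  expect_error(boundaryMetaplot(tr2, bps, "chr1", 2500), "multiple")
})

test_that("loop calling finds planted dots and stays quiet on nulls", {
  set.seed(7)
  n <- 200; bs <- 40000L
  d <- abs(outer(1:n, 1:n, "-"))
  mu <- 200 * pmax(d, 1)^-1
  dots <- cbind(c(50, 120), c(62, 140))
  for (k in 1:2) {
    i <- dots[k, 1]; j <- dots[k, 2]
    mu[i, j] <- mu[i, j] * 5; mu[j, i] <- mu[i, j]
  }
  x <- mu; up <- upper.tri(x, diag = TRUE)
  x[up] <- rpois(sum(up), mu[up])
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  lp <- callLoops(ContactMatrix(x, bs), 2 * bs, 150 * bs)
  a1 <- (GenomicRanges::start(loopAnchors(lp, 1)) - 1) / bs + 1
  a2 <- (GenomicRanges::start(loopAnchors(lp, 2)) - 1) / bs + 1
  ## each planted dot is recovered within one bin
  for (k in 1:2)
    expect_true(any(abs(a1 - dots[k, 1]) <= 1 & abs(a2 - dots[k, 2]) <= 1))
  ## anchors are always ordered
  expect_true(all(a1 <= a2))
  ## pure power law: no loops at FDR 0.1 in most seeded runs
  zeroRuns <- vapply(1:10, function(s) {
    set.seed(s)
    cmp <- powerLawContacts(150, bs, 1.0, depth = 60)
    length(callLoops(cmp, 2 * bs, 100 * bs)) == 0
  }, logical(1))
  expect_gte(mean(zeroRuns), 0.95)
})

test_that("decay profiles integrate to one and rank by exponent", {
  set.seed(15)
  cm <- powerLawContacts(300, 40000, 1.0, depth = 80)
  dp <- decayProfile(cm)
  expect_equal(sum(dp$prob), 1)
  ## short/long ratio responds monotonically to the decay exponent
  r <- vapply(c(0.7, 1.0, 1.3), function(a) {
    decayProfile(powerLawContacts(300, 40000, a, depth = 80))$shortLongRatio
  }, numeric(1))
  expect_true(all(diff(r) > 0))
  ## contacts at a single short distance: ratio Inf
  m <- matrix(0, 30, 30); m[cbind(1:25, 6:30)] <- 3
  m <- m + t(m)
  expect_equal(decayProfile(ContactMatrix(m, 40000))$shortLongRatio, Inf)
  expect_error(decayProfile(ContactMatrix(matrix(0, 20, 20), 40000)),
               "all-zero")
})

test_that("signal correlation is higher within than between TADs", {
  ## identical stage profiles everywhere: intra = inter = 1
  nb <- 100; bs <- 40000L
  tads <- TADSet(seq(11, 91, by = 10), nb, bs)
  prof <- c(1, 3, 5, 2, 4)
  mkStage <- function(vals, st) mkTrack(vals, bin = bs, stage = st)
  same <- lapply(1:5, function(s) mkStage(rep(prof[s], nb) + 0.001 *
                                          rep(c(1, -1), nb / 2), s))
  ## tiny alternating jitter keeps per-bin variance nonzero
  res <- intraInterTadCorrelation(same, tads, maxPairDist = 10 * bs)
  expect_equal(res$intra, res$inter, tolerance = 1e-6)
  ## TAD-coherent planted signals: intra exceeds inter
  set.seed(16)
  dom <- pmin(findInterval(1:nb, boundaries(tads)),
              length(boundaries(tads)) - 1)
  coher <- lapply(1:5, function(s) {
    domEffect <- rnorm(max(dom), sd = 2)[dom]
    mkStage(pmax(domEffect + rnorm(nb, sd = 0.7) + 5, 0), s)
  })
  res2 <- intraInterTadCorrelation(coher, tads, maxPairDist = 10 * bs)
  expect_gt(res2$intra, res2$inter)
  ## matched inter distances track the intra distances
  expect_equal(res2$interDist, res2$intraDist,
               tolerance = 0.25)
  expect_error(intraInterTadCorrelation(same[1:2], tads, 10 * bs),
               "3 stages")
})

test_that("intra/inter contact ratio matches pair counting on uniforms", {
  nb <- 60; bs <- 40000L
  tads <- TADSet(c(21, 41), nb, bs)    # three equal 20-bin domains
  m <- matrix(1, nb, nb)
  cm <- ContactMatrix(m, bs)
  d <- domains(tads)
  dom <- pmin(findInterval(1:nb, boundaries(tads)), 3)
  maxD <- 2 * 20
  intra <- 0; inter <- 0
  for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
    if (j - i > maxD) next
    if (dom[i] == dom[j]) intra <- intra + 1 else inter <- inter + 1
  }
  expect_equal(intraInterContactRatio(cm, tads), intra / inter)
  ## block diagonal with empty off-blocks: Inf
  mb <- matrix(0, nb, nb)
  for (k in 1:3) {
    idx <- ((k - 1) * 20 + 1):(k * 20)
    mb[idx, idx] <- 2
  }
  expect_equal(intraInterContactRatio(ContactMatrix(mb, bs), tads), Inf)
})

test_that("boundary permutation enrichment is calibrated", {
  set.seed(17)
  bnd <- gr("chr1", seq(1e5, 9e5, by = 1e5), width = 2000)
  GenomeInfoDb::seqlengths(bnd) <- c(chr1 = 1e6)
  onTop <- GenomicRanges::resize(bnd, 1, fix = "center")
  res <- regionSetBoundaryEnrichment(onTop, bnd, nShuffle = 500)
  expect_equal(res$p, 1 / 501)
  expect_gt(res$fold, 5)
  expect_equal(regionSetBoundaryEnrichment(GenomicRanges::GRanges(),
                                           bnd)$p, 1)
  unif <- gr("chr1", sort(sample(1e6, 3000)), width = 1)
  res2 <- regionSetBoundaryEnrichment(unif, bnd, nShuffle = 400)
  expect_equal(res2$fold, 1, tolerance = 0.35)
  expect_warning(regionSetBoundaryEnrichment(unif, bnd, nShuffle = 50),
                 "100")
})
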