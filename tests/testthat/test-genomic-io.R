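test_that("BED annotation parsing assigns strand-aware TSS", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1000\t5000\tgeneA\t0\t+",
               "chr1\t8000\t9000\tgeneB\t0\t-"), bed)
  ann <- readAnnotation(bed, "BED12", chromSizes = c(chr1 = 20000))
  expect_equal(ann$gene_id, c("geneA", "geneB"))
  ## 0-based half-open [1000,5000) -> 1-based [1001,5000]
  expect_equal(tssOf(ann), c(1001L, 9000L))
})

test_that("duplicate gene ids and malformed files raise errors", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500\tg\t0\t+", "chr1\t600\t900\tg\t0\t+"), bed)
  expect_error(readAnnotation(bed, "BED12"), "duplicate")
  expect_error(readAnnotation(tempfile(), "BED12"), "not found")
})

test_that("GTF transcripts collapse to outermost gene coordinates", {
  gtf <- tempfile(fileext = ".gtf")
  att <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  writeLines(c(
    paste("chr1", "src", "transcript", 2001, 6000, ".", "+", ".",
          att("gA", "t1"), sep = "\t"),
    paste("chr1", "src", "transcript", 4001, 9000, ".", "+", ".",
          att("gA", "t2"), sep = "\t")), gtf)
  ann <- readAnnotation(gtf, "GTF", chromSizes = c(chr1 = 20000))
  ## oracle: independent per-line parse and min/max reduction
  raw <- read.table(gtf, sep = "\t")
  expect_equal(GenomicRanges::start(ann), min(raw$V4))
  expect_equal(GenomicRanges::end(ann), max(raw$V5))
  expect_equal(ann$gene_id, "gA")
})

test_that("promoter windows follow TSS +/- halfwidth with clipping", {
  g <- gr("chr1", 10001, 15000, strand = "+", gene_id = "g1")
  GenomeInfoDb::seqlengths(g) <- c(chr1 = 1e6)
  p <- promoterOf(g, 2000)
  ## 0-based [8000, 12000) == 1-based [8001, 12000]
  expect_equal(GenomicRanges::start(p), 8001L)
  expect_equal(GenomicRanges::end(p), 12000L)
  g2 <- gr("chr1", 501, 2000, strand = "+", gene_id = "g2")
  GenomeInfoDb::seqlengths(g2) <- c(chr1 = 1e6)
  p2 <- promoterOf(g2, 2000)
  expect_equal(GenomicRanges::start(p2), 1L)
  expect_equal(GenomicRanges::end(p2), 2500L)
  expect_equal(GenomicRanges::width(promoterOf(g, 0)), 0L)
})

test_that("triplet contact files are symmetrised and duplicates summed", {
  f <- tempfile()
  writeLines(c("0\t1\t5", "1\t0\t3", "2\t2\t4"), f)
  cm <- readContacts(f, 10000, 50000)
  m <- as.matrix(contactCounts(cm))
  expect_equal(m[1, 2], 8)
  expect_equal(m[2, 1], 8)
  expect_equal(m[3, 3], 4)
  expect_equal(dim(m), c(5L, 5L))
  ## empty file -> zero matrix of correct dimension
  f2 <- tempfile(); file.create(f2)
  expect_equal(sum(contactCounts(readContacts(f2, 10000, 50000))), 0)
  f3 <- tempfile(); writeLines("0\t1\t-2", f3)
  expect_error(readContacts(f3, 10000, 50000), "negative")
  f4 <- tempfile(); writeLines("0\t9\t2", f4)
  expect_error(readContacts(f4, 10000, 50000), "beyond")
})

test_that("contact matrices round-trip through triplet files", {
  set.seed(11)
  m <- matrix(rpois(100, 3), 10, 10)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  cm <- ContactMatrix(m, 5000)
  f <- tempfile()
  writeContacts(cm, f)
  back <- readContacts(f, 5000, 50000)
  expect_equal(as.matrix(contactCounts(back)),
               as.matrix(contactCounts(cm)), ignore_attr = TRUE)
})

test_that("bedGraph round trip preserves bin values", {
  set.seed(4)
  v <- round(runif(1000, 0, 50), 6)
  tr <- mkTrack(v, bin = 200L, mark = "DHS", stage = "E50")
  f <- tempfile(fileext = ".bedGraph")
  writeBedGraph(tr, f)
  back <- readBedGraph(f, "DHS", "E50", 200L, c(chr1 = 200L * 1000))
  expect_equal(trackValues(back)$chr1, v, tolerance = 1e-6)
})

test_that("BEDPE round trip keeps ordered anchors", {
  a1 <- gr("chr1", c(100001, 500001), c(110000, 510000))
  a2 <- gr("chr1", c(300001, 200001), c(310000, 210000))
  ls <- LoopSet(a1, a2, strength = c(2.5, 3.5), stage = "E50")
  ## construction reorders the second pair
  expect_true(all(GenomicRanges::start(loopAnchors(ls, 1)) <=
                  GenomicRanges::start(loopAnchors(ls, 2))))
  f <- tempfile(fileext = ".bedpe")
  writeBedpe(ls, f)
  back <- readBedpe(f, stage = "E50")
  expect_equal(GenomicRanges::start(loopAnchors(back, 1)),
               GenomicRanges::start(loopAnchors(ls, 1)))
  expect_equal(loopStrength(back), loopStrength(ls))
})

test_that("BED and stage-matrix writers round trip", {
  g <- GenomicRanges::sort(gr("chr1", c(1001, 5001), c(2000, 9000)))
  f <- tempfile(fileext = ".bed")
  writeBed(g, f)
  back <- readBed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(g))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(g))
  m <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  f2 <- tempfile(fileext = ".tsv")
  writeStageMatrix(m, f2)
  expect_equal(readStageMatrix(f2), m)
})

test_that("GMT gene sets are read as named lists", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), f)
  gs <- readGmt(f)
  expect_equal(gs$setA, c("g1", "g2", "g3"))
  expect_equal(gs$setB, "g4")
})
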