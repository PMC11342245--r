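## shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

## the default study-conditions bundle (seed fixed in simConfig)
sharedBundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- simulateBundle(simConfig())
  .fixtures$bundle
}

## a desk-scale configuration for unit tests (one 10-Mb chromosome)
smallConfig <- function(...) {
  simConfig(nChroms = 1L, chromLength = 10e6, geneRegionEnd = 7.5e6,
            nGenes = 300L, nBivalent = 60L, nHandoff = 30L,
            nEnhancers = 20L, nSnps = 150L, nBackgroundSnps = 30L, ...)
}

smallNoiseFreeBundle <- function() {
  if (is.null(.fixtures$nfBundle))
    .fixtures$nfBundle <- simulateBundle(smallConfig(noiseFree = TRUE))
  .fixtures$nfBundle
}

## one-chromosome track from a numeric vector
mkTrack <- function(values, bin = 100L, mark = "H3K4me3", stage = "s1",
                    chrom = "chr1") {
  SignalTrack(as.character(mark), as.character(stage), bin,
              stats::setNames(list(values), chrom),
              stats::setNames(length(values) * bin, chrom))
}

## GRanges shorthand
gr <- function(chrom, start, end = NULL, width = NULL, ...) {
  ir <- if (is.null(width)) IRanges::IRanges(start, end)
        else IRanges::IRanges(start, width = width)
  GenomicRanges::GRanges(chrom, ir, ...)
}
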