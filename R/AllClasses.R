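#' @import methods
#' @importFrom Matrix Matrix sparseMatrix forceSymmetric t diag
#' @importClassesFrom Matrix Matrix
NULL

#' SignalTrack: fixed-width binned genomic signal for one mark at one stage
#'
#' Holds one value per fixed-width bin for each chromosome. Values are
#' non-negative; 5mC tracks are additionally bounded in [0, 1].
#'
#' @slot mark character, e.g. "H3K4me3", "DHS", "5mC".
#' @slot stage character stage label, e.g. "E50".
#' @slot binSize integer bin width in bp.
#' @slot values named list, one numeric vector per chromosome with
#'   \code{ceiling(seqlength / binSize)} entries.
#' @slot seqlengths named numeric, chromosome lengths in bp.
#' @exportClass SignalTrack
setClass("SignalTrack",
  representation(mark = "character", stage = "character",
                 binSize = "integer", values = "list",
                 seqlengths = "numeric"))

setValidity("SignalTrack", function(object) {
  msg <- NULL
  if (length(object@binSize) != 1L || object@binSize < 1L)
    msg <- c(msg, "binSize must be a single positive integer")
  if (!identical(sort(names(object@values)), sort(names(object@seqlengths))))
    msg <- c(msg, "values and seqlengths must name the same chromosomes")
  for (chr in names(object@values)) {
    v <- object@values[[chr]]
    nbin <- ceiling(object@seqlengths[[chr]] / object@binSize)
    if (length(v) != nbin)
      msg <- c(msg, sprintf("chromosome %s: expected %d bins, got %d",
                            chr, nbin, length(v)))
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, sprintf("chromosome %s: negative signal values", chr))
    if (identical(object@mark, "5mC") && any(v > 1 + 1e-9, na.rm = TRUE))
      msg <- c(msg, sprintf("chromosome %s: 5mC values must lie in [0,1]", chr))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a SignalTrack
#'
#' @param mark mark name.
#' @param stage stage label.
#' @param binSize bin width in bp.
#' @param values named list of per-chromosome numeric vectors.
#' @param seqlengths named chromosome lengths in bp.
#' @return A \linkS4class{SignalTrack}.
#' @export
SignalTrack <- function(mark, stage, binSize, values, seqlengths) {
  new("SignalTrack", mark = mark, stage = stage,
      binSize = as.integer(binSize), values = as.list(values),
      seqlengths = seqlengths[names(values)])
}

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack: %s @ %s, %d bp bins, %d chromosome(s)\n",
              object@mark, object@stage, object@binSize,
              length(object@values)))
})

#' ContactMatrix: symmetric binned cis Hi-C counts for one chromosome
#'
#' @slot stage character stage label.
#' @slot chrom character chromosome name.
#' @slot binSize integer bin width in bp.
#' @slot counts symmetric sparse \code{Matrix} of non-negative counts,
#'   dimension \code{ceiling(chrom length / binSize)}.
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  representation(stage = "character", chrom = "character",
                 binSize = "integer", counts = "Matrix"))

setValidity("ContactMatrix", function(object) {
  msg <- NULL
  m <- object@counts
  if (nrow(m) != ncol(m)) msg <- c(msg, "counts must be square")
  if (!Matrix::isSymmetric(m, tol = 1e-8))
    msg <- c(msg, "counts must be symmetric")
  if (any(m@x < 0)) msg <- c(msg, "counts must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ContactMatrix
#'
#' @param counts square symmetric matrix (dense or sparse) of counts.
#' @param binSize bin width in bp.
#' @param chrom chromosome name.
#' @param stage stage label.
#' @return A \linkS4class{ContactMatrix}.
#' @export
ContactMatrix <- function(counts, binSize, chrom = "chr1", stage = "") {
  counts <- forceSymmetric(Matrix(counts, sparse = TRUE))
  new("ContactMatrix", stage = stage, chrom = chrom,
      binSize = as.integer(binSize), counts = counts)
}

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %s %s, %d bins of %d bp, %.0f total counts\n",
              object@stage, object@chrom, nrow(object@counts),
              object@binSize, sum(object@counts)))
})

#' TADSet: insulation-based domain segmentation of one chromosome
#'
#' Boundaries are 1-based bin indices and include the first and last
#' analysed bin, so that the domains tile the chromosome and
#' \code{length(boundaries) == nDomains + 1}.
#'
#' @slot stage character stage label.
#' @slot chrom character chromosome name.
#' @slot binSize integer bin width in bp.
#' @slot nBins integer number of bins on the chromosome.
#' @slot boundaries sorted integer bin indices, first == 1.
#' @slot insulation per-bin insulation score (NA near edges), may be empty.
#' @exportClass TADSet
setClass("TADSet",
  representation(stage = "character", chrom = "character",
                 binSize = "integer", nBins = "integer",
                 boundaries = "integer", insulation = "numeric"))

setValidity("TADSet", function(object) {
  b <- object@boundaries
  msg <- NULL
  if (length(b) < 2L) msg <- c(msg, "need at least two boundaries (chromosome ends)")
  if (is.unsorted(b, strictly = TRUE)) msg <- c(msg, "boundaries must be strictly increasing")
  if (length(b) && (b[1L] != 1L || b[length(b)] > object@nBins))
    msg <- c(msg, "boundaries must start at bin 1 and stay within the chromosome")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TADSet
#'
#' @param boundaries sorted bin indices (interior boundaries; chromosome ends
#'   are added if absent).
#' @param nBins number of bins on the chromosome.
#' @param binSize bin width in bp.
#' @param chrom chromosome name.
#' @param stage stage label.
#' @param insulation optional per-bin insulation score.
#' @return A \linkS4class{TADSet}.
#' @export
TADSet <- function(boundaries, nBins, binSize, chrom = "chr1", stage = "",
                   insulation = numeric(0)) {
  b <- sort(unique(as.integer(c(1L, boundaries, nBins))))
  new("TADSet", stage = stage, chrom = chrom, binSize = as.integer(binSize),
      nBins = as.integer(nBins), boundaries = b,
      insulation = as.numeric(insulation))
}

setMethod("show", "TADSet", function(object) {
  d <- domains(object)
  cat(sprintf("TADSet: %s %s, %d domains (median %.0f kb)\n",
              object@stage, object@chrom, nrow(d),
              stats::median(d$end - d$start + 1) * object@binSize / 1000))
})

#' CompartmentProfile: A/B compartment eigenvector for one chromosome
#'
#' @slot stage character stage label.
#' @slot chrom character chromosome.
#' @slot binSize integer analysis bin width in bp.
#' @slot eigen leading eigenvector of the O/E correlation matrix.
#' @slot labels per-bin "A"/"B" (NA for masked bins).
#' @slot orientation one of "oriented", "unoriented", "undetermined".
#' @exportClass CompartmentProfile
setClass("CompartmentProfile",
  representation(stage = "character", chrom = "character",
                 binSize = "integer", eigen = "numeric",
                 labels = "character", orientation = "character"))

setMethod("show", "CompartmentProfile", function(object) {
  cat(sprintf("CompartmentProfile: %s %s, %d bins (%s), %d A / %d B\n",
              object@stage, object@chrom, length(object@eigen),
              object@orientation,
              sum(object@labels == "A", na.rm = TRUE),
              sum(object@labels == "B", na.rm = TRUE)))
})

#' LoopSet: cis chromatin loops with ordered anchors
#'
#' @slot stage character stage label.
#' @slot anchors1 GRanges of upstream anchors.
#' @slot anchors2 GRanges of downstream anchors (same chromosome, start
#'   not before the matching anchor1).
#' @slot strength numeric loop strength (e.g. observed/expected).
#' @exportClass LoopSet
setClass("LoopSet",
  representation(stage = "character", anchors1 = "GRanges",
                 anchors2 = "GRanges", strength = "numeric"))

setValidity("LoopSet", function(object) {
  msg <- NULL
  n <- length(object@anchors1)
  if (length(object@anchors2) != n || length(object@strength) != n)
    msg <- c(msg, "anchors1, anchors2 and strength must have equal length")
  if (n > 0) {
    if (!all(as.character(GenomeInfoDb::seqnames(object@anchors1)) ==
             as.character(GenomeInfoDb::seqnames(object@anchors2))))
      msg <- c(msg, "loop anchors must lie on the same chromosome")
    if (any(BiocGenerics::start(object@anchors1) >
            BiocGenerics::start(object@anchors2)))
      msg <- c(msg, "anchor1 must not lie downstream of anchor2")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a LoopSet
#'
#' Anchor pairs are reordered so that anchor1 is the upstream anchor.
#'
#' @param anchors1,anchors2 GRanges of equal length.
#' @param strength numeric loop strengths (default 1).
#' @param stage stage label.
#' @return A \linkS4class{LoopSet}.
#' @export
LoopSet <- function(anchors1, anchors2, strength = rep(1, length(anchors1)),
                    stage = "") {
  swap <- BiocGenerics::start(anchors1) > BiocGenerics::start(anchors2)
  if (any(swap)) {
    tmp <- anchors1[swap]
    anchors1[swap] <- anchors2[swap]
    anchors2[swap] <- tmp
  }
  new("LoopSet", stage = stage, anchors1 = anchors1, anchors2 = anchors2,
      strength = as.numeric(strength))
}

setMethod("show", "LoopSet", function(object) {
  cat(sprintf("LoopSet: %s, %d loops\n", object@stage,
              length(object@anchors1)))
})

setMethod("length", "LoopSet", function(x) length(x@anchors1))

## ---- generics and accessors -------------------------------------------------

#' @rdname accessors
#' @param x an epidyn object.
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))
#' Accessors for epidyn S4 containers
#'
#' \code{stageLabel}, \code{chromName}, \code{binSize}, \code{trackValues},
#' \code{contactCounts}, \code{boundaries}, \code{insulation},
#' \code{domains}, \code{eigenvector}, \code{compartmentLabels},
#' \code{loopAnchors} and \code{loopStrength} read the corresponding slots.
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("stageLabel", "SignalTrack", function(x) x@stage)
#' @rdname accessors
#' @export
setMethod("stageLabel", "ContactMatrix", function(x) x@stage)
#' @rdname accessors
#' @export
setMethod("stageLabel", "TADSet", function(x) x@stage)
#' @rdname accessors
#' @export
setMethod("stageLabel", "CompartmentProfile", function(x) x@stage)
#' @rdname accessors
#' @export
setMethod("stageLabel", "LoopSet", function(x) x@stage)

#' @rdname accessors
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @rdname accessors
#' @export
setMethod("chromName", "ContactMatrix", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("chromName", "TADSet", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("chromName", "CompartmentProfile", function(x) x@chrom)

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setMethod("binSize", "SignalTrack", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "TADSet", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "CompartmentProfile", function(x) x@binSize)

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("markName", function(x) standardGeneric("markName"))
#' @rdname accessors
#' @export
setMethod("markName", "SignalTrack", function(x) x@mark)

#' @rdname accessors
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @rdname accessors
#' @export
setMethod("contactCounts", "ContactMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("boundaries", function(x) standardGeneric("boundaries"))
#' @rdname accessors
#' @export
setMethod("boundaries", "TADSet", function(x) x@boundaries)

#' @rdname accessors
#' @export
setGeneric("insulation", function(x) standardGeneric("insulation"))
#' @rdname accessors
#' @export
setMethod("insulation", "TADSet", function(x) x@insulation)

#' @rdname accessors
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))
#' @rdname accessors
#' @details \code{domains} returns a data.frame of per-domain start/end bin
#'   indices (inclusive); domain i spans bins \code{boundaries[i]} to
#'   \code{boundaries[i+1] - 1}, the last domain extends to the final bin.
#' @export
setMethod("domains", "TADSet", function(x) {
  b <- x@boundaries
  k <- length(b) - 1L
  data.frame(start = b[-length(b)],
             end = c(b[-c(1L, length(b))] - 1L, b[length(b)]))
})

#' @rdname accessors
#' @export
setGeneric("eigenvector", function(x) standardGeneric("eigenvector"))
#' @rdname accessors
#' @export
setMethod("eigenvector", "CompartmentProfile", function(x) x@eigen)

#' @rdname accessors
#' @export
setGeneric("compartmentLabels", function(x) standardGeneric("compartmentLabels"))
#' @rdname accessors
#' @export
setMethod("compartmentLabels", "CompartmentProfile", function(x) x@labels)

#' @rdname accessors
#' @param which 1 or 2, which anchor set to return.
#' @export
setGeneric("loopAnchors", function(x, which = 1L) standardGeneric("loopAnchors"))
#' @rdname accessors
#' @export
setMethod("loopAnchors", "LoopSet", function(x, which = 1L) {
  if (which == 1L) x@anchors1 else x@anchors2
})

#' @rdname accessors
#' @export
setGeneric("loopStrength", function(x) standardGeneric("loopStrength"))
#' @rdname accessors
#' @export
setMethod("loopStrength", "LoopSet", function(x) x@strength)
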