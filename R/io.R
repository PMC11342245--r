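#' @importFrom GenomicRanges GRanges promoters trim reduce findOverlaps
#'   countOverlaps seqnames strand width resize
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels keepSeqlevels
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom BiocGenerics start end range
#' @importFrom utils read.table write.table
NULL

#' Read a gene annotation (BED12 or GTF) into a GRanges
#'
#' Gene records carry \code{gene_id} and \code{biotype} metadata columns.
#' For GTF input, multiple transcripts of one gene are collapsed to the
#' outermost coordinates. The TSS is the strand-aware 5' end
#' (\code{start} for "+", \code{end} for "-").
#'
#' @param path annotation file.
#' @param dialect "BED12", "GTF", or "auto" (by file extension).
#' @param chromSizes optional named vector of chromosome lengths; inferred
#'   from the outermost annotated coordinate per chromosome when absent.
#' @return GRanges with \code{gene_id} and \code{biotype} columns and
#'   seqlengths set.
#' @export
readAnnotation <- function(path, dialect = c("auto", "BED12", "GTF"),
                           chromSizes = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "GTF" else "BED12"
  }
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "BED12") {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e) stop("BED parse error in ", path,
                                            ": ", conditionMessage(e)))
    ids <- mcols(gr)$name
    if (anyDuplicated(ids))
      stop("duplicate gene_id in annotation: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    mcols(gr) <- DataFrame(gene_id = ids,
                           biotype = rep("unknown", length(gr)))
  } else {
    raw <- tryCatch(rtracklayer::import(path, format = "GTF"),
                    error = function(e) stop("GTF parse error in ", path,
                                             ": ", conditionMessage(e)))
    if (is.null(mcols(raw)$gene_id)) stop("GTF lacks gene_id attributes")
    spl <- S4Vectors::split(raw, mcols(raw)$gene_id)
    rng <- unlist(range(spl))
    bt <- vapply(spl, function(x) {
      b <- mcols(x)$gene_biotype
      if (is.null(b)) b <- mcols(x)$gene_type
      if (is.null(b) || all(is.na(b))) "unknown" else as.character(b[!is.na(b)][1L])
    }, character(1))
    gr <- rng
    mcols(gr) <- DataFrame(gene_id = names(rng), biotype = bt[names(rng)])
    names(gr) <- NULL
  }
  chroms <- as.character(unique(seqnames(gr)))
  if (is.null(chromSizes)) {
    chromSizes <- vapply(chroms, function(ch)
      max(end(gr[seqnames(gr) == ch])), numeric(1))
  }
  seqlengths(gr) <- chromSizes[seqlevels(gr)]
  bad <- end(gr) > seqlengths(gr)[as.character(seqnames(gr))]
  if (any(bad))
    stop("gene(s) beyond chromosome bounds: ",
         paste(mcols(gr)$gene_id[bad], collapse = ", "))
  gr
}

#' Strand-aware TSS positions of gene records
#'
#' @param genes GRanges of genes.
#' @return integer vector of TSS coordinates (1-based).
#' @export
tssOf <- function(genes) {
  ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' Promoter window around the TSS
#'
#' Returns the window TSS +/- \code{halfwidth}, clipped to the chromosome.
#' With \code{halfwidth = 0} the result is a zero-width range at the TSS.
#'
#' @param genes GRanges of genes (seqlengths set for clipping).
#' @param halfwidth half-width in bp (default 2000, i.e. TSS +/- 2 kb).
#' @return GRanges of promoter windows, parallel to \code{genes}.
#' @export
promoterOf <- function(genes, halfwidth = 2000) {
  p <- suppressWarnings(promoters(genes, upstream = halfwidth,
                                  downstream = halfwidth))
  suppressWarnings(trim(p))
}

#' Read a triplet-format cis contact matrix
#'
#' The file holds whitespace-separated lines \code{bin_i bin_j count} with
#' 0-based bin indices. Duplicate pairs (including mirrored ones) are
#' summed; the matrix is symmetrised and missing pairs are zero.
#'
#' @param path triplet file.
#' @param binSize bin width in bp.
#' @param chromLength chromosome length in bp (sets the dimension).
#' @param chrom,stage labels carried into the object.
#' @return A \linkS4class{ContactMatrix}.
#' @export
readContacts <- function(path, binSize, chromLength, chrom = "chr1",
                         stage = "") {
  n <- as.integer(ceiling(chromLength / binSize))
  if (file.size(path) == 0) {
    m <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                      dims = c(n, n))
    return(ContactMatrix(m, binSize, chrom, stage))
  }
  tr <- read.table(path, header = FALSE,
                   col.names = c("i", "j", "count"))
  if (any(tr$count < 0)) stop("negative contact count in ", path)
  if (any(tr$i < 0 | tr$j < 0 | tr$i >= n | tr$j >= n))
    stop("bin index beyond chromosome in ", path)
  a <- sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$count,
                    dims = c(n, n))
  s <- a + Matrix::t(a)
  diag(s) <- diag(s) / 2
  ContactMatrix(s, binSize, chrom, stage)
}

#' Write a ContactMatrix as a 0-based triplet file (upper triangle)
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param path output file.
#' @export
writeContacts <- function(cm, path) {
  m <- Matrix::triu(as(contactCounts(cm), "generalMatrix"))
  tm <- as(m, "TsparseMatrix")
  o <- order(tm@i, tm@j)
  write.table(data.frame(i = tm@i[o], j = tm@j[o], count = tm@x[o]),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read/write BED interval files
#'
#' Thin wrappers over rtracklayer keeping BED's 0-based half-open
#' convention at the file boundary.
#'
#' @param path file path.
#' @return \code{readBed} returns a GRanges.
#' @export
readBed <- function(path) rtracklayer::import(path, format = "BED")

#' @rdname readBed
#' @param gr GRanges to write.
#' @param sort sort by position before writing (default TRUE).
#' @export
writeBed <- function(gr, path, sort = TRUE) {
  if (sort) gr <- GenomicRanges::sort(gr)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Convert a SignalTrack to a GRanges of bins with a score column
#'
#' @param track a \linkS4class{SignalTrack}.
#' @return GRanges with one range per bin and \code{score} metadata.
#' @export
trackToGRanges <- function(track) {
  bs <- binSize(track)
  pieces <- lapply(names(track@values), function(ch) {
    v <- track@values[[ch]]
    len <- track@seqlengths[[ch]]
    starts <- seq(1L, by = bs, length.out = length(v))
    GRanges(ch, IRanges(starts, pmin(starts + bs - 1L, len)), score = v)
  })
  gr <- do.call(c, pieces)
  seqlengths(gr) <- track@seqlengths[seqlevels(gr)]
  gr
}

#' Write / read a SignalTrack as bedGraph
#'
#' Round-trip stable for fixed-bin tracks: \code{readBedGraph(writeBedGraph(x))}
#' reproduces the bin values at the written precision.
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param path file path.
#' @export
writeBedGraph <- function(track, path) {
  rtracklayer::export(trackToGRanges(track), path, format = "bedGraph")
  invisible(path)
}

#' @rdname writeBedGraph
#' @param mark,stage labels for the rebuilt track.
#' @param binSize bin width in bp.
#' @param seqlengths named chromosome lengths.
#' @return \code{readBedGraph} returns a \linkS4class{SignalTrack}; bins not
#'   covered by any record are zero.
#' @export
readBedGraph <- function(path, mark, stage, binSize, seqlengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(names(seqlengths), function(ch) {
    nb <- ceiling(seqlengths[[ch]] / binSize)
    v <- numeric(nb)
    sel <- gr[as.character(seqnames(gr)) == ch]
    if (length(sel)) {
      idx <- (start(sel) - 1L) %/% binSize + 1L
      v[idx] <- mcols(sel)$score
    }
    v
  })
  names(vals) <- names(seqlengths)
  SignalTrack(mark, stage, binSize, vals, seqlengths)
}

#' Write / read loops as BEDPE
#'
#' BEDPE is 0-based half-open; anchor1 is written first and is always the
#' upstream anchor.
#'
#' @param loops a \linkS4class{LoopSet}.
#' @param path file path.
#' @export
writeBedpe <- function(loops, path) {
  a1 <- loopAnchors(loops, 1L); a2 <- loopAnchors(loops, 2L)
  df <- data.frame(
    chrom1 = as.character(seqnames(a1)), start1 = start(a1) - 1L,
    end1 = end(a1),
    chrom2 = as.character(seqnames(a2)), start2 = start(a2) - 1L,
    end2 = end(a2),
    name = ".", score = loopStrength(loops))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBedpe
#' @param stage stage label for the rebuilt LoopSet.
#' @return \code{readBedpe} returns a \linkS4class{LoopSet}.
#' @export
readBedpe <- function(path, stage = "") {
  if (file.size(path) == 0)
    return(LoopSet(GRanges(), GRanges(), numeric(0), stage = stage))
  df <- read.table(path, header = FALSE)
  a1 <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
  a2 <- GRanges(df[[4]], IRanges(df[[5]] + 1L, df[[6]]))
  s <- if (ncol(df) >= 8) as.numeric(df[[8]]) else rep(1, nrow(df))
  LoopSet(a1, a2, s, stage = stage)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' Read / write a gene-by-stage numeric matrix as TSV
#'
#' @param path TSV with gene ids in the first column and one column per
#'   stage.
#' @return numeric matrix with gene rownames.
#' @export
readStageMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname readStageMatrix
#' @param m matrix to write.
#' @export
writeStageMatrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
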