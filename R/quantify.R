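#' @importFrom SummarizedExperiment SummarizedExperiment assays assay
#'   assayNames rowRanges colData
#' @importFrom S4Vectors metadata metadata<-
NULL

#' Length-weighted mean signal over a region
#'
#' Averages the bin values of a \linkS4class{SignalTrack} over a genomic
#' region, weighting each bin by the number of bp it contributes, i.e. the
#' per-bp mean across the region.
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param region GRanges of length >= 1 (vectorised).
#' @return numeric, one value per region; empty (zero-width) regions give 0
#'   with a warning.
#' @export
quantifyRegion <- function(track, region) {
  bs <- binSize(track)
  out <- numeric(length(region))
  w <- width(region)
  if (any(w == 0)) warning("empty region(s): returning 0")
  chs <- as.character(seqnames(region))
  for (ch in unique(chs)) {
    v <- track@values[[ch]]
    if (is.null(v)) stop("track has no chromosome ", ch)
    cs <- cumsum(as.numeric(v))
    sel <- which(chs == ch & w > 0)
    if (!length(sel)) next
    s <- start(region)[sel]; e <- end(region)[sel]
    b1 <- (s - 1L) %/% bs + 1L
    b2 <- (e - 1L) %/% bs + 1L
    ## bp-weighted sum = partial first bin + partial last bin + full middle
    firstEnd <- pmin(b1 * bs, e)
    lastStart <- pmax((b2 - 1L) * bs + 1L, s)
    sums <- v[b1] * (firstEnd - s + 1)
    multi <- b2 > b1
    sums[multi] <- sums[multi] + v[b2[multi]] *
      (e[multi] - lastStart[multi] + 1)
    mid <- b2 - b1 > 1L
    if (any(mid))
      sums[mid] <- sums[mid] +
        (cs[b2[mid] - 1L] - cs[b1[mid]]) * bs
    out[sel] <- sums / (e - s + 1)
  }
  out
}

#' Quantify gene signals into a genes x stages x marks container
#'
#' Builds a \link[SummarizedExperiment]{SummarizedExperiment} whose rows are
#' genes, columns are stages (in the given order) and assays are marks:
#' each cell is the length-weighted mean signal over the promoter window or
#' gene body.
#'
#' @param tracks list of \linkS4class{SignalTrack} covering the required
#'   (mark, stage) combinations.
#' @param genes GRanges of genes (with \code{gene_id}).
#' @param stages ordered character vector of stage labels.
#' @param region "promoter" (TSS +/- \code{halfwidth}) or "body" (the full
#'   gene extent).
#' @param halfwidth promoter half-width in bp.
#' @return SummarizedExperiment with one assay per mark;
#'   \code{metadata(x)$region} records the region type and
#'   \code{metadata(x)$normalized} is "none".
#' @export
quantifySignals <- function(tracks, genes, stages,
                            region = c("promoter", "body"),
                            halfwidth = 2000) {
  region <- match.arg(region)
  reg <- if (region == "promoter") promoterOf(genes, halfwidth) else genes
  marks <- unique(vapply(tracks, markName, character(1)))
  am <- lapply(marks, function(mk) {
    m <- matrix(NA_real_, length(genes), length(stages),
                dimnames = list(mcols(genes)$gene_id, stages))
    for (tr in tracks) {
      if (markName(tr) != mk) next
      st <- stageLabel(tr)
      if (!st %in% stages) next
      m[, st] <- quantifyRegion(tr, reg)
    }
    if (anyNA(m)) stop("missing track for mark ", mk, " at stage(s) ",
                       paste(stages[colSums(is.na(m)) > 0], collapse = ", "))
    m
  })
  names(am) <- marks
  se <- SummarizedExperiment(assays = am, rowRanges = genes,
                             colData = DataFrame(stage = stages,
                                                 row.names = stages))
  metadata(se)$region <- region
  metadata(se)$normalized <- "none"
  se
}

#' Normalise a gene-signal matrix across stages
#'
#' Makes stage columns comparable within each mark. Methods: "quantile"
#' (columns share the same sorted values; robust to stage-to-stage
#' efficiency shifts), "z" (column standardisation; constant columns give
#' zeros with a warning) and "minmax" (column [0,1] scaling).
#'
#' @param se SummarizedExperiment from \code{\link{quantifySignals}}.
#' @param method normalisation method.
#' @return SummarizedExperiment with the same shape;
#'   \code{metadata(x)$normalized} records the method.
#' @export
normalizeStages <- function(se, method = c("quantile", "z", "minmax")) {
  method <- match.arg(method)
  if (ncol(se) < 2) stop("need at least two stages")
  norm1 <- function(m) {
    switch(method,
      quantile = limma::normalizeQuantiles(m),
      z = {
        sds <- apply(m, 2, sd)
        if (any(sds == 0)) warning("constant column under z: returning zeros")
        out <- scale(m)
        out[, sds == 0] <- 0
        out[] <- ifelse(is.finite(out), out, 0)
        out
      },
      minmax = {
        apply(m, 2, function(x) {
          r <- range(x)
          if (r[1] == r[2]) rep(0, length(x)) else (x - r[1]) / diff(r)
        })
      })
  }
  out <- se
  for (mk in assayNames(se)) {
    m <- assay(se, mk)
    nm <- norm1(m)
    dimnames(nm) <- dimnames(m)
    SummarizedExperiment::assay(out, mk) <- nm
  }
  metadata(out)$normalized <- method
  out
}

#' Call stage-specific signals per gene
#'
#' A gene is specific to its maximal stage s iff value(s) >= foldMin x the
#' maximum over the other stages, and the z-score of value(s) against the
#' other stages is >= zMin. Both criteria are invariant to global
#' rescaling of the mark.
#'
#' @param se normalised SummarizedExperiment (>= 3 stages).
#' @param mark assay name to call on.
#' @param zMin minimal z-score of the candidate stage against the rest.
#' @param foldMin minimal fold over the maximum of the other stages.
#' @return DataFrame with \code{gene_id}, \code{stage} (NA when not
#'   specific) and \code{score} (the z-score).
#' @export
callStageSpecific <- function(se, mark, zMin = 1.5, foldMin = 2.0) {
  if (ncol(se) < 3) stop("need at least 3 stages for a robust z-score")
  m <- assay(se, mark)
  idx <- max.col(m, ties.method = "first")
  n <- nrow(m)
  vmax <- m[cbind(seq_len(n), idx)]
  rest <- t(vapply(seq_len(n), function(i) m[i, -idx[i]],
                   numeric(ncol(m) - 1L)))
  restMax <- apply(rest, 1, max)
  mu <- rowMeans(rest)
  sdv <- apply(rest, 1, sd)
  z <- ifelse(sdv > 0, (vmax - mu) / sdv,
              ifelse(vmax > mu, Inf, 0))
  fold <- ifelse(restMax > 0, vmax / restMax, ifelse(vmax > 0, Inf, 1))
  ok <- z >= zMin & fold >= foldMin
  DataFrame(gene_id = rownames(m),
            stage = ifelse(ok, colnames(m)[idx], NA_character_),
            score = z)
}

#' Proportion of enriched features changing at the next stage
#'
#' For each adjacent stage pair (s, s+1): among features enriched (or
#' expressed) at stage s, the fraction whose signal changes by at least
#' \code{changeFold} in either direction. A pseudocount tames zeros before
#' the fold computation.
#'
#' @param values features x stages numeric matrix of quantified signal or
#'   expression.
#' @param enriched logical matrix of the same shape flagging the features
#'   considered enriched/expressed at each stage; by default
#'   \code{values >= exprMin}.
#' @param changeFold fold threshold (default 2).
#' @param exprMin enrichment threshold used when \code{enriched} is NULL.
#' @param pseudocount added before the ratio (default 0.5).
#' @return named numeric, one proportion per transition (NA when the
#'   enriched set at the earlier stage is empty).
#' @export
dynamicRate <- function(values, enriched = NULL, changeFold = 2.0,
                        exprMin = 1.0, pseudocount = 0.5) {
  if (ncol(values) < 2) stop("need at least two consecutive stages")
  if (is.null(enriched)) enriched <- values >= exprMin
  stopifnot(all(dim(enriched) == dim(values)))
  out <- numeric(ncol(values) - 1L)
  names(out) <- paste(colnames(values)[-ncol(values)],
                      colnames(values)[-1], sep = "->")
  for (s in seq_len(ncol(values) - 1L)) {
    sel <- enriched[, s]
    if (!any(sel)) { out[s] <- NA_real_; next }
    lfc <- abs(log2((values[sel, s + 1] + pseudocount) /
                    (values[sel, s] + pseudocount)))
    out[s] <- mean(lfc >= log2(changeFold))
  }
  out
}

#' Pearson correlation between two replicate tracks
#'
#' Computed over bins where at least one of the two tracks is nonzero.
#'
#' @param trackA,trackB \linkS4class{SignalTrack}s on the same binning.
#' @return Pearson r.
#' @export
replicateCorrelation <- function(trackA, trackB) {
  if (binSize(trackA) != binSize(trackB))
    stop("tracks must share the same binning")
  a <- unlist(trackA@values, use.names = FALSE)
  b <- unlist(trackB@values, use.names = FALSE)
  if (length(a) != length(b)) stop("tracks must cover the same bins")
  keep <- a != 0 | b != 0
  if (sum(keep) < 2) stop("fewer than 2 informative bins")
  cor(a[keep], b[keep])
}
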