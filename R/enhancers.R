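#' @importFrom IRanges subsetByOverlaps
#' @importFrom S4Vectors List
NULL

#' Call putative enhancers by the multi-evidence rule
#'
#' The enhancer unit is the merged union of H3K27ac peaks (book-ended
#' peaks joined). A unit is called when it (i) also carries CTCF and DHS
#' peak signal (>= 1 bp overlap each), (ii) does not overlap any promoter,
#' and (iii) overlaps a loop anchor whose partner anchor overlaps a
#' promoter whose TSS lies within \code{window} bp of the element. Target
#' genes are recorded.
#'
#' @param k27acPeaks,ctcfPeaks,dhsPeaks GRanges of peaks at one stage.
#' @param promoters GRanges of promoter windows with \code{gene_id}.
#' @param genes GRanges of genes (for TSS distances), parallel to
#'   \code{promoters}.
#' @param loops a \linkS4class{LoopSet} for the stage.
#' @param window maximal TSS distance in bp (default 3 Mb).
#' @param stage stage label attached to the calls.
#' @return GRanges of enhancer calls with \code{targets} (CharacterList),
#'   \code{nTargets} and \code{stage}; empty (with a warning) when no
#'   loops are supplied.
#' @export
callEnhancers <- function(k27acPeaks, ctcfPeaks, dhsPeaks, promoters,
                          genes, loops, window = 3e6, stage = "") {
  if (is.null(k27acPeaks) || is.null(ctcfPeaks) || is.null(dhsPeaks))
    stop("missing mark: enhancer calling needs H3K27ac, CTCF and DHS peaks")
  cand <- reduce(k27acPeaks, min.gapwidth = 1L)
  cand <- cand[countOverlaps(cand, ctcfPeaks) > 0 &
               countOverlaps(cand, dhsPeaks) > 0]
  cand <- cand[countOverlaps(cand, promoters) == 0]
  empty <- function() {
    out <- GRanges()
    mcols(out) <- DataFrame(targets = S4Vectors::SimpleList(),
                            nTargets = integer(0),
                            stage = character(0))
    out
  }
  if (length(loops) == 0) {
    warning("no loops supplied: no enhancers called")
    return(empty())
  }
  tss <- tssOf(genes)
  a1 <- loopAnchors(loops, 1L); a2 <- loopAnchors(loops, 2L)
  targets <- vector("list", length(cand))
  for (side in 1:2) {
    ea <- if (side == 1) a1 else a2
    pa <- if (side == 1) a2 else a1
    hit <- findOverlaps(cand, ea)
    if (length(hit) == 0) next
    ph <- findOverlaps(pa[subjectHits(hit)], promoters)
    for (k in seq_along(ph)) {
      ci <- queryHits(hit)[queryHits(ph)[k]]
      gi <- subjectHits(ph)[k]
      mid <- (start(cand)[ci] + end(cand)[ci]) / 2
      if (abs(tss[gi] - mid) <= window)
        targets[[ci]] <- c(targets[[ci]], mcols(promoters)$gene_id[gi])
    }
  }
  keep <- lengths(targets) > 0
  out <- cand[keep]
  mcols(out)$targets <- S4Vectors::SimpleList(lapply(targets[keep], unique))
  mcols(out)$nTargets <- lengths(mcols(out)$targets)
  mcols(out)$stage <- rep(stage, length(out))
  out
}

#' Classify enhancer calls into super versus typical enhancers
#'
#' Pure size rule on the merged call: length >= 8000 bp is an SE,
#' otherwise a TE.
#'
#' @param calls GRanges of enhancer calls (already merged).
#' @param seMinLength SE length cutoff in bp (default 8000, inclusive).
#' @return the calls with a \code{class} column ("SE"/"TE").
#' @export
classifySeTe <- function(calls, seMinLength = 8000L) {
  mcols(calls)$class <- ifelse(width(calls) >= seMinLength, "SE", "TE")
  calls
}

#' Partition enhancers into stage-specific and stage-common lineages
#'
#' Calls from different stages are linked into lineages by reciprocal
#' overlap (interval Jaccard >= \code{jaccardMin}); lineages present at
#' every stage are common, those present at exactly one stage are
#' specific, the rest partial.
#'
#' @param callsByStage named list (stage -> GRanges) of enhancer calls.
#' @param jaccardMin minimal interval Jaccard linking two calls (default
#'   0.5).
#' @return list with \code{lineage} (per-stage integer lineage ids,
#'   parallel to the input calls), \code{lineageClass} (named by lineage:
#'   "specific", "common", "partial") and counts.
#' @export
stagePartition <- function(callsByStage, jaccardMin = 0.5) {
  stages <- names(callsByStage)
  if (length(stages) < 2) stop("need at least two stages")
  all <- do.call(c, lapply(stages, function(st) {
    g <- callsByStage[[st]]
    mcols(g) <- DataFrame(stg = rep(st, length(g)))
    g
  }))
  n <- length(all)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  hits <- findOverlaps(all, all)
  for (k in seq_along(hits)) {
    i <- queryHits(hits)[k]; j <- subjectHits(hits)[k]
    if (i >= j) next
    if (mcols(all)$stg[i] == mcols(all)$stg[j]) next
    inter <- min(end(all)[i], end(all)[j]) - max(start(all)[i],
                                                 start(all)[j]) + 1L
    uni <- max(end(all)[i], end(all)[j]) - min(start(all)[i],
                                               start(all)[j]) + 1L
    if (inter / uni >= jaccardMin) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  lid <- match(root, sort(unique(root)))
  nStagesPerLineage <- tapply(mcols(all)$stg, lid,
                              function(s) length(unique(s)))
  cls <- ifelse(nStagesPerLineage == length(stages), "common",
                ifelse(nStagesPerLineage == 1L, "specific", "partial"))
  perStage <- split(lid, factor(mcols(all)$stg, levels = stages))
  list(lineage = perStage,
       lineageClass = setNames(as.character(cls),
                               names(nStagesPerLineage)),
       nSpecific = sum(cls == "specific"),
       nCommon = sum(cls == "common"),
       nPartial = sum(cls == "partial"))
}

.targetBins <- c("1", "2-5", "6-14", "15-30", ">30")

.binTargets <- function(n) {
  cut(n, breaks = c(0, 1, 5, 14, 30, Inf), labels = .targetBins)
}

#' Target-count distribution and SE/TE odds ratios per target bin
#'
#' Bins enhancers by their number of loop-linked promoter targets
#' (1, 2-5, 6-14, 15-30, >30) and computes, per bin, the odds ratio of SE
#' to TE membership (bin vs rest) with a two-sided Fisher p.
#'
#' @param calls GRanges of classified enhancer calls (with \code{class}
#'   and \code{nTargets}).
#' @return list with \code{histogram} (class x bin counts),
#'   \code{fractionSingleTarget}, and a data.frame \code{oddsRatios}.
#' @export
targetCountDistribution <- function(calls) {
  bin <- .binTargets(mcols(calls)$nTargets)
  cls <- factor(mcols(calls)$class, c("SE", "TE"))
  h <- table(cls, bin)
  ors <- do.call(rbind, lapply(.targetBins, function(b) {
    a <- h["SE", b]; bb <- sum(h["SE", ]) - a
    cc <- h["TE", b]; dd <- sum(h["TE", ]) - cc
    tab <- matrix(c(a, bb, cc, dd), 2, 2, byrow = TRUE)
    data.frame(bin = b, se = a, te = cc,
               oddsRatio = oddsRatio(tab),
               p = fisherExact(tab))
  }))
  list(histogram = h,
       fractionSingleTarget = mean(mcols(calls)$nTargets == 1),
       oddsRatios = ors)
}

#' Per-element active score over stages
#'
#' Element-level analogue of the gene active signal: normalised H3K27ac +
#' DHS - H3K27me3 averaged over the element, per stage.
#'
#' @param elements GRanges of cis-elements.
#' @param tracksByMark named list (mark -> list of SignalTracks, one per
#'   stage) for H3K27ac, DHS and H3K27me3.
#' @param stages ordered stage labels.
#' @return elements x stages numeric matrix.
#' @export
elementActiveScore <- function(elements, tracksByMark, stages) {
  get <- function(mark) {
    trs <- tracksByMark[[mark]]
    out <- vapply(stages, function(st) {
      tr <- trs[[st]]
      if (is.null(tr)) stop("missing track for ", mark, " at ", st)
      quantifyRegion(tr, elements)
    }, numeric(length(elements)))
    matrix(out, nrow = length(elements),
           dimnames = list(NULL, stages))
  }
  sc <- get("H3K27ac") + get("DHS") - get("H3K27me3")
  rownames(sc) <- if (!is.null(names(elements))) names(elements)
                  else as.character(seq_along(elements))
  sc
}

#' Select cis-elements whose activity tracks target expression
#'
#' Keeps an element iff the Pearson correlation between its per-stage
#' active-score trajectory and the expression trajectory of one of its
#' target genes is >= \code{rMin} (one-sided; anti-correlated elements are
#' dropped). Ties to multiple targets keep the maximal-r pairing;
#' constant trajectories are skipped with a note.
#'
#' @param scores elements x stages active-score matrix.
#' @param expr genes x stages expression matrix.
#' @param targets list of character vectors: target gene ids per element.
#' @param rMin correlation threshold (default 0.8).
#' @return DataFrame with \code{element}, \code{gene}, \code{r} for the
#'   selected elements.
#' @export
selectCorrelatedElements <- function(scores, expr, targets, rMin = 0.8) {
  if (ncol(scores) < 4) stop("need at least 4 stages for a meaningful r")
  sel <- lapply(seq_len(nrow(scores)), function(i) {
    tr <- scores[i, ]
    if (sd(tr) == 0) {
      message("element ", rownames(scores)[i],
              ": constant trajectory, skipped")
      return(NULL)
    }
    tg <- intersect(targets[[i]], rownames(expr))
    if (length(tg) == 0) return(NULL)
    rs <- vapply(tg, function(g) {
      e <- expr[g, ]
      if (sd(e) == 0) return(NA_real_)
      cor(tr, e)
    }, numeric(1))
    if (all(is.na(rs))) return(NULL)
    best <- which.max(rs)
    if (rs[best] >= rMin)
      data.frame(element = rownames(scores)[i], gene = tg[best],
                 r = rs[best])
    else NULL
  })
  out <- do.call(rbind, sel)
  if (is.null(out))
    out <- data.frame(element = character(0), gene = character(0),
                      r = numeric(0))
  DataFrame(out)
}

#' Cluster cis-element trajectories into modules
#'
#' Average-linkage hierarchical clustering on 1 - Pearson correlation of
#' the stage trajectories; k chosen by mean silhouette over 2..8 when not
#' given. Module labels are renumbered by order of first occurrence over
#' lexicographically sorted element names, so the partition is invariant
#' to input order.
#'
#' @param scores elements x stages matrix of the selected elements.
#' @param k number of modules, or NULL for the silhouette choice.
#' @param kRange candidate k values when \code{k} is NULL.
#' @return named integer vector of module labels.
#' @export
clusterElements <- function(scores, k = NULL, kRange = 2:8) {
  if (nrow(scores) < 2) stop("need at least two elements")
  o <- order(rownames(scores))
  scores <- scores[o, , drop = FALSE]
  cc <- suppressWarnings(cor(t(scores)))
  cc[!is.finite(cc)] <- 0
  dd <- stats::as.dist(1 - cc)
  hc <- stats::hclust(dd, method = "average")
  if (is.null(k)) {
    kRange <- kRange[kRange < nrow(scores)]
    if (length(kRange) == 0) kRange <- 2L
    silw <- vapply(kRange, function(kk) {
      ct <- stats::cutree(hc, k = kk)
      mean(cluster::silhouette(ct, dd)[, "sil_width"])
    }, numeric(1))
    k <- kRange[which.max(silw)]
  }
  if (k > nrow(scores)) stop("fewer elements than clusters requested")
  ct <- stats::cutree(hc, k = k)
  lab <- match(ct, unique(ct))
  names(lab) <- rownames(scores)
  lab
}
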