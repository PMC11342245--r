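#' @importFrom S4Vectors metadata
NULL

.gasActive <- c("H3K4me3", "H3K27ac", "Pol2", "DHS")
.gasRepressive <- "H3K27me3"

#' Compute the gene active signal (GAS)
#'
#' GAS[g, s] = normalised H3K4me3 + H3K27ac + Pol2 + DHS minus normalised
#' H3K27me3 at gene g and stage s. By default H3K4me3, DHS and H3K27me3
#' are taken from the promoter-level container and Pol2/H3K27ac from the
#' gene-body container when one is supplied; with a single container all
#' five marks come from it.
#'
#' @param se normalised SummarizedExperiment carrying the five marks
#'   (promoter-level when \code{bodySe} is given).
#' @param bodySe optional normalised gene-body-level container for the
#'   marks in \code{bodyMarks}.
#' @param bodyMarks marks read from \code{bodySe} (default Pol2 and
#'   H3K27ac).
#' @return SummarizedExperiment with assay "GAS" plus the five component
#'   matrices retained.
#' @export
computeGAS <- function(se, bodySe = NULL,
                       bodyMarks = c("Pol2", "H3K27ac")) {
  if (identical(metadata(se)$normalized, "none"))
    stop("signals must be normalised before computing GAS")
  pick <- function(mk) {
    src <- if (!is.null(bodySe) && mk %in% bodyMarks) bodySe else se
    if (!mk %in% assayNames(src)) stop("missing mark: ", mk)
    assay(src, mk)
  }
  comp <- lapply(c(.gasActive, .gasRepressive), pick)
  names(comp) <- c(.gasActive, .gasRepressive)
  gas <- comp$H3K4me3 + comp$H3K27ac + comp$Pol2 + comp$DHS - comp$H3K27me3
  args <- list(assays = c(list(GAS = gas), comp), colData = colData(se))
  if (is(se, "RangedSummarizedExperiment"))
    args$rowRanges <- rowRanges(se)
  out <- do.call(SummarizedExperiment, args)
  metadata(out) <- metadata(se)
  out
}

#' Classify promoter chromatin states from peak presence
#'
#' A promoter overlapping (>= \code{minOverlap} bp) both an H3K4me3 and an
#' H3K27me3 peak is bivalent; only H3K4me3 is active; only H3K27me3 is
#' repressive; neither is none.
#'
#' @param k4Peaks,k27Peaks GRanges of H3K4me3 / H3K27me3 peaks at one
#'   stage.
#' @param promoters GRanges of promoter windows.
#' @param minOverlap minimal overlap in bp (default 1).
#' @return character vector of states parallel to \code{promoters}.
#' @export
classifyPromoterState <- function(k4Peaks, k27Peaks, promoters,
                                  minOverlap = 1L) {
  h4 <- countOverlaps(promoters, k4Peaks, minoverlap = minOverlap) > 0
  h27 <- countOverlaps(promoters, k27Peaks, minoverlap = minOverlap) > 0
  ifelse(h4 & h27, "bivalent",
         ifelse(h4, "active", ifelse(h27, "repressive", "none")))
}

#' Promoter states across all stages
#'
#' @param k4PeaksByStage,k27PeaksByStage named lists (stage -> GRanges) of
#'   peaks.
#' @param promoters GRanges of promoter windows with \code{gene_id}.
#' @param stages ordered stage labels.
#' @param minOverlap minimal overlap in bp.
#' @return character matrix genes x stages of states.
#' @export
promoterStates <- function(k4PeaksByStage, k27PeaksByStage, promoters,
                           stages, minOverlap = 1L) {
  m <- vapply(stages, function(st)
    classifyPromoterState(k4PeaksByStage[[st]], k27PeaksByStage[[st]],
                          promoters, minOverlap),
    character(length(promoters)))
  rownames(m) <- mcols(promoters)$gene_id
  m
}

.promStates <- c("bivalent", "active", "repressive", "none")

#' Promoter-state transitions between adjacent stages
#'
#' For each adjacent stage pair, counts every state-to-state transition
#' (each gene counted exactly once per pair, so each 4x4 table sums to the
#' number of genes). BTA genes at stage s were bivalent at stage s-1 (or,
#' with \code{lookback > 1}, at any of the previous \code{lookback} stages
#' while not active in between) and are active at s; BTR genes transition
#' to repressive instead.
#'
#' @param states genes x stages character matrix from
#'   \code{\link{promoterStates}}.
#' @param lookback how many previous stages count as "earlier" for the
#'   bivalent origin (default 1 = the immediately preceding stage).
#' @return list with \code{counts} (4 x 4 x nPairs array), \code{bta} and
#'   \code{btr} (named lists of gene ids per arrival stage).
#' @export
stateTransitions <- function(states, lookback = 1L) {
  ns <- ncol(states)
  if (ns < 2) stop("need at least two stages")
  pairs <- paste(colnames(states)[-ns], colnames(states)[-1], sep = "->")
  counts <- array(0L, dim = c(4, 4, ns - 1L),
                  dimnames = list(from = .promStates, to = .promStates,
                                  pair = pairs))
  bta <- btr <- setNames(vector("list", ns - 1L), colnames(states)[-1])
  for (s in 2:ns) {
    tab <- table(factor(states[, s - 1], .promStates),
                 factor(states[, s], .promStates))
    counts[, , s - 1L] <- as.integer(tab)
    lo <- max(1L, s - lookback)
    wasBivalent <- apply(states[, lo:(s - 1L), drop = FALSE] == "bivalent",
                         1, any)
    notYet <- if (s - 1L >= lo)
      !apply(states[, lo:(s - 1L), drop = FALSE] == "active", 1, any)
    else TRUE
    bta[[s - 1L]] <- rownames(states)[wasBivalent & notYet &
                                      states[, s] == "active"]
    notYetR <- if (s - 1L >= lo)
      !apply(states[, lo:(s - 1L), drop = FALSE] == "repressive", 1, any)
    else TRUE
    btr[[s - 1L]] <- rownames(states)[wasBivalent & notYetR &
                                      states[, s] == "repressive"]
  }
  list(counts = counts, bta = bta, btr = btr)
}

#' Detect the H3K27me3-to-DNA-methylation handoff
#'
#' Flags genes whose promoter H3K27me3 is high at an earlier stage (above
#' the stage-wise \code{k27HighQ} quantile), drops below it at a later
#' stage, and whose promoter methylation at that later stage is at least
#' \code{mCHigh} -- the repressive-mark replacement seen at postnatal
#' stages.
#'
#' @param k27 genes x stages numeric matrix of promoter H3K27me3 signal.
#' @param mC genes x stages matrix of promoter methylation betas in [0,1].
#' @param k27HighQ quantile defining "high" H3K27me3 per stage (default
#'   0.75).
#' @param mCHigh methylation beta threshold (default 0.6).
#' @return DataFrame with \code{gene_id}, \code{handoff} flag and the
#'   first qualifying stage indices \code{s1}, \code{s2} (NA otherwise).
#' @export
methylationHandoff <- function(k27, mC, k27HighQ = 0.75, mCHigh = 0.6) {
  stopifnot(all(dim(k27) == dim(mC)))
  if (any(mC < 0 | mC > 1)) stop("methylation betas must lie in [0, 1]")
  thr <- apply(k27, 2, quantile, probs = k27HighQ)
  high <- sweep(k27, 2, thr, ">=")
  ns <- ncol(k27)
  s1 <- s2 <- rep(NA_integer_, nrow(k27))
  for (i in seq_len(nrow(k27))) {
    hs <- which(high[i, ])
    for (a in hs) {
      later <- which(!high[i, ] & mC[i, ] >= mCHigh)
      later <- later[later > a]
      if (length(later)) { s1[i] <- a; s2[i] <- later[1L]; break }
    }
  }
  DataFrame(gene_id = rownames(k27), handoff = !is.na(s1), s1 = s1, s2 = s2)
}

#' Cumulative activation curves of gene sets
#'
#' For each gene set, the fraction of member genes whose GAS first reaches
#' \code{activeThreshold} by each stage (non-decreasing in stage). The
#' fold contrasts the set fraction against the reference set at
#' \code{atStage}, and significance comes from a seeded label permutation:
#' random sets of the same size drawn from the reference.
#'
#' @param gas genes x stages numeric GAS matrix (or the "GAS" assay of a
#'   \code{\link{computeGAS}} result).
#' @param geneSets named list of character vectors (subsets of the rows).
#' @param activeThreshold GAS value counting as active (default 10, well
#'   above the background sum of the four quantile-normalised active
#'   marks and well below the level of a fully active promoter).
#' @param reference reference gene ids (default all rows).
#' @param atStage stage (index or name) at which the fold is taken
#'   (default the first stage).
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed for the permutation draw.
#' @return list with \code{curves} (sets x stages), \code{refCurve},
#'   \code{fold} and \code{p} per set.
#' @export
cumulativeActivation <- function(gas, geneSets, activeThreshold = 10,
                                 reference = rownames(gas), atStage = 1L,
                                 nPerm = 10000L, seed = 1L) {
  if (inherits(gas, "SummarizedExperiment")) gas <- assay(gas, "GAS")
  if (any(lengths(geneSets) == 0)) stop("empty gene set")
  if (!all(unlist(geneSets) %in% rownames(gas)))
    stop("gene sets must be subsets of the annotated genes")
  if (is.character(atStage)) atStage <- match(atStage, colnames(gas))
  ns <- ncol(gas)
  firstActive <- apply(gas >= activeThreshold, 1, function(x)
    if (any(x)) which(x)[1L] else NA_integer_)
  cumFrac <- function(ids) {
    fa <- firstActive[ids]
    vapply(seq_len(ns), function(s) mean(!is.na(fa) & fa <= s), numeric(1))
  }
  refCurve <- cumFrac(reference)
  curves <- t(vapply(geneSets, cumFrac, numeric(ns)))
  colnames(curves) <- colnames(gas)
  fold <- curves[, atStage] / refCurve[atStage]
  set.seed(seed)
  p <- vapply(seq_along(geneSets), function(k) {
    nset <- length(geneSets[[k]])
    obs <- fold[k]
    permFold <- vapply(seq_len(nPerm), function(j) {
      ids <- sample(reference, nset)
      mean(!is.na(firstActive[ids]) & firstActive[ids] <= atStage) /
        refCurve[atStage]
    }, numeric(1))
    (1 + sum(permFold >= obs)) / (nPerm + 1)
  }, numeric(1))
  names(p) <- names(fold) <- names(geneSets)
  list(curves = curves, refCurve = refCurve, fold = fold, p = p,
       nPerm = nPerm, atStage = colnames(gas)[atStage])
}
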