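#' @importFrom stats lm coef
NULL

.denseCounts <- function(cm) as.matrix(contactCounts(cm))

#' Mean contact count per genomic distance
#'
#' @param cm a \linkS4class{ContactMatrix} (or square matrix).
#' @return numeric vector e with e[d + 1] = mean count at bin distance d
#'   (zeros included), d = 0 .. n-1.
#' @export
expectedByDistance <- function(cm) {
  m <- if (is(cm, "ContactMatrix")) contactCounts(cm) else cm
  n <- nrow(m)
  tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@j >= tm@i
  d <- tm@j[keep] - tm@i[keep]
  sums <- numeric(n)
  if (length(d)) {
    agg <- tapply(tm@x[keep], d, sum)
    sums[as.integer(names(agg)) + 1L] <- agg
  }
  sums / (n - 0:(n - 1L))
}

#' Observed/expected transformation of a contact matrix
#'
#' Each cell is divided by the mean contact count at its distance.
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @return dense numeric O/E matrix (0 where the expected value is 0).
#' @export
oeMatrix <- function(cm) {
  m <- .denseCounts(cm)
  e <- expectedByDistance(cm)
  n <- nrow(m)
  ed <- matrix(e[abs(row(m) - col(m)) + 1L], n, n)
  ifelse(ed > 0, m / ed, 0)
}

#' Iterative correction to equal row sums
#'
#' Simple matrix balancing: repeatedly divides rows/columns by their
#' current coverage until row sums are uniform, masking empty bins.
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param maxIter,tol iteration controls.
#' @return balanced \linkS4class{ContactMatrix} (mean total preserved).
#' @export
balanceMatrix <- function(cm, maxIter = 50L, tol = 1e-4) {
  m <- .denseCounts(cm)
  live <- rowSums(m) > 0
  for (it in seq_len(maxIter)) {
    rs <- rowSums(m)
    target <- mean(rs[live])
    f <- ifelse(live, sqrt(rs / target), 1)
    f[f == 0] <- 1
    m <- m / outer(f, f)
    if (max(abs(rowSums(m)[live] / target - 1)) < tol) break
  }
  ContactMatrix(m, binSize(cm), chromName(cm), stageLabel(cm))
}

.aggregateBins <- function(m, f) {
  n <- nrow(m)
  g <- (seq_len(n) - 1L) %/% f + 1L
  ng <- max(g)
  agg <- matrix(0, ng, ng)
  for (a in seq_len(ng)) {
    ra <- which(g == a)
    for (b in a:ng) {
      agg[a, b] <- agg[b, a] <- sum(m[ra, g == b])
    }
  }
  agg
}

#' Call A/B compartments from a contact matrix
#'
#' Pipeline: optional aggregation to a coarser analysis bin, optional
#' balancing, observed/expected by distance, Pearson correlation matrix,
#' leading eigenvector. The sign is oriented so that "A" (positive)
#' correlates with the orientation signal (DHS signal or gene density);
#' with no orientation input the profile is flagged "unoriented", and an
#' uninformative eigenvector is flagged "undetermined".
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param orient orientation input: a \linkS4class{SignalTrack}, a GRanges
#'   of genes (density is used), a numeric vector per analysis bin, or
#'   NULL.
#' @param targetBinSize analysis bin size in bp (default 400000; must be a
#'   multiple of the matrix bin size). Use the matrix binning when NA.
#' @param balance iteratively correct the matrix first (default TRUE).
#' @return a \linkS4class{CompartmentProfile} at the analysis bin size.
#' @export
callCompartments <- function(cm, orient = NULL, targetBinSize = 400000,
                             balance = TRUE) {
  f <- 1L
  if (!is.na(targetBinSize)) {
    if (targetBinSize %% binSize(cm) != 0)
      stop("targetBinSize must be a multiple of the matrix bin size")
    f <- as.integer(targetBinSize / binSize(cm))
  }
  work <- if (balance) balanceMatrix(cm) else cm
  m <- .denseCounts(work)
  if (f > 1L) m <- .aggregateBins(m, f)
  acm <- ContactMatrix(m, binSize(cm) * f, chromName(cm), stageLabel(cm))
  if (nrow(m) < 10) stop("need at least 10 informative bins")
  oe <- oeMatrix(acm)
  live <- which(rowSums(m) > 0 & apply(oe, 1, sd) > 0)
  if (length(live) < 10) stop("zero-variance matrix: compartments undefined")
  cc <- suppressWarnings(cor(oe[live, live]))
  cc[!is.finite(cc)] <- 0
  ev <- eigen(cc, symmetric = TRUE)
  e1 <- ev$vectors[, 1]
  eig <- rep(NA_real_, nrow(m))
  eig[live] <- e1
  orientation <- "unoriented"
  if (sd(e1) == 0 || ev$values[1] <= 1e-8) orientation <- "undetermined"
  ov <- NULL
  if (!is.null(orient)) {
    if (is(orient, "SignalTrack")) {
      nb <- nrow(m)
      bs <- binSize(acm)
      gr <- GRanges(chromName(cm),
                    IRanges(seq(1L, by = bs, length.out = nb),
                            width = bs))
      GenomeInfoDb::seqlengths(gr) <- setNames(nb * bs, chromName(cm))
      ov <- quantifyRegion(orient, trim(gr))
    } else if (is(orient, "GRanges")) {
      bs <- binSize(acm)
      idx <- (tssOf(orient) - 1L) %/% bs + 1L
      ov <- tabulate(idx[as.character(seqnames(orient)) == chromName(cm)],
                     nbins = nrow(m))
    } else ov <- as.numeric(orient)
    if (orientation != "undetermined") {
      r <- suppressWarnings(cor(eig[live], ov[live]))
      if (is.na(r) || abs(r) < 0.1) orientation <- "undetermined"
      else {
        if (r < 0) eig <- -eig
        orientation <- "oriented"
      }
    }
  }
  labels <- ifelse(is.na(eig), NA_character_, ifelse(eig > 0, "A", "B"))
  new("CompartmentProfile", stage = stageLabel(cm), chrom = chromName(cm),
      binSize = as.integer(binSize(acm)), eigen = eig, labels = labels,
      orientation = orientation)
}

#' Per-bin compartment switches between two stages
#'
#' @param p1,p2 \linkS4class{CompartmentProfile}s on the same binning.
#' @return list with \code{switch} (per-bin "A->B", "B->A", "stable", NA
#'   for masked bins), \code{fracSwitched} and a count table.
#' @export
compartmentSwitches <- function(p1, p2) {
  if (binSize(p1) != binSize(p2) ||
      length(eigenvector(p1)) != length(eigenvector(p2)))
    stop("compartment profiles must share the same binning")
  l1 <- compartmentLabels(p1); l2 <- compartmentLabels(p2)
  sw <- ifelse(is.na(l1) | is.na(l2), NA_character_,
               ifelse(l1 == l2, "stable", paste0(l1, "->", l2)))
  ok <- !is.na(sw)
  list(switch = sw,
       fracSwitched = mean(sw[ok] != "stable"),
       table = table(sw[ok]))
}

#' Insulation score along the diagonal
#'
#' For each bin, the mean contact count in the window x window square of
#' pixels crossing it, log2-scaled against the chromosome-wide mean of the
#' same statistic. Local minima mark TAD boundaries.
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param window window size in bins (default 10).
#' @return numeric per-bin score (NA within \code{window} of the edges).
#' @export
insulationScore <- function(cm, window = 10L) {
  m <- .denseCounts(cm)
  n <- nrow(m)
  if (window < 2) stop("window must be >= 2")
  if (2 * window >= n) stop("window larger than the matrix allows")
  ## square of contacts crossing the junction upstream of bin i, so a
  ## boundary bin (the first bin of a domain) is the insulation minimum
  raw <- rep(NA_real_, n)
  for (i in (window + 1L):(n - window + 1L)) {
    raw[i] <- mean(m[(i - window):(i - 1L), i:(i + window - 1L)])
  }
  mu <- mean(raw, na.rm = TRUE)
  if (mu == 0) return(rep(NA_real_, n))
  log2(ifelse(raw > 0, raw / mu, NA))
}

#' Boundary detection from an insulation profile
#'
#' A boundary is a local minimum of the insulation score within
#' \code{span} bins whose prominence (the smaller of the maximal rises to
#' its left and right within \code{span}) is at least
#' \code{minProminence}.
#'
#' @param ins per-bin insulation score.
#' @param minProminence minimal prominence in log2 units (default 0.2).
#' @param span neighbourhood half-width in bins (default 10).
#' @return integer bin indices of boundaries.
#' @export
boundariesFromInsulation <- function(ins, minProminence = 0.2, span = 10L) {
  n <- length(ins)
  out <- integer(0)
  for (i in seq_len(n)) {
    v <- ins[i]
    if (is.na(v)) next
    lo <- max(1L, i - span); hi <- min(n, i + span)
    neigh <- ins[lo:hi]
    if (any(neigh < v, na.rm = TRUE)) next
    ties <- which(ins[lo:hi] == v) + lo - 1L
    if (i != ties[1L]) next                     # one call per plateau
    left <- suppressWarnings(max(ins[lo:max(lo, i - 1L)], na.rm = TRUE))
    right <- suppressWarnings(max(ins[min(hi, i + 1L):hi], na.rm = TRUE))
    if (!is.finite(left) || !is.finite(right)) next
    if (min(left, right) - v >= minProminence) out <- c(out, i)
  }
  out
}

#' Call TADs by insulation minima
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param window insulation window in bins.
#' @param minProminence boundary prominence threshold.
#' @return a \linkS4class{TADSet} (boundaries include chromosome ends).
#' @export
callTADs <- function(cm, window = 10L, minProminence = 0.2) {
  ins <- insulationScore(cm, window)
  b <- boundariesFromInsulation(ins, minProminence,
                                span = max(3L, window %/% 2L))
  TADSet(b, nBins = nrow(contactCounts(cm)), binSize = binSize(cm),
         chrom = chromName(cm), stage = stageLabel(cm), insulation = ins)
}

#' Mean intra-domain observed/expected strength per TAD
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param tads a \linkS4class{TADSet} on the same binning.
#' @return numeric, one strength per domain.
#' @export
domainStrength <- function(cm, tads) {
  oe <- oeMatrix(cm)
  d <- domains(tads)
  vapply(seq_len(nrow(d)), function(i) {
    idx <- d$start[i]:d$end[i]
    mean(oe[idx, idx])
  }, numeric(1))
}

#' Classify TAD changes between two stages
#'
#' Assigns each earlier-stage domain exactly one type: \code{split} (its
#' extent is subdivided in the later stage), \code{merge} (it is absorbed,
#' with neighbours, into one larger later-stage domain), \code{shift}
#' (a boundary moved by more than \code{shiftTol} but at most
#' \code{shiftMax} bins), \code{strength_change} (same extent, intra-domain
#' O/E changed by >= \code{strengthFold}), \code{stable}, or
#' \code{complex}. Merge and split are mutually inverse on swapped inputs.
#'
#' @param tads1,tads2 \linkS4class{TADSet}s on the same chromosome and
#'   binning.
#' @param cm1,cm2 optional matching \linkS4class{ContactMatrix}s enabling
#'   the strength_change type.
#' @param shiftTol boundary-match tolerance in bins (default 2).
#' @param shiftMax maximal boundary movement still called a shift
#'   (default 5 bins).
#' @param strengthFold intra-domain strength ratio calling a
#'   strength_change (default 1.5).
#' @return data.frame with one row per earlier-stage domain: bin extent,
#'   \code{type}, boundary \code{offset} (bins) and \code{strengthRatio}.
#' @export
classifyTadChanges <- function(tads1, tads2, cm1 = NULL, cm2 = NULL,
                               shiftTol = 2L, shiftMax = 5L,
                               strengthFold = 1.5) {
  if (chromName(tads1) != chromName(tads2) ||
      binSize(tads1) != binSize(tads2))
    stop("TAD sets must share chromosome and binning")
  b1 <- boundaries(tads1); b2 <- boundaries(tads2)
  if (length(b1) < 2 || length(b2) < 2) stop("empty TADSet")
  d1 <- domains(tads1); d2 <- domains(tads2)
  s1 <- if (!is.null(cm1)) domainStrength(cm1, tads1) else NULL
  s2 <- if (!is.null(cm2)) domainStrength(cm2, tads2) else NULL
  nearestDist <- function(x, set) min(abs(x - set))
  ## stage-2 domain containing a bin
  d2Of <- function(bin) which(d2$start <= bin & d2$end >= bin)[1L]
  n1 <- nrow(d1)
  type <- character(n1); offset <- numeric(n1); sRatio <- rep(NA_real_, n1)
  for (i in seq_len(n1)) {
    L <- b1[i]; R <- b1[i + 1L]
    dL <- nearestDist(L, b2); dR <- nearestDist(R, b2)
    inner2 <- b2[b2 > L + shiftTol & b2 < R - shiftTol]
    if (dL <= shiftTol && dR <= shiftTol) {
      if (length(inner2) > 0) { type[i] <- "split"; next }
      ## same extent: stable or strength change
      if (!is.null(s1) && !is.null(s2)) {
        j <- d2Of((L + R) %/% 2L)
        sRatio[i] <- s2[j] / s1[i]
        if (sRatio[i] >= strengthFold || sRatio[i] <= 1 / strengthFold) {
          type[i] <- "strength_change"; next
        }
      }
      type[i] <- "stable"
      next
    }
    ## merge: a larger stage-2 domain with b1-matching outer boundaries
    ## covers this domain together with at least one removed b1 boundary
    j <- d2Of((L + R) %/% 2L)
    if (!is.na(j)) {
      L2 <- d2$start[j]; R2 <- if (j < nrow(d2)) d2$end[j] + 1L else d2$end[j]
      covers <- L2 <= L + shiftTol && R2 >= R - shiftTol
      outerMatch <- nearestDist(L2, b1) <= shiftTol &&
        nearestDist(R2, b1) <= shiftTol
      swallowed <- sum(b1 > L2 + shiftTol & b1 < R2 - shiftTol)
      if (covers && outerMatch && swallowed >= 1 &&
          (R2 - L2) > (R - L) + shiftTol) {
        type[i] <- "merge"; next
      }
    }
    if (dL <= shiftMax && dR <= shiftMax && length(inner2) == 0) {
      type[i] <- "shift"; offset[i] <- max(dL, dR)
      next
    }
    type[i] <- "complex"
  }
  data.frame(chrom = chromName(tads1), start = d1$start, end = d1$end,
             type = type, offset = offset, strengthRatio = sRatio)
}

#' Boundary positions of a TADSet in bp
#'
#' Boundaries sit at the start of their bin (the junction between
#' domains).
#'
#' @param tads a \linkS4class{TADSet}.
#' @param interior drop the chromosome-end boundaries (default TRUE).
#' @return numeric bp positions (0-based junction coordinates).
#' @export
boundaryPositions <- function(tads, interior = TRUE) {
  b <- boundaries(tads)
  if (interior) b <- b[-c(1L, length(b))]
  (b - 1L) * binSize(tads)
}

#' Signed TSS distance to the nearest TAD boundary
#'
#' @param genes GRanges of genes with \code{gene_id}.
#' @param tads a \linkS4class{TADSet} (only genes on its chromosome are
#'   scored).
#' @return data.frame with \code{gene_id}, \code{distance} (bp, signed,
#'   TSS minus boundary) and \code{boundary} (bp position).
#' @export
boundaryGeneDistance <- function(genes, tads) {
  sel <- as.character(seqnames(genes)) == chromName(tads)
  g <- genes[sel]
  pos <- boundaryPositions(tads, interior = FALSE)
  tss0 <- tssOf(g) - 1L
  idx <- vapply(tss0, function(t) which.min(abs(t - pos)), integer(1))
  data.frame(gene_id = mcols(g)$gene_id,
             distance = tss0 - pos[idx],
             boundary = pos[idx])
}

#' Genes near dynamic TAD boundaries (dTADBAGs)
#'
#' @param genes GRanges with \code{gene_id}.
#' @param dynamicBoundariesBp bp positions of boundaries classified
#'   dynamic between two stages.
#' @param chrom chromosome of those boundaries.
#' @param window distance window in bp (default 80000, i.e. 80 kb up- or
#'   downstream).
#' @return character vector of gene ids with |TSS - boundary| <= window.
#' @export
dTADBAG <- function(genes, dynamicBoundariesBp, chrom, window = 80000) {
  sel <- as.character(seqnames(genes)) == chrom
  g <- genes[sel]
  if (length(g) == 0 || length(dynamicBoundariesBp) == 0) return(character(0))
  tss0 <- tssOf(g) - 1L
  dmin <- vapply(tss0, function(t) min(abs(t - dynamicBoundariesBp)),
                 numeric(1))
  mcols(g)$gene_id[dmin <= window]
}

#' Mean signal profile across aligned TAD boundaries
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param boundariesBp boundary positions in bp (0-based junctions).
#' @param chrom chromosome of the boundaries.
#' @param flank flank in bp (multiple of the track bin size).
#' @return data.frame with \code{offset} (bp), \code{mean} signal and
#'   \code{n} contributing boundaries (edge-clipped).
#' @export
boundaryMetaplot <- function(track, boundariesBp, chrom, flank) {
  bs <- binSize(track)
  if (flank %% bs != 0) stop("flank must be a multiple of the bin size")
  if (length(boundariesBp) == 0) stop("no boundaries")
  v <- track@values[[chrom]]
  k <- flank %/% bs
  offs <- (-k):k
  sums <- numeric(length(offs)); cnt <- integer(length(offs))
  for (b in boundariesBp) {
    bin <- b %/% bs + 1L
    for (t in seq_along(offs)) {
      j <- bin + offs[t]
      if (j >= 1L && j <= length(v)) {
        sums[t] <- sums[t] + v[j]
        cnt[t] <- cnt[t] + 1L
      }
    }
  }
  data.frame(offset = offs * bs, mean = sums / cnt, n = cnt)
}

#' Call chromatin loops against a local donut background
#'
#' For every pixel within the distance range, the expected count is the
#' distance expectation scaled by the observed/expected level of a donut
#' annulus around the pixel; enrichment is tested by a Poisson upper tail,
#' BH-corrected, and adjacent significant pixels are merged into loops.
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param minDist,maxDist tested distance range in bp.
#' @param oeMin minimal local fold enrichment (default 2).
#' @param fdr BH threshold (default 0.1).
#' @param donutInner,donutOuter annulus radii in bins (default 2 and 5).
#' @return a \linkS4class{LoopSet}; anchors are bin-sized, anchor1
#'   upstream.
#' @export
callLoops <- function(cm, minDist, maxDist, oeMin = 2.0, fdr = 0.1,
                      donutInner = 2L, donutOuter = 5L) {
  m <- .denseCounts(cm)
  n <- nrow(m)
  bs <- binSize(cm)
  e <- expectedByDistance(cm)
  dmin <- max(1L, as.integer(ceiling(minDist / bs)))
  dmax <- min(n - 1L, as.integer(floor(maxDist / bs)))
  if (dmin > dmax) stop("distance range outside the matrix span")
  oemat <- oeMatrix(cm)
  cand <- which(outer(seq_len(n), seq_len(n),
                      function(i, j) j - i >= dmin & j - i <= dmax),
                arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(LoopSet(GRanges(), GRanges(), numeric(0), stage = stageLabel(cm)))
  ## donut background via summed-area tables (square minus inner square)
  sat <- function(M) {
    P <- matrix(0, n + 1L, n + 1L)
    P[-1, -1] <- apply(apply(M, 2, cumsum), 1, cumsum)
    t(P)
  }
  P <- sat(oemat)
  Pc <- sat(matrix(1, n, n))
  rectSum <- function(P, r1, r2, c1, c2) {
    r1 <- pmax(r1, 1L); c1 <- pmax(c1, 1L)
    r2 <- pmin(r2, n); c2 <- pmin(c2, n)
    P[cbind(r2 + 1L, c2 + 1L)] - P[cbind(r1, c2 + 1L)] -
      P[cbind(r2 + 1L, c1)] + P[cbind(r1, c1)]
  }
  i <- cand[, 1]; j <- cand[, 2]
  oSum <- rectSum(P, i - donutOuter, i + donutOuter,
                  j - donutOuter, j + donutOuter)
  oCnt <- rectSum(Pc, i - donutOuter, i + donutOuter,
                  j - donutOuter, j + donutOuter)
  iSum <- rectSum(P, i - donutInner, i + donutInner,
                  j - donutInner, j + donutInner)
  iCnt <- rectSum(Pc, i - donutInner, i + donutInner,
                  j - donutInner, j + donutInner)
  bg <- (oSum - iSum) / pmax(oCnt - iCnt, 1)
  bg[!is.finite(bg) | bg <= 0] <- 1
  lam <- bg * e[j - i + 1L]
  obs <- m[cbind(i, j)]
  pv <- ifelse(lam > 0, ppois(obs - 1, lam, lower.tail = FALSE), NA_real_)
  oeLoc <- ifelse(lam > 0, obs / lam, NA_real_)
  ok <- !is.na(pv)
  q <- rep(NA_real_, length(pv))
  q[ok] <- bhFdr(pv[ok])
  sig <- which(ok & q <= fdr & oeLoc >= oeMin)
  if (length(sig) == 0)
    return(LoopSet(GRanges(), GRanges(), numeric(0), stage = stageLabel(cm)))
  ## merge 8-connected significant pixels
  si <- cand[sig, 1]; sj <- cand[sig, 2]
  comp <- seq_along(sig)
  repeat {
    changed <- FALSE
    for (a in seq_along(sig)) {
      nb <- which(abs(si - si[a]) <= 1 & abs(sj - sj[a]) <= 1 &
                  comp != comp[a])
      if (length(nb)) {
        newc <- min(comp[a], comp[nb])
        if (any(c(comp[a], comp[nb]) != newc)) {
          comp[c(a, nb)] <- newc
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  reps <- vapply(unique(comp), function(cmp) {
    members <- which(comp == cmp)
    members[which.max(oeLoc[sig][members])]
  }, integer(1))
  bi <- si[reps]; bj <- sj[reps]
  mkAnchor <- function(b)
    GRanges(chromName(cm), IRanges((b - 1L) * bs + 1L, b * bs))
  LoopSet(mkAnchor(bi), mkAnchor(bj), strength = oeLoc[sig][reps],
          stage = stageLabel(cm))
}

#' Distance-decay profile and short/long-range contact ratio
#'
#' P(s) is the fraction of total cis contact frequency in log-spaced
#' distance bins (sums to 1, diagonal excluded). The short/long ratio is
#' total frequency below the distance threshold over that at or above it
#' (Inf when no long-range contacts exist).
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param threshold short/long split in bp (default 730000).
#' @param nLogBins number of log-spaced distance bins (default 30).
#' @return list with \code{distBp}, \code{prob}, \code{meanByDist},
#'   \code{shortLongRatio}, \code{threshold}.
#' @export
decayProfile <- function(cm, threshold = 730000, nLogBins = 30L) {
  m <- contactCounts(cm)
  n <- nrow(m)
  if (sum(m) == 0) stop("all-zero contact matrix")
  tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@j > tm@i
  d <- (tm@j[keep] - tm@i[keep])
  x <- tm@x[keep]
  bs <- binSize(cm)
  sums <- numeric(n - 1L)
  agg <- tapply(x, d, sum)
  sums[as.integer(names(agg))] <- agg
  distBp <- (1:(n - 1L)) * bs
  brk <- unique(round(exp(seq(log(1), log(n - 1L),
                              length.out = nLogBins + 1L))))
  bin <- cut(1:(n - 1L), breaks = c(0, brk), labels = FALSE)
  prob <- tapply(sums, bin, sum) / sum(sums)
  mids <- tapply(distBp, bin, function(z) exp(mean(log(z))))
  short <- sum(sums[distBp < threshold])
  long <- sum(sums[distBp >= threshold])
  meanByDist <- sums / (n - 1:(n - 1L))
  list(distBp = as.numeric(mids), prob = as.numeric(prob),
       meanByDist = meanByDist,
       shortLongRatio = if (long > 0) short / long else Inf,
       threshold = threshold)
}

#' Fit the distance-decay exponent
#'
#' Linear regression of log mean contact versus log distance over the
#' given range; returns the (positive) decay exponent alpha of
#' P(s) ~ s^-alpha.
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param minDist,maxDist fit range in bp.
#' @return numeric exponent.
#' @export
fitDecayExponent <- function(cm, minDist = NULL, maxDist = NULL) {
  bs <- binSize(cm)
  prof <- decayProfile(cm, nLogBins = 30L)
  d <- seq_along(prof$meanByDist) * bs
  y <- prof$meanByDist
  if (is.null(minDist)) minDist <- bs
  if (is.null(maxDist)) maxDist <- max(d) / 4
  keep <- d >= minDist & d <= maxDist & y > 0
  fit <- lm(log(y[keep]) ~ log(d[keep]))
  -as.numeric(coef(fit)[2])
}

#' Across-stage signal correlation of bin pairs within versus between TADs
#'
#' For bin pairs closer than \code{maxPairDist}, computes the Pearson
#' correlation of their across-stage signal vectors, then averages
#' separately over same-TAD and different-TAD pairs, with the inter-TAD
#' pairs subsampled to match the intra-TAD distance distribution
#' (stratified, \code{nStrata} strata).
#'
#' @param tracks list of \linkS4class{SignalTrack}s for one mark, one per
#'   stage (>= 3 stages).
#' @param tads a \linkS4class{TADSet}.
#' @param maxPairDist maximal pair distance in bp.
#' @param nStrata distance strata for matching (default 10).
#' @param seed RNG seed for the subsampling.
#' @return list with \code{intra}, \code{inter} (mean r), pair counts and
#'   the matched distance summaries.
#' @export
intraInterTadCorrelation <- function(tracks, tads, maxPairDist,
                                     nStrata = 10L, seed = 1L) {
  if (length(tracks) < 3) stop("need at least 3 stages")
  bs <- binSize(tads)
  chrom <- chromName(tads)
  agg <- vapply(tracks, function(tr) {
    f <- bs / binSize(tr)
    if (f != round(f)) stop("track bins must divide the TAD bin size")
    v <- tr@values[[chrom]]
    n <- ceiling(length(v) / f)
    vapply(seq_len(n), function(i)
      mean(v[((i - 1L) * f + 1L):min(i * f, length(v))]), numeric(1))
  }, numeric(ceiling(length(tracks[[1]]@values[[chrom]]) /
                     (bs / binSize(tracks[[1]])))))
  n <- nrow(agg)
  dom <- integer(n)
  d <- domains(tads)
  for (i in seq_len(nrow(d))) dom[d$start[i]:min(d$end[i], n)] <- i
  sds <- apply(agg, 1, sd)
  live <- which(sds > 0 & dom > 0)
  z <- agg[live, , drop = FALSE]
  z <- (z - rowMeans(z)) / apply(z, 1, sd)
  maxD <- floor(maxPairDist / bs)
  pairs <- do.call(rbind, lapply(seq_len(maxD), function(dd) {
    i <- seq_len(length(live) - dd)
    keep <- live[i + dd] - live[i] <= maxD
    cbind(i[keep], i[keep] + dd)
  }))
  if (is.null(pairs) || nrow(pairs) == 0) stop("too few bin pairs")
  ns <- ncol(agg)
  r <- rowSums(z[pairs[, 1], , drop = FALSE] *
               z[pairs[, 2], , drop = FALSE]) / (ns - 1)
  pd <- live[pairs[, 2]] - live[pairs[, 1]]
  same <- dom[live[pairs[, 1]]] == dom[live[pairs[, 2]]]
  if (sum(same) < 10 || sum(!same) < 10)
    stop("too few pairs in one of the classes")
  qs <- quantile(pd[same], probs = seq(0, 1, length.out = nStrata + 1L))
  strat <- cut(pd, breaks = unique(c(-Inf, qs[-1])), labels = FALSE)
  set.seed(seed)
  ## symmetric per-stratum matching: both classes subsampled to the
  ## smaller count so the distance distributions coincide
  pickI <- integer(0); pickE <- integer(0)
  for (s in sort(unique(strat[same]))) {
    ii <- which(same & strat == s)
    ee <- which(!same & strat == s)
    n <- min(length(ii), length(ee))
    if (n == 0) next
    pickI <- c(pickI, if (length(ii) > n) sample(ii, n) else ii)
    pickE <- c(pickE, if (length(ee) > n) sample(ee, n) else ee)
  }
  if (length(pickI) < 10) stop("too few distance-matched pairs")
  list(intra = mean(r[pickI]), inter = mean(r[pickE]),
       nIntra = length(pickI), nInter = length(pickE),
       intraDist = mean(pd[pickI]) * bs, interDist = mean(pd[pickE]) * bs)
}

#' Ratio of intra-TAD to inter-TAD contact frequency
#'
#' Total contact counts with both ends in one domain over counts crossing
#' domains, restricted to distances at most twice the median TAD size.
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param tads a \linkS4class{TADSet} on the same binning.
#' @return numeric ratio (Inf when no inter-TAD contacts are in range).
#' @export
intraInterContactRatio <- function(cm, tads) {
  m <- contactCounts(cm)
  n <- nrow(m)
  d <- domains(tads)
  medSize <- median(d$end - d$start + 1L)
  maxD <- 2L * medSize
  dom <- integer(n)
  for (i in seq_len(nrow(d))) dom[d$start[i]:min(d$end[i], n)] <- i
  tm <- as(as(m, "generalMatrix"), "TsparseMatrix")
  keep <- tm@j > tm@i & (tm@j - tm@i) <= maxD
  i <- tm@i[keep] + 1L; j <- tm@j[keep] + 1L; x <- tm@x[keep]
  same <- dom[i] == dom[j] & dom[i] > 0
  intra <- sum(x[same]); inter <- sum(x[!same])
  if (inter > 0) intra / inter else Inf
}

#' Permutation enrichment of a feature set at TAD boundaries
#'
#' Counts features overlapping boundary intervals and compares against
#' \code{nShuffle} random placements of the boundary set (lengths and
#' per-chromosome counts preserved, uniform placement).
#'
#' @param features GRanges of features (e.g. transposon copies).
#' @param boundaryRegions GRanges of boundary intervals with seqlengths
#'   set.
#' @param nShuffle number of shuffles (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @return list with \code{observed}, \code{expected}, \code{fold} and
#'   empirical \code{p} (add-one corrected).
#' @export
regionSetBoundaryEnrichment <- function(features, boundaryRegions,
                                        nShuffle = 1000L, seed = 1L) {
  if (nShuffle < 100) warning("fewer than 100 shuffles: p is coarse")
  obs <- sum(countOverlaps(features, boundaryRegions) > 0)
  if (length(features) == 0)
    return(list(observed = 0, expected = NA_real_, fold = 0, p = 1))
  sl <- seqlengths(boundaryRegions)
  if (anyNA(sl)) stop("boundaryRegions needs seqlengths for shuffling")
  set.seed(seed)
  null <- vapply(seq_len(nShuffle), function(k) {
    pieces <- lapply(GenomeInfoDb::seqlevels(boundaryRegions), function(ch) {
      b <- boundaryRegions[as.character(seqnames(boundaryRegions)) == ch]
      if (length(b) == 0) return(GRanges())
      w <- width(b)
      st <- floor(runif(length(b), 1, sl[[ch]] - w + 1))
      GRanges(ch, IRanges(st, width = w))
    })
    shuf <- suppressWarnings(do.call(c, pieces))
    sum(countOverlaps(features, shuf) > 0)
  }, numeric(1))
  expct <- mean(null)
  list(observed = obs, expected = expct,
       fold = if (expct > 0) obs / expct else ifelse(obs > 0, Inf, 0),
       p = (1 + sum(null >= obs)) / (nShuffle + 1))
}
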