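#' Configuration for the synthetic multi-stage epigenome
#'
#' Returns the default study design: seven ordered stages spanning
#' prenatal development to aging, two 30-Mb chromosomes, 10-kb signal
#' bins, 40-kb Hi-C bins and 1500 genes, with planted stage-specific
#' genes, bivalent-promoter fates, an H3K27me3-to-5mC handoff cohort,
#' loop-linked SE/TE enhancers, TAD merge/split/shift/strength events,
#' A/B compartment switches and SNPs enriched in SEs. Any field can be
#' overridden through \code{...}.
#'
#' @param ... named overrides of the defaults listed below.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(...) {
  cfg <- list(
    stages = c("E50", "E90", "E120", "P0", "P4M", "PY4.5", "PY20"),
    nChroms = 2L,
    chromLength = 30e6,
    signalBinSize = 10000L,
    hicBinSize = 40000L,
    nGenes = 1500L,
    geneRegionEnd = 24e6,        # genes upstream, enhancers downstream
    fracStageSpecific = 0.10,    # per stage
    fracConstitutive = 0.60,     # of the leftover pool
    nBivalent = 210L,
    bivalentFateProbs = c(bta = 0.5, btr = 0.25, maintain = 0.25),
    nHandoff = 100L,
    handoffHighStages = 1:2,
    handoffMethStage = 4L,
    nEnhancers = 80L,
    fracSE = 0.25,
    fracCommonEnhancer = 0.2,
    teLengthRange = c(1000, 7000),
    seLengthRange = c(8000, 25000),
    enhancerWindow = 3e6,
    tadSizeRange = c(10L, 28L),  # hic bins
    tadEventsPerPair = c(merge = 2L, split = 2L, shift = 2L,
                         strength = 2L),
    tadShiftBins = 3L,
    tadStrengthBoost = 1.8,
    compBinSize = 400000L,
    compBlockRange = c(5L, 10L),
    compSwitchFrac = 0.15,
    decayExponent = rep(1.0, 7L),
    contactDepth = 60,
    tadBoost = 2.2,
    compBoostAmp = 0.3,
    loopBoost = 6,
    enrichment = 8,
    bgMean = 1,
    bgShape = 4,
    dhsCompartmentBoost = 1.5,
    peakDropout = 0.01,
    exprSlope = 1.2,
    exprIntercept = -1,
    exprSdLog = 0.3,
    methBaseline = 0.1,
    methHigh = 0.8,
    methConcentration = 60,
    nSnps = 500L,
    snpSeWeight = 3,             # per-bp placement odds SE : TE
    nBackgroundSnps = 100L,
    noiseFree = FALSE,
    aging = NULL,                # set by agingVariant()
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown SimConfig field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (length(cfg$decayExponent) == 1L)
    cfg$decayExponent <- rep(cfg$decayExponent, length(cfg$stages))
  stopifnot(cfg$fracStageSpecific >= 0, cfg$fracStageSpecific <= 1,
            cfg$seLengthRange[1] >= 8000, cfg$teLengthRange[2] < 8000,
            length(cfg$decayExponent) == length(cfg$stages))
  structure(cfg, class = "SimConfig")
}

#' Derive the aged-brain variant of a configuration
#'
#' Raises the final stage's distance-decay exponent and splits a fraction
#' of its TADs, reproducing the aging signature: relatively more
#' short-range and fewer long-range contacts, plus newly formed
#' boundaries.
#'
#' @param config a \code{\link{simConfig}} (>= 2 stages).
#' @param decayBoost added to the final stage's decay exponent (default
#'   0.4).
#' @param splitFraction fraction of final-stage TADs split in two
#'   (default 0.3).
#' @return modified config.
#' @export
agingVariant <- function(config, decayBoost = 0.4, splitFraction = 0.3) {
  if (length(config$stages) < 2) stop("need at least two stages")
  config$decayExponent[length(config$stages)] <-
    config$decayExponent[length(config$stages)] + decayBoost
  config$aging <- list(splitFraction = splitFraction)
  config
}

.softplus <- function(x) log1p(exp(x))

.gammaNoise <- function(mu, shape, noiseFree) {
  if (noiseFree) return(mu)
  rgamma(length(mu), shape = shape, scale = mu / shape)
}

## sample TAD boundary sets per stage with planted events
.simTads <- function(cfg) {
  nBins <- as.integer(cfg$chromLength / cfg$hicBinSize)
  ns <- length(cfg$stages)
  chroms <- paste0("chr", seq_len(cfg$nChroms))
  tads <- list(); events <- list(); strength <- list()
  for (ch in chroms) {
    b <- 1L
    repeat {
      step <- sample(cfg$tadSizeRange[1]:cfg$tadSizeRange[2], 1L)
      if (b[length(b)] + step >= nBins - cfg$tadSizeRange[1]) break
      b <- c(b, b[length(b)] + step)
    }
    b <- c(b, nBins)
    perStage <- vector("list", ns); perStage[[1]] <- b
    boost <- vector("list", ns); boost[[1]] <- integer(0)
    for (s in 2:ns) {
      prev <- perStage[[s - 1L]]
      cur <- prev
      curBoost <- boost[[s - 1L]]
      ev <- cfg$tadEventsPerPair
      if (!is.null(cfg$aging) && s == ns)
        ev["split"] <- ev["split"] +
          round(cfg$aging$splitFraction * (length(prev) - 1L))
      interior <- setdiff(prev, c(1L, nBins))
      used <- integer(0)   # boundaries adjacent to an already-used event
      pickDomain <- function(minSize) {
        dstart <- cur[-length(cur)]; dend <- cur[-1]
        ok <- which(dend - dstart >= minSize &
                    !(dstart %in% used) & !(dend %in% used) &
                    dstart != 1L & dend != nBins)
        if (length(ok) == 0) return(NA_integer_)
        ok[sample.int(length(ok), 1L)]
      }
      evRows <- list()
      for (k in seq_len(ev[["merge"]])) {
        i <- pickDomain(cfg$tadSizeRange[1])
        if (is.na(i) || i >= length(cur) - 1L) next
        bRemove <- cur[i + 1L]
        if (bRemove %in% used || cur[i] %in% used ||
            cur[i + 2L] %in% used) next
        evRows <- c(evRows, list(data.frame(chrom = ch, type = "merge",
          start = cur[i], end = cur[i + 2L], pair = s - 1L)))
        used <- c(used, cur[i], bRemove, cur[i + 2L])
        cur <- setdiff(cur, bRemove)
      }
      for (k in seq_len(ev[["split"]])) {
        i <- pickDomain(2L * cfg$tadSizeRange[1])
        if (is.na(i)) next
        dstart <- cur[i]; dend <- cur[i + 1L]
        newB <- as.integer((dstart + dend) / 2)
        evRows <- c(evRows, list(data.frame(chrom = ch, type = "split",
          start = dstart, end = dend, pair = s - 1L)))
        used <- c(used, dstart, dend, newB)
        cur <- sort(c(cur, newB))
      }
      for (k in seq_len(ev[["shift"]])) {
        i <- pickDomain(cfg$tadSizeRange[1] + cfg$tadShiftBins + 2L)
        if (is.na(i) || i >= length(cur) - 1L) next
        bMove <- cur[i + 1L]
        if (bMove %in% used || bMove == nBins) next
        nxt <- cur[i + 2L]
        if (nxt - bMove <= cfg$tadShiftBins + cfg$tadSizeRange[1] / 2) next
        evRows <- c(evRows, list(data.frame(chrom = ch, type = "shift",
          start = cur[i], end = bMove, pair = s - 1L)))
        used <- c(used, cur[i], bMove, bMove + cfg$tadShiftBins, nxt)
        cur <- sort(c(setdiff(cur, bMove), bMove + cfg$tadShiftBins))
      }
      for (k in seq_len(ev[["strength"]])) {
        i <- NA_integer_
        for (try in 1:10) {              # an already-boosted domain would
          i <- pickDomain(cfg$tadSizeRange[1])   # show no new change
          if (!is.na(i) && !(cur[i] %in% curBoost)) break
          i <- NA_integer_
        }
        if (is.na(i)) next
        evRows <- c(evRows, list(data.frame(chrom = ch,
          type = "strength", start = cur[i], end = cur[i + 1L],
          pair = s - 1L)))
        used <- c(used, cur[i], cur[i + 1L])
        curBoost <- c(curBoost, cur[i])   # keyed by domain start
      }
      perStage[[s]] <- cur
      boost[[s]] <- curBoost
      events[[paste(ch, s - 1L)]] <- if (length(evRows))
        do.call(rbind, evRows) else NULL
    }
    tads[[ch]] <- perStage
    strength[[ch]] <- boost
  }
  list(boundaries = tads, events = do.call(rbind, events),
       strengthBoost = strength, nBins = nBins)
}

.simCompartments <- function(cfg) {
  nComp <- as.integer(cfg$chromLength / cfg$compBinSize)
  ns <- length(cfg$stages)
  chroms <- paste0("chr", seq_len(cfg$nChroms))
  out <- list()
  for (ch in chroms) {
    lab <- character(0)
    cl <- sample(c("A", "B"), 1L)
    while (length(lab) < nComp) {
      blk <- sample(cfg$compBlockRange[1]:cfg$compBlockRange[2], 1L)
      lab <- c(lab, rep(cl, blk))
      cl <- if (cl == "A") "B" else "A"
    }
    lab <- lab[seq_len(nComp)]
    perStage <- vector("list", ns); perStage[[1]] <- lab
    for (s in 2:ns) {
      cur <- perStage[[s - 1L]]
      target <- round(cfg$compSwitchFrac * nComp)
      ## flip short contiguous segments until the target bin count is
      ## reached, keeping the genome a mixture of A and B
      flipped <- 0L
      guard <- 0L
      while (flipped < target && guard < 100L) {
        guard <- guard + 1L
        len <- sample(2:4, 1L)
        st0 <- sample.int(nComp - len + 1L, 1L)
        idx <- st0:(st0 + len - 1L)
        cur[idx] <- ifelse(cur[idx] == "A", "B", "A")
        flipped <- flipped + len
      }
      perStage[[s]] <- cur
    }
    out[[ch]] <- perStage
  }
  out
}

.simGenes <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$nChroms))
  perChrom <- ceiling(cfg$nGenes / cfg$nChroms)
  bs <- cfg$signalBinSize
  ## bin-aligned gene slots so no two planted genes share a signal bin
  spacing <- (cfg$geneRegionEnd %/% perChrom) %/% bs * bs
  if (spacing < 2L * bs) stop("gene region too small for nGenes")
  lenMax <- min(20000L, spacing - bs - 2001L)
  rows <- list()
  gi <- 0L
  for (ch in chroms) {
    for (k in seq_len(perChrom)) {
      gi <- gi + 1L
      if (gi > cfg$nGenes) break
      tss <- (k - 1L) * spacing + bs + 1L
      len <- sample(6000:lenMax, 1L)
      rows[[gi]] <- data.frame(gene_id = sprintf("g%04d", gi),
                               chrom = ch, tss = tss,
                               tes = tss + len, strand = "+")
    }
  }
  genes <- do.call(rbind, rows)
  ns <- length(cfg$stages)
  ng <- nrow(genes)
  nSpec <- round(cfg$fracStageSpecific * ng)
  pool <- sample(ng)        # randomised assignment order
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
  class <- rep("silent", ng)
  specStage <- rep(NA_integer_, ng)
  for (s in seq_len(ns)) {
    idx <- take(nSpec)
    class[idx] <- "specific"
    specStage[idx] <- s
  }
  bivIdx <- take(min(cfg$nBivalent, length(pool)))
  class[bivIdx] <- "bivalent"
  hoIdx <- take(min(cfg$nHandoff, length(pool)))
  class[hoIdx] <- "handoff"
  nConst <- round(cfg$fracConstitutive * length(pool))
  class[take(nConst)] <- "constitutive"
  fate <- rep(NA_character_, ng)
  transStage <- rep(NA_integer_, ng)
  fate[bivIdx] <- sample(names(cfg$bivalentFateProbs), length(bivIdx),
                         replace = TRUE, prob = cfg$bivalentFateProbs)
  transStage[bivIdx] <- sample(2:ns, length(bivIdx), replace = TRUE)
  genes$class <- class
  genes$specificStage <- specStage
  genes$bivalentFate <- fate
  genes$transitionStage <- transStage
  genes
}

## planted promoter state matrix (genes x stages)
.plantStates <- function(genes, cfg) {
  ns <- length(cfg$stages)
  m <- matrix("none", nrow(genes), ns,
              dimnames = list(genes$gene_id, cfg$stages))
  for (i in seq_len(nrow(genes))) {
    cl <- genes$class[i]
    if (cl == "constitutive") m[i, ] <- "active"
    else if (cl == "specific") m[i, genes$specificStage[i]] <- "active"
    else if (cl == "handoff")
      m[i, cfg$handoffHighStages] <- "repressive"
    else if (cl == "bivalent") {
      t <- genes$transitionStage[i]
      fate <- genes$bivalentFate[i]
      if (fate == "maintain") m[i, ] <- "bivalent"
      else {
        m[i, seq_len(t - 1L)] <- "bivalent"
        m[i, t:ns] <- if (fate == "bta") "active" else "repressive"
      }
    }
  }
  m
}

.simEnhancers <- function(cfg, genes) {
  chroms <- paste0("chr", seq_len(cfg$nChroms))
  perChrom <- ceiling(cfg$nEnhancers / cfg$nChroms)
  ## distal to every gene but within looping reach of the nearest ones
  geneEnd <- max(genes$tes)
  region <- c(geneEnd + 200000, geneEnd + 2.4e6)
  if (region[2] > cfg$chromLength - 200000)
    stop("chromosome too short for the enhancer region")
  spacing <- floor((region[2] - region[1]) / perChrom)
  ns <- length(cfg$stages)
  rows <- list(); targets <- list()
  ei <- 0L
  for (ch in chroms) {
    gch <- genes[genes$chrom == ch, ]
    for (k in seq_len(perChrom)) {
      ei <- ei + 1L
      if (ei > cfg$nEnhancers) break
      isSE <- runif(1) < cfg$fracSE
      len <- if (isSE) round(runif(1, cfg$seLengthRange[1],
                                   cfg$seLengthRange[2]))
             else round(runif(1, cfg$teLengthRange[1],
                              cfg$teLengthRange[2]))
      start <- region[1] + (k - 1L) * spacing
      mid <- start + len / 2
      common <- runif(1) < cfg$fracCommonEnhancer
      activeStages <- if (common) seq_len(ns) else sample(ns, 1L)
      nT <- if (isSE) sample(c(1, 4, 10, 20, 35), 1L,
                             prob = c(.2, .2, .2, .3, .1))
            else sample(1:3, 1L, prob = c(.6, .3, .1))
      nearby <- gch[abs(gch$tss - mid) <= cfg$enhancerWindow - 100000, ]
      nT <- min(nT, nrow(nearby))
      tg <- nearby$gene_id[order(abs(nearby$tss - mid))[seq_len(nT)]]
      rows[[ei]] <- data.frame(enh_id = sprintf("e%03d", ei), chrom = ch,
                               start = start, end = start + len - 1L,
                               class = if (isSE) "SE" else "TE",
                               common = common,
                               activeStages = paste(activeStages,
                                                    collapse = ","))
      targets[[ei]] <- tg
    }
  }
  enh <- do.call(rbind, rows)
  enh$targets <- vapply(targets, paste, character(1), collapse = ",")
  enh
}

## one contact matrix: power-law decay, TAD blocks, compartment plaid,
## loop dots, Poisson sampling
.simContactMatrix <- function(cfg, nBins, bnd, boostStarts, compLab,
                              loopPix, alpha, stage, chrom) {
  d <- abs(outer(seq_len(nBins), seq_len(nBins), "-"))
  mu <- cfg$contactDepth * pmax(d, 1)^(-alpha)
  dom <- pmin(findInterval(seq_len(nBins), bnd), length(bnd) - 1L)
  same <- outer(dom, dom, "==")
  mu <- mu * ifelse(same, cfg$tadBoost, 1)
  if (length(boostStarts)) {
    boostDom <- findInterval(boostStarts, bnd)
    inBoost <- dom %in% boostDom
    mu <- mu * ifelse(outer(inBoost, inBoost, "&") & same,
                      cfg$tadStrengthBoost, 1)
  }
  f <- cfg$compBinSize / cfg$hicBinSize
  e <- ifelse(compLab[ceiling(seq_len(nBins) / f)] == "A", 1, -1)
  mu <- mu * (1 + cfg$compBoostAmp * outer(e, e))
  if (!is.null(loopPix) && nrow(loopPix)) {
    for (r in seq_len(nrow(loopPix))) {
      i <- loopPix$bin1[r]; j <- loopPix$bin2[r]
      mu[i, j] <- mu[i, j] * cfg$loopBoost
      mu[j, i] <- mu[i, j]
    }
  }
  cnt <- if (cfg$noiseFree) mu else {
    up <- upper.tri(mu, diag = TRUE)
    x <- mu
    x[up] <- rpois(sum(up), mu[up])
    x[lower.tri(x)] <- t(x)[lower.tri(x)]
    x
  }
  ContactMatrix(cnt, cfg$hicBinSize, chrom, stage)
}

#' A pure power-law contact matrix (no domains, no loops)
#'
#' Poisson counts around depth * distance^-exponent; used to validate the
#' distance-decay machinery against the closed form.
#'
#' @param nBins number of bins.
#' @param binSize bin width in bp.
#' @param exponent decay exponent alpha.
#' @param depth expected count at distance one bin.
#' @param noiseFree return the expectation itself.
#' @param stage,chrom labels.
#' @return a \linkS4class{ContactMatrix}.
#' @export
powerLawContacts <- function(nBins, binSize, exponent, depth = 60,
                             noiseFree = FALSE, stage = "", chrom = "chr1") {
  d <- abs(outer(seq_len(nBins), seq_len(nBins), "-"))
  mu <- depth * pmax(d, 1)^(-exponent)
  cnt <- if (noiseFree) mu else {
    up <- upper.tri(mu, diag = TRUE)
    x <- mu
    x[up] <- rpois(sum(up), mu[up])
    x[lower.tri(x)] <- t(x)[lower.tri(x)]
    x
  }
  ContactMatrix(cnt, binSize, chrom, stage)
}

#' Simulate the complete multi-stage bundle with planted ground truth
#'
#' Generates annotation, per-mark/per-stage signal tracks and peak sets,
#' per-stage/per-chromosome contact matrices, loops, promoter methylation,
#' expression, SNPs and the \code{truth} record of everything planted.
#' Signal at a bin is gamma background times the planted enrichment of
#' marks active there; expression is a softplus link of the true gene
#' activity with log-normal noise; contacts follow a distance power law
#' with TAD-block, compartment-plaid and loop-dot factors under Poisson
#' sampling. The same seed always yields the identical bundle.
#'
#' @param config a \code{\link{simConfig}}.
#' @return named list: \code{annotation} (GRanges), \code{tracks},
#'   \code{peaks}, \code{contacts}, \code{loops}, \code{expression},
#'   \code{methylation}, \code{snps}, \code{truth}, \code{config}.
#' @export
simulateBundle <- function(config = simConfig()) {
  cfg <- config
  set.seed(cfg$seed)
  stages <- cfg$stages
  ns <- length(stages)
  chroms <- paste0("chr", seq_len(cfg$nChroms))
  seqlen <- setNames(rep(cfg$chromLength, cfg$nChroms), chroms)

  genes <- .simGenes(cfg)
  states <- .plantStates(genes, cfg)
  tadSim <- .simTads(cfg)
  comp <- .simCompartments(cfg)
  enh <- .simEnhancers(cfg, genes)
  enhStages <- lapply(strsplit(enh$activeStages, ","), as.integer)
  enhTargets <- strsplit(enh$targets, ",")

  annotation <- GRanges(genes$chrom,
                        IRanges(genes$tss, genes$tes), strand = "+",
                        gene_id = genes$gene_id,
                        biotype = "protein_coding")
  seqlengths(annotation) <- seqlen
  proms <- promoterOf(annotation)

  sigBins <- as.integer(cfg$chromLength / cfg$signalBinSize)
  binOf <- function(pos) pmin(pmax((as.integer(pos) - 1L) %/%
                                   cfg$signalBinSize + 1L, 1L), sigBins)
  marks <- c("H3K4me3", "H3K27me3", "H3K27ac", "Pol2", "CTCF", "DHS")

  ## per gene: signal bins of promoter and body
  promBins <- lapply(seq_len(nrow(genes)), function(i)
    unique(binOf(c(genes$tss[i] - 2000, genes$tss[i], genes$tss[i] + 1999))))
  bodyBins <- lapply(seq_len(nrow(genes)), function(i)
    unique(binOf(c(genes$tss[i], genes$tes[i] - 1,
                   seq(genes$tss[i], genes$tes[i],
                       by = cfg$signalBinSize)))))
  enhBins <- lapply(seq_len(nrow(enh)), function(i)
    unique(binOf(seq(enh$start[i], enh$end[i], by = cfg$signalBinSize / 2))))

  hasMark <- function(state, mark) {
    switch(mark,
      H3K4me3 = state %in% c("active", "bivalent"),
      H3K27me3 = state %in% c("repressive", "bivalent"),
      FALSE)
  }

  tracks <- list(); peaks <- list(); enhEvidence <- list()
  for (mk in marks) peaks[[mk]] <- list()
  drop1 <- function() !cfg$noiseFree && runif(1) < cfg$peakDropout

  for (s in seq_len(ns)) {
    st <- stages[s]
    ## enrichment mean per bin per chrom per mark
    mean0 <- lapply(chroms, function(ch) {
      m <- matrix(cfg$bgMean, sigBins, length(marks),
                  dimnames = list(NULL, marks))
      ## DHS baseline boosted in A compartments (orientation signal)
      f <- cfg$compBinSize / cfg$signalBinSize
      aBins <- comp[[ch]][[s]][ceiling(seq_len(sigBins) / f)] == "A"
      m[aBins, "DHS"] <- cfg$bgMean * cfg$dhsCompartmentBoost
      m
    })
    names(mean0) <- chroms
    peakRows <- lapply(marks, function(mk) list())
    names(peakRows) <- marks
    addPeak <- function(mk, ch, s1, s2) {
      if (drop1()) return(invisible())
      peakRows[[mk]][[length(peakRows[[mk]]) + 1L]] <<-
        data.frame(chrom = ch, start = s1, end = s2)
    }
    for (i in seq_len(nrow(genes))) {
      stt <- states[i, s]
      ch <- genes$chrom[i]
      if (stt == "none") next
      if (hasMark(stt, "H3K4me3")) {
        mean0[[ch]][promBins[[i]], "H3K4me3"] <- cfg$bgMean * cfg$enrichment
        addPeak("H3K4me3", ch, genes$tss[i] - 2000, genes$tss[i] + 2000)
      }
      if (hasMark(stt, "H3K27me3")) {
        mean0[[ch]][promBins[[i]], "H3K27me3"] <- cfg$bgMean * cfg$enrichment
        addPeak("H3K27me3", ch, genes$tss[i] - 2000, genes$tss[i] + 2000)
      }
      if (stt == "active") {
        mean0[[ch]][promBins[[i]], "DHS"] <- cfg$bgMean * cfg$enrichment
        mean0[[ch]][bodyBins[[i]], "Pol2"] <- cfg$bgMean * cfg$enrichment
        mean0[[ch]][bodyBins[[i]], "H3K27ac"] <- cfg$bgMean * cfg$enrichment
        addPeak("DHS", ch, genes$tss[i] - 2000, genes$tss[i] + 2000)
      }
    }
    ## enhancer evidence
    evRows <- list()
    for (i in seq_len(nrow(enh))) {
      if (!(s %in% enhStages[[i]])) next
      ch <- enh$chrom[i]
      mid <- round((enh$start[i] + enh$end[i]) / 2)
      got <- c(k27ac = !drop1(), ctcf = !drop1(), dhs = !drop1())
      if (got["k27ac"]) {
        mean0[[ch]][enhBins[[i]], "H3K27ac"] <- cfg$bgMean * cfg$enrichment
        peakRows[["H3K27ac"]][[length(peakRows[["H3K27ac"]]) + 1L]] <-
          data.frame(chrom = ch, start = enh$start[i], end = enh$end[i])
      }
      if (got["ctcf"])
        peakRows[["CTCF"]][[length(peakRows[["CTCF"]]) + 1L]] <-
          data.frame(chrom = ch, start = mid - 750, end = mid + 750)
      if (got["dhs"]) {
        mean0[[ch]][binOf(mid), "DHS"] <- cfg$bgMean * cfg$enrichment
        peakRows[["DHS"]][[length(peakRows[["DHS"]]) + 1L]] <-
          data.frame(chrom = ch, start = mid - 750, end = mid + 750)
      }
      evRows[[length(evRows) + 1L]] <-
        data.frame(enh_id = enh$enh_id[i], stage = st,
                   k27ac = got[["k27ac"]], ctcf = got[["ctcf"]],
                   dhs = got[["dhs"]])
    }
    ## CTCF at TAD boundaries
    for (ch in chroms) {
      for (bp in (setdiff(tadSim$boundaries[[ch]][[s]],
                          c(1L, tadSim$nBins)) - 1L) * cfg$hicBinSize) {
        mean0[[ch]][binOf(bp), "CTCF"] <- cfg$bgMean * cfg$enrichment
        addPeak("CTCF", ch, max(1, bp - 1000), bp + 1000)
      }
    }
    for (mk in marks) {
      vals <- lapply(chroms, function(ch)
        .gammaNoise(mean0[[ch]][, mk], cfg$bgShape, cfg$noiseFree))
      names(vals) <- chroms
      tracks[[paste(mk, st, sep = ".")]] <-
        SignalTrack(mk, st, cfg$signalBinSize, vals, seqlen)
      df <- if (length(peakRows[[mk]]))
        do.call(rbind, peakRows[[mk]]) else NULL
      peaks[[mk]][[st]] <- if (is.null(df)) GRanges() else {
        g <- GRanges(df$chrom, IRanges(df$start, df$end))
        seqlengths(g) <- seqlen[GenomeInfoDb::seqlevels(g)]
        GenomicRanges::sort(g)
      }
    }
    enhEvidence[[st]] <- if (length(evRows)) do.call(rbind, evRows)
                         else NULL
  }

  ## loops and contacts
  hicBinOf <- function(pos) pmin(pmax((as.integer(pos) - 1L) %/%
                                      cfg$hicBinSize + 1L, 1L),
                                 tadSim$nBins)
  loopRows <- list()
  for (i in seq_len(nrow(enh))) {
    mid <- round((enh$start[i] + enh$end[i]) / 2)
    for (g in enhTargets[[i]]) {
      gi <- match(g, genes$gene_id)
      loopRows[[length(loopRows) + 1L]] <-
        data.frame(enh_id = enh$enh_id[i], chrom = enh$chrom[i],
                   enhBin = hicBinOf(mid), promBin = hicBinOf(genes$tss[gi]),
                   gene = g,
                   stages = enh$activeStages[i])
    }
  }
  loopTruth <- do.call(rbind, loopRows)
  contacts <- list(); loops <- list()
  for (s in seq_len(ns)) {
    st <- stages[s]
    contacts[[st]] <- list()
    la1 <- la2 <- list()
    for (ch in chroms) {
      lp <- loopTruth[loopTruth$chrom == ch &
                      vapply(strsplit(loopTruth$stages, ","),
                             function(z) s %in% as.integer(z),
                             logical(1)), , drop = FALSE]
      pix <- if (nrow(lp)) data.frame(
        bin1 = pmin(lp$enhBin, lp$promBin),
        bin2 = pmax(lp$enhBin, lp$promBin)) else NULL
      pix <- if (!is.null(pix)) pix[pix$bin2 - pix$bin1 >= 2, , drop = FALSE]
        else NULL
      contacts[[st]][[ch]] <- .simContactMatrix(
        cfg, tadSim$nBins, tadSim$boundaries[[ch]][[s]],
        tadSim$strengthBoost[[ch]][[s]], comp[[ch]][[s]], pix,
        cfg$decayExponent[s], st, ch)
      if (!is.null(pix) && nrow(pix)) {
        bs <- cfg$hicBinSize
        la1[[ch]] <- GRanges(ch, IRanges((pix$bin1 - 1L) * bs + 1L,
                                         pix$bin1 * bs))
        la2[[ch]] <- GRanges(ch, IRanges((pix$bin2 - 1L) * bs + 1L,
                                         pix$bin2 * bs))
      }
    }
    a1 <- if (length(la1)) suppressWarnings(do.call(c, unname(la1)))
          else GRanges()
    a2 <- if (length(la2)) suppressWarnings(do.call(c, unname(la2)))
          else GRanges()
    loops[[st]] <- LoopSet(a1, a2, stage = st)
  }

  ## expression and methylation
  gasTrue <- matrix(0, nrow(genes), ns,
                    dimnames = list(genes$gene_id, stages))
  gasTrue[states == "active"] <- 4
  gasTrue[states == "bivalent"] <- 1
  gasTrue[states == "repressive"] <- -1
  mu <- .softplus(cfg$exprSlope * gasTrue + cfg$exprIntercept)
  expr <- if (cfg$noiseFree) mu else
    mu * matrix(rlnorm(length(mu), 0, cfg$exprSdLog), nrow(mu))
  dimnames(expr) <- dimnames(gasTrue)

  methMu <- matrix(cfg$methBaseline, nrow(genes), ns,
                   dimnames = list(genes$gene_id, stages))
  ho <- which(genes$class == "handoff")
  methMu[ho, cfg$handoffMethStage:ns] <- cfg$methHigh
  meth <- if (cfg$noiseFree) methMu else {
    cc <- cfg$methConcentration
    matrix(rbeta(length(methMu), methMu * cc, (1 - methMu) * cc),
           nrow(methMu), dimnames = dimnames(methMu))
  }

  ## SNPs: per-bp weighted placement in SE vs TE, plus background
  seRows <- enh[enh$class == "SE", ]; teRows <- enh[enh$class == "TE", ]
  segment <- rbind(
    data.frame(chrom = seRows$chrom, start = seRows$start,
               end = seRows$end, where = rep("SE", nrow(seRows)),
               w = cfg$snpSeWeight * (seRows$end - seRows$start + 1)),
    data.frame(chrom = teRows$chrom, start = teRows$start,
               end = teRows$end, where = rep("TE", nrow(teRows)),
               w = 1 * (teRows$end - teRows$start + 1)))
  nSnps <- if (nrow(segment)) cfg$nSnps else 0L
  pickSeg <- sample(nrow(segment), nSnps, replace = TRUE,
                    prob = segment$w)
  snpPos <- floor(runif(nSnps, segment$start[pickSeg],
                        segment$end[pickSeg] + 1))
  bgPos <- floor(runif(cfg$nBackgroundSnps, cfg$chromLength - 150000,
                       cfg$chromLength))
  snps <- data.frame(
    chrom = c(segment$chrom[pickSeg],
              sample(chroms, cfg$nBackgroundSnps, replace = TRUE)),
    pos = c(snpPos, bgPos),
    where = c(segment$where[pickSeg], rep("background",
                                          cfg$nBackgroundSnps)))
  snpGR <- GRanges(snps$chrom, IRanges(snps$pos, width = 1L),
                   where = snps$where)
  seqlengths(snpGR) <- seqlen[GenomeInfoDb::seqlevels(snpGR)]

  truth <- list(genes = genes, states = states,
                handoff = data.frame(gene_id = genes$gene_id[ho],
                                     s1 = cfg$handoffHighStages[1],
                                     s2 = cfg$handoffMethStage),
                enhancers = enh,
                enhancerEvidence = do.call(rbind, enhEvidence),
                tadBoundaries = tadSim$boundaries,
                tadEvents = tadSim$events,
                tadStrengthBoost = tadSim$strengthBoost,
                nHicBins = tadSim$nBins,
                compartments = comp,
                loops = loopTruth,
                snps = snps)

  list(annotation = annotation, promoters = proms, tracks = tracks,
       peaks = peaks, contacts = contacts, loops = loops,
       expression = expr, methylation = meth, snps = snpGR,
       truth = truth, config = cfg)
}

#' Write a simulated bundle to disk in standard formats
#'
#' Annotation and SNPs as BED, tracks as bedGraph, peaks as BED, contacts
#' as triplet text, loops as BEDPE, expression/methylation as TSV, ground
#' truth as TSV/JSON under \code{truth/}.
#'
#' @param bundle result of \code{\link{simulateBundle}}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- bundle$annotation
  mcols(ann)$name <- mcols(ann)$gene_id
  writeBed(ann, file.path(dir, "genes.bed"))
  writeBed(bundle$snps, file.path(dir, "snps.bed"))
  for (nm in names(bundle$tracks))
    writeBedGraph(bundle$tracks[[nm]],
                  file.path(dir, paste0(nm, ".bedGraph")))
  for (mk in names(bundle$peaks))
    for (st in names(bundle$peaks[[mk]]))
      writeBed(bundle$peaks[[mk]][[st]],
               file.path(dir, sprintf("peaks_%s_%s.bed", mk, st)))
  for (st in names(bundle$contacts))
    for (ch in names(bundle$contacts[[st]]))
      writeContacts(bundle$contacts[[st]][[ch]],
                    file.path(dir, sprintf("contacts_%s_%s.txt", st, ch)))
  for (st in names(bundle$loops))
    writeBedpe(bundle$loops[[st]],
               file.path(dir, sprintf("loops_%s.bedpe", st)))
  writeStageMatrix(bundle$expression, file.path(dir, "expression.tsv"))
  writeStageMatrix(bundle$methylation, file.path(dir, "methylation.tsv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in c("genes", "enhancers", "snps")) {
    write.table(bundle$truth[[nm]], file.path(tdir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(tadBoundaries = bundle$truth$tadBoundaries,
         compartments = bundle$truth$compartments),
    file.path(tdir, "structure.json"))
  invisible(dir)
}
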