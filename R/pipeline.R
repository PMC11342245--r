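#' Validate a data bundle for cross-input consistency
#'
#' Checks stage-label alignment across tracks, peaks, contacts, loops,
#' expression and methylation; bin-size uniformity of the signal tracks
#' and of the contact matrices; and chromosome-name concordance with the
#' annotation. Reports issues instead of raising.
#'
#' @param bundle list shaped like a \code{\link{simulateBundle}} result.
#' @return character vector of human-readable issues (empty when valid).
#' @export
validateInputs <- function(bundle) {
  issues <- character(0)
  stages <- bundle$config$stages
  if (is.null(stages)) stages <- colnames(bundle$expression)
  chroms <- GenomeInfoDb::seqlevels(bundle$annotation)
  sbs <- unique(vapply(bundle$tracks, binSize, integer(1)))
  if (length(sbs) > 1)
    issues <- c(issues, paste("inconsistent signal bin sizes:",
                              paste(sbs, collapse = ", ")))
  hbs <- unique(unlist(lapply(bundle$contacts, function(x)
    vapply(x, binSize, integer(1)))))
  if (length(hbs) > 1)
    issues <- c(issues, paste("inconsistent contact bin sizes:",
                              paste(hbs, collapse = ", ")))
  for (tr in bundle$tracks) {
    if (!stageLabel(tr) %in% stages)
      issues <- c(issues, sprintf("track %s has unknown stage %s",
                                  markName(tr), stageLabel(tr)))
    miss <- setdiff(chroms, names(trackValues(tr)))
    if (length(miss))
      issues <- c(issues, sprintf("track %s@%s lacks chromosome(s) %s",
                                  markName(tr), stageLabel(tr),
                                  paste(miss, collapse = ",")))
  }
  for (mk in names(bundle$peaks)) {
    miss <- setdiff(stages, names(bundle$peaks[[mk]]))
    if (length(miss))
      issues <- c(issues, sprintf("missing peaks for (%s, %s)", mk,
                                  paste(miss, collapse = ",")))
  }
  miss <- setdiff(stages, names(bundle$contacts))
  if (length(miss))
    issues <- c(issues, paste("missing contact matrices for stage(s)",
                              paste(miss, collapse = ",")))
  for (m in list(bundle$expression, bundle$methylation)) {
    if (!identical(colnames(m), stages))
      issues <- c(issues, "stage columns of a gene matrix do not match the stage series")
  }
  issues
}

## ---- truth-evaluation helpers ----------------------------------------------

#' Precision/recall of stage-specific calls against planted truth
#'
#' @param calls DataFrame from \code{\link{callStageSpecific}}.
#' @param truthGenes the \code{truth$genes} table of a simulated bundle.
#' @param stages ordered stage labels (taken from
#'   \code{attr(truthGenes, "stages")} when absent).
#' @return list with \code{precision}, \code{recall}, counts.
#' @export
evaluateStageSpecific <- function(calls, truthGenes, stages = NULL) {
  if (is.null(stages)) stages <- attr(truthGenes, "stages")
  called <- !is.na(calls$stage)
  planted <- truthGenes$class == "specific"
  k <- match(calls$gene_id, truthGenes$gene_id)
  truthStage <- ifelse(planted[k], stages[truthGenes$specificStage[k]],
                       NA_character_)
  tp <- sum(called & !is.na(truthStage) & calls$stage == truthStage,
            na.rm = TRUE)
  list(precision = tp / sum(called), recall = tp / sum(planted),
       nCalled = sum(called), nPlanted = sum(planted), tp = tp)
}

#' Boundary recovery against planted truth
#'
#' @param called integer bin indices of called interior boundaries.
#' @param planted integer bin indices of planted interior boundaries.
#' @param tol match tolerance in bins (default 1).
#' @return list with \code{recall}, \code{precision}, counts.
#' @export
evaluateBoundaries <- function(called, planted, tol = 1L) {
  if (length(planted) == 0) return(list(recall = NA, precision = NA))
  hit <- vapply(planted, function(b) any(abs(called - b) <= tol),
                logical(1))
  phit <- if (length(called))
    vapply(called, function(b) any(abs(planted - b) <= tol), logical(1))
  else logical(0)
  list(recall = mean(hit),
       precision = if (length(called)) mean(phit) else NA,
       nCalled = length(called), nPlanted = length(planted))
}

#' Confusion of TAD-change classification against planted events
#'
#' Maps each planted event to the classified type of its earlier-stage
#' domain(s): all constituent domains of a merge must be labelled merge;
#' split/shift/strength events map to the single recorded domain.
#'
#' @param changes data.frame from \code{\link{classifyTadChanges}} for one
#'   chromosome and stage pair.
#' @param events the truth \code{tadEvents} rows for that chromosome/pair.
#' @return data.frame with \code{expected} and \code{observed} type per
#'   event.
#' @export
evaluateTadChanges <- function(changes, events) {
  rows <- lapply(seq_len(nrow(events)), function(k) {
    ev <- events[k, ]
    expected <- c(merge = "merge", split = "split", shift = "shift",
                  strength = "strength_change")[[ev$type]]
    obs <- if (ev$type == "merge") {
      sel <- changes$start >= ev$start & changes$end < ev$end
      tys <- changes$type[sel]
      if (length(tys) && all(tys == "merge")) "merge"
      else if (length(tys)) tys[tys != "merge"][1] else NA_character_
    } else {
      sel <- which(changes$start == ev$start)
      if (length(sel)) changes$type[sel[1]] else NA_character_
    }
    data.frame(expected = expected, observed = obs)
  })
  do.call(rbind, rows)
}

#' Fraction of bins with correctly recovered compartment labels
#'
#' @param profile a \linkS4class{CompartmentProfile}.
#' @param plantedLabels character "A"/"B" per analysis bin.
#' @return accuracy in [0, 1].
#' @export
evaluateCompartments <- function(profile, plantedLabels) {
  called <- compartmentLabels(profile)
  n <- min(length(called), length(plantedLabels))
  ok <- !is.na(called[seq_len(n)])
  mean(called[seq_len(n)][ok] == plantedLabels[seq_len(n)][ok])
}

## ---- the pipeline -----------------------------------------------------------

.gasMarks <- c("H3K4me3", "H3K27me3", "H3K27ac", "Pol2", "DHS")

#' Run the full synthetic-data analysis pipeline
#'
#' simulate -> quantify -> normalise -> GAS & stage-specific calls ->
#' promoter states, transitions & methylation handoff -> compartments,
#' TADs, TAD-change taxonomy & distance decay -> enhancers, SE/TE &
#' SNP enrichment -> machine-readable report. All randomness flows from
#' \code{config$seed}; a rerun with the same config produces a
#' byte-identical report file.
#'
#' @param config a \code{\link{simConfig}}, or the path to a YAML file
#'   whose top-level keys override simConfig defaults.
#' @param outDir output directory for the report and tables (NULL = no
#'   files written).
#' @param truthComparison add precision/recall blocks for every planted
#'   feature class (default TRUE).
#' @param callLoopsToo also run the donut loop caller on the first and
#'   last stage (slower; default FALSE -- planted loops are used).
#' @return list: the \code{report} (what is written as JSON), plus the
#'   intermediate objects (\code{bundle}, \code{gas}, \code{states},
#'   \code{tads}, \code{compartments}, \code{enhancers}).
#' @export
runPipeline <- function(config = simConfig(), outDir = NULL,
                        truthComparison = TRUE, callLoopsToo = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(what) {
    timings[[what]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }
  if (is.character(config)) {
    cfgList <- yaml::read_yaml(config)
    config <- do.call(simConfig, cfgList)
  }
  stages <- config$stages
  bundle <- simulateBundle(config)
  tick("simulate")
  issues <- validateInputs(bundle)
  if (length(issues)) stop("invalid inputs: ", paste(issues, collapse = "; "))

  tracks <- bundle$tracks
  gasTracks <- Filter(function(t) markName(t) %in% .gasMarks, tracks)
  promSE <- quantifySignals(gasTracks, bundle$annotation, stages,
                            region = "promoter")
  bodySE <- quantifySignals(gasTracks, bundle$annotation, stages,
                            region = "body")
  promN <- normalizeStages(promSE, "quantile")
  bodyN <- normalizeStages(bodySE, "quantile")
  gas <- computeGAS(promN, bodyN)
  specific <- callStageSpecific(gas, "GAS")
  tick("quantify_gas")

  states <- promoterStates(bundle$peaks$H3K4me3, bundle$peaks$H3K27me3,
                           bundle$promoters, stages)
  trans <- stateTransitions(states)
  handoff <- methylationHandoff(assay(promSE, "H3K27me3"),
                                bundle$methylation)
  tick("states")

  chroms <- GenomeInfoDb::seqlevels(bundle$annotation)
  tads <- lapply(stages, function(st)
    lapply(setNames(chroms, chroms), function(ch)
      callTADs(bundle$contacts[[st]][[ch]])))
  names(tads) <- stages
  comps <- lapply(stages, function(st)
    lapply(setNames(chroms, chroms), function(ch)
      callCompartments(bundle$contacts[[st]][[ch]],
        orient = tracks[[paste0("DHS.", st)]])))
  names(comps) <- stages
  tick("tads_compartments")

  pairNames <- paste(stages[-length(stages)], stages[-1], sep = "->")
  tadChangeCounts <- list(); switchFrac <- c()
  changeTables <- list()
  for (p in seq_along(pairNames)) {
    cnts <- c(merge = 0, split = 0, shift = 0, strength_change = 0,
              stable = 0, complex = 0)
    sw <- c()
    for (ch in chroms) {
      df <- classifyTadChanges(tads[[p]][[ch]], tads[[p + 1]][[ch]],
                               bundle$contacts[[stages[p]]][[ch]],
                               bundle$contacts[[stages[p + 1]]][[ch]])
      changeTables[[paste(pairNames[p], ch)]] <- df
      tb <- table(factor(df$type, names(cnts)))
      cnts <- cnts + as.numeric(tb)
      sw <- c(sw, compartmentSwitches(comps[[p]][[ch]],
                                      comps[[p + 1]][[ch]])$fracSwitched)
    }
    tadChangeCounts[[pairNames[p]]] <- as.list(cnts)
    switchFrac[pairNames[p]] <- mean(sw)
  }
  tick("tad_changes")

  decay <- lapply(stages, function(st) {
    profs <- lapply(chroms, function(ch)
      decayProfile(bundle$contacts[[st]][[ch]]))
    shorts <- vapply(profs, function(p) p$shortLongRatio, numeric(1))
    list(shortLongRatio = mean(shorts))
  })
  names(decay) <- stages
  tick("decay")

  enhCalls <- lapply(stages, function(st) {
    calls <- callEnhancers(bundle$peaks$H3K27ac[[st]],
                           bundle$peaks$CTCF[[st]],
                           bundle$peaks$DHS[[st]],
                           bundle$promoters, bundle$annotation,
                           bundle$loops[[st]], stage = st)
    classifySeTe(calls)
  })
  names(enhCalls) <- stages
  allCalls <- unique(do.call(c, unname(enhCalls)))
  seRegions <- reduce(allCalls[mcols(allCalls)$class == "SE"])
  teRegions <- reduce(allCalls[mcols(allCalls)$class == "TE"])
  snpEnr <- if (length(seRegions) && length(teRegions))
    snpRegionEnrichment(bundle$snps, seRegions, teRegions)
  else NULL
  tick("enhancers")

  calledLoops <- NULL
  if (callLoopsToo) {
    calledLoops <- lapply(stages[c(1, length(stages))], function(st)
      callLoops(bundle$contacts[[st]][[chroms[1]]],
                minDist = 2 * config$hicBinSize, maxDist = 3e6))
    tick("loops")
  }

  report <- list(
    stages = stages,
    nGenes = length(bundle$annotation),
    parameters = config[setdiff(names(config), "aging")],
    validation = issues,
    stageSpecificCounts = as.list(table(factor(specific$stage, stages))),
    btaCounts = lapply(trans$bta, length),
    btrCounts = lapply(trans$btr, length),
    handoffCount = sum(handoff$handoff),
    tadCounts = lapply(tads, function(x)
      sum(vapply(x, function(t) length(boundaries(t)) - 1L, integer(1)))),
    tadChangeCounts = tadChangeCounts,
    compartmentSwitchFrac = as.list(switchFrac),
    shortLongRatio = lapply(decay, function(d) d$shortLongRatio),
    enhancerCounts = lapply(enhCalls, length),
    seCounts = lapply(enhCalls, function(x)
      sum(mcols(x)$class == "SE")),
    snpEnrichment = if (!is.null(snpEnr))
      list(oddsRatio = snpEnr$oddsRatio, p = snpEnr$p,
           snpsInSE = snpEnr$snpsInA, snpsInTE = snpEnr$snpsInB)
      else NULL)

  if (truthComparison) {
    truth <- bundle$truth
    attr(truth$genes, "stages") <- stages
    ss <- evaluateStageSpecific(specific, truth$genes)
    plantedBta <- truth$genes[truth$genes$class == "bivalent" &
                              !is.na(truth$genes$bivalentFate) &
                              truth$genes$bivalentFate == "bta", ]
    btaHit <- mapply(function(g, t)
      g %in% trans$bta[[stages[t]]],
      plantedBta$gene_id, plantedBta$transitionStage)
    bnd <- list()
    for (st in stages) for (ch in chroms) {
      planted <- setdiff(truth$tadBoundaries[[ch]][[match(st, stages)]],
                         c(1L, truth$nHicBins))
      called <- boundaries(tads[[st]][[ch]])
      called <- setdiff(called, range(called))
      e <- evaluateBoundaries(called, planted)
      bnd[[paste(st, ch)]] <- c(recall = e$recall,
                                precision = e$precision)
    }
    confusion <- do.call(rbind, lapply(seq_along(pairNames), function(p) {
      do.call(rbind, lapply(chroms, function(ch) {
        ev <- truth$tadEvents[truth$tadEvents$chrom == ch &
                              truth$tadEvents$pair == p, , drop = FALSE]
        if (nrow(ev) == 0) return(NULL)
        evaluateTadChanges(changeTables[[paste(pairNames[p], ch)]], ev)
      }))
    }))
    ## taxonomy accuracy on the planted domain catalog itself (separating
    ## the classifier from insulation-caller noise)
    confusionPlanted <- do.call(rbind, lapply(seq_along(pairNames),
                                              function(p) {
      do.call(rbind, lapply(chroms, function(ch) {
        ev <- truth$tadEvents[truth$tadEvents$chrom == ch &
                              truth$tadEvents$pair == p, , drop = FALSE]
        if (nrow(ev) == 0) return(NULL)
        t1 <- TADSet(truth$tadBoundaries[[ch]][[p]], truth$nHicBins,
                     config$hicBinSize, ch, stages[p])
        t2 <- TADSet(truth$tadBoundaries[[ch]][[p + 1]], truth$nHicBins,
                     config$hicBinSize, ch, stages[p + 1])
        df <- classifyTadChanges(t1, t2,
                                 bundle$contacts[[stages[p]]][[ch]],
                                 bundle$contacts[[stages[p + 1]]][[ch]])
        evaluateTadChanges(df, ev)
      }))
    }))
    compAcc <- mean(unlist(lapply(seq_along(stages), function(s)
      lapply(chroms, function(ch)
        evaluateCompartments(comps[[s]][[ch]],
                             truth$compartments[[ch]][[s]])))))
    hoPlanted <- truth$handoff$gene_id
    hoRecall <- mean(hoPlanted %in% handoff$gene_id[handoff$handoff])
    report$truthComparison <- list(
      stageSpecific = list(precision = ss$precision, recall = ss$recall),
      btaRecall = mean(btaHit),
      boundaryRecall = mean(vapply(bnd, `[[`, numeric(1), "recall")),
      boundaryPrecision = mean(vapply(bnd, `[[`, numeric(1),
                                      "precision")),
      tadChangeDiagonal = mean(confusionPlanted$expected ==
                               confusionPlanted$observed, na.rm = TRUE),
      tadChangeDiagonalCalledTads = mean(confusion$expected ==
                                         confusion$observed,
                                         na.rm = TRUE),
      compartmentAccuracy = compAcc,
      handoffRecall = hoRecall)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeStageMatrix(assay(gas, "GAS"), file.path(outDir, "gas.tsv"))
    write.table(as.data.frame(specific),
                file.path(outDir, "stage_specific.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(paste(names(timings), unlist(timings), sep = "\t"),
               file.path(outDir, "timings.log"))
  }

  invisible(list(
    report = report, bundle = bundle, gas = gas, specific = specific,
    states = states, transitions = trans, handoff = handoff,
    tads = tads, compartments = comps, changeTables = changeTables,
    enhancers = enhCalls, snpEnrichment = snpEnr, decay = decay,
    calledLoops = calledLoops))
}
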