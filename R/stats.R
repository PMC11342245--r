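#' @importFrom stats dhyper phyper p.adjust cor quantile sd setNames rpois
#'   rgamma rlnorm rbeta runif rbinom ecdf ks.test median ppois
NULL

#' Odds ratio of a 2x2 table
#'
#' OR = (a d) / (b c) for the table \code{rbind(c(a, b), c(c, d))}. With
#' \code{haldane = TRUE} (default) 0.5 is added to every cell when any cell
#' is zero, keeping the estimate finite.
#'
#' @param tab 2x2 numeric matrix, or the cell \code{a} when \code{b,c,d}
#'   are given.
#' @param b,c,d remaining cells when \code{tab} is scalar.
#' @param haldane apply the Haldane-Anscombe 0.5 correction on zero cells.
#' @return numeric odds ratio.
#' @export
oddsRatio <- function(tab, b = NULL, c = NULL, d = NULL, haldane = TRUE) {
  if (!is.null(b)) tab <- matrix(c(tab, b, c, d), 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (haldane && any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test computed in log space. The two-sided p-value
#' follows the point-probability rule: the sum of probabilities of all
#' tables (with the observed margins) whose probability does not exceed
#' that of the observed table.
#'
#' @param tab 2x2 non-negative integer matrix \code{rbind(c(a,b),c(c,d))}.
#' @param alternative "two.sided" (default), "greater" (enrichment of cell
#'   a) or "less".
#' @return p-value in [0, 1].
#' @export
fisherExact <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]
  m <- tab[1, 1] + tab[1, 2]          # row 1 margin
  n <- tab[2, 1] + tab[2, 2]          # row 2 margin
  k <- tab[1, 1] + tab[2, 1]          # column 1 margin
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  lp <- dhyper(lo:hi, m, n, k, log = TRUE)
  lobs <- dhyper(a, m, n, k, log = TRUE)
  p <- switch(alternative,
    greater   = sum(exp(lp[(lo:hi) >= a])),
    less      = sum(exp(lp[(lo:hi) <= a])),
    two.sided = sum(exp(lp[lp <= lobs + 1e-7])))
  min(1, p)
}

#' Hypergeometric gene-set over-representation
#'
#' Tests whether \code{hits} over-represents \code{set} within
#' \code{universe}. Fold = (overlap/|hits|) / (|set|/|universe|).
#'
#' @param hits character vector of selected genes (subset of universe).
#' @param set character vector, the gene set (subset of universe).
#' @param universe character vector of all genes.
#' @return list with \code{overlap}, \code{fold}, \code{p} (hypergeometric
#'   upper tail), \code{table} and \code{test}.
#' @export
genesetEnrichment <- function(hits, set, universe) {
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(hits); set <- unique(set); universe <- unique(universe)
  if (!all(hits %in% universe) || !all(set %in% universe))
    stop("hits and set must be subsets of the universe")
  q <- length(intersect(hits, set))
  p <- phyper(q - 1, length(set), length(universe) - length(set),
              length(hits), lower.tail = FALSE)
  fold <- (q / length(hits)) / (length(set) / length(universe))
  tab <- matrix(c(q, length(hits) - q,
                  length(set) - q,
                  length(universe) - length(hits) - length(set) + q),
                2, 2, byrow = TRUE)
  list(overlap = q, fold = fold, p = p, table = tab,
       test = "hypergeometric")
}

#' SNP enrichment in one region class versus another
#'
#' Builds a 2x2 table of SNP counts in the two (disjoint) region classes
#' against a background of per-bp length ("bp" mode, default: a random SNP
#' falls into a class proportionally to its length) or per-region counts
#' ("region" mode).
#'
#' @param snps GRanges of SNP positions.
#' @param regionsA,regionsB disjoint GRanges region classes (e.g. SEs and
#'   TEs).
#' @param mode background construction, "bp" or "region".
#' @param haldane zero-cell correction for the odds ratio.
#' @return list with \code{oddsRatio}, \code{p} (two-sided Fisher),
#'   \code{table}, \code{mode} and per-class SNP counts.
#' @export
snpRegionEnrichment <- function(snps, regionsA, regionsB,
                                mode = c("bp", "region"), haldane = TRUE) {
  mode <- match.arg(mode)
  if (length(GenomicRanges::intersect(regionsA, regionsB)) > 0)
    stop("regionsA and regionsB must be disjoint")
  a <- sum(countOverlaps(snps, regionsA) > 0)
  b <- sum(countOverlaps(snps, regionsB) > 0)
  if (mode == "bp") {
    cc <- sum(width(reduce(regionsA))) - a
    dd <- sum(width(reduce(regionsB))) - b
  } else {
    cc <- sum(countOverlaps(regionsA, snps) == 0)
    dd <- sum(countOverlaps(regionsB, snps) == 0)
  }
  tab <- matrix(c(a, b, cc, dd), 2, 2, byrow = TRUE)
  list(oddsRatio = oddsRatio(tab, haldane = haldane),
       p = fisherExact(round(tab)),
       table = tab, mode = mode, snpsInA = a, snpsInB = b)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up control of the false discovery rate.
#'
#' @param p numeric p-values in [0, 1]; NaN is an error.
#' @return q-values, same length and order as \code{p}.
#' @export
bhFdr <- function(p) {
  if (any(is.nan(p))) stop("NaN p-value")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
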