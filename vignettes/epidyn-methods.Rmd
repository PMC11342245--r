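---
title: "Methods: chromatin-state dynamics across a developmental time course"
author: "epidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state dynamics across a developmental time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

epidyn implements an integrated analysis of how chromatin state evolves
over an ordered series of developmental stages in one tissue. The default
stage series (E50, E90, E120, P0, P4M, PY4.5, PY20) spans prenatal
development, birth, maturation and aging of the primate prefrontal
cortex, where this style of multi-omic profiling — histone marks,
chromatin accessibility, Pol2 and CTCF occupancy, Hi-C contact maps,
promoter DNA methylation and expression — is the standard design. Every
analysis is keyed to that time axis.

The components are:

* **Gene active signal (GAS).** Per gene and stage, the sum of the
  normalised active signals (H3K4me3, H3K27ac, Pol2, DHS) minus the
  normalised repressive H3K27me3 signal. By default H3K4me3, DHS and
  H3K27me3 are quantified over the promoter window (TSS ± 2 kb) and
  Pol2/H3K27ac over the gene body; the split is configurable because
  either convention is defensible and the two summaries are produced
  separately by `quantifySignals()`.
* **Stage-specific calling.** A gene (or region) is specific to its
  maximal stage when that stage's value is at least `foldMin` (default
  2) times the maximum of the other stages *and* its z-score against the
  other stages is at least `zMin` (default 1.5). Both parts are
  scale-free, so the call is invariant to global rescaling of a mark.
  The criterion is deliberately simple and exposed as configuration; any
  fold/z pair can be substituted.
* **Promoter-state machine.** Promoter states are defined purely by peak
  presence: both H3K4me3 and H3K27me3 peaks over the promoter is
  bivalent, H3K4me3 alone active, H3K27me3 alone repressive, neither
  none. `stateTransitions()` tabulates every state-to-state transition
  between adjacent stages (each gene counted once per pair, so counts
  are conserved) and extracts BTA genes (bivalent at the previous stage,
  active now) and their BTR counterparts. A `lookback` argument widens
  "previous" to a window when bivalency further back should count.
* **H3K27me3-to-5mC handoff.** A gene is flagged when its promoter
  H3K27me3 is above the stage-wise 75th percentile at an earlier stage,
  below it at a later stage, and promoter methylation at the later stage
  is at least 0.6. The two thresholds are quantile- and beta-scaled so
  they transfer across normalisations.
* **3D genome.** A/B compartments come from the leading eigenvector of
  the Pearson correlation of the distance-normalised (O/E) contact
  matrix, computed at a 400-kb analysis bin; the sign is oriented by
  correlation with DHS signal (or gene density). TADs come from an
  insulation score (log2 of the mean contact in a `window`-by-`window`
  square of pixels crossing each bin junction against the chromosome-wide
  mean), with boundaries at local minima of prominence ≥ 0.2. The
  TAD-change taxonomy compares two domain segmentations and assigns each
  earlier-stage domain exactly one of merge / split / shift /
  strength_change / stable / complex; merge and split are inverse under
  input swap. Distance decay, short/long-range contact ratios (default
  threshold 730 kb), intra/inter-TAD contact ratios and distance-matched
  intra/inter-TAD signal correlations complete the 3D summary.
* **Enhancers.** Candidate elements are merged H3K27ac peaks that also
  carry CTCF and DHS peaks, do not overlap any promoter, and loop to a
  promoter whose TSS lies within 3 Mb. Super enhancers are merged calls
  of length ≥ 8 kb (inclusive), typical enhancers shorter ones.
  Stage-specific versus stage-common lineages are built by reciprocal
  interval overlap (Jaccard ≥ 0.5) across stages. Elements whose active
  score (H3K27ac + DHS − H3K27me3 over the element) tracks target
  expression with Pearson r ≥ 0.8 are retained for module clustering.
* **Statistics.** 2×2 odds ratios (Haldane–Anscombe 0.5 on zero cells),
  Fisher's exact test computed in log space with the two-sided
  point-probability rule, hypergeometric gene-set enrichment, SNP
  enrichment in one region class versus another (per-bp or per-region
  background), and Benjamini–Hochberg FDR control.

# The synthetic-data generator

`simulateBundle()` produces a complete dataset with planted ground truth
so that every caller is testable without any download. Its defaults *are*
the study conditions used throughout the tests and the acceptance
script: 7 stages, 2 chromosomes of 30 Mb, 10-kb signal bins, 40-kb Hi-C
bins, 1500 genes, 10% of genes planted stage-specific per stage, 210
bivalent genes with planted fates (50% bivalent-to-active, 25%
bivalent-to-repressive, 25% maintained; transition stage uniform), 100
H3K27me3-to-5mC handoff genes, 80 enhancers (25% SE by length, 20%
present at all stages), TAD catalogs with 2 planted merges, splits,
shifts and strength changes per chromosome per adjacent stage pair, A/B
blocks of 2–4 Mb with ~15% of bins switching per stage pair, and 500
SNPs placed per-bp with 3:1 odds in SEs over TEs.

Signal at a bin is gamma background (shape 4, mean 1) multiplied by the
planted enrichment (8×) of marks active there; peaks are emitted for
planted features with a 1% dropout; expression is
softplus(1.2·activity − 1) with log-normal noise (sdlog 0.3);
methylation betas concentrate around 0.1 (or 0.8 after a handoff) with
concentration 60; contacts follow depth·s^−α (α = 1, depth 60 at one
bin) times a 2.2× same-TAD block factor, a (1 + 0.3·e·e′) compartment
plaid, and 6× loop dots, under Poisson sampling. DHS background is 1.5×
higher in A-compartment bins, which mirrors the accessibility bias of
active compartments and supplies the eigenvector orientation signal.
Where the underlying study does not state an effect size, these defaults
were chosen once as values a practitioner would call realistic for
deeply sequenced bulk data, and are exposed in `simConfig()` as free
parameters, not claims about any real dataset.

Genes occupy bin-aligned slots with the TSS at a fixed offset, so no two
planted genes share a signal bin; enhancers live in a dedicated distal
region 0.2–2.4 Mb beyond the last gene, within looping reach (< 3 Mb) of
the nearest promoters but never overlapping one. With `noiseFree = TRUE`
all noise collapses to its expectation, and every planted feature is
recoverable exactly — the suite asserts this for promoter states and
transition counts.

`agingVariant()` raises the final stage's decay exponent (default +0.4)
and splits 30% of its TADs, reproducing the qualitative aging signature:
the short/long-range contact ratio at 730 kb rises and new boundaries
appear. What the generator does *not* emulate: replicate-level ChIP
efficiency variation, read-level artefacts, trans contacts,
copy-number structure, or correlated noise between marks. Green tests
therefore demonstrate that the algorithms recover what they claim from
data of this structure — not that any particular biological dataset will
behave as cleanly.

# Numerical and design choices

* **Coordinates.** All interval containers are GRanges (1-based,
  closed), the Bioconductor convention; BED/bedGraph/BEDPE half-open
  coordinates are converted at the file boundary by rtracklayer or the
  package's writers, and GTF is collapsed per gene on read. Round-trip
  identity is asserted in the suite.
* **Normalisation.** The cross-stage default is quantile normalisation
  (via limma) per mark: it is robust to stage-to-stage
  immunoprecipitation efficiency shifts and makes the GAS components
  commensurable. z and min-max column scaling are provided. Contact
  matrices are balanced to equal row sums (simple iterative correction)
  before O/E; raw mode is available because public matrices often arrive
  pre-normalised.
* **Compartment bin.** Compartments are computed at 400 kb — a megabase
  scale analysis bin that is an integer multiple of the 40-kb Hi-C bins.
  Bins with zero coverage or zero O/E variance are masked; an
  uninformative eigenvector or an orientation correlation below 0.1
  flags the profile "undetermined" rather than guessing a sign.
* **Insulation.** Window 10 bins (400 kb at the default binning); the
  square of pixels strictly crossing the junction upstream of bin i is
  used, so a boundary bin (the first bin of a domain) is the score
  minimum. Local minima are searched within ±window/2 bins with
  prominence ≥ 0.2 log2 units.
* **TAD-change tolerances.** Boundary matching tolerance 2 bins; a
  boundary moved by more than 2 but at most 5 bins is a shift;
  intra-domain mean O/E ratio ≥ 1.5 (either direction) on otherwise
  matching extents is a strength change. All are arguments.
* **Loop caller.** A donut-background Poisson test: local expected value
  = (mean O/E in a Chebyshev annulus of radii 2–5 bins) × distance
  expectation, Poisson upper-tail p, BH at FDR 0.1, adjacent significant
  pixels merged. This is a deliberate simplification of pixel-level loop
  detection; it is exact on locally smooth backgrounds (zero false loops
  on pure power-law matrices in the suite) but, like all donut tests,
  loses specificity at domain corners, so the pipeline prefers supplied
  loop calls (BEDPE) when they exist and never feeds its own calls into
  enhancer target assignment by default.
* **Module clustering.** Cis-element modules come from average-linkage
  hierarchical clustering on 1 − Pearson correlation of stage
  trajectories, with k chosen by mean silhouette over 2–8 — an explicit,
  documented stand-in for weighted co-expression network module
  detection. Labels are renumbered over sorted element names, so the
  partition is invariant to input order; labels are not comparable to
  any published module colouring.
* **Fisher's exact test.** Two-sided p sums the probabilities of all
  tables (fixed margins) whose point probability does not exceed the
  observed one (with a 1e−7 relative guard against floating-point ties);
  computed from log hypergeometric masses, exact for all margins the
  suite enumerates (≤ 30) and stable for margins in the tens of
  thousands. Degenerate margins return p = 1.
* **Permutations.** Cumulative-activation contrasts use a seeded label
  permutation (default 10^4) with add-one correction; boundary-feature
  enrichment shuffles boundary placements chromosome- and
  length-preserving. All randomness in the package flows from a single
  seed (the generator seeds once and draws sequentially; permutation
  functions take explicit seeds), which is what makes the end-to-end
  report byte-reproducible.

# Problem sizes and runtime

The default conditions (2 × 30 Mb, 1500 genes, 750 Hi-C bins per
chromosome) were chosen so that a full pipeline run — simulation,
quantification, GAS, state machine, compartments, TADs, change taxonomy,
decay, enhancers, SNP enrichment, truth comparison and report — completes
in well under a minute on one CPU, and the entire test suite in a few
minutes. Unit tests use a single 10-Mb chromosome. Chromosome-scale
inputs (hundreds of Mb) work with the same code paths; the dense-matrix
steps (O/E, insulation, loop scan) are the ones whose memory grows
quadratically with bins per chromosome, so very large chromosomes should
be processed per chromosome, as the pipeline already does.

# Known limitations

* Stage-specificity at the last stage cannot be distinguished from a
  late bivalent-to-active transition by the GAS criterion alone; a
  planted BTA gene arriving at the final stage is (correctly, given the
  data) called stage-specific there, which bounds precision against the
  planted labels slightly below 1.
* The insulation caller over-segments noisy matrices relative to the
  planted catalog (recall ≈ 1 at the default depth, precision lower);
  boundary-level precision is reported alongside recall in the pipeline
  report rather than hidden.
* The TAD-change taxonomy is exact on domain catalogs; run on called
  TADs its accuracy is bounded by caller noise, and the report carries
  both numbers (`tadChangeDiagonal` for the planted catalog,
  `tadChangeDiagonalCalledTads` end-to-end).
* Compartment eigenvectors on short chromosomes (tens of analysis bins)
  are less stable; the default conditions use 75 bins per chromosome
  where recovery is complete.
* Fisher p-values on discrete tables are conservative; the
  null-calibration check uses large balanced margins where the lattice
  spacing is small compared to the 0.02 KS tolerance.
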