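# epidyn

Chromatin-state dynamics across a developmental time course, in one
tested R package.

Bulk multi-omic profiling of a tissue across ordered stages — histone
marks (H3K4me3, H3K27me3, H3K27ac), Pol2 and CTCF occupancy, DNase
hypersensitivity, Hi-C contact maps, promoter DNA methylation and
expression — raises the same set of questions every time: which genes
carry stage-specific regulatory signal, which promoters are bivalent and
when do they resolve, where do A/B compartments switch and TADs merge or
split, which distal elements are enhancers and which of those are super
enhancers, and how does the contact spectrum shift with aging. epidyn
implements this analysis surface for an ordered stage series (the
default series E50 → PY20 models prefrontal-cortex development and
aging), together with a synthetic-data generator that plants ground
truth for every feature class, so each caller is tested end to end
without downloading anything.

## The core quantities

* **Gene active signal.** For gene *g* at stage *s*, with
  quantile-normalised signals,

  GAS(g, s) = H3K4me3 + H3K27ac + Pol2 + DHS − H3K27me3,

  promoter-level for H3K4me3/DHS/H3K27me3 (TSS ± 2 kb) and gene-body for
  Pol2/H3K27ac by default. Stage-specific genes satisfy
  value(s) ≥ 2 × max(other stages) and z(s) ≥ 1.5.
* **Promoter states.** bivalent = H3K4me3 ∧ H3K27me3 peaks over the
  promoter; active = H3K4me3 only; repressive = H3K27me3 only. BTA
  genes transition bivalent → active between adjacent stages.
* **3D genome.** Compartments: sign of the leading eigenvector of the
  O/E correlation matrix at 400 kb, oriented by DHS. TADs: insulation
  score minima (window 10 bins). TAD changes: merge / split / shift /
  strength_change / stable / complex per earlier-stage domain.
  Distance decay P(s) and the short/long-range contact ratio at 730 kb.
* **Enhancers.** Merged H3K27ac peaks carrying CTCF + DHS, outside
  promoters, looped to a promoter within 3 Mb; super enhancers are
  calls ≥ 8 kb. SNP enrichment in SE versus TE is a 2×2 odds ratio with
  an exact Fisher p.

## Worked example

```r
library(epidyn)

cfg <- simConfig(nChroms = 1, chromLength = 10e6, geneRegionEnd = 7.5e6,
                 nGenes = 300, nBivalent = 60, nHandoff = 30,
                 nEnhancers = 20, nSnps = 150, nBackgroundSnps = 30)
res <- runPipeline(cfg, outDir = "epidyn_run")
r <- res$report

unlist(r$stageSpecificCounts)
#>   E50   E90  E120    P0   P4M PY4.5  PY20
#>    32    32    30    30    30    30    32

unlist(r$btaCounts)
#>   E90  E120    P0   P4M PY4.5  PY20
#>     6     7     4     5     9     2

round(r$snpEnrichment$oddsRatio, 2); signif(r$snpEnrichment$p, 3)
#> [1] 3.12
#> [1] 7.88e-12

round(unlist(r$shortLongRatio), 2)
#>   E50   E90  E120    P0   P4M PY4.5  PY20
#>  4.85  4.37  4.55  4.08  3.66  3.64  3.90
```

About 10% of the 300 genes are called stage-specific per stage (the
planted fraction); bivalent promoters resolve to active across the
series; the SNPs planted with 3:1 per-bp odds in super enhancers are
recovered at an odds ratio of 3.12 with an exact p of 8×10⁻¹²; the
short/long contact ratio is flat because this config plants no aging
shift. `r$truthComparison` holds precision/recall per planted feature
class — in this run, stage-specific precision 0.97 / recall 0.99, BTA
recall 0.94, boundary recall 1.0, planted TAD-change diagonal 1.0,
handoff recall 0.97.

`runPipeline()` writes `report.json` (byte-identical under a fixed
seed), the GAS matrix and the stage-specific calls into `outDir`. The
individual steps are exported (`quantifySignals`, `computeGAS`,
`promoterStates`, `stateTransitions`, `callCompartments`, `callTADs`,
`classifyTadChanges`, `callEnhancers`, `classifySeTe`,
`snpRegionEnrichment`, ...) and operate on plain Bioconductor objects
(GRanges, SummarizedExperiment) plus small S4 containers for tracks,
contact matrices, TAD sets, compartment profiles and loops.

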