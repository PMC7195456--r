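# emtflux

Comparative analysis of epithelial–mesenchymal transition (EMT) dynamics
from sample-multiplexed single-cell RNA-seq.

The EMT is not one program: when the same panel of cell lines is pushed
through the transition by different inducers, the responding genes overlap
only modestly between conditions, and inhibitor screens reveal that single
responses decompose into independently perturbable modules. Quantifying
that context specificity takes a pipeline, not a single test: demultiplex
barcoded pools into samples, order each condition's cells along its own
transition, call response genes along that ordering, and then compare
programs — and inhibitor effects — across conditions on a common footing.
`emtflux` implements that pipeline for R, in Bioconductor idiom
(`SingleCellExperiment` containers, S4 result classes), together with a
ground-truth synthetic generator so every stage is testable end to end on
one machine.

## What it computes

* **Demultiplexing** (`demultiplex`): per-barcode thresholds between the
  density modes of log counts, at the global quantile q that maximizes the
  singlet yield; cells positive for one barcode are singlets, for several
  doublets, for none negatives.
* **Supervised pseudotime** (`fitPseudotime`, `projectPseudotime`): a
  penalized cumulative-logit model on ordered time-point labels,
  P(y ≤ k | x) = logistic(θₖ − w·x), with elastic-net-sparse w chosen by
  cross-validated ordinal accuracy (one-standard-error rule). Withdrawal
  and screen cells are scored by projection (a matrix product) and rescaled
  to [0,1] on the training range.
* **Gene dynamics** (`deOverPseudotime`, `linearDirection`): per gene,
  `expr ~ s(pseudotime, k = 4) + batch` (penalized spline, REML), BH
  adjustment, significance restricted to the top-variable universe;
  directional β from the no-smoother variant; 200-point fitted trends.
* **Scoring** (`moduleScore`, `aucellScore`, `gseaPreranked`,
  `nesDifference`, `hypergeomEnrichment`): binned-control gene-set scores,
  rank-based recovery-curve AUC for regulon activity, running-sum ES/NES
  with permutation p-values, recovery-NES differences between gene lists,
  and hypergeometric over-representation.
* **Cross-condition comparison** (`jaccardMatrix`, `deFrequency`,
  `conservedSets`, `regulonFrequency`, `setIntersections`): pairwise
  Jaccard of response sets, frequency spectra, conserved signed sets
  (significant in ≥ 2/3 of conditions with unanimous direction), UpSet
  tables.
* **Screen interpretation** (`scoreScreen`, `classifyBlock`,
  `partitionResponseGenes`, `temporalBlockCheck`): projected pseudotime
  per inhibitor, none/partial/full block classification by rank-sum
  bracketing, partition of the induced program into inhibited vs unaffected
  genes, and a Kolmogorov–Smirnov test against the temporal-block
  alternative.
* **Synthetic experiments** (`panelConfig`, `simulateConditionPanel`,
  `poolAndBarcode`, `simulateScreen`): negative-binomial time courses with
  programmed response overlap, withdrawal reversion, barcode doublets and
  negatives, embedded regulons, and full/partial/inert inhibitors — with
  complete ground truth.

## Worked example

Simulate two conditions, order one along its transition, call its response
program, and compare the two programs:

```r
library(emtflux)

cfg <- panelConfig(nConditions = 2, cellsPerSample = 100, nGenes = 600,
                   nResponseGenes = 60, seed = 1)
panel <- simulateConditionPanel(cfg)

run <- function(sce) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  cd     <- SingleCellExperiment::colData(sce)
  logc   <- normalizeLog(counts)
  vg     <- selectVariableGenes(counts, n = 300)
  genes  <- rownames(vg)[vg$selected]
  treat  <- cd$phase == "treatment"
  model  <- fitPseudotime(logc[genes, treat], cd$timepoint[treat], seed = 1)
  pt     <- projectPseudotime(model, logc[genes, ])
  dyn    <- deOverPseudotime(logc[, treat], pt$raw[treat], cd$batch[treat],
                             universe = genes)
  list(model = model, pt = pt, dyn = dyn)
}
r1 <- run(panel$sces$cond01)
r2 <- run(panel$sces$cond02)

r1$model
#> PseudotimeModel: 5 ordered labels, 300 genes ( 39 non-zero )
#>   lambda: 0.02432  alpha: 0.5  CV accuracy: 0.722
#>   training score range: [ -7.339 , 5.558 ]

round(tapply(r1$pt$rescaled, SingleCellExperiment::colData(panel$sces$cond01)$timepoint, mean), 2)
#>      0d      8h      1d      3d      7d w0.333d w1.000d w3.000d
#>    0.24    0.37    0.57    0.78    0.87    0.81    0.57    0.32

r1$dyn
#> GeneDynamics: 600 genes, 62 significant; 200 grid points

J <- jaccardMatrix(list(cond01 = significantGenes(r1$dyn),
                        cond02 = significantGenes(r2$dyn)))
round(J$matrix, 2)
#>        cond01 cond02
#> cond01   1.00   0.17
#> cond02   0.17   1.00
J$meanOffdiag
#> [1] 0.1730769   # generator target: 0.2
```

The projected means rise monotonically through treatment and fall back
through withdrawal (near-complete reversion by three days), the 62
recovered response genes cover 54 of the 60 programmed ones, and the
between-condition Jaccard lands near the overlap the generator was asked
to build — the three behaviours the pipeline exists to measure.

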