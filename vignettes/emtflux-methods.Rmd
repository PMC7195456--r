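---
title: "Models and methods behind emtflux"
author: "emtflux authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods behind emtflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`emtflux` implements a comparative analysis of epithelial–mesenchymal
transition (EMT) time courses measured by sample-multiplexed single-cell
RNA-seq: barcode demultiplexing, quality control and normalization,
supervised pseudotime per condition, pseudotime-resolved differential
expression, gene-set and regulon activity scoring, cross-condition
context-specificity statistics, and interpretation of kinase-inhibitor
screens projected onto the time-course models. Because the questions the
pipeline answers are about *recovery* — does the analysis find the response
programs, their overlap structure and the inhibitor effects that are really
there? — the package ships a first-class synthetic-data generator with
complete ground truth, and every downstream stage is validated against it.

# The synthetic experiment

`simulateConditionPanel()` emulates a panel of EMT time-course experiments:
by default 12 conditions (think four cell lines crossed with three
inducers), five ordered treatment time points, three post-withdrawal time
points, and 200 cells per sample.

**Latent progression.** Each cell carries a latent coordinate
$t \in [0, 1]$: treatment time points tile $[0,1]$ evenly (plus per-cell
Gaussian jitter, sd 0.05, reflecting asynchrony within a well), and after
withdrawal $t$ decays exponentially with a configurable half-life (default
1 day), so the three-day withdrawal sample has reverted almost completely —
the qualitative behaviour seen in inducible EMT models.

**Response programs and their overlap.** Each condition owns a signed
response program of $m$ genes (default 150). Programs are built from a
conserved core of size $\lceil f_c m \rceil$ (default $f_c = 0.2$) present
in every condition with a consistent sign, plus $m - \lceil f_c m \rceil$
genes drawn per condition from a common pool. The pool size $P$ is solved
from the target pairwise Jaccard $J$: the expected intersection of two
programs is $c + (m-c)^2/P$, and $P$ is chosen so this equals
$2mJ/(1+J)$. Infeasible geometries (a core larger than the implied
intersection, a pool smaller than the per-condition draw, or a gene budget
overrun) are rejected with an error rather than silently approximated.
A pleasant side effect of the pool construction is that non-core response
genes end up active in only one or two conditions each — the frequency
spectrum dominated by condition-restricted genes that motivates the
comparison in the first place.

**Observation model.** Counts are negative binomial with gene-specific
baseline means drawn log-normally (meanlog $\log 0.3$, sdlog 1.2 — a
realistic abundance ladder at ~10⁴-UMI depth) and dispersion 0.1. A
response gene's log-mean follows its assigned shape — linear, sigmoid, or
transient — scaled by a per-gene effect of 1–2 natural-log units and its
sign. Core genes are restricted to monotone shapes so that a "conserved
direction" is well defined. Two batches receive additive per-gene log-mean
shifts (sd 0.1), mirroring paired replicate mixes. Response genes draw
their baselines from the detectable stratum (floored at mean 0.3): a
programmed response on a gene with essentially no counts is unobservable at
this depth and would make the truth labels unidentifiable for any method —
the generator defines ground truth that is in-principle recoverable, and
leaves sensitivity at realistic expression levels to the acceptance checks.

**Multiplexing.** `poolAndBarcode()` pools all cells and attaches a
cell × barcode count matrix: a singlet has log-normal counts (median 300)
for exactly its sample's barcode and Poisson ambient counts (mean 1)
elsewhere. A configured fraction of cells are doublets — the sum of two
cells' expression with both barcodes positive; the partner is drawn from a
*different* sample, because a same-sample doublet carries a single barcode
and is indistinguishable from a singlet by construction of the assay — or
negatives (ambient-only barcodes).

**Screens.** `simulateScreen()` reuses a condition's generative parameters
to produce end-point (day-7) profiles per inhibitor: an inert inhibitor
leaves the program intact, a full block holds every response gene at its
day-0 level, and a partial block holds only a stated module at day 0.
Cytotoxic inhibitors are emulated as reduced cell counts. Untreated
(day-0) control cells are always included.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: ambient RNA contamination, cell-cycle structure,
UMI saturation, non-additive batch effects, doublets in expression space
beyond simple sums, clock-time versus response-time decoupling, and
cross-talk between conditions. The generator validates the *statistical
machinery*; biological validity of any specific finding still rests on the
experimental design.

# Demultiplexing

For each barcode, counts across cells are log-scaled (`log1p`) and smoothed
with a Gaussian kernel density (Silverman bandwidth, 512-point grid). The
lowest and highest local maxima (prominence above 1% of the tallest peak)
define the negative and positive modes. The mode pair must be separated by
at least 2 log units; otherwise the barcode is deemed absent (threshold
above all observed counts) and a warning is recorded — this guards against
the ripples that discrete low counts produce in a kernel density. For a
candidate quantile $q$, the threshold sits at the $q$-quantile of the
inter-mode interval; the single global $q$ maximizing the fraction of cells
called singlets is selected, with ties broken toward smaller $q$.
Classification is then per cell: positive for one barcode → singlet with
that sample label, more than one → doublet, none → negative. Only singlets
proceed downstream.

Two points were genuinely open and are resolved as follows. The
optimization target of the "optimal quantile" is taken as the singlet
fraction, the natural yield criterion. And the values being thresholded are
per-barcode log counts rather than per-cell barcode fractions: with a
fraction normalization the positive mode collapses to a near-spike (the
count magnitude cancels in the fraction) while a doublet's two barcodes
split the cell's total and land strictly below it, so a singlet-maximizing
threshold would systematically re-label doublets as singlets.

# Quality control and preprocessing

Cells must exceed 200 detected genes (strict inequality; a 201-gene cell is
kept) and stay at or below a mitochondrial fraction of 0.20 by default —
the threshold is configurable and recorded in the QC log attached to the
result. Genes detected in fewer than 1% of cells (strict) are removed.
Normalization is library-size scaling with log transform,
$\log(1 + 10^4\,c_{gi}/\sum_g c_{gi})$.

Variable genes are ranked by a variance-stabilizing scheme: a loess trend
(span 0.3, degree 2) of $\log_{10}$ variance on $\log_{10}$ mean predicts
each gene's expected standard deviation; counts standardized with it are
clipped at $\sqrt{n_{\text{cells}}}$ and the variance of the clipped values
is the ranking statistic. `scaleAndRegress()` removes technical covariates
(mitochondrial fraction, molecule counts, cell-cycle scores computed with
`moduleScore()` on user-supplied S/G2M lists, batch) by per-gene ordinary
least squares, then z-scores residuals and clips at ±10. Genes left with
numerically no residual variation are set to zero rather than amplifying
floating-point noise. PCA runs on the scaled residuals (30 components by
default).

# Supervised pseudotime

The pseudotime model is a cumulative-logit (ordinal logistic) regression on
the ordered time-point labels $y_i \in \{1,\dots,K\}$:
$$P(y_i \le k \mid x_i) = \mathrm{logit}^{-1}(\theta_k - w^\top x_i),$$
with an elastic-net penalty on the gene coefficients $w$ (mixing
$\alpha = 0.5$). The fit uses the binary-expansion form of the ordinal
likelihood — each cell contributes $K-1$ binary outcomes
$\mathbb{1}(y_i \le k)$ sharing one $w$, with threshold-specific
unpenalized intercepts playing the role of the cutpoints $\theta_k$ — which
reduces the problem to penalized logistic regression (solved with glmnet
along an automatic $\lambda$ path). This is the formulation the supervised
single-cell ordering literature itself uses; a direct proximal-gradient
solver for the exact cumulative likelihood would differ only in the
correlation structure it retains between a cell's $K-1$ pseudo-observations
and was not worth the numerical risk of a bespoke optimizer. Cutpoints are
re-sorted in the rare event the expansion returns a non-monotone set.

$\lambda$ is chosen by 5-fold cross-validation, stratified by label, scored
by *ordinal classification accuracy* (argmax over the implied class
probabilities), with the one-standard-error rule: the strongest penalty
whose mean accuracy is within one standard error of the best. This biases
toward sparse, transferable score functions — important because the score
is later applied to withdrawal cells and to screens measured with a
different library chemistry.

Projection is a matrix multiplication: raw score $= w^\top z$ with the
model's stored standardization applied to the new matrix. Model genes
missing from the target (up to 20%; more is an error) contribute zero after
standardization, i.e. mean imputation in raw space. Withdrawal samples are
*never* used in fitting — they are projected afterwards. When models are
compared on a common axis, scores are rescaled to $[0,1]$ with the
*training* range and clipped, so a screen cell below the training minimum
maps to 0. Projection uses the same representation as training
(log-normalized values), recorded in the model. Models serialize to JSON
with 17 significant digits, which round-trips IEEE doubles exactly.

# Gene dynamics along pseudotime

Per gene, a Gaussian generalized additive model
`expr ~ s(pseudotime, k = 4) + batch` with a penalized cubic regression
spline, smoothing parameter by REML (via mgcv). The basis dimension
$k = 4$ is the package default and exposed, since residual diagnostics
could in principle ask for more. The reported p-value is the approximate
smooth-term test based on effective degrees of freedom; it is approximate
by construction, so its null calibration (rejection rate at
$\alpha = 0.05$ within $[0.02, 0.08]$ over 500 null genes) is verified by
simulation in the test suite rather than assumed. Exactly constant genes
short-circuit to $p = 1$ with a flat trend — the REML profile is undefined
there.

P-values are Benjamini–Hochberg adjusted across all tested genes. A gene is
*significant* only if its adjusted p falls below 0.05 **and** it belongs to
the top-variable universe (top 2000 by default at full scale): many genes
vary statistically but at effect sizes too small to interpret, and the
variance filter also absorbs the compositional artifact of library-size
normalization (a strong response program inflates cell totals and drags
every other gene's normalized value slightly, which is detectable at large
n but low-variance). Directional summaries use the same model with the
smoother removed — `values ~ pseudotime + batch` — reporting the single
pseudotime coefficient $\beta$; this is the statistic used for regulon
activities and cytokine scores, where only the direction of change is of
interest. Fitted trends are evaluated at 200 evenly spaced pseudotime
values spanning $[\min t, \max t]$, with standard errors. Inhibitor-only
contrasts reuse the linear machinery as `expr ~ inhibitor` with the
no-inhibitor control as intercept and a per-gene F-test.

# Scoring

**Module scores.** Mean expression of a gene set minus the mean of control
genes; each member contributes up to 100 controls drawn (seeded) from its
average-expression bin among 24 equal-frequency bins. With one bin the
controls are effectively the whole panel and the score reduces to set mean
minus global mean.

**Regulon activity (recovery AUC).** Per cell, genes are ranked by
decreasing expression with ties broken by the fixed input gene order —
determinism across platforms is worth more than an unbiased tie — and the
score is the area under the cumulative recovery curve of the regulon's
targets within the top 5% of the ranking, normalized by the maximum
attainable area. The score is invariant to any monotone transform of a
cell's profile. Regulons enter as plain gene sets (GMT); network inference
and motif pruning are upstream concerns, out of scope here.

**Preranked enrichment.** Classic running-sum ES: members increment by
$|s|^w$ (normalized over members), non-members decrement by a constant; ES
is the maximum deviation. NES divides ES by the mean |ES| of sign-matched
gene-label permutations (1000 by default) and the p-value is the
permutation tail.

**Enrichment differences between two gene lists.** For each collection set
with its own ranking of all genes, the recovery AUC of list A and of list B
is standardized across the collection ((AUC − mean)/sd — the convention of
recovery-based motif-ranking tools) and the difference NES$_A$ − NES$_B$ is
ranked. The recovery-based form (rather than permutation GSEA) was chosen
because the quantity of interest is a *ranking of collection sets by
list-specific enrichment*, which is exactly what the standardized AUC
provides; the choice is recorded in the result's metadata.

**Over-representation.** Upper-tail hypergeometric p per annotation
(observed overlap or larger), BH-adjusted across annotations.

# Cross-condition comparison

Pairwise Jaccard $J(A,B) = |A\cap B|/|A\cup B|$ over per-condition
significant-gene sets, with the mean off-diagonal entry as the headline
context-specificity number; the per-gene frequency spectrum (in how many
conditions each gene is called); and conserved signed sets: genes
significant in at least two-thirds of conditions (8 of 12 — parameterized
as a fraction, not a constant), assigned up or down only when their
$\beta$ signs are *unanimous* across the conditions where they are
significant. Mixed-sign genes are surfaced in a `conflicted` list rather
than silently dropped or majority-voted: a gene that rises in some
contexts and falls in others is itself a finding. Regulon conservation is
analogous with a default threshold of 6 conditions (half the panel) and
returns the per-condition $\beta$ matrix. `setIntersections()` produces the
exclusive membership-pattern counts (UpSet-style) whose total equals the
union size.

# Screen interpretation

Screen cells are projected with the matching condition's model and
rescaled by its training range; conditions with fewer than 20 cells are
flagged, not scored, keeping cytotoxic drop-out visible. Inhibitor effect
classes come from one-sided rank-sum bracketing at $\alpha = 0.05$: not
significantly below the induced control → `none`; below the control but
not significantly above untreated → `full`; in between → `partial`. The
bracketing (and the residual-effect rule below) is this package's
operationalization — the distinction in the source analyses was made
visually — so both thresholds are exposed and logged.

The induced response program is partitioned per inhibitor: with induced
effect $\Delta = \bar{x}_{\text{ind}} - \bar{x}_{\text{untr}}$ and residual
effect $\Delta' = \bar{x}_{\text{ind+inh}} - \bar{x}_{\text{untr}}$, a gene
is *inhibited* when $|\Delta'| < 0.5\,|\Delta|$ or $\Delta'$ changes sign;
otherwise *unaffected*. The partition is exhaustive and exclusive over the
induced DE universe. Finally, the temporal-block alternative — "the
inhibitor merely froze progression at an earlier stage" — is tested by
comparing activation times (the first grid point where a gene's fitted
trend crosses half of its total change) between inhibited and unaffected
genes with a two-sample Kolmogorov–Smirnov test: a module block predicts no
shift; a temporal block predicts inhibited genes concentrated late.

# Numerical choices and degenerate inputs

* Quantile-grid default 0.01–0.99 step 0.01; ties toward smaller q.
* Constant pseudotime, single labels, empty universes, rank-deficient
  covariate designs, empty gene sets, and sets covering the whole ranking
  all raise immediate errors naming the offender.
* All stochastic steps (generator, control draws, permutations, CV folds)
  take explicit seeds; rerunning a pipeline with the same configuration
  reproduces byte-identical CSV/GMT/MTX/JSON outputs.
* Problem sizes used in the validation suite are deliberately moderate —
  e.g. a 2,000-cell pool for demultiplexing, a 1,600-cell / 2,000-gene
  course for pseudotime recovery, 12 conditions at 250 cells and 400 genes
  for the overlap statistics — chosen so the whole suite documents the
  pipeline's behaviour at single-workstation scale while preserving the
  study's design ratios (12 conditions, 5+3 time points, ~100 samples per
  pool).

# Known limitations

The demultiplexing quantile search assumes a visible positive mode; very
shallow barcode libraries degrade to "absent barcode" warnings. The
pseudotime score is linear in standardized expression, so strongly
non-monotone programs are ordered only as well as their monotone
components allow. The GAM p-value is approximate (calibration is verified,
not exact). Module scores inherit the usual binned-control caveat: if a
set's members dominate the top expression bins, controls overlap the set
and scores compress toward zero. The compare statistics treat significance
calls as exchangeable across conditions and do not model shared cells or
replicates.
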