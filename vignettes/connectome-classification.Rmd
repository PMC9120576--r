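---
title: "Functional connectome classification: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectome classification: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific model behind `fbnclass`, the
parameters that matter and why their defaults are what they are, the
design choices made where the design was genuinely open, and what the
synthetic cohorts used in the tests can and cannot tell you about real
imaging data.

## The pipeline in one paragraph

Given per-subject regional BOLD time series, the package estimates a
functional brain network per subject as the matrix of Pearson
correlations between regional series, binarizes each network at a grid
of proportional sparsity thresholds, computes global and nodal
graph-theory measurements on every binary graph (normalizing the
small-world quantities against degree-preserving rewired null networks),
collapses each measurement's threshold curve into a single
area-under-curve (AUC) feature, and classifies subjects with a
multi-kernel support vector machine (MK-SVM) that combines three linear
kernels — connection weights, global metric AUCs, nodal metric AUCs —
under leave-one-out cross-validation (LOOCV) with fold-wise t-test
feature selection and nested hyperparameter tuning. Group-level
descriptive analyses (mean networks, hubs, metric contrasts) and
ROC/DeLong model comparisons complete the picture.

## Network estimation and sparsity thresholding

The connectivity matrix is the plain Pearson correlation
$$W_{ij} = \frac{(x_i-\bar x_i)^\top (x_j-\bar x_j)}
{\lVert x_i-\bar x_i\rVert\,\lVert x_j-\bar x_j\rVert},$$
with the diagonal fixed at 1. No Fisher transform is applied anywhere:
connection features are raw correlation entries, which is what the
classifier trains on.

Binarization is proportional: at sparsity $s$ the
$m = \mathrm{round}(s\,n(n-1)/2)$ edges with the largest *signed*
correlations are kept. Three numerical conventions make this exactly
reproducible:

* rounding is half-away-from-zero (R's `round()` is banker's rounding,
  which is grid-unstable at exact halves);
* ties at the cut break by ascending lexicographic edge index;
* the whole stack comes from one global edge ranking with an increasing
  cut, so graphs are nested by construction — an edge present at a
  sparser threshold can never disappear at a denser one.

Ranking by signed value (not magnitude) follows standard binary-network
practice; strong negative correlations therefore only enter after all
positive ones. An `absolute = TRUE` switch provides magnitude ranking
for sensitivity analyses.

The default grid is 0.02 to 0.50 in steps of 0.01 (49 thresholds). Note
that at the sparse end small graphs can fail to define some
measurements (see *Degenerate inputs* below); the desk-scale analyses
in `analysis/` use 0.14–0.44 in steps of 0.02, a range over which all
measurements stay defined for the cohort sizes simulated there.

## Graph measurements

Eleven global measurements (`Lp`, `Cp`, `lambda`, `gamma`, `sigma`,
`Eglobal`, `Elocal`, `Q`, `Ar`, `Hr`, `Sr`) and five nodal ones (degree,
nodal efficiency, betweenness, shortest path length, nodal clustering)
are computed per binary graph. Standard algorithms (BFS distances,
Brandes betweenness, greedy agglomerative modularity, degree-preserving
double-edge-swap rewiring) are delegated to `igraph`; the remaining
definitions are implemented here:

* **Characteristic path length** averages over *reachable* unordered
  pairs only. Proportional thresholding at low sparsity necessarily
  produces disconnected graphs, and dropping unreachable pairs is the
  convention that keeps the quantity finite; the efficiency-based
  measurements handle disconnection natively through $1/\infty = 0$.
* **Hierarchy** `Hr` is the exponent $\beta$ of the power-law decline of
  nodal clustering with degree, fit by least squares as
  $\log C_i = a - \beta\log k_i$ over nodes with $k_i \ge 2$ and
  $C_i > 0$.
* **Synchronization** `Sr` is the Laplacian eigenratio
  $\lambda_2/\lambda_{\max}$.
* **Assortativity** `Ar` is the Pearson correlation of endpoint degrees
  over the (doubled, both orientations) edge list.
* `gamma` and `lambda` divide `Cp` and `Lp` by their means over
  degree-preserving rewired nulls (default: 100 nulls, 10 swap attempts
  per edge, seeded); `sigma = gamma/lambda`. A graph admitting no valid
  swap (a star, a triangle) yields nulls identical to itself and hence
  `gamma = lambda = 1`, flagged.

Published group tables in this literature sometimes report values for
the modularity-like and synchronization-like columns on scales (e.g.
$Q \approx 16$, $S_r \approx -11$) that are impossible for a modularity
in $[-0.5, 1]$ or an eigenratio in $(0, 1]$. The package does not guess
any such rescaling: it reports the standard definitions above and leaves
the discrepancy documented here.

**AUC aggregation.** The default collapses a 49-value threshold curve by
plain summation (`mode = "sum"`), which is the literal "sum of the
values" definition used when these features feed the classifier; a
step-weighted mode (`mode = "step"`, sum times grid step) is available
because published group-level magnitudes for several global metrics are
only consistent with step weighting. The mode is recorded on the output.

**Degenerate inputs.** `Ar` is undefined on degree-regular graphs and
`Hr` needs at least two eligible nodes; both come back as flagged `NA`.
The aggregation then either refuses (`na_action = "error"`, default) or
sums the defined thresholds (`na_action = "omit"`), which the desk-scale
analyses use together with grids dense enough that omission is rare.
Within the default grid's sparse end, very small graphs also have empty
clustering curves; choosing the analysis grid so the measurements stay
defined is a scientific choice, not a computational one.

## Feature blocks and fold-wise selection

Each subject contributes three blocks in fixed order: $n(n-1)/2$
connection weights (upper triangle, lexicographic $(i,j)$ order), 11
global AUCs, and $5n$ nodal AUCs (metric-major, then region). At the
conventional 90-region parcellation this is 4005 + 11 + 450 features.

Selection is the simplest defensible filter: a per-feature two-sample
two-tailed t-test on training subjects only, keep $p < 0.05$. The
pooled-variance (Student) form is the default, matching the two-sample
two-tailed convention of demographic tables; Welch is behind
`var_equal = FALSE`, and a Benjamini–Hochberg option exists but is off
by default because the uncorrected rule is the one this literature
reports. If nothing in a block survives, the single smallest-p feature
is kept and the fold flagged — a zero-feature block would make the
kernel degenerate, and the fallback uses training data only, so no
leakage is introduced.

**Consensus connections** are the connection features selected in
*every* LOOCV fold (the strict intersection reading of "all selected
connections during the entire validation process"); the union and a
per-edge selection-frequency table are always emitted alongside, since
the looser reading is also defensible. Each edge is annotated with the
sign of the positive-minus-negative group mean difference and its worst
(largest) p across folds; the most significant consensus connection is
the one with the smallest worst-case p.

## The multi-kernel SVM

Per block, features are z-scored with training-fold statistics and
turned into a linear Gram matrix normalized by the mean of its training
diagonal, so blocks are scale-commensurable. The combined kernel is the
convex combination $\sum_m \beta_m K_m$ with $\beta$ on the probability
simplex. The dual problem
$$\max_\alpha\ \sum_i \alpha_i - \tfrac12 \sum_{i,j}
\alpha_i\alpha_j y_i y_j \sum_m \beta_m K_m(x_i, x_j)
\quad\text{s.t.}\quad \sum_i \alpha_i y_i = 0,\ 0\le\alpha_i\le C$$
is solved in-package by sequential minimal optimization with
second-order working-set selection, followed by an active-set refinement
that solves the free-variable KKT system exactly. The two-phase design
is deliberate: SMO alone can enter floating-point limit cycles below a
duality gap of about $10^{-3}$ (which is why the reference SVM
implementations stop there), while the refinement lands residuals near
machine precision; every fitted model's KKT residual is checked against
$10^{-6}$ and stored. Decision values follow
$f(x) = \sum_i y_i\alpha_i \sum_m \beta_m K_m(x_i, x) + b$; a decision
value of exactly zero is assigned to the negative class, a convention
that must exist and is hereby fixed.

Open design points resolved here:

* **Kernel type** — linear per block. Nothing nonlinear is needed for
  the vertex-weight reduction to hold exactly: an MK model with
  $\beta$ at a simplex vertex is identical (to $10^{-8}$) to the plain
  single-kernel SVM on that block, which is precisely how the
  single-modality baselines are computed.
* **$\beta$ selection** — no published rule exists, so $\beta$ is grid
  searched on the simplex (default step 0.1, 66 candidates over three
  blocks) jointly with $C \in \{2^{-5},\dots,2^5\}$ inside the inner
  cross-validation (stratified 5-fold by default), scored by inner-CV
  accuracy. Ties break toward the most uniform $\beta$ (largest
  entropy), then the smallest $C$ — deterministic and preferring the
  least committal model.

## Validation discipline

The outer loop is LOOCV: every subject is held out once, and *all*
training computation — selection, standardization, kernel
normalization, tuning, fitting — uses the remaining subjects only. The
tests enforce this two ways: corrupting a held-out subject's features
must leave its fold's selection mask and tuned hyperparameters
bit-identical, and zero-effect synthetic cohorts must produce mean LOOCV
accuracy statistically indistinguishable from chance for every kernel
configuration (the band used is 0.5 ± 0.12 over ten seeds, wide enough
to absorb the well-known pessimistic bias of LOOCV on small balanced
cohorts, where removing one subject tilts the training class balance
against the held-out class).

Accuracy, sensitivity, and specificity are the usual confusion-matrix
ratios with the positive class being the clinical-like group; exact
fold-count fractions are kept alongside two-decimal percentage
formatting, because on a cohort of 92 only multiples of 1/92 are
attainable and rounding artifacts in published tables should not be
chased. ROC curves are built from continuous decision values; the AUC
is the Mann–Whitney statistic with midrank tie handling, and correlated
AUCs are compared with the DeLong structural-components test (midrank
formulation, two-sided normal p). A paired-bootstrap oracle backs the
DeLong implementation in the tests.

## The synthetic cohort generator

The generator is the package's stand-in for a real two-group
resting-state cohort and defines the study conditions for every
stochastic test. Each group has a population correlation matrix; the
positive group's differs on a planted edge set by a configurable shift.
The shared base structure is a random sparse symmetric matrix (default
density 0.15) with entry magnitudes in $[0.2, 0.5]$ and random signs —
realistic in that resting-state correlation matrices are neither
identity nor dense — repaired to positive definiteness by eigenvalue
flooring (headroom above the $10^{-6}$ floor, because re-normalizing the
diagonal slightly shrinks the smallest eigenvalue) and re-standardized
to unit diagonal. Subjects are drawn as zero-mean multivariate normal
series plus independent Gaussian observation noise (default sd 0.3),
which attenuates all sample correlations uniformly — the simplest noise
mechanism consistent with training on raw correlations. Generation is a
pure function of the specification including its seed.

Defaults mirror a 92-subject, 90-region, 170-timepoint cohort. What the
generator deliberately does **not** emulate: temporal autocorrelation
and band-pass structure (the pipeline consumes correlations only, and
preprocessing is out of scope), hemodynamics, head motion, scanner
drift, site effects, and subject covariates (the classification stage
adjusts for none, so none are planted). Passing tests on these cohorts
therefore demonstrates the *pipeline's* statistical integrity — no
leakage, honest nulls, recoverable planted effects — not that any
particular accuracy level transfers to real imaging data.

**Desk-scale study conditions.** The test suite and the analysis scripts
run reduced problem sizes chosen once: zero-effect integrity uses 24
subjects × 16 regions × 60 timepoints over a 7-point grid; the
planted-effect condition uses a clique of elevated correlations among 8
of 16 regions (effect 0.22) on short noisy series (30 timepoints) over a
16-point grid; consensus recovery uses the 30+30-subject, 170-timepoint,
10-planted-edge condition with effect 0.4. The clique-on-noisy-series
design is what makes the three blocks complementary: per-edge
correlation estimates at 30 timepoints are noisy, while degree,
clustering, and efficiency aggregate the same perturbation over many
edges and thresholds.

## Known limitations

* Topology features are deterministic functions of the connectivity
  matrix, so the connection block is information-complete with respect
  to the other two; the multi-kernel combination can match and slightly
  exceed the best single block through finite-sample aggregation, but
  large dominance of the combined model should not be expected on
  cohorts whose only group difference is planted in the correlations.
  The corresponding test asserts the combination is at least as good on
  average, the qualitative ordering reported for this method family.
* Greedy agglomerative modularity is deterministic but, like all greedy
  optimizers, not guaranteed to find the optimal partition; the tests
  bound it by the brute-force optimum on small graphs.
* The rewired-null normalization inherits Monte-Carlo noise when few
  nulls are used; at the package default (100 nulls) this is negligible,
  at the desk-scale test setting (2–5 nulls) it is absorbed by the test
  tolerances.
* LOOCV variance is high on small cohorts; single-seed accuracy tables
  (as in `analysis/04_classification.R`) are illustrations, and any
  claim should rest on multi-seed averages as in the acceptance tests.
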