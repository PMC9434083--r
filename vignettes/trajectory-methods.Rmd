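---
title: "Models and methods behind crestflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crestflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crestflow)
```

crestflow analyses branching differentiation trajectories in single-cell
transcriptomic data, with the neural-crest-to-Schwann-cell-precursor system
as its motivating biology: a multipotent "hub" state shared by late neural
crest cells and early Schwann cell precursors, from which cells commit to
glial or sympathoadrenal fates. This vignette explains each model the
package implements, the parameters that matter, the design choices made
where the method was genuinely open, and what the synthetic validation
data does and does not demonstrate.

## The principal tree and pseudotime

`fit_principal_tree()` fits a SimplePPT-style principal tree to a
low-dimensional embedding $X \in \mathbb{R}^{n \times d}$ by alternating
three steps over node positions $C \in \mathbb{R}^{k \times d}$:

1. **Soft assignment.** $R_{ij} \propto \exp(-\lVert x_i - c_j\rVert^2 /
   \sigma)$, row-normalised, so every cell distributes one unit of
   responsibility over the tree nodes.
2. **Tree structure.** Edges are the minimum spanning tree of the current
   node-to-node squared distances.
3. **Node update.** $C$ solves the linear system minimising
   $\sum_{ij} R_{ij}\lVert x_i - c_j\rVert^2 + \lambda \sum_{(j,k) \in E}
   \lVert c_j - c_k\rVert^2$, i.e.
   $(\mathrm{diag}(R^\top \mathbf{1}) + \lambda L)\,C = R^\top X$ with $L$
   the tree Laplacian.

Iteration stops when the maximal node displacement falls below `tol`. The
exact Lyapunov function of this iteration is the free energy
$\sum_{ij} R_{ij} d_{ij}^2 + \sigma \sum_{ij} R_{ij}\log R_{ij} + \lambda
\cdot \text{elastic}$ — the soft R-step minimises this, not the bare data
term, so the package tracks both: the free energy is non-increasing to
machine precision on every run, while the data+elastic objective tracks it
to within a fraction of a percent. Both traces are stored on the fitted
object and asserted in the test suite.

**Parameters.** `sigma` (squared-embedding-distance units) controls how
sharply cells commit to nodes; the default is $0.05\times$ the median
pairwise squared distance of the embedding. In a scan over the shipped
presets, a factor of $0.1$ blurred the fork region enough to drop
three-segment recovery toward 0.90; $0.05$ was the stable optimum and is
the documented default. `lambda` (default 1) is the elastic stiffness;
large-atlas workflows on diffusion coordinates are known to use extreme
settings such as $\sigma = 5\times10^{-4}$, $\lambda = 200$ with thousands
of nodes — those remain available as explicit arguments but are not
meaningful for desk-scale embeddings. Node initialisation is
k-means++-style seeding followed by a few Lloyd iterations, under the
caller's seed; the method's originators do not state an initialisation, so
a seeded standard one was chosen.

**Pseudotime.** With a root chosen (`select_root()` picks the tip whose
cells maximise a user-supplied score — root choice is a biological
judgment, e.g. developmental stage, and is deliberately explicit input),
node pseudotime is geodesic distance from the root along edges, and cell
pseudotime is either the $R$-weighted mean of node pseudotimes (`soft`,
default) or the maximum-responsibility node's value (`hard`). Whether
upstream work projects by weighted mean or nearest node is not
documented; both are provided and the choice is recorded in the result.
Ties everywhere break toward the lower node id. Soft projection shrinks
pseudotime slightly near the tips (a weighted mean can never reach the
extreme node values); rank-based recovery is unaffected.

`probabilistic_mappings()` samples hard assignments from the rows of $R$,
propagating assignment uncertainty into any downstream statistic;
`correlations_over_mappings()` uses it to put error bars on windowed
correlations.

**Milestones** are tips (degree 1) and forks (degree ≥ 3). A cell is
assigned to the nearer, in pseudotime, of the milestones bounding its
position on its own root-to-tip path; exact ties go to the earlier
milestone.

## Association testing and trend fitting

`test_association()` models each feature as an unpenalised natural cubic
spline of pseudotime fitted independently per tree segment (per-segment
intercept + `splines::ns` basis, `spline_df = 5` by default) and compares
it against the global-intercept null with an F-test on residual sums of
squares, degrees of freedom $(p - 1,\; n - p)$ where $p$ is the full
parameter count. P-values are Benjamini–Hochberg corrected; BH was chosen
as the field default because the multiple-testing method is otherwise
unspecified in the tradition this follows. A feature is significant when
$q$ falls below `fdr_threshold` (default $10^{-4}$) *and* its fitted
amplitude $A = \max \hat f - \min \hat f$ exceeds `a_cut` — $A$ needed a
definition, and max-minus-min of the fitted trend across segments is the
implemented one. The conventional cutoffs are $0.025$ on regulon-activity
scales and $0.02$ when pre-filtering regulons for clustering; for
log-expression data a larger value is appropriate. Penalised-GAM smoothing
parameter selection (REML/GCV) is deliberately out of scope: unpenalised
splines with fixed df give exact F-tests and reproducible amplitudes.

`fit_trends()` evaluates the same per-segment fits on an equal-spaced
pseudotime grid (no extrapolation: the grid spans the observed range).
Constant features yield constant trends; linear features are reproduced to
numerical precision (splines contain linear functions).

## Bifurcation analysis

`test_fork()` fits, per gene, the model
$g \sim s(t) + s(t)\!:\!\mathrm{Branch} + \mathrm{Branch}$ — a shared
smooth plus branch-specific smooth deviations and branch intercepts — and
extracts the interaction p-value by an F-test of the full model against
$g \sim s(t) + \mathrm{Branch}$. The fit uses the post-fork cells only:
how pre-fork cells should enter a branch-interaction model is not
specified anywhere, and restricting to post-fork cells makes the test
exactly symmetric under swapping branch labels (asserted in the tests)
with clean degrees of freedom. BH correction with `fdr_cut = 0.1` flags
candidates. The interaction smooth is implemented as spline-coefficient
deviations (full basis × centred branch contrast); the originating
description names the model but not the basis.

`assign_branch_specific()` then tests each candidate for upregulation
along each progenitor-to-terminal path with the linear model
$g \sim t$, requiring a positive slope at BH fdr < 0.05 and a post-fork
mean-expression margin of at least `effect_cutoff` (default 0.2 on the
log scale; always overridable, since real analyses set this per
bifurcation and publish no values). Genes qualifying on both branches are
left unassigned and logged.

`activation_timing()` splits each progenitor-to-branch trend into
`n_bins = 10` equal-width pseudotime bins, computes the relative
expression rate at interior bins

$$r_b = \frac{f(b+1) - f(b-1)}{\max f - \min f},$$

with $f(b)$ the mean fitted expression in bin $b$, and calls activation at
the first bin whose rate exceeds `rate_threshold` (default 0.1 per bin
step; the threshold is "a defined threshold" by tradition and is echoed
into every report). Genes activating at or before the fork pseudotime are
*early*, after it *late*; flat trends are flagged degenerate rather than
dividing zero by zero. $r_b \in [-1, 1]$ always, since the numerator is
bounded by the range. Note that rate onset is an earlier functional of a
trend than its logistic midpoint: recovery tests therefore compare
estimated activation bins against the same rate rule applied to the
noiseless true curve, not against the planted midpoint parameter.

## Windowed module correlations

`make_windows()` orders cells by pseudotime and cuts either sliding
windows (`window_size` cells advancing by `step`; count
$\lfloor (n - \text{size})/\text{step} \rfloor + 1$) or non-intersecting
blocks (a final short block is kept when at least half-size). Published
analyses never state their window parameters; the package defaults to
`window_size = max(30, n/20)` with a step of a third of the window, and
echoes both into outputs. Windows below 10 cells warn: correlations on
fewer cells are unstable.

`window_module_correlations()` computes, per window, the Pearson
correlation matrix over the genes of two disjoint modules. Intra-module
correlation is the mean over distinct unordered pairs within a module;
inter-module the mean over all cross pairs; a per-gene series records each
gene's mean correlation with the opposing module. Genes constant within a
window are excluded from that window's pairs — not zero-imputed, which
would deflate the means — and a window where everything is constant is
`NA`, not zero.

The fate-choice signature this machinery exists to expose has three
phases: competing early modules first rise together (positive inter-module
correlation while both programs co-activate in the same cells), then
become mutually exclusive after the fork (strongly negative inter-module
correlation as each branch silences the opposing program), while
intra-module coherence stays high throughout. Windows before either
module activates carry no correlation signal in either direction, so the
signature test is a single binomial sign test over all windows — pre-fork
windows counting a success when inter > 0, post-fork when inter < 0 —
rather than a demand that every pre-fork window be individually positive.

## Regulon dynamics and metaregulons

Regulon activity matrices (AUC-style target-recovery scores in $[0,1]$,
from an upstream regulon-inference pipeline; inference itself is out of
scope) are first weighted by the expression of each regulon's
transcription factor: the weight is the TF's log10 expression clamped to
$[0,1]$ — equal to the log10 value between 0 and 1, set to 1 above 1 —
and the weighted score is weight × score. Whether the original weighting
multiplied or thresholded is ambiguous from its description;
multiplication is the implemented reading, stated here prominently.
Weighting never increases a score and is idempotent at weight 1.

`cluster_metaregulons()` z-scores each regulon's fitted trend ("scaled
fitted activity" needed a definition; per-regulon z-scoring is it), builds
a k-nearest-neighbour graph under cosine distance (`n_neighbors = 40`,
reduced with a warning when it reaches the regulon count) and partitions
it with seeded modularity-based Leiden-style community detection. Two
desk-scale adaptations matter here. First, edges carry the
clipped-positive cosine similarity as weights: with 30 regulons the
40-neighbour default saturates the graph, and an unweighted complete graph
is unclusterable. Second, the resolution defaults to 2 rather than the
conventional 1.0: on a similarity-weighted cosine graph over tens of
regulons, unit resolution demonstrably merges trend groups with
between-cluster cosine as high as 0.37. A **metaregulon's trend is exactly
the unweighted arithmetic mean of its member regulons' trends** — this
identity is asserted, not approximated — and cluster labels are reordered
by mean trend centre-of-mass so reports are stable across runs.

`bin_summaries()` produces the standard trend heatmap inputs: equal-width
pseudotime bins globally (20-bin summaries) or per tree segment
(five-bins-per-segment summaries; 3 segments × 5 bins = 15 values per
feature). Empty bins are `NA`.

## Cell-type scoring and the hub rule

`score_cell_types()` scores each cell for each type as the mean of
per-gene min–max-scaled (z-scoring available as an option) imputed
expression over the type's markers; "gene scoring" has no published
formula, so this simple transparent definition is the implemented one,
applied to kNN-smoothed expression (`knn_smooth()` is a linear diffusion
operator, $(\text{row-normalised } A + I)^{\text{steps}}$, standing in for
heavier graph-imputation methods with an exactly characterised
behaviour: identity at 0 steps, fixes constants, provably linear). A cell
is labelled with the unique type whose score passes its threshold; cells
passing two or more are discarded from annotation as ambiguous. One
consequence worth knowing: raising a threshold does not monotonically
increase total unassigned cells, because a two-type cell can become singly
assigned — only the no-type count is monotone.

The **hub rule**: cells belonging to a community whose unassigned fraction
is at least 80% are hub cells. The inclusive ≥ convention was chosen over
a strict >, is configurable, and matters only exactly at the boundary.
Communities come from seeded modularity-based detection on the cell kNN
graph. The rule's granularity requirement is worth spelling out: a
community that straddles the hub boundary dilutes its unassigned fraction
below the cutoff and silently drops its hub members, so hub calling needs
communities of tens of cells, not hundreds. The pipeline therefore
clusters for the hub stage with `k = 10, resolution = 8` (about 40
communities on ~800 cells) while generic `cluster_cells()` keeps the
conventional resolution 1; the pairing `marker_threshold = 0.45` with
that granularity was fixed once on the synthetic preset (sensitivity
0.90–0.98, false inclusion ≤ 0.08 across ten generator seeds) and not
revisited.

`hub_markers()` is a per-gene two-sided Wilcoxon rank-sum test of hub
versus rest with BH correction, ranked hub-elevated first; all-tied genes
get p = 1.

## Label transfer

`correlation_knn()` correlates each query profile against every reference
cell over their shared features (an optional exclusion list — e.g. genes
correlated with cell cycle, supplied by the caller — is honoured; at least
50 shared features are required) and keeps the top `k = 5`. Weights are
correlations shifted by the minimum neighbour correlation plus a small
epsilon and normalised to sum 1: the joint-graph connectivities this
stands in for are not reproducible from their description, so a
transparent scheme is used and stated in output metadata.
`project_and_propagate()` then takes weighted averages of neighbour
coordinates and values (projections live in the neighbours' convex hull by
construction) and transfers the label with maximal summed weight,
flagging lexicographically broken ties.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
validation conditions; they were chosen once and the reasoning is
recorded here.

**Trajectory.** The default topology is a Y: a trunk of pseudotime length
1 (multipotent progenitors) forking into two unit-length branches (glial
and sympathoadrenal), allocation (0.5, 0.25, 0.25), cells uniform along
arc-length, embedding = backbone + isotropic Gaussian noise (sd 0.05
default — at that noise the arms are visually distinct but overlap near
the fork, which is the regime that actually stresses branch assignment).

**Expression.** Counts are negative binomial (size 10, roughly the
overdispersion of deep plate-based protocols) around
$\mu_g(\text{cell}) = \text{baseline} + \text{amplitude} \cdot
\text{logistic}((t - t_{\text{act}})/\text{steepness})$ on the relevant
segments, times a lognormal library factor (meanlog 0, sdlog 0.2). Early
modules activate at $t_{\text{act}} = \text{fork} - 0.5$ with steepness
0.15 — slow enough that co-activation spans the progenitor segment, which
is the structure the fate-choice analyses assume — and decay back toward
baseline past the fork on the opposing branch (reverse logistic),
emulating mutual repression. Late modules are steep switches
($t_{\text{act}} = \text{fork} + 0.4$, steepness 0.05) on their own branch
only. Hub markers carry a logistic-up/logistic-down bump around the fork;
type markers either decay from the trunk (progenitor type) or activate on
a terminal branch. Baselines (300 for dynamic modules, 1000–2000 for
noise/neutral genes) put per-cell totals near $1.5\times10^5$, inside the
(5×10^4, 6×10^6) transcript QC bounds with comfortable margin. Twenty
ERCC spike-in rows are drawn so clean cells carry 1–10% spike fractions.
Injected low-quality cells violate the filter by construction: half have
tiny spike-dominated libraries with most genes undetected, half have 35%
ERCC fractions.

The published QC text prints a self-contradictory transcript interval
("5 × 10^4 ≤ transcripts ≥ 6 × 10^4"); the package reads it as a
configurable [min, max] pair with defaults (5×10^4, 6×10^6). The
1,000-gene lower bound presumes genome-scale panels, so the preset scales
it to 100 for its 190-gene panel. No attempt is made to reproduce any
particular retained-cell count on real data.

**Hub ground truth** follows its own definition rather than an arbitrary
band: a cell is a hub cell when every type-marker module's true mean is
within 5% of amplitude of baseline — which, by construction of the marker
kinetics, is a pseudotime band around the fork (≈ [0.65, 1.15] under the
defaults).

**Regulon activity** follows five distinct smooth templates of pseudotime
(early decline, late rise, mid and early Gaussian bumps, and a two-peak
trend — multipotency programs reactivated before commitment show exactly
such twin activity peaks), assigned round-robin, plus Gaussian noise
clipped to [0,1]; TF log10 expression is proportional to the template so
weighting has signal. An earlier draft used a linear ramp as the fifth
template; its cosine similarity of 0.87 with the late-rise template made
the two clusters indistinguishable in principle, violating the premise
that planted clusters are distinct, so it was replaced.

**What passing these tests shows — and does not.** The generator emulates
branch-dependent logistic means with NB noise, spike-ins, and smooth
regulon trends. It does **not** simulate doublets beyond QC violators,
batch or plate effects, transcriptional bursting, cell-cycle structure,
correlated gene-gene noise within a state, spliced/unspliced counts, or
ambient RNA. Recovery at the stated tolerances therefore demonstrates
correctness of the algorithms under their own assumptions, not robustness
to everything real data does.

## Problem sizes and numerical choices

The validation suite runs at 600–800 cells, 30 tree nodes, ~200 genes and
30 regulons — sizes at which every linear system is solved exactly and
the whole suite completes in well under a minute per analysis; these are
the package's chosen reference conditions for its correctness claims.
Degenerate inputs are handled explicitly rather than by accident:
constant features get p = 1 and a degenerate flag; flat trends are
not-activated, never 0/0; all-zero kernel rows fall back to
nearest-node assignment with a warning; zero-total cells are dropped from
normalisation with a warning; disconnected cells smooth with their
self-loop only; empty hub calls are valid results. All randomness flows
from explicit seed arguments, and `run_pipeline()` derives per-stage seeds
from one master seed, writing md5 checksums of every output into its
manifest so that bit-identical reruns are checkable.

## Known limitations

- Path-graph and Y topologies are first-class; deeper cascades of forks
  work through recursive pairwise fork analysis, but three-way forks are
  not modelled directly.
- The fork interaction test conditions on the fitted tree: uncertainty in
  the fork's position is not propagated into the gene-level p-values
  (probabilistic mappings propagate it into windowed correlations only).
- Soft pseudotime compresses near tips; analyses that need absolute
  pseudotime scales should use rank-based summaries, as the tests do.
- `metric` is euclidean only; cosine tree-fitting was not needed for any
  supported workflow.
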