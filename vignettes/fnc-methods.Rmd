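---
title: "Graph-theoretic functional network connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic functional network connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fncgraph)
```

## The problem

Resting-state fMRI scans can be decomposed by independent component
analysis (ICA) into spatial networks, each with a temporal amplitude
series — the component timecourses.  Functional network connectivity
(FNC) asks how those networks interact over time within a subject, and
whether the pattern of interaction differs between diagnostic groups
(here the motivating contrast is schizophrenia patients versus healthy
controls).  `fncgraph` implements the full analysis path from component
timecourses to group-level results; the scan preprocessing and ICA
unmixing themselves are out of scope — the pipeline consumes
already-unmixed timecourse matrices (one row per timepoint, one column
per component), written in the whitespace-delimited "melodic_mix"
dialect that ICA tools emit.

## From timecourses to a pseudo-distance matrix

For two component timecourses $x$ and $y$ of length $T$, the lagged
cross-correlation at lag $l \ge 0$ is

$$
\mathrm{CCF}(l) \;=\; \frac{1}{T}\sum_{t=1}^{T-l}
  \frac{(x_{t+l}-\bar x)(y_t - \bar y)}{s_x\, s_y},
$$

with full-series means and divisor-$T$ standard deviations; negative
lags swap the roles of $x$ and $y$.  The pairwise *pseudo-distance* is

$$
d(x, y) \;=\; 1 - \max_{|l| \le L} \left|\mathrm{CCF}(l)\right|,
$$

so that 0 means perfectly coupled (anti-correlation counts as coupling,
hence the absolute value) and 1 means uncoupled.  The default lag bound
is $L = 3$ timepoints (6 s at a repetition time of 2 s): larger lags
leave fewer terms in the sum and are neurophysiologically implausible
for network coupling.  Two numerical choices deserve a note:

* **Both lag signs are evaluated.**  The analysis window is described as
  lags 0–3, but the standard `ccf` convention evaluates $-L..L$; we take
  the maximum of $|\mathrm{CCF}|$ over the full symmetric window, which
  supersets the one-sided window and matches how the reference tooling
  actually behaves.
* **Divisor $T$ at every lag.**  The normalization uses full-series
  moments rather than lag-dependent ones, following the expectation form
  of the definition.  Finite-sample values can then marginally exceed 1
  in magnitude, so $d$ is clamped into $[0,1]$.

Columns with zero variance are a hard error (listed by index): a
degenerate ICA timecourse indicates an upstream problem, and silently
imputing it would distort every downstream graph.

`distance_matrix()` computes all pairs via standardized cross-products
(BLAS), which is arithmetically identical to the pairwise formula; the
test suite verifies agreement with an independent nested-loop
implementation to $10^{-12}$.

## Graph creation: pruning, geodesics, embedding, weights

Each subject's $M \times M$ distance matrix describes a fully connected
configuration.  The graph-creation stage (`prune_graph()`) proceeds:

1. **k-NN retention** (`knn_retention()`): vertex pairs stay connected
   iff either vertex lists the other among its $k$ nearest neighbours
   (union symmetrization), with $k = \max(\lfloor M/10 \rfloor, 2)$ —
   10% of the subject's component count or 2, whichever is greater
   (`choose_k()`).  Ties at the $k$-th distance break deterministically
   toward the lower column index.  The union rule (rather than mutual
   k-NN) is the denser and more common convention and matches the
   behaviour of the reference isomap implementation in `vegan`, against
   which the test suite checks this stage exactly.
2. **Geodesic re-distancing** (`geodesic_distances()`): retained edges
   keep their pseudo-distance as length; distances between pruned pairs
   are recomputed as shortest paths through intermediaries.  Unreachable
   pairs are `Inf` — fragmentation is representable, not fatal.
3. **Classical MDS** (`classical_mds()`): the geodesic matrix is
   double-centered ($-\tfrac12 J G^{(2)} J$) and eigendecomposed; the
   embedding keeps $q = \min(15, M-1, \#\{\lambda_i > 0\})$ coordinate
   axes, scaled by $\sqrt{\lambda_i}$.  All retained axes are used for
   distance computation.  Fifteen is generous for graphs of 15–40
   vertices; it avoids discarding geometry while capping the embedding
   rank for large subjects.
4. **Inverse-distance weights** (`build_weighted_graph()`): each
   retained edge gets weight $1/\max(\varepsilon, \delta_{ij})$ where
   $\delta_{ij}$ is the *embedded* Euclidean distance and
   $\varepsilon = 10^{-8}$ floors the reciprocal against coincident
   points.  Weights are deliberately computed from the embedded
   coordinates rather than the geodesic matrix — a surprising but
   faithful choice, mirroring how the makegraph conversion in the
   original analysis derives weights from the isomap point
   configuration.

**Fragmentation policy.**  Union k-NN with $k \ge 2$ usually keeps the
graph connected, but this is not a theorem, and clustered connectivity
structure can fragment the pruned graph.  The default policy embeds the
largest connected component, leaves the remaining vertices as weight-0
rows, and records a per-subject fragmentation flag (surfaced in
`fnc_study()` results), so a disconnection-rate hypothesis can itself be
tested.  Strict mode (`fragmented_ok = FALSE`) errors instead.

## The 13-feature fingerprint

`feature_vector()` summarizes each pruned graph by 13 features, in this
column order: Average Path Length, Clique Number, Graph Density, Edge
Connectivity, Median Closeness, Median Graph Coreness, Max Degree,
Median Degree, Min Degree, Vertex Count, Edge Count, Transitivity,
Small Worldness.  Definitional choices:

* Transitivity is the global clustering coefficient
  $3\,\#\text{triangles} / \#\text{connected triples}$ on the binarized
  adjacency; it is `NA` when no connected triple exists, and `NA`s
  propagate (tests omit them per feature) rather than fail.
* Average path length averages over *connected* pairs only, so
  fragmented graphs average within components; edge connectivity of a
  fragmented graph is 0.
* Closeness is the reciprocal of the summed distances from a vertex to
  the other members of its component (the usual convention; the
  "number of steps" gloss sometimes seen inverts it), `NA` for isolated
  vertices; the feature takes the median over vertices.
* With `weighted = TRUE` (default) the two path-based features — average
  path length and median closeness — use edge lengths $1/w$; all
  triangle, degree, clique, core and count features, and the
  small-world coefficient, are computed on the binarized adjacency.
  The weighted default reflects that the group difference of interest
  was reported on weighted graphs; the flag exposes both modes.

### Small-worldness

$$\sigma = \frac{\gamma}{\lambda}, \qquad
\gamma = \frac{C}{\bar C_{\text{rand}}}, \qquad
\lambda = \frac{L}{\bar L_{\text{rand}}},$$

where $C$ and $L$ are the graph's transitivity and average path length
and the reference means are taken over an ensemble of Erdős–Rényi
$G(n,m)$ graphs with the same vertex and edge counts
(`erdos_renyi_reference()`).  The ensemble default is 5000 replicates
(conventional range 500–5000), configurable downward for simulation
studies; replicates with undefined transitivity are skipped and
counted.  $\sigma \gg 1$ indicates small-world organization.  The
$\sigma = \gamma/\lambda$ identity and the self-calibration property
(graphs drawn from $G(n,m)$ score $\sigma \approx 1$ against their own
ensemble) are both under test.

## Group inference

* **Welch t-tests** (`welch_t_tests()`): per-feature two-sided
  unequal-variance tests, missing values omitted per feature, judged
  against the Bonferroni threshold $\alpha/13 = 0.05/13 \approx 0.0038$.
  Features with fewer than two valid values in a group are flagged
  untestable rather than erroring.
* **Classification** (`svm_cross_validate()`): radial-kernel SVM with
  default hyperparameters (cost 1, $\gamma = 1/\#\text{features}$) and
  no tuning, 10-fold cross-validation with unstratified seeded fold
  assignment.  Overall accuracy is subject-weighted (total correct over
  total subjects), matching the total-accuracy convention.  One
  deliberate deviation from the reference procedure: standardization
  and median imputation are fit on training folds only, inside the
  loop, to avoid information leakage; the reference scales globally.
  The imputation count is recorded in the result.
* Subjects labelled `"Disenrolled"` receive features but are excluded
  from both inference stages; subject–label joins are by explicit ID
  throughout, never by file position, which removes the classic
  sort-order alignment hazard of positional joins.
* Demographic covariates are deliberately unused.

## The synthetic cohort generator

No public generative model exists for per-subject ICA timecourses, so
`simulate_cohort()` uses the minimal model that exhibits the three
properties the pipeline is sensitive to: temporal autocorrelation,
*lagged* inter-component coupling, and a tunable group contrast in
coupling strength.  Per subject: $M \sim U\{15, \dots, 40\}$ components
(per-subject model-order variability is a deliberate feature — the
pipeline must cope with variable column counts), each assigned to one
of `n_clusters` (default 4) latent clusters; one stationary AR(1) base
signal per cluster (coefficient 0.3, unit marginal variance); component
$j$ is $\alpha\, b_{c(j)}(t-\ell_j) + \sqrt{1-\alpha^2}\, e_j(t)$ with
$\ell_j \sim U\{0..3\}$ (matching the analysis lag window) and
independent AR(1) noise $e_j$; columns are standardized.  Default
$T = 150$ timepoints corresponds to a ~5-minute scan at TR = 2 s — a
convention, since the source protocol states TR only in its
preprocessing script.  The group contrast defaults are
$\alpha_{\text{control}} = 0.8$, $\alpha_{\text{patient}} = 0.4$:
weaker coupling in patients operationalizes the hypothesis that their
networks are less synchronized, and produces the qualitative signature
the pipeline should recover — lower patient transitivity and lower
small-worldness.

Reproducibility: one master seed; each subject draws from a private
substream indexed by its position counter, so cohorts are bit-identical
across runs and stable under reordering.

What the generator does *not* emulate: hemodynamics, spatial maps,
scanner/motion artifacts, non-stationarity, and realistic ICA noise
structure.  Passing tests on synthetic cohorts therefore demonstrate
that the pipeline recovers planted coupling structure of this
statistical form — not that any particular clinical effect would be
recovered from real scans.

## Simulation study sizes and calibration checks

The test suite runs three statistical studies, sized to give stable
Monte-Carlo estimates:

* *Small-world self-calibration*: 50 graphs from $G(30, 90)$, each
  scored against a 2000-replicate ensemble; mean $\sigma$ must lie in
  $[0.8, 1.2]$.
* *Null calibration*: 500 cohorts with equal coupling (0.6) in both
  groups, 15 subjects per group, $M \in [12, 18]$, 20-replicate
  small-world ensembles.  The pooled rejection rate of the per-feature
  Welch tests at $\alpha = 0.05$ must sit within two standard errors of
  5%, with the cohort as the replicate unit
  ($\mathrm{SE} = \sqrt{0.05 \cdot 0.95 / 500} \approx 0.01$), and the
  familywise rate at $0.05/13$ must not exceed 0.05 plus simulation
  error.  The pooled rate is the right calibration summary here:
  individual heavily discrete features (clique number on 15-vertex
  graphs takes 2–3 values) make the t approximation per-feature erratic
  in both directions at realistic cohort sizes — and only
  approximately, not exactly, calibrated even in aggregate — while
  their average over the feature set is what the Bonferroni correction
  controls.  Fifteen subjects per group is the smallest size at which a
  pilot showed the t approximation stable across the feature set.
* *Effect recovery*: 100 replicate cohorts at the generator defaults
  (coupling 0.8 vs 0.4, 40 per group); the control-minus-patient
  transitivity contrast must pass the Bonferroni bar in at least 80% of
  replicates, and mean 10-fold SVM accuracy over 20 fold seeds must
  beat chance by 5+ points.

Reduced ensemble sizes (20–500 instead of 5000) are used inside the
simulation studies; the small-world ensemble mean is itself an average,
so reducing replicates adds noise to $\sigma$ without biasing the null
calibration.

## Known limitations

* The union k-NN rule does not guarantee connectivity; fragmentation is
  monitored per subject rather than assumed away.
* $\sigma$ compares against $G(n,m)$, not degree-preserving rewiring; a
  lattice-referenced small-world index is out of scope.
* Welch tests on strongly discrete features at small $n$ are only
  approximately calibrated (see above); with 13 correlated features the
  Bonferroni correction is conservative.
* The SVM stage intentionally performs no hyperparameter tuning or
  feature selection, so its accuracy is a floor, not a ceiling.
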