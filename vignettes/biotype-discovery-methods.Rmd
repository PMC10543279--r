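---
title: "Methods: graph-convolutional biotype discovery from functional network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-convolutional biotype discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fncbiotype)
```

## The problem

Neuropsychiatric diagnoses such as ADHD lump together patients whose
underlying brain physiology may differ in ways that matter for treatment.
This package searches for *biotypes*: patient subgroups defined by
functional network connectivity (FNC) rather than symptoms, discovered in
one cohort, validated by projection onto an independent cohort, and
characterised against cognitive, clinical and longitudinal treatment-response
data.

## FNC features

A subject is summarised by the Pearson correlations between the time courses
of `C` independent component networks. With the default 53-component atlas
(7 functional domains: subcortical 5, auditory 2, sensorimotor 9, visual 9,
cognitive control 17, default mode 7, cerebellar 4) this gives a symmetric
53×53 matrix whose strict upper triangle — read row by row, the canonical
edge order shared by every module — is a 1378-vector per subject
(`compute_fnc_matrix()`, `vectorize_upper_triangle()`).

Two preprocessing choices are deliberately conservative:

* **No Fisher z-transform by default.** Raw correlations are the feature;
  `fisher_z()` is available for users who want variance-stabilised edges,
  but nothing in the pipeline assumes it. Whether such a transform improves
  biotype discovery is an open empirical question.
* **Standardization.** Each of the 1378 edges is z-scored over the
  *discovery* subjects before graph construction and training
  (`fit_scaler()`); the same scaler is reused for any validation cohort so
  that both live in one space. Correlation edges have heterogeneous
  variances, and the deep model's losses would otherwise be dominated by a
  few high-variance edges. Template projection, in contrast, operates on the
  raw correlation scale, where "mean FNC of a biotype" has its natural
  meaning.

Site and scanner effects are removed by ordinary least squares residualization
(`regress_covariates()`), per cohort, before any statistical comparison.
Covariates nested inside one another (scanners within sites) are aliased in
the design; the pipeline drops aliased columns explicitly rather than
silently reparameterising.

## The population graph

Subjects are nodes; node features are the standardized FNC vectors; edges
encode phenotypic similarity:

\[ w_{ij} = \mathbf{1}[g_i = g_j] + \mathbf{1}[|a_i - a_j| \le \tau] \]

with gender \(g\), age \(a\) in months and tolerance \(\tau = 24\) months
(ages in the emulated design span roughly 9–15 years). Weights therefore
take values {0, 1, 2}. Convolution uses the symmetric renormalized operator
\(S = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}\); self-loops exist only inside
the operator, never in the stored graph, and an isolated node reduces to an
identity row.

**Why the feature-similarity kernel is on in the discovery pipeline.** In a
demographically homogeneous cohort nearly every pair of subjects falls
within the age tolerance, so the purely phenotypic graph is close to
complete. The renormalized operator then averages each subject with about
half the cohort, and each node's own contribution enters with weight
\(\approx 1/\bar d\) (mean degree \(\bar d\) in the hundreds): graph
convolution behaves as a low-pass filter that replaces individual patterns
with neighbourhood noise, and the patient subgroups become unrecoverable
from the embeddings even when plain K-means on the raw features separates
them perfectly. We verified exactly this failure on planted synthetic
cohorts. The standard remedy in population-graph disease models is to
weight each phenotypic edge by the similarity of the imaging features
themselves; `build_graph(feature_kernel = TRUE)` multiplies \(w_{ij}\) by
the nonnegative part of the Pearson correlation between the two subjects'
standardized FNC vectors. Same-subgroup edges then dominate, the graph
sparsifies (roughly half the edges vanish), and recovery is restored. The
bare `build_graph()` default remains the pure phenotypic graph — the
documented {0, 1, 2} contract — while `pipeline_discover()` and the
benchmark turn the kernel on.

## The model

The biotyper is a graph-convolutional autoencoder with two auxiliary heads:

* encoder 1378 → 256 → 64 (rectifier on the hidden layer, linear embedding
  layer), decoder mirrored, every layer computing \( \mathrm{act}(S\,H\,W) \);
* a single fully connected logistic head on the embeddings predicting
  patient vs. control for *all* subjects (mean binary cross-entropy,
  probabilities clipped at \(10^{-7}\));
* a deep-K-means head on the *patient subgraph only* ("connection
  unchanged": the induced patient-patient edges keep their weights): the
  loss is the mean squared Euclidean distance of patient embeddings to
  their assigned centroids.

The joint objective is

\[ L = \gamma_1 L_{rec} + \gamma_2 L_{CE} + \gamma_3 L_{cluster}, \qquad
   \gamma_1 = 0.1,\; \gamma_2 = 0.5,\; \gamma_3 = 1, \]

optimized with Adam at learning rate 0.001. The reconstruction target is the
node feature matrix (not the adjacency); adjacency reconstruction would
optimise for phenotypic structure we already control by construction.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `hidden`, `embedding` | 256, 64 | encoder widths; embedding dimension must be ≥ K |
| `gamma1/2/3` | 0.1 / 0.5 / 1 | loss trade-off (reconstruction / diagnosis / clustering) |
| `learning_rate` | 0.001 | Adam step size |
| `epochs` | 300 | total training epochs |
| `warmup_epochs` | 50 | epochs with \(\gamma_3\) off before centroids are seeded |
| `centroid_update_period` | 5 | epochs between hard reassignment/centroid refreshes |
| `age_tol` | 24 months | phenotypic age-proximity tolerance |
| `K` | 2 (or elbow) | biotype count |

**Deep-K-means variant.** The clustering term uses hard assignments with
alternating minimization: between refreshes the centroids are constants and
the loss is differentiable in the embeddings; every
`centroid_update_period` epochs assignments are recomputed
(nearest centroid, ties to the lowest index) and centroids re-estimated as
cluster means. With the embeddings frozen this update cannot increase the
loss, and the trainer asserts that invariant at every refresh. An empty
cluster is re-seeded at the point farthest from its nearest centroid — the
one logged exception to monotonicity. A soft-min variant
(`cluster_assignment = "soft"`, temperature \(T\)) is available but not the
default.

**Warm-up and seeding.** Centroids seeded on untrained embeddings are
meaningless, so the first `warmup_epochs` epochs train the autoencoder and
classifier only; centroids are then placed by greedy farthest-point seeding
(first seed: the point farthest from the embedding mean; ties to the lowest
index) and the clustering term activates. Training is deterministic given
the seed and configuration, up to floating-point reduction order in the
BLAS; identical seeds reproduce the assignment vector exactly.

When \(\gamma_3 = 0\) the model degenerates to an autoencoder(+classifier)
and final assignments are computed post hoc by K-means on the learned
patient embeddings — the definitional reference point for the clustering
term's effect.

## Choosing K and benchmarking

`sse_elbow_curve()` runs seeded multi-restart K-means (10 restarts: one
deterministic farthest-point start plus 9 random starts, Lloyd iterations,
best within-cluster SSE kept) over a K range; `choose_k_elbow()` picks the
K whose (K, SSE) point lies farthest from the chord joining the curve's
endpoints, on raw coordinates — this reproduces the intended choice on
curves whose initial drop dominates, which is the regime where the elbow
heuristic is meaningful at all. Ties go to the smaller K; an exactly linear
curve yields the smallest K with a warning.

Baselines (`run_baseline()`): Ward-linkage agglomerative clustering
(`ward.D2`; linkage unspecified in the comparison literature, Ward is the
default that matches the variance-based indices), multi-restart K-means, a
fully connected deep-K-means autoencoder (identical widths, operator =
identity, no diagnosis head), and a reconstruction-only graph autoencoder
followed by K-means.

**Validity-index space.** `benchmark_methods()` scores every method's
*partition* with Davies-Bouldin and Calinski-Harabasz indices computed in
the shared standardized feature space. The alternative — scoring each deep
method in its own embedding space — measures how hard an objective
compresses its own representation, not how good its partition is: a pure
clustering objective trivially produces the most compact embedding (we
observed the plain deep-K-means baseline "winning" on its own embedding in
every seed while finding the same partition). Native-space scoring remains
available via `metric_space = "native"`, clearly labelled in the report.

## Validation, edge statistics, longitudinal response

* **Projection**: a validation subject joins the biotype whose mean-FNC
  template (raw correlation scale) is nearest in Euclidean distance; ties
  to the lowest template index. Assignments are invariant to any common
  affine rescaling of subjects and templates.
* **Replication**: Pearson correlation (with the t-transform p-value)
  between discovery and validation biotype-minus-control mean difference
  patterns, over all 1378 edges or a selected subset.
* **Edge screens**: pooled-variance two-sample t-tests per edge;
  the top k = 100 edges by |t| (ties to the lower canonical index) are the
  discriminative set; selection is by rank, so no multiplicity threshold is
  applied at this exploratory stage. Scale families (cognitive or clinical
  scores) use Bonferroni correction; longitudinal contrasts use
  Benjamini-Hochberg FDR within the family of all scales at a given week.
* **Effect sizes**: Cohen's d from group summaries with the
  root-mean-square of the two SDs as denominator,
  \( d = |m_1 - m_2| / \sqrt{(s_1^2 + s_2^2)/2} \); this is the convention
  that consistently reproduces published biotype characterisation tables at
  their printed precision (an n-weighted pooled-SD variant is available).
* **Treatment response**: the reduction rate \((x_0 - x_w)/x_0\) — the
  standard proportional-improvement measure in ADHD trials, invariant to
  the scale's unit — compared between biotypes, and between biotype 1 on
  methylphenidate and biotype 2 on atomoxetine, per week, with per-week FDR
  families. Zero-baseline records are excluded and logged; missing mid-week
  scores are analysed per available week without interpolation.

## The synthetic-cohort generator

`generate_cohort()` emulates the structure the pipeline is designed to
detect, at one tenth of the emulated study's group sizes: 116 controls,
82 + 25 patients in two biotypes. Per edge, a baseline mean (drawn once per
pattern seed, shared between paired cohorts), a biotype-specific
network-block shift (default: ±0.3 on seven blocks for biotype 1, a
partially opposite six-block pattern for biotype 2), a per-site offset
(SD 0.02, two sites) and independent Gaussian noise (SD 0.1) are summed and
clipped to (−0.99, 0.99). Ages are uniform over 9–11 years, genders 64%
male, cognitive scores carry a configurable biotype-2 deficit (defaults
chosen to give standardized gaps of ~0.2–0.4), and longitudinal symptom
scores follow an exponential approach to a plateau with biotype 2's
improvement frozen after week 4 and the atomoxetine arm 15% slower — the
qualitative signature the longitudinal module is meant to detect.

What the generator does **not** emulate: edge-to-edge covariance (noise is
diagonal; real FNC edges are strongly correlated through shared components),
realistic covariate-connectivity confounding, distributional asymmetries of
r values, or any biophysics. Passing tests on these cohorts therefore
demonstrate the *mechanics and statistical calibration* of the pipeline —
recovery when structure is present at a known strength, silence when it is
absent — not performance on real imaging data.

## Numerical choices and problem sizes

* Logistic probabilities clipped at \(10^{-7}\); Glorot-uniform weight
  initialization; no dropout or weight decay (at these cohort sizes and
  epoch budgets the models do not overfit, and adding unexercised
  regularisers would only widen the configuration surface).
* K-means: Lloyd, 10 restarts, 500 iteration cap, tolerance \(10^{-6}\);
  degenerate inputs with fewer distinct points than K short-circuit to the
  exact partition.
* Davies-Bouldin rejects coincident centroids (division by zero) rather
  than returning infinity; Calinski-Harabasz rejects zero within-group
  scatter.
* Test and acceptance runs use cohorts of 223 subjects × 1378 edges with a
  128/32 encoder trained 120 epochs (30 warm-up) — sizes chosen so the
  planted-recovery analyses complete in seconds while leaving the default
  configuration (256/64, 300 epochs) for real-data scale; most unit tests
  use a 12-component/3-network atlas (66 edges).

## Known limitations

* The graph similarity function, architecture widths, warm-up schedule and
  refresh period are engineering choices on axes where the emulated design
  is underdetermined; all are configurable, none were tuned beyond "the
  planted structure is recovered robustly".
* Internal validity indices compared across methods remain sensitive to the
  space they are computed in; the shared-feature-space default is the
  defensible comparison, but absolute index values still depend on the
  standardization.
* The classifier head is an auxiliary loss shaping the embedding; the
  package deliberately does not expose diagnosis prediction as a product
  feature.
* Cross-cohort projection assumes both cohorts' FNC live on comparable
  correlation scales after per-cohort residualization; systematic
  acquisition differences beyond site/scanner offsets are out of scope.
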