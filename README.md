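# fncbiotype

Data-driven patient subgroups ("biotypes") defined by resting-state brain
connectivity, rather than by symptoms, are a candidate route to more
targeted treatment in heterogeneous neuropsychiatric disorders such as
ADHD. `fncbiotype` implements an end-to-end pipeline for discovering such
biotypes from functional network connectivity (FNC), validating them on an
independent cohort, and characterising them clinically:

1. **FNC features.** Each subject's component time courses (53 independent
   component networks in the default atlas, grouped into 7 functional
   domains: SC, AU, SM, VI, CC, DM, CB) are correlated pairwise; the strict
   upper triangle of the 53×53 Pearson matrix gives a 1378-dimensional
   feature vector per subject.
2. **Population graph.** Nodes are subjects carrying standardized FNC
   features; edges encode phenotypic similarity
   `w_ij = 1[gender_i = gender_j] + 1[|age_i − age_j| ≤ τ]`
   (τ = 24 months), optionally weighted by FNC similarity. Graph
   convolutions use the symmetric renormalized operator
   `S = D̃^{−1/2}(A + I)D̃^{−1/2}`.
3. **Graph-convolutional biotyper.** A graph-convolutional autoencoder
   (encoder 1378 → 256 → 64 by default, mirrored decoder; each layer
   computes `act(S H W)`) is trained jointly with a logistic
   patient-vs-control head and a deep-K-means clustering head on the
   patient subgraph, minimizing

   `L = γ₁ L_rec + γ₂ L_CE + γ₃ L_cluster`,  γ₁ = 0.1, γ₂ = 0.5, γ₃ = 1,

   with Adam (learning rate 0.001), a warm-up phase before the clustering
   term activates, farthest-point centroid seeding and periodic hard
   reassignment. `L_cluster` is the mean squared distance of patient
   embeddings to their assigned centroids, so the representation is shaped
   to be cluster-friendly while staying faithful to the data and to the
   diagnosis labels.
4. **Model selection and benchmarking.** K is chosen by the elbow of the
   within-cluster sum-of-squares curve; the biotyper is compared against
   agglomerative clustering, K-means, a fully connected deep-K-means
   autoencoder and a reconstruction-only graph autoencoder using the
   Davies-Bouldin and Calinski-Harabasz indices.
5. **Validation and characterisation.** Mean-FNC biotype templates are
   projected onto an independent cohort by nearest Euclidean distance;
   replication is quantified by Pearson correlation of
   biotype-minus-control difference patterns; discriminative edges are
   screened with two-sample t-tests (top-100 by |t|), aggregated into
   network blocks, and correlated with cognitive/symptom scales; effect
   sizes use Cohen's d with an RMS-SD denominator; longitudinal symptom
   reduction rates `(score₀ − score_w)/score₀` are compared between
   biotypes (and biotype×medication cells) per week under
   Benjamini-Hochberg FDR control.

Because the cohorts such a pipeline targets are access-restricted, the
package ships a seeded synthetic-cohort generator
(`generate_cohort()`) that plants two patient biotypes with
network-block connectivity shifts, site effects, correlated cognitive
scores and longitudinal medication-response trajectories, so every stage
is testable end to end.

## Worked example

```r
library(fncbiotype)

cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> synthetic_cohort: 223 subjects x 1378 edges;
#> biotype1 biotype2       hc
#>       82       25      116

scaler <- fit_scaler(cohort$features)
graph <- build_graph(apply_scaler(cohort$features, scaler),
                     cohort$phenotypes,
                     labels = cohort$phenotypes$diagnosis,
                     subject_ids = cohort$phenotypes$subject_id,
                     feature_kernel = TRUE)

sse <- sse_elbow_curve(patient_subgraph(graph)$features, 1:6, seed = 1)
round(sse)
#>      1      2      3      4      5      6
#> 156317 105828 103198 102013 101333 100251
choose_k_elbow(sse)
#> [1] 2

cfg <- biotyper_config(input_dim = 1378, hidden = 128, embedding = 32,
                       K = 2, epochs = 120, warmup_epochs = 30, seed = 1)
fit <- train_gcn_biotyper(graph, cfg)
fit
#> gcn_biotyper: 107 patients in 2 biotypes; final total loss 0.1422
#> biotype
#>  1  2
#> 25 82
```

The elbow lands on K = 2 (the sharp drop from K = 1 to 2, flat
afterwards), and the two recovered biotypes split 82/25 — exactly the
planted groups (adjusted Rand index 1 against the generator's truth
labels). Mean-FNC templates for projection onto another cohort come from
`extract_biotype_templates(cohort$features, fit$assignments)`.

Effect sizes can be recomputed directly from published group summaries
(n, mean, SD per group):

```r
cohens_d_from_summary(summary_stats(821, 105.97, 15.81),
                      summary_stats(248, 101.62, 15.37))
#> [1] 0.279  # 0.28 at the conventional 2-decimal display
```

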