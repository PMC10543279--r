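#' Population graphs
#'
#' A population graph has one node per subject; node features are the
#' (standardized) FNC vectors and edge weights encode phenotypic similarity.
#' Graph convolution over it lets demographically similar subjects share
#' information during representation learning.
#'
#' @name population-graph
NULL

#' Phenotypic similarity between two subjects
#'
#' Additive indicator form: one point for matching gender (case-insensitive
#' string equality) plus one point for ages within `age_tol` months.
#'
#' @param age_i,age_j ages in months (positive; vectorized).
#' @param gender_i,gender_j gender categories.
#' @param age_tol age proximity tolerance in months (default 24).
#' @return integer weight in {0, 1, 2}.
#' @export
phenotypic_similarity <- function(age_i, age_j, gender_i, gender_j,
                                  age_tol = 24) {
  if (any(c(age_i, age_j) <= 0)) stop("ages must be positive")
  g_same <- tolower(as.character(gender_i)) == tolower(as.character(gender_j))
  a_near <- abs(age_i - age_j) <= age_tol
  as.integer(g_same) + as.integer(a_near)
}

#' Build a population graph
#'
#' @param features subjects x edges numeric matrix (rows in subject order;
#'   rownames used as subject ids when `subject_ids` is missing).
#' @param phenotypes data.frame with columns `age_months` and `gender`
#'   aligned with the feature rows (extra columns kept).
#' @param labels binary diagnosis per subject (patient = 1, control = 0).
#' @param subject_ids optional explicit ids.
#' @param age_tol age tolerance in months for the similarity indicator.
#' @param feature_kernel if `TRUE`, multiply each phenotypic weight by the
#'   (nonnegative part of the) Pearson correlation between the two subjects'
#'   feature vectors. Off by default.
#' @return a `population_graph`: list with `subject_ids`, `features`,
#'   `labels`, `adjacency` (symmetric, zero diagonal), `phenotypes`,
#'   `age_tol`.
#' @export
build_graph <- function(features, phenotypes, labels, subject_ids = NULL,
                        age_tol = 24, feature_kernel = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 subjects")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(features)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  }
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  phenotypes <- as.data.frame(phenotypes)
  if (nrow(phenotypes) != n || length(labels) != n) {
    stop("features, phenotypes and labels must align")
  }
  if (!all(c("age_months", "gender") %in% names(phenotypes))) {
    stop("phenotypes need columns age_months, gender")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")

  age <- phenotypes$age_months
  gen <- tolower(as.character(phenotypes$gender))
  if (any(age <= 0)) stop("ages must be positive")
  A <- outer(gen, gen, "==") + (abs(outer(age, age, "-")) <= age_tol)
  A <- matrix(as.numeric(A), n, n)
  if (feature_kernel) {
    K <- stats::cor(t(features))
    A <- A * pmax(K, 0)
  }
  diag(A) <- 0
  dimnames(A) <- list(subject_ids, subject_ids)
  structure(list(
    subject_ids = subject_ids,
    features = features,
    labels = labels,
    adjacency = A,
    phenotypes = phenotypes,
    age_tol = age_tol
  ), class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  cat("population_graph:", length(x$subject_ids), "subjects (",
      sum(x$labels == 1L), "patients /", sum(x$labels == 0L), "controls ),",
      ncol(x$features), "features;",
      sum(x$adjacency > 0) / 2, "edges\n")
  invisible(x)
}

#' Symmetric renormalized graph operator
#'
#' Adds self-loops and normalizes: `S = D^(-1/2) (A + I) D^(-1/2)` with `D`
#' the degree matrix of `A + I`. Eigenvalues lie in (-1, 1]; an isolated node
#' reduces to an identity row, so a graph with no edges degenerates to a
#' plain (non-graph) network.
#'
#' @param g a `population_graph`, or a bare symmetric nonnegative adjacency
#'   matrix with zero diagonal.
#' @return dense symmetric `N x N` operator matrix.
#' @export
normalize_adjacency <- function(g) {
  A <- if (inherits(g, "population_graph")) g$adjacency else as.matrix(g)
  if (any(A < 0)) stop("adjacency weights must be nonnegative")
  if (max(abs(A - t(A))) > 1e-10) stop("adjacency must be symmetric")
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  inv_sqrt <- 1 / sqrt(d)
  S <- At * tcrossprod(inv_sqrt)
  (S + t(S)) / 2
}

#' Restrict a population graph to its patients
#'
#' The patient-induced subgraph keeps every edge weight between two patients
#' unchanged; control nodes and their incident edges are removed. The deep
#' K-means clustering head operates on this subgraph.
#'
#' @param g a `population_graph`.
#' @param min_patients minimum patient count required (e.g. the cluster
#'   count).
#' @return a `population_graph` over the patients only.
#' @export
patient_subgraph <- function(g, min_patients = 2L) {
  stopifnot(inherits(g, "population_graph"))
  keep <- which(g$labels == 1L)
  if (length(keep) < min_patients) {
    stop("only ", length(keep), " patients; need at least ", min_patients)
  }
  structure(list(
    subject_ids = g$subject_ids[keep],
    features = g$features[keep, , drop = FALSE],
    labels = g$labels[keep],
    adjacency = g$adjacency[keep, keep, drop = FALSE],
    phenotypes = g$phenotypes[keep, , drop = FALSE],
    age_tol = g$age_tol
  ), class = "population_graph")
}

#' Export a graph's edges as an edge-list data.frame
#'
#' @param g a `population_graph`.
#' @return data.frame `id_i`, `id_j`, `weight` for every positive-weight pair.
#' @export
graph_edge_list <- function(g) {
  stopifnot(inherits(g, "population_graph"))
  A <- g$adjacency
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  data.frame(
    id_i = g$subject_ids[idx[, 1L]],
    id_j = g$subject_ids[idx[, 2L]],
    weight = A[idx]
  )
}
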