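#' Cross-cohort biotype projection and replication
#'
#' A discovery cohort's biotypes are summarized by their mean-FNC templates;
#' subjects of an independent cohort are assigned to the biotype whose
#' template is nearest in Euclidean distance, and replication of the
#' connectivity difference patterns is quantified by Pearson correlation.
#'
#' @name biotype-transfer
NULL

#' Project one subject onto biotype templates
#'
#' @param fnc FNC vector (correlation scale, canonical edge order).
#' @param templates a `biotype_templates` matrix (`K x edges`).
#' @return list with `biotype` (argmin distance; ties to the lowest index)
#'   and `distances` (Euclidean distance to each template).
#' @export
project_subject <- function(fnc, templates) {
  templates <- as.matrix(templates)
  if (length(fnc) != ncol(templates)) {
    stop("FNC length ", length(fnc), " does not match templates (",
         ncol(templates), ")")
  }
  d <- sqrt(rowSums(sweep(templates, 2L, as.numeric(fnc), "-")^2))
  list(biotype = unname(which.min(d)), distances = unname(d))
}

#' Project a whole cohort onto biotype templates
#'
#' @param features subjects x edges matrix on the same scale as the
#'   templates.
#' @param templates `K x edges` template matrix.
#' @return data.frame with `subject_id`, `biotype`, and one
#'   `distance_<k>` column per template.
#' @export
project_cohort <- function(features, templates) {
  features <- as.matrix(features)
  templates <- as.matrix(templates)
  if (ncol(features) != ncol(templates)) {
    stop("feature dimension does not match templates")
  }
  D <- sqrt(pmax(
    outer(rowSums(features^2), rowSums(templates^2), "+") -
      2 * tcrossprod(features, templates),
    0
  ))
  biotype <- apply(D, 1L, which.min)  # ties -> lowest index
  ids <- rownames(features)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(features)))
  out <- data.frame(subject_id = ids, biotype = as.integer(biotype))
  for (k in seq_len(nrow(templates))) out[[paste0("distance_", k)]] <- D[, k]
  out
}

#' Mean connectivity difference pattern between two groups
#'
#' @param features subjects x edges matrix (correlation scale); rownames are
#'   subject ids.
#' @param group_a,group_b subject id vectors (or integer row indices).
#' @return numeric vector of `mean(a) - mean(b)` per edge.
#' @export
mean_difference_pattern <- function(features, group_a, group_b) {
  features <- as.matrix(features)
  pick <- function(g) {
    if (is.character(g)) {
      miss <- setdiff(g, rownames(features))
      if (length(miss)) stop("unknown subjects: ", paste(miss, collapse = ", "))
      features[g, , drop = FALSE]
    } else features[g, , drop = FALSE]
  }
  A <- pick(group_a); B <- pick(group_b)
  if (!nrow(A) || !nrow(B)) stop("both groups must be nonempty")
  colMeans(A) - colMeans(B)
}

#' Correlation between two connectivity patterns
#'
#' Pearson correlation over all edges (or an edge subset such as the top-k
#' discriminative edges), with the two-sided p-value from the t-distribution
#' transform of r.
#'
#' @param pattern_a,pattern_b equal-length numeric vectors.
#' @param subset optional integer edge indices to correlate over.
#' @return list with `r`, `p`, `n` (edges used).
#' @export
replication_correlation <- function(pattern_a, pattern_b, subset = NULL) {
  if (length(pattern_a) != length(pattern_b)) stop("pattern lengths differ")
  if (!is.null(subset)) {
    if (any(subset < 1L | subset > length(pattern_a))) {
      stop("subset indices out of range")
    }
    pattern_a <- pattern_a[subset]
    pattern_b <- pattern_b[subset]
  }
  if (stats::sd(pattern_a) == 0 || stats::sd(pattern_b) == 0) {
    stop("zero-variance pattern; correlation undefined")
  }
  ct <- stats::cor.test(pattern_a, pattern_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(pattern_a))
}
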