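#' Discriminative edge statistics and effect sizes
#'
#' Edge-level two-sample t-statistics between groups, top-k selection of
#' discriminative connectivity, cross-cohort overlap, effect sizes from
#' summary statistics, and edge-scale correlations, with Bonferroni
#' correction for the cognitive/clinical scale families.
#'
#' @name discriminative-stats
NULL

#' Student's pooled-variance two-sample t-test
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @param welch use the Welch (unequal-variance) variant instead.
#' @return list with `t`, `p` (two-sided), `df`.
#' @export
two_sample_t <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("zero pooled variance; t undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Summary statistics for one group
#'
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @return a `summary_stats` list.
#' @export
summary_stats <- function(n, mean, sd) {
  if (n < 2L) stop("n must be >= 2")
  if (sd < 0) stop("sd must be nonnegative")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "summary_stats")
}

#' Two-sample t-test from summary statistics
#'
#' Same pooled-variance formula as [two_sample_t()], computed from group
#' sizes, means and standard deviations — this is what allows published
#' summary tables to be re-analyzed without subject-level data.
#'
#' @param a,b `summary_stats` objects.
#' @return list with `t`, `p`, `df = n_a + n_b - 2`.
#' @export
two_sample_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 == 0) stop("zero pooled variance; t undefined")
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Cohen's d from summary statistics
#'
#' Standardized mean difference using the root-mean-square of the two group
#' standard deviations as the denominator:
#' `d = |m_a - m_b| / sqrt((sd_a^2 + sd_b^2) / 2)`. The n-weighted pooled-SD
#' variant is available via `pooling = "n_weighted"`.
#'
#' @param a,b `summary_stats` objects.
#' @param pooling `"rms"` (default) or `"n_weighted"`.
#' @return nonnegative effect size (full precision; display at 2 decimals).
#' @export
cohens_d_from_summary <- function(a, b, pooling = c("rms", "n_weighted")) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  pooling <- match.arg(pooling)
  denom2 <- if (pooling == "rms") {
    (a$sd^2 + b$sd^2) / 2
  } else {
    ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  }
  if (denom2 == 0) stop("both group SDs are zero; d undefined")
  abs(a$mean - b$mean) / sqrt(denom2)
}

#' Effect sizes and tests for a table of group summaries
#'
#' Convenience wrapper over [two_sample_t_from_summary()] and
#' [cohens_d_from_summary()] for a data.frame with one row per scale and
#' columns `scale`, `n1`, `mean1`, `sd1`, `n2`, `mean2`, `sd2`.
#'
#' @param tab data.frame of group summaries (or path to such a TSV).
#' @param pooling passed to [cohens_d_from_summary()].
#' @return data.frame with scale, t, p, df, cohens_d.
#' @export
summary_table_stats <- function(tab, pooling = "rms") {
  if (is.character(tab)) tab <- utils::read.delim(tab, stringsAsFactors = FALSE)
  need <- c("scale", "n1", "mean1", "sd1", "n2", "mean2", "sd2")
  if (!all(need %in% names(tab))) {
    stop("summary table needs columns ", paste(need, collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    a <- summary_stats(tab$n1[i], tab$mean1[i], tab$sd1[i])
    b <- summary_stats(tab$n2[i], tab$mean2[i], tab$sd2[i])
    tt <- two_sample_t_from_summary(a, b)
    data.frame(scale = tab$scale[i], t = tt$t, p = tt$p, df = tt$df,
               cohens_d = cohens_d_from_summary(a, b, pooling = pooling))
  }))
  rownames(out) <- NULL
  out
}

#' Edge-wise two-sample t-tests over a cohort
#'
#' One pooled-variance two-sample t-test per canonical edge between two
#' subject groups. Edges with zero pooled variance are flagged (`valid =
#' FALSE`, `t`/`p` set to `NA`) rather than aborting the screen.
#'
#' @param features subjects x edges matrix; rownames are subject ids.
#' @param group_a,group_b disjoint subject id vectors (or row indices).
#' @param atlas optional `network_atlas` used to annotate component and
#'   network pairs (must match the edge count).
#' @return data.frame (one row per edge): edge, i, j, network_i, network_j,
#'   t, p, df, valid.
#' @export
edge_ttests <- function(features, group_a, group_b, atlas = NULL) {
  features <- as.matrix(features)
  idx_of <- function(g) {
    if (is.character(g)) match(g, rownames(features)) else as.integer(g)
  }
  ia <- idx_of(group_a); ib <- idx_of(group_b)
  if (anyNA(ia) || anyNA(ib)) stop("unknown subject ids in groups")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  if (!length(ia) || !length(ib)) stop("groups must be nonempty")
  A <- features[ia, , drop = FALSE]
  B <- features[ib, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 subjects")
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colSums(sweep(A, 2L, ma, "-")^2) / (na - 1)
  vb <- colSums(sweep(B, 2L, mb, "-")^2) / (nb - 1)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  valid <- sp2 > 0
  t <- ifelse(valid, (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb)), NA_real_)
  p <- ifelse(valid, 2 * stats::pt(-abs(t), df), NA_real_)

  C <- n_components_from_edges(ncol(features))
  et <- edge_index_table(C)
  net_i <- net_j <- NA_character_
  if (!is.null(atlas)) {
    if (length(atlas$component_ids) != C) stop("atlas does not match edge count")
    net_i <- atlas$network_of[et$i]
    net_j <- atlas$network_of[et$j]
  }
  data.frame(edge = et$edge, i = et$i, j = et$j,
             network_i = net_i, network_j = net_j,
             t = unname(t), p = unname(p), df = df, valid = valid)
}

#' Select the top-k discriminative edges
#'
#' The k valid edges with the largest |t|; ties broken by the smaller
#' canonical edge index.
#'
#' @param stats data.frame from [edge_ttests()].
#' @param k number of edges to keep (default 100).
#' @return the input rows for the selected edges, ordered by decreasing |t|,
#'   with a `selected` column added.
#' @export
top_k_edges <- function(stats, k = 100L) {
  if (k < 1L) stop("k must be >= 1")
  valid <- stats[stats$valid & is.finite(stats$t), , drop = FALSE]
  if (k > nrow(valid)) {
    stop("k = ", k, " exceeds the ", nrow(valid), " valid edges")
  }
  ord <- order(-abs(valid$t), valid$edge)
  sel <- valid[ord[seq_len(k)], , drop = FALSE]
  sel$selected <- TRUE
  rownames(sel) <- NULL
  sel
}

#' Overlap of two discriminative edge selections
#'
#' @param selected_a,selected_b data.frames from [top_k_edges()] (or integer
#'   edge index vectors) sharing the canonical edge ordering.
#' @return list with `edges` (sorted shared indices) and `count`.
#' @export
edge_overlap <- function(selected_a, selected_b) {
  ia <- if (is.data.frame(selected_a)) selected_a$edge else as.integer(selected_a)
  ib <- if (is.data.frame(selected_b)) selected_b$edge else as.integer(selected_b)
  shared <- sort(intersect(ia, ib))
  list(edges = shared, count = length(shared))
}

#' Correlations between edge values and behavioral scales
#'
#' Pearson correlation (and two-sided p) of each requested edge with each
#' scale across subjects; missing scale entries are dropped pairwise with
#' the retained n reported.
#'
#' @param features subjects x edges matrix; rownames are subject ids.
#' @param scales data.frame of scale scores, rownames (or a `subject_id`
#'   column) matching the feature rows.
#' @param edges integer edge indices to test (default: all).
#' @return data.frame edge, scale, r, p, n, valid.
#' @export
scale_correlations <- function(features, scales, edges = NULL) {
  features <- as.matrix(features)
  scales <- as.data.frame(scales)
  if ("subject_id" %in% names(scales)) {
    rownames(scales) <- scales$subject_id
    scales$subject_id <- NULL
  }
  common <- intersect(rownames(features), rownames(scales))
  if (length(common) < 3L) stop("need at least 3 subjects with scale data")
  features <- features[common, , drop = FALSE]
  scales <- scales[common, , drop = FALSE]
  if (is.null(edges)) edges <- seq_len(ncol(features))
  rows <- list()
  for (e in edges) {
    x <- features[, e]
    for (s in names(scales)) {
      y <- suppressWarnings(as.numeric(scales[[s]]))
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          edge = e, scale = s, r = NA_real_, p = NA_real_, n = n, valid = FALSE)
        next
      }
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        edge = e, scale = s, r = unname(ct$estimate), p = ct$p.value,
        n = n, valid = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bonferroni correction
#'
#' `min(1, m * p)` per test; `m` defaults to the number of p-values but may
#' be set larger (e.g. the full family size).
#'
#' @param p p-values in (0, 1].
#' @param m family size (>= `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be at least the number of tests")
  stats::p.adjust(p, method = "bonferroni", n = m)
}
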