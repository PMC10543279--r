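#' Cluster validity and baseline clusterers
#'
#' Internal cluster-validity indices (Davies-Bouldin, Calinski-Harabasz),
#' the elbow rule on the within-cluster sum of squares for choosing K, and
#' the four baseline clusterers the biotyper is benchmarked against.
#'
#' @name cluster-eval
NULL

split_clusters <- function(points, assignments) {
  points <- as.matrix(points)
  if (nrow(points) != length(assignments)) stop("assignments do not align")
  labs <- sort(unique(assignments))
  if (length(labs) < 2L) stop("need at least 2 nonempty clusters")
  lapply(labs, function(k) points[assignments == k, , drop = FALSE])
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio `(s_i + s_j) / d(mu_i, mu_j)`,
#' where `s_i` is the mean Euclidean distance of cluster `i`'s members to its
#' centroid. Lower is better.
#'
#' @param points `n x d` matrix.
#' @param assignments cluster label per row (>= 2 nonempty clusters).
#' @return nonnegative scalar.
#' @export
davies_bouldin <- function(points, assignments) {
  parts <- split_clusters(points, assignments)
  K <- length(parts)
  mu <- do.call(rbind, lapply(parts, colMeans))
  s <- vapply(seq_len(K), function(k) {
    mean(sqrt(rowSums(sweep(parts[[k]], 2L, mu[k, ], "-")^2)))
  }, numeric(1))
  Dc <- as.matrix(stats::dist(mu))
  if (any(Dc[upper.tri(Dc)] == 0)) {
    stop("coincident cluster centroids; Davies-Bouldin index undefined")
  }
  r <- vapply(seq_len(K), function(i) {
    max(vapply(setdiff(seq_len(K), i), function(j) (s[i] + s[j]) / Dc[i, j],
               numeric(1)))
  }, numeric(1))
  mean(r)
}

#' Calinski-Harabasz index
#'
#' `(B / (K - 1)) / (W / (N - K))` with `B` the between-group and `W` the
#' within-group sum of squares. Higher is better.
#'
#' @inheritParams davies_bouldin
#' @return nonnegative scalar.
#' @export
calinski_harabasz <- function(points, assignments) {
  points <- as.matrix(points)
  parts <- split_clusters(points, assignments)
  K <- length(parts)
  N <- nrow(points)
  grand <- colMeans(points)
  W <- sum(vapply(parts, function(P) {
    sum(sweep(P, 2L, colMeans(P), "-")^2)
  }, numeric(1)))
  B <- sum(vapply(parts, function(P) {
    nrow(P) * sum((colMeans(P) - grand)^2)
  }, numeric(1)))
  if (W == 0) stop("zero within-group sum of squares; index undefined")
  (B / (K - 1)) / (W / (N - K))
}

#' Seeded multi-restart K-means
#'
#' Lloyd's algorithm via [stats::kmeans()]: the first start uses
#' deterministic greedy farthest-point seeds, the remaining starts random
#' seeded draws; the run with the lowest within-cluster sum of squares wins.
#'
#' @param points `n x d` matrix.
#' @param K cluster count.
#' @param seed RNG seed.
#' @param nstart number of starts (default 10).
#' @param iter_max,tol Lloyd iteration cap and convergence tolerance.
#' @return list with `cluster`, `centers`, `tot_withinss`.
#' @export
kmeans_fit <- function(points, K, seed = 1L, nstart = 10L, iter_max = 500L,
                       tol = 1e-6) {
  points <- as.matrix(points)
  if (K > nrow(points)) stop("K exceeds number of points")
  uniq <- unique(points)
  if (nrow(uniq) <= K) {
    # fewer distinct points than clusters: each distinct point is a center
    cl <- match(data.frame(t(points)), data.frame(t(uniq)))
    return(list(cluster = as.integer(cl), centers = uniq, tot_withinss = 0))
  }
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- if (r == 1L) {
      farthest_point_seeds(points, K)
    } else {
      points[sample.int(nrow(points), K), , drop = FALSE]
    }
    if (anyDuplicated(round(centers, 12))) next
    km <- suppressWarnings(
      stats::kmeans(points, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss - tol) best <- km
  }
  if (is.null(best)) stop("all K-means starts degenerate")
  list(cluster = as.integer(best$cluster), centers = best$centers,
       tot_withinss = best$tot.withinss)
}

#' Within-cluster sum of squares across K (elbow curve)
#'
#' @param points `n x d` matrix.
#' @param k_range integer vector of cluster counts (max <= n).
#' @param seed base RNG seed; each K gets a derived seed.
#' @param nstart restarts per K.
#' @return named numeric vector, SSE per K.
#' @export
sse_elbow_curve <- function(points, k_range = 1:8, seed = 1L, nstart = 10L) {
  points <- as.matrix(points)
  if (max(k_range) > nrow(points)) stop("max K exceeds number of points")
  sse <- vapply(k_range, function(K) {
    if (K == 1L) {
      sum(sweep(points, 2L, colMeans(points), "-")^2)
    } else {
      kmeans_fit(points, K, seed = seed + K, nstart = nstart)$tot_withinss
    }
  }, numeric(1))
  stats::setNames(sse, k_range)
}

#' Elbow rule on an SSE curve
#'
#' Returns the K whose (K, SSE) point lies farthest (perpendicular distance)
#' from the chord joining the curve's endpoints; ties go to the smaller K.
#' An exactly linear curve has no elbow: the smallest K is returned with a
#' warning.
#'
#' @param sse_by_k named numeric vector from [sse_elbow_curve()] (>= 3
#'   values).
#' @return integer K.
#' @export
choose_k_elbow <- function(sse_by_k) {
  if (length(sse_by_k) < 3L) stop("need at least 3 K values")
  ks <- as.numeric(names(sse_by_k))
  if (anyNA(ks)) ks <- seq_along(sse_by_k)
  y <- as.numeric(sse_by_k)
  x1 <- ks[1L]; y1 <- y[1L]
  x2 <- ks[length(ks)]; y2 <- y[length(y)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * ks - (x2 - x1) * y + x2 * y1 - y2 * x1) / len
  if (max(d) < 1e-10 * max(1, abs(y1))) {
    warning("SSE curve is linear; no elbow, returning smallest K")
    return(as.integer(ks[1L]))
  }
  as.integer(ks[which.max(d)])
}

#' Run a baseline clusterer
#'
#' The four reference methods the biotyper is compared against:
#' \describe{
#'   \item{`agglomerative`}{Ward-linkage (`ward.D2`) hierarchical clustering
#'     on the raw features, cut at `K`.}
#'   \item{`kmeans`}{multi-restart K-means on the raw features.}
#'   \item{`dnn_kmeans`}{the same autoencoder + deep-K-means objective as the
#'     biotyper but with the graph operator replaced by the identity (a plain
#'     fully connected network; no diagnosis head).}
#'   \item{`gcn_kmeans`}{the graph-convolutional autoencoder trained with the
#'     reconstruction loss only, followed by K-means on the embeddings.}
#' }
#' For the two embedding methods the result carries the learned patient
#' embeddings so that validity indices can be computed in embedding space.
#'
#' @param method one of `"agglomerative"`, `"kmeans"`, `"dnn_kmeans"`,
#'   `"gcn_kmeans"`.
#' @param features patients x edges matrix (standardized scale recommended).
#' @param K cluster count.
#' @param seed RNG seed.
#' @param graph optional `population_graph` (required for `gcn_kmeans`;
#'   when supplied its patient subgraph provides the operator).
#' @param config optional `biotyper_config` template for the deep baselines
#'   (gammas are overridden per method).
#' @return list with `assignments` (integer vector), `embedding` (matrix, or
#'   `NULL` for feature-space methods), `method`.
#' @export
run_baseline <- function(method, features, K, seed = 1L, graph = NULL,
                         config = NULL) {
  method <- match.arg(method,
                      c("agglomerative", "kmeans", "dnn_kmeans", "gcn_kmeans"))
  features <- as.matrix(features)
  if (method == "agglomerative") {
    hc <- stats::hclust(stats::dist(features), method = "ward.D2")
    return(list(assignments = as.integer(stats::cutree(hc, k = K)),
                embedding = NULL, method = method))
  }
  if (method == "kmeans") {
    km <- kmeans_fit(features, K, seed = seed)
    return(list(assignments = km$cluster, embedding = NULL, method = method))
  }
  if (is.null(config)) {
    config <- biotyper_config(input_dim = ncol(features),
                              hidden = 256L, embedding = 64L, K = K, seed = seed)
  }
  if (method == "dnn_kmeans") {
    # identity operator: an edgeless graph over the patients
    n <- nrow(features)
    phen <- data.frame(age_months = seq_len(n) * 1000, # no two ages close
                       gender = paste0("g", seq_len(n)))  # no two genders equal
    g0 <- build_graph(features, phen, labels = rep(1L, n),
                      subject_ids = rownames(features), age_tol = 0)
    cfg <- modify_config(config, input_dim = ncol(features), K = K,
                         gamma2 = 0, seed = seed)
    st <- train_gcn_biotyper(g0, cfg)
    return(list(assignments = unname(st$assignments),
                embedding = st$embeddings, method = method))
  }
  # gcn_kmeans: reconstruction-only graph autoencoder, then K-means
  if (is.null(graph)) stop("gcn_kmeans requires the population graph")
  gp <- patient_subgraph(graph, min_patients = K)
  cfg <- modify_config(config, input_dim = ncol(gp$features), K = K,
                       gamma2 = 0, gamma3 = 0, seed = seed)
  st <- train_gcn_biotyper(gp, cfg)
  list(assignments = unname(st$assignments), embedding = st$embeddings,
       method = method)
}

modify_config <- function(config, ...) {
  upd <- list(...)
  args <- unclass(config)
  args[names(upd)] <- upd
  do.call(biotyper_config, args)
}

#' Benchmark the biotyper against all baselines
#'
#' Computes Davies-Bouldin and Calinski-Harabasz indices for the biotyper and
#' the four baselines on one cohort. By default every method's *partition*
#' is scored in the shared standardized feature space
#' (`metric_space = "shared_feature"`), which keeps the indices commensurable
#' across methods; `metric_space = "native"` instead scores each
#' embedding-based method in its own embedding space, which measures how
#' compact the learned representation is rather than how good the partition
#' is (a pure clustering objective always compresses its own embedding
#' hardest, so native-space values are not comparable across objectives).
#'
#' @param g a `population_graph` (standardized features).
#' @param config a `biotyper_config`.
#' @param methods baseline methods to include.
#' @param seed seed for the baselines (the biotyper uses `config$seed`).
#' @param state optional pre-trained `gcn_biotyper` to reuse.
#' @param metric_space `"shared_feature"` (default) or `"native"`.
#' @return data.frame with columns method, K, dbi, chi, space, seed.
#' @export
benchmark_methods <- function(g, config,
                              methods = c("agglomerative", "kmeans",
                                          "dnn_kmeans", "gcn_kmeans"),
                              seed = config$seed, state = NULL,
                              metric_space = c("shared_feature", "native")) {
  metric_space <- match.arg(metric_space)
  gp <- patient_subgraph(g, min_patients = config$K)
  feats <- gp$features
  if (is.null(state)) state <- train_gcn_biotyper(g, config)
  Zp <- state$embeddings[match(gp$subject_ids, g$subject_ids), , drop = FALSE]
  score <- function(assignments, embedding, method_seed, method) {
    pts <- if (metric_space == "shared_feature" || is.null(embedding)) {
      feats
    } else embedding
    data.frame(
      method = method, K = config$K,
      dbi = davies_bouldin(pts, assignments),
      chi = calinski_harabasz(pts, assignments),
      space = if (identical(pts, feats)) "feature" else "embedding",
      seed = method_seed
    )
  }
  rows <- list(score(unname(state$assignments), Zp, config$seed,
                     "gcn_biotyper"))
  for (m in methods) {
    res <- run_baseline(m, feats, K = config$K, seed = seed, graph = g,
                        config = config)
    rows[[m]] <- score(res$assignments, res$embedding, seed, m)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
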