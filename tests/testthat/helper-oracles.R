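# Independently coded brute-force oracles. These deliberately avoid the
# package's implementations (and their vectorized shortcuts): plain loops
# and textbook formulas only.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

oracle_pearson_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}

oracle_t_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

oracle_dbi <- function(points, labels) {
  labs <- sort(unique(labels))
  K <- length(labs)
  cent <- list(); scat <- numeric(K)
  for (k in seq_len(K)) {
    P <- points[labels == labs[k], , drop = FALSE]
    cent[[k]] <- colMeans(P)
    scat[k] <- mean(apply(P, 1, function(p) sqrt(sum((p - cent[[k]])^2))))
  }
  total <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (scat[i] + scat[j]) / dij)
    }
    total <- total + worst
  }
  total / K
}

oracle_chi <- function(points, labels) {
  labs <- sort(unique(labels))
  K <- length(labs); N <- nrow(points)
  grand <- colMeans(points)
  W <- 0; B <- 0
  for (k in seq_len(K)) {
    P <- points[labels == labs[k], , drop = FALSE]
    mu <- colMeans(P)
    W <- W + sum(apply(P, 1, function(p) sum((p - mu)^2)))
    B <- B + nrow(P) * sum((mu - grand)^2)
  }
  (B / (K - 1)) / (W / (N - K))
}

oracle_bonferroni <- function(p, m) pmin(1, m * p)

# hand-stepped Benjamini-Hochberg
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

oracle_nearest_template <- function(x, templates) {
  d <- apply(templates, 1, function(tpl) sqrt(sum((x - tpl)^2)))
  which.min(d)
}

oracle_top_k <- function(t_values, k) {
  ord <- order(-abs(t_values), seq_along(t_values))
  sort(ord[seq_len(k)])
}

oracle_cor_matrix <- function(ts) {
  C <- nrow(ts)
  m <- diag(C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    if (i != j) m[i, j] <- oracle_pearson(ts[i, ], ts[j, ])
  }
  m
}

# single alternating K-means step: reassign then recompute means
oracle_kmeans_step <- function(points, centers) {
  n <- nrow(points); K <- nrow(centers)
  assign <- integer(n)
  for (i in seq_len(n)) {
    d <- apply(centers, 1, function(m) sum((points[i, ] - m)^2))
    assign[i] <- which.min(d)
  }
  for (k in seq_len(K)) {
    if (any(assign == k)) {
      centers[k, ] <- colMeans(points[assign == k, , drop = FALSE])
    }
  }
  list(centers = centers, assign = assign)
}
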