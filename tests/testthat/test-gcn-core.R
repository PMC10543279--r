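test_that("encode/decode reduce to closed forms on trivial operators", {
  # identity operator + identity weights + single linear layer -> input
  X <- matrix(rnorm(12), 4, 3)
  S <- diag(4)
  expect_equal(encode(S, X, list(diag(3))), X)

  # two-node graph with weight 1: operator entries all 0.5 -> row means
  S2 <- matrix(0.5, 2, 2)
  X2 <- matrix(c(1, 3, 2, 6), 2, 2)
  out <- encode(S2, X2, list(diag(2)))
  expect_equal(out[1, ], colMeans(X2))
  expect_equal(out[2, ], colMeans(X2))
})

test_that("encode matches an explicit matrix-chain oracle", {
  set.seed(40)
  n <- 7; p <- 5
  A <- matrix(sample(0:2, n * n, TRUE), n); A <- A + t(A); diag(A) <- 0
  S <- normalize_adjacency(A)
  X <- matrix(rnorm(n * p), n)
  W1 <- matrix(rnorm(p * 4), p, 4)
  W2 <- matrix(rnorm(4 * 2), 4, 2)
  Z <- encode(S, X, list(W1, W2))
  H1 <- pmax(S %*% X %*% W1, 0)
  expect_equal(Z, S %*% H1 %*% W2, tolerance = 1e-6)
  # decode mirrors
  W3 <- matrix(rnorm(2 * 4), 2, 4); W4 <- matrix(rnorm(4 * p), 4, p)
  Xhat <- decode(S, Z, list(W3, W4))
  expect_equal(Xhat, S %*% pmax(S %*% Z %*% W3, 0) %*% W4, tolerance = 1e-6)
  expect_error(encode(S, X, list(matrix(0, 3, 2))), "input dim")
})

test_that("loss components follow their definitions", {
  X <- matrix(rnorm(20), 4, 5)
  expect_equal(reconstruction_loss(X, X), 0)
  expect_equal(reconstruction_loss(X, X + 1), 1)
  Y <- matrix(rnorm(20), 4, 5)
  expect_equal(reconstruction_loss(X, Y), sum((X - Y)^2) / 20)
  expect_error(reconstruction_loss(X, Y * NA), "non-finite")

  # predicted probability 0.5 -> ln 2
  Z <- matrix(0, 6, 3)
  head <- list(w = matrix(0, 3, 1), b = 0)
  expect_equal(classification_loss(Z, rep(c(0, 1), 3), head), log(2))
  # hand-computed cross-entropy on a fixture
  set.seed(41)
  Z2 <- matrix(rnorm(12), 4, 3)
  head2 <- list(w = matrix(c(1, -1, 0.5), 3, 1), b = 0.2)
  y <- c(1, 0, 1, 0)
  p <- 1 / (1 + exp(-(Z2 %*% head2$w + head2$b)))
  expect_equal(classification_loss(Z2, y, head2),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-12)
  expect_warning(classification_loss(Z2, rep(1, 4), head2), "single-class")
})

test_that("deep K-means loss equals the brute-force distance mean", {
  M <- rbind(c(0, 0), c(10, 0))
  Z <- rbind(c(0, 0), c(10, 0))
  expect_equal(deep_kmeans_loss(Z, M, c(1, 2)), 0)
  # 2 points at distance 2 sharing their midpoint centroid -> loss 1
  Z2 <- rbind(c(-1, 0), c(1, 0))
  expect_equal(deep_kmeans_loss(Z2, matrix(c(0, 0), 1, 2), c(1, 1)), 1)

  M2 <- rbind(c(0, 0), c(5, 5))
  expect_error(deep_kmeans_loss(Z2, M2, c(1, 1)), "empty cluster")
  expect_equal(deep_kmeans_loss(rbind(Z2, c(5, 5)), M2, c(1, 1, 2)), 2 / 3)

  set.seed(43)
  Z <- matrix(rnorm(30), 10, 3)
  M <- matrix(rnorm(9), 3, 3)
  a <- apply(Z, 1, function(z) which.min(colSums((t(M) - z)^2)))
  if (length(unique(a)) == 3) {
    brute <- mean(sapply(1:10, function(i) min(colSums((t(M) - Z[i, ])^2))))
    expect_equal(deep_kmeans_loss(Z, M, a), brute, tolerance = 1e-12)
  }
})

test_that("centroid/assignment updates are monotone and match a K-means step", {
  # 1-D points {0,1,10,11}, centroids {0,10}
  Z <- matrix(c(0, 1, 10, 11), 4, 1)
  M <- matrix(c(0, 10), 2, 1)
  upd <- update_centroids_and_assignments(Z, M)
  expect_equal(upd$assignments, c(1L, 1L, 2L, 2L))
  expect_equal(as.numeric(upd$centroids), c(0.5, 10.5))

  # fixed point when points sit on K distinct centroids
  Zf <- matrix(c(0, 5, 9), 3, 1)
  updf <- update_centroids_and_assignments(Zf, Zf)
  expect_equal(as.numeric(updf$centroids), c(0, 5, 9))

  # random fixtures: never increases the loss; equals reference step
  set.seed(44)
  for (rep in 1:10) {
    P <- matrix(rnorm(24), 8, 3)
    M0 <- P[sample(8, 3), , drop = FALSE]
    a0 <- apply(P, 1, function(z) which.min(colSums((t(M0) - z)^2)))
    if (length(unique(a0)) < 3) next
    before <- deep_kmeans_loss(P, M0, a0)
    upd <- update_centroids_and_assignments(P, M0)
    expect_lte(deep_kmeans_loss(P, upd$centroids, upd$assignments),
               before + 1e-12)
    ref <- oracle_kmeans_step(P, M0)
    expect_equal(upd$assignments, ref$assign)
    expect_equal(upd$centroids, ref$centers, ignore_attr = TRUE)
  }
})

test_that("total loss is the stated weighted combination and linear in each gamma", {
  cfg <- biotyper_config(input_dim = 10)
  expect_equal(total_loss(2, 4, 1, cfg), 0.1 * 2 + 0.5 * 4 + 1 * 1)
  cfg0 <- biotyper_config(input_dim = 10, gamma2 = 0, gamma3 = 0)
  expect_equal(total_loss(2, 4, 1, cfg0), 0.2)
  # numeric linearity in each gamma
  set.seed(45)
  l <- runif(3, 0.5, 2)
  for (nm in c("gamma1", "gamma2", "gamma3")) {
    args <- list(input_dim = 10)
    args[[nm]] <- 0.3
    lo <- do.call(biotyper_config, args)
    args[[nm]] <- 0.6
    hi <- do.call(biotyper_config, args)
    args[[nm]] <- 0.9
    hi2 <- do.call(biotyper_config, args)
    d1 <- total_loss(l[1], l[2], l[3], hi) - total_loss(l[1], l[2], l[3], lo)
    d2 <- total_loss(l[1], l[2], l[3], hi2) - total_loss(l[1], l[2], l[3], hi)
    expect_equal(d1, d2, tolerance = 1e-12)
  }
  expect_error(biotyper_config(input_dim = 10, gamma1 = -1), "nonnegative")
})

test_that("config validation enforces the documented invariants", {
  expect_error(biotyper_config(input_dim = 10, embedding = 1, K = 2), ">= K")
  expect_error(biotyper_config(input_dim = 10, learning_rate = 0), "positive")
  expect_error(biotyper_config(input_dim = 10, epochs = 10, warmup_epochs = 10),
               "warmup")
  cfg <- biotyper_config(input_dim = 10)
  expect_equal(c(cfg$gamma1, cfg$gamma2, cfg$gamma3), c(0.1, 0.5, 1))
  expect_equal(cfg$learning_rate, 0.001)
})

test_that("farthest-point seeding is deterministic and spreads points", {
  P <- matrix(c(0, 0, 0.1, 0, 10, 0, 10.1, 0), 4, 2, byrow = TRUE)
  seeds <- farthest_point_seeds(P, 2)
  # the two seeds come from opposite point masses
  expect_equal(sort(abs(seeds[, 1] - 5) > 0), c(TRUE, TRUE))
  expect_gt(abs(seeds[1, 1] - seeds[2, 1]), 5)
  expect_identical(farthest_point_seeds(P, 2), seeds)
  expect_error(farthest_point_seeds(P, 5), "exceeds")
})

test_that("single-epoch total loss equals the sum of independent components", {
  fix <- tiny_discovery(scale = 0.3, seed = 2)
  cfg <- tiny_model_config(ncol(fix$graph$features), epochs = 1,
                           warmup_epochs = 0, gamma3 = 0)
  st <- train_gcn_biotyper(fix$graph, cfg)
  h <- st$loss_history
  expect_equal(h$total, 0.1 * h$l_rec + 0.5 * h$l_ce + 1 * h$l_cluster,
               tolerance = 1e-12)
})

test_that("training is reproducible and permutation-equivariant", {
  fix <- tiny_discovery(scale = 0.3, seed = 3)
  cfg <- tiny_model_config(ncol(fix$graph$features), epochs = 40,
                           warmup_epochs = 10)
  st1 <- train_gcn_biotyper(fix$graph, cfg)
  st2 <- train_gcn_biotyper(fix$graph, cfg)
  expect_identical(st1$assignments, st2$assignments)
  expect_equal(st1$loss_history, st2$loss_history, tolerance = 1e-12)

  # encoder output permutes with the subjects (weights fixed)
  g <- fix$graph
  S <- normalize_adjacency(g)
  set.seed(46)
  W <- list(matrix(rnorm(ncol(g$features) * 6, sd = 0.1), ncol(g$features), 6),
            matrix(rnorm(6 * 3, sd = 0.1), 6, 3))
  Z <- encode(S, g$features, W)
  perm <- sample(nrow(g$features))
  g2 <- build_graph(g$features[perm, ], g$phenotypes[perm, ], g$labels[perm],
                    subject_ids = g$subject_ids[perm],
                    feature_kernel = TRUE)
  Z2 <- encode(normalize_adjacency(g2), g2$features, W)
  expect_equal(Z2, Z[perm, ], tolerance = 1e-8)
})

test_that("planted two-biotype structure is recovered and scales with effect size", {
  fix <- tiny_discovery(scale = 0.3, seed = 5)
  cfg <- tiny_model_config(ncol(fix$graph$features), seed = 5)
  st <- train_gcn_biotyper(fix$graph, cfg)
  expect_gte(ari(unname(st$assignments), fix$truth_patients), 0.9)

  # ARI non-decreasing over 3 planted effect levels (majority of seeds)
  levels <- c(0, 0.12, 0.3)
  wins <- 0
  for (seed in 1:3) {
    aris <- sapply(levels, function(sc) {
      f <- tiny_discovery(scale = sc, seed = seed)
      s <- train_gcn_biotyper(f$graph,
                              tiny_model_config(ncol(f$graph$features),
                                                seed = seed))
      ari(unname(s$assignments), f$truth_patients)
    })
    if (all(diff(aris) >= -0.05)) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("gamma3 = 0 reduces to post-hoc K-means on the embeddings", {
  fix <- tiny_discovery(scale = 0.3, seed = 7)
  cfg <- tiny_model_config(ncol(fix$graph$features), gamma3 = 0, epochs = 60,
                           warmup_epochs = 10, seed = 7)
  st <- train_gcn_biotyper(fix$graph, cfg)
  pat <- match(st$patient_ids, fix$graph$subject_ids)
  km <- kmeans_fit(st$embeddings[pat, ], 2, seed = cfg$seed)
  expect_equal(unname(st$assignments), km$cluster)
})

test_that("biotype templates are cluster means on the raw scale", {
  set.seed(47)
  feats <- matrix(runif(40, -1, 1), 10, 4,
                  dimnames = list(paste0("s", 1:10), NULL))
  a <- rep(c(1L, 2L), each = 5)
  names(a) <- rownames(feats)
  tpl <- extract_biotype_templates(feats, a)
  expect_equal(unclass(tpl)[1, ], colMeans(feats[1:5, ]), ignore_attr = TRUE)
  expect_equal(unclass(tpl)[2, ], colMeans(feats[6:10, ]), ignore_attr = TRUE)
  # singleton and pair clusters
  b <- c(1L, rep(2L, 9L)); names(b) <- rownames(feats)
  tplb <- extract_biotype_templates(feats, b)
  expect_equal(unclass(tplb)[1, ], feats[1, ], ignore_attr = TRUE)
  expect_error(extract_biotype_templates(feats, rep(1L, 10), K = 2), "empty")
})

test_that("checkpoints round-trip through save/load", {
  fix <- tiny_discovery(scale = 0.3, seed = 8)
  cfg <- tiny_model_config(ncol(fix$graph$features), epochs = 20,
                           warmup_epochs = 5)
  st <- train_gcn_biotyper(fix$graph, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_biotyper(st, path, scaler = fix$scaler)
  back <- load_biotyper(path)
  expect_identical(back$state$assignments, st$assignments)
  expect_equal(back$scaler$center, fix$scaler$center)
})
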