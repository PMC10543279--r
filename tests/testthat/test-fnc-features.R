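test_that("FNC matrix is the Pearson correlation of component time courses", {
  set.seed(42)
  ts <- matrix(rnorm(3 * 5), nrow = 3)
  m <- compute_fnc_matrix(ts)
  expect_equal(m, oracle_cor_matrix(ts), tolerance = 1e-12)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(1, 3))

  # perfect correlation / anti-correlation
  ts2 <- rbind(1:10, 1:10, -(1:10))
  m2 <- compute_fnc_matrix(ts2 + matrix(rnorm(30, sd = 1e-12), 3))
  expect_equal(m2[1, 2], 1, tolerance = 1e-6)
  expect_equal(m2[1, 3], -1, tolerance = 1e-6)
})

test_that("degenerate time courses are rejected with diagnostics", {
  expect_error(compute_fnc_matrix(matrix(1, 3, 10)), "zero-variance")
  expect_error(compute_fnc_matrix(rbind(rnorm(5), rep(2, 5)), subject_id = "s1"),
               "component.*2.*s1")
  expect_error(compute_fnc_matrix(matrix(rnorm(4), 2, 2)), "timepoints")
  expect_error(compute_fnc_matrix(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "missing")
})

test_that("vectorize/devectorize are mutually inverse in canonical order", {
  # explicit 3x3: off-diagonals a,b,c in row-major order
  m3 <- matrix(c(1, .1, .2, .1, 1, .3, .2, .3, 1), 3, 3)
  expect_equal(vectorize_upper_triangle(m3), c(.1, .2, .3))
  expect_equal(devectorize(c(.1, .2, .3)), m3)

  # round-trip property over random sizes
  set.seed(7)
  for (C in c(2, 5, 10, 53)) {
    m <- random_sym_matrix(C)
    v <- vectorize_upper_triangle(m)
    expect_length(v, C * (C - 1) / 2)
    expect_equal(devectorize(v)[upper.tri(m)], m[upper.tri(m)])
    expect_equal(vectorize_upper_triangle(devectorize(v)), v)
  }
  expect_equal(dim(devectorize(numeric(1378))), c(53L, 53L))
  expect_equal(dim(devectorize(0.5)), c(2L, 2L))
})

test_that("invalid shapes are rejected", {
  m <- matrix(rnorm(9), 3, 3)
  expect_error(vectorize_upper_triangle(m), "asymmetric")
  expect_error(devectorize(numeric(4)), "triangular")
  expect_error(n_components_from_edges(5), "triangular")
  expect_identical(n_components_from_edges(1378L), 53L)
})

test_that("covariate regression matches the normal-equations oracle", {
  set.seed(11)
  n <- 20
  site <- rep(c("s1", "s2"), each = 10)
  feats <- matrix(rnorm(n * 6), n, 6)
  res <- regress_covariates(feats, data.frame(site = site))
  # oracle: explicit normal equations per column
  X <- cbind(1, as.numeric(site == "s2"))
  beta <- solve(t(X) %*% X, t(X) %*% feats)
  expect_equal(res, feats - X %*% beta, tolerance = 1e-8,
               ignore_attr = TRUE)
  # residuals orthogonal to design
  expect_lt(max(abs(t(X) %*% res)), 1e-6 * max(abs(feats)) * n)
  # idempotence
  expect_equal(regress_covariates(res, data.frame(site = site)), res,
               tolerance = 1e-8)
})

test_that("constant covariates mean-center; collinear designs are rejected", {
  set.seed(12)
  feats <- matrix(rnorm(30), 10, 3)
  out <- regress_covariates(feats, data.frame(site = rep("one", 10)))
  expect_equal(out, sweep(feats, 2, colMeans(feats)), ignore_attr = TRUE)

  # feature exactly linear in the site indicator -> residuals ~ 0
  site <- rep(c("a", "b"), 5)
  f2 <- cbind(2 + 3 * (site == "b"))
  expect_lt(max(abs(regress_covariates(f2, data.frame(site = site)))), 1e-10)

  dup <- data.frame(x = rnorm(10))
  dup$y <- 2 * dup$x
  expect_error(regress_covariates(feats, dup), "rank-deficient")
})

test_that("network block summary aggregates and conserves edge counts", {
  atl <- tiny_atlas()
  n_edges <- 12 * 11 / 2
  bs <- network_block_summary(rep(1, n_edges), atl)
  expect_true(all(bs$mean == 1, na.rm = TRUE))
  expect_equal(sum(bs$count[upper.tri(bs$count)]) + sum(diag(bs$count)), n_edges)

  # brute enumeration on a 3-component, 2-network atlas
  atl2 <- make_atlas(1:3, c("X", "X", "Y"))
  v <- c(10, 20, 30)  # edges (1,2), (1,3), (2,3)
  bs2 <- network_block_summary(v, atl2)
  expect_equal(bs2$count["X", "X"], 1L)
  expect_equal(bs2$count["X", "Y"], 2L)
  expect_equal(bs2$count["Y", "Y"], 0L)
  expect_equal(bs2$mean["X", "X"], 10)
  expect_equal(bs2$mean["X", "Y"], 25)

  expect_error(network_block_summary(rep(0, 10), atl), "does not match")
})

test_that("the default atlas has the canonical 53/7 composition", {
  atl <- default_atlas()
  expect_equal(unname(atl$component_counts),
               c(5L, 2L, 9L, 9L, 17L, 7L, 4L))
  expect_equal(atl$network_order, c("SC", "AU", "SM", "VI", "CC", "DM", "CB"))
  expect_equal(sum(atl$component_counts), 53L)
  # within-SC block holds choose(5,2) edges
  bs <- network_block_summary(rep(1, 1378), atl)
  expect_equal(bs$count["SC", "SC"], 10L)
})

test_that("scaler standardizes and is reusable across cohorts", {
  set.seed(5)
  X <- matrix(rnorm(200, mean = 3, sd = 2), 20, 10)
  sc <- fit_scaler(X)
  Xs <- apply_scaler(X, sc)
  expect_equal(colMeans(Xs), rep(0, 10), tolerance = 1e-12)
  expect_equal(apply(Xs, 2, sd), rep(1, 10), tolerance = 1e-12)
  # validation data uses the discovery scaler, not its own moments
  Y <- matrix(rnorm(50, mean = 10), 5, 10)
  expect_equal(apply_scaler(Y, sc), sweep(sweep(Y, 2, sc$center), 2, sc$scale, "/"))
})

test_that("manifest-driven FNC derivation round-trips through devectorize", {
  dir <- withr::local_tempdir()
  atl <- make_atlas(1:4, c("A", "A", "B", "B"))
  set.seed(9)
  ids <- c("s1", "s2")
  paths <- file.path(dir, paste0(ids, ".txt"))
  mats <- list()
  for (k in 1:2) {
    ts <- matrix(rnorm(4 * 30), 4)
    write.table(ts, paths[k], row.names = FALSE, col.names = FALSE)
    mats[[k]] <- compute_fnc_matrix(ts)
  }
  feats <- cohort_fnc_from_manifest(data.frame(subject_id = ids, path = paths),
                                    atlas = atl)
  expect_equal(dim(feats), c(2L, 6L))
  expect_equal(devectorize(feats["s1", ]), mats[[1]], tolerance = 1e-10)
  expect_error(
    cohort_fnc_from_manifest(data.frame(subject_id = "x", path = "no/such.txt"),
                             atlas = atl),
    "not found")
})
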