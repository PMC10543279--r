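test_that("pooled two-sample t matches the textbook oracle and is antisymmetric", {
  set.seed(70)
  a <- c(0, 0, 0, 1); b <- c(1, 1, 1, 0)
  got <- two_sample_t(a, b)
  want <- oracle_t_pooled(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$df, 6)
  # swap negates t, preserves p
  sw <- two_sample_t(b, a)
  expect_equal(sw$t, -got$t)
  expect_equal(sw$p, got$p)
  # identical groups -> t = 0, p = 1
  x <- rnorm(5)
  id <- two_sample_t(x, x)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("summary-statistic t agrees with the raw-data path", {
  # closed form: n=4 each, means 1 vs 0, sd 1 -> t = sqrt(2)
  tt <- two_sample_t_from_summary(summary_stats(4, 1, 1), summary_stats(4, 0, 1))
  expect_equal(tt$t, sqrt(2), tolerance = 1e-12)
  expect_equal(tt$df, 6)
  expect_equal(two_sample_t_from_summary(summary_stats(5, 2, 1),
                                         summary_stats(7, 2, 3))$t, 0)
  set.seed(71)
  for (r in 1:10) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = 0.5)
    raw <- two_sample_t(a, b)
    summ <- two_sample_t_from_summary(
      summary_stats(length(a), mean(a), sd(a)),
      summary_stats(length(b), mean(b), sd(b)))
    expect_equal(raw$t, summ$t, tolerance = 1e-10)
    expect_equal(raw$p, summ$p, tolerance = 1e-10)
  }
})

test_that("Cohen's d from summaries uses the RMS-SD denominator", {
  a <- summary_stats(821, 105.97, 15.81)
  b <- summary_stats(248, 101.62, 15.37)
  expect_equal(round(cohens_d_from_summary(a, b), 2), 0.28)
  fl_a <- summary_stats(821, 92.72, 17.00)
  fl_b <- summary_stats(248, 85.98, 16.32)
  expect_equal(round(cohens_d_from_summary(fl_a, fl_b), 2), 0.40)
  expect_equal(cohens_d_from_summary(summary_stats(5, 3, 1),
                                     summary_stats(5, 3, 2)), 0)
  # explicit formula check, both poolings
  x <- summary_stats(10, 1, 2); y <- summary_stats(30, 0, 1)
  expect_equal(cohens_d_from_summary(x, y), 1 / sqrt((4 + 1) / 2))
  expect_equal(cohens_d_from_summary(x, y, pooling = "n_weighted"),
               1 / sqrt((9 * 4 + 29 * 1) / 38))
  expect_error(cohens_d_from_summary(summary_stats(5, 1, 0),
                                     summary_stats(5, 0, 0)), "zero")
})

test_that("edge-wise t-tests flag degenerate edges and find planted signal", {
  set.seed(72)
  n <- 30
  X <- matrix(rnorm(n * 15), n, 15, dimnames = list(paste0("s", 1:n), NULL))
  X[, 4] <- X[, 4] + rep(c(3, 0), each = n / 2)  # planted shift on edge 4
  X[, 7] <- 0.5                                   # degenerate edge
  es <- edge_ttests(X, paste0("s", 1:15), paste0("s", 16:30))
  expect_equal(nrow(es), 15L)
  expect_false(es$valid[7])
  expect_true(es$valid[4])
  expect_equal(which.max(abs(es$t)), 4L)
  # each edge equals the scalar oracle
  for (e in c(1, 4, 9)) {
    want <- oracle_t_pooled(X[1:15, e], X[16:30, e])
    expect_equal(es$t[e], want$t, tolerance = 1e-10)
    expect_equal(es$p[e], want$p, tolerance = 1e-10)
  }
  # permuting subject order leaves statistics unchanged
  perm <- sample(n)
  es2 <- edge_ttests(X[perm, ], paste0("s", 1:15), paste0("s", 16:30))
  expect_equal(es2$t, es$t, tolerance = 1e-12)
  expect_error(edge_ttests(X, "s1", "s1"), "disjoint")
})

test_that("edge screen is calibrated under the null", {
  co <- generate_cohort(tiny_cohort_config(scale = 0, seed = 42,
                                           n_hc = 2, n_biotype1 = 40,
                                           n_biotype2 = 40))
  ids <- split(co$truth$subject_id, co$truth$group)
  es <- edge_ttests(co$features, ids$biotype1, ids$biotype2)
  frac <- mean(es$p < 0.05)
  m <- nrow(es)
  bounds <- 0.05 + c(-1, 1) * 2.58 * sqrt(0.05 * 0.95 / m)
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("top-k selection matches a sort oracle with index tie-breaks", {
  t_vals <- c(2, -5, 5, 0.1, -2, 4)
  es <- data.frame(edge = 1:6, i = 1, j = 2, network_i = NA, network_j = NA,
                   t = t_vals, p = 0.5, df = 10, valid = TRUE)
  sel <- top_k_edges(es, 3)
  expect_equal(sort(sel$edge), oracle_top_k(t_vals, 3))
  # tie between edges 2 (|t|=5) and 3 (|t|=5): smaller index first
  expect_equal(sel$edge[1:2], c(2L, 3L))
  # k = all -> identity selection; monotone transform of |t| leaves it alone
  expect_setequal(top_k_edges(es, 6)$edge, 1:6)
  es2 <- es; es2$t <- sign(es2$t) * exp(abs(es2$t))
  expect_equal(sort(top_k_edges(es2, 3)$edge), sort(sel$edge))
  expect_error(top_k_edges(es, 0), "k must be")
  expect_error(top_k_edges(es, 7), "exceeds")
})

test_that("edge overlap is symmetric set intersection", {
  set.seed(73)
  a <- sample(1378, 100); b <- sample(1378, 100)
  ov <- edge_overlap(a, b)
  expect_equal(ov$count, length(intersect(a, b)))
  expect_equal(edge_overlap(b, a)$count, ov$count)
  expect_equal(edge_overlap(a, a)$count, 100L)
  expect_equal(edge_overlap(1:10, 11:20)$count, 0L)
  # expected overlap under independence ~ 100*100/1378
  ovs <- replicate(200, edge_overlap(sample(1378, 100), sample(1378, 100))$count)
  expect_lt(abs(mean(ovs) - 100 * 100 / 1378), 1.5)
})

test_that("scale correlations match cor.test and handle missing data", {
  set.seed(74)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("s", 1:n), NULL))
  scl <- data.frame(subject_id = paste0("s", 1:n),
                    iq = 2 * X[, 1] + rnorm(n),
                    flat = rep(1, n))
  scl$iq[1:5] <- NA
  res <- scale_correlations(X, scl, edges = 1:2)
  r11 <- res[res$edge == 1 & res$scale == "iq", ]
  ok <- 6:n
  expect_equal(r11$r, oracle_pearson(X[ok, 1], scl$iq[ok]), tolerance = 1e-12)
  expect_equal(r11$n, 45)
  expect_false(res$valid[res$scale == "flat"][1])
  # affine scale -> |r| = 1
  scl2 <- data.frame(subject_id = paste0("s", 1:n), lin = -3 * X[, 2] + 7)
  res2 <- scale_correlations(X, scl2, edges = 2)
  expect_equal(abs(res2$r), 1, tolerance = 1e-12)
})

test_that("Bonferroni and BH adjustments match hand-stepped oracles", {
  expect_equal(bonferroni_adjust(0.01, m = 10), 0.1)
  expect_equal(bonferroni_adjust(0.5, m = 10), 1)
  set.seed(75)
  p <- runif(20)
  expect_equal(bonferroni_adjust(p, m = 25), oracle_bonferroni(p, 25))
  expect_error(bonferroni_adjust(p, m = 5), "at least")

  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 4)), rep(1, 4))
  for (r in 1:5) {
    p <- runif(sample(3:30, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("summary-table wrapper reproduces reported effect sizes", {
  tab <- summary_table_stats(
    system.file("extdata", "biotype_cognition_summary_discovery.tsv",
                package = "fncbiotype"))
  expect_equal(nrow(tab), 7L)
  expect_true(all(tab$p < 0.01))
  expect_equal(round(tab$cohens_d[tab$scale == "Fluid"], 2), 0.40)
})
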