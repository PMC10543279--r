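# Shared fixtures: a small 12-component / 3-network atlas keeps most tests
# fast; the full 53/7 atlas is reserved for the acceptance suite.

tiny_atlas <- function() {
  make_atlas(1:12, rep(c("A", "B", "C"), c(4, 4, 4)))
}

tiny_block_effects <- function(scale = 0.3) {
  nets <- c("A", "B", "C")
  blank <- matrix(0, 3, 3, dimnames = list(nets, nets))
  b1 <- blank
  b1["A", "A"] <- scale
  b1["B", "C"] <- b1["C", "B"] <- -scale
  b2 <- blank
  b2["A", "A"] <- -scale
  b2["B", "B"] <- scale
  b2["B", "C"] <- b2["C", "B"] <- scale
  list(biotype1 = b1, biotype2 = b2)
}

tiny_cohort_config <- function(scale = 0.3, seed = 1L, n_hc = 30L,
                               n_biotype1 = 20L, n_biotype2 = 12L, ...) {
  cohort_config(n_hc = n_hc, n_biotype1 = n_biotype1, n_biotype2 = n_biotype2,
                effect_size = tiny_block_effects(scale), atlas = tiny_atlas(),
                seed = seed, ...)
}

tiny_model_config <- function(input_dim, seed = 1L, ...) {
  args <- list(input_dim = input_dim, hidden = 32L, embedding = 8L, K = 2L,
               epochs = 120L, warmup_epochs = 30L, seed = seed)
  upd <- list(...)
  args[names(upd)] <- upd
  do.call(biotyper_config, args)
}

# standardized discovery graph + truth labels for a tiny cohort
tiny_discovery <- function(scale = 0.3, seed = 1L, feature_kernel = TRUE, ...) {
  co <- generate_cohort(tiny_cohort_config(scale = scale, seed = seed, ...))
  scaler <- fit_scaler(co$features)
  g <- build_graph(apply_scaler(co$features, scaler), co$phenotypes,
                   labels = co$phenotypes$diagnosis,
                   subject_ids = co$phenotypes$subject_id,
                   feature_kernel = feature_kernel)
  truth_pat <- co$truth$group[co$truth$group != "hc"]
  list(cohort = co, graph = g, scaler = scaler, truth_patients = truth_pat)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random symmetric correlation-like matrix with unit diagonal
random_sym_matrix <- function(C) {
  m <- matrix(stats::runif(C * C, -1, 1), C, C)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
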