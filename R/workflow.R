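#' End-to-end pipeline steps
#'
#' Exported functions tying the modules into the full flow — feature
#' derivation, biotype discovery, cross-cohort validation, discriminative
#' statistics, and longitudinal comparison — each writing its outputs plus a
#' run manifest (seed, config hash, input checksums, package version) to an
#' output directory. A thin command-line wrapper over these functions ships
#' in `inst/cli/fncbiotype-cli.R`.
#'
#' @name workflow
NULL

write_manifest <- function(out_dir, step, seed, config = NULL, inputs = character()) {
  cfg_hash <- NA_character_
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf), add = TRUE)
    saveRDS(unclass(config), tf)
    cfg_hash <- unname(tools::md5sum(tf))
  }
  checks <- vapply(inputs, function(p) {
    if (is.character(p) && length(p) == 1L && file.exists(p)) {
      unname(tools::md5sum(p))
    } else NA_character_
  }, character(1))
  manifest <- list(
    step = step, seed = seed, config_md5 = cfg_hash,
    inputs = as.list(checks),
    package_version = as.character(utils::packageVersion("fncbiotype")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Derive cohort FNC features from a time-course manifest
#'
#' @param manifest manifest TSV path (or data.frame) with `subject_id`,
#'   `path`.
#' @param out_dir output directory.
#' @param atlas a `network_atlas`.
#' @return the feature matrix, invisibly; writes `features.tsv` and a
#'   manifest.
#' @export
pipeline_features <- function(manifest, out_dir, atlas = default_atlas()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- cohort_fnc_from_manifest(manifest, atlas)
  tab <- data.frame(subject_id = rownames(feats), feats, check.names = FALSE)
  utils::write.table(tab, file.path(out_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "features", seed = NA,
                 inputs = if (is.character(manifest)) manifest else character())
  invisible(feats)
}

#' Discover biotypes on a cohort
#'
#' Standardizes the features, builds the population graph, selects K by the
#' elbow rule when not fixed, trains the graph-convolutional biotyper,
#' extracts raw-scale biotype templates and benchmarks against the
#' baselines.
#'
#' @param features subjects x edges matrix (raw correlation scale).
#' @param phenotypes data.frame with `subject_id`, `diagnosis`,
#'   `age_months`, `gender` (+ optional `site`, `scanner`).
#' @param out_dir output directory.
#' @param config optional `biotyper_config`; defaults are built for the
#'   data.
#' @param choose_k if `TRUE`, run the elbow rule on patient features over
#'   `k_range` and override `config$K`.
#' @param k_range candidate cluster counts for the elbow rule.
#' @param age_tol population-graph age tolerance (months).
#' @param feature_kernel weight phenotypic edges by FNC similarity (the
#'   standard population-graph construction; default `TRUE` here — a purely
#'   phenotypic graph over a demographically homogeneous cohort is close to
#'   complete and oversmooths).
#' @param benchmark also run the baseline comparison.
#' @param seed seed (overrides `config$seed`).
#' @return list with `state`, `templates`, `scaler`, `graph`, `sse_by_k`,
#'   `chosen_k`, `benchmark` (or NULL), `assignments` data.frame.
#' @export
pipeline_discover <- function(features, phenotypes, out_dir, config = NULL,
                              choose_k = FALSE, k_range = 1:6, age_tol = 24,
                              feature_kernel = TRUE,
                              benchmark = FALSE, seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  features <- as.matrix(features)
  phenotypes <- as.data.frame(phenotypes)
  ord <- match(rownames(features), phenotypes$subject_id)
  if (anyNA(ord)) stop("phenotypes missing for some subjects")
  phenotypes <- phenotypes[ord, , drop = FALSE]

  scaler <- fit_scaler(features)
  Xs <- apply_scaler(features, scaler)
  g <- build_graph(Xs, phenotypes, labels = phenotypes$diagnosis,
                   subject_ids = phenotypes$subject_id, age_tol = age_tol,
                   feature_kernel = feature_kernel)
  if (is.null(config)) {
    config <- biotyper_config(input_dim = ncol(features))
  }
  if (!is.null(seed)) config <- modify_config(config, seed = seed)

  sse <- NULL; chosen_k <- config$K
  if (choose_k) {
    gp <- patient_subgraph(g)
    sse <- sse_elbow_curve(gp$features, k_range, seed = config$seed)
    chosen_k <- choose_k_elbow(sse)
    config <- modify_config(config, K = chosen_k)
    utils::write.table(
      data.frame(K = as.integer(names(sse)), sse = unname(sse)),
      file.path(out_dir, "elbow_sse.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  state <- train_gcn_biotyper(g, config)
  templates <- extract_biotype_templates(features, state$assignments)
  assignments <- data.frame(subject_id = names(state$assignments),
                            biotype = unname(state$assignments))
  utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(state$loss_history, file.path(out_dir, "training_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tpl_tab <- data.frame(biotype = rownames(templates), templates,
                        check.names = FALSE)
  utils::write.table(tpl_tab, file.path(out_dir, "templates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  save_biotyper(state, file.path(out_dir, "checkpoint.rds"), scaler = scaler)

  bench <- NULL
  if (benchmark) {
    bench <- benchmark_methods(g, config, state = state)
    utils::write.table(bench, file.path(out_dir, "benchmark.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "discover", seed = config$seed, config = config)
  invisible(list(state = state, templates = templates, scaler = scaler,
                 graph = g, sse_by_k = sse, chosen_k = chosen_k,
                 benchmark = bench, assignments = assignments))
}

#' Project a validation cohort onto discovery templates
#'
#' Residualizes the validation features on site/scanner (when present),
#' projects every patient onto the templates by nearest Euclidean distance,
#' and quantifies replication of the biotype-vs-control difference patterns
#' when control labels are available.
#'
#' @param features validation subjects x edges matrix (correlation scale).
#' @param phenotypes validation phenotype table (`subject_id`, `diagnosis`,
#'   optional `site`/`scanner`).
#' @param templates `biotype_templates` (or path to a `templates.tsv`).
#' @param out_dir output directory.
#' @param discovery_patterns optional list of discovery mean-difference
#'   patterns (one per biotype) for replication correlations.
#' @param residualize regress site/scanner out of the features used for the
#'   *statistics* (projection always uses the raw correlation scale).
#' @return list with `projection` (data.frame), `replication` (data.frame or
#'   NULL).
#' @export
pipeline_validate <- function(features, phenotypes, templates, out_dir,
                              discovery_patterns = NULL, residualize = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  features <- as.matrix(features)
  phenotypes <- as.data.frame(phenotypes)
  if (is.character(templates)) {
    tab <- utils::read.delim(templates, check.names = FALSE)
    templates <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(templates) <- tab[[1L]]
  }
  ord <- match(rownames(features), phenotypes$subject_id)
  if (anyNA(ord)) stop("phenotypes missing for some subjects")
  phenotypes <- phenotypes[ord, , drop = FALSE]

  pat_ids <- phenotypes$subject_id[phenotypes$diagnosis == 1L]
  proj <- project_cohort(features[pat_ids, , drop = FALSE], templates)
  utils::write.table(proj, file.path(out_dir, "projection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  repl <- NULL
  hc_ids <- phenotypes$subject_id[phenotypes$diagnosis == 0L]
  if (!is.null(discovery_patterns) && length(hc_ids)) {
    stat_feats <- features
    if (residualize && all(c("site", "scanner") %in% names(phenotypes))) {
      stat_feats <- suppressMessages(regress_covariates(
        features, phenotypes[, c("site", "scanner"), drop = FALSE],
        drop_aliased = TRUE))
    }
    rows <- lapply(seq_len(nrow(templates)), function(k) {
      ids_k <- proj$subject_id[proj$biotype == k]
      if (!length(ids_k)) {
        return(data.frame(biotype = k, r = NA_real_, p = NA_real_, n_edges = NA))
      }
      pat_k <- mean_difference_pattern(stat_feats, ids_k, hc_ids)
      rc <- replication_correlation(discovery_patterns[[k]], pat_k)
      data.frame(biotype = k, r = rc$r, p = rc$p, n_edges = rc$n)
    })
    repl <- do.call(rbind, rows)
    utils::write.table(repl, file.path(out_dir, "replication.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "validate", seed = NA)
  invisible(list(projection = proj, replication = repl))
}

#' Edge statistics, effect sizes and scale correlations for assigned biotypes
#'
#' Runs per-biotype biotype-vs-control edge screens, selects the top-k
#' discriminative edges, aggregates them by network block, and tests
#' biotype differences on the supplied scales with Bonferroni correction.
#'
#' @param features subjects x edges matrix (correlation scale).
#' @param phenotypes phenotype table with `subject_id`, `diagnosis`.
#' @param assignments data.frame `subject_id`, `biotype` for the patients.
#' @param scales optional data.frame of per-subject scale scores.
#' @param out_dir output directory.
#' @param atlas a `network_atlas`.
#' @param k top-k edge count (default 100).
#' @param contrast `"vs_control"` (per-biotype vs controls, default) or
#'   `"between_biotypes"`.
#' @return list with `edge_stats` (per contrast), `top_edges`,
#'   `block_counts`, `scale_tests`.
#' @export
pipeline_stats <- function(features, phenotypes, assignments, scales = NULL,
                           out_dir, atlas = default_atlas(), k = 100L,
                           contrast = c("vs_control", "between_biotypes")) {
  contrast <- match.arg(contrast)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  features <- as.matrix(features)
  phenotypes <- as.data.frame(phenotypes)
  hc_ids <- phenotypes$subject_id[phenotypes$diagnosis == 0L]
  groups <- split(assignments$subject_id, assignments$biotype)

  contrasts <- if (contrast == "vs_control") {
    if (!length(hc_ids)) stop("vs_control contrast needs control subjects")
    stats::setNames(
      lapply(names(groups), function(k2) list(a = groups[[k2]], b = hc_ids)),
      paste0("biotype", names(groups), "_vs_hc"))
  } else {
    if (length(groups) < 2L) stop("between-biotype contrast needs 2 biotypes")
    list(biotype1_vs_biotype2 = list(a = groups[[1L]], b = groups[[2L]]))
  }

  edge_stats <- list(); top_edges <- list(); block_counts <- list()
  for (nm in names(contrasts)) {
    es <- edge_ttests(features, contrasts[[nm]]$a, contrasts[[nm]]$b,
                      atlas = atlas)
    te <- top_k_edges(es, k = min(k, sum(es$valid)))
    indicator <- as.numeric(es$edge %in% te$edge)
    bc <- network_block_summary(indicator, atlas)
    edge_stats[[nm]] <- es; top_edges[[nm]] <- te
    block_counts[[nm]] <- bc$mean * bc$count  # selected-edge counts per block
    es$selected <- es$edge %in% te$edge
    utils::write.table(es, file.path(out_dir, paste0("edges_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  scale_tests <- NULL
  if (!is.null(scales) && length(groups) >= 2L) {
    scales <- as.data.frame(scales)
    rownames(scales) <- scales$subject_id
    nm_scales <- setdiff(names(scales), "subject_id")
    rows <- lapply(nm_scales, function(s) {
      a <- scales[groups[[1L]], s]; b <- scales[groups[[2L]], s]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L) {
        return(data.frame(scale = s, t = NA, p = NA, cohens_d = NA,
                          flagged = TRUE))
      }
      tt <- two_sample_t(a, b)
      d <- cohens_d_from_summary(
        summary_stats(length(a), mean(a), stats::sd(a)),
        summary_stats(length(b), mean(b), stats::sd(b)))
      data.frame(scale = s, t = tt$t, p = tt$p, cohens_d = d, flagged = FALSE)
    })
    scale_tests <- do.call(rbind, rows)
    scale_tests$p_bonf <- NA_real_
    ok <- !scale_tests$flagged
    scale_tests$p_bonf[ok] <- bonferroni_adjust(scale_tests$p[ok])
    utils::write.table(scale_tests, file.path(out_dir, "scale_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_manifest(out_dir, "stats", seed = NA)
  invisible(list(edge_stats = edge_stats, top_edges = top_edges,
                 block_counts = block_counts, scale_tests = scale_tests))
}

#' Longitudinal treatment-response comparison for assigned biotypes
#'
#' @param longitudinal long-format table (`subject_id`, `scale`, `week`,
#'   `score`).
#' @param assignments data.frame `subject_id`, `biotype`.
#' @param phenotypes phenotype table carrying `medication` (for the
#'   biotype-by-medication grouping).
#' @param out_dir output directory.
#' @param grouping passed to [compare_groups_over_weeks()].
#' @param correction multiplicity correction (default FDR).
#' @return the contrast data.frame.
#' @export
pipeline_longitudinal <- function(longitudinal, assignments, phenotypes,
                                  out_dir, grouping = "biotype",
                                  correction = "fdr") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pheno <- merge(assignments,
                 phenotypes[, intersect(c("subject_id", "medication"),
                                        names(phenotypes)), drop = FALSE],
                 by = "subject_id", all.x = TRUE)
  res <- compare_groups_over_weeks(longitudinal, pheno, grouping = grouping,
                                   correction = correction)
  utils::write.table(res, file.path(out_dir, "longitudinal_contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "longitudinal", seed = NA)
  invisible(res)
}

#' Simulate a cohort and write it to disk
#'
#' @param out_dir output directory.
#' @param cfg a `cohort_config`.
#' @return the cohort, invisibly.
#' @export
pipeline_simulate <- function(out_dir, cfg = cohort_config()) {
  cohort <- generate_cohort(cfg)
  write_cohort(cohort, out_dir)
  write_manifest(out_dir, "simulate", seed = cfg$seed, config = cfg)
  invisible(cohort)
}
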