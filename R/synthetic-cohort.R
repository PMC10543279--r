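#' Synthetic cohorts with planted biotype structure
#'
#' Seeded generator emulating the study design every other module is tested
#' against: healthy controls plus two patient biotypes whose FNC differs by
#' network-block mean shifts, with site offsets, age/gender covariates,
#' biotype-linked cognitive scores, and longitudinal symptom trajectories
#' under two medication arms (the second biotype's improvement plateaus
#' after week 4). Truth labels are stored separately from anything an
#' analysis would see.
#'
#' @name synthetic-cohort
NULL

#' Default planted network-block effect patterns
#'
#' Two 7x7 symmetric block-shift matrices (correlation units) over the
#' default atlas networks, qualitatively mirroring the kind of biotype
#' contrast the pipeline is meant to detect: the first biotype gains
#' within-default-mode and sensorimotor/cognitive-control coupling and loses
#' sensorimotor-default-mode coupling; the second shows the broader,
#' partially opposite pattern.
#'
#' @param scale peak absolute shift (default 0.3, a strong planted effect).
#' @return list with elements `biotype1` and `biotype2` (7x7, default atlas
#'   network order).
#' @export
planted_block_effects <- function(scale = 0.3) {
  networks <- c("SC", "AU", "SM", "VI", "CC", "DM", "CB")
  nn <- length(networks)
  blank <- matrix(0, nn, nn, dimnames = list(networks, networks))
  set_block <- function(M, a, b, v) {
    M[a, b] <- M[b, a] <- v
    M
  }
  b1 <- blank
  b1 <- set_block(b1, "DM", "DM", scale)
  b1 <- set_block(b1, "SM", "CC", scale)
  b1 <- set_block(b1, "CC", "CB", scale)
  b1 <- set_block(b1, "VI", "SM", scale)
  b1 <- set_block(b1, "VI", "SC", scale)
  b1 <- set_block(b1, "SM", "DM", -scale)
  b1 <- set_block(b1, "VI", "CB", -scale)
  b2 <- blank
  b2 <- set_block(b2, "SM", "DM", scale)
  b2 <- set_block(b2, "VI", "CB", scale)
  b2 <- set_block(b2, "VI", "SM", -scale)
  b2 <- set_block(b2, "SM", "CB", -scale)
  b2 <- set_block(b2, "DM", "CB", -scale)
  b2 <- set_block(b2, "DM", "DM", -scale)
  list(biotype1 = b1, biotype2 = b2)
}

#' Synthetic cohort generator configuration
#'
#' Defaults emulate the discovery cohort at one tenth of its reported group
#' sizes (116 controls, 82 + 25 patients), two acquisition sites, ages 9-11
#' years, and strongly planted network-block effects.
#'
#' @param n_hc,n_biotype1,n_biotype2 group sizes (each >= 2).
#' @param effect_size list of two symmetric block-shift matrices over the
#'   atlas networks (see [planted_block_effects()]); use
#'   `planted_block_effects(0)` for a null cohort.
#' @param noise_sd edge noise standard deviation (correlation units).
#' @param n_sites number of sites; each contributes a small additive
#'   per-edge offset with standard deviation `site_sd`.
#' @param site_sd site offset scale.
#' @param age_range_months age range (uniform).
#' @param male_prop probability of gender "M".
#' @param cognition_loading named vector: mean cognitive deficit of the
#'   second biotype relative to the first, per scale (score units).
#' @param cognition_sd within-group score standard deviation.
#' @param hc_bonus mean cognitive advantage of controls over biotype 1.
#' @param long_scales named vector of baseline symptom-scale means for the
#'   longitudinal table.
#' @param long_noise_sd additive score noise for longitudinal records.
#' @param mph_prop probability a medicated patient receives MPH (vs ATX).
#' @param response list of per-biotype response parameters: `f_max`
#'   (asymptotic proportional reduction), `tau` (weeks), `plateau_week`
#'   (NA = none; improvement freezes after this week), `atx_factor`
#'   (multiplier on `f_max` under ATX).
#' @param atlas a `network_atlas` (block shifts are expanded through it).
#' @param pattern_seed seed of the shared baseline edge-mean pattern; cohort
#'   pairs drawn with the same `pattern_seed` share their planted pattern.
#' @param seed cohort RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_hc = 116L, n_biotype1 = 82L, n_biotype2 = 25L,
                          effect_size = planted_block_effects(0.3),
                          noise_sd = 0.1, n_sites = 2L, site_sd = 0.02,
                          age_range_months = c(108, 132), male_prop = 0.64,
                          cognition_loading = c(PVT = 4.4, LSWMT = 4.0,
                                                DCCST = 4.3, PCPST = 7.0,
                                                PSMT = 3.7, Fluid = 6.7,
                                                Total = 6.5),
                          cognition_sd = 15, hc_bonus = 3,
                          long_scales = c(RS_IN = 22, RS_HI = 20,
                                          RS_Total = 45, CPRS_LP = 8),
                          long_noise_sd = 2,
                          mph_prop = 0.6,
                          response = list(
                            biotype1 = list(f_max = 0.72, tau = 2.5,
                                            plateau_week = NA, atx_factor = 0.85),
                            biotype2 = list(f_max = 0.60, tau = 2.5,
                                            plateau_week = 4, atx_factor = 0.85)
                          ),
                          atlas = default_atlas(),
                          pattern_seed = 777L, seed = 1L) {
  if (min(n_hc, n_biotype1, n_biotype2) < 2L) stop("group sizes must be >= 2")
  if (!is.list(effect_size) ||
      !all(c("biotype1", "biotype2") %in% names(effect_size))) {
    stop("effect_size must be a list with biotype1 and biotype2 matrices")
  }
  nn <- length(atlas$network_order)
  for (nm in c("biotype1", "biotype2")) {
    M <- effect_size[[nm]]
    if (!is.matrix(M) || any(dim(M) != nn)) {
      stop("effect_size$", nm, " must be ", nn, "x", nn)
    }
    if (max(abs(M - t(M))) > 1e-10) stop("effect_size$", nm, " must be symmetric")
    if (max(abs(M)) > 0.9) {
      stop("planted shift exceeds 0.9; would be destroyed by clipping")
    }
  }
  if (noise_sd < 0 || site_sd < 0 || long_noise_sd < 0) {
    stop("noise parameters must be nonnegative")
  }
  structure(list(
    n_hc = as.integer(n_hc), n_biotype1 = as.integer(n_biotype1),
    n_biotype2 = as.integer(n_biotype2), effect_size = effect_size,
    noise_sd = noise_sd, n_sites = as.integer(n_sites), site_sd = site_sd,
    age_range_months = age_range_months, male_prop = male_prop,
    cognition_loading = cognition_loading, cognition_sd = cognition_sd,
    hc_bonus = hc_bonus, long_scales = long_scales,
    long_noise_sd = long_noise_sd, mph_prop = mph_prop, response = response,
    atlas = atlas, pattern_seed = as.integer(pattern_seed),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# expand a block-shift matrix to the canonical edge vector
block_shift_to_edges <- function(M, atlas) {
  C <- length(atlas$component_ids)
  net <- factor(atlas$network_of, levels = atlas$network_order)
  et <- edge_index_table(C)
  M[cbind(as.integer(net[et$i]), as.integer(net[et$j]))]
}

#' Generate a synthetic cohort
#'
#' Baseline edge means are drawn once from `pattern_seed` (shared across
#' groups and, for cohort pairs, across cohorts); biotype block shifts,
#' site offsets and independent Gaussian edge noise are added and the result
#' clipped to (-0.99, 0.99). Ages, genders, cognitive scores and
#' longitudinal symptom trajectories (exponential approach to a plateau,
#' frozen after `plateau_week` where set) are sampled per group. Fully
#' reproducible from the seeds.
#'
#' @param cfg a `cohort_config`.
#' @return a `synthetic_cohort`: list with `features` (subjects x edges,
#'   correlation scale), `phenotypes` (subject_id, diagnosis, age_months,
#'   gender, site, scanner, medication), `truth` (subject_id, group),
#'   `scales` (cognitive scores), `longitudinal` (long-format symptom
#'   scores), `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  atlas <- cfg$atlas
  C <- length(atlas$component_ids)
  n_edges <- C * (C - 1L) / 2L
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }

  set.seed(cfg$pattern_seed)
  mu <- pmin(pmax(stats::rnorm(n_edges, 0.1, 0.12), -0.6), 0.7)

  set.seed(cfg$seed)
  n <- c(hc = cfg$n_hc, biotype1 = cfg$n_biotype1, biotype2 = cfg$n_biotype2)
  N <- sum(n)
  group <- rep(names(n), n)
  ids <- sprintf("sub%04d", seq_len(N))

  shift <- rbind(
    hc = rep(0, n_edges),
    biotype1 = block_shift_to_edges(cfg$effect_size$biotype1, atlas),
    biotype2 = block_shift_to_edges(cfg$effect_size$biotype2, atlas)
  )
  site <- sample.int(cfg$n_sites, N, replace = TRUE)
  site_offsets <- matrix(stats::rnorm(cfg$n_sites * n_edges, 0, cfg$site_sd),
                         cfg$n_sites, n_edges)
  X <- matrix(mu, N, n_edges, byrow = TRUE) +
    shift[group, , drop = FALSE] +
    site_offsets[site, , drop = FALSE] +
    matrix(stats::rnorm(N * n_edges, 0, cfg$noise_sd), N, n_edges)
  X <- pmin(pmax(X, -0.99), 0.99)
  rownames(X) <- ids
  colnames(X) <- edge_names(C)

  age <- stats::runif(N, cfg$age_range_months[1L], cfg$age_range_months[2L])
  gender <- ifelse(stats::runif(N) < cfg$male_prop, "M", "F")
  diagnosis <- as.integer(group != "hc")
  medication <- rep("none", N)
  pat <- which(diagnosis == 1L)
  medication[pat] <- ifelse(stats::runif(length(pat)) < cfg$mph_prop,
                            "MPH", "ATX")
  # two scanners per site so site and scanner are not confounded
  scanner <- (site - 1L) * 2L + sample.int(2L, N, replace = TRUE)
  phenotypes <- data.frame(
    subject_id = ids, diagnosis = diagnosis, age_months = age,
    gender = gender, site = paste0("site", site),
    scanner = paste0("scanner", scanner), medication = medication
  )

  scales <- data.frame(subject_id = ids)
  for (s in names(cfg$cognition_loading)) {
    base <- 100 + cfg$hc_bonus * (group == "hc") -
      cfg$cognition_loading[[s]] * (group == "biotype2")
    scales[[s]] <- stats::rnorm(N, base, cfg$cognition_sd)
  }

  weeks <- c(0, 1, 2, 3, 4, 8)
  long_rows <- vector("list", 0L)
  for (i in pat) {
    g <- group[i]
    rsp <- cfg$response[[g]]
    f_arm <- rsp$f_max * if (medication[i] == "ATX") rsp$atx_factor else 1
    w_eff <- if (is.na(rsp$plateau_week)) weeks else pmin(weeks, rsp$plateau_week)
    frac <- f_arm * (1 - exp(-w_eff / rsp$tau))
    for (s in names(cfg$long_scales)) {
      base_s <- max(stats::rnorm(1, cfg$long_scales[[s]],
                                 cfg$long_scales[[s]] * 0.15), 1)
      score <- base_s * (1 - frac) +
        c(0, stats::rnorm(length(weeks) - 1L, 0, cfg$long_noise_sd))
      score <- pmax(score, 0)
      long_rows[[length(long_rows) + 1L]] <- data.frame(
        subject_id = ids[i], scale = s, week = weeks, score = score)
    }
  }
  longitudinal <- if (length(long_rows)) {
    do.call(rbind, long_rows)
  } else {
    data.frame(subject_id = character(), scale = character(),
               week = numeric(), score = numeric())
  }

  structure(list(
    features = X, phenotypes = phenotypes,
    truth = data.frame(subject_id = ids, group = group),
    scales = scales, longitudinal = longitudinal, config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$features), "subjects x",
      ncol(x$features), "edges;")
  print(table(x$truth$group))
  invisible(x)
}

#' Generate a discovery / validation cohort pair
#'
#' Two independent cohorts sharing the planted block-effect pattern and the
#' baseline edge means (same `pattern_seed`), emulating a discovery cohort
#' plus an independently acquired validation cohort. Overrides may change
#' group sizes, noise, sites, or the seed of the validation cohort.
#'
#' @param cfg `cohort_config` for the discovery cohort.
#' @param overrides named list of config fields to change for the validation
#'   cohort (its `seed` defaults to `cfg$seed + 10000`).
#' @return list with `discovery` and `validation` cohorts.
#' @export
generate_cohort_pair <- function(cfg, overrides = list()) {
  stopifnot(inherits(cfg, "cohort_config"))
  args <- unclass(cfg)
  if (is.null(overrides$seed)) overrides$seed <- cfg$seed + 10000L
  args[names(overrides)] <- overrides
  cfg_val <- do.call(cohort_config, args)
  list(discovery = generate_cohort(cfg), validation = generate_cohort(cfg_val))
}

#' Write a synthetic cohort to delimited files
#'
#' Emits the exact formats the pipeline consumes: `features.tsv` (subject_id
#' plus one column per canonical edge), `phenotypes.tsv`, `scales.tsv`,
#' `longitudinal.tsv`, and `truth.tsv` (kept separate from analysis inputs).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feat <- data.frame(subject_id = rownames(cohort$features),
                     cohort$features, check.names = FALSE)
  utils::write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in c("phenotypes", "scales", "longitudinal", "truth")) {
    utils::write.table(cohort[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort feature matrix written by [write_cohort()]
#'
#' @param path `features.tsv` path.
#' @return subjects x edges numeric matrix with subject ids as rownames.
#' @export
read_cohort_features <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m
}
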