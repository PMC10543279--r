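#' Functional network connectivity (FNC) features
#'
#' FNC summarises a subject's resting-state activity as the Pearson
#' correlation between the time courses of independent component networks
#' (ICNs). With `C` components the correlation matrix is `C x C`; its strict
#' upper triangle, read row by row, is the subject's FNC feature vector of
#' length `C*(C-1)/2` (1378 for the default 53-component atlas). All modules
#' in this package share that canonical edge order.
#'
#' @name fnc-features
NULL

#' Pearson FNC matrix from component time courses
#'
#' @param ts numeric matrix, `C` components (rows) by `T` timepoints
#'   (columns), `C >= 2`, `T >= 3`, no missing values.
#' @param subject_id optional subject identifier used in diagnostics.
#' @return symmetric `C x C` correlation matrix with unit diagonal.
#' @examples
#' ts <- matrix(rnorm(5 * 20), nrow = 5)
#' m <- compute_fnc_matrix(ts)
#' all(diag(m) == 1)
#' @export
compute_fnc_matrix <- function(ts, subject_id = NULL) {
  if (!is.matrix(ts) || !is.numeric(ts)) {
    stop("time courses must be a numeric matrix (components x timepoints)")
  }
  if (nrow(ts) < 2L) stop("need at least 2 components")
  if (ncol(ts) < 3L) stop("need at least 3 timepoints")
  if (anyNA(ts) || any(!is.finite(ts))) {
    stop("time courses contain missing or non-finite values",
         if (!is.null(subject_id)) paste0(" (subject ", subject_id, ")") else "")
  }
  v <- apply(ts, 1L, stats::var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    stop("zero-variance component(s): ", paste(bad, collapse = ", "),
         if (!is.null(subject_id)) paste0(" (subject ", subject_id, ")") else "")
  }
  m <- stats::cor(t(ts))
  # enforce exact symmetry / unit diagonal against rounding in cor()
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Canonical row-major order: (1,2), (1,3), ..., (1,C), (2,3), ...
#'
#' @param m symmetric numeric matrix.
#' @param tol symmetry tolerance.
#' @return numeric vector of length `C*(C-1)/2`.
#' @export
vectorize_upper_triangle <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  if (nrow(m) < 2L) stop("matrix must be at least 2 x 2")
  if (max(abs(m - t(m))) > tol) {
    stop("matrix is asymmetric beyond tolerance ", format(tol))
  }
  # t(m)[lower.tri(m)] walks the upper triangle in row-major order
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric unit-diagonal matrix from an FNC vector
#'
#' Inverse of [vectorize_upper_triangle()].
#'
#' @param v numeric vector whose length is `C*(C-1)/2` for an integer `C >= 2`.
#' @return symmetric `C x C` matrix with unit diagonal.
#' @export
devectorize <- function(v) {
  n <- length(v)
  if (n < 1L) stop("empty vector")
  C <- (1 + sqrt(1 + 8 * n)) / 2
  if (abs(C - round(C)) > 1e-9) {
    stop("length ", n, " is not a triangular number C*(C-1)/2")
  }
  C <- as.integer(round(C))
  m <- matrix(0, C, C)
  m[lower.tri(m)] <- v          # fills column-major lower = row-major upper
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  m
}

#' Number of components implied by an FNC vector length
#' @param n_edges integer edge count.
#' @return integer component count `C`.
#' @export
n_components_from_edges <- function(n_edges) {
  C <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (abs(C - round(C)) > 1e-9) stop("not a triangular number: ", n_edges)
  as.integer(round(C))
}

#' Canonical edge index table
#'
#' @param C component count.
#' @return data.frame with columns `edge`, `i`, `j` (component indices,
#'   `i < j`) in canonical row-major upper-triangle order.
#' @export
edge_index_table <- function(C) {
  stopifnot(C >= 2)
  i <- rep(seq_len(C - 1L), times = (C - 1L):1L)
  j <- unlist(lapply(seq_len(C - 1L), function(a) (a + 1L):C))
  data.frame(edge = seq_along(i), i = i, j = j)
}

#' Edge names of the form "icn03_icn17"
#' @param C component count.
#' @return character vector of canonical edge names.
#' @export
edge_names <- function(C) {
  et <- edge_index_table(C)
  sprintf("icn%02d_icn%02d", et$i, et$j)
}

#' The default 53-component / 7-network atlas
#'
#' Components are grouped into seven functional domains in the fixed order
#' SC (subcortical, 5), AU (auditory, 2), SM (sensorimotor, 9),
#' VI (visual, 9), CC (cognitive control, 17), DM (default mode, 7),
#' CB (cerebellar, 4).
#'
#' @return a `network_atlas` object: list with `component_ids`, `network_of`
#'   (character vector, one network per component), `network_order`,
#'   `component_counts`.
#' @export
default_atlas <- function() {
  path <- system.file("extdata", "atlas_53icn_7networks.tsv",
                      package = "fncbiotype", mustWork = TRUE)
  read_atlas(path)
}

#' Read a component-to-network atlas from a two-column TSV
#'
#' @param path TSV with columns `component_id`, `network_name`.
#' @param network_order optional explicit network ordering; defaults to the
#'   order of first appearance.
#' @return a `network_atlas` object.
#' @export
read_atlas <- function(path, network_order = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("component_id", "network_name") %in% names(tab))) {
    stop("atlas file must have columns component_id, network_name")
  }
  make_atlas(tab$component_id, tab$network_name, network_order)
}

#' Construct a network atlas
#'
#' @param component_ids integer component ids (atlas order defines canonical
#'   component order).
#' @param networks character network name per component.
#' @param network_order optional network ordering.
#' @return a `network_atlas` object.
#' @export
make_atlas <- function(component_ids, networks, network_order = NULL) {
  if (length(component_ids) != length(networks)) {
    stop("component_ids and networks must have equal length")
  }
  if (anyDuplicated(component_ids)) stop("duplicate component ids in atlas")
  if (anyNA(networks) || any(networks == "")) stop("unmapped component in atlas")
  if (is.null(network_order)) network_order <- unique(networks)
  if (!all(networks %in% network_order)) {
    stop("networks not covered by network_order: ",
         paste(setdiff(networks, network_order), collapse = ", "))
  }
  counts <- table(factor(networks, levels = network_order))
  structure(list(
    component_ids = as.integer(component_ids),
    network_of = as.character(networks),
    network_order = network_order,
    component_counts = stats::setNames(as.integer(counts), network_order)
  ), class = "network_atlas")
}

#' @export
print.network_atlas <- function(x, ...) {
  cat("network_atlas:", length(x$component_ids), "components,",
      length(x$network_order), "networks\n")
  print(x$component_counts)
  invisible(x)
}

#' Residualize features on nuisance covariates
#'
#' Each feature column is replaced by the residuals of an ordinary
#' least-squares fit on the covariates plus an intercept (site/scanner
#' regression). Constant covariate columns are absorbed by the intercept and
#' dropped; a genuinely rank-deficient design is rejected.
#'
#' @param features numeric matrix, subjects x features.
#' @param covariates data.frame or matrix of nuisance covariates aligned with
#'   the feature rows; character/factor columns are expanded to indicator
#'   columns.
#' @param drop_aliased drop linearly dependent covariate columns (with a
#'   message) instead of rejecting the design — needed e.g. when scanners
#'   are nested within sites.
#' @return matrix of residuals, same shape and dimnames as `features`.
#' @export
regress_covariates <- function(features, covariates, drop_aliased = FALSE) {
  features <- as.matrix(features)
  X <- build_design(covariates, nrow(features))
  qr_x <- qr(X, LAPACK = FALSE)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]]
    if (!drop_aliased) {
      stop("rank-deficient covariate design; offending column(s): ",
           paste(aliased, collapse = ", "))
    }
    message("dropping aliased covariate column(s): ",
            paste(aliased, collapse = ", "))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  res <- stats::resid(stats::lm.fit(X, features))
  res <- as.matrix(res)
  dimnames(res) <- dimnames(features)
  res
}

# Intercept + expanded covariate columns; constant columns dropped.
build_design <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (nrow(covariates) != n) stop("covariate rows do not align with subjects")
  cols <- list("(Intercept)" = rep(1, n))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      lev <- sort(unique(v))
      if (length(lev) < 2L) next  # constant -> intercept
      for (l in lev[-1L]) cols[[paste0(nm, l)]] <- as.numeric(v == l)
    } else {
      if (anyNA(v)) stop("missing values in covariate ", nm)
      if (stats::var(v) == 0) next
      cols[[nm]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}

#' Fit / apply feature standardization
#'
#' Z-scores each feature over the discovery subjects; the fitted scaler is
#' reused unchanged on validation cohorts so both live in the same space.
#' Zero-variance features get unit scale (centred only).
#'
#' @param features subjects x features matrix.
#' @return `fit_scaler`: a `feature_scaler` (list with `center`, `scale`).
#' @export
fit_scaler <- function(features) {
  features <- as.matrix(features)
  ctr <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  structure(list(center = ctr, scale = sdv), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @export
apply_scaler <- function(features, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  features <- as.matrix(features)
  if (ncol(features) != length(scaler$center)) {
    stop("feature dimension does not match scaler")
  }
  sweep(sweep(features, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' Optional Fisher z-transform of correlation features
#'
#' Off by default throughout the pipeline; raw Pearson r is the feature.
#'
#' @param v correlations in (-1, 1).
#' @return atanh-transformed values.
#' @export
fisher_z <- function(v) {
  if (any(abs(v) >= 1)) stop("Fisher transform requires |r| < 1")
  atanh(v)
}

#' Aggregate edge values into network-by-network blocks
#'
#' @param edge_values numeric vector in canonical edge order (length
#'   `C*(C-1)/2` for the atlas' `C`).
#' @param atlas a `network_atlas`.
#' @return list with `mean` and `count`: symmetric `n_networks x n_networks`
#'   matrices. Block (a, b) aggregates the edges with one endpoint in each
#'   network; counts sum to the total edge count.
#' @export
network_block_summary <- function(edge_values, atlas) {
  stopifnot(inherits(atlas, "network_atlas"))
  C <- length(atlas$component_ids)
  n_edges <- C * (C - 1L) / 2L
  if (length(edge_values) != n_edges) {
    stop("edge vector length ", length(edge_values),
         " does not match atlas (expected ", n_edges, ")")
  }
  net <- factor(atlas$network_of, levels = atlas$network_order)
  et <- edge_index_table(C)
  a <- as.integer(net[et$i])
  b <- as.integer(net[et$j])
  lo <- pmin(a, b); hi <- pmax(a, b)
  nn <- length(atlas$network_order)
  sums <- matrix(0, nn, nn, dimnames = list(atlas$network_order, atlas$network_order))
  cnts <- matrix(0L, nn, nn, dimnames = dimnames(sums))
  key <- (lo - 1L) * nn + hi
  agg_s <- tapply(edge_values, key, sum)
  agg_n <- tapply(edge_values, key, length)
  for (k in seq_along(agg_s)) {
    idx <- as.integer(names(agg_s)[k])
    i <- (idx - 1L) %/% nn + 1L
    j <- (idx - 1L) %% nn + 1L
    sums[i, j] <- sums[j, i] <- agg_s[k]
    cnts[i, j] <- cnts[j, i] <- as.integer(agg_n[k])
  }
  means <- sums / ifelse(cnts == 0, NA, cnts)
  list(mean = means, count = cnts)
}

#' Compute cohort FNC features from a manifest of time-course files
#'
#' Reads one delimited numeric matrix (components x timepoints) per subject,
#' computes the Pearson FNC matrix and vectorizes it. Subjects whose FNC
#' contains non-finite entries fail QC and are dropped with a message.
#'
#' @param manifest data.frame with columns `subject_id`, `path`, or path to a
#'   TSV with those columns.
#' @param atlas a `network_atlas`; component count must match the data.
#' @return subjects x edges matrix with rownames = subject ids and colnames =
#'   canonical edge names.
#' @export
cohort_fnc_from_manifest <- function(manifest, atlas = default_atlas()) {
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  if (!all(c("subject_id", "path") %in% names(manifest))) {
    stop("manifest needs columns subject_id, path")
  }
  C <- length(atlas$component_ids)
  rows <- list()
  for (k in seq_len(nrow(manifest))) {
    sid <- as.character(manifest$subject_id[k])
    p <- manifest$path[k]
    if (!file.exists(p)) stop("time-course file not found: ", p)
    ts <- as.matrix(utils::read.table(p))
    if (nrow(ts) != C) {
      stop("subject ", sid, ": ", nrow(ts), " components, atlas has ", C)
    }
    v <- vectorize_upper_triangle(compute_fnc_matrix(ts, subject_id = sid))
    if (any(!is.finite(v))) {
      message("dropping subject ", sid, ": non-finite FNC entries (QC fail)")
      next
    }
    rows[[sid]] <- v
  }
  if (!length(rows)) stop("no subjects passed FNC QC")
  out <- do.call(rbind, rows)
  colnames(out) <- edge_names(C)
  out
}
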