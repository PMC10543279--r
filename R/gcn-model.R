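#' Graph-convolutional biotyper
#'
#' The core model is a graph-convolutional autoencoder over the population
#' graph with two auxiliary heads, trained by minimizing
#'
#'   L = gamma1 * L_rec + gamma2 * L_CE + gamma3 * L_cluster
#'
#' where `L_rec` is the mean-squared feature reconstruction error over all
#' subjects, `L_CE` the mean binary cross-entropy of a linear+logistic
#' diagnosis head on the embeddings (patients vs. controls), and `L_cluster`
#' a deep-K-means loss (mean squared distance of each patient embedding to
#' its assigned centroid) evaluated on the patient subgraph only. Each
#' graph-convolutional layer computes `act(S H W)` with `S` the symmetric
#' renormalized operator from [normalize_adjacency()]; hidden layers use a
#' rectifier, the embedding and reconstruction layers are linear. Training
#' uses Adam, a warm-up phase without the clustering term, farthest-point
#' centroid seeding on the warm-up embeddings, and periodic hard
#' reassignment/centroid refresh.
#'
#' @name gcn-biotyper
NULL

#' Model configuration
#'
#' @param input_dim feature dimension (1378 for the default atlas).
#' @param hidden integer vector of hidden encoder widths (decoder mirrors).
#' @param embedding embedding dimension `d` (must be >= `K`).
#' @param K number of biotypes (clusters).
#' @param gamma1,gamma2,gamma3 nonnegative loss weights; defaults 0.1, 0.5, 1.
#' @param learning_rate Adam step size; default 0.001.
#' @param epochs total training epochs; default 300.
#' @param warmup_epochs epochs trained with the clustering term off before
#'   centroids are seeded; default 50.
#' @param centroid_update_period epochs between assignment/centroid
#'   refreshes; default 5.
#' @param cluster_assignment `"hard"` (alternating minimization, default) or
#'   `"soft"` (soft-min responsibilities at temperature `temperature`).
#' @param temperature soft-assignment temperature (ignored for hard).
#' @param seed RNG seed controlling weight initialization.
#' @return a `biotyper_config` list.
#' @export
biotyper_config <- function(input_dim, hidden = 256L, embedding = 64L, K = 2L,
                            gamma1 = 0.1, gamma2 = 0.5, gamma3 = 1,
                            learning_rate = 0.001, epochs = 300L,
                            warmup_epochs = 50L, centroid_update_period = 5L,
                            cluster_assignment = c("hard", "soft"),
                            temperature = 1, seed = 1L) {
  cluster_assignment <- match.arg(cluster_assignment)
  if (any(c(gamma1, gamma2, gamma3) < 0)) stop("loss weights must be nonnegative")
  if (learning_rate <= 0) stop("learning rate must be positive")
  if (K < 2L) stop("K must be >= 2")
  if (embedding < K) stop("embedding dimension must be >= K")
  if (epochs < 1L || warmup_epochs < 0L || warmup_epochs >= epochs) {
    stop("need 0 <= warmup_epochs < epochs")
  }
  structure(list(
    input_dim = as.integer(input_dim), hidden = as.integer(hidden),
    embedding = as.integer(embedding), K = as.integer(K),
    gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
    learning_rate = learning_rate, epochs = as.integer(epochs),
    warmup_epochs = as.integer(warmup_epochs),
    centroid_update_period = as.integer(centroid_update_period),
    cluster_assignment = cluster_assignment, temperature = temperature,
    seed = as.integer(seed)
  ), class = "biotyper_config")
}

# ---- layer plumbing ---------------------------------------------------------

relu <- function(x) pmax(x, 0)

glorot_init <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

init_weights <- function(config) {
  enc_dims <- c(config$input_dim, config$hidden, config$embedding)
  dec_dims <- rev(enc_dims)
  enc <- lapply(seq_len(length(enc_dims) - 1L), function(l) {
    glorot_init(enc_dims[l], enc_dims[l + 1L])
  })
  dec <- lapply(seq_len(length(dec_dims) - 1L), function(l) {
    glorot_init(dec_dims[l], dec_dims[l + 1L])
  })
  cls_w <- glorot_init(config$embedding, 1L)
  list(enc = enc, dec = dec, cls_w = cls_w, cls_b = 0)
}

# Forward through a graph-convolutional stack. Hidden layers relu, final
# linear. Returns activations plus the cached propagated inputs S %*% H
# needed for the backward pass. `SX` short-circuits the (expensive, constant)
# first propagation when the input never changes across epochs.
gcn_stack_forward <- function(S, X, weights, SX = NULL) {
  L <- length(weights)
  H <- vector("list", L + 1L); M <- vector("list", L); A <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    M[[l]] <- if (l == 1L && !is.null(SX)) SX else S %*% H[[l]]
    A[[l]] <- M[[l]] %*% weights[[l]]
    H[[l + 1L]] <- if (l < L) relu(A[[l]]) else A[[l]]
  }
  list(out = H[[L + 1L]], H = H, M = M, A = A)
}

# Backward: given dOut (gradient w.r.t. the stack output), return gradients
# for each weight matrix and for the stack input.
gcn_stack_backward <- function(S, fwd, weights, dOut, need_input_grad = TRUE) {
  L <- length(weights)
  dW <- vector("list", L)
  dH <- dOut
  for (l in L:1) {
    dA <- if (l < L) dH * (fwd$A[[l]] > 0) else dH
    dW[[l]] <- crossprod(fwd$M[[l]], dA)
    if (l > 1L || need_input_grad) {
      dH <- S %*% tcrossprod(dA, weights[[l]])
    }
  }
  list(dW = dW, dInput = if (need_input_grad) dH else NULL)
}

# ---- exported forward ops ---------------------------------------------------

#' Encode node features into embeddings
#'
#' Applies a graph-convolutional stack `act(S H W_l)` (rectifier on hidden
#' layers, linear final layer) to the node features.
#'
#' @param operator normalized graph operator from [normalize_adjacency()].
#' @param features `N x p` feature matrix.
#' @param weights list of layer weight matrices (input to embedding).
#' @return `N x d` embedding matrix.
#' @export
encode <- function(operator, features, weights) {
  check_stack_dims(operator, features, weights)
  gcn_stack_forward(operator, features, weights)$out
}

#' Decode embeddings back to feature space
#'
#' Mirror-architecture graph-convolutional stack mapping embeddings to
#' reconstructed features.
#'
#' @param operator normalized graph operator.
#' @param Z `N x d` embedding matrix.
#' @param weights list of decoder weight matrices (embedding to input).
#' @return `N x p` reconstruction.
#' @export
decode <- function(operator, Z, weights) {
  check_stack_dims(operator, Z, weights)
  gcn_stack_forward(operator, Z, weights)$out
}

check_stack_dims <- function(operator, X, weights) {
  if (nrow(operator) != ncol(operator)) stop("operator must be square")
  if (nrow(X) != nrow(operator)) stop("operator and features are inconsistent")
  din <- ncol(X)
  for (l in seq_along(weights)) {
    if (nrow(weights[[l]]) != din) {
      stop("weight layer ", l, " expects input dim ", nrow(weights[[l]]),
           ", got ", din)
    }
    din <- ncol(weights[[l]])
  }
  invisible(TRUE)
}

# ---- losses -----------------------------------------------------------------

#' Mean-squared reconstruction loss
#' @param X,Xhat equal-shape numeric matrices.
#' @return mean of squared entrywise differences.
#' @export
reconstruction_loss <- function(X, Xhat) {
  if (!all(dim(X) == dim(Xhat))) stop("shape mismatch")
  if (any(!is.finite(X)) || any(!is.finite(Xhat))) stop("non-finite input")
  mean((X - Xhat)^2)
}

#' Binary cross-entropy diagnosis loss
#'
#' A single fully connected layer plus logistic link on the embeddings
#' predicts patient vs. control; the loss is the mean binary cross-entropy
#' over all subjects. Probabilities are clipped at `eps` for stability.
#'
#' @param Z `N x d` embeddings.
#' @param labels binary 0/1 vector of length `N`.
#' @param head list with elements `w` (`d x 1`) and `b` (scalar).
#' @param eps probability clip.
#' @return nonnegative scalar loss.
#' @export
classification_loss <- function(Z, labels, head, eps = 1e-7) {
  labels <- as.numeric(labels)
  if (length(labels) != nrow(Z)) stop("labels do not align with embeddings")
  if (length(unique(labels)) < 2L) {
    warning("single-class label vector; classification loss is degenerate")
  }
  p <- stats::plogis(drop(Z %*% head$w) + head$b)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Deep K-means clustering loss
#'
#' Mean squared Euclidean distance of each patient embedding to its assigned
#' centroid.
#'
#' @param Z_patients `n x d` patient embeddings.
#' @param centroids `K x d` centroid matrix.
#' @param assignments integer vector in `1..K`.
#' @return nonnegative scalar.
#' @export
deep_kmeans_loss <- function(Z_patients, centroids, assignments) {
  K <- nrow(centroids)
  if (length(assignments) != nrow(Z_patients)) stop("assignment length mismatch")
  if (!all(assignments %in% seq_len(K))) stop("assignments out of 1..K")
  if (!all(seq_len(K) %in% assignments)) {
    stop("empty cluster at evaluation: ",
         paste(setdiff(seq_len(K), assignments), collapse = ", "))
  }
  diffs <- Z_patients - centroids[assignments, , drop = FALSE]
  mean(rowSums(diffs^2))
}

#' Weighted total loss
#' @param l_rec,l_ce,l_cluster finite component losses.
#' @param config a `biotyper_config` (only the gammas are used).
#' @return `gamma1*l_rec + gamma2*l_ce + gamma3*l_cluster`.
#' @export
total_loss <- function(l_rec, l_ce, l_cluster, config) {
  if (!all(is.finite(c(l_rec, l_ce, l_cluster)))) stop("non-finite loss component")
  config$gamma1 * l_rec + config$gamma2 * l_ce + config$gamma3 * l_cluster
}

# ---- centroid machinery -----------------------------------------------------

# squared-distance matrix points (n x d) vs centers (K x d)
sqdist_to_centers <- function(P, M) {
  D <- outer(rowSums(P^2), rowSums(M^2), "+") - 2 * tcrossprod(P, M)
  pmax(D, 0)
}

#' Greedy farthest-point centroid seeding
#'
#' First centroid is the point farthest from the data mean; each subsequent
#' centroid is the point maximizing its distance to the nearest already
#' chosen centroid. Deterministic; ties broken by lowest point index.
#'
#' @param points `n x d` matrix.
#' @param K number of seeds (`K <= n`).
#' @return `K x d` matrix of seed points.
#' @export
farthest_point_seeds <- function(points, K) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (K > n) stop("K exceeds number of points")
  chosen <- integer(K)
  ctr <- colMeans(points)
  d2 <- rowSums(sweep(points, 2L, ctr, "-")^2)
  chosen[1L] <- which.max(d2)
  mind <- rowSums(sweep(points, 2L, points[chosen[1L], ], "-")^2)
  if (K > 1L) for (k in 2:K) {
    chosen[k] <- which.max(mind)
    dk <- rowSums(sweep(points, 2L, points[chosen[k], ], "-")^2)
    mind <- pmin(mind, dk)
  }
  points[chosen, , drop = FALSE]
}

#' One hard K-means update on fixed embeddings
#'
#' Reassigns every point to its nearest centroid (Euclidean; ties to the
#' lowest centroid index) and then recomputes each centroid as the mean of
#' its assigned points. With the embeddings fixed, the update never increases
#' [deep_kmeans_loss()]. A cluster left empty after reassignment is re-seeded
#' at the point farthest from its nearest centroid (logged via `message()`);
#' re-seeding is the one case where the loss may move up.
#'
#' @param Z_patients `n x d` patient embeddings.
#' @param centroids `K x d` centroids.
#' @return list with `centroids`, `assignments`, `reseeded` (logical).
#' @export
update_centroids_and_assignments <- function(Z_patients, centroids) {
  Z_patients <- as.matrix(Z_patients)
  K <- nrow(centroids)
  D <- sqdist_to_centers(Z_patients, centroids)
  assignments <- apply(D, 1L, which.min)
  reseeded <- FALSE
  empty <- setdiff(seq_len(K), unique(assignments))
  if (length(empty)) {
    reseeded <- TRUE
    for (k in empty) {
      far <- which.max(apply(D, 1L, min))
      message("re-seeding empty cluster ", k, " at point ", far)
      centroids[k, ] <- Z_patients[far, ]
      D <- sqdist_to_centers(Z_patients, centroids)
      assignments <- apply(D, 1L, which.min)
    }
  }
  for (k in seq_len(K)) {
    idx <- which(assignments == k)
    if (length(idx)) centroids[k, ] <- colMeans(Z_patients[idx, , drop = FALSE])
  }
  list(centroids = centroids, assignments = assignments, reseeded = reseeded)
}

# soft responsibilities at temperature T: softmax over -d2/T per row
soft_responsibilities <- function(Z_patients, centroids, temperature) {
  D <- sqdist_to_centers(Z_patients, centroids)
  E <- exp(-(D - apply(D, 1L, min)) / temperature)
  E / rowSums(E)
}

# ---- training ---------------------------------------------------------------

#' Train the graph-convolutional biotyper
#'
#' Runs the joint objective on a population graph: `warmup_epochs` epochs of
#' autoencoder + diagnosis-head training, then centroid seeding by greedy
#' farthest-point selection on the patient embeddings and joint training
#' with the clustering term active, refreshing assignments and centroids
#' every `centroid_update_period` epochs. Optimization is Adam throughout.
#' The run is deterministic given the seed and configuration (up to
#' floating-point reduction order in the BLAS).
#'
#' When `gamma3 = 0` the clustering term never activates and the final
#' assignments are computed post hoc by plain K-means on the learned patient
#' embeddings.
#'
#' @param g a `population_graph` (features are expected to be standardized;
#'   see [fit_scaler()]).
#' @param config a `biotyper_config` with `input_dim == ncol(g$features)`.
#' @param verbose print a progress line every 25 epochs.
#' @return a `gcn_biotyper` train state: list with `weights`, `centroids`,
#'   `assignments` (named integer vector over patients), `embeddings`
#'   (`N x d`), `loss_history` (data.frame epoch/l_rec/l_ce/l_cluster/total),
#'   `config`, `patient_ids`, `reseed_events`.
#' @export
train_gcn_biotyper <- function(g, config, verbose = FALSE) {
  stopifnot(inherits(g, "population_graph"), inherits(config, "biotyper_config"))
  if (ncol(g$features) != config$input_dim) {
    stop("config input_dim ", config$input_dim, " != feature dim ", ncol(g$features))
  }
  pat <- which(g$labels == 1L)
  if (length(pat) < config$K) stop("fewer patients than clusters")

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  S <- normalize_adjacency(g)
  X <- g$features
  y <- as.numeric(g$labels)
  N <- nrow(X); p <- ncol(X); n_pat <- length(pat)
  W <- init_weights(config)
  opt <- adam_state(W)
  SX <- S %*% X

  centroids <- NULL
  assignments <- NULL
  reseed_events <- integer(0)
  hist <- matrix(NA_real_, config$epochs, 4L)
  soft <- config$cluster_assignment == "soft"

  for (epoch in seq_len(config$epochs)) {
    enc <- gcn_stack_forward(S, X, W$enc, SX = SX)
    Z <- enc$out
    dec <- gcn_stack_forward(S, Z, W$dec)
    Xhat <- dec$out

    logits <- drop(Z %*% W$cls_w) + W$cls_b
    prob <- pmin(pmax(stats::plogis(logits), 1e-7), 1 - 1e-7)
    l_rec <- mean((X - Xhat)^2)
    l_ce <- -mean(y * log(prob) + (1 - y) * log(1 - prob))

    cluster_on <- config$gamma3 > 0 && epoch > config$warmup_epochs
    if (cluster_on && is.null(centroids)) {
      centroids <- farthest_point_seeds(Z[pat, , drop = FALSE], config$K)
      upd <- update_centroids_and_assignments(Z[pat, , drop = FALSE], centroids)
      centroids <- upd$centroids; assignments <- upd$assignments
    } else if (cluster_on &&
               (epoch - config$warmup_epochs - 1L) %% config$centroid_update_period == 0L) {
      before <- deep_kmeans_loss(Z[pat, , drop = FALSE], centroids, assignments)
      upd <- update_centroids_and_assignments(Z[pat, , drop = FALSE], centroids)
      after <- deep_kmeans_loss(Z[pat, , drop = FALSE], upd$centroids, upd$assignments)
      if (upd$reseeded) {
        reseed_events <- c(reseed_events, epoch)
      } else if (after > before + 1e-8) {
        stop("deep K-means loss increased under refresh at epoch ", epoch)
      }
      centroids <- upd$centroids; assignments <- upd$assignments
    }

    Zp <- Z[pat, , drop = FALSE]
    if (cluster_on) {
      if (soft) {
        R <- soft_responsibilities(Zp, centroids, config$temperature)
        D <- sqdist_to_centers(Zp, centroids)
        l_cluster <- mean(rowSums(R * D))
      } else {
        l_cluster <- deep_kmeans_loss(Zp, centroids, assignments)
      }
    } else l_cluster <- 0

    total <- config$gamma1 * l_rec + config$gamma2 * l_ce +
      config$gamma3 * l_cluster
    if (!is.finite(total)) stop("non-finite loss at epoch ", epoch)
    hist[epoch, ] <- c(l_rec, l_ce, l_cluster, total)
    if (verbose && epoch %% 25L == 0L) {
      cat(sprintf("epoch %d: rec %.4f ce %.4f cluster %.4f total %.4f\n",
                  epoch, l_rec, l_ce, l_cluster, total))
    }

    # ---- backward ----
    dXhat <- config$gamma1 * 2 * (Xhat - X) / (N * p)
    bw_dec <- gcn_stack_backward(S, dec, W$dec, dXhat, need_input_grad = TRUE)
    dZ <- bw_dec$dInput

    dlogit <- config$gamma2 * (prob - y) / N
    dZ <- dZ + tcrossprod(dlogit, W$cls_w)
    d_cls_w <- crossprod(Z, dlogit)
    d_cls_b <- sum(dlogit)

    if (cluster_on) {
      if (soft) {
        R <- soft_responsibilities(Zp, centroids, config$temperature)
        dZp <- config$gamma3 * 2 * (Zp - R %*% centroids) / n_pat
      } else {
        dZp <- config$gamma3 * 2 *
          (Zp - centroids[assignments, , drop = FALSE]) / n_pat
      }
      dZ[pat, ] <- dZ[pat, ] + dZp
    }

    bw_enc <- gcn_stack_backward(S, enc, W$enc, dZ, need_input_grad = FALSE)

    grads <- list(enc = bw_enc$dW, dec = bw_dec$dW,
                  cls_w = d_cls_w, cls_b = d_cls_b)
    res <- adam_step(W, grads, opt, config$learning_rate)
    W <- res$weights; opt <- res$state
  }

  # final embeddings and assignments
  Z <- gcn_stack_forward(S, X, W$enc, SX = SX)$out
  Zp <- Z[pat, , drop = FALSE]
  if (config$gamma3 > 0) {
    upd <- update_centroids_and_assignments(Zp, centroids)
    centroids <- upd$centroids; assignments <- upd$assignments
  } else {
    km <- kmeans_fit(Zp, config$K, seed = config$seed)
    centroids <- km$centers; assignments <- km$cluster
  }
  names(assignments) <- g$subject_ids[pat]

  loss_history <- data.frame(
    epoch = seq_len(config$epochs),
    l_rec = hist[, 1L], l_ce = hist[, 2L],
    l_cluster = hist[, 3L], total = hist[, 4L]
  )
  structure(list(
    weights = W, centroids = centroids, assignments = assignments,
    embeddings = Z, loss_history = loss_history, config = config,
    patient_ids = g$subject_ids[pat], reseed_events = reseed_events
  ), class = "gcn_biotyper")
}

#' @export
print.gcn_biotyper <- function(x, ...) {
  cat("gcn_biotyper:", length(x$patient_ids), "patients in",
      x$config$K, "biotypes; final total loss",
      format(utils::tail(x$loss_history$total, 1), digits = 5), "\n")
  print(table(biotype = x$assignments))
  invisible(x)
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(W) {
  zeros <- function(w) {
    if (is.list(w)) lapply(w, zeros) else w * 0
  }
  list(m = zeros(W), v = zeros(W), t = 0L)
}

adam_step <- function(W, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    w <- w - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(w = w, m = m, v = v)
  }
  for (part in c("enc", "dec")) {
    for (l in seq_along(W[[part]])) {
      r <- upd(W[[part]][[l]], grads[[part]][[l]],
               state$m[[part]][[l]], state$v[[part]][[l]])
      W[[part]][[l]] <- r$w
      state$m[[part]][[l]] <- r$m
      state$v[[part]][[l]] <- r$v
    }
  }
  for (nm in c("cls_w", "cls_b")) {
    r <- upd(W[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    W[[nm]] <- r$w; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  list(weights = W, state = state)
}

# ---- templates & checkpoints ------------------------------------------------

#' Mean-FNC biotype templates
#'
#' Template `k` is the arithmetic mean, on the raw correlation scale, of the
#' FNC vectors of all patients assigned to biotype `k`.
#'
#' @param features_raw patients x edges matrix on the correlation scale,
#'   rows aligned with `assignments` (or with rownames matching its names).
#' @param assignments integer biotype per patient (1..K).
#' @param K optional cluster count (defaults to `max(assignments)`).
#' @return a `biotype_templates` object: `K x edges` matrix with attribute
#'   `n_per_biotype`.
#' @export
extract_biotype_templates <- function(features_raw, assignments, K = NULL) {
  features_raw <- as.matrix(features_raw)
  if (!is.null(names(assignments)) && !is.null(rownames(features_raw))) {
    if (!all(names(assignments) %in% rownames(features_raw))) {
      stop("assignment names not found among feature rows")
    }
    features_raw <- features_raw[names(assignments), , drop = FALSE]
  }
  if (nrow(features_raw) != length(assignments)) {
    stop("features and assignments do not align")
  }
  if (is.null(K)) K <- max(assignments)
  counts <- tabulate(assignments, nbins = K)
  if (any(counts == 0L)) {
    stop("empty biotype(s): ", paste(which(counts == 0L), collapse = ", "))
  }
  tpl <- t(vapply(seq_len(K), function(k) {
    colMeans(features_raw[assignments == k, , drop = FALSE])
  }, numeric(ncol(features_raw))))
  rownames(tpl) <- paste0("biotype", seq_len(K))
  structure(tpl, n_per_biotype = counts, class = c("biotype_templates", "matrix"))
}

#' Save / load a trained biotyper checkpoint
#'
#' Single-file archive of weights, configuration, centroids and (optionally)
#' the feature scaler, with a schema id for forward compatibility.
#'
#' @param state a `gcn_biotyper`.
#' @param path file path.
#' @param scaler optional `feature_scaler` to store alongside.
#' @export
save_biotyper <- function(state, path, scaler = NULL) {
  stopifnot(inherits(state, "gcn_biotyper"))
  saveRDS(list(schema = "fncbiotype/checkpoint/v1", state = state,
               scaler = scaler), path)
  invisible(path)
}

#' @rdname save_biotyper
#' @return `load_biotyper`: list with `state` and `scaler`.
#' @export
load_biotyper <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "fncbiotype/checkpoint/v1")) {
    stop("unrecognized checkpoint schema")
  }
  obj[c("state", "scaler")]
}
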