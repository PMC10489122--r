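#' Z-scored regional morphology profiles
#'
#' Builds the inputs of the morphological clustering stage from a feature
#' matrix: (a) one profile per cortical region — the cohort-mean value of
#' each metric, z-scored — used to train the map, and (b) each participant's
#' z-scored region vectors, used for intra-cluster distances. With the
#' default `axis = "regions"` the z-scoring constants are the mean and sd
#' across the 68 regions of the cohort-mean regional values, per metric; the
#' same constants standardize the participant vectors so centroids and
#' participants live in one space. `axis = "participants"` z-scores each
#' (region, metric) feature across participants instead (for pooled
#' region-by-participant training).
#'
#' @param features feature matrix with canonical names (see
#'   [generate_features()]).
#' @param metrics cortical metrics to include; default all four. Subcortical
#'   volumes are never part of the region profiles.
#' @param axis z-scoring axis policy (see Details).
#' @return list of class `region_profiles`: `profiles` (68 x metrics matrix),
#'   `tensor` (participants x 68 x metrics array), `constants` (the recorded
#'   z-scoring means/sds), `axis`.
#' @export
zscore_profiles <- function(features, metrics = cortical_metrics(),
                            axis = c("regions", "participants")) {
  axis <- match.arg(axis)
  features <- as.matrix(features)
  regions <- cortical_regions()
  cols <- as.vector(t(outer(regions, metrics, paste, sep = "_")))
  miss <- setdiff(cols, colnames(features))
  if (length(miss)) {
    stop("features lack column(s): ", paste(miss[seq_len(min(5, length(miss)))],
                                            collapse = ", "))
  }
  n <- nrow(features)
  raw <- array(features[, cols], dim = c(n, length(metrics), 68))
  raw <- aperm(raw, c(1, 3, 2))  # n x region x metric
  dimnames(raw) <- list(rownames(features), regions, metrics)

  if (axis == "regions") {
    cohort_mean <- apply(raw, c(2, 3), mean)           # 68 x m
    mu <- colMeans(cohort_mean)
    s <- apply(cohort_mean, 2, stats::sd)
    if (n == 1L) s <- apply(raw[1, , , drop = TRUE], 2, stats::sd)
    zero <- s == 0 | !is.finite(s)
    if (any(zero)) {
      stop("zero variance across regions for metric(s): ",
           paste(metrics[zero], collapse = ", "))
    }
    profiles <- sweep(sweep(cohort_mean, 2, mu), 2, s, `/`)
    tensor <- sweep(sweep(raw, 3, mu), 3, s, `/`)
    constants <- list(mean = mu, sd = s)
  } else {
    mu <- apply(raw, c(2, 3), mean)
    s <- apply(raw, c(2, 3), stats::sd)
    zero <- s == 0 | !is.finite(s)
    if (any(zero)) {
      bad <- which(zero, arr.ind = TRUE)[1, ]
      stop("zero variance across participants for feature: ",
           regions[bad[1]], "_", metrics[bad[2]])
    }
    tensor <- raw
    for (m in seq_along(metrics)) {
      tensor[, , m] <- sweep(sweep(raw[, , m, drop = FALSE], 2, mu[, m]),
                             2, s[, m], `/`)[, , 1]
    }
    profiles <- apply(tensor, c(2, 3), mean)
    constants <- list(mean = mu, sd = s)
  }
  structure(list(profiles = profiles, tensor = tensor, constants = constants,
                 axis = axis, metrics = metrics),
            class = "region_profiles")
}

# --- internal SOM machinery ---------------------------------------------

grid_coords <- function(nr, nc) {
  cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
}

bmu_of <- function(data, W) {
  d2 <- outer(rowSums(data^2), rowSums(W^2), `+`) - 2 * data %*% t(W)
  max.col(-d2, ties.method = "first")
}

node_qe <- function(data, W, bmu) {
  d <- sqrt(rowSums((data - W[bmu, , drop = FALSE])^2))
  qe <- rep(NA_real_, nrow(W))
  agg <- tapply(d, bmu, mean)
  qe[as.integer(names(agg))] <- agg
  qe
}

map_mqe <- function(qe) mean(qe, na.rm = TRUE)

# Batch SOM epochs with linearly decaying Gaussian neighborhood, then a
# Lloyd polish (radius zero) run to convergence. The polish guarantees that
# growing the map never increases the mean quantization error: the inserted
# configuration retains all previous prototypes, and Lloyd iterations are
# monotone.
train_som_map <- function(data, W, nr, nc, epochs, r0) {
  G <- grid_coords(nr, nc)
  gd2 <- as.matrix(stats::dist(G))^2
  for (e in seq_len(epochs)) {
    r <- max(r0 * (1 - (e - 1) / epochs), 1e-3)
    bmu <- bmu_of(data, W)
    H <- exp(-gd2 / (2 * r^2))[bmu, , drop = FALSE]   # n x nodes
    denom <- colSums(H)
    num <- t(H) %*% data
    upd <- denom > 1e-12
    W[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  bmu <- bmu_of(data, W)
  for (it in seq_len(200)) {
    for (j in unique(bmu)) {
      W[j, ] <- colMeans(data[bmu == j, , drop = FALSE])
    }
    new_bmu <- bmu_of(data, W)
    if (identical(new_bmu, bmu)) break
    bmu <- new_bmu
  }
  list(W = W, bmu = bmu)
}

insert_row_col <- function(W, nr, nc, err_node, nbr_node) {
  A <- array(t(W), dim = c(ncol(W), nr, nc))   # d x nr x nc
  e <- c((err_node - 1) %% nr + 1, (err_node - 1) %/% nr + 1)
  b <- c((nbr_node - 1) %% nr + 1, (nbr_node - 1) %/% nr + 1)
  if (e[1] != b[1]) {               # neighbor differs in row: insert a row
    lo <- min(e[1], b[1])
    newA <- array(0, dim = c(dim(A)[1], nr + 1, nc))
    newA[, seq_len(lo), ] <- A[, seq_len(lo), ]
    newA[, lo + 1, ] <- (A[, lo, ] + A[, lo + 1, ]) / 2
    newA[, (lo + 2):(nr + 1), ] <- A[, (lo + 1):nr, ]
    nr <- nr + 1
  } else {                          # insert a column
    lo <- min(e[2], b[2])
    newA <- array(0, dim = c(dim(A)[1], nr, nc + 1))
    newA[, , seq_len(lo)] <- A[, , seq_len(lo)]
    newA[, , lo + 1] <- (A[, , lo] + A[, , lo + 1]) / 2
    newA[, , (lo + 2):(nc + 1)] <- A[, , (lo + 1):nc]
    nc <- nc + 1
  }
  list(W = t(matrix(newA, dim(newA)[1], nr * nc)), nr = nr, nc = nc)
}

# Initial 2 x 2 weights spread over the first two principal components of
# the data (signs fixed for determinism), so small maps unfold onto
# well-separated groups instead of stranding nodes at the mean.
init_weights_2x2 <- function(data, seed_noise) {
  d <- ncol(data)
  ctr <- colMeans(data)
  W <- matrix(rep(ctr, each = 4), 4, d)
  centered <- sweep(data, 2, ctr)
  if (nrow(data) > 2L && any(centered != 0)) {
    sv <- svd(centered, nu = 0, nv = min(2L, d))
    for (k in seq_len(ncol(sv$v))) {
      v <- sv$v[, k]
      lead <- which(abs(v) > 1e-12)[1]
      if (!is.na(lead) && v[lead] < 0) v <- -v
      spread <- sv$d[k] / sqrt(nrow(data)) * v   # ~1 sd of the scores
      signs <- if (k == 1L) c(-1, -1, 1, 1) else c(-1, 1, -1, 1)
      W <- W + outer(signs, spread)
    }
  }
  W + matrix(stats::rnorm(4 * d, 0, seed_noise), 4, d)
}

grow_map <- function(data, parent_mqe, tau1, epochs, max_nodes, seed_noise) {
  d <- ncol(data)
  nr <- 2L; nc <- 2L
  W <- init_weights_2x2(data, seed_noise)
  history <- numeric(0)
  grown <- TRUE
  repeat {
    res <- train_som_map(data, W, nr, nc, epochs, r0 = max(nr, nc) / 2)
    qe <- node_qe(data, res$W, res$bmu)
    m <- map_mqe(qe)
    if (length(history) && m > history[length(history)] + 1e-12) {
      # fall back to a pure Lloyd pass from the inserted configuration,
      # which cannot increase the previous converged error
      res <- train_som_map(data, W, nr, nc, epochs = 0, r0 = 1e-3)
      qe <- node_qe(data, res$W, res$bmu)
      m <- map_mqe(qe)
    }
    history <- c(history, m)
    W <- res$W
    bmu <- res$bmu
    if (m < tau1 * parent_mqe || nr * nc >= max_nodes ||
        length(unique(bmu)) < 2L) {
      break
    }
    err_node <- which.max(ifelse(is.na(qe), -Inf, qe))
    G <- grid_coords(nr, nc)
    adj <- which(rowSums(abs(sweep(G, 2, G[err_node, ]))) == 1L)
    nbr <- adj[which.max(sqrt(rowSums((W[adj, , drop = FALSE] -
                                         matrix(W[err_node, ], length(adj),
                                                ncol(W),
                                                byrow = TRUE))^2)))]
    ins <- insert_row_col(W, nr, nc, err_node, nbr)
    W <- ins$W; nr <- ins$nr; nc <- ins$nc
  }
  list(weights = W, nr = nr, nc = nc, bmu = bmu, qe = qe,
       mqe = map_mqe(qe), mqe_history = history)
}

#' Train a growing hierarchical self-organizing map
#'
#' Standard GHSOM procedure: start from a 2 x 2 map initialized near the data
#' mean, train batch SOM epochs with a shrinking Gaussian neighborhood
#' followed by a Lloyd polish, then grow in breadth by inserting a row or
#' column between the node with the highest quantization error and its most
#' dissimilar grid neighbor, until the map's mean quantization error (MQE)
#' falls below `tau1` times the parent unit's error. Nodes whose own error
#' still exceeds `tau2` times the root error (the mean distance of the data
#' to its global mean) are expanded into child maps, recursively. Only the
#' top-layer map defines the clusters used downstream; deeper maps are kept
#' for inspection.
#'
#' @param profiles numeric matrix (samples x dimensions), e.g. the `profiles`
#'   element of [zscore_profiles()].
#' @param tau1 breadth-growth threshold in (0, 1]; smaller values demand a
#'   finer top map.
#' @param tau2 depth-expansion threshold in (0, 1); smaller values expand
#'   more nodes into child maps.
#' @param epochs SOM training epochs per growth cycle.
#' @param max_nodes node budget per map; growth past it stops with a warning.
#' @param max_depth maximum hierarchy depth.
#' @param seed integer seed; training is deterministic given the seed.
#' @return object of class `ghsom`: list with `map` (top-layer weights, grid
#'   shape, per-node quantization errors, `mqe_history`), `children`
#'   (per-node child maps or NULL), `mqe0` (root error) and the training
#'   parameters.
#' @export
train_ghsom <- function(profiles, tau1 = 0.6, tau2 = 0.1, epochs = 30,
                        max_nodes = 64, max_depth = 3, seed = NULL) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1L) stop("need at least one profile")
  if (!(tau1 > 0 && tau1 <= 1) || !(tau2 > 0 && tau2 < 1)) {
    stop("require 0 < tau1 <= 1 and 0 < tau2 < 1")
  }
  with_seed(seed, {
    ctr <- colMeans(profiles)
    mqe0 <- mean(sqrt(rowSums(sweep(profiles, 2, ctr)^2)))
    noise <- 0.01 * max(mean(apply(profiles, 2, stats::sd)), 1e-8)
    build <- function(data, parent_mqe, depth) {
      map <- grow_map(data, parent_mqe, tau1, epochs, max_nodes, noise)
      if (map$nr * map$nc >= max_nodes && map$mqe >= tau1 * parent_mqe) {
        warning("map growth stopped at the node budget (", max_nodes,
                " nodes) before reaching the tau1 target")
      }
      children <- vector("list", nrow(map$weights))
      if (depth < max_depth && mqe0 > 0) {
        for (j in seq_len(nrow(map$weights))) {
          members <- which(map$bmu == j)
          if (length(members) > 1L && !is.na(map$qe[j]) &&
              map$qe[j] > tau2 * mqe0) {
            children[[j]] <- build(data[members, , drop = FALSE],
                                   map$qe[j], depth + 1L)
          }
        }
      }
      list(map = map, children = children)
    }
    top <- build(profiles, mqe0, 1L)
    structure(list(map = top$map, children = top$children, mqe0 = mqe0,
                   tau1 = tau1, tau2 = tau2, epochs = epochs,
                   dim = colnames(profiles)),
              class = "ghsom")
  })
}

#' @export
print.ghsom <- function(x, ...) {
  cat("GHSOM: top layer", x$map$nr, "x", x$map$nc, "nodes,",
      sum(!is.na(x$map$qe)), "populated; MQE",
      format(x$map$mqe, digits = 4), "(root error",
      format(x$mqe0, digits = 4), ")\n")
  invisible(x)
}

#' Assign regions to the nearest top-layer centroid
#'
#' Nearest-centroid assignment under Euclidean distance; the top-layer node
#' weight vectors are the cluster centroids (the typical morphological
#' pattern of each class). Empty clusters are dropped and indices compacted;
#' exact ties go to the lowest cluster index.
#'
#' @param model a trained [train_ghsom()] model.
#' @param profiles matrix of region profiles (rows named by region).
#' @return object of class `cluster_assignment`: list with `cluster` (named
#'   integer vector), `centroids` (cluster x dimension matrix), `distance`
#'   (each region's distance to its centroid) and `sizes`.
#' @export
assign_regions <- function(model, profiles) {
  if (!inherits(model, "ghsom")) stop("model must be a ghsom")
  profiles <- as.matrix(profiles)
  W <- model$map$weights
  d2 <- outer(rowSums(profiles^2), rowSums(W^2), `+`) -
    2 * profiles %*% t(W)
  raw <- max.col(-d2, ties.method = "first")
  keep <- sort(unique(raw))
  cluster <- match(raw, keep)
  names(cluster) <- rownames(profiles)
  centroids <- W[keep, , drop = FALSE]
  rownames(centroids) <- paste0("cluster", seq_along(keep))
  dist_to <- sqrt(pmax(d2[cbind(seq_len(nrow(profiles)), raw)], 0))
  structure(list(cluster = cluster, centroids = centroids,
                 distance = stats::setNames(dist_to, rownames(profiles)),
                 sizes = tabulate(cluster, length(keep))),
            class = "cluster_assignment")
}

#' Per-participant intra-cluster distances
#'
#' For each participant and each cluster, the mean Euclidean distance between
#' the participant's z-scored region vectors (for the cluster's regions) and
#' the cluster centroid. This is the per-participant statistic tested for a
#' gene-gene interaction downstream.
#'
#' @param assignment a [assign_regions()] result.
#' @param tensor participants x regions x metrics array of z-scored vectors
#'   (the `tensor` element of [zscore_profiles()]).
#' @return numeric matrix participants x clusters, non-negative; the
#'   `ClusterDistanceTable`.
#' @export
intra_cluster_distances <- function(assignment, tensor) {
  if (!inherits(assignment, "cluster_assignment")) {
    stop("assignment must come from assign_regions()")
  }
  regions <- dimnames(tensor)[[2]]
  miss <- setdiff(names(assignment$cluster), regions)
  if (length(miss)) {
    stop("tensor lacks region(s): ", paste(miss, collapse = ", "))
  }
  n <- dim(tensor)[1]
  K <- nrow(assignment$centroids)
  out <- matrix(NA_real_, n, K,
                dimnames = list(dimnames(tensor)[[1]],
                                rownames(assignment$centroids)))
  for (k in seq_len(K)) {
    members <- names(assignment$cluster)[assignment$cluster == k]
    sub <- tensor[, members, , drop = FALSE]
    ctr <- assignment$centroids[k, ]
    diff <- sweep(sub, 3, ctr)
    d <- sqrt(apply(diff^2, c(1, 2), sum))
    d <- matrix(d, nrow = n)
    out[, k] <- rowMeans(d)
  }
  out
}
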