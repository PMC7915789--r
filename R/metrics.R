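check_adjacency <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be a square matrix")
  if (any(!is.finite(W)) || any(W < 0)) stop("weights must be finite and >= 0")
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  invisible(W)
}

#' Pairwise shortest-path distances on a similarity-weighted network
#'
#' Edge length is the reciprocal weight `l_ij = 1/w_ij` (the dominant
#' convention for similarity-weighted connectivity, and the one under
#' which global efficiency is at most 1 when all weights are at most 1).
#' Unreachable pairs get `Inf`.
#'
#' @param W symmetric weighted adjacency matrix (weights >= 0, zero
#'   diagonal).
#' @return symmetric matrix of shortest-path distances (zero diagonal).
#' @export
shortest_path_distances <- function(W) {
  check_adjacency(W)
  D <- dist_matrix_cpp(W)
  dimnames(D) <- dimnames(W)
  D
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance,
#' with unreachable pairs contributing 0. Equals 1 for a complete
#' unit-weight graph and 0 for an empty one.
#'
#' @inheritParams shortest_path_distances
#' @return scalar in `[0, 1]` for weights in `(0, 1]`.
#' @export
global_efficiency <- function(W) {
  check_adjacency(W)
  if (nrow(W) < 2) stop("need at least 2 nodes")
  global_metrics_cpp(W, 0L)$eglob
}

#' Characteristic path length
#'
#' Mean shortest-path distance over reachable node pairs; unreachable
#' (infinite-distance) pairs are excluded from the mean, which keeps Lp
#' finite on networks that fragment at low densities.
#'
#' @inheritParams shortest_path_distances
#' @return scalar Lp.
#' @export
characteristic_path_length <- function(W) {
  check_adjacency(W)
  if (nrow(W) < 2) stop("need at least 2 nodes")
  lp <- global_metrics_cpp(W, 0L)$lp
  if (is.na(lp)) stop("fully disconnected network: no reachable pair")
  lp
}

#' Weighted clustering coefficient per node
#'
#' Default is the Onnela geometric-mean form on weights normalized by the
#' network maximum:
#' `C_i = sum_{j,h} (w'_ij w'_jh w'_ih)^{1/3} / (k_i (k_i - 1))`
#' with `w' = w / max(w)` and `k_i` the binary degree; `C_i = 0` for
#' nodes with fewer than 2 neighbors. `variant = "barrat"` gives the
#' Barrat arithmetic form as an alternative.
#'
#' @inheritParams shortest_path_distances
#' @param variant `"onnela"` (default) or `"barrat"`.
#' @return numeric vector of per-node coefficients.
#' @export
weighted_clustering <- function(W, variant = c("onnela", "barrat")) {
  variant <- match.arg(variant)
  check_adjacency(W)
  out <- clustering_cpp(W, if (variant == "onnela") 0L else 1L)
  names(out) <- colnames(W)
  out
}

#' Local efficiency per node
#'
#' The global efficiency of the subgraph induced by a node's neighbors
#' (the node itself excluded), computed on the original weights; 0 for
#' nodes with fewer than 2 neighbors.
#'
#' @inheritParams shortest_path_distances
#' @return numeric vector of per-node local efficiencies.
#' @export
local_efficiency <- function(W) {
  check_adjacency(W)
  out <- local_efficiency_cpp(W)
  names(out) <- colnames(W)
  out
}

#' Degree centrality: nodal strength and binary degree
#'
#' On the weighted thresholded networks of this pipeline "degree
#' centrality" defaults to nodal strength (sum of incident weights); the
#' binary degree (count of incident edges) is returned alongside.
#'
#' @inheritParams shortest_path_distances
#' @return list with numeric vectors `strength` and `degree`.
#' @export
degree_centrality <- function(W) {
  check_adjacency(W)
  list(strength = rowSums(W), degree = rowSums(W > 0))
}

#' Nodal path length and nodal efficiency
#'
#' Per node: the mean shortest-path distance to reachable other nodes
#' (0 if no other node is reachable) and the mean inverse distance to
#' all other nodes (unreachable pairs contribute 0).
#'
#' @inheritParams shortest_path_distances
#' @return list with numeric vectors `path_length` and `efficiency`.
#' @export
nodal_integration <- function(W) {
  D <- shortest_path_distances(W)
  diag(D) <- NA
  fin <- is.finite(D)
  pl <- rowSums(ifelse(fin, D, 0)) / pmax(rowSums(fin, na.rm = TRUE), 1)
  pl[rowSums(fin, na.rm = TRUE) == 0] <- 0
  inv <- ifelse(fin, 1 / D, 0)
  eff <- rowSums(inv, na.rm = TRUE) / (nrow(D) - 1)
  list(path_length = unname(pl), efficiency = unname(eff))
}

#' Degree-preserving random reference networks
#'
#' Generates Maslov-Sneppen null networks by repeated double-edge swaps:
#' edges (a,b) and (c,d) become (a,d) and (c,b) when this creates no
#' self-loop or duplicate edge. Weights travel with their edges, so each
#' null preserves the node count, edge count, binary degree sequence,
#' and the multiset of nonzero weights exactly. The generator is fully
#' determined by `seed` (an internal Mersenne-Twister stream independent
#' of R's RNG).
#'
#' @inheritParams shortest_path_distances
#' @param n_nulls number of null networks.
#' @param rewires_per_edge attempted swaps per edge (default 100).
#' @param seed integer seed.
#' @return list of `n_nulls` rewired adjacency matrices.
#' @export
random_reference <- function(W, n_nulls = 1, rewires_per_edge = 100, seed = 1) {
  check_adjacency(W)
  m <- sum(W[upper.tri(W)] > 0)
  if (m < 2) stop("too few edges to rewire (need >= 2 independent edge pairs)")
  lapply(seq_len(n_nulls), function(r) {
    Wr <- ms_rewire_cpp(W, rewires_per_edge, derive_seed(seed, r, 0))
    dimnames(Wr) <- dimnames(W)
    Wr
  })
}

#' Small-world normalization against a null ensemble
#'
#' Computes `gamma = Cp_real / mean(Cp_null)`,
#' `lambda = Lp_real / mean(Lp_null)` and the small-world index
#' `sigma = gamma / lambda`, with the small-world criterion
#' `sigma > 1.1`. Nulls are degree-preserving rewirings
#' (see [random_reference()]); pass `nulls` explicitly to normalize
#' against a fixed ensemble instead.
#'
#' @inheritParams random_reference
#' @param nulls optional list of null adjacency matrices; when `NULL`
#'   (default) `n_nulls` rewired networks are generated internally on a
#'   fast path.
#' @param variant clustering variant, see [weighted_clustering()].
#' @return list with `cp_real`, `lp_real`, `cp_random`, `lp_random`,
#'   `gamma`, `lambda`, `sigma`, `small_world` (logical).
#' @export
small_world <- function(W, nulls = NULL, n_nulls = 100, rewires_per_edge = 100,
                        seed = 1, variant = c("onnela", "barrat")) {
  variant <- match.arg(variant)
  vi <- if (variant == "onnela") 0L else 1L
  check_adjacency(W)
  g <- global_metrics_cpp(W, vi)
  if (is.na(g$lp)) stop("fully disconnected network")
  if (is.null(nulls)) {
    m <- sum(W[upper.tri(W)] > 0)
    if (m < 2) stop("too few edges to rewire")
    nm <- null_cp_lp_cpp(W, as.integer(n_nulls), rewires_per_edge, seed, vi)
    cp_rand <- mean(nm[, 1]); lp_rand <- mean(nm[, 2], na.rm = TRUE)
  } else {
    cps <- vapply(nulls, function(N) global_metrics_cpp(N, vi)$cp, 0)
    lps <- vapply(nulls, function(N) global_metrics_cpp(N, vi)$lp, 0)
    cp_rand <- mean(cps); lp_rand <- mean(lps, na.rm = TRUE)
  }
  if (!is.finite(cp_rand) || cp_rand <= 0 || !is.finite(lp_rand) || lp_rand <= 0)
    stop("degenerate null ensemble (Cp_random or Lp_random not positive)")
  gamma <- g$cp / cp_rand
  lambda <- g$lp / lp_rand
  sigma <- gamma / lambda
  list(cp_real = g$cp, lp_real = g$lp, cp_random = cp_rand,
       lp_random = lp_rand, gamma = gamma, lambda = lambda, sigma = sigma,
       small_world = sigma > 1.1)
}

#' Area under the curve over the density sweep
#'
#' Trapezoidal integral of a metric over the density grid; the scalar
#' summary that removes dependence on any single threshold. For a metric
#' constant at `c` over densities 0.10-0.40 the AUC is `0.30 * c`, and
#' the operator is linear in the metric values.
#'
#' @param values numeric vector of metric values, one per density.
#' @param densities the density grid the values were computed on
#'   (default [density_grid()], 31 values).
#' @return scalar AUC.
#' @export
auc_over_density <- function(values, densities = density_grid()) {
  if (length(values) != length(densities))
    stop("values length (", length(values), ") does not match densities (",
         length(densities), ")")
  if (length(values) < 2) stop("need at least 2 densities")
  if (is.unsorted(densities, strictly = TRUE)) stop("densities must be increasing")
  dd <- diff(densities)
  sum(dd * (values[-length(values)] + values[-1]) / 2)
}

# counter-based seed derivation: substreams for (unit, counter) pairs are
# reproducible and independent of processing order; subject substreams
# hash the subject id so results do not depend on subject ordering
#' @keywords internal
derive_seed <- function(seed, unit, counter) {
  (seed * 69069 + unit * 7919 + counter * 104729) %% 2147483629 + 1
}

#' @keywords internal
hash_id <- function(id) {
  h <- 5381
  for (code in utf8ToInt(as.character(id))) h <- (h * 31 + code) %% 2147483629
  h
}

#' Density-swept graph metrics for one subject network
#'
#' Thresholds the network over the density grid and computes, at each
#' density, the global metrics (mean clustering Cp, characteristic path
#' length Lp, global efficiency) and optionally the nodal metrics
#' (strength, binary degree, clustering, nodal path length, nodal
#' efficiency, local efficiency) and the null-normalized small-world
#' measures (gamma, lambda, sigma, using `n_nulls` degree-preserving
#' rewirings per density). Each metric is then reduced to its AUC over
#' the sweep.
#'
#' @param W unthresholded covariance network
#'   (see [build_covariance_network()]).
#' @param densities density grid (default [density_grid()]).
#' @param n_nulls nulls per density for small-world normalization; only
#'   used when `small_world = TRUE`.
#' @param rewires_per_edge attempted swaps per edge for each null.
#' @param seed base seed for the null-model substreams.
#' @param small_world compute gamma/lambda/sigma (needs nulls; the
#'   expensive part).
#' @param nodal compute nodal metrics.
#' @param variant clustering variant.
#' @return list with `densities`, `global` (data.frame, one row per
#'   density), `global_auc` (named vector), and when `nodal = TRUE`
#'   `nodal_auc` (nodes x metrics matrix).
#' @export
sweep_metrics <- function(W, densities = density_grid(), n_nulls = 100,
                          rewires_per_edge = 100, seed = 1,
                          small_world = TRUE, nodal = TRUE,
                          variant = c("onnela", "barrat")) {
  variant <- match.arg(variant)
  vi <- if (variant == "onnela") 0L else 1L
  sweep <- density_sweep(W, densities)
  nd <- length(densities)
  n <- nrow(W)
  glob <- data.frame(density = densities, cp = NA_real_, lp = NA_real_,
                     eglob = NA_real_, cp_random = NA_real_,
                     lp_random = NA_real_, gamma = NA_real_,
                     lambda = NA_real_, sigma = NA_real_)
  nodal_metrics <- c("strength", "degree", "clustering", "path_length",
                     "nodal_efficiency", "local_efficiency")
  nod <- if (nodal) array(NA_real_, c(nd, n, length(nodal_metrics)),
                          dimnames = list(NULL, colnames(W), nodal_metrics))
         else NULL
  for (t in seq_len(nd)) {
    Wt <- sweep$networks[[t]]
    g <- graph_metrics_cpp(Wt, vi, nodal, nodal)
    glob$cp[t] <- g$cp
    glob$lp[t] <- g$lp
    glob$eglob[t] <- g$eglob
    if (small_world) {
      nm <- null_cp_lp_cpp(Wt, as.integer(n_nulls), rewires_per_edge,
                           derive_seed(seed, 0, t), vi)
      glob$cp_random[t] <- mean(nm[, 1])
      glob$lp_random[t] <- mean(nm[, 2], na.rm = TRUE)
      glob$gamma[t] <- glob$cp[t] / glob$cp_random[t]
      glob$lambda[t] <- glob$lp[t] / glob$lp_random[t]
      glob$sigma[t] <- glob$gamma[t] / glob$lambda[t]
    }
    if (nodal) {
      nod[t, , "strength"] <- g$strength
      nod[t, , "degree"] <- g$degree
      nod[t, , "clustering"] <- g$clustering
      nod[t, , "path_length"] <- g$path_length
      nod[t, , "nodal_efficiency"] <- g$nodal_efficiency
      nod[t, , "local_efficiency"] <- g$local_efficiency
    }
  }
  gm <- c("cp", "lp", "eglob", if (small_world) c("gamma", "lambda", "sigma"))
  global_auc <- vapply(gm, function(m) auc_over_density(glob[[m]], densities), 0)
  out <- list(densities = densities, global = glob, global_auc = global_auc)
  if (nodal) {
    out$nodal_auc <- apply(nod, c(2, 3), auc_over_density, densities = densities)
  }
  out
}
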