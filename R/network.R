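#' Build a single-subject structural covariance network
#'
#' Edge weights quantify the joint variation of two regions' z-scored
#' morphometry within one subject:
#' `w_ij = 1 / exp((z_i - z_j)^2) = exp(-(z_i - z_j)^2)`,
#' so identical z-scores give weight 1 and the weight decays
#' monotonically with `|z_i - z_j|`. Weights depend only on z-score
#' differences, hence are invariant to adding a constant to all
#' z-scores. The diagonal is fixed to 0 (no self-loops; the literal
#' formula would give `w_ii = 1`, but graph metrics assume loop-free
#' networks, the standard connectivity convention).
#'
#' @param z numeric vector of node z-scores (length 74 in the standard
#'   pipeline; any length >= 2 is accepted).
#' @return symmetric weighted adjacency matrix with zero diagonal and
#'   off-diagonal entries in (0, 1].
#' @export
build_covariance_network <- function(z) {
  if (!is.numeric(z) || length(z) < 2) stop("z must be a numeric vector, length >= 2")
  if (any(!is.finite(z))) {
    nm <- names(z)[!is.finite(z)]
    stop("non-finite z-score at node: ",
         paste(if (is.null(nm)) which(!is.finite(z)) else nm, collapse = ", "))
  }
  d <- outer(z, z, "-")
  W <- exp(-d^2)
  diag(W) <- 0
  dimnames(W) <- list(names(z), names(z))
  W
}

#' The density grid for the threshold sweep
#'
#' @param lo,hi,step density range bounds and increment; defaults
#'   0.10-0.40 in steps of 0.01 (31 densities).
#' @return numeric vector of densities.
#' @export
density_grid <- function(lo = 0.10, hi = 0.40, step = 0.01) {
  if (!(lo > 0 && hi <= 1 && lo < hi && step > 0)) stop("invalid density range")
  n <- round((hi - lo) / step)
  if (abs(lo + n * step - hi) > 1e-9)
    stop("step does not divide the density range")
  round(lo + step * (0:n), 10)
}

# number of edges retained at density d for an n-node network
# (round half away from zero, so the realized density matches d to
# within one edge)
#' @keywords internal
edge_count_at_density <- function(d, n_nodes) {
  emax <- n_nodes * (n_nodes - 1) / 2
  floor(d * emax + 0.5)
}

# upper-triangle edge ranking shared by threshold_proportional and
# density_sweep: descending weight, ties broken by ascending (i, j)
# node-index order, so thresholding is deterministic and nested
#' @keywords internal
ranked_edges <- function(W) {
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  ord <- order(-w, ut[, 1], ut[, 2])
  list(i = ut[ord, 1], j = ut[ord, 2], w = w[ord], n = n)
}

#' Proportional-density thresholding
#'
#' Retains exactly `k(d) = round(d * n(n-1)/2)` strongest off-diagonal
#' edges with their original weights (the network stays weighted, it is
#' not binarized); all other entries are set to 0. Ties at the cutoff are
#' broken deterministically: descending weight, then ascending (i, j)
#' node-index order. Thresholding at `d` then at `d' <= d` equals
#' thresholding at `d'` directly (nesting).
#'
#' @param W symmetric weighted adjacency matrix, zero diagonal.
#' @param d target density in (0, 1].
#' @return thresholded symmetric weighted adjacency matrix.
#' @export
threshold_proportional <- function(W, d) {
  if (!is.numeric(d) || length(d) != 1 || d <= 0 || d > 1)
    stop("density d must be in (0, 1]")
  re <- ranked_edges(W)
  k <- edge_count_at_density(d, re$n)
  out <- matrix(0, re$n, re$n, dimnames = dimnames(W))
  if (k > 0) {
    keep <- seq_len(min(k, length(re$w)))
    idx <- cbind(re$i[keep], re$j[keep])
    out[idx] <- re$w[keep]
    out[idx[, c(2, 1), drop = FALSE]] <- re$w[keep]
  }
  out
}

#' Threshold a network over the full density sweep
#'
#' Applies [threshold_proportional()] at each density of the grid using a
#' single shared edge ranking, so the retained edge sets are nested:
#' every edge present at density d is present at every d' > d.
#'
#' @param W symmetric weighted adjacency matrix, zero diagonal.
#' @param densities density grid (default [density_grid()], 31 values).
#' @return object of class `density_sweep`: list with `densities` and
#'   `networks` (one thresholded matrix per density).
#' @export
density_sweep <- function(W, densities = density_grid()) {
  re <- ranked_edges(W)
  nets <- lapply(densities, function(d) {
    k <- edge_count_at_density(d, re$n)
    out <- matrix(0, re$n, re$n, dimnames = dimnames(W))
    if (k > 0) {
      keep <- seq_len(min(k, length(re$w)))
      idx <- cbind(re$i[keep], re$j[keep])
      out[idx] <- re$w[keep]
      out[idx[, c(2, 1), drop = FALSE]] <- re$w[keep]
    }
    out
  })
  structure(list(densities = densities, networks = nets),
            class = "density_sweep")
}

#' @export
print.density_sweep <- function(x, ...) {
  cat(sprintf("density_sweep: %d densities (%.2f-%.2f), %d nodes\n",
              length(x$densities), min(x$densities), max(x$densities),
              nrow(x$networks[[1]])))
  invisible(x)
}

#' Export a network in BrainNet Viewer text formats
#'
#' Writes `<prefix>.edge` (whitespace-separated adjacency matrix) and
#' `<prefix>.node` (rows `x y z color size label`). The pipeline carries
#' no anatomical coordinates, so synthetic placeholder coordinates on a
#' circle are written; replace them with real atlas centroids for
#' anatomically meaningful renderings.
#'
#' @param W adjacency matrix.
#' @param prefix output path prefix.
#' @param labels node labels (default from `colnames(W)` or the roster).
#' @param color,size numeric vectors recycled to the node count (e.g. a
#'   group-difference statistic and nodal strength).
#' @export
export_brainnet <- function(W, prefix, labels = NULL, color = 1, size = 1) {
  n <- nrow(W)
  if (is.null(labels))
    labels <- if (!is.null(colnames(W))) colnames(W) else node_roster()$label[seq_len(n)]
  write.table(format(W, digits = 6, trim = TRUE), paste0(prefix, ".edge"),
              sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- data.frame(x = round(80 * cos(theta), 2),
                      y = round(80 * sin(theta), 2), z = 0,
                      color = rep_len(color, n), size = rep_len(size, n),
                      label = labels)
  write.table(nodes, paste0(prefix, ".node"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Write an adjacency matrix as TSV
#' @param W adjacency matrix.
#' @param path output path.
#' @export
write_adjacency <- function(W, path) {
  write.table(W, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = !is.null(colnames(W)))
  invisible(path)
}
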