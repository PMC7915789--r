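# Independent brute-force oracles for the graph kernels, kept deliberately
# naive (exhaustive relaxation, exhaustive triple enumeration) so they share
# no code path with the package implementation.

rand_weighted_graph <- function(n, p = 0.5) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < p]
  W[on] <- runif(length(on), 0.05, 1)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

# Floyd-Warshall on lengths 1/w
fw_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && W[i, j] > 0) D[i, j] <- 1 / W[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

brute_eglob <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- fw_distances(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

brute_lp <- function(W) {
  D <- fw_distances(W)
  diag(D) <- NA
  mean(D[is.finite(D)], na.rm = TRUE)
}

brute_nodal_integration <- function(W) {
  D <- fw_distances(W)
  diag(D) <- NA
  n <- nrow(W)
  pl <- eff <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    fin <- which(is.finite(d))
    pl[i] <- if (length(fin) == 0) 0 else mean(d[fin])
    eff[i] <- sum(1 / d[fin]) / (n - 1)
  }
  list(path_length = pl, efficiency = eff)
}

# exhaustive triple enumeration, Onnela form with max-weight normalization
brute_clustering_onnela <- function(W) {
  n <- nrow(W)
  wmax <- max(W)
  out <- numeric(n)
  if (wmax <= 0) return(out)
  Wn <- W / wmax
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (j in nb) for (h in nb)
      if (j != h && W[j, h] > 0)
        acc <- acc + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    out[i] <- acc / (k * (k - 1))
  }
  out
}

brute_local_efficiency <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    out[i] <- brute_eglob(W[nb, nb, drop = FALSE])
  }
  out
}

# step-up BH definition, literal
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (r in m:1) {
    prev <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- prev
  }
  pmin(adj, 1)
}

# ring lattice: each node joined to k/2 nearest neighbors per side
ring_lattice <- function(n, k) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (s in seq_len(k / 2)) {
    j <- ((i - 1 + s) %% n) + 1
    W[i, j] <- W[j, i] <- 1
  }
  W
}

# Watts-Strogatz style rewiring: each edge reattached with prob p at one end
ws_rewire <- function(W, p) {
  n <- nrow(W)
  ed <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  for (e in seq_len(nrow(ed))) {
    if (runif(1) >= p) next
    i <- ed[e, 1]; j <- ed[e, 2]
    cand <- which(W[i, ] == 0 & seq_len(n) != i)
    if (length(cand) == 0) next
    jnew <- cand[sample.int(length(cand), 1)]
    W[i, j] <- W[j, i] <- 0
    W[i, jnew] <- W[jnew, i] <- 1
  }
  W
}

er_graph <- function(n, m_edges) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- sample(ut, m_edges)
  W[on] <- 1
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

# small synthetic cohort for fast pipeline tests
tiny_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_spec(seed = seed, ...))
}
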