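test_that("closed-form values on canonical small graphs", {
  path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(shortest_path_distances(path3)[1, 3], 2)
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3)
  expect_equal(characteristic_path_length(path3), (1 + 1 + 2) / 3)

  half <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(shortest_path_distances(half)[1, 2], 2)   # l = 1/w

  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(global_efficiency(K5), 1)
  expect_equal(characteristic_path_length(K5), 1)
  expect_equal(unname(weighted_clustering(K5)), rep(1, 5))
  expect_equal(unname(local_efficiency(K5)), rep(1, 5))

  tri <- matrix(0.4, 3, 3); diag(tri) <- 0
  expect_equal(unname(weighted_clustering(tri)), rep(1, 3))  # max-normalized

  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 0.8
  expect_equal(unname(weighted_clustering(star))[1], 0)
  expect_equal(unname(local_efficiency(star)), rep(0, 5))
  dc <- degree_centrality(star)
  expect_equal(dc$strength[1], 3.2)
  expect_equal(dc$degree[1], 4)
  expect_equal(dc$strength[2], 0.8)

  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 0.5
  expect_equal(degree_centrality(iso)$strength[3], 0)
  # disconnected pair policy: two disjoint unit edges -> Lp = 1
  two <- matrix(0, 4, 4); two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1
  expect_equal(characteristic_path_length(two), 1)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "disconnected")
})

test_that("all metrics match brute-force oracles on random graphs", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    W <- rand_weighted_graph(n, p = runif(1, 0.25, 0.9))
    D <- shortest_path_distances(W)
    expect_equal(D, fw_distances(W), tolerance = 1e-12)
    g <- scnet:::graph_metrics_cpp(W, 0L, TRUE, TRUE)
    expect_equal(g$eglob, brute_eglob(W), tolerance = 1e-12)
    if (any(is.finite(fw_distances(W)[upper.tri(W)])))
      expect_equal(g$lp, brute_lp(W), tolerance = 1e-12)
    expect_equal(unname(weighted_clustering(W)), brute_clustering_onnela(W),
                 tolerance = 1e-12)
    expect_equal(unname(local_efficiency(W)), brute_local_efficiency(W),
                 tolerance = 1e-12)
    ni <- nodal_integration(W)
    oracle <- brute_nodal_integration(W)
    expect_equal(ni$path_length, oracle$path_length, tolerance = 1e-12)
    expect_equal(ni$efficiency, oracle$efficiency, tolerance = 1e-12)
  }
})

test_that("distances agree with igraph as an independent library cross-check", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:10) {
    W <- rand_weighted_graph(10, p = 0.5)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    Dig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(unname(shortest_path_distances(W)), unname(Dig),
                 tolerance = 1e-12)
  }
})

test_that("metric scaling behavior under global weight rescaling", {
  set.seed(43)
  W <- rand_weighted_graph(12, p = 0.6)
  c0 <- 0.37
  expect_equal(weighted_clustering(W * c0), weighted_clustering(W),
               tolerance = 1e-12)
  expect_equal(shortest_path_distances(W * c0),
               shortest_path_distances(W) / c0, tolerance = 1e-12)
  sw1 <- small_world(W, n_nulls = 5, seed = 9)
  sw2 <- small_world(W * c0, n_nulls = 5, seed = 9)
  expect_equal(sw1$gamma, sw2$gamma, tolerance = 1e-10)
  expect_equal(sw1$lambda, sw2$lambda, tolerance = 1e-10)
  expect_equal(sw1$sigma, sw2$sigma, tolerance = 1e-10)
})

test_that("AUC reduction: closed forms and linearity", {
  d <- density_grid()
  expect_equal(length(d), 31)
  expect_equal(auc_over_density(rep(2.5, 31)), 0.30 * 2.5, tolerance = 1e-12)
  expect_equal(auc_over_density(d), 0.5 * (0.40^2 - 0.10^2), tolerance = 1e-12)
  set.seed(44)
  x <- rnorm(31); y <- rnorm(31)
  expect_equal(auc_over_density(2 * x + 3 * y),
               2 * auc_over_density(x) + 3 * auc_over_density(y),
               tolerance = 1e-12)
  expect_error(auc_over_density(rnorm(30)), "does not match")
})

test_that("small-world normalization against the network itself is 1", {
  set.seed(45)
  W <- threshold_proportional(build_covariance_network(rnorm(30)), 0.3)
  sw <- small_world(W, nulls = list(W))
  expect_equal(sw$gamma, 1, tolerance = 1e-12)
  expect_equal(sw$lambda, 1, tolerance = 1e-12)
  expect_equal(sw$sigma, 1, tolerance = 1e-12)
  expect_false(sw$small_world)
})

test_that("sweep_metrics assembles per-density values and AUCs coherently", {
  set.seed(46)
  W <- build_covariance_network(rnorm(74))
  s <- sweep_metrics(W, n_nulls = 10, seed = 5, small_world = TRUE)
  expect_equal(nrow(s$global), 31)
  expect_equal(s$global$sigma, s$global$gamma / s$global$lambda)
  expect_true(all(is.finite(s$global$sigma)))
  expect_equal(unname(s$global_auc["eglob"]),
               auc_over_density(s$global$eglob), tolerance = 1e-12)
  expect_equal(dim(s$nodal_auc), c(74, 6))
  # eglob increases with density (more strong edges can only help)
  expect_true(all(diff(s$global$eglob) > 0))
  # same seed reproduces, different seed varies the null normalization
  s2 <- sweep_metrics(W, n_nulls = 10, seed = 5, small_world = TRUE,
                      nodal = FALSE)
  expect_equal(s$global$gamma, s2$global$gamma, tolerance = 1e-15)
  s3 <- sweep_metrics(W, n_nulls = 10, seed = 6, small_world = TRUE,
                      nodal = FALSE)
  expect_false(identical(s$global$gamma, s3$global$gamma))
})
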