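test_that("betweenness: hand cases", {
  path3 <- adjacency_from_edges(3, list(c(1, 2), c(2, 3)))
  b <- betweenness_centrality(path3)
  expect_equal(unname(b), c(0, 1, 0))
  k4 <- 1 - diag(1, 4)
  dimnames(k4) <- list(paste0("g", 1:4), paste0("g", 1:4))
  expect_equal(unname(betweenness_centrality(k4)), rep(0, 4))
  # fewer than 3 nodes: all zeros
  expect_equal(unname(betweenness_centrality(matrix(c(0, 1, 1, 0), 2, 2))),
               c(0, 0))
  expect_error(betweenness_centrality(random_weighted_adjacency(5)),
               "binary")
})

test_that("betweenness equals the BFS path-counting oracle", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    a <- random_binary_adjacency(n, p = runif(1, 0.2, 0.6))
    expect_equal(unname(betweenness_centrality(a)), oracle_betweenness(a),
                 tolerance = 1e-12)
  }
})

test_that("unnormalized betweenness conserves path-interior incidences", {
  set.seed(13)
  for (rep in 1:5) {
    a <- random_binary_adjacency(8, 0.4)
    b <- betweenness_centrality(a, normalized = FALSE)
    geo <- oracle_geodesics(a)
    total <- 0  # sum over unordered pairs of (interior incidences / paths)
    for (i in 1:7) for (j in (i + 1):8) {
      if (!is.finite(geo$dist[i, j]) || geo$dist[i, j] < 2) next
      total <- total + (geo$dist[i, j] - 1)  # interior nodes per geodesic
    }
    expect_equal(sum(b), total, tolerance = 1e-10)
  }
})

test_that("closeness: hand cases under the component-scaled convention", {
  path3 <- adjacency_from_edges(3, list(c(1, 2), c(2, 3)))
  cc <- closeness_centrality(path3)
  expect_equal(unname(cc), c(2 / 3, 1, 2 / 3))
  k4 <- 1 - diag(1, 4)
  expect_equal(unname(closeness_centrality(k4)), rep(1, 4))
  # two disjoint K2 components in n = 4: each node (1/3) * (1/1)
  two_k2 <- adjacency_from_edges(4, list(c(1, 2), c(3, 4)))
  expect_equal(unname(closeness_centrality(two_k2)), rep(1 / 3, 4))
  # isolated node gets 0
  iso <- adjacency_from_edges(3, list(c(1, 2)))
  expect_equal(unname(closeness_centrality(iso)), c(1 / 2, 1 / 2, 0))
})

test_that("clustering coefficients: hand cases and oracle equivalence", {
  tri <- adjacency_from_edges(3, list(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(unname(clustering_coefficients(tri)), rep(1, 3))
  star <- adjacency_from_edges(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  expect_equal(unname(clustering_coefficients(star)), rep(0, 5))
  set.seed(14)
  for (rep in 1:20) {
    a <- random_weighted_adjacency(8)
    expect_equal(unname(clustering_coefficients(a)), oracle_clustering(a),
                 tolerance = 1e-12)
  }
})

test_that("weighted clustering reduces to the binary formula on 0/1 input", {
  set.seed(15)
  for (rep in 1:10) {
    a <- random_binary_adjacency(10, 0.5)
    cc <- clustering_coefficients(a)
    k <- rowSums(a)
    tri <- diag(a %*% a %*% a) / 2
    manual <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
    expect_equal(unname(cc), unname(manual), tolerance = 1e-12)
  }
})

test_that("degree fits recover noiseless power laws", {
  k <- 1:20
  pk <- k^-2 / sum(k^-2)
  fit <- degree_distribution_fit(bins = data.frame(k = k, pk = pk))
  expect_equal(fit$exponent_r, -2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # constant p(k): exponent 0
  flat <- degree_distribution_fit(bins = data.frame(k = 1:10, pk = 0.1))
  expect_equal(flat$exponent_r, 0, tolerance = 1e-12)
})

test_that("truncated fit recovers (r, alpha) and beats the pure power law", {
  k <- 1:20
  pk <- k^-1 * exp(-0.2 * k); pk <- pk / sum(pk)
  tr <- degree_distribution_fit(bins = data.frame(k = k, pk = pk),
                                model = "truncated_power_law")
  expect_equal(tr$exponent_r, -1, tolerance = 1e-6)
  expect_equal(tr$alpha, 0.2, tolerance = 1e-6)
  expect_equal(tr$r_squared, 1, tolerance = 1e-9)
  pl <- degree_distribution_fit(bins = data.frame(k = k, pk = pk))
  expect_lt(pl$r_squared, tr$r_squared)
})

test_that("degree fit input contract", {
  expect_error(degree_distribution_fit(), "degrees or bins")
  expect_error(degree_distribution_fit(bins = data.frame(k = 1:2,
                                                         pk = c(.5, .5))),
               "3 usable bins")
  # integer degrees are binned per integer
  fit <- degree_distribution_fit(c(1, 1, 1, 1, 2, 2, 3, 4))
  expect_equal(fit$bins$k, c(1, 2, 3, 4))
  expect_equal(fit$bins$pk, c(4, 2, 1, 1) / 8)
})

test_that("preferential-attachment networks fit a negative power law", {
  set.seed(16)
  g <- igraph::sample_pa(5000, power = 1, m = 1, directed = FALSE)
  deg <- igraph::degree(g)
  fit <- degree_distribution_fit(deg, binning = "log", n_bins = 12)
  expect_lt(fit$exponent_r, 0)
  # theoretical exponent for linear preferential attachment is 3
  expect_equal(abs(fit$exponent_r), 3, tolerance = 0.5 / 3)
  expect_gt(fit$r_squared, 0.8)
})

test_that("node_topology assembles consistent columns", {
  set.seed(17)
  a <- random_binary_adjacency(12, 0.3)
  prof <- node_topology(a)
  expect_equal(prof$degree, as.numeric(rowSums(a)))
  expect_equal(prof$betweenness,
               unname(betweenness_centrality(a)))
  expect_true(all(prof$closeness >= 0 & prof$closeness <= 1))
  expect_true(all(prof$clustering_coefficient >= 0 &
                    prof$clustering_coefficient <= 1))
})

test_that("candidate selection: union, tags and tie-breaks", {
  prof <- data.frame(
    gene_id = sprintf("g%02d", 1:8),
    degree = c(9, 8, 7, 6, 5, 4, 3, 2),
    betweenness = c(0.01, 0.02, 0.01, 0.9, 0.8, 0.7, 0.6, 0.5))
  out <- select_candidates(prof, n_top_degree = 3, n_top_bc = 3)
  expect_setequal(out$gene_id[out$selected_by %in% c("degree", "both")],
                  c("g01", "g02", "g03"))
  expect_setequal(out$gene_id[out$selected_by %in% c("bc", "both")],
                  c("g04", "g05", "g06"))
  expect_equal(nrow(out), 6)
  # overlapping winner tagged both, appears once
  out2 <- select_candidates(prof, 1, 4)
  expect_equal(sum(out2$gene_id == "g01"), 1)
  expect_true("both" %in% out2$selected_by[out2$gene_id == "g04"] ||
                out2$selected_by[out2$gene_id == "g04"] == "bc")
  expect_equal(nrow(select_candidates(prof, 0, 0)), 0)
  expect_error(select_candidates(prof, 9, 2), "exceed")
  # degree tie broken by betweenness
  proft <- data.frame(gene_id = c("a", "b", "c"),
                      degree = c(5, 5, 1),
                      betweenness = c(0.1, 0.3, 0))
  expect_equal(select_candidates(proft, 1, 0)$gene_id, "b")
})

test_that("disjoint top sets give the published 6 + 5 = 11 candidates", {
  set.seed(18)
  prof <- data.frame(gene_id = sprintf("g%02d", 1:40),
                     degree = c(40:35, sample(10, 34, replace = TRUE)),
                     betweenness = c(rep(0, 6), 0.9, 0.8, 0.7, 0.6, 0.5,
                                     runif(29, 0, 0.1)))
  out <- select_candidates(prof, n_top_degree = 6, n_top_bc = 5)
  expect_equal(nrow(out), 11)
  expect_equal(sum(out$selected_by == "degree"), 6)
  expect_equal(sum(out$selected_by == "bc"), 5)
})
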