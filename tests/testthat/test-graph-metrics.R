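test_that("degree centrality counts neighbors and rejects asymmetric input", {
  expect_identical(unname(degree_centrality(path_graph(3))), c(1L, 2L, 1L))
  expect_identical(unname(degree_centrality(complete_graph(5))), rep(4L, 5))
  bad <- path_graph(3)
  bad[1, 3] <- 1
  expect_error(degree_centrality(bad), "symmetric")
})

test_that("betweenness matches enumeration on canonical graphs", {
  expect_equal(unname(betweenness_centrality(path_graph(3))), c(0, 1, 0))
  b <- unname(betweenness_centrality(star_graph(5)))
  expect_equal(b, c(1, 0, 0, 0, 0))
})

test_that("clustering coefficient follows the triangle-count definition", {
  expect_equal(clustering_coefficient(complete_graph(3)), 1)
  expect_equal(clustering_coefficient(star_graph(5)), 0)
  # 4-cycle with one chord: (2/3 + 1 + 2/3 + 1)/4 = 5/6
  cyc <- matrix(0, 4, 4)
  cyc[1, 2] <- cyc[2, 3] <- cyc[3, 4] <- cyc[4, 1] <- cyc[1, 3] <- 1
  cyc <- cyc + t(cyc)
  cyc[cyc > 1] <- 1
  expect_equal(clustering_coefficient(cyc), 5 / 6)
})

test_that("characteristic path length averages over reachable pairs", {
  expect_equal(characteristic_path_length(complete_graph(6))$lp, 1)
  p3 <- characteristic_path_length(path_graph(3))
  expect_equal(p3$lp, 4 / 3)
  expect_equal(p3$reachable_fraction, 1)
  two_k3 <- rbind(cbind(complete_graph(3), matrix(0, 3, 3)),
                  cbind(matrix(0, 3, 3), complete_graph(3)))
  res <- characteristic_path_length(two_k3)
  expect_equal(res$lp, 1)
  expect_equal(res$reachable_fraction, 6 / 15)
  expect_error(characteristic_path_length(matrix(0, 4, 4)), "no edges")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(77)
  for (i in 1:50) {
    adj <- random_adjacency(8, p = runif(1, 0.2, 0.7))
    expect_identical(unname(degree_centrality(adj)), as.integer(rowSums(adj)))
    expect_equal(unname(betweenness_centrality(adj)), oracle_betweenness(adj),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(adj), oracle_clustering(adj),
                 tolerance = 1e-12)
    if (sum(adj) > 0) {
      got <- characteristic_path_length(adj)
      want <- oracle_lp(adj)
      expect_equal(got$lp, want$lp, tolerance = 1e-12)
      expect_equal(got$reachable_fraction, want$reachable_fraction,
                   tolerance = 1e-12)
    }
  }
})

test_that("adding an edge never decreases degree nor increases reachable-pair Lp", {
  set.seed(5)
  for (i in 1:20) {
    adj <- random_adjacency(10, 0.3)
    free <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(free) || sum(adj) == 0) next
    pick <- free[sample(nrow(free), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1
    expect_true(all(degree_centrality(adj2) >= degree_centrality(adj)))
    # compare Lp on the pair set reachable in the sparser graph
    d1 <- oracle_distances(adj)
    d2 <- oracle_distances(adj2)
    reach <- is.finite(d1) & upper.tri(d1)
    expect_lte(mean(d2[reach]), mean(d1[reach]))
  }
})

test_that("small-world index is 1 on complete graphs and reproducible", {
  sw <- suppressWarnings(small_world(complete_graph(10), n_null = 20,
                                     null_seed = 3))
  expect_identical(sw$cp, 1)
  expect_identical(sw$lp, 1)
  expect_identical(sw$sigma, 1)

  co <- simulate_cohort(sim_config(n_per_group = 12, seed = 2))
  adj <- binarize_by_density(
    build_mcn(residualize_age(co$thickness, co$clinical$age)), 0.15)
  a <- small_world(adj, n_null = 20, null_seed = 7)
  b <- small_world(adj, n_null = 20, null_seed = 7)
  expect_identical(a, b)
  c <- small_world(adj, n_null = 20, null_seed = 8)
  expect_false(identical(a$cp_rand, c$cp_rand))
  expect_identical(a$null_model, "degree-preserving")
})

test_that("unrewirable degree sequences fall back to density-matched nulls", {
  expect_warning(sw <- small_world(star_graph(12), n_null = 20, null_seed = 1),
                 "density-matched")
  expect_identical(sw$null_model, "density-matched")
  expect_true(is.finite(sw$sigma))
})

test_that("predominant nodes require jointly high degree and betweenness", {
  # equal metrics everywhere: nothing can exceed mean + 1 SD
  k <- complete_graph(10)
  dimnames(k) <- list(paste0("n", 1:10), paste0("n", 1:10))
  expect_length(predominant_nodes(node_metrics(k))$regions, 0)

  s <- star_graph(12)
  dimnames(s) <- list(paste0("n", 1:12), paste0("n", 1:12))
  expect_identical(predominant_nodes(node_metrics(s))$regions, "n1")

  # planted connector bridging three cliques
  n <- 16
  adj <- matrix(0, n, n)
  for (b in 0:2) {
    idx <- b * 5 + 1:5
    adj[idx, idx] <- 1
  }
  adj[16, c(1, 2, 6, 7, 11, 12)] <- adj[c(1, 2, 6, 7, 11, 12), 16] <- 1
  diag(adj) <- 0
  dimnames(adj) <- list(paste0("n", 1:n), paste0("n", 1:n))
  expect_true("n16" %in% predominant_nodes(node_metrics(adj))$regions)
})

test_that("metrics supplied over a density grid are averaged before thresholding", {
  s <- star_graph(8)
  dimnames(s) <- list(paste0("n", 1:8), paste0("n", 1:8))
  stacked <- rbind(node_metrics(s, density = 0.1), node_metrics(s, density = 0.2))
  out <- predominant_nodes(stacked)
  expect_identical(out$regions, "n1")
  expect_identical(nrow(out$metrics), 8L)
})
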