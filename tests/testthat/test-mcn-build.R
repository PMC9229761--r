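test_that("pearson_r matches hand values and the classical test", {
  expect_equal(pearson_r(1:4, c(2, 4, 6, 8))$r, 1)
  expect_equal(pearson_r(1:4, c(8, 6, 4, 2))$r, -1)
  out <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(out$r, 0.8)
  ct <- cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(out$p, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_r(1:3, c(2, 4, 6)), "n >= 4")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("the n = 24 edge mask corresponds to the |r| ~ 0.404 threshold", {
  set.seed(21)
  X <- matrix(rnorm(24 * 30), 24, 30, dimnames = list(NULL, paste0("R", 1:30)))
  m <- build_mcn(X, alpha = 0.05)
  ut <- upper.tri(m$r)
  r_crit <- sqrt(qt(0.975, 22)^2 / (qt(0.975, 22)^2 + 22))  # 0.4044
  expect_equal(r_crit, 0.4044, tolerance = 1e-4)
  expect_true(all(abs(m$r[ut & m$sig_mask]) > r_crit - 1e-12))
  expect_true(all(abs(m$r[ut & !m$sig_mask]) < r_crit + 1e-12))
})

test_that("MCN construction is symmetric, masked and subject-order invariant", {
  co <- simulate_cohort(sim_config(n_per_group = 12, seed = 4))
  res <- residualize_age(co$thickness, co$clinical$age)
  m <- build_mcn(res)
  expect_identical(m$r, t(m$r))
  expect_identical(m$p, t(m$p))
  expect_equal(unname(diag(m$r)), rep(1, 66))
  expect_false(any(diag(m$sig_mask)))
  set.seed(1)
  perm <- sample(nrow(res$residuals))
  m2 <- build_mcn(res$residuals[perm, ])
  expect_equal(m2$r, m$r, tolerance = 1e-12)

  bad <- res$residuals
  bad[, 3] <- 0
  expect_error(build_mcn(bad), colnames(bad)[3])
})

test_that("strongly modular cohorts produce fully significant within-module blocks", {
  co <- simulate_cohort(sim_config(n_per_group = 25, seed = 8,
                                   rho_within = 0.95, rho_between = 0))
  m <- build_mcn(residualize_age(co$thickness, co$clinical$age))
  mods <- mcnet:::module_assignment(66, 6)
  within <- outer(mods, mods, "==") & upper.tri(m$r)
  expect_true(all(m$sig_mask[within]))
})

test_that("independent noise yields ~alpha significant edges", {
  set.seed(31)
  frac <- replicate(10, {
    X <- matrix(rnorm(24 * 66), 24, 66, dimnames = list(NULL, paste0("R", 1:66)))
    m <- build_mcn(X)
    mean(m$sig_mask[upper.tri(m$r)])
  })
  expect_gt(mean(frac), 0.03)
  expect_lt(mean(frac), 0.07)
})

test_that("edge-wise Fisher z comparison follows the two-correlation formula", {
  co <- simulate_cohort(sim_config(n_per_group = 12, seed = 4))
  res <- residualize_age(co$thickness, co$clinical$age)
  m <- build_mcn(res)
  z0 <- edge_z_compare(m, m)
  expect_equal(max(abs(z0$z)), 0)

  # hand evaluation: r_a = 0.9, r_b = 0, n = 12 each
  ra <- m$r; ra[] <- 0.9; diag(ra) <- 1
  rb <- m$r; rb[] <- 0; diag(rb) <- 1
  ma <- m; ma$r <- ra; ma$n_subjects <- 12L
  mb <- m; mb$r <- rb; mb$n_subjects <- 12L
  z <- edge_z_compare(ma, mb)
  expect_equal(z$z[1, 2], atanh(0.9) / sqrt(2 / 9), tolerance = 1e-12)
  expect_equal(z$z[1, 2], 3.12, tolerance = 0.01)

  # antisymmetry under swapping groups
  m2 <- build_mcn(res$residuals[1:12, ])
  m3 <- build_mcn(res$residuals[13:24, ])
  expect_equal(edge_z_compare(m2, m3)$z, -edge_z_compare(m3, m2)$z,
               tolerance = 1e-12)

  # |r| = 1 is clamped with a warning
  mc <- m
  mc$r[1, 2] <- mc$r[2, 1] <- 1
  expect_warning(edge_z_compare(mc, m), "clamped")
})

test_that("density binarization keeps floor(density x pairs) top-|r| edges", {
  m <- fake_full_mcn()
  adj <- binarize_by_density(m, 0.1)
  expect_identical(sum(adj) / 2, floor(0.1 * 2145))  # 214
  expect_identical(unname(diag(adj)), rep(0, 66))
  expect_identical(adj, t(adj))

  full <- binarize_by_density(m, 1)
  expect_identical(sum(full) / 2, 2145)
  tiny <- binarize_by_density(m, 1e-4)
  expect_identical(sum(tiny), 0)
  expect_error(binarize_by_density(m, 1.5), "density")
  expect_error(binarize_by_density(m, 0), "density")

  # retained edges are exactly the largest |r| among significant pairs
  kept <- abs(m$r[upper.tri(m$r)])[adj[upper.tri(adj)] == 1]
  dropped <- abs(m$r[upper.tri(m$r)])[adj[upper.tri(adj)] == 0]
  expect_gte(min(kept), max(dropped))

  # edge signs are carried for reporting
  sgn <- attr(adj, "edge_sign")
  expect_true(all(sgn[adj == 1] %in% c(-1, 1)))
  expect_true(all(sgn[adj == 0] == 0))
})

test_that("edge sets are nested across increasing densities", {
  co <- simulate_cohort(sim_config(n_per_group = 12, seed = 6))
  m <- build_mcn(residualize_age(co$thickness, co$clinical$age))
  grid <- seq(0.05, 0.30, by = 0.05)
  adjs <- lapply(grid, function(d) suppressWarnings(binarize_by_density(m, d)))
  for (i in seq_len(length(grid) - 1)) {
    expect_true(all(adjs[[i + 1]][adjs[[i]] == 1] == 1))
  }
})

test_that("requesting more edges than significant pairs warns and truncates", {
  set.seed(12)
  X <- matrix(rnorm(24 * 66), 24, 66, dimnames = list(NULL, paste0("R", 1:66)))
  m <- build_mcn(X)   # ~5% of pairs significant
  expect_warning(adj <- binarize_by_density(m, 0.5), "keeping all significant")
  expect_equal(sum(adj) / 2, sum(m$sig_mask[upper.tri(m$r)]))
})
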