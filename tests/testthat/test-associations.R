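test_that("partial correlation handles exact and null relationships", {
  set.seed(1)
  ages <- runif(50, 20, 70)
  th <- 2.5 + rnorm(50, 0, 0.1)
  # outcome equal to thickness itself: partial r = 1 exactly
  out <- partial_correlation_age(th, th, ages)
  expect_equal(out$partial_r, 1, tolerance = 1e-12)
  expect_equal(out$r_squared, out$partial_r^2)

  # outcome driven only by age: no residual association with thickness
  set.seed(2)
  ages2 <- runif(200, 20, 70)
  th2 <- 2.5 + rnorm(200, 0, 0.1)
  y2 <- 3 * ages2 + rnorm(200, 0, 1)
  expect_lt(abs(partial_correlation_age(th2, y2, ages2)$partial_r), 0.15)

  expect_error(partial_correlation_age(th[1:4], th[1:4], ages[1:4]), "n >= 5")
  expect_error(partial_correlation_age(rep(2, 50), th, ages), "constant")
  expect_error(partial_correlation_age(th, rep(1, 50), ages), "outcome")
})

test_that("partial correlation recovers a planted thickness-outcome link", {
  set.seed(3)
  ages <- runif(100, 20, 70)
  th <- 2.5 - 0.005 * (ages - 45) + rnorm(100, 0, 0.1)
  y <- 10 + 0.5 * th + rnorm(100, 0, 0.1)
  truth <- 0.5 * 0.1 / sqrt((0.5 * 0.1)^2 + 0.1^2)  # ~0.447
  est <- partial_correlation_age(th, y, ages)$partial_r
  expect_lt(abs(est - truth), 0.15)
})

test_that("partial correlation is invariant to affine rescaling", {
  set.seed(4)
  ages <- runif(40, 20, 70)
  th <- 2.5 + 0.01 * ages + rnorm(40, 0, 0.2)
  y <- 50 - 5 * th + rnorm(40, 0, 1)
  r0 <- partial_correlation_age(th, y, ages)$partial_r
  r1 <- partial_correlation_age(1000 * th - 3, 0.2 * y + 7,
                                2 * ages - 30)$partial_r
  expect_lt(abs(r0 - r1), 1e-10)
})

test_that("group t-test matches hand computation and sign convention", {
  g <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
  same <- group_ttest(rep(c(2, 3, 4), 2), g)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  out <- group_ttest(c(2, 3, 4, 4, 5, 6), g)
  expect_equal(out$t_statistic, -3 / sqrt(1.5), tolerance = 1e-12)  # -2.449
  expect_equal(sign(out$t_statistic), sign(out$mean_a - out$mean_b))
  expect_error(group_ttest(c(2, 3, 4, 5), factor(c("a", "a", "a", "b"))),
               "at least 2")

  # mean-shifted groups are detected with high power
  set.seed(5)
  hits <- mean(replicate(40, {
    x <- c(rnorm(50, 0), rnorm(50, 1))
    group_ttest(x, factor(rep(c("a", "b"), each = 50)))$p_value < 0.05
  }))
  expect_gte(hits, 0.95)
})

test_that("region scan ranks a generator-planted outcome link first", {
  cfg <- sim_config(n_per_group = 50, seed = 17,
                    outcome_links = list(list(region = "l STG",
                                              outcome = "pci",
                                              slope = 100, noise_sd = 16)))
  co <- simulate_cohort(cfg)
  res <- scan_all_regions(co, "pci")
  expect_identical(res$region[1], "lh_superiortemporal_thickness")
  expect_true(res$significant[1])
  expect_identical(nrow(res), 66L)
  expect_equal(res$r_squared, res$partial_r^2)
  expect_false(is.unsorted(res$p_value))
})

test_that("region scan flags ~alpha regions for a pure-noise outcome", {
  set.seed(19)
  counts <- replicate(20, {
    co <- simulate_cohort(sim_config(n_per_group = 12,
                                     seed = sample.int(1e6, 1),
                                     outcome_links = list()))
    co$clinical$pci_score <- rnorm(24)
    sum(scan_all_regions(co, "pci")$significant)
  })
  expect_gt(mean(counts), 1.5)
  expect_lt(mean(counts), 5.5)
})

test_that("degenerate outcomes and unknown outcome names are rejected", {
  co <- simulate_cohort(sim_config(n_per_group = 6, seed = 1))
  co$clinical$pci_score <- rep(40, 12)
  expect_error(scan_all_regions(co, "pci"), "constant")
  expect_error(scan_all_regions(co, "nonesuch"), "unknown outcome")
})

test_that("FDR switch adjusts the significance flags", {
  co <- simulate_cohort(sim_config(n_per_group = 20, seed = 23,
                                   outcome_links = list()))
  co$clinical$pci_score <- rnorm(40)
  raw <- scan_all_regions(co, "pci")
  adj <- scan_all_regions(co, "pci", fdr = TRUE)
  expect_true("p_adjusted" %in% names(adj))
  expect_lte(sum(adj$significant), sum(raw$significant))
})
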