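test_that("copula draws have the right Beta marginals and cross-correlation", {
  pr <- table2_priors()
  n <- 5e4
  q <- sample_correlated_betas(pr, rho = 0.1, n = n, seed = 101)
  for (nm in names(pr)) {
    m <- beta_moments(pr[[nm]])
    mcse <- sqrt(m[["variance"]] / n)
    expect_lt(abs(mean(q[[nm]]) - m[["mean"]]), 4 * mcse)
  }
  # correlated pairs near 0.1 (the Gaussian copula's rank correlation at
  # rho = 0.1 is (6/pi) asin(rho/2) ~ 0.0955), independent pairs near 0
  expect_lt(abs(cor(q$se_cases, q$se_controls, method = "spearman") - 0.1), 0.02)
  expect_lt(abs(cor(q$sp_cases, q$sp_controls, method = "spearman") - 0.1), 0.02)
  expect_lt(abs(cor(q$se_cases, q$sp_cases)), 0.02)
  expect_lt(abs(cor(q$se_controls, q$sp_cases)), 0.02)

  q0 <- sample_correlated_betas(pr, rho = 0, n = n, seed = 102)
  cors <- cor(q0)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.02)
})

test_that("degenerate priors yield point draws", {
  pt <- misclass_priors(beta_point(0.8), beta_point(0.9),
                        beta_point(0.8), beta_point(0.9))
  q <- sample_correlated_betas(pt, rho = 0.1, n = 100, seed = 1)
  expect_true(all(q$se_cases == 0.8 & q$sp_cases == 0.9))
  # huge-shape Betas approach the same limit
  m <- 0.8
  big <- misclass_priors(beta_spec(1e9 * m, 1e9 * (1 - m)), beta_point(0.9),
                         beta_point(0.8), beta_point(0.9))
  q2 <- sample_correlated_betas(big, rho = 0, n = 1000, seed = 2)
  expect_equal(max(abs(q2$se_cases - m)), 0, tolerance = 1e-4)
})

test_that("copula sampling is deterministic given a seed", {
  pr <- table2_priors()
  expect_identical(sample_correlated_betas(pr, 0.1, 500, seed = 7),
                   sample_correlated_betas(pr, 0.1, 500, seed = 7))
})

test_that("with point-mass priors and no random error PBA equals the fixed correction", {
  obs <- observed_table(80, 120, 100, 100)
  pt <- misclass_priors(beta_point(0.8), beta_point(0.9),
                        beta_point(0.8), beta_point(0.9))
  cfg <- pba_config(n_iter = 500, rho = 0.1, include_random_error = FALSE, seed = 5)
  res <- run_pba(obs, pt, cfg)
  fixed <- odds_ratio_ci(correct_counts(obs, 0.8, 0.9, 0.8, 0.9))
  expect_equal(res$n_rejected, 0)
  expect_identical(unique(res$draws), fixed$or_point)
  expect_equal(res$median, fixed$or_point)
})

test_that("perfect-classification point priors recover the crude OR", {
  obs <- observed_table(80, 120, 100, 100)
  pt <- misclass_priors(beta_point(1 - 1e-12), beta_point(1 - 1e-12),
                        beta_point(1 - 1e-12), beta_point(1 - 1e-12))
  res <- run_pba(obs, pt, pba_config(n_iter = 200, include_random_error = FALSE, seed = 5))
  crude <- odds_ratio_ci(obs)$or_point
  expect_equal(res$median, crude, tolerance = 1e-8)
})

test_that("the PBA median is Monte-Carlo stable when doubling iterations", {
  obs <- observed_table(800, 1200, 1000, 1000)
  pr <- table2_priors()
  r1 <- run_pba(obs, pr, pba_config(n_iter = 20000, include_random_error = FALSE, seed = 31))
  r2 <- run_pba(obs, pr, pba_config(n_iter = 40000, include_random_error = FALSE, seed = 31))
  # MC standard error of the median ~ 1.25 * sd / sqrt(n) on the log scale
  mcse <- 1.25 * sd(log(r1$draws)) / sqrt(length(r1$draws))
  expect_lt(abs(log(r1$median) - log(r2$median)), 3 * mcse)
})

test_that("simulation intervals are nested in the level", {
  obs <- observed_table(800, 1200, 1000, 1000)
  pr <- table2_priors()
  r95 <- run_pba(obs, pr, pba_config(n_iter = 10000, seed = 9, level = 0.95))
  r99 <- run_pba(obs, pr, pba_config(n_iter = 10000, seed = 9, level = 0.99))
  expect_lt(r99$lo, r95$lo)
  expect_gt(r99$hi, r95$hi)
  expect_true(r95$lo <= r95$median && r95$median <= r95$hi)
})

test_that("draws are rejected only when the correction is infeasible", {
  pr <- table2_priors()
  # apparent proportions ~0.4, far inside (1-sp, se) for any plausible draw
  obs <- observed_table(800, 1200, 820, 1180)
  res <- run_pba(obs, pr, pba_config(n_iter = 5000, seed = 12))
  expect_equal(res$n_rejected, 0)
  expect_length(res$draws, 5000)

  # apparent exposure below the false-positive floor: every draw infeasible
  pt <- misclass_priors(beta_point(0.8), beta_point(0.9),
                        beta_point(0.8), beta_point(0.9))
  expect_error(run_pba(observed_table(5, 195, 5, 195), pt,
                       pba_config(n_iter = 50, seed = 1)),
               "degenerate probabilistic bias analysis")
})

test_that("retained draws plus rejections account for every iteration", {
  # priors wide enough that some draws land outside the feasible region
  wide <- misclass_priors(beta_spec(3, 1.2), beta_spec(3, 1.2),
                          beta_spec(3, 1.2), beta_spec(3, 1.2))
  obs <- observed_table(60, 140, 50, 150)
  res <- run_pba(obs, wide, pba_config(n_iter = 4000, seed = 77))
  expect_gt(res$n_rejected, 0)
  expect_equal(length(res$draws) + res$n_rejected, 4000)
})

test_that("config validation catches bad inputs", {
  expect_error(pba_config(n_iter = 0), "positive integer")
  expect_error(pba_config(rho = 1), "rho")
  expect_error(pba_config(level = 1), "level")
})
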