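test_that("simulated genetic variance hits its target", {
  cfg <- sim_config(M = 100, N = 2000, h2 = 0.1, K = 0.1,
                    n_replicates = 1)
  set.seed(1)
  vg <- replicate(40, var(simulate_cohort(cfg)$g))
  se <- sd(vg) / sqrt(length(vg))
  expect_lt(abs(mean(vg) - 0.1), 3 * se)
  # liability has unit variance overall
  set.seed(2)
  y <- simulate_cohort(cfg)$liability
  expect_lt(abs(var(y) - 1), 0.1)
})

test_that("a null architecture yields no genetic variance and the population case rate", {
  cfg <- sim_config(M = 50, N = 5000, h2 = 0, K = 0.1)
  set.seed(3)
  coh <- simulate_cohort(cfg)
  expect_equal(var(coh$g), 0)
  expect_lt(abs(mean(coh$status) - 0.1), 3 * sqrt(0.1 * 0.9 / 5000))
})

test_that("ascertainment fills exact quotas with the expected number of draws", {
  cfg <- sim_config(M = 20, N = 2000, h2 = 0.1, K = 0.1, P = 0.5,
                    ascertained = TRUE)
  set.seed(4)
  draws <- replicate(30, {
    coh <- simulate_cohort(cfg)
    expect_identical(sum(coh$status), 1000L)
    expect_identical(length(coh$status), 2000L)
    coh$draws
  })
  # geometric-waiting argument: ~1000 / K population draws needed for
  # the case quota (batching overshoots a little)
  expect_lt(abs(mean(draws) - 1000 / 0.1) / (1000 / 0.1), 0.2)
})

test_that("an exhausted ascertainment budget fails loudly", {
  cfg <- sim_config(M = 10, N = 2000, h2 = 0.1, K = 0.01, P = 0.5,
                    ascertained = TRUE, max_draws = 5000)
  set.seed(5)
  expect_error(simulate_cohort(cfg), "budget")
})

test_that("response codings derive from liability and status", {
  cfg <- sim_config(M = 30, N = 500, h2 = 0.2, K = 0.2, P = 0.5,
                    ascertained = TRUE, design = "QB")
  set.seed(6)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$response[coh$status] ==
                    coh$liability[coh$status]))
  expect_true(all(coh$response[!coh$status] == 0))
  expect_true(all(coh$liability[coh$status] > qnorm(0.8)))
  expect_equal(coh$liability, coh$g + coh$e)
})

test_that("association scan is calibrated under the null", {
  cfg <- sim_config(M = 600, N = 800, h2 = 0, K = 0.1)
  set.seed(7)
  coh <- simulate_cohort(cfg)
  scan <- association_scan(coh, response = rnorm(800))
  rate <- mean(scan$p_value < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 600))
})

test_that("score statistic agrees with per-marker OLS t-squared", {
  cfg <- sim_config(M = 20, N = 200, h2 = 0, K = 0.3)
  set.seed(8)
  coh <- simulate_cohort(cfg)
  y <- rnorm(200)
  scan <- association_scan(coh, response = y)
  t2 <- ols_scan_oracle(coh$genotypes, y)
  # exact algebra: t^2 = (N - 2) r^2 / (1 - r^2) with r^2 = stat / N
  r2 <- scan$statistic / 200
  expect_equal(t2, (200 - 2) * r2 / (1 - r2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # under the null the two statistics coincide up to O(1/N) terms
  expect_lt(max(abs(scan$statistic - t2)), 1)
})

test_that("degenerate scan inputs are handled", {
  cfg <- sim_config(M = 5, N = 100, h2 = 0.1, K = 0.2)
  set.seed(9)
  coh <- simulate_cohort(cfg)
  expect_error(association_scan(coh, response = rep(1, 100)),
               "zero variance")
  coh$genotypes[, 3] <- 2L  # monomorphic marker
  scan <- association_scan(coh, response = coh$liability)
  expect_equal(scan$statistic[3], 0)
  expect_equal(scan$p_value[3], 1)
})

test_that("empirical power is reproducible and tracks the analytic value", {
  cfg <- sim_config(M = 100, N = 2000, h2 = 0.1, K = 0.1, P = 0.5,
                    design = "BT", ascertained = TRUE,
                    n_replicates = 10, seed = 33)
  s1 <- empirical_power(cfg)
  s2 <- empirical_power(cfg)
  expect_identical(s1$estimate, s2$estimate)
  expect_identical(s1$se, s2$se)
  analytic <- chisq_power(ncp_bt_cc(2000, 1e-3, 0.1, 0.5))
  expect_lt(abs(s1$estimate - analytic), 3 * s1$se)
})

test_that("binary and cases-only codings give similar empirical power", {
  # share the simulated cohorts between the two codings so the
  # comparison is paired
  cfg <- sim_config(M = 100, N = 2000, h2 = 0.1, K = 0.01, P = 0.5,
                    ascertained = TRUE, n_replicates = 8, seed = 44)
  p_bt <- p_qb <- numeric(cfg$n_replicates)
  for (i in seq_len(cfg$n_replicates)) {
    set.seed(gwasdesign:::replicate_seed(cfg$seed, i))
    coh <- simulate_cohort(cfg)
    qb <- ifelse(coh$status, coh$liability, 0)
    p_bt[i] <- mean(association_scan(coh,
                      response = as.numeric(coh$status))$p_value < 0.05)
    p_qb[i] <- mean(association_scan(coh, response = qb)$p_value < 0.05)
  }
  expect_lt(abs(mean(p_qb) - mean(p_bt)), 0.03)
})

test_that("a perfect effect estimate gives perfect prediction", {
  cfg <- sim_config(M = 50, N = 500, h2 = 0.5, K = 0.1)
  set.seed(10)
  coh <- simulate_cohort(cfg)
  ghat <- drop(coh$genotypes %*% coh$beta)
  expect_equal(cor(coh$g, ghat), 1, tolerance = 1e-12)
})

test_that("empirical accuracy tracks the closed form and is distribution-robust", {
  base <- list(M = 500, N = 1000, h2 = 0.5, K = 0.5,
               ascertained = TRUE, n_replicates = 6,
               N_validation = 1000, seed = 55)
  expected <- accuracy_disease_cc(1000, 500, 0.5, 0.5, 0.5)$r
  est <- sapply(c("equal", "normal", "exponential"), function(dist) {
    cfg <- do.call(sim_config, c(base, effect_distribution = dist))
    s <- empirical_accuracy(cfg)
    expect_lt(abs(s$estimate - expected), 3 * s$se + 0.02)
    s$estimate
  })
  expect_lt(max(est) - min(est), 0.06)
})

test_that("cohort export round-trips through TSV", {
  cfg <- sim_config(M = 8, N = 40, h2 = 0.2, K = 0.2)
  set.seed(12)
  coh <- simulate_cohort(cfg)
  gf <- tempfile(fileext = ".tsv"); pf <- tempfile(fileext = ".tsv")
  export_cohort(coh, gf, pf)
  X <- as.matrix(read.delim(gf))
  ph <- read.delim(pf)
  expect_equal(unname(X), unname(coh$genotypes))
  expect_equal(ph$g, coh$g, tolerance = 1e-6)
  expect_equal(as.logical(ph$status), coh$status)
  unlink(c(gf, pf))
})
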