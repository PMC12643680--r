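test_that("wald ratio matches the closed form", {
  expect_equal(mr_wald_ratio(make_pairs(0.5, 0.5, 0.05))[, c("beta", "se")],
               data.frame(beta = 1, se = 0.1))
  expect_equal(mr_wald_ratio(make_pairs(1, 0, 0.1))[, c("beta", "se")],
               data.frame(beta = 0, se = 0.1))
  expect_equal(mr_wald_ratio(make_pairs(-0.5, 0.25, 0.05))[, c("beta", "se")],
               data.frame(beta = -0.5, se = 0.1))
  expect_error(mr_wald_ratio(make_pairs(0, 0.1, 0.1)), class = "mr_domain_error")
})

test_that("IVW reproduces the two-instrument closed form", {
  h <- ivw_fixture()
  fe <- mr_ivw(h, "fixed")
  expect_equal(fe$beta, 0.6)
  expect_equal(fe$se, sqrt(1 / 200))
  q <- cochran_q(h)
  expect_equal(q$q_stat, 2)
  expect_equal(q$q_df, 1)
  mre <- mr_ivw(h, "multiplicative_random")
  expect_equal(mre$beta, 0.6)
  expect_equal(mre$se, sqrt(1 / 200) * sqrt(2))
  expect_error(mr_ivw(make_pairs(1, 0.5, 0.1)),
               class = "mr_insufficient_instruments")
})

test_that("perfectly proportional pairs give Q = 0 and identical SEs", {
  h <- make_pairs(c(1, 2, 3), c(0.4, 0.8, 1.2), c(0.1, 0.2, 0.05))
  expect_equal(mr_ivw(h, "fixed")$beta, 0.4)
  expect_equal(cochran_q(h)$q_stat, 0, tolerance = 1e-12)
  expect_equal(mr_ivw(h, "fixed")$se, mr_ivw(h, "multiplicative_random")$se)
})

test_that("IVW with equal outcome SEs equals unweighted origin regression", {
  set.seed(7)
  bx <- rnorm(10, 0.2, 0.05)
  by <- 0.3 * bx + rnorm(10, 0, 0.02)
  h <- make_pairs(bx, by, 0.1)
  expect_equal(mr_ivw(h, "fixed")$beta, sum(bx * by) / sum(bx^2))
})

test_that("Egger recovers a constructed intercept and slope exactly", {
  fit <- suppressWarnings(mr_egger(egger_fixture()))
  expect_equal(fit$beta, 1)
  expect_equal(fit$intercept, 0.1)
  h2 <- make_pairs(c(1, 2, 3), c(2, 4, 6), 0.1)
  fit2 <- suppressWarnings(mr_egger(h2))
  expect_equal(fit2$beta, 2)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
  expect_error(mr_egger(ivw_fixture()), class = "mr_insufficient_instruments")
  expect_error(mr_egger(make_pairs(c(1, 1, 1), c(1, 1, 1), 0.1)),
               class = "mr_degenerate_design")
})

test_that("Egger slope equals the matrix-form WLS solution", {
  set.seed(11)
  for (rep in 1:5) {
    j <- 8
    bx <- abs(rnorm(j, 0.2, 0.08)) + 0.05
    sy <- runif(j, 0.05, 0.2)
    by <- 0.05 + 0.4 * bx + rnorm(j, 0, sy)
    h <- make_pairs(bx, by, sy)
    fit <- mr_egger(h)
    # independent normal-equations oracle
    X <- cbind(1, bx)
    W <- diag(1 / sy^2)
    coef <- solve(t(X) %*% W %*% X, t(X) %*% W %*% by)
    expect_equal(fit$intercept, coef[1], tolerance = 1e-10)
    expect_equal(fit$beta, coef[2], tolerance = 1e-10)
  }
})

test_that("weighted median follows the percentile interpolation rule", {
  h <- make_pairs(c(1, 1, 1), c(0.4, 0.6, 10), 1)
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.6)
  # identical ratios are invariant to weights
  h2 <- make_pairs(c(1, 2, 4), c(0.3, 0.6, 1.2), c(0.1, 0.3, 0.9))
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$beta, 0.3)
  # weight concentrated on one SNP pulls the estimate to its ratio
  h3 <- make_pairs(c(1, 1, 1), c(0.2, 0.5, 0.9), c(0.001, 5, 5))
  expect_equal(mr_weighted_median(h3, n_boot = 50, seed = 1)$beta, 0.2,
               tolerance = 1e-6)
})

test_that("weighted median with equal weights and odd J hits the sample median", {
  # J = 5 equal weights: percentile of the 3rd ratio is exactly 0.5
  h <- make_pairs(rep(1, 5), c(0.1, 0.2, 0.3, 0.8, 0.9), 1)
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.3)
})

test_that("mode estimators find the majority cluster", {
  h <- make_pairs(rep(1, 4), c(0.3, 0.3, 0.3, 0.3), 0.1)
  expect_equal(mr_mode(h, n_boot = 20, seed = 1)$beta, 0.3)
  h2 <- make_pairs(rep(1, 4), c(0.5, 0.5, 0.5, 5), 0.1)
  m <- mr_mode(h2, bandwidth_factor = 0.1, n_boot = 20, seed = 1)
  expect_equal(m$beta, 0.5, tolerance = 0.05)
  # grid-search density oracle at the same bandwidth
  r <- c(0.5, 0.5, 0.5, 5)
  bw <- 0.1 * 0.9 * sd(r) * 4^(-1 / 5)
  grid <- seq(-1, 6, by = 1e-3)
  dens <- vapply(grid, function(x) sum(dnorm((x - r) / bw)), numeric(1))
  expect_equal(m$beta, grid[which.max(dens)], tolerance = 0.05)
  # weighted variant with outlier down-weighted stays in the cluster
  h3 <- make_pairs(rep(1, 4), c(0.5, 0.5, 0.5, 5), c(0.1, 0.1, 0.1, 50))
  mw <- mr_mode(h3, weighted = TRUE, bandwidth_factor = 1, n_boot = 20, seed = 1)
  expect_equal(mw$beta, 0.5, tolerance = 0.2)
})

test_that("run_all_methods respects per-method instrument minima", {
  one <- run_all_methods(make_pairs(1, 0.5, 0.1))
  expect_equal(one$method, "wald_ratio")
  expect_false(any(one$primary))

  two <- run_all_methods(ivw_fixture(), mr_settings(n_boot = 20))
  expect_setequal(two$method,
                  c("ivw_fe", "ivw_mre", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_false("egger" %in% two$method)
  expect_equal(sum(two$primary), 1)

  three <- suppressWarnings(
    run_all_methods(egger_fixture(), mr_settings(n_boot = 20)))
  expect_true("egger" %in% three$method)
})

test_that("all methods recover a simulated true effect", {
  set.seed(101)
  j <- 10
  bx <- seq(0.1, 0.5, length.out = j)
  by <- 0.2 * bx + rnorm(j, 0, 0.003)
  h <- make_pairs(bx, by, 0.003, se_exp = 0.001)
  est <- run_all_methods(h, mr_settings(n_boot = 100))
  expect_true(all(abs(est$beta - 0.2) < 0.05))
})

test_that("estimates are sign-equivariant in the outcome", {
  h <- make_pairs(c(0.2, 0.3, 0.25, 0.4), c(0.05, 0.08, 0.06, 0.1),
                  c(0.02, 0.03, 0.02, 0.04))
  hn <- h
  hn$beta_out <- -hn$beta_out
  s <- mr_settings(n_boot = 50)
  a <- run_all_methods(h, s)
  b <- run_all_methods(hn, s)
  expect_equal(b$beta, -a$beta)
  # bootstrap SEs flip-symmetric only in distribution; closed-form SEs exact
  cf <- a$method %in% c("ivw_fe", "ivw_mre", "egger")
  expect_equal(b$se[cf], a$se[cf])
})

test_that("estimates are scale-equivariant in the exposure", {
  h <- make_pairs(c(0.2, 0.3, 0.25, 0.4), c(0.05, 0.08, 0.06, 0.1),
                  c(0.02, 0.03, 0.02, 0.04))
  hc <- h
  hc$beta_exp <- 2 * hc$beta_exp
  hc$se_exp <- 2 * hc$se_exp
  s <- mr_settings(n_boot = 50)
  a <- run_all_methods(h, s)
  b <- run_all_methods(hc, s)
  expect_equal(b$beta, a$beta / 2, tolerance = 1e-10)
})

test_that("estimate rows satisfy their own invariants", {
  est <- suppressWarnings(
    run_all_methods(make_pairs(c(1, 2, 3, 4), c(0.5, 1.1, 1.4, 2.2),
                               c(0.1, 0.1, 0.2, 0.1)),
                    mr_settings(n_boot = 50)))
  expect_true(all(est$ci_low <= est$beta & est$beta <= est$ci_high))
  expect_equal(est$or_, exp(est$beta))
  expect_equal(est$or_ci_low, exp(est$ci_low))
})

test_that("weighted median is less biased than IVW under directional pleiotropy", {
  n_rep <- 200
  bias_ivw <- bias_med <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    sim <- simulate_summary_direct(
      sim_config(prop_invalid = 0.3, pleio_mean = 0.05, pleio_sd = 0.02,
                 seed = s))
    h <- harmonize(sim$exposure, sim$outcome)
    bias_ivw[s] <- mr_ivw(h, "fixed")$beta - sim$truth$beta0_true
    bias_med[s] <- mr_weighted_median(h, n_boot = 20, seed = s)$beta -
      sim$truth$beta0_true
  }
  expect_lt(mean(abs(bias_med)), mean(abs(bias_ivw)))
})
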