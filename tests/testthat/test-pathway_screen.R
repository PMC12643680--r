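test_that("BH adjustment reproduces hand step-up computations", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.001, 0.5, 0.9)), c(0.003, 0.75, 0.9))
  expect_error(adjust_pvalues(c(0.1, 0)), class = "mr_domain_error")
})

test_that("BH adjustment is monotone, bounded, and twice-applied never decreases", {
  set.seed(9)
  for (i in 1:20) {
    p <- runif(15)
    a <- adjust_pvalues(p)
    expect_true(all(a >= p))
    expect_true(all(a <= 1))
    expect_equal(order(a[order(p)]), seq_along(p))  # order-preserving
    expect_true(all(adjust_pvalues(a) >= a))
  }
})

test_that("run_leg recovers a planted effect with full diagnostics", {
  sim <- simulate_summary_direct(
    sim_config(n_exp = 20000, n_out = 100000, seed = 42))
  leg <- run_leg(sim$exposure, sim$outcome, sim$ld,
                 settings = mr_settings(n_boot = 50, presso_n_sim = 200))
  expect_s3_class(leg, "mr_leg")
  expect_equal(leg$status, "ok")
  expect_equal(leg$exposure_name, "exposure")
  expect_lt(abs(leg$beta - sim$truth$beta0_true), 0.05)
  expect_true(leg$primary$method %in% c("ivw_fe", "ivw_mre"))
  expect_false(is.null(leg$sensitivity))
  # reverse leg: outcome SNP effects are too weak to pass selection
  expect_true(is.na(leg$reverse_pval))
})

test_that("run_leg degrades to wald_only and non_estimable", {
  sim <- simulate_summary_direct(sim_config(seed = 7))
  exp1 <- sim$exposure[1, ]
  attr(exp1, "trait_name") <- "exposure"; attr(exp1, "trait_type") <- "quantitative"
  class(exp1) <- class(sim$exposure)
  leg1 <- run_leg(exp1, sim$outcome, sim$ld, reverse = FALSE)
  expect_equal(leg1$status, "wald_only")
  expect_equal(leg1$primary$method, "wald_ratio")
  expect_false(leg1$primary$primary)

  weak <- sim$exposure
  weak$pval <- rep(0.5, nrow(weak))
  leg0 <- run_leg(weak, sim$outcome, sim$ld, reverse = FALSE)
  expect_equal(leg0$status, "non_estimable")
  expect_true(is.na(leg0$pval))
})

test_that("null legs produce approximately uniform primary p-values", {
  n_rep <- 150
  pvals <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    sim <- simulate_summary_direct(
      sim_config(beta0_true = 0, beta1_true = 0, seed = 5000 + s))
    h <- harmonize(sim$exposure, sim$outcome)
    q <- cochran_q(h)
    pvals[s] <- mr_ivw(h, choose_ivw_model(q$q_pval))$pval
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

make_leg <- function(x, y, p, beta = 0.2, se = 0.05, rev_p = NA_real_) {
  structure(list(exposure_name = x, outcome_name = y, status = "ok",
                 n_snp = 10L, estimates = NULL,
                 primary = NULL, pval = p, beta = beta, se = se,
                 sensitivity = NULL, reverse_pval = rev_p),
            class = "mr_leg")
}

test_that("assemble_pathways applies the three-leg and reverse rules", {
  legs_xo <- list(make_leg("X1", "Y1", 0.01), make_leg("X2", "Y1", 0.5))
  legs_xm <- list(make_leg("X1", "M1", 0.001), make_leg("X2", "M1", 0.001))
  legs_mo <- list(make_leg("M1", "Y1", 0.02))
  pw <- assemble_pathways(legs_xo, legs_xm, legs_mo)
  expect_equal(nrow(pw), 1)
  expect_equal(pw$exposure, "X1")
  expect_equal(pw$mediator, "M1")
  # the mediation row carries the leg betas bit-identically
  expect_identical(pw$beta0, 0.2)
  expect_identical(pw$beta1, 0.2)
  expect_identical(pw$beta2, 0.2)

  # significant reverse leg excludes the pathway with a recorded reason
  legs_xo_rev <- list(make_leg("X1", "Y1", 0.01, rev_p = 0.001),
                      make_leg("X2", "Y1", 0.5))
  pw2 <- assemble_pathways(legs_xo_rev, legs_xm, legs_mo)
  expect_equal(nrow(pw2), 0)
  excl <- attr(pw2, "excluded")
  expect_equal(excl$reason, "reverse_direction_significant")
  expect_equal(excl$exposure, "X1")
})

test_that("assemble_pathways is invariant to leg-collection ordering", {
  legs_xo <- list(make_leg("X1", "Y1", 0.01), make_leg("X2", "Y1", 0.02),
                  make_leg("X1", "Y2", 0.9), make_leg("X2", "Y2", 0.01))
  legs_xm <- list(make_leg("X1", "M1", 0.001), make_leg("X2", "M1", 0.01))
  legs_mo <- list(make_leg("M1", "Y1", 0.02), make_leg("M1", "Y2", 0.01))
  a <- assemble_pathways(legs_xo, legs_xm, legs_mo)
  b <- assemble_pathways(rev(legs_xo), rev(legs_xm), rev(legs_mo))
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("the BH-strict rule is more conservative than the raw rule", {
  legs_xo <- list(make_leg("X1", "Y1", 0.04), make_leg("X2", "Y1", 0.9),
                  make_leg("X3", "Y1", 0.8))
  legs_xm <- list(make_leg("X1", "M1", 0.001), make_leg("X2", "M1", 0.9),
                  make_leg("X3", "M1", 0.9))
  legs_mo <- list(make_leg("M1", "Y1", 0.001))
  raw <- assemble_pathways(legs_xo, legs_xm, legs_mo, rule = "ivw")
  strict <- assemble_pathways(legs_xo, legs_xm, legs_mo, rule = "bh")
  expect_equal(nrow(raw), 1)
  expect_equal(nrow(strict), 0)  # 0.04 * 3 families-adjusted exceeds 0.05
})

test_that("a planted pathway is recovered from a small screening grid", {
  g <- simulate_grid(sim_config(seed = 11), n_exposure = 2, n_mediator = 2,
                     n_outcome = 1)
  scr <- run_screen(g$exposures, g$mediators, g$outcomes, g$ld,
                    settings = mr_settings(n_boot = 30, presso_n_sim = 100))
  pw <- scr$pathways
  expect_equal(nrow(pw), 1)
  expect_equal(pw$exposure, g$truth$exposure)
  expect_equal(pw$mediator, g$truth$mediator)
  expect_equal(pw$outcome, g$truth$outcome)
  expect_lt(abs(pw$proportion - g$truth$proportion_true), 0.15)
  # candidate betas are bit-identical to the leg primaries
  leg <- scr$legs_xo[[which(vapply(scr$legs_xo, function(l)
    l$exposure_name == pw$exposure && l$outcome_name == pw$outcome,
    logical(1)))]]
  expect_identical(pw$beta0, leg$beta)
})
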