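# Two-sample MR estimators on harmonized exposure/outcome pairs.
#
# All estimators take a harmonized set (or any data.frame with beta_exp,
# se_exp, beta_out, se_out columns), work on the retained pairs, and
# return one tidy estimate row. Causal effects are per SD of the
# exposure; odds ratios are exp(beta) for log-odds outcomes.

#' Estimation settings
#'
#' @param n_boot parametric-bootstrap resamples for the median and mode
#'   SEs.
#' @param seed default RNG seed for bootstrap and simulation-based
#'   diagnostics.
#' @param bandwidth_factor multiplier on the modified Silverman bandwidth
#'   of the mode estimators.
#' @param conf_level confidence level for all intervals.
#' @param presso whether pipeline wrappers run MR-PRESSO.
#' @param presso_n_sim simulations for the MR-PRESSO null distribution.
#' @param presso_significance outlier significance level (applied to
#'   Bonferroni-adjusted per-SNP p-values).
#' @return list of class `mr_settings`.
#' @export
mr_settings <- function(n_boot = 1000, seed = 20240101, bandwidth_factor = 1,
                        conf_level = 0.95, presso = TRUE, presso_n_sim = 1000,
                        presso_significance = 0.05) {
  structure(list(n_boot = n_boot, seed = seed,
                 bandwidth_factor = bandwidth_factor,
                 conf_level = conf_level, presso = presso,
                 presso_n_sim = presso_n_sim,
                 presso_significance = presso_significance),
            class = "mr_settings")
}

# One tidy estimate row. `df` = NULL uses the normal reference, a number
# uses Student's t with that df (Egger).
mr_estimate <- function(method, beta, se, n_snp, pval = NULL, df = NULL,
                        conf_level = 0.95,
                        intercept = NA_real_, intercept_se = NA_real_,
                        intercept_pval = NA_real_) {
  alpha <- 1 - conf_level
  crit <- if (is.null(df)) stats::qnorm(1 - alpha / 2) else stats::qt(1 - alpha / 2, df)
  if (is.null(pval)) {
    z <- beta / se
    pval <- if (is.null(df)) 2 * stats::pnorm(-abs(z)) else 2 * stats::pt(-abs(z), df)
    if (!is.finite(se) || se == 0) pval <- if (beta == 0) 1 else 0
  }
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  data.frame(method = method, beta = beta, se = se,
             ci_low = ci_low, ci_high = ci_high, pval = pval,
             or_ = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
             n_snp = n_snp, intercept = intercept, intercept_se = intercept_se,
             intercept_pval = intercept_pval, stringsAsFactors = FALSE)
}

.pairs <- function(h, min_n, caller) {
  p <- retained_pairs(h)
  if (nrow(p) < min_n) {
    mr_abort(sprintf("%s needs at least %d harmonized pair(s), got %d",
                     caller, min_n, nrow(p)), "mr_insufficient_instruments")
  }
  p
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_out / beta_exp`, first-order SE `se_out / |beta_exp|`.
#'
#' @param pair one harmonized pair (a one-row data.frame with `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`).
#' @param conf_level confidence level.
#' @return one-row estimate data.frame.
#' @export
mr_wald_ratio <- function(pair, conf_level = 0.95) {
  p <- .pairs(pair, 1, "mr_wald_ratio")[1, ]
  if (p$beta_exp == 0) mr_abort("exposure beta is zero", "mr_domain_error")
  mr_estimate("wald_ratio", p$beta_out / p$beta_exp, p$se_out / abs(p$beta_exp),
              n_snp = 1, conf_level = conf_level)
}

# Closed-form IVW slope pieces; shared by estimators and diagnostics.
.ivw_fit <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  q <- sum(w * (by - beta * bx)^2)
  list(beta = beta, se_fixed = sqrt(1 / sxx), q = q, j = length(bx))
}

#' Inverse-variance-weighted estimator
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_out^2` (equivalent to the inverse-variance
#' meta-analysis of per-SNP Wald ratios with first-order weights). The
#' multiplicative-random-effects model inflates the fixed-effects SE by
#' `max(1, sqrt(Q/(J-1)))`, never deflating below it.
#'
#' @param h harmonized set with at least 2 retained pairs.
#' @param model `"fixed"` or `"multiplicative_random"`.
#' @param conf_level confidence level.
#' @return one-row estimate data.frame (method `ivw_fe` or `ivw_mre`).
#' @export
mr_ivw <- function(h, model = c("fixed", "multiplicative_random"),
                   conf_level = 0.95) {
  model <- match.arg(model)
  p <- .pairs(h, 2, "mr_ivw")
  fit <- .ivw_fit(p$beta_exp, p$beta_out, p$se_out)
  se <- if (model == "fixed") fit$se_fixed else
    fit$se_fixed * max(1, sqrt(fit$q / (fit$j - 1)))
  mr_estimate(if (model == "fixed") "ivw_fe" else "ivw_mre",
              fit$beta, se, n_snp = fit$j, conf_level = conf_level)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept (weights `1/se_out^2`), after jointly flipping pair signs so
#' all exposure betas are non-negative. The slope is the pleiotropy-
#' robust causal estimate; a non-zero intercept indicates directional
#' horizontal pleiotropy. SEs and p-values use Student's t with J-2 df.
#'
#' @param h harmonized set with at least 3 retained pairs.
#' @param conf_level confidence level.
#' @return one-row estimate data.frame (method `egger`) carrying
#'   `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(h, conf_level = 0.95) {
  p <- .pairs(h, 3, "mr_egger")
  sgn <- ifelse(p$beta_exp < 0, -1, 1)
  x <- p$beta_exp * sgn
  y <- p$beta_out * sgn
  if (stats::var(x) == 0) {
    mr_abort("exposure betas have zero variance; Egger design is degenerate",
             "mr_degenerate_design")
  }
  fit <- stats::lm(y ~ x, weights = 1 / p$se_out^2)
  cf <- summary(fit)$coefficients
  j <- nrow(p)
  mr_estimate("egger", cf["x", 1], cf["x", 2], n_snp = j, df = j - 2,
              pval = 2 * stats::pt(-abs(cf["x", 1] / cf["x", 2]), j - 2),
              conf_level = conf_level,
              intercept = cf["(Intercept)", 1],
              intercept_se = cf["(Intercept)", 2],
              intercept_pval = 2 * stats::pt(
                -abs(cf["(Intercept)", 1] / cf["(Intercept)", 2]), j - 2))
}

# Bowden percentile rule: weighted median of ordered ratios by linear
# interpolation of the centered cumulative weights at 0.5.
.weighted_median_point <- function(ratios, w) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w)
  p <- s - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  k <- max(which(p <= 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

.boot_se <- function(p, n_boot, seed, point_fun) {
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(p), p$beta_exp, p$se_exp)
      by <- stats::rnorm(nrow(p), p$beta_out, p$se_out)
      point_fun(bx, by, p$se_out)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median estimator
#'
#' Per-SNP Wald ratios ordered ascending; with inverse-variance weights
#' (ratio variance `se_out^2 / beta_exp^2`) normalized to sum one, the
#' estimate interpolates the ratios at cumulative percentile 0.5.
#' Consistent when at least half the weight comes from valid
#' instruments. SE by seeded parametric bootstrap.
#'
#' @param h harmonized set with at least 2 retained pairs.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param conf_level confidence level.
#' @return one-row estimate data.frame (method `weighted_median`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 20240101,
                               conf_level = 0.95) {
  p <- .pairs(h, 2, "mr_weighted_median")
  point <- function(bx, by, sy) .weighted_median_point(by / bx, bx^2 / sy^2)
  beta <- point(p$beta_exp, p$beta_out, p$se_out)
  se <- .boot_se(p, n_boot, seed, point)
  mr_estimate("weighted_median", beta, se, n_snp = nrow(p),
              conf_level = conf_level)
}

.mode_point <- function(ratios, w, bandwidth_factor) {
  if (diff(range(ratios)) < .Machine$double.eps^0.5) return(ratios[1])
  j <- length(ratios)
  spread <- min(stats::sd(ratios), stats::mad(ratios))
  if (spread <= 0) spread <- max(stats::sd(ratios), stats::mad(ratios))
  bw <- bandwidth_factor * 0.9 * spread * j^(-1 / 5)
  d <- stats::density(ratios, weights = w / sum(w), bw = bw, n = 1024)
  d$x[which.max(d$y)]
}

#' Mode-based estimators (simple and weighted)
#'
#' Kernel-density mode of the per-SNP Wald ratios with a normal kernel
#' and a modified Silverman bandwidth
#' `bandwidth_factor * 0.9 * min(sd, mad) * J^(-1/5)` (falling back to
#' the non-zero of sd/mad when ties make the MAD zero). The weighted
#' variant weights each ratio's kernel by its inverse first-order
#' variance. Consistent when the largest group of instruments sharing a
#' causal estimate is valid (ZEMPA). SE by seeded parametric bootstrap.
#'
#' @param h harmonized set with at least 2 retained pairs.
#' @param weighted use inverse-variance kernel weights.
#' @param bandwidth_factor bandwidth multiplier.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @param conf_level confidence level.
#' @return one-row estimate data.frame (method `simple_mode` or
#'   `weighted_mode`).
#' @export
mr_mode <- function(h, weighted = FALSE, bandwidth_factor = 1, n_boot = 1000,
                    seed = 20240101, conf_level = 0.95) {
  p <- .pairs(h, 2, "mr_mode")
  wfun <- if (weighted) function(bx, sy) bx^2 / sy^2 else
    function(bx, sy) rep(1, length(bx))
  point <- function(bx, by, sy) .mode_point(by / bx, wfun(bx, sy), bandwidth_factor)
  beta <- point(p$beta_exp, p$beta_out, p$se_out)
  se <- .boot_se(p, n_boot, seed, point)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode", beta, se,
              n_snp = nrow(p), conf_level = conf_level)
}

#' Run every applicable MR method
#'
#' Applies all estimators whose minimum instrument count is met: with a
#' single pair only the Wald ratio; with two or more both IVW models,
#' weighted median and both modes; with three or more also MR-Egger. The
#' primary estimate is the IVW model selected by the Cochran's Q
#' heterogeneity rule (multiplicative random effects when the Q p-value
#' is below 0.05, fixed effects otherwise); a lone Wald ratio is
#' reported but not marked primary.
#'
#' @param h harmonized set with at least 1 retained pair.
#' @param settings an [mr_settings()] list.
#' @return data.frame of class `mr_result`, one row per method, with a
#'   logical `primary` column and attribute `q` (the Cochran's Q triple
#'   when computed).
#' @export
run_all_methods <- function(h, settings = mr_settings()) {
  p <- .pairs(h, 1, "run_all_methods")
  cl <- settings$conf_level
  if (nrow(p) == 1) {
    out <- mr_wald_ratio(p, conf_level = cl)
    out$primary <- FALSE
    return(structure(out, class = c("mr_result", "data.frame"), q = NULL))
  }
  q <- cochran_q(p)
  model <- choose_ivw_model(q$q_pval)
  rows <- list(
    mr_ivw(p, "fixed", conf_level = cl),
    mr_ivw(p, "multiplicative_random", conf_level = cl),
    mr_weighted_median(p, settings$n_boot, settings$seed, conf_level = cl),
    mr_mode(p, FALSE, settings$bandwidth_factor, settings$n_boot,
            split_seed(settings$seed, 1), conf_level = cl),
    mr_mode(p, TRUE, settings$bandwidth_factor, settings$n_boot,
            split_seed(settings$seed, 2), conf_level = cl)
  )
  if (nrow(p) >= 3) rows <- c(rows, list(mr_egger(p, conf_level = cl)))
  out <- do.call(rbind, rows)
  primary_method <- if (model == "fixed") "ivw_fe" else "ivw_mre"
  out$primary <- out$method == primary_method
  structure(out, class = c("mr_result", "data.frame"), q = q)
}
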