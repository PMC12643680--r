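# Heterogeneity and pleiotropy diagnostics: Cochran's Q, the Egger
# intercept test and MR-PRESSO.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (ratio_j - beta_ivw)^2` with first-order ratio weights
#' `w_j = beta_exp_j^2 / se_out_j^2`; p-value from the chi-square
#' distribution with J-1 degrees of freedom.
#'
#' @param h harmonized set with at least 2 retained pairs.
#' @return list with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(h) {
  p <- .pairs(h, 2, "cochran_q")
  fit <- .ivw_fit(p$beta_exp, p$beta_out, p$se_out)
  list(q_stat = fit$q, q_df = fit$j - 1,
       q_pval = stats::pchisq(fit$q, fit$j - 1, lower.tail = FALSE))
}

#' Choose the primary IVW model from the heterogeneity test
#'
#' Multiplicative random effects when the Q p-value is strictly below
#' 0.05 (heterogeneity present), fixed effects otherwise (including at
#' exactly 0.05).
#'
#' @param q_pval Cochran's Q p-value.
#' @return `"multiplicative_random"` or `"fixed"`.
#' @export
choose_ivw_model <- function(q_pval) {
  if (!is.numeric(q_pval) || is.na(q_pval)) {
    mr_abort("`q_pval` must be a number", "mr_domain_error")
  }
  if (q_pval < 0.05) "multiplicative_random" else "fixed"
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' @param h harmonized set with at least 3 retained pairs.
#' @return list with `intercept`, `se`, `pval` (two-sided t, J-2 df).
#' @export
egger_intercept_test <- function(h) {
  fit <- mr_egger(h)
  list(intercept = fit$intercept, se = fit$intercept_se,
       pval = fit$intercept_pval)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Global test: the observed residual sum of squares
#' `RSS = sum_j w_j (beta_out_j - beta_ivw^(-j) beta_exp_j)^2` (weights
#' `1/se_out^2`, leave-one-out IVW slopes) is compared with its
#' distribution under `n_sim` parametric simulations of the outcome
#' betas from the no-pleiotropy model with the observed SEs; the
#' empirical p carries the +1 correction so it lies in (0, 1]. Outlier
#' test: each SNP's observed weighted squared residual is compared with
#' its own simulated distribution; per-SNP empirical p-values are
#' Bonferroni-adjusted and SNPs below `significance` are flagged.
#' Distortion test: the shift between the all-SNP IVW estimate and the
#' outlier-removed estimate is compared with the shifts from removing
#' random subsets of the same size.
#'
#' @param h harmonized set with at least 4 retained pairs.
#' @param n_sim number of simulations.
#' @param seed RNG seed (reported back for reproducibility).
#' @param significance outlier flagging level.
#' @return list with `global_rss`, `global_pval`, `outliers`,
#'   `outlier_pvals` (Bonferroni-adjusted, named by SNP),
#'   `distortion_pval` (NA when no outliers are flagged or too few SNPs
#'   remain), `beta_ivw`, `beta_ivw_corrected` (outlier-free IVW, NA
#'   when nothing is flagged), `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 20240101, significance = 0.05) {
  p <- .pairs(h, 4, "mr_presso")
  j <- nrow(p)
  snp <- if (!is.null(p$snp_id)) p$snp_id else as.character(seq_len(j))
  bx <- p$beta_exp; by <- p$beta_out; sy <- p$se_out
  w <- 1 / sy^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  b_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)
  res_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res_obs)

  with_seed(seed, {
    ysim <- matrix(stats::rnorm(j * n_sim, mean = b_loo * bx, sd = sy), j, n_sim)
    sxy_sim <- colSums((w * bx) * ysim)
    bloo_sim <- (matrix(sxy_sim, j, n_sim, byrow = TRUE) - (w * bx) * ysim) /
      (sxx - w * bx^2)
    res_sim <- w * (ysim - bloo_sim * bx)^2
    rss_sim <- colSums(res_sim)
    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    outlier_p <- (1 + rowSums(res_sim >= res_obs)) / (n_sim + 1)
    outlier_p <- pmin(1, outlier_p * j)  # Bonferroni
    names(outlier_p) <- snp
    outliers <- snp[outlier_p < significance]

    beta_all <- sxy / sxx
    beta_corr <- NA_real_
    distortion_pval <- NA_real_
    k <- length(outliers)
    if (k > 0 && j - k >= 2) {
      keep <- !(snp %in% outliers)
      beta_corr <- sum(w[keep] * bx[keep] * by[keep]) / sum(w[keep] * bx[keep]^2)
      d_obs <- beta_all - beta_corr
      d_sim <- vapply(seq_len(n_sim), function(s) {
        drop <- sample.int(j, k)
        beta_all - sum(w[-drop] * bx[-drop] * by[-drop]) /
          sum(w[-drop] * bx[-drop]^2)
      }, numeric(1))
      distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
    }
    list(global_rss = rss_obs, global_pval = global_pval,
         outliers = outliers, outlier_pvals = outlier_p,
         distortion_pval = distortion_pval,
         beta_ivw = beta_all, beta_ivw_corrected = beta_corr,
         n_sim = n_sim, seed = seed)
  })
}

#' Full sensitivity suite for one harmonized set
#'
#' Runs Cochran's Q (J >= 2), the Egger intercept test (J >= 3) and
#' MR-PRESSO (J >= 4 and `settings$presso`); diagnostics whose minimum
#' instrument count is not met are reported as NA.
#'
#' @param h harmonized set.
#' @param settings an [mr_settings()].
#' @return list of class `mr_sensitivity` with fields `q_stat`, `q_df`,
#'   `q_pval`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`, `presso` (the [mr_presso()] list or NULL),
#'   `n_snp`, `seed`.
#' @export
sensitivity_report <- function(h, settings = mr_settings()) {
  p <- retained_pairs(h)
  j <- nrow(p)
  q <- if (j >= 2) cochran_q(p) else list(q_stat = NA_real_, q_df = NA_real_,
                                          q_pval = NA_real_)
  eg <- if (j >= 3) egger_intercept_test(p) else
    list(intercept = NA_real_, se = NA_real_, pval = NA_real_)
  pr <- if (j >= 4 && isTRUE(settings$presso)) {
    mr_presso(p, n_sim = settings$presso_n_sim,
              seed = split_seed(settings$seed, 3),
              significance = settings$presso_significance)
  } else NULL
  structure(list(q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
                 egger_intercept = eg$intercept,
                 egger_intercept_se = eg$se,
                 egger_intercept_pval = eg$pval,
                 presso = pr, n_snp = j, seed = settings$seed),
            class = "mr_sensitivity")
}
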