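# Product-of-coefficients mediation with delta-method intervals.
#
# Coefficients: beta0 = total exposure->outcome effect (log-odds per SD),
# beta1 = exposure->mediator effect (SD per SD), beta2 = mediator->
# outcome effect (log-odds per SD). Indirect effect beta1*beta2, direct
# effect beta0 - beta1*beta2, mediation proportion beta1*beta2/beta0.

.check_se <- function(se, name) {
  stopifnot_scalar_num(se, name)
  if (se <= 0) mr_abort(sprintf("`%s` must be > 0", name), "mr_domain_error")
}

#' Mediation (indirect) effect with delta-method interval
#'
#' Indirect effect `beta1 * beta2`; first-order (Sobel) delta variance
#' `beta2^2 se1^2 + beta1^2 se2^2`, with an optional exact second-order
#' term `+ se1^2 se2^2`.
#'
#' @param beta1,se1 exposure->mediator effect and SE.
#' @param beta2,se2 mediator->outcome effect and SE.
#' @param second_order add the second-order variance term.
#' @param conf_level confidence level.
#' @return list with `indirect`, `se`, `ci` (length-2 vector).
#' @export
mediation_effect <- function(beta1, se1, beta2, se2, second_order = FALSE,
                             conf_level = 0.95) {
  .check_se(se1, "se1"); .check_se(se2, "se2")
  indirect <- beta1 * beta2
  v <- beta2^2 * se1^2 + beta1^2 * se2^2
  if (second_order) v <- v + se1^2 * se2^2
  se <- sqrt(v)
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(indirect = indirect, se = se, ci = c(indirect - crit * se, indirect + crit * se))
}

#' Direct effect
#'
#' `beta0 - beta1 * beta2`, so that direct + indirect = total exactly.
#'
#' @param beta0 total exposure->outcome effect.
#' @param beta1,beta2 path coefficients.
#' @return the direct effect.
#' @export
direct_effect <- function(beta0, beta1, beta2) {
  beta0 - beta1 * beta2
}

#' Mediation proportion with delta-method interval
#'
#' `beta1 * beta2 / beta0`. When the indirect effect and the total
#' effect have opposite signs the mediation is inconsistent and the
#' proportion is uninterpretable: the flag is FALSE and the proportion
#' and its CI are reported NA. The delta-method CI uses the gradient
#' `(-beta1 beta2 / beta0^2, beta2 / beta0, beta1 / beta0)` with the
#' three estimates treated as independent (they come from disjoint
#' two-sample fits); a seeded Monte-Carlo interval over normal draws of
#' the three coefficients is available as an alternative.
#'
#' @param beta0,se0 total effect and SE.
#' @param beta1,se1 exposure->mediator effect and SE.
#' @param beta2,se2 mediator->outcome effect and SE.
#' @param ci_method `"delta"` or `"montecarlo"`.
#' @param n_draw Monte-Carlo draws.
#' @param seed Monte-Carlo seed.
#' @param conf_level confidence level.
#' @return list with `proportion` (NA when inconsistent), `ci`,
#'   `consistent`.
#' @export
mediation_proportion <- function(beta0, se0, beta1, se1, beta2, se2,
                                 ci_method = c("delta", "montecarlo"),
                                 n_draw = 5e5, seed = 20240101,
                                 conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot_scalar_num(beta0, "beta0")
  if (beta0 == 0) {
    mr_abort("mediation proportion undefined for beta0 = 0", "mr_domain_error")
  }
  .check_se(se0, "se0"); .check_se(se1, "se1"); .check_se(se2, "se2")
  indirect <- beta1 * beta2
  consistent <- sign(indirect) == sign(beta0) || indirect == 0
  if (!consistent) {
    return(list(proportion = NA_real_, ci = c(NA_real_, NA_real_),
                consistent = FALSE))
  }
  prop <- indirect / beta0
  if (ci_method == "delta") {
    g <- c(-indirect / beta0^2, beta2 / beta0, beta1 / beta0)
    se <- sqrt(sum(g^2 * c(se0, se1, se2)^2))
    crit <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(prop - crit * se, prop + crit * se)
  } else {
    ci <- with_seed(seed, {
      b0 <- stats::rnorm(n_draw, beta0, se0)
      b1 <- stats::rnorm(n_draw, beta1, se1)
      b2 <- stats::rnorm(n_draw, beta2, se2)
      stats::quantile(b1 * b2 / b0,
                      c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                      names = FALSE)
    })
  }
  list(proportion = prop, ci = ci, consistent = TRUE)
}

#' Sobel-type p-value for the indirect effect
#'
#' Two-sided normal p-value of `indirect / indirect_se` with the
#' first-order delta SE.
#'
#' @inheritParams mediation_effect
#' @return two-sided p-value.
#' @export
mediation_pvalue <- function(beta1, se1, beta2, se2) {
  eff <- mediation_effect(beta1, se1, beta2, se2)
  if (eff$indirect == 0) return(1)
  2 * stats::pnorm(-abs(eff$indirect / eff$se))
}

#' Full mediation decomposition for one pathway
#'
#' Combines the indirect effect (delta-method CI), direct effect,
#' mediation proportion and Sobel p-value into one tidy row. The total
#' effect can be supplied either as `beta0` on the log-odds scale or as
#' an odds ratio `or0` (converted with `log`).
#'
#' @param beta0 total effect (log-odds per SD); ignored when `or0` given.
#' @param se0 SE of the total effect.
#' @param beta1,se1 exposure->mediator effect and SE.
#' @param beta2,se2 mediator->outcome effect and SE.
#' @param or0 optional odds ratio per SD for the total effect.
#' @param second_order use the second-order delta variance for the
#'   indirect effect.
#' @param ci_method proportion CI method, see [mediation_proportion()].
#' @param conf_level confidence level.
#' @param n_draw,seed Monte-Carlo controls.
#' @return one-row data.frame of class `mr_mediation` with columns
#'   `beta0`, `beta1`, `beta2`, `indirect`, `indirect_se`,
#'   `indirect_ci_low/high`, `direct`, `proportion` (NA when
#'   inconsistent), `proportion_ci_low/high`, `pval`, `consistent`.
#' @export
mediate <- function(beta0 = NULL, se0, beta1, se1, beta2, se2, or0 = NULL,
                    second_order = FALSE, ci_method = c("delta", "montecarlo"),
                    conf_level = 0.95, n_draw = 5e5, seed = 20240101) {
  ci_method <- match.arg(ci_method)
  if (!is.null(or0)) {
    stopifnot_scalar_num(or0, "or0")
    if (or0 <= 0) mr_abort("`or0` must be > 0", "mr_domain_error")
    beta0 <- log(or0)
  }
  if (is.null(beta0)) mr_abort("supply `beta0` or `or0`", "mr_domain_error")
  if (beta0 == 0) {
    mr_abort("mediation proportion undefined for beta0 = 0 (OR = 1)",
             "mr_domain_error")
  }
  eff <- mediation_effect(beta1, se1, beta2, se2, second_order, conf_level)
  prop <- mediation_proportion(beta0, se0, beta1, se1, beta2, se2,
                               ci_method = ci_method, n_draw = n_draw,
                               seed = seed, conf_level = conf_level)
  data.frame(
    beta0 = beta0, se0 = se0, beta1 = beta1, se1 = se1,
    beta2 = beta2, se2 = se2,
    indirect = eff$indirect, indirect_se = eff$se,
    indirect_ci_low = eff$ci[1], indirect_ci_high = eff$ci[2],
    direct = direct_effect(beta0, beta1, beta2),
    proportion = prop$proportion,
    proportion_ci_low = prop$ci[1], proportion_ci_high = prop$ci[2],
    pval = mediation_pvalue(beta1, se1, beta2, se2),
    consistent = prop$consistent,
    stringsAsFactors = FALSE
  ) -> out
  class(out) <- c("mr_mediation", "data.frame")
  out
}
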