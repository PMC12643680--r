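# Three-leg screening: exposure->outcome, exposure->mediator,
# mediator->outcome, with reverse-direction checks, BH adjustment and
# candidate-pathway assembly feeding the mediation calculus.

#' Run one MR leg
#'
#' Pipeline: select instruments from the exposure table, harmonize with
#' the outcome table, run every applicable MR method with the IVW model
#' chosen by Cochran's Q, run the sensitivity suite, and record the IVW
#' p-value of the reversed direction (instruments selected from the
#' outcome table under `reverse_params`). A leg with a single surviving
#' instrument reports its Wald ratio but is flagged `wald_only`; a leg
#' with none is `non_estimable` (neither is fatal).
#'
#' @param exposure,outcome [association_table()] objects.
#' @param ld an [ld_matrix()] covering the SNP universe.
#' @param params instrument-selection thresholds for the forward leg.
#' @param settings an [mr_settings()].
#' @param reverse_params selection thresholds for the reverse leg
#'   (default: the disease/cytokine outcome preset).
#' @param reverse whether to estimate the reverse leg.
#' @return list of class `mr_leg`: `exposure_name`, `outcome_name`,
#'   `status` (`"ok"`, `"wald_only"`, `"non_estimable"`), `n_snp`,
#'   `estimates` (an `mr_result` or NULL), `primary` (one-row estimate
#'   or NULL), `pval`, `beta`, `se`, `sensitivity`, `reverse_pval`.
#' @export
run_leg <- function(exposure, outcome, ld, params = selection_preset("immune"),
                    settings = mr_settings(),
                    reverse_params = selection_preset("cytokine_outcome"),
                    reverse = TRUE) {
  iv <- suppressWarnings(select_instruments(exposure, ld, params))
  exposure_name <- attr(exposure, "trait_name")
  outcome_name <- attr(outcome, "trait_name")
  leg <- list(exposure_name = exposure_name, outcome_name = outcome_name,
              status = "non_estimable", n_snp = 0L, estimates = NULL,
              primary = NULL, pval = NA_real_, beta = NA_real_, se = NA_real_,
              sensitivity = NULL, reverse_pval = NA_real_)
  class(leg) <- "mr_leg"

  if (nrow(iv) > 0) {
    h <- tryCatch(harmonize(iv, outcome), error = function(e) NULL)
    j <- if (is.null(h)) 0L else nrow(retained_pairs(h))
    if (j >= 1) {
      est <- run_all_methods(h, settings)
      leg$estimates <- est
      leg$n_snp <- j
      if (j == 1) {
        leg$status <- "wald_only"
        leg$primary <- est[1, ]
      } else {
        leg$status <- "ok"
        leg$primary <- est[est$primary, ][1, ]
        leg$sensitivity <- sensitivity_report(h, settings)
      }
      leg$pval <- leg$primary$pval
      leg$beta <- leg$primary$beta
      leg$se <- leg$primary$se
    }
  }

  if (reverse) {
    riv <- suppressWarnings(select_instruments(outcome, ld, reverse_params))
    if (nrow(riv) > 0) {
      rh <- tryCatch(harmonize(riv, exposure), error = function(e) NULL)
      rj <- if (is.null(rh)) 0L else nrow(retained_pairs(rh))
      if (rj >= 2) {
        rq <- cochran_q(rh)
        leg$reverse_pval <- mr_ivw(rh, choose_ivw_model(rq$q_pval))$pval
      } else if (rj == 1) {
        leg$reverse_pval <- mr_wald_ratio(retained_pairs(rh))$pval
      }
    }
  }
  leg
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; order-preserving, each adjusted
#' value is at least the raw p and at most 1.
#'
#' @param pvals p-values in (0, 1].
#' @param method adjustment method (only `"BH"`).
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(pvals, method = "BH") {
  method <- match.arg(method, "BH")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    mr_abort("p-values must lie in (0, 1]", "mr_domain_error")
  }
  stats::p.adjust(pvals, method = method)
}

.leg_key <- function(leg) paste(leg$exposure_name, leg$outcome_name, sep = "\r")

# BH-adjust a leg collection within families sharing the same outcome.
.adjust_legs <- function(legs) {
  ok <- vapply(legs, function(l) is.finite(l$pval), logical(1))
  fam <- vapply(legs, function(l) l$outcome_name, character(1))
  adj <- rep(NA_real_, length(legs))
  for (f in unique(fam[ok])) {
    idx <- which(ok & fam == f)
    adj[idx] <- adjust_pvalues(vapply(legs[idx], function(l) l$pval, numeric(1)))
  }
  for (i in seq_along(legs)) legs[[i]]$pval_adj <- adj[i]
  legs
}

#' Assemble candidate mediated pathways from three leg collections
#'
#' A pathway (X, M, Y) is a candidate when its exposure->outcome,
#' exposure->mediator and mediator->outcome legs are all significant
#' under `rule` (`"ivw"`: primary IVW p < `alpha`, the primary screening
#' threshold; `"bh"`: BH-adjusted p < `alpha`, adjusted within each
#' (outcome, leg-type) family) and the reverse X<-Y direction is not
#' significant (`reverse_pval` missing or >= `reverse_alpha`). Mediation
#' is computed for every candidate from the three primary estimates.
#' Pathways failing only the reverse-direction rule are recorded in the
#' `excluded` attribute with their reason. A leg whose Egger intercept
#' test fires (p < 0.05) has `flag_pleiotropy` set on the candidate row
#' (a downgrade, not an exclusion).
#'
#' @param legs_xo,legs_xm,legs_mo lists of [run_leg()] results for the
#'   exposure->outcome, exposure->mediator and mediator->outcome legs.
#' @param rule `"ivw"` (raw primary p) or `"bh"` (BH-strict).
#' @param alpha leg significance threshold.
#' @param reverse_alpha reverse-direction exclusion threshold.
#' @return data.frame of class `mr_pathways`, one row per candidate,
#'   sorted by (exposure, mediator, outcome); attribute `excluded` lists
#'   reverse-significant pathways.
#' @export
assemble_pathways <- function(legs_xo, legs_xm, legs_mo,
                              rule = c("ivw", "bh"), alpha = 0.05,
                              reverse_alpha = 0.05) {
  rule <- match.arg(rule)
  if (rule == "bh") {
    legs_xo <- .adjust_legs(legs_xo)
    legs_xm <- .adjust_legs(legs_xm)
    legs_mo <- .adjust_legs(legs_mo)
  }
  key_xo <- vapply(legs_xo, .leg_key, character(1))
  key_xm <- vapply(legs_xm, .leg_key, character(1))
  key_mo <- vapply(legs_mo, .leg_key, character(1))
  exposures <- sort(unique(vapply(legs_xo, function(l) l$exposure_name, character(1))))
  mediators <- sort(unique(vapply(legs_xm, function(l) l$outcome_name, character(1))))
  outcomes <- sort(unique(vapply(legs_xo, function(l) l$outcome_name, character(1))))

  sig <- function(leg) {
    p <- if (rule == "bh") leg$pval_adj else leg$pval
    is.finite(p) && p < alpha
  }

  rows <- list()
  excluded <- list()
  for (x in exposures) for (m in mediators) for (y in outcomes) {
    i_xo <- match(paste(x, y, sep = "\r"), key_xo)
    i_xm <- match(paste(x, m, sep = "\r"), key_xm)
    i_mo <- match(paste(m, y, sep = "\r"), key_mo)
    if (any(is.na(c(i_xo, i_xm, i_mo)))) next
    l_xo <- legs_xo[[i_xo]]; l_xm <- legs_xm[[i_xm]]; l_mo <- legs_mo[[i_mo]]
    if (!(sig(l_xo) && sig(l_xm) && sig(l_mo))) next
    rev_p <- l_xo$reverse_pval
    if (is.finite(rev_p) && rev_p < reverse_alpha) {
      excluded[[length(excluded) + 1]] <- data.frame(
        exposure = x, mediator = m, outcome = y,
        reason = "reverse_direction_significant", reverse_pval = rev_p,
        stringsAsFactors = FALSE)
      next
    }
    med <- mediate(beta0 = l_xo$beta, se0 = l_xo$se,
                   beta1 = l_xm$beta, se1 = l_xm$se,
                   beta2 = l_mo$beta, se2 = l_mo$se)
    flag <- function(l) {
      !is.null(l$sensitivity) && is.finite(l$sensitivity$egger_intercept_pval) &&
        l$sensitivity$egger_intercept_pval < 0.05
    }
    row <- data.frame(exposure = x, mediator = m, outcome = y,
                      pval_xo = l_xo$pval, pval_xm = l_xm$pval,
                      pval_mo = l_mo$pval, reverse_pval = rev_p,
                      flag_pleiotropy = flag(l_xo) || flag(l_xm) || flag(l_mo),
                      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- cbind(row, med)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(exposure = character(0), mediator = character(0),
               outcome = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("mr_pathways", "data.frame"), rule = rule,
            alpha = alpha, reverse_alpha = reverse_alpha,
            excluded = if (length(excluded) > 0) do.call(rbind, excluded) else NULL)
}

#' Run the full three-leg screen over trait collections
#'
#' Computes every exposure->outcome, exposure->mediator and
#' mediator->outcome leg and assembles candidate pathways. Exposure legs
#' use `exposure_params` for instrument selection; mediator->outcome
#' legs use `mediator_params` (mediator instruments are selected under
#' the disease/cytokine profile).
#'
#' @param exposures,mediators,outcomes named lists of
#'   [association_table()] objects.
#' @param ld an [ld_matrix()] covering the shared SNP universe.
#' @param exposure_params,mediator_params selection presets.
#' @param settings an [mr_settings()].
#' @param rule,alpha,reverse_alpha see [assemble_pathways()].
#' @return list with `legs_xo`, `legs_xm`, `legs_mo`, `pathways`.
#' @export
run_screen <- function(exposures, mediators, outcomes, ld,
                       exposure_params = selection_preset("immune"),
                       mediator_params = selection_preset("cytokine_outcome"),
                       settings = mr_settings(), rule = c("ivw", "bh"),
                       alpha = 0.05, reverse_alpha = 0.05) {
  rule <- match.arg(rule)
  legs_xo <- list(); legs_xm <- list(); legs_mo <- list()
  for (e in exposures) for (o in outcomes) {
    legs_xo[[length(legs_xo) + 1]] <-
      run_leg(e, o, ld, exposure_params, settings)
  }
  for (e in exposures) for (m in mediators) {
    legs_xm[[length(legs_xm) + 1]] <-
      run_leg(e, m, ld, exposure_params, settings)
  }
  for (m in mediators) for (o in outcomes) {
    legs_mo[[length(legs_mo) + 1]] <-
      run_leg(m, o, ld, mediator_params, settings)
  }
  list(legs_xo = legs_xo, legs_xm = legs_xm, legs_mo = legs_mo,
       pathways = assemble_pathways(legs_xo, legs_xm, legs_mo, rule = rule,
                                    alpha = alpha, reverse_alpha = reverse_alpha))
}
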