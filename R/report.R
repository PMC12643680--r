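# Reporting helpers: tidy tables on disk, human-readable summaries and
# run manifests. Every printed number round-trips through the tidy
# tables; formatting is display-only.

#' Tidy results table for a collection of legs
#'
#' One row per (exposure, outcome, method) with beta, SE, CI, p, OR and
#' instrument count, plus the leg's heterogeneity/pleiotropy summary.
#'
#' @param legs list of [run_leg()] results.
#' @return data.frame.
#' @export
leg_results_table <- function(legs) {
  rows <- lapply(legs, function(l) {
    if (is.null(l$estimates)) {
      return(data.frame(exposure = l$exposure_name, outcome = l$outcome_name,
                        method = NA_character_, beta = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
                        or_ = NA_real_, or_ci_low = NA_real_,
                        or_ci_high = NA_real_, n_snp = 0L, primary = FALSE,
                        status = l$status, q_pval = NA_real_,
                        egger_intercept_pval = NA_real_,
                        presso_global_pval = NA_real_,
                        reverse_pval = l$reverse_pval,
                        stringsAsFactors = FALSE))
    }
    est <- as.data.frame(l$estimates)
    s <- l$sensitivity
    data.frame(exposure = l$exposure_name, outcome = l$outcome_name,
               est[, c("method", "beta", "se", "ci_low", "ci_high", "pval",
                       "or_", "or_ci_low", "or_ci_high", "n_snp", "primary")],
               status = l$status,
               q_pval = if (is.null(s)) NA_real_ else s$q_pval,
               egger_intercept_pval = if (is.null(s)) NA_real_ else s$egger_intercept_pval,
               presso_global_pval = if (is.null(s) || is.null(s$presso))
                 NA_real_ else s$presso$global_pval,
               reverse_pval = l$reverse_pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a mediation table for display
#'
#' Lays out mediation rows in the standard reporting shape: the three
#' path coefficients, the direct effect, the mediation effect with its
#' 95% CI, the mediation proportion in percent (NA for inconsistent
#' mediation) and the Sobel p-value. Values are rounded to 4 significant
#' digits for display; use the tidy row itself for full precision.
#'
#' @param med an `mr_mediation` row or an `mr_pathways` table.
#' @return data.frame of formatted character/numeric columns.
#' @export
format_mediation_table <- function(med) {
  s4 <- function(x) signif(x, 4)
  data.frame(
    beta0 = s4(med$beta0), beta1 = s4(med$beta1), beta2 = s4(med$beta2),
    direct_effect = s4(med$direct),
    mediation_effect = sprintf("%s (%s to %s)", s4(med$indirect),
                               s4(med$indirect_ci_low), s4(med$indirect_ci_high)),
    mediation_proportion_pct = ifelse(is.na(med$proportion), NA,
                                      s4(100 * med$proportion)),
    pval = s4(med$pval),
    stringsAsFactors = FALSE
  )
}

#' Write a tidy table to tab-delimited text
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, package version, seeds, input
#' file digests and a timestamp as JSON, so a rerun with an identical
#' manifest reproduces identical stochastic outputs.
#'
#' @param dir output directory (created if needed).
#' @param config list of configuration values.
#' @param seeds named seeds used in the run.
#' @param inputs character vector of input file paths to digest.
#' @return path of the manifest file, invisibly.
#' @export
write_manifest <- function(dir, config = list(), seeds = list(), inputs = character(0)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  digests <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "mrmediate",
    version = as.character(utils::packageVersion("mrmediate")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config, seeds = seeds, input_digests = digests
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimates (%d method%s):\n", nrow(x), if (nrow(x) > 1) "s" else ""))
  show <- as.data.frame(x)[, c("method", "beta", "se", "ci_low", "ci_high",
                               "pval", "or_", "n_snp", "primary")]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], signif, 4)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("Mediation decomposition:\n")
  print(format_mediation_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
print.mr_leg <- function(x, ...) {
  cat(sprintf("MR leg %s -> %s [%s], %d instrument(s)\n",
              x$exposure_name, x$outcome_name, x$status, x$n_snp))
  if (!is.null(x$primary)) {
    cat(sprintf("  primary %s: beta %.4g (se %.4g), p %.3g; reverse p %.3g\n",
                x$primary$method, x$beta, x$se, x$pval, x$reverse_pval))
  }
  invisible(x)
}
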