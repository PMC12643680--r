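# Instrument selection: p-value thresholding, greedy LD clumping and
# instrument-strength (R^2 / F) filtering.

#' Selection parameter set
#'
#' @param p_threshold genome-wide candidate p-value cutoff (strict `<`).
#' @param clump_r2 LD r-squared cutoff; SNPs in LD at or above it within
#'   the window are removed in favour of the smaller-p SNP.
#' @param clump_window_kb clumping window in kilobases.
#' @param f_min minimum instrument F-statistic (default 10; instruments
#'   with F below it are conventionally considered weak and excluded).
#' @return list of class `selection_params`.
#' @export
selection_params <- function(p_threshold, clump_r2, clump_window_kb, f_min = 10) {
  for (v in c("p_threshold", "clump_r2", "clump_window_kb", "f_min")) {
    stopifnot_scalar_num(get(v), v)
    if (get(v) <= 0) mr_abort(sprintf("`%s` must be > 0", v), "mr_domain_error")
  }
  if (clump_r2 > 1) mr_abort("`clump_r2` must be in (0, 1]", "mr_domain_error")
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min),
            class = "selection_params")
}

#' Named threshold presets
#'
#' `"immune"`: p < 1e-5, r2 < 0.1 within 500 kb (the immune-trait
#' exposure profile). `"cytokine_outcome"`: p < 5e-6, r2 < 0.001 within
#' 10,000 kb (the cytokine / disease-outcome profile).
#'
#' @param name preset name.
#' @return a [selection_params()] object.
#' @export
selection_preset <- function(name = c("immune", "cytokine_outcome")) {
  name <- match.arg(name)
  switch(name,
    immune = selection_params(1e-5, 0.1, 500),
    cytokine_outcome = selection_params(5e-6, 0.001, 10000)
  )
}

#' Construct an LD matrix
#'
#' @param snp_ids SNP labels.
#' @param r2 symmetric matrix of pairwise LD r-squared values with unit
#'   diagonal, ordered as `snp_ids`.
#' @param positions optional base-pair positions aligned to `snp_ids`.
#' @return list of class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, r2, positions = NULL) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != length(snp_ids) || ncol(r2) != length(snp_ids)) {
    mr_abort("r2 matrix dimensions must match snp_ids", "mr_format_error")
  }
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1 + 1e-12)) {
    mr_abort("LD r2 entries must lie in [0, 1]", "mr_domain_error")
  }
  if (max(abs(r2 - t(r2))) > 1e-8 || max(abs(diag(r2) - 1)) > 1e-8) {
    mr_abort("LD matrix must be symmetric with unit diagonal", "mr_domain_error")
  }
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2,
                 positions = positions), class = "ld_matrix")
}

#' Read an LD matrix from file
#'
#' Accepts either a square matrix file (tab-delimited, header row of SNP
#' ids, one row per SNP in the same order) or a long-format triplet file
#' with columns `snp_a`, `snp_b`, `r2` (unlisted pairs default to 0).
#'
#' @param path file path.
#' @return an [ld_matrix()].
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) mr_abort(sprintf("file not found: %s", path), "mr_format_error")
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(raw) == 3 && all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    ids <- unique(c(raw$snp_a, raw$snp_b))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(raw))) {
      m[raw$snp_a[i], raw$snp_b[i]] <- raw$r2[i]
      m[raw$snp_b[i], raw$snp_a[i]] <- raw$r2[i]
    }
    ld_matrix(ids, m)
  } else {
    ids <- names(raw)
    ld_matrix(ids, as.matrix(raw))
  }
}

#' Proportion of trait variance explained by one variant
#'
#' `R2 = beta^2 / (beta^2 + se^2 * n)`.
#'
#' @param beta allele effect size.
#' @param se its standard error (> 0).
#' @param n GWAS sample size (> 2).
#' @return variance proportion in \[0, 1). Vectorized.
#' @export
variance_explained <- function(beta, se, n) {
  if (any(!is.finite(se)) || any(se <= 0)) mr_abort("`se` must be > 0", "mr_domain_error")
  if (any(!is.finite(n)) || any(n <= 2)) mr_abort("`n` must be > 2", "mr_domain_error")
  beta^2 / (beta^2 + se^2 * n)
}

#' Instrument F-statistic
#'
#' `F = R2 * (n - 2) / (1 - R2)`.
#'
#' @param r2 variance proportion in \[0, 1).
#' @param n GWAS sample size (> 2).
#' @return F value (>= 0). Vectorized.
#' @export
f_statistic <- function(r2, n) {
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 >= 1)) {
    mr_abort("`r2` must lie in [0, 1)", "mr_domain_error")
  }
  if (any(!is.finite(n)) || any(n <= 2)) mr_abort("`n` must be > 2", "mr_domain_error")
  r2 * (n - 2) / (1 - r2)
}

#' Greedy LD clumping
#'
#' Repeatedly retains the remaining SNP with the smallest p-value (ties
#' broken lexicographically by `snp_id`) and removes all remaining SNPs
#' on the same chromosome within `clump_window_kb` kilobases whose LD
#' r-squared with it is at or above `clump_r2`. SNP pairs absent from the
#' LD matrix are treated as LD-independent (a warning is issued once);
#' cross-chromosome pairs never clump.
#'
#' @param table an [association_table()].
#' @param ld an [ld_matrix()] (may cover only part of the table).
#' @param params a [selection_params()].
#' @return the retained subset of `table`, in the input row order.
#' @export
clump <- function(table, ld, params) {
  stopifnot(inherits(table, "assoc_table"), inherits(params, "selection_params"))
  n <- nrow(table)
  if (n == 0) return(table)
  in_ld <- table$snp_id %in% ld$snp_ids
  if (any(!in_ld)) {
    warning(sprintf("%d SNP(s) absent from the LD matrix; treated as LD-independent",
                    sum(!in_ld)))
  }
  ord <- order(table$pval, table$snp_id)
  state <- rep("free", n)  # free | kept | removed
  window_bp <- params$clump_window_kb * 1000
  for (i in ord) {
    if (state[i] != "free") next
    state[i] <- "kept"
    if (!in_ld[i]) next
    cand <- which(state == "free" & in_ld &
                    table$chrom == table$chrom[i] &
                    abs(table$pos - table$pos[i]) <= window_bp)
    if (length(cand) == 0) next
    r2 <- ld$r2[table$snp_id[i], table$snp_id[cand]]
    state[cand[r2 >= params$clump_r2]] <- "removed"
  }
  keep <- table[state == "kept", , drop = FALSE]
  rownames(keep) <- NULL
  structure(keep, class = class(table),
            trait_name = attr(table, "trait_name"),
            trait_type = attr(table, "trait_type"))
}

#' Select instrumental variables
#'
#' Pipeline: filter `pval < p_threshold`, clump by LD, compute per-SNP
#' variance explained and F-statistic (with each record's own sample
#' size), then drop instruments with `F < f_min`.
#'
#' @inheritParams clump
#' @return the surviving subset of `table` (class `assoc_table`, still
#'   usable downstream) with extra columns `r2_explained` and `f_stat`.
#' @export
select_instruments <- function(table, ld, params) {
  stopifnot(inherits(table, "assoc_table"))
  hits <- table[table$pval < params$p_threshold, , drop = FALSE]
  hits <- structure(hits, class = class(table),
                    trait_name = attr(table, "trait_name"),
                    trait_type = attr(table, "trait_type"))
  if (nrow(hits) == 0) {
    hits$r2_explained <- numeric(0)
    hits$f_stat <- numeric(0)
    return(hits)
  }
  kept <- clump(hits, ld, params)
  kept$r2_explained <- variance_explained(kept$beta, kept$se, kept$n)
  kept$f_stat <- f_statistic(kept$r2_explained, kept$n)
  strong <- kept[kept$f_stat >= params$f_min, , drop = FALSE]
  rownames(strong) <- NULL
  structure(strong, class = class(table),
            trait_name = attr(table, "trait_name"),
            trait_type = attr(table, "trait_type"))
}
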