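# Reading, validating, writing and harmonizing GWAS summary statistics.
#
# On-disk format: tab-delimited text with a header line and canonical
# columns SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N. Other dialects are
# absorbed through `column_map`. Gzip input is read transparently.

.canonical_cols <- c(
  SNP = "snp_id", CHR = "chrom", POS = "pos", EA = "effect_allele",
  OA = "other_allele", EAF = "eaf", BETA = "beta", SE = "se",
  P = "pval", N = "n"
)
.mandatory_cols <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE", "P", "N")

#' Construct a validated association table
#'
#' An association table holds one SNP-trait summary association per row:
#' effect and other allele, effect-allele frequency, effect size (log-odds
#' for binary traits, SD units for quantitative traits), its standard
#' error, p-value and sample size.
#'
#' Rows violating the record invariants (`se > 0`, `0 < pval <= 1`,
#' non-empty distinct alleles, `eaf` in (0,1) when present, positive `n`)
#' are dropped with a warning; duplicated `snp_id`s keep the first
#' occurrence.
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_name label for the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @return data.frame of class `assoc_table` with attributes
#'   `trait_name` and `trait_type`.
#' @export
association_table <- function(records, trait_name = "trait",
                              trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  needed <- unname(.canonical_cols)
  missing <- setdiff(setdiff(needed, "eaf"), names(records))
  if (length(missing) > 0) {
    mr_abort(sprintf("missing mandatory column(s): %s",
                     paste(missing, collapse = ", ")), "mr_format_error")
  }
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  records <- records[, needed]

  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  ok <- !is.na(records$snp_id) & nzchar(records$snp_id) &
    !is.na(records$pos) & records$pos >= 1 &
    nzchar(records$effect_allele) & nzchar(records$other_allele) &
    records$effect_allele != records$other_allele &
    is.finite(records$beta) &
    is.finite(records$se) & records$se > 0 &
    is.finite(records$pval) & records$pval > 0 & records$pval <= 1 &
    is.finite(records$n) & records$n > 0 &
    (is.na(records$eaf) | (records$eaf > 0 & records$eaf < 1))
  ok[is.na(ok)] <- FALSE
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("dropped %d row(s) violating association-record invariants", n_bad))
    records <- records[ok, , drop = FALSE]
  }
  dup <- duplicated(records$snp_id)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicated snp_id row(s), keeping first occurrence", sum(dup)))
    records <- records[!dup, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    mr_abort("no valid association records remain", "mr_empty_error")
  }
  rownames(records) <- NULL
  structure(records, class = c("assoc_table", "data.frame"),
            trait_name = trait_name, trait_type = trait_type)
}

#' Read a GWAS summary-statistics table
#'
#' @param path tab-delimited file (optionally gzip-compressed) with a
#'   header line.
#' @param column_map named character vector mapping canonical column
#'   names (`SNP`, `CHR`, `POS`, `EA`, `OA`, `EAF`, `BETA`, `SE`, `P`,
#'   `N`) to the names used in the file; unmapped names are taken as-is.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_name label for the trait; defaults to the file name.
#' @return an [association_table()].
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("quantitative", "binary"),
                               trait_name = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) {
    mr_abort(sprintf("file not found: %s", path), "mr_format_error")
  }
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  lookup <- stats::setNames(names(.canonical_cols), names(.canonical_cols))
  if (!is.null(column_map)) lookup[names(column_map)] <- unname(column_map)

  missing <- .mandatory_cols[!lookup[.mandatory_cols] %in% names(raw)]
  if (length(missing) > 0) {
    mr_abort(sprintf("missing mandatory column(s): %s (after column_map)",
                     paste(lookup[missing], collapse = ", ")), "mr_format_error")
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    snp_id = raw[[lookup["SNP"]]])
  for (canon in names(.canonical_cols)) {
    src <- lookup[canon]
    out[[.canonical_cols[canon]]] <-
      if (src %in% names(raw)) raw[[src]] else NA
  }
  association_table(out, trait_name = trait_name %||% basename(path),
                    trait_type = trait_type)
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-delimited layout at full double precision so
#' that a write/read round trip reproduces betas and SEs exactly. A
#' `.gz` suffix triggers gzip compression.
#'
#' @param table an [association_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(table, path) {
  stopifnot(inherits(table, "assoc_table"))
  out <- data.frame(
    SNP = table$snp_id, CHR = table$chrom,
    POS = sprintf("%.17g", table$pos),
    EA = table$effect_allele, OA = table$other_allele,
    EAF = ifelse(is.na(table$eaf), "NA", sprintf("%.17g", table$eaf)),
    BETA = sprintf("%.17g", table$beta), SE = sprintf("%.17g", table$se),
    P = sprintf("%.17g", table$pval), N = sprintf("%.17g", table$n),
    stringsAsFactors = FALSE
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) {
  nchar(ea) == 1 & nchar(oa) == 1 & oa == .complement(ea)
}

#' Harmonize exposure and outcome associations to a common effect allele
#'
#' Intersects the two tables on `snp_id` and aligns every outcome record
#' to the exposure's effect allele. Swapped alleles flip the outcome beta
#' sign; strand flips (e.g. A/G recorded as T/C) are resolved by
#' complementing before matching. Palindromic SNPs (A/T or G/C) cannot be
#' strand-resolved from alleles alone: they are dropped when either
#' effect-allele frequency is missing or within `palindrome_eaf_window`
#' of 0.5 (default window: EAF in \[0.42, 0.58\]), and otherwise oriented
#' by frequency agreement. Allele sets matching neither orientation are
#' dropped as incompatible.
#'
#' @param exposure,outcome [association_table()] objects.
#' @param palindrome_eaf_window half-width of the ambiguity window around
#'   EAF 0.5 for palindromic SNPs.
#' @return data.frame of class `mr_harmonized` with columns `snp_id`,
#'   `beta_exp`, `se_exp`, `pval_exp`, `beta_out`, `se_out`, `pval_out`,
#'   `eaf` (exposure EAF) and `action` (one of `kept`, `flipped`,
#'   `dropped_palindromic`, `dropped_incompatible`). Dropped rows are
#'   retained in the object for provenance but excluded from estimation
#'   (see [retained_pairs()]).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "assoc_table"), inherits(outcome, "assoc_table"))
  common <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(common) == 0) {
    mr_abort("no overlapping SNPs between exposure and outcome", "mr_no_overlap_error")
  }
  e <- exposure[match(common, exposure$snp_id), ]
  o <- outcome[match(common, outcome$snp_id), ]

  n <- length(common)
  action <- character(n)
  beta_out <- o$beta
  pal <- .is_palindromic(e$effect_allele, e$other_allele)

  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swap <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  csame <- .complement(o$effect_allele) == e$effect_allele &
    .complement(o$other_allele) == e$other_allele
  cswap <- .complement(o$effect_allele) == e$other_allele &
    .complement(o$other_allele) == e$effect_allele

  for (i in seq_len(n)) {
    if (pal[i]) {
      if (!(same[i] || swap[i])) {
        action[i] <- "dropped_incompatible"
        next
      }
      ambiguous <- is.na(e$eaf[i]) || is.na(o$eaf[i]) ||
        abs(e$eaf[i] - 0.5) <= palindrome_eaf_window ||
        abs(o$eaf[i] - 0.5) <= palindrome_eaf_window
      if (ambiguous) {
        action[i] <- "dropped_palindromic"
      } else if ((e$eaf[i] - 0.5) * (o$eaf[i] - 0.5) > 0) {
        action[i] <- "kept"
      } else {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
      }
    } else if (same[i] || csame[i]) {
      action[i] <- "kept"
    } else if (swap[i] || cswap[i]) {
      action[i] <- "flipped"
      beta_out[i] <- -beta_out[i]
    } else {
      action[i] <- "dropped_incompatible"
    }
  }

  res <- data.frame(
    snp_id = common,
    beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval,
    beta_out = beta_out, se_out = o$se, pval_out = o$pval,
    eaf = e$eaf, action = action,
    stringsAsFactors = FALSE
  )
  structure(res, class = c("mr_harmonized", "data.frame"),
            exposure_name = attr(exposure, "trait_name"),
            outcome_name = attr(outcome, "trait_name"))
}

#' Retained exposure/outcome pairs of a harmonized set
#'
#' @param h an `mr_harmonized` object (or a plain data.frame with
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out` columns, returned as-is).
#' @return data.frame of the pairs usable for estimation.
#' @export
retained_pairs <- function(h) {
  if (!is.null(h$action)) {
    h <- h[h$action %in% c("kept", "flipped"), , drop = FALSE]
  }
  needed <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(needed %in% names(h))) {
    mr_abort("harmonized pairs need beta_exp/se_exp/beta_out/se_out columns",
             "mr_format_error")
  }
  h
}
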