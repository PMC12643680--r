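# Fixtures built in code; no data files.

# A minimal well-formed association data.frame.
make_records <- function(n = 3, beta = 0.1, se = 0.02, pval = 1e-6,
                         nn = 3757, ea = "A", oa = "G") {
  data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1e6,
    effect_allele = rep_len(ea, n),
    other_allele = rep_len(oa, n),
    eaf = seq(0.2, 0.4, length.out = n),
    beta = rep_len(beta, n),
    se = rep_len(se, n),
    pval = rep_len(pval, n),
    n = rep_len(nn, n),
    stringsAsFactors = FALSE
  )
}

make_table <- function(..., trait_name = "trait", trait_type = "quantitative") {
  association_table(make_records(...), trait_name, trait_type)
}

# Harmonized pairs without going through allele matching.
make_pairs <- function(beta_exp, beta_out, se_out, se_exp = 0.01,
                       snp_id = NULL) {
  data.frame(
    snp_id = snp_id %||% sprintf("rs%03d", seq_along(beta_exp)),
    beta_exp = beta_exp, se_exp = rep_len(se_exp, length(beta_exp)),
    beta_out = beta_out, se_out = rep_len(se_out, length(beta_exp)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-instrument IVW fixture: beta 0.6, fixed SE 1/sqrt(200), Q = 2.
ivw_fixture <- function() make_pairs(c(1, 1), c(0.5, 0.7), c(0.1, 0.1))

# Collinear Egger fixture on the line y = 0.1 + x.
egger_fixture <- function() make_pairs(c(1, 2, 3), c(1.1, 2.1, 3.1), 0.1)

harmonize_sim <- function(sim) harmonize(sim$exposure, sim$outcome)
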