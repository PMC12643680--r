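# Simulators of GWAS summary statistics with known causal structure.
#
# Structural model (per SD / log-odds scales):
#   X = sum_j gamma_j G_j + e_X          (exposure, variance 1)
#   M = beta1 * X + e_M                  (mediator, variance 1)
#   Y: liability (beta0 - beta1*beta2) X + beta2 M + pleiotropy + e_Y,
#      dichotomized at the prevalence threshold; summary effects are
#      reported on the logistic scale, internally calibrated so the
#      planted beta0/beta2 are the values an IVW fit of the emitted
#      logistic-scale statistics recovers.
# Exposure, mediator and outcome cohorts are disjoint (two-sample MR).

#' Simulation configuration
#'
#' Defaults mirror the data regime of the source GWAS resources this
#' package is aimed at: an exposure cohort of 3757 (flow-cytometry
#' immune-trait GWAS), a mediator cohort of 8293 (circulating-cytokine
#' GWAS), an outcome cohort of 20,000 (lung-cancer phenotype GWAS range
#' roughly 10k-420k), 30 instruments per trait with per-SNP standardized
#' effects around `gamma_scale = 0.09` (instrument F about 30 at these
#' cohort sizes), and a disease prevalence of 0.1.
#'
#' @param n_snp number of instrument SNPs.
#' @param n_exp,n_med,n_out cohort sizes (disjoint samples, >= 100).
#' @param maf_range minor-allele-frequency interval.
#' @param gamma_scale scale of per-SNP standardized exposure effects;
#'   magnitudes are drawn uniformly in `gamma_scale * [0.7, 1.3]` so
#'   every planted instrument clears F = 10 at the default cohort
#'   sizes. Effect alleles are oriented as exposure-increasing, so a
#'   non-zero `pleio_mean` yields directional pleiotropy on the Wald
#'   ratio scale.
#' @param beta0_true total exposure->outcome effect (log-odds per SD).
#' @param beta1_true exposure->mediator effect (SD per SD, |.| < 1).
#' @param beta2_true mediator->outcome effect (log-odds per SD).
#' @param pleio_mean,pleio_sd distribution of direct SNP->outcome
#'   effects on invalid instruments (directional when the mean is
#'   non-zero).
#' @param prop_invalid fraction of SNPs given pleiotropic effects.
#' @param ld_blocks NULL for LD-independent SNPs, else
#'   `list(size = , r2 = )` giving the block size and within-block
#'   r-squared.
#' @param prevalence outcome prevalence for the liability threshold.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snp = 30, n_exp = 3757, n_med = 8293, n_out = 20000,
                       maf_range = c(0.1, 0.4), gamma_scale = 0.09,
                       beta0_true = 0.16, beta1_true = 0.3, beta2_true = 0.2,
                       pleio_mean = 0, pleio_sd = 0, prop_invalid = 0,
                       ld_blocks = NULL, prevalence = 0.1, seed = 20240101) {
  if (prop_invalid < 0 || prop_invalid > 1) {
    mr_abort("`prop_invalid` must lie in [0, 1]", "mr_config_error")
  }
  if (min(n_exp, n_med, n_out) < 100) {
    mr_abort("cohort sizes must be >= 100", "mr_config_error")
  }
  if (abs(beta1_true) >= 1) {
    mr_abort("`beta1_true` must have magnitude < 1 (SD-per-SD path)", "mr_config_error")
  }
  h2 <- n_snp * (1.3 * gamma_scale)^2
  if (h2 >= 1) {
    mr_abort("variance budget exceeded: n_snp * (1.3*gamma_scale)^2 >= 1",
             "mr_config_error")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    mr_abort("`prevalence` must lie in (0, 1)", "mr_config_error")
  }
  structure(list(n_snp = n_snp, n_exp = n_exp, n_med = n_med, n_out = n_out,
                 maf_range = maf_range, gamma_scale = gamma_scale,
                 beta0_true = beta0_true, beta1_true = beta1_true,
                 beta2_true = beta2_true, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, prop_invalid = prop_invalid,
                 ld_blocks = ld_blocks, prevalence = prevalence, seed = seed),
            class = "sim_config")
}

# Shared draws of the genetic architecture: MAFs, standardized exposure
# effects, pleiotropic effects, positions, block structure.
.sim_architecture <- function(cfg) {
  n <- cfg$n_snp
  maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
  # effect alleles oriented as exposure-increasing (gamma > 0), so a
  # non-zero pleio_mean is genuinely directional on the ratio scale
  u <- cfg$gamma_scale * stats::runif(n, 0.7, 1.3)
  gamma <- u / sqrt(2 * maf * (1 - maf))  # per-allele, standardized trait
  n_invalid <- round(cfg$prop_invalid * n)
  invalid <- if (n_invalid > 0) sort(sample.int(n, n_invalid)) else integer(0)
  alpha <- numeric(n)
  if (n_invalid > 0) alpha[invalid] <- stats::rnorm(n_invalid, cfg$pleio_mean, cfg$pleio_sd)

  size <- if (is.null(cfg$ld_blocks)) 1L else as.integer(cfg$ld_blocks$size)
  block <- rep(seq_len(ceiling(n / size)), each = size)[seq_len(n)]
  # same MAF within a block so the haplotype-copy chain keeps marginals
  if (size > 1) maf <- ave(maf, block)
  within <- stats::ave(seq_len(n), block, FUN = seq_along)
  pos <- (block - 1) * 2e6 + (within - 1) * 1000 + 1
  snp_id <- sprintf("rs%05d", seq_len(n))
  list(snp_id = snp_id, maf = maf, u = u, gamma = gamma, alpha = alpha,
       invalid = invalid, block = block, pos = pos)
}

.assoc_from_stats <- function(arch, beta, se, n, trait_name, trait_type) {
  association_table(data.frame(
    snp_id = arch$snp_id, chrom = "1", pos = arch$pos,
    effect_allele = "A", other_allele = "G", eaf = arch$maf,
    beta = beta, se = se,
    pval = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n, stringsAsFactors = FALSE
  ), trait_name = trait_name, trait_type = trait_type)
}

.block_ld <- function(arch, cfg) {
  n <- length(arch$snp_id)
  r2 <- diag(1, n)
  if (!is.null(cfg$ld_blocks)) {
    for (b in unique(arch$block)) {
      idx <- which(arch$block == b)
      if (length(idx) > 1) {
        # chain correlation: adjacent r2 as configured, decaying with lag
        for (i in idx) for (k in idx) {
          if (i != k) r2[i, k] <- cfg$ld_blocks$r2^abs(i - k)
        }
      }
    }
  }
  ld_matrix(arch$snp_id, r2, positions = arch$pos)
}

.truth_record <- function(cfg, arch) {
  ind <- cfg$beta1_true * cfg$beta2_true
  r2_true <- arch$u^2  # standardized per-SNP variance explained
  list(beta0_true = cfg$beta0_true, beta1_true = cfg$beta1_true,
       beta2_true = cfg$beta2_true, indirect_true = ind,
       proportion_true = if (cfg$beta0_true != 0) ind / cfg$beta0_true else NA_real_,
       invalid_snp_ids = arch$snp_id[arch$invalid],
       gamma_std = arch$u,
       f_true = r2_true * (cfg$n_exp - 2) / (1 - r2_true),
       seed = cfg$seed)
}

#' Fast direct simulation of summary statistics
#'
#' Draws per-SNP summary betas directly: the exposure beta is the planted
#' per-allele effect plus noise at the SE implied by the cohort size and
#' MAF; mediator betas are `beta1 * gamma`; outcome betas are
#' `beta0 * gamma` plus the pleiotropic effect on invalid SNPs, with the
#' logistic-scale SE implied by the outcome cohort size, MAF and
#' prevalence. Bypasses individual-level simulation; intended for
#' large-replicate calibration suites. Betas are drawn independently
#' across SNPs, so configured LD blocks shape only the emitted LD matrix.
#'
#' @param cfg a [sim_config()].
#' @return list with `exposure`, `mediator`, `outcome` (association
#'   tables), `ld` (an [ld_matrix()]) and `truth` (the planted effects
#'   and invalid SNP ids).
#' @export
simulate_summary_direct <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    arch <- .sim_architecture(cfg)
    het <- 2 * arch$maf * (1 - arch$maf)
    se_x <- 1 / sqrt(het * cfg$n_exp)
    se_m <- 1 / sqrt(het * cfg$n_med)
    se_y <- 1 / sqrt(het * cfg$n_out * cfg$prevalence * (1 - cfg$prevalence))
    bx <- arch$gamma + stats::rnorm(cfg$n_snp, 0, se_x)
    bm <- cfg$beta1_true * arch$gamma + stats::rnorm(cfg$n_snp, 0, se_m)
    by <- cfg$beta0_true * arch$gamma + arch$alpha + stats::rnorm(cfg$n_snp, 0, se_y)
    list(
      exposure = .assoc_from_stats(arch, bx, se_x, cfg$n_exp, "exposure", "quantitative"),
      mediator = .assoc_from_stats(arch, bm, se_m, cfg$n_med, "mediator", "quantitative"),
      outcome = .assoc_from_stats(arch, by, se_y, cfg$n_out, "outcome", "binary"),
      ld = .block_ld(arch, cfg),
      truth = .truth_record(cfg, arch)
    )
  })
}

# Genotype matrix with block-LD structure via a haplotype-copy chain:
# within a block each haplotype allele copies its left neighbour with
# probability sqrt(r2), else is drawn fresh at the block MAF.
.sim_genotypes <- function(n_ind, arch, cfg) {
  n_snp <- length(arch$maf)
  rho <- if (is.null(cfg$ld_blocks)) 0 else sqrt(cfg$ld_blocks$r2)
  hap <- function() {
    h <- matrix(0L, n_ind, n_snp)
    for (j in seq_len(n_snp)) {
      fresh <- stats::rbinom(n_ind, 1L, arch$maf[j])
      if (j > 1 && arch$block[j] == arch$block[j - 1] && rho > 0) {
        copy <- stats::runif(n_ind) < rho
        h[, j] <- ifelse(copy, h[, j - 1], fresh)
      } else {
        h[, j] <- fresh
      }
    }
    h
  }
  hap() + hap()
}

# Vectorized per-SNP linear ("score") regression; binary traits are
# rescaled to the logistic scale by 1 / (pbar * (1 - pbar)).
.assoc_scan <- function(G, y, binary) {
  n <- length(y)
  gc <- scale(G, scale = FALSE)
  yc <- y - mean(y)
  vg <- colSums(gc^2)
  beta <- colSums(gc * yc) / vg
  rss <- pmax(sum(yc^2) - beta^2 * vg, 0)
  se <- sqrt(rss / ((n - 2) * vg))
  if (binary) {
    s <- mean(y) * (1 - mean(y))
    beta <- beta / s
    se <- se / s
  }
  list(beta = beta, se = se, eaf = colMeans(G) / 2)
}

#' Individual-level simulation of a GWAS triplet
#'
#' Draws genotypes for three disjoint cohorts, builds the exposure,
#' mediator and binary outcome from the structural model, computes
#' per-SNP summary statistics in each cohort (vectorized score
#' regression; logistic-scale conversion for the binary outcome), and
#' emits the LD matrix realized in the exposure cohort.
#'
#' @param cfg a [sim_config()].
#' @return as [simulate_summary_direct()].
#' @export
simulate_triplet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    arch <- .sim_architecture(cfg)
    var_g <- sum(arch$u^2)
    if (var_g >= 1) mr_abort("variance budget exceeded", "mr_config_error")

    # liability calibration so emitted logistic-scale totals equal beta0
    thr <- stats::qnorm(1 - cfg$prevalence)
    k <- cfg$prevalence * (1 - cfg$prevalence) / stats::dnorm(thr)
    c_x <- k * (cfg$beta0_true - cfg$beta1_true * cfg$beta2_true)
    c_m <- k * cfg$beta2_true
    alpha_liab <- k * arch$alpha

    make_traits <- function(G) {
      n <- nrow(G)
      gx <- G %*% arch$gamma
      x <- gx + stats::rnorm(n, 0, sqrt(1 - var_g))
      m <- cfg$beta1_true * x + stats::rnorm(n, 0, sqrt(1 - cfg$beta1_true^2))
      g_pl <- if (length(arch$invalid) > 0) G %*% alpha_liab else 0
      struct <- c_x * x + c_m * m + g_pl
      v_struct <- c_x^2 + c_m^2 + 2 * c_x * c_m * cfg$beta1_true +
        sum((alpha_liab * sqrt(2 * arch$maf * (1 - arch$maf)))^2) +
        2 * (c_x + c_m * cfg$beta1_true) * sum(alpha_liab * arch$gamma *
                                                 2 * arch$maf * (1 - arch$maf))
      if (v_struct >= 1) mr_abort("variance budget exceeded on the liability scale",
                                  "mr_config_error")
      liab <- struct + stats::rnorm(n, 0, sqrt(1 - v_struct))
      list(x = as.numeric(x), m = as.numeric(m), y = as.integer(liab > thr))
    }

    g_exp <- .sim_genotypes(cfg$n_exp, arch, cfg)
    g_med <- .sim_genotypes(cfg$n_med, arch, cfg)
    g_out <- .sim_genotypes(cfg$n_out, arch, cfg)
    t_exp <- make_traits(g_exp)
    t_med <- make_traits(g_med)
    t_out <- make_traits(g_out)

    sx <- .assoc_scan(g_exp, t_exp$x, binary = FALSE)
    sm <- .assoc_scan(g_med, t_med$m, binary = FALSE)
    sy <- .assoc_scan(g_out, t_out$y, binary = TRUE)

    r2 <- suppressWarnings(stats::cor(g_exp))^2
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 1
    r2 <- pmin(pmax(r2, 0), 1)

    mk <- function(s, n, nm, ty) {
      a <- arch; a$maf <- pmin(pmax(s$eaf, 1e-6), 1 - 1e-6)
      .assoc_from_stats(a, s$beta, s$se, n, nm, ty)
    }
    list(
      exposure = mk(sx, cfg$n_exp, "exposure", "quantitative"),
      mediator = mk(sm, cfg$n_med, "mediator", "quantitative"),
      outcome = mk(sy, cfg$n_out, "outcome", "binary"),
      ld = ld_matrix(arch$snp_id, r2, positions = arch$pos),
      truth = .truth_record(cfg, arch)
    )
  })
}

#' Simulate a multi-trait screening grid
#'
#' Builds summary statistics over a shared SNP panel for `n_exposure`
#' exposures, `n_mediator` mediators and `n_outcome` binary outcomes in
#' which exactly one pathway (exposure `true_idx[1]` -> mediator
#' `true_idx[2]` -> outcome `true_idx[3]`) carries the planted
#' beta0/beta1/beta2 effects; every other trait pair is null. Each
#' exposure and each mediator has its own instrument set; every trait
#' table covers the full panel so all screening legs (including reverse
#' legs) can be estimated. The outcome cohort defaults to 50,000, the
#' mid-range of large case-control lung-cancer GWAS.
#'
#' @param cfg a [sim_config()]; `n_out` is overridden by `n_out_grid`.
#' @param n_exposure,n_mediator,n_outcome grid dimensions.
#' @param true_idx integer triple picking the true pathway.
#' @param n_out_grid outcome cohort size for the grid.
#' @return list with `exposures`, `mediators`, `outcomes` (named lists
#'   of association tables), `ld` and `truth` (planted effects plus the
#'   true pathway's labels).
#' @export
simulate_grid <- function(cfg = sim_config(), n_exposure = 5, n_mediator = 3,
                          n_outcome = 2, true_idx = c(1, 1, 1),
                          n_out_grid = 50000) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_traits <- n_exposure + n_mediator
    n_panel <- n_traits * cfg$n_snp
    maf <- stats::runif(n_panel, cfg$maf_range[1], cfg$maf_range[2])
    u <- cfg$gamma_scale * stats::runif(n_panel, 0.7, 1.3)
    per_allele <- u / sqrt(2 * maf * (1 - maf))
    snp_id <- sprintf("rs%05d", seq_len(n_panel))
    pos <- (seq_len(n_panel) - 1) * 2e6 + 1
    owner <- rep(seq_len(n_traits), each = cfg$n_snp)  # 1..n_exposure exposures
    arch <- list(snp_id = snp_id, maf = maf, pos = pos)

    het <- 2 * maf * (1 - maf)
    se_x <- 1 / sqrt(het * cfg$n_exp)
    se_m <- 1 / sqrt(het * cfg$n_med)
    se_y <- 1 / sqrt(het * n_out_grid * cfg$prevalence * (1 - cfg$prevalence))

    exposures <- list()
    for (i in seq_len(n_exposure)) {
      mean_b <- ifelse(owner == i, per_allele, 0)
      b <- mean_b + stats::rnorm(n_panel, 0, se_x)
      exposures[[sprintf("X%d", i)]] <-
        .assoc_from_stats(arch, b, se_x, cfg$n_exp, sprintf("X%d", i), "quantitative")
    }
    mediators <- list()
    for (j in seq_len(n_mediator)) {
      own <- owner == (n_exposure + j)
      mean_b <- ifelse(own, per_allele, 0)
      if (j == true_idx[2]) {
        from_x <- owner == true_idx[1]
        mean_b <- mean_b + ifelse(from_x, cfg$beta1_true * per_allele, 0)
      }
      b <- mean_b + stats::rnorm(n_panel, 0, se_m)
      mediators[[sprintf("M%d", j)]] <-
        .assoc_from_stats(arch, b, se_m, cfg$n_med, sprintf("M%d", j), "quantitative")
    }
    outcomes <- list()
    for (kk in seq_len(n_outcome)) {
      mean_b <- numeric(n_panel)
      if (kk == true_idx[3]) {
        mean_b <- mean_b +
          ifelse(owner == true_idx[1], cfg$beta0_true * per_allele, 0) +
          ifelse(owner == (n_exposure + true_idx[2]),
                 cfg$beta2_true * per_allele, 0)
      }
      b <- mean_b + stats::rnorm(n_panel, 0, se_y)
      outcomes[[sprintf("Y%d", kk)]] <-
        .assoc_from_stats(arch, b, se_y, n_out_grid, sprintf("Y%d", kk), "binary")
    }
    truth <- list(
      exposure = sprintf("X%d", true_idx[1]),
      mediator = sprintf("M%d", true_idx[2]),
      outcome = sprintf("Y%d", true_idx[3]),
      beta0_true = cfg$beta0_true, beta1_true = cfg$beta1_true,
      beta2_true = cfg$beta2_true,
      indirect_true = cfg$beta1_true * cfg$beta2_true,
      proportion_true = cfg$beta1_true * cfg$beta2_true / cfg$beta0_true,
      seed = cfg$seed
    )
    list(exposures = exposures, mediators = mediators, outcomes = outcomes,
         ld = ld_matrix(snp_id, diag(1, n_panel), positions = pos),
         truth = truth)
  })
}
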