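test_that("variance_explained matches the closed form", {
  expect_equal(variance_explained(0, 0.02, 3757), 0)
  expect_equal(variance_explained(0.1, 0.02, 3757),
               0.01 / (0.01 + 0.0004 * 3757))
  expect_equal(variance_explained(0.1, 0.1, 100), 0.01 / 1.01)
  expect_error(variance_explained(0.1, 0.02, 2), class = "mr_domain_error")
  expect_error(variance_explained(0.1, 0, 100), class = "mr_domain_error")
})

test_that("f_statistic matches the closed form and its F = 10 boundary", {
  expect_equal(f_statistic(0, 1000), 0)
  r2 <- variance_explained(0.1, 0.02, 3757)
  expect_equal(f_statistic(r2, 3757), r2 * 3755 / (1 - r2))
  # boundary: solve r2 * 3755 / (1 - r2) = 10
  r2_b <- 10 / (10 + 3755)
  expect_gt(f_statistic(r2_b + 1e-5, 3757), 10)
  expect_lt(f_statistic(r2_b - 1e-5, 3757), 10)
  expect_error(f_statistic(1, 100), class = "mr_domain_error")
})

test_that("f_statistic is monotone in r2 and in n", {
  r2 <- seq(0.001, 0.5, length.out = 20)
  expect_true(all(diff(f_statistic(r2, 500)) > 0))
  ns <- seq(10, 1e5, length.out = 20)
  expect_true(all(diff(f_statistic(0.01, ns)) > 0))
})

make_ld <- function(ids, r2val = 0, pos = NULL) {
  m <- matrix(r2val, length(ids), length(ids))
  diag(m) <- 1
  ld_matrix(ids, m, positions = pos)
}

test_that("clump drops the dominated member of a pair in LD", {
  rec <- make_records(2)
  rec$pos <- c(1e6, 1.1e6)  # 100 kb apart
  rec$pval <- c(1e-8, 1e-6)
  tab <- association_table(rec)
  ld <- make_ld(rec$snp_id, 0.5)
  params <- selection_params(1e-5, 0.1, 500)
  kept <- clump(tab, ld, params)
  expect_equal(kept$snp_id, "rs001")
})

test_that("clump keeps pairs outside the window even in LD", {
  rec <- make_records(2)
  rec$pos <- c(1e6, 1e6 + 600e3)  # 600 kb apart
  tab <- association_table(rec)
  ld <- make_ld(rec$snp_id, 0.5)
  kept <- clump(tab, ld, selection_params(1e-5, 0.1, 500))
  expect_equal(nrow(kept), 2)
})

test_that("clump keeps everything when all pairwise r2 are zero", {
  rec <- make_records(5)
  rec$pos <- seq(1e6, 1.4e6, by = 1e5)
  tab <- association_table(rec)
  kept <- clump(tab, make_ld(rec$snp_id, 0), selection_params(1e-5, 0.1, 500))
  expect_equal(kept$snp_id, tab$snp_id)
})

test_that("clump output is a maximal independent set under the greedy order", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 12
    rec <- make_records(n)
    rec$pos <- sort(sample.int(2e6, n))
    rec$pval <- runif(n, 1e-9, 1e-6)
    tab <- association_table(rec)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    ld <- ld_matrix(rec$snp_id, m)
    params <- selection_params(1e-5, 0.3, 300)
    kept <- clump(tab, ld, params)
    ki <- match(kept$snp_id, rec$snp_id)
    # no retained pair jointly violates (window, r2)
    for (a in ki) for (b in ki) {
      if (a < b && abs(rec$pos[a] - rec$pos[b]) <= 300e3) {
        expect_lt(m[a, b], 0.3)
      }
    }
    # every removed SNP conflicts with a retained SNP of <= p
    for (r in setdiff(seq_len(n), ki)) {
      conflicts <- vapply(ki, function(k) {
        abs(rec$pos[r] - rec$pos[k]) <= 300e3 && m[r, k] >= 0.3 &&
          rec$pval[k] <= rec$pval[r]
      }, logical(1))
      expect_true(any(conflicts))
    }
  }
})

test_that("select_instruments applies p, LD and F filters in sequence", {
  rec <- make_records(4)
  rec$pos <- c(1e6, 5e6, 9e6, 13e6)
  rec$pval <- c(1e-8, 2e-5, 1e-8, 1e-8)        # rs002 fails p < 1e-5
  rec$beta <- c(0.1, 0.1, 0.012, 0.1)          # rs003 weak: F < 10
  tab <- association_table(rec)
  iv <- suppressWarnings(
    select_instruments(tab, make_ld(rec$snp_id, 0), selection_preset("immune")))
  expect_setequal(iv$snp_id, c("rs001", "rs004"))
  expect_true(all(iv$f_stat >= 10))
  expect_equal(iv$r2_explained, variance_explained(iv$beta, iv$se, iv$n))
})

test_that("select_instruments is invariant to input row order", {
  rec <- make_records(6)
  rec$pval <- c(1e-8, 1e-7, 1e-6, 1e-8, 1e-7, 1e-9)
  rec$pos <- c(1e6, 1.05e6, 3e6, 3.02e6, 8e6, 8.01e6)
  m <- diag(1, 6)
  m[1, 2] <- m[2, 1] <- 0.9
  m[3, 4] <- m[4, 3] <- 0.9
  m[5, 6] <- m[6, 5] <- 0.05
  ld <- ld_matrix(rec$snp_id, m)
  tab1 <- association_table(rec)
  tab2 <- association_table(rec[sample.int(6), ])
  iv1 <- select_instruments(tab1, ld, selection_preset("immune"))
  iv2 <- select_instruments(tab2, ld, selection_preset("immune"))
  expect_setequal(iv1$snp_id, iv2$snp_id)
})

test_that("SNPs absent from the LD matrix are retained with a warning", {
  rec <- make_records(3)
  rec$pos <- c(1e6, 1.01e6, 1.02e6)
  tab <- association_table(rec)
  ld <- make_ld(rec$snp_id[1:2], 0.9)
  expect_warning(kept <- clump(tab, ld, selection_params(1e-5, 0.1, 500)),
                 "absent from the LD matrix")
  expect_true("rs003" %in% kept$snp_id)
})

test_that("presets carry the published thresholds", {
  p1 <- selection_preset("immune")
  expect_equal(c(p1$p_threshold, p1$clump_r2, p1$clump_window_kb, p1$f_min),
               c(1e-5, 0.1, 500, 10))
  p2 <- selection_preset("cytokine_outcome")
  expect_equal(c(p2$p_threshold, p2$clump_r2, p2$clump_window_kb, p2$f_min),
               c(5e-6, 0.001, 10000, 10))
})

test_that("LD matrices round-trip through both file formats", {
  ids <- c("rs001", "rs002", "rs003")
  m <- diag(1, 3)
  m[1, 2] <- m[2, 1] <- 0.4
  ld <- ld_matrix(ids, m)
  # square format
  sq <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(ld$r2), sq, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_ld(sq)$r2, ld$r2)
  # triplet format
  tr <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(snp_a = "rs001", snp_b = "rs002", r2 = 0.4),
                     tr, sep = "\t", quote = FALSE, row.names = FALSE)
  ld2 <- read_ld(tr)
  expect_equal(ld2$r2["rs001", "rs002"], 0.4)
  expect_error(ld_matrix(ids, m - 2), class = "mr_domain_error")
})
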