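test_that("LRT statistic maps to chi-squared(1) tail probabilities", {
  expect_equal(lrt_pvalue(-10, -10), list(stat = 0, pvalue = 1))
  # frozen chi-squared(1) critical values checked via erfc identity
  expect_equal(lrt_pvalue(0, 3.841459 / 2)$pvalue, 0.05, tolerance = 1e-4)
  expect_equal(lrt_pvalue(0, 6.634897 / 2)$pvalue, 0.01, tolerance = 1e-4)
  expect_true(is.na(lrt_pvalue(NaN, 1)$pvalue))
  # tiny negative differences from optimizer tolerance clamp to zero
  expect_equal(lrt_pvalue(-5, -5 - 1e-12)$stat, 0)
})

test_that("BH adjustment follows the step-up rule and preserves missing", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(c(NA, 0.03, NA)), c(NA, 0.03, NA))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (rep in 1:5) {
    p <- runif(50)^2
    got <- adjust_bh(p)
    expect_equal(got, brute_bh(p), tolerance = 1e-12)
    expect_true(all(got >= p))
    expect_true(all(diff(got[order(p)]) >= -1e-12))
  }
})

test_that("TE ratios follow their definition and symmetry", {
  d <- balanced_design(2L)
  norm <- rbind(c(10, 10, 10, 10, 10, 10, 20, 20),
                c(7, 7, 7, 7, 3, 3, 3, 3))
  te <- compute_te(norm, d)
  expect_equal(te$TE_control[1], 1)
  expect_equal(te$TE_treatment[1], 2)
  expect_equal(te$log2FC_TE[1], 1)
  expect_equal(te$log2FC_TE[2], 0)
  zero_rna <- rbind(c(0, 0, 0, 0, 5, 5, 5, 5))
  expect_true(is.na(compute_te(zero_rna, d)$TE_control))
})

test_that("saturated fit ties the interaction coefficient to the TE ratio", {
  d <- balanced_design(3L)
  alt <- build_design(d, "ALT")
  set.seed(12)
  for (rep in 1:5) {
    y <- rnbinom(12, size = 3, mu = 60) + 1
    fit <- fit_coefficients(y, alt, kappa = 0.2)
    te <- compute_te(matrix(y, nrow = 1), d)
    expect_equal(fit$beta[["interaction"]], log(2) * te$log2FC_TE,
                 tolerance = 1e-6)
  }
})

test_that("swapping condition labels negates effects and keeps p-values", {
  run <- sim_joined(n_genes = 80L, reps = 3L, seed = 13L)
  joined <- run$joined
  res <- suppressWarnings(run_pipeline(joined))
  flipped <- joined
  flipped$design$condition <- 1L - flipped$design$condition
  res2 <- suppressWarnings(run_pipeline(flipped))
  ok <- !is.na(res$pval) & !is.na(res2$pval)
  expect_gt(sum(ok), 70)
  expect_equal(res2$pval[ok], res$pval[ok], tolerance = 1e-6)
  okf <- !is.na(res$log2FC_TE) & !is.na(res2$log2FC_TE)
  expect_equal(res2$log2FC_TE[okf], -res$log2FC_TE[okf], tolerance = 1e-9)
})

test_that("exchangeable conditions yield no significant genes", {
  set.seed(14)
  r <- 2L
  block_rna <- matrix(rnbinom(60 * r, size = 1 / 0.2, mu = 40), ncol = r)
  block_rf <- matrix(rnbinom(60 * r, size = 1 / 0.3, mu = 25), ncol = r)
  m <- cbind(block_rna, block_rna, block_rf, block_rf)  # treatment == control
  j <- joined_from_matrix(m, r = r)
  res <- suppressWarnings(run_pipeline(j, fdr = 0.9))
  expect_true(all(res$lrt_stat < 1e-6, na.rm = TRUE))
  expect_true(all(res$padj > 0.9999, na.rm = TRUE))
  expect_equal(unname(attr(res, "n_signif")), c(0L, 0L))
})

test_that("pipeline output is deterministic and round-trips through TSV", {
  run <- sim_joined(n_genes = 60L, reps = 3L, seed = 15L)
  res1 <- suppressWarnings(run_pipeline(run$joined))
  res2 <- suppressWarnings(run_pipeline(run$joined))
  expect_identical(as.data.frame(res1), as.data.frame(res2))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_te_test(res1, f1)
  write_te_test(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
  header <- readLines(f1, n = 1L)
  expect_match(header, "^# size_factor ")
  tab <- read.delim(f1, comment.char = "#")
  expect_equal(nrow(tab), 60L)
  expect_identical(tab$geneID, run$joined$gene_ids)
})

test_that("degenerate genes get missing p-values without inflating the correction", {
  run <- sim_joined(n_genes = 40L, reps = 3L, seed = 16L)
  joined <- run$joined
  joined$counts[3, ] <- 0
  joined$counts[7, joined$design$protocol == "RIBO"] <- 0
  is_rna <- joined$design$protocol == "RNASEQ"
  joined$testable <- rowSums(joined$counts[, is_rna]) > 0 &
    rowSums(joined$counts[, !is_rna]) > 0
  joined$zero_protocol <- (rowSums(joined$counts[, is_rna]) == 0) !=
    (rowSums(joined$counts[, !is_rna]) == 0)
  res <- suppressWarnings(run_pipeline(joined))
  expect_true(is.na(res$pval[3]) && is.na(res$padj[3]))
  expect_true(is.na(res$pval[7]))
  expect_equal(res$flags[3], "untestable")
  expect_equal(res$flags[7], "untestable")
  tested <- !is.na(res$pval)
  expect_equal(res$padj[tested], adjust_bh(res$pval)[tested])
})

test_that("type-I error is near nominal once replication is adequate", {
  run <- sim_joined(n_genes = 300L, reps = 8L, kappa_rna = 0.05, kappa_rf = 0.2,
                    fraction_affected = 0, seed = 3L)
  res <- suppressWarnings(run_pipeline(run$joined))
  frac <- mean(res$pval < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})
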