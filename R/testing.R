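#' Likelihood-ratio test p-value against chi-squared(1)
#'
#' The alternative model has exactly one parameter more than the null
#' (the translation-efficiency interaction), so the LRT statistic is
#' referred to a chi-squared distribution with 1 degree of freedom.
#'
#' @param loglik_null Maximized null log-likelihood.
#' @param loglik_alt Maximized alternative log-likelihood.
#' @return List with `stat` and `pvalue` (`NA` if a log-likelihood is
#'   not finite).
#' @export
lrt_pvalue <- function(loglik_null, loglik_alt) {
  if (!is.finite(loglik_null) || !is.finite(loglik_alt)) {
    return(list(stat = NA_real_, pvalue = NA_real_))
  }
  stat <- 2 * max(0, loglik_alt - loglik_null)
  list(stat = stat, pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment with missing values
#'
#' Step-up FDR adjustment over the non-missing p-values, with the
#' number of tests equal to the count of non-missing entries (genes
#' excluded from testing do not inflate the correction). Missing stays
#' missing.
#'
#' @param pvalues Vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  if (any(ok)) {
    out[ok] <- stats::p.adjust(pvalues[ok], method = "BH", n = sum(ok))
  }
  out
}

#' Per-gene translation efficiency and its fold change
#'
#' TE in a condition is the ratio of the mean normalized footprint
#' count to the mean normalized RNA-Seq count over that condition's
#' libraries. The reported effect is log2(TE_treatment / TE_control);
#' it is missing whenever a denominator mean is zero or a TE is zero.
#'
#' @param norm Matrix of normalized counts (genes x all libraries).
#' @param design `experiment_design` aligned to the columns.
#' @return data.frame with `TE_control`, `TE_treatment`,
#'   `log2FC_TE`.
#' @export
compute_te <- function(norm, design) {
  stopifnot(ncol(norm) == nrow(design))
  grp_mean <- function(prot, cond) {
    idx <- design$protocol == prot & design$condition == cond
    rowMeans(norm[, idx, drop = FALSE])
  }
  te <- function(cond) {
    num <- grp_mean("RIBO", cond)
    den <- grp_mean("RNASEQ", cond)
    ifelse(den > 0, num / den, NA_real_)
  }
  te0 <- te(0L)
  te1 <- te(1L)
  lfc <- ifelse(!is.na(te0) & !is.na(te1) & te0 > 0 & te1 > 0,
                log2(te1 / te0), NA_real_)
  data.frame(TE_control = te0, TE_treatment = te1, log2FC_TE = lfc)
}

# Fit one gene end to end given shrunken per-library dispersions:
# refit ALT and NULL at fixed dispersion; repair any nesting violation
# by restarting ALT from the null solution.
.fit_gene_lrt <- function(y, spec_alt, spec_null, offsets, kappa_sample,
                          init_alt = NULL) {
  fa <- fit_coefficients(y, spec_alt, offsets, kappa_sample, init = init_alt)
  f0 <- fit_coefficients(y, spec_null, offsets, kappa_sample)
  if (fa$loglik < f0$loglik - 1e-9) {
    fa2 <- fit_coefficients(y, spec_alt, offsets, kappa_sample,
                            init = c(f0$beta, 0))
    if (fa2$loglik > fa$loglik) fa <- fa2
  }
  list(alt = fa, null = f0)
}

#' Run the differential translation-efficiency pipeline
#'
#' For every testable gene: alternating NB GLM fit under the
#' alternative (interaction) model to obtain raw dispersions; a
#' genome-wide mean-dispersion trend and empirical Bayes shrinkage
#' (run once per protocol in `SEPARATE` mode, once overall in `JOINT`
#' mode); a refit of the alternative and null models with the shrunken
#' dispersions held fixed; a likelihood-ratio test against
#' chi-squared(1); Benjamini-Hochberg correction; and translation
#' efficiency estimates from normalized counts.
#'
#' @param joined A `joined_dataset` from [join_datasets()].
#' @param mode Dispersion mode, `"SEPARATE"` (default) or `"JOINT"`.
#' @param fdr FDR threshold used to report the significant set.
#' @param kappa_bounds Dispersion search interval.
#' @return A `te_test` data.frame, one row per gene in input order,
#'   with attributes `size_factors`, `trend` (per-tag lambda),
#'   `prior_sd`, `mode`, `fdr` and `n_signif` (up/down counts at the
#'   threshold).
#' @export
run_pipeline <- function(joined, mode = c("SEPARATE", "JOINT"), fdr = 0.05,
                         kappa_bounds = c(1e-6, 10)) {
  mode <- match.arg(mode)
  stopifnot(inherits(joined, "joined_dataset"))
  if (!is.numeric(fdr) || length(fdr) != 1L || fdr <= 0 || fdr >= 1) {
    stop("fdr must lie strictly between 0 and 1")
  }
  counts <- joined$counts
  design <- joined$design
  G <- nrow(counts)
  sf <- size_factors(counts, design)
  offsets <- log(sf)
  norm <- normalized_counts(counts, sf)
  spec_alt <- build_design(design, "ALT")
  spec_null <- build_design(design, "NULL")
  prot <- as.character(design$protocol)
  tags <- if (mode == "JOINT") "ALL" else c("RNASEQ", "RIBO")
  tag_idx <- if (mode == "JOINT") list(ALL = seq_len(ncol(counts))) else
    split(seq_len(ncol(counts)), factor(prot, levels = tags))

  testable <- which(joined$testable)
  raw_k <- matrix(NA_real_, G, length(tags), dimnames = list(NULL, tags))
  bound_k <- matrix(FALSE, G, length(tags), dimnames = list(NULL, tags))
  alt_beta <- vector("list", G)
  mu_store <- vector("list", G)
  for (i in testable) {
    af <- alternating_fit(counts[i, ], spec_alt, offsets, prot, mode,
                          bounds = kappa_bounds)
    raw_k[i, ] <- af$kappa[tags]
    bound_k[i, ] <- af$at_boundary[tags]
    alt_beta[[i]] <- af$fit$beta
    mu_store[[i]] <- af$fit$mu_hat
  }

  # genome-wide trend + prior width per tag, then MAP shrinkage
  shr_k <- raw_k
  trends <- list()
  prior_sds <- stats::setNames(numeric(length(tags)), tags)
  for (tg in tags) {
    idx <- tag_idx[[tg]]
    abscissa <- rowMeans(norm[, idx, drop = FALSE])
    usable <- !is.na(raw_k[, tg]) & !bound_k[, tg]
    lam <- fit_trend(abscissa[usable], raw_k[usable, tg])
    trends[[tg]] <- lam
    tk <- trend_dispersion(abscissa, lam, kappa_bounds)
    prior_sds[tg] <- estimate_prior_sd(raw_k[usable, tg], tk[usable])
    for (i in testable) {
      shr_k[i, tg] <- shrink_dispersion(raw_k[i, tg], tk[i], prior_sds[tg],
                                        counts[i, idx], mu_store[[i]][idx],
                                        kappa_bounds)
    }
  }

  # final fits with frozen shrunken dispersions, shared by both models
  lrt_stat <- pvalue <- ll0 <- ll1 <- beta_int <- rep(NA_real_, G)
  conv <- rep(NA, G)
  kappa_sample <- numeric(ncol(counts))
  for (i in testable) {
    for (tg in tags) kappa_sample[tag_idx[[tg]]] <- shr_k[i, tg]
    fits <- .fit_gene_lrt(counts[i, ], spec_alt, spec_null, offsets,
                          kappa_sample, init_alt = alt_beta[[i]])
    ll1[i] <- fits$alt$loglik
    ll0[i] <- fits$null$loglik
    beta_int[i] <- fits$alt$beta[["interaction"]]
    conv[i] <- fits$alt$converged && fits$null$converged
    lr <- lrt_pvalue(ll0[i], ll1[i])
    lrt_stat[i] <- lr$stat
    pvalue[i] <- lr$pvalue
  }
  padj <- adjust_bh(pvalue)
  te <- compute_te(norm, design)

  flags <- ifelse(!joined$testable, "untestable",
                  ifelse(joined$zero_protocol, "zero_protocol",
                         ifelse(!is.na(conv) & !conv, "no_convergence", "ok")))
  res <- data.frame(
    geneID = joined$gene_ids,
    loglik_null = ll0, loglik_alt = ll1,
    lrt_stat = lrt_stat, pval = pvalue, padj = padj,
    TE_control = te$TE_control, TE_treatment = te$TE_treatment,
    log2FC_TE = te$log2FC_TE,
    interaction_coef = beta_int,
    flags = flags,
    stringsAsFactors = FALSE)
  if (mode == "SEPARATE") {
    res$raw_dispersion_rna <- raw_k[, "RNASEQ"]
    res$shrunken_dispersion_rna <- shr_k[, "RNASEQ"]
    res$raw_dispersion_rf <- raw_k[, "RIBO"]
    res$shrunken_dispersion_rf <- shr_k[, "RIBO"]
  } else {
    res$raw_dispersion <- raw_k[, "ALL"]
    res$shrunken_dispersion <- shr_k[, "ALL"]
  }
  sig <- !is.na(res$padj) & res$padj <= fdr & !is.na(res$log2FC_TE)
  attr(res, "size_factors") <- sf
  attr(res, "trend") <- trends
  attr(res, "prior_sd") <- prior_sds
  attr(res, "mode") <- mode
  attr(res, "fdr") <- fdr
  attr(res, "n_signif") <- c(up = sum(sig & res$log2FC_TE > 0),
                             down = sum(sig & res$log2FC_TE < 0))
  class(res) <- c("te_test", "data.frame")
  res
}

#' Write a pipeline result table
#'
#' Tab-separated output, one row per gene in input order, missing
#' encoded as `NA`; size factors are recorded as `# size_factor`
#' comment lines in a header block.
#'
#' @param res A `te_test` result from [run_pipeline()].
#' @param path Output path.
#' @export
write_te_test <- function(res, path) {
  sf <- attr(res, "size_factors")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in names(sf)) {
    writeLines(sprintf("# size_factor %s %.10g", s, sf[[s]]), con)
  }
  df <- as.data.frame(res)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, signif(x, 10)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
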