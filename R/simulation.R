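#' Simulation configuration
#'
#' Defines the generative model for paired RNA-Seq / ribosome-footprint
#' count data with known truth. Per gene a baseline abundance mu is
#' drawn log-normally; the RNA-Seq mean is mu in both conditions
#' (optionally perturbed via `rna_log_fc` to emulate transcriptional
#' confounding), and the footprint mean is mu * te_base, multiplied in
#' the treatment condition by the gene's TE fold change. Counts are NB
#' draws with a protocol-specific dispersion — either a scalar or trend
#' coefficients `c(lambda0, lambda1)` giving kappa = lambda1/mu +
#' lambda0 — and each library's mean is scaled by its depth multiplier.
#'
#' Defaults emulate the regime where the footprint libraries are far
#' noisier than the RNA-Seq libraries (dispersion ratio 50), with 10%
#' of genes carrying a 4-fold TE change.
#'
#' @param n_genes Number of genes.
#' @param reps Replicates per (protocol, condition) group.
#' @param mean_log,sd_log Log-normal parameters of the baseline mean.
#' @param kappa_rna,kappa_rf Dispersion per protocol: scalar, or length-2
#'   `c(lambda0, lambda1)` for a mean-dependent trend.
#' @param fraction_affected Fraction of genes with a true TE change.
#' @param effect_log_fc Magnitude of the true TE change, natural log.
#' @param effect_sign `"both"` (random sign), `"up"` or `"down"`.
#' @param te_base Baseline TE relating footprint to RNA-Seq means.
#' @param rna_log_fc Natural-log transcriptional change applied to
#'   affected genes in treatment (default 0: translation-only signal).
#' @param libsize_log_range Library-depth multipliers are drawn
#'   log-uniformly from this natural-log interval.
#' @param seed Integer seed driving every random draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, reps = 3L,
                       mean_log = log(100), sd_log = 1.5,
                       kappa_rna = 0.01, kappa_rf = 0.5,
                       fraction_affected = 0.1,
                       effect_log_fc = log(4),
                       effect_sign = c("both", "up", "down"),
                       te_base = 1, rna_log_fc = 0,
                       libsize_log_range = c(log(0.5), log(2)),
                       seed = 1L) {
  effect_sign <- match.arg(effect_sign)
  stopifnot(n_genes >= 1L, reps >= 1L,
            fraction_affected >= 0, fraction_affected <= 1,
            all(kappa_rna >= 0), all(kappa_rf >= 0), te_base > 0)
  structure(list(n_genes = as.integer(n_genes), reps = as.integer(reps),
                 mean_log = mean_log, sd_log = sd_log,
                 kappa_rna = kappa_rna, kappa_rf = kappa_rf,
                 fraction_affected = fraction_affected,
                 effect_log_fc = effect_log_fc, effect_sign = effect_sign,
                 te_base = te_base, rna_log_fc = rna_log_fc,
                 libsize_log_range = libsize_log_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.sim_kappa <- function(spec_kappa, mu) {
  if (length(spec_kappa) == 2L) {
    pmax(spec_kappa[1L] + spec_kappa[2L] / mu, 0)
  } else {
    rep_len(spec_kappa, length(mu))
  }
}

.rnb <- function(n, mu, kappa) {
  out <- numeric(n)
  pois <- kappa < 1e-12
  if (any(pois)) out[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    out[!pois] <- stats::rnbinom(sum(!pois), size = 1 / kappa[!pois],
                                 mu = mu[!pois])
  }
  out
}

#' Simulate a paired RNA-Seq / footprint dataset with known truth
#'
#' @param cfg A `sim_config`.
#' @return List with `rna` and `ribo` (`count_table`s), `design`
#'   (`experiment_design`) and `truth` (data.frame with `gene_id`,
#'   `affected`, `true_log_te_fc`, `true_baseline_mean`, per-protocol
#'   true dispersions).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  r <- cfg$reps
  gene_ids <- sprintf("gene_%05d", seq_len(G))

  base_mu <- stats::rlnorm(G, cfg$mean_log, cfg$sd_log)
  n_aff <- round(cfg$fraction_affected * G)
  affected <- rep(FALSE, G)
  if (n_aff > 0L) affected[sample.int(G, n_aff)] <- TRUE
  sgn <- switch(cfg$effect_sign,
                both = sample(c(-1, 1), G, replace = TRUE),
                up = rep(1, G), down = rep(-1, G))
  beta_delta <- ifelse(affected, sgn * cfg$effect_log_fc, 0)
  rna_delta <- ifelse(affected, cfg$rna_log_fc, 0)

  samp <- function(prefix) paste0(prefix, "_", seq_len(r))
  design <- experiment_design(
    sample_id = c(samp("rna_ctl"), samp("rna_trt"), samp("rf_ctl"), samp("rf_trt")),
    protocol = rep(c("RNA", "RNA", "RF", "RF"), each = r),
    condition = rep(c("control", "treatment", "control", "treatment"), each = r))
  libsize <- exp(stats::runif(nrow(design), cfg$libsize_log_range[1L],
                              cfg$libsize_log_range[2L]))
  names(libsize) <- design$sample_id

  mu_rna <- cbind(ctl = base_mu, trt = base_mu * exp(rna_delta))
  mu_rf <- cbind(ctl = base_mu * cfg$te_base,
                 trt = base_mu * cfg$te_base * exp(rna_delta + beta_delta))
  k_rna <- .sim_kappa(cfg$kappa_rna, base_mu)
  k_rf <- .sim_kappa(cfg$kappa_rf, base_mu)

  draw_block <- function(mu_cond, kappa) {
    m <- matrix(0, G, 2L * r)
    for (j in seq_len(2L * r)) {
      cond <- if (j <= r) "ctl" else "trt"
      m[, j] <- .rnb(G, mu_cond[, cond], kappa)
    }
    m
  }
  rna_m <- draw_block(mu_rna, k_rna)
  rf_m <- draw_block(mu_rf, k_rf)
  rna_ids <- design$sample_id[design$protocol == "RNASEQ"]
  rf_ids <- design$sample_id[design$protocol == "RIBO"]
  rna_m <- sweep(rna_m, 2L, libsize[rna_ids], "*")
  rf_m <- sweep(rf_m, 2L, libsize[rf_ids], "*")
  # depth multipliers scale the expected counts; realised counts stay integral
  rna_m <- round(rna_m)
  rf_m <- round(rf_m)

  list(
    rna = count_table(gene_ids, rna_ids, rna_m),
    ribo = count_table(gene_ids, rf_ids, rf_m),
    design = design,
    truth = data.frame(gene_id = gene_ids, affected = affected,
                       true_log_te_fc = beta_delta,
                       true_baseline_mean = base_mu,
                       true_kappa_rna = k_rna, true_kappa_rf = k_rf,
                       stringsAsFactors = FALSE),
    libsize = libsize
  )
}

#' ROC curve and AUC for a gene ranking against simulation truth
#'
#' Sweeps thresholds over the unique score values (ties grouped) with
#' higher scores ranked as stronger evidence of a TE change; for
#' p-values pass e.g. `1 - p` or `-log(p)`. Missing scores rank last.
#'
#' @param scores Per-gene scores, higher = more significant.
#' @param labels Logical (or 0/1) truth flags, aligned to `scores`.
#' @return List with `fpr`, `tpr` (threshold sweep, ties grouped,
#'   starting at (0, 0)) and trapezoid `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(labels)))
  if (!any(labels) || all(labels)) {
    stop("ROC needs at least one affected and one unaffected gene")
  }
  scores[is.na(scores)] <- -Inf
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  lab <- labels[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tpr <- c(0, tp[last_of_tie] / sum(labels))
  fpr <- c(0, fp[last_of_tie] / sum(!labels))
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Z-score baseline for differential translation efficiency
#'
#' The classical fold-change approach: per gene the log TE difference
#' between treatment and control, standardized against genes of
#' comparable expression. Genes are grouped into equal-occupancy bins
#' by mean normalized RNA-Seq count; within each bin z = (d - mean(d))
#' / sd(d), with a two-sided normal p-value. `bins = 1` gives the
#' unbinned variant, whose inflated scores for low-count genes this
#' package's GLM test is designed to avoid.
#'
#' @param joined A `joined_dataset`.
#' @param bins Number of equal-occupancy expression bins (default 20).
#' @return data.frame with `geneID`, `log_te_diff`, `z`, `pval`,
#'   `bin`.
#' @export
zscore_baseline <- function(joined, bins = 20L) {
  stopifnot(inherits(joined, "joined_dataset"), bins >= 1L)
  sf <- size_factors(joined$counts, joined$design)
  norm <- normalized_counts(joined$counts, sf)
  design <- joined$design
  grp <- function(prot, cond) {
    rowMeans(norm[, design$protocol == prot & design$condition == cond,
                  drop = FALSE])
  }
  lte <- function(cond) {
    num <- grp("RIBO", cond)
    den <- grp("RNASEQ", cond)
    ifelse(num > 0 & den > 0, log(num / den), NA_real_)
  }
  d <- lte(1L) - lte(0L)
  expr <- rowMeans(norm[, design$protocol == "RNASEQ", drop = FALSE])

  G <- length(d)
  bins <- min(as.integer(bins), max(1L, floor(sum(!is.na(d)) / 2L)))
  bin <- rep(NA_integer_, G)
  ok <- !is.na(d)
  # equal-occupancy binning on the rank of expression
  bin[ok] <- if (bins == 1L) 1L else {
    as.integer(cut(rank(expr[ok], ties.method = "first"),
                   breaks = bins, labels = FALSE, include.lowest = TRUE))
  }
  z <- rep(NA_real_, G)
  for (b in sort(unique(bin[ok]))) {
    mem <- which(!is.na(bin) & bin == b)
    idx <- mem
    bb <- b
    while (length(idx) < 2L && bb < bins) {  # merge undersized bin rightwards
      bb <- bb + 1L
      idx <- c(idx, which(!is.na(bin) & bin == bb))
    }
    s <- stats::sd(d[idx])
    if (!is.finite(s) || s == 0) next
    z[mem] <- (d[mem] - mean(d[idx])) / s
  }
  data.frame(geneID = joined$gene_ids, log_te_diff = d, z = z,
             pval = 2 * stats::pnorm(-abs(z)), bin = bin,
             stringsAsFactors = FALSE)
}
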