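#' Fit the mean-dispersion trend f(mu) = lambda1 / mu + lambda0
#'
#' Regresses gene-wise raw dispersions on the reciprocal of the mean
#' normalized count by least squares on the basis (1, 1/mean). The fit
#' is repeated twice after discarding genes whose raw/fitted dispersion
#' ratio falls outside [0.1, 10], which robustifies the trend against
#' the heavy right tail of dispersion MLEs. Negative coefficient
#' estimates are clipped to zero with a warning.
#'
#' @param means Positive vector of per-gene mean normalized counts.
#' @param raw_kappas Positive vector of gene-wise dispersion MLEs
#'   (boundary estimates should be excluded by the caller).
#' @return Named numeric `c(lambda0, lambda1)`.
#' @export
fit_trend <- function(means, raw_kappas) {
  keep <- is.finite(means) & is.finite(raw_kappas) & means > 0 & raw_kappas > 0
  means <- means[keep]
  raw_kappas <- raw_kappas[keep]
  if (length(means) < 10L) {
    stop("fewer than 10 usable genes for the mean-dispersion trend; ",
         "consider joint dispersion mode or more replicates")
  }
  use <- rep(TRUE, length(means))
  lam <- c(0, 0)
  clipped <- FALSE
  for (pass in 1:3) {
    B <- cbind(1, 1 / means[use])
    lam <- drop(qr.solve(qr(B), raw_kappas[use]))
    if (any(lam < 0)) {
      # refit the single-term model when one coefficient goes negative
      if (lam[1L] < 0 && lam[2L] < 0) {
        lam <- c(0, 0)
      } else if (lam[1L] < 0) {
        lam <- c(0, sum(raw_kappas[use] / means[use]) / sum(1 / means[use]^2))
      } else {
        lam <- c(mean(raw_kappas[use]), 0)
      }
      lam <- pmax(lam, 0)
      clipped <- TRUE
    }
    if (pass == 3L) break
    fitted <- lam[1L] + lam[2L] / means
    ratio <- raw_kappas / pmax(fitted, 1e-12)
    use <- ratio >= 0.1 & ratio <= 10
    if (sum(use) < 10L) {
      use <- rep(TRUE, length(means))
      break
    }
  }
  if (clipped) warning("negative trend coefficient clipped to 0")
  stats::setNames(lam, c("lambda0", "lambda1"))
}

#' Evaluate the mean-dispersion trend
#'
#' @param means Positive vector of mean normalized counts.
#' @param lambda Named trend coefficients from [fit_trend()].
#' @param bounds Dispersion bounds the value is clipped into.
#' @return Trend dispersion per gene.
#' @export
trend_dispersion <- function(means, lambda, bounds = c(1e-6, 10)) {
  pmin(pmax(lambda[["lambda0"]] + lambda[["lambda1"]] / means, bounds[1L]),
       bounds[2L])
}

#' Width of the log-normal dispersion prior
#'
#' Estimated as the median absolute deviation (scaled for normal
#' consistency) of log(raw / trend) over non-boundary genes, floored at
#' 0.25 so that clean data cannot collapse the prior and over-shrink.
#'
#' @param raw_kappas Gene-wise raw dispersions.
#' @param trend_kappas Trend values at the same genes.
#' @param floor Lower bound on the returned width.
#' @return Positive scalar prior standard deviation (log scale).
#' @export
estimate_prior_sd <- function(raw_kappas, trend_kappas, floor = 0.25) {
  keep <- is.finite(raw_kappas) & is.finite(trend_kappas) &
    raw_kappas > 0 & trend_kappas > 0
  if (sum(keep) < 10L) stop("fewer than 10 usable genes for prior width estimation")
  resid <- log(raw_kappas[keep] / trend_kappas[keep])
  max(floor, stats::mad(resid, center = stats::median(resid)))
}

#' Empirical Bayes shrinkage of one gene's dispersion
#'
#' Maximum a posteriori estimate of the dispersion under a log-normal
#' prior centred at the trend value: maximizes the NB log-likelihood at
#' the gene's fitted means plus the log-prior density over log-kappa,
#' by bounded 1-D optimization. The estimate always lies between the
#' raw MLE and the trend on the log scale.
#'
#' @param raw_kappa Gene-wise dispersion MLE.
#' @param trend_kappa Trend dispersion at the gene's mean count.
#' @param prior_sd Prior standard deviation on the log scale.
#' @param y Count vector (the libraries the dispersion applies to).
#' @param mu_hat Fitted means for those libraries.
#' @param bounds Dispersion search interval.
#' @return Shrunken dispersion (scalar).
#' @export
shrink_dispersion <- function(raw_kappa, trend_kappa, prior_sd, y, mu_hat,
                              bounds = c(1e-6, 10)) {
  stopifnot(raw_kappa > 0, trend_kappa > 0, prior_sd > 0)
  lmu0 <- log(trend_kappa)
  obj <- function(lk) {
    nb_log_likelihood(y, mu_hat, exp(lk)) - (lk - lmu0)^2 / (2 * prior_sd^2)
  }
  lb <- log(bounds)
  opt <- stats::optimize(obj, interval = lb, maximum = TRUE, tol = 1e-7)
  cand <- c(opt$maximum, lb[1L], lb[2L])
  best <- cand[which.max(c(opt$objective, obj(lb[1L]), obj(lb[2L])))]
  # MAP of a unimodal posterior lies between prior mode and MLE;
  # clamp guards the invariant against optimizer tolerance.
  lo <- min(log(raw_kappa), lmu0)
  hi <- max(log(raw_kappa), lmu0)
  exp(min(max(best, lo), hi))
}
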