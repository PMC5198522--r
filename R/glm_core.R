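#' Negative binomial log-likelihood
#'
#' Log-likelihood of counts `y` under independent NB distributions with
#' means `mu` and dispersions `kappa`, in the mean-dispersion
#' parameterisation Var(y) = mu + kappa * mu^2. `kappa = 0` is the
#' Poisson limit and is evaluated with the Poisson pmf.
#'
#' @param y Non-negative integer count vector.
#' @param mu Positive vector of expected counts (recycled if scalar).
#' @param kappa Non-negative dispersion, scalar or per-sample vector.
#' @return Scalar log-likelihood.
#' @export
nb_log_likelihood <- function(y, mu, kappa) {
  n <- length(y)
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  if (any(kappa < 0)) stop("kappa must be non-negative")
  if (any(mu <= 0)) stop("mu must be positive")
  ll <- numeric(n)
  pois <- kappa == 0
  if (any(pois)) ll[pois] <- stats::dpois(y[pois], mu[pois], log = TRUE)
  if (any(!pois)) {
    ll[!pois] <- stats::dnbinom(y[!pois], size = 1 / kappa[!pois],
                                mu = mu[!pois], log = TRUE)
  }
  sum(ll)
}

#' Build the GLM design matrix
#'
#' The alternative model has one column per effect: intercept, protocol
#' (footprint vs RNA-Seq), condition (treatment vs control) and their
#' interaction; it is saturated over the four (protocol, condition)
#' groups. The null model drops the interaction column, i.e. it forbids
#' any treatment effect specific to the footprint libraries — exactly a
#' zero treatment effect on translation efficiency. The interaction
#' coefficient is the log fold change of translation efficiency.
#'
#' @param design An `experiment_design`.
#' @param kind `"ALT"` (4 columns) or `"NULL"` (3 columns).
#' @return A `model_spec`: list with `kind`, design matrix `X` and
#'   column `labels`.
#' @export
build_design <- function(design, kind = c("ALT", "NULL")) {
  kind <- match.arg(kind)
  stopifnot(inherits(design, "experiment_design"))
  rf <- as.numeric(design$protocol == "RIBO")
  trt <- as.numeric(design$condition == 1L)
  if (length(unique(rf)) < 2L) stop("design has a single protocol; interaction undefined")
  if (length(unique(trt)) < 2L) stop("design has a single condition; interaction undefined")
  X <- cbind(intercept = 1, protocolRF = rf, conditionT = trt)
  if (kind == "ALT") X <- cbind(X, interaction = rf * trt)
  structure(list(kind = kind, X = X, labels = colnames(X)), class = "model_spec")
}

# Log-likelihood at a coefficient vector, with a floor on fitted means
# so an all-zero group cannot drive the objective to -Inf.
.mu_from_beta <- function(X, beta, offsets) {
  pmax(exp(pmin(offsets + drop(X %*% beta), 700)), 1e-8)
}

#' Fit GLM coefficients at fixed dispersion
#'
#' Maximizes the NB log-likelihood over the coefficients of a log-link
#' GLM by iteratively reweighted least squares with step halving, which
#' keeps the log-likelihood non-decreasing. Falls back to Nelder-Mead
#' if the weighted normal equations are numerically singular.
#'
#' @param y Count vector (one gene, all libraries).
#' @param spec A `model_spec` from [build_design()].
#' @param offsets Per-library log offsets (log size factors); defaults
#'   to zero.
#' @param kappa Per-library dispersion vector (or scalar), held fixed.
#' @param init Optional starting coefficients; default is least squares
#'   on log(normalized count + 0.5).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Iteration cap.
#' @return A `gene_fit`: list with `beta`, `mu_hat`, `loglik`,
#'   `converged`, `iterations`.
#' @export
fit_coefficients <- function(y, spec, offsets = NULL, kappa = 0,
                             init = NULL, tol = 1e-10, max_iter = 100L) {
  X <- if (inherits(spec, "model_spec")) spec$X else spec
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (is.null(offsets)) offsets <- numeric(n)
  kappa <- rep_len(kappa, n)
  if (sum(y) <= 0) stop("fit_coefficients requires at least one positive count")

  beta <- if (is.null(init)) {
    q <- log(y / exp(offsets) + 0.5)
    drop(qr.solve(qr(X), q))
  } else rep_len(init, ncol(X))

  mu <- .mu_from_beta(X, beta, offsets)
  ll <- nb_log_likelihood(y, mu, kappa)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- mu / (1 + kappa * mu)
    z <- (log(mu) - offsets) + (y - mu) / mu
    beta_new <- tryCatch({
      xw <- X * w
      drop(solve(crossprod(xw, X), crossprod(xw, z)))
    }, error = function(e) NULL)
    if (is.null(beta_new)) {
      opt <- stats::optim(beta, function(b)
        -nb_log_likelihood(y, .mu_from_beta(X, b, offsets), kappa),
        method = "Nelder-Mead", control = list(maxit = 500))
      beta_new <- opt$par
    }
    beta_new <- pmin(pmax(beta_new, -50), 50)
    step <- beta_new - beta
    ll_new <- nb_log_likelihood(y, .mu_from_beta(X, beta_new, offsets), kappa)
    halvings <- 0L
    while (ll_new < ll && halvings < 30L) {
      step <- step / 2
      beta_new <- beta + step
      ll_new <- nb_log_likelihood(y, .mu_from_beta(X, beta_new, offsets), kappa)
      halvings <- halvings + 1L
    }
    if (ll_new < ll) break
    delta <- ll_new - ll
    beta <- beta_new
    ll <- ll_new
    mu <- .mu_from_beta(X, beta, offsets)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(beta = stats::setNames(beta, colnames(X)), mu_hat = mu,
                 loglik = ll, converged = converged, iterations = iter),
            class = "gene_fit")
}

#' Gene-wise dispersion maximum likelihood estimate
#'
#' Bounded 1-D maximization of the NB log-likelihood over a dispersion
#' shared by the given libraries, at fixed fitted means. The search is
#' on the log scale over `bounds`.
#'
#' @param y Count vector.
#' @param mu_hat Fitted means from the current coefficient fit.
#' @param bounds Dispersion search interval, default `c(1e-6, 10)`.
#' @return List with `kappa` and logical `at_boundary`.
#' @export
dispersion_mle <- function(y, mu_hat, bounds = c(1e-6, 10)) {
  f <- function(lk) nb_log_likelihood(y, mu_hat, exp(lk))
  lb <- log(bounds)
  opt <- stats::optimize(f, interval = lb, maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, lb[1L], lb[2L])
  vals <- c(opt$objective, f(lb[1L]), f(lb[2L]))
  best <- cand[which.max(vals)]
  kappa <- exp(best)
  # optimize() resolves endpoints only to ~1e-4 on this scale
  at_boundary <- best <= lb[1L] + 1e-3 || best >= lb[2L] - 1e-3
  if (at_boundary) kappa <- bounds[which.min(abs(log(bounds) - best))]
  list(kappa = kappa, at_boundary = at_boundary)
}

# Method-of-moments dispersion start, pooled over the given libraries.
.kappa_mom <- function(q, bounds = c(1e-6, 10)) {
  m <- mean(q)
  if (m <= 0 || length(q) < 2L) return(bounds[1L])
  v <- stats::var(q)
  min(max((v - m) / m^2, bounds[1L]), bounds[2L])
}

#' Alternating coefficient / dispersion fit for one gene
#'
#' Iterates coefficient maximization at fixed dispersion and dispersion
#' maximization at fixed coefficients until the joint log-likelihood
#' stabilises. In `SEPARATE` mode the RNA-Seq and footprint libraries
#' each get their own dispersion (the mean model stays shared); in
#' `JOINT` mode a single dispersion is common to all libraries.
#'
#' @param y Count vector for one gene over all libraries.
#' @param spec A `model_spec`.
#' @param offsets Per-library log offsets.
#' @param protocol Factor/character of per-library protocol
#'   (`RNASEQ`/`RIBO`); required for `SEPARATE` mode.
#' @param mode `"SEPARATE"` or `"JOINT"`.
#' @param bounds Dispersion bounds.
#' @param outer_tol Convergence tolerance on the joint log-likelihood.
#' @param max_outer Cap on alternating iterations.
#' @return List with `fit` (a `gene_fit`), `kappa` (named per-group
#'   dispersions), `kappa_sample` (per-library expansion), and
#'   `at_boundary` flags.
#' @export
alternating_fit <- function(y, spec, offsets = NULL, protocol = NULL,
                            mode = c("SEPARATE", "JOINT"),
                            bounds = c(1e-6, 10),
                            outer_tol = 1e-6, max_outer = 50L) {
  mode <- match.arg(mode)
  n <- length(y)
  if (is.null(offsets)) offsets <- numeric(n)
  groups <- if (mode == "JOINT") {
    list(ALL = seq_len(n))
  } else {
    if (is.null(protocol)) stop("SEPARATE mode needs the per-library protocol")
    protocol <- as.character(protocol)
    split(seq_len(n), factor(protocol, levels = c("RNASEQ", "RIBO")))
  }

  q <- y / exp(offsets)
  kap <- vapply(groups, function(idx) .kappa_mom(q[idx], bounds), numeric(1))
  at_bound <- stats::setNames(rep(FALSE, length(groups)), names(groups))
  kappa_sample <- numeric(n)
  for (g in names(groups)) kappa_sample[groups[[g]]] <- kap[g]

  fit <- NULL
  ll_prev <- -Inf
  for (it in seq_len(max_outer)) {
    fit <- fit_coefficients(y, spec, offsets, kappa_sample,
                            init = if (is.null(fit)) NULL else fit$beta)
    for (g in names(groups)) {
      idx <- groups[[g]]
      dm <- dispersion_mle(y[idx], fit$mu_hat[idx], bounds)
      kap[g] <- dm$kappa
      at_bound[g] <- dm$at_boundary
      kappa_sample[idx] <- dm$kappa
    }
    ll <- nb_log_likelihood(y, fit$mu_hat, kappa_sample)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < outer_tol) break
    ll_prev <- ll
  }
  list(fit = fit, kappa = kap, kappa_sample = kappa_sample,
       at_boundary = at_bound, outer_iterations = it)
}
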