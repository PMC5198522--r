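test_that("NB log-likelihood matches closed forms and the Poisson limit", {
  # pmf at zero is (1 + kappa*mu)^(-1/kappa): mu=1, kappa=1 -> 1/2
  expect_equal(nb_log_likelihood(0, 1, 1), log(0.5), tolerance = 1e-12)
  y <- c(0, 3, 7, 1)
  mu <- c(2, 2.5, 6, 1.2)
  expect_equal(nb_log_likelihood(y, mu, 1e-10),
               sum(dpois(y, mu, log = TRUE)), tolerance = 1e-8)
  expect_equal(nb_log_likelihood(y, mu, 0), sum(dpois(y, mu, log = TRUE)))
  expect_error(nb_log_likelihood(1, 1, -0.1), "non-negative")
})

test_that("iid likelihood in mu is maximized at the sample mean", {
  set.seed(1)
  y <- rnbinom(40, size = 5, mu = 9)
  grid <- seq(1, 25, length.out = 4001)
  ll <- vapply(grid, function(m) nb_log_likelihood(y, m, 0.2), numeric(1))
  expect_equal(grid[which.max(ll)], mean(y), tolerance = 0.02)
})

test_that("design matrices have the documented structure", {
  d <- balanced_design(2L)
  alt <- build_design(d, "ALT")
  nul <- build_design(d, "NULL")
  expect_equal(dim(alt$X), c(8L, 4L))
  expect_equal(qr(alt$X)$rank, 4L)
  expect_equal(dim(nul$X), c(8L, 3L))
  expect_identical(nul$X, alt$X[, 1:3])
  expect_equal(alt$X[, "interaction"],
               alt$X[, "protocolRF"] * alt$X[, "conditionT"])
  one_prot <- experiment_design(c("a", "b", "c", "d"),
                                rep("RNA", 4),
                                c("control", "control", "treatment", "treatment"))
  expect_error(build_design(one_prot, "ALT"), "single protocol")
})

test_that("saturated fits reproduce group means; constant genes collapse", {
  d <- balanced_design(3L)
  alt <- build_design(d, "ALT")
  set.seed(2)
  y <- rpois(12, c(rep(20, 3), rep(35, 3), rep(12, 3), rep(50, 3)))
  fit <- fit_coefficients(y, alt, kappa = 0.15)
  groups <- interaction(d$protocol, d$condition)
  expect_equal(unname(tapply(fit$mu_hat, groups, mean)),
               unname(tapply(y, groups, mean)), tolerance = 1e-6)

  fit_const <- fit_coefficients(rep(13, 12), alt, kappa = 0.3)
  expect_equal(unname(fit_const$beta), c(log(13), 0, 0, 0), tolerance = 1e-7)
})

test_that("coefficient fits reach the grid-refinement optimum", {
  d <- balanced_design(2L)
  alt <- build_design(d, "ALT")
  set.seed(3)
  for (g in 1:5) {
    y <- rnbinom(8, size = 1 / 0.1, mu = exp(rnorm(1, log(60), 1)))
    if (sum(y) == 0) next
    off <- rnorm(8, 0, 0.2)
    fit <- fit_coefficients(y, alt, offsets = off, kappa = 0.1)
    oracle <- grid_refine_loglik(y, alt$X, off, 0.1, start = fit$beta * 0 + log(mean(y) + 1))
    expect_gte(fit$loglik, oracle$loglik - 1e-4)
  }
})

test_that("log-likelihood never decreases across IRLS iterations", {
  d <- balanced_design(2L)
  alt <- build_design(d, "ALT")
  set.seed(4)
  for (g in 1:20) {
    y <- rnbinom(8, size = 2, mu = 30)
    if (sum(y) == 0) next
    fit <- fit_coefficients(y, alt, kappa = 0.5)
    expect_true(fit$converged)
    expect_true(is.finite(fit$loglik))
  }
})

test_that("dispersion MLE agrees with a log-spaced grid search", {
  set.seed(5)
  y <- rnbinom(30, size = 1 / 0.3, mu = 50)
  mu <- rep(mean(y), 30)
  est <- dispersion_mle(y, mu)
  grid <- exp(seq(log(1e-6), log(10), length.out = 1e4))
  ll <- vapply(grid, function(k) nb_log_likelihood(y, mu, k), numeric(1))
  spacing <- log(grid[2]) - log(grid[1])
  expect_lt(abs(log(est$kappa) - log(grid[which.max(ll)])), 2 * spacing)
})

test_that("underdispersed data drives the dispersion to the lower bound", {
  y <- rep(8, 10)
  est <- dispersion_mle(y, rep(8, 10))
  expect_equal(est$kappa, 1e-6)
  expect_true(est$at_boundary)
})

test_that("dispersion MLE is consistent at large n", {
  set.seed(6)
  y <- rnbinom(200, size = 1 / 0.1, mu = 80)
  est <- dispersion_mle(y, rep(mean(y), 200))
  expect_gte(est$kappa, 0.05)
  expect_lte(est$kappa, 0.2)
})

test_that("one outer iteration reproduces fit_coefficients at the start kappa", {
  d <- balanced_design(2L)
  alt <- build_design(d, "ALT")
  set.seed(7)
  y <- rnbinom(8, size = 4, mu = 40)
  prot <- as.character(d$protocol)
  af <- alternating_fit(y, alt, protocol = prot, mode = "SEPARATE", max_outer = 1L)
  q <- y
  k0 <- vapply(split(seq_along(y), factor(prot, c("RNASEQ", "RIBO"))),
               function(i) tediff:::.kappa_mom(q[i]), numeric(1))
  ks <- k0[ifelse(prot == "RNASEQ", 1L, 2L)]
  direct <- fit_coefficients(y, alt, kappa = ks)
  expect_equal(af$fit$beta, direct$beta, tolerance = 1e-12)
})

test_that("separate mode brackets distinct protocol dispersions; joint lies between", {
  run <- sim_joined(n_genes = 400L, reps = 5L, kappa_rna = 0.01, kappa_rf = 0.5,
                    fraction_affected = 0, libsize_log_range = c(0, 0), seed = 9L)
  joined <- run$joined
  alt <- build_design(joined$design, "ALT")
  prot <- as.character(joined$design$protocol)
  idx <- which(joined$testable)[1:300]
  sep <- t(vapply(idx, function(i)
    alternating_fit(joined$counts[i, ], alt, protocol = prot,
                    mode = "SEPARATE")$kappa, numeric(2)))
  joint <- vapply(idx, function(i)
    alternating_fit(joined$counts[i, ], alt, mode = "JOINT")$kappa, numeric(1))
  med_rna <- median(sep[, "RNASEQ"])
  med_rf <- median(sep[, "RIBO"])
  expect_lt(med_rna, 0.01 * 2)          # within a factor of 2 above truth
  expect_gt(med_rf, 0.5 / 2)
  expect_lt(med_rf, 0.5 * 2)
  med_joint <- median(joint)
  expect_gt(med_joint, med_rna)
  expect_lt(med_joint, med_rf)
})

test_that("joint and separate modes agree when protocol dispersions are equal", {
  run <- sim_joined(n_genes = 300L, reps = 5L, kappa_rna = 0.2, kappa_rf = 0.2,
                    fraction_affected = 0, libsize_log_range = c(0, 0), seed = 10L)
  joined <- run$joined
  alt <- build_design(joined$design, "ALT")
  prot <- as.character(joined$design$protocol)
  idx <- which(joined$testable)[1:200]
  sep <- t(vapply(idx, function(i)
    alternating_fit(joined$counts[i, ], alt, protocol = prot,
                    mode = "SEPARATE")$kappa, numeric(2)))
  joint <- vapply(idx, function(i)
    alternating_fit(joined$counts[i, ], alt, mode = "JOINT")$kappa, numeric(1))
  expect_lt(abs(median(joint) - median(sep)) / median(sep), 0.25)
})

test_that("alternative log-likelihood dominates the null for every gene", {
  run <- sim_joined(n_genes = 80L, reps = 3L, seed = 12L)
  res <- suppressWarnings(run_pipeline(run$joined))
  ok <- !is.na(res$loglik_alt)
  expect_true(all(res$loglik_alt[ok] >= res$loglik_null[ok] - 1e-9))
})
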