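test_that("category probabilities match closed forms", {
  # full symmetry: theta = beta, flat thresholds -> uniform over categories
  expect_equal(rsm_probs(0.7, 0.7, c(0, 0, 0, 0)), rep(0.2, 5),
               tolerance = 1e-12)
  # dichotomous midpoint
  expect_equal(rsm_probs(1, 1, 0), c(0.5, 0.5), tolerance = 1e-12)
  # dichotomous logistic: theta - beta = 1
  expect_equal(rsm_probs(1, 0, 0)[2], exp(1) / (1 + exp(1)),
               tolerance = 1e-10)
  expect_error(rsm_probs(Inf, 0, 0), "finite")
})

test_that("probabilities normalize and are translation invariant", {
  set.seed(5)
  for (rep in 1:25) {
    K <- sample(1:6, 1)
    tau <- rnorm(K); tau <- tau - mean(tau)
    th <- rnorm(1, 0, 2); be <- rnorm(1, 0, 2)
    p <- rsm_probs(th, be, tau)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # shifting theta and beta by the same constant changes nothing
    c0 <- rnorm(1, 0, 5)
    expect_equal(rsm_probs(th + c0, be + c0, tau), p, tolerance = 1e-10)
  }
  # extreme offsets stay finite and normalized
  expect_equal(sum(rsm_probs(400, -400, c(-1, 0, 1))), 1, tolerance = 1e-12)
})

test_that("expected score and variance behave per closed forms and limits", {
  tau <- c(-1.5, -0.5, 0.5, 1.5)
  expect_equal(rsm_expected(0.3, 0.3, tau), 2, tolerance = 1e-10) # K/2
  expect_equal(rsm_expected(-30, 0, tau), 0, tolerance = 1e-8)
  expect_equal(rsm_expected(30, 0, tau), 4, tolerance = 1e-8)
  expect_equal(rsm_expected(1, 0, 0), exp(1) / (1 + exp(1)), tolerance = 1e-10)
  # strictly increasing in theta
  grid <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(rsm_expected(grid, 0, tau)) > 0))
  # variance: Bernoulli(0.5) and uniform on {0..4}
  expect_equal(rsm_variance(0, 0, 0), 0.25, tolerance = 1e-12)
  expect_equal(rsm_variance(0, 0, c(0, 0, 0, 0)), 2.0, tolerance = 1e-12)
  expect_lt(rsm_variance(-30, 0, tau), 1e-8)
})

test_that("log-likelihood matches an independent cell-by-cell oracle", {
  set.seed(8)
  m <- matrix(sample(c(0:3, NA), 40, TRUE, prob = c(rep(0.225, 4), 0.1)), 8, 5)
  rm <- response_matrix(m, n_categories = 4)
  theta <- rnorm(8); beta <- rnorm(5); beta <- beta - mean(beta)
  tau <- c(-1, 0.2, 0.8)
  expect_equal(rsm_loglik(rm, theta, beta, tau),
               oracle_loglik(m, theta, beta, tau, 3), tolerance = 1e-9)
  # single response in category k with P(k) = 0.2
  rm1 <- response_matrix(matrix(c(2L, NA, NA, NA), 2, 2), n_categories = 5)
  expect_equal(rsm_loglik(rm1, c(0, 0), c(0, 0), rep(0, 4)), log(0.2),
               tolerance = 1e-12)
  # permuting person order leaves the value unchanged
  perm <- sample(8)
  rm_p <- response_matrix(m[perm, ], n_categories = 4)
  expect_equal(rsm_loglik(rm_p, theta[perm], beta, tau),
               rsm_loglik(rm, theta, beta, tau), tolerance = 1e-10)
})

test_that("JMLE recovers generating parameters on simulated data", {
  sim <- simulate_responses(sim_config(n_persons = 500, n_items = 10, seed = 1))
  fit <- fit_rsm(sim$responses)
  expect_true(fit$converged)
  expect_gte(cor(fit$beta, sim$truth$beta), 0.98)
  expect_lte(sqrt(mean((fit$beta - sim$truth$beta)^2)), 0.15)
  expect_gt(cor(fit$theta, sim$truth$theta[names(fit$theta)]), 0.85)
  # identification constraints hold to machine precision
  expect_equal(mean(fit$beta), 0, tolerance = 1e-10)
  expect_equal(sum(fit$tau), 0, tolerance = 1e-10)
  # standard errors are positive and finite
  expect_true(all(fit$se_beta > 0 & is.finite(fit$se_beta)))
  expect_true(all(fit$se_theta > 0 & is.finite(fit$se_theta)))
  # likelihood non-decreasing across accepted cycles
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
})

test_that("bias-corrected beta error shrinks as the sample grows", {
  # JMLE item estimates carry a finite-test-length bias that does not vanish
  # with more persons (incidental parameters); the (I-1)/I correction removes
  # its leading term, after which the error shrinks with the sample.
  seeds <- c(4L, 5L, 6L)
  rmse <- function(n) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_responses(sim_config(n_persons = n, n_items = 10,
                                           seed = s))
      fit <- fit_rsm(sim$responses, quiet = TRUE, bias_correction = TRUE)
      sqrt(mean((fit$beta - sim$truth$beta)^2))
    }, numeric(1)))
  }
  r100 <- rmse(100); r500 <- rmse(500)
  expect_lt(r500, r100)
  expect_lt(r500, 0.10)
})

test_that("JMLE matches brute-force grid likelihood maximization on a toy", {
  # 2 persons x 2 items, 3 categories, every category observed
  X <- rbind(c(0L, 1L), c(2L, 0L))
  rm <- response_matrix(X, n_categories = 3)
  fit <- fit_rsm(rm, tolerance = 1e-6, max_iter = 500, quiet = TRUE)
  oracle <- oracle_grid_fit(X, K = 2)
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 0.01)
  expect_equal(unname(fit$tau), oracle$tau, tolerance = 0.01)
  expect_equal(unname(fit$theta), oracle$theta, tolerance = 0.01)
  # and the engine's likelihood is at least the oracle's maximum
  expect_gte(fit$log_likelihood, oracle$loglik - 1e-6)
})

test_that("dichotomous data reduce to a dedicated dichotomous-Rasch oracle", {
  set.seed(21)
  theta <- rnorm(80); beta <- seq(-1.5, 1.5, length.out = 6)
  P <- plogis(outer(theta, beta, "-"))
  X <- matrix(rbinom(length(P), 1, P), nrow(P))
  r <- rowSums(X)
  keep <- r > 0 & r < ncol(X)
  X <- X[keep, ]
  stopifnot(all(colSums(X) > 0), all(colSums(X) < nrow(X)))
  fit <- fit_rsm(response_matrix(X, n_categories = 2), tolerance = 1e-7,
                 max_iter = 500, quiet = TRUE)
  oracle <- oracle_dichotomous_fit(X)
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-3)
  expect_equal(unname(fit$theta), oracle$theta, tolerance = 1e-3)
  # K = 1 has a single threshold pinned at 0 by the sum constraint
  expect_equal(unname(fit$tau), 0, tolerance = 1e-12)
})

test_that("missing responses are skipped consistently in estimation", {
  sim <- simulate_responses(sim_config(n_persons = 400, n_items = 10, seed = 9))
  fit0 <- fit_rsm(sim$responses, quiet = TRUE)
  rm_miss <- inject_missing(sim$responses, 0.10, seed = 10)
  fit1 <- fit_rsm(rm_miss, quiet = TRUE)
  # MCAR deletion moves item difficulties by less than 2 joint SEs
  lim <- 2 * sqrt(fit0$se_beta^2 + fit1$se_beta^2)
  expect_true(all(abs(fit1$beta - fit0$beta) < lim))
})

test_that("extreme and degenerate units are flagged or dropped", {
  set.seed(14)
  m <- matrix(sample(0:4, 30 * 6, TRUE), 30, 6)
  m[1, ] <- 4L          # all-maximum person
  m[2, ] <- 0L          # all-minimum person
  rm <- response_matrix(m, n_categories = 5)
  fit <- fit_rsm(rm, quiet = TRUE)
  expect_true(fit$extreme_persons[["p1"]])
  expect_true(fit$extreme_persons[["p2"]])
  expect_true(all(is.finite(fit$theta)))
  expect_gt(fit$theta[["p1"]], max(fit$theta[!fit$extreme_persons]))
  expect_lt(fit$theta[["p2"]], min(fit$theta[!fit$extreme_persons]))
  # an item with a single observed category is dropped with a warning
  m2 <- m; m2[, 3] <- 2L
  expect_warning(fit2 <- fit_rsm(response_matrix(m2, n_categories = 5)),
                 "degenerate items")
  expect_false("i3" %in% names(fit2$beta))
  expect_identical(fit2$dropped_items, "i3")
  # all-missing person is dropped
  m3 <- m; m3[5, ] <- NA_integer_
  expect_warning(fit3 <- fit_rsm(response_matrix(m3, n_categories = 5)),
                 "all-missing")
  expect_false("p5" %in% names(fit3$theta))
})

test_that("non-convergence is reported, never silent", {
  sim <- simulate_responses(sim_config(n_persons = 120, n_items = 8, seed = 6))
  expect_warning(fit <- fit_rsm(sim$responses, max_iter = 2L),
                 "did not converge")
  expect_false(fit$converged)
  expect_identical(fit$iterations, 2L)
  expect_gt(fit$max_last_change, 1e-3)
})

test_that("anchored person scoring agrees with the joint calibration", {
  sim <- simulate_responses(sim_config(n_persons = 300, n_items = 12, seed = 13))
  fit <- fit_rsm(sim$responses, quiet = TRUE)
  sc <- score_persons(sim$responses, fit$beta, fit$tau)
  ok <- !fit$extreme_persons
  expect_equal(unname(sc$theta[names(fit$theta)[ok]]),
               unname(fit$theta[ok]), tolerance = 5e-3)
})
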