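test_that("standardized residuals follow the (x - E)/sqrt(W) definition", {
  sim <- simulate_responses(sim_config(n_persons = 200, n_items = 8, seed = 3))
  fit <- fit_rsm(sim$responses, quiet = TRUE)
  z <- standardized_residuals(fit)
  # a cell where x equals the model expectation exactly gives z = 0
  E <- outer(seq_along(fit$theta), seq_along(fit$beta),
             function(n, i) rsm_expected(fit$theta[n], fit$beta[i], fit$tau))
  W <- outer(seq_along(fit$theta), seq_along(fit$beta),
             function(n, i) rsm_variance(fit$theta[n], fit$beta[i], fit$tau))
  X <- fit$data$responses
  expect_equal(unname(z), unname((X - E) / sqrt(W)), tolerance = 1e-8)
  # dichotomous item with P(1) = 0.5, x = 1 -> z = 1
  rm <- response_matrix(rbind(c(1L, 0L), c(0L, 1L)), n_categories = 2)
  fit2 <- fit_rsm(rm, quiet = TRUE)  # symmetric data: theta = beta = 0
  z2 <- standardized_residuals(fit2)
  expect_equal(abs(unname(z2)), matrix(1, 2, 2), tolerance = 1e-3)
  # mean residual over model-consistent data is near 0
  expect_lt(abs(mean(z, na.rm = TRUE)), 0.05)
  # missingness propagates
  rm3 <- inject_missing(sim$responses, 0.2, seed = 4)
  fit3 <- fit_rsm(rm3, quiet = TRUE)
  expect_identical(is.na(standardized_residuals(fit3)),
                   is.na(fit3$data$responses))
})

test_that("INFIT/OUTFIT are centered near 1 under the model and catch misfit", {
  sim <- simulate_responses(sim_config(n_persons = 500, n_items = 10, seed = 1))
  fit <- fit_rsm(sim$responses, quiet = TRUE)
  it <- infit_outfit(fit, "items")
  expect_true(mean(it$infit_mnsq) > 0.9 && mean(it$infit_mnsq) < 1.1)
  expect_true(mean(it$outfit_mnsq) > 0.9 && mean(it$outfit_mnsq) < 1.1)
  pe <- infit_outfit(fit, "persons")
  expect_true(abs(mean(pe$outfit_mnsq) - 1) < 0.1)
  # a person answering uniformly at random on a well-targeted test
  rm_bad <- inject_random_responders(sim$responses, 2 / 500, seed = 2)
  bad <- attr(rm_bad, "injected_persons")
  fit_bad <- fit_rsm(rm_bad, quiet = TRUE)
  pf <- infit_outfit(fit_bad, "persons")
  expect_true(all(pf$outfit_mnsq[pf$unit %in% bad] > 1.5))
})

test_that("OUTFIT equals the mean squared standardized residual", {
  sim <- simulate_responses(sim_config(n_persons = 60, n_items = 6, seed = 17))
  fit <- fit_rsm(sim$responses, quiet = TRUE)
  z <- standardized_residuals(fit)
  it <- infit_outfit(fit, "items")
  expect_equal(it$outfit_mnsq, unname(colMeans(z^2, na.rm = TRUE)),
               tolerance = 1e-8)
  # INFIT is the information-weighted version
  W <- outer(seq_along(fit$theta), seq_along(fit$beta),
             function(n, i) rsm_variance(fit$theta[n], fit$beta[i], fit$tau))
  expect_equal(it$infit_mnsq,
               unname(colSums((z^2 * W), na.rm = TRUE) / colSums(W * !is.na(z))),
               tolerance = 1e-8)
})

test_that("item-total correlations use the rest score", {
  sim <- simulate_responses(sim_config(n_persons = 300, n_items = 8, seed = 23))
  fit <- fit_rsm(sim$responses, quiet = TRUE)
  it <- infit_outfit(fit, "items")
  X <- fit$data$responses
  manual <- cor(X[, 1], rowSums(X[, -1]))
  expect_equal(it$item_total_correlation[1], manual, tolerance = 1e-10)
  expect_true(all(it$item_total_correlation > 0))
})

test_that("mean-square bands partition [0, Inf) with the stated boundaries", {
  expect_identical(classify_mnsq(1.00), "productive")
  expect_identical(classify_mnsq(1.84), "unproductive")
  expect_identical(classify_mnsq(0.40), "overfit-deterministic")
  # boundary membership: 0.5 and 1.5 productive, 2.0 unproductive, >2 degrading
  expect_identical(classify_mnsq(c(0, 0.4999, 0.5, 1.5, 1.5001, 2.0, 2.0001)),
                   c("overfit-deterministic", "overfit-deterministic",
                     "productive", "productive", "unproductive",
                     "unproductive", "degrading"))
  # every nonnegative value receives exactly one label
  set.seed(31)
  vals <- c(runif(200, 0, 4), rexp(50, 0.2))
  labs <- classify_mnsq(vals)
  expect_false(anyNA(labs))
  expect_true(all(labs %in% c("degrading", "unproductive", "productive",
                              "overfit-deterministic")))
  expect_error(classify_mnsq(-0.1), "nonnegative")
})

test_that("separation summaries follow the closed-form identities", {
  sim <- simulate_responses(sim_config(n_persons = 455, n_items = 12, seed = 2))
  fit <- fit_rsm(sim$responses, quiet = TRUE)
  for (margin in c("persons", "items")) {
    s <- separation(fit, margin)
    expect_equal(s$adjusted_sd^2, max(s$observed_sd^2 - s$rmse^2, 0),
                 tolerance = 1e-12)
    expect_equal(s$separation_index, s$adjusted_sd / s$rmse, tolerance = 1e-12)
    expect_equal(s$reliability, s$adjusted_sd^2 / s$observed_sd^2,
                 tolerance = 1e-12)
    expect_equal(s$strata, (4 * s$separation_index + 1) / 3, tolerance = 1e-12)
  }
  # reliability 0.8 <-> separation 2: verdict boundary for persons
  # (G = sqrt(R/(1-R)))
  s <- separation(fit, "persons")
  expect_equal(s$separation_index, sqrt(s$reliability / (1 - s$reliability)),
               tolerance = 1e-10)
  # a person separation index below 2 is judged inadequate
  expect_identical(s$verdict, if (s$separation_index < 2) "inadequate"
                   else "adequate")
})

test_that("person separation grows with test length and trait spread", {
  g <- function(n_items, sd) {
    sim <- simulate_responses(sim_config(n_persons = 350, n_items = n_items,
                                         theta_sd = sd, seed = 12))
    separation(fit_rsm(sim$responses, quiet = TRUE), "persons")$separation_index
  }
  expect_gt(g(12, 1), g(4, 1))
  expect_gt(g(8, 1.6), g(8, 0.7))
})

test_that("trait SD of zero collapses person reliability toward zero", {
  sim <- simulate_responses(sim_config(n_persons = 300, n_items = 10,
                                       theta_sd = 0, seed = 19))
  fit <- fit_rsm(sim$responses, quiet = TRUE)
  s <- separation(fit, "persons")
  # no true spread: observed SD is nearly all error
  expect_lt(s$reliability, 0.25)
  expect_identical(s$verdict, "inadequate")
})

test_that("information curves invert the standard error and add over items", {
  sim <- simulate_responses(sim_config(n_persons = 200, n_items = 10, seed = 5))
  fit <- fit_rsm(sim$responses, quiet = TRUE)
  ic <- information_function(fit)
  expect_true(all(ic$information > 0))
  expect_equal(ic$se * sqrt(ic$information), rep(1, nrow(ic)),
               tolerance = 1e-12)
  # a test is at least as informative as any item subset, everywhere
  sub <- information_function(fit, items = names(fit$beta)[c(2, 5, 8)])
  expect_true(all(ic$information >= sub$information))
  # one dichotomous item at theta = beta: Bernoulli variance 0.25
  rm2 <- response_matrix(rbind(c(1L, 0L), c(0L, 1L)), n_categories = 2)
  fit2 <- fit_rsm(rm2, quiet = TRUE)
  one <- information_function(fit2, theta_grid = fit2$beta[1],
                              items = names(fit2$beta)[1])
  expect_equal(one$information, 0.25, tolerance = 1e-6)
})

test_that("empirical precision of person measures matches the information function", {
  # fixed items; many replicate response vectors at a known trait level
  beta <- seq(-1.5, 1.5, length.out = 10)
  tau <- c(-1.5, -0.5, 0.5, 1.5)
  theta0 <- 0.5
  set.seed(77)
  n_rep <- 400
  est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    p <- rsm_probs(rep(theta0, length(beta)), beta, tau)
    x <- vapply(seq_along(beta),
                function(i) sample(0:4, 1, prob = p[i, ]), integer(1))
    if (sum(x) == 0 || sum(x) == 4 * length(beta)) { est[r] <- NA; next }
    rm1 <- response_matrix(matrix(x, 1), n_categories = 5)
    est[r] <- score_persons(rm1, beta, tau)$theta
  }
  info <- sum(rsm_variance(rep(theta0, length(beta)), beta, tau))
  expect_equal(sd(est, na.rm = TRUE), 1 / sqrt(info), tolerance = 0.15)
})

test_that("item maps order by difficulty with stable gaps", {
  sim <- simulate_responses(sim_config(n_persons = 150, n_items = 6, seed = 25))
  fit <- fit_rsm(sim$responses, quiet = TRUE)
  mp <- item_map(fit)
  expect_true(!is.unsorted(mp$beta))
  expect_equal(mp$gap[-1], diff(mp$beta), tolerance = 1e-12)
  expect_true(is.na(mp$gap[1]))
  # permutation invariance: reordering input columns changes nothing
  perm <- c(4, 1, 6, 3, 5, 2)
  rm_p <- response_matrix(sim$responses$responses[, perm],
                          item_ids = sim$responses$item_ids[perm],
                          n_categories = 5)
  mp2 <- item_map(fit_rsm(rm_p, quiet = TRUE))
  expect_identical(mp2$item, mp$item)
  expect_equal(mp2$beta, mp$beta, tolerance = 1e-3)
})
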