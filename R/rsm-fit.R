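#' Fit the Rating Scale Model by joint maximum likelihood
#'
#' Estimates person measures (theta), item difficulties (beta) and the shared
#' category thresholds (tau) of the Andrich Rating Scale Model by alternating
#' damped Newton-Raphson updates of the joint likelihood (JMLE), the
#' estimation method of classical Rasch calibration software. Missing
#' responses are skipped in all sums. The model is identified by centering:
#' `mean(beta) = 0` and `sum(tau) = 0` are enforced every cycle.
#'
#' Persons or items with extreme raw scores (all-minimum or all-maximum)
#' have no finite maximum-likelihood estimate; their raw scores are pulled
#' `extreme_adjust` score points toward the interior before estimation and
#' the resulting measures are flagged. Items on which only a single response
#' category was observed are dropped with a warning. Standard errors are
#' \eqn{SE(\theta_n) = 1/\sqrt{\sum_i W_{ni}}} and analogously for items,
#' where W is the model score variance at the estimates.
#'
#' @param rm A [response_matrix()].
#' @param tolerance Convergence tolerance: maximum absolute parameter change
#'   (logits) between cycles. Default 0.001.
#' @param max_iter Maximum number of JMLE cycles. Default 100.
#' @param extreme_adjust Score-point adjustment applied to extreme raw
#'   scores. Default 0.3.
#' @param bias_correction If `TRUE`, multiply the final item difficulties by
#'   `(I - 1)/I` (I = number of items), a standard correction for the
#'   finite-test bias of JMLE. Off by default.
#' @param quiet Suppress warnings about dropped units and non-convergence.
#'
#' @return An object of class `rsm_fit`: a list with components
#'   \describe{
#'     \item{theta, beta, tau}{parameter estimates in logits (named)}
#'     \item{se_theta, se_beta}{standard errors in logits}
#'     \item{extreme_persons, extreme_items}{logical flags for adjusted
#'       extreme-score units}
#'     \item{converged, iterations, max_last_change}{convergence record}
#'     \item{log_likelihood}{joint log-likelihood at the estimates}
#'     \item{loglik_trace}{log-likelihood after each accepted cycle}
#'     \item{data}{the (possibly reduced) [response_matrix()] actually fitted}
#'     \item{dropped_persons, dropped_items}{ids removed before fitting}
#'   }
#' @export
fit_rsm <- function(rm, tolerance = 1e-3, max_iter = 100L,
                    extreme_adjust = 0.3, bias_correction = FALSE,
                    quiet = FALSE) {
  stopifnot(inherits(rm, "response_matrix"))
  K <- rm$n_categories - 1L
  X <- rm$responses
  warn <- function(...) if (!quiet) warning(..., call. = FALSE)

  # drop all-missing persons/items
  dropped_p <- rm$person_ids[rowSums(!is.na(X)) == 0L]
  dropped_i <- rm$item_ids[colSums(!is.na(X)) == 0L]
  # drop items with a single observed category (no information about beta)
  single_cat <- apply(X, 2L, function(x) length(unique(x[!is.na(x)])) <= 1L)
  dropped_i <- union(dropped_i, rm$item_ids[single_cat])
  if (length(dropped_p)) warn("dropping all-missing persons: ",
                              paste(dropped_p, collapse = ", "))
  if (length(dropped_i)) warn("dropping degenerate items: ",
                              paste(dropped_i, collapse = ", "))
  keep_p <- !rm$person_ids %in% dropped_p
  keep_i <- !rm$item_ids %in% dropped_i
  if (sum(keep_p) < 2L || sum(keep_i) < 2L) {
    stop("need at least 2 usable persons and 2 usable items", call. = FALSE)
  }
  rm <- response_matrix(X[keep_p, keep_i, drop = FALSE],
                        rm$person_ids[keep_p], rm$item_ids[keep_i],
                        rm$n_categories)
  X <- rm$responses
  n <- nrow(X); I <- ncol(X)

  obs <- !is.na(X)
  cat_counts <- tabulate(X + 1L, nbins = K + 1L)
  if (any(cat_counts == 0L)) {
    warn("response categories never observed: ",
         paste(which(cat_counts == 0L) - 1L, collapse = ", "),
         "; thresholds for these steps rest on the model structure only")
  }

  r_p <- rowSums(X, na.rm = TRUE); max_p <- K * rowSums(obs)
  s_i <- colSums(X, na.rm = TRUE); max_i <- K * colSums(obs)
  extreme_p <- r_p == 0L | r_p == max_p
  extreme_i <- s_i == 0L | s_i == max_i
  r_adj <- pmin(pmax(r_p, extreme_adjust), max_p - extreme_adjust)
  s_adj <- pmin(pmax(s_i, extreme_adjust), max_i - extreme_adjust)
  if (sum(!extreme_p) < 2L || sum(!extreme_i) < 2L) {
    stop("need at least 2 non-extreme persons and items", call. = FALSE)
  }

  # PROX-style initialization: log-odds of normalized raw scores;
  # thresholds from log ratios of adjacent category frequencies.
  theta <- log(r_adj / (max_p - r_adj))
  beta <- log((max_i - s_adj) / s_adj)
  beta <- beta - mean(beta)
  cc <- pmax(cat_counts, 0.5)
  tau <- log(cc[1:K] / cc[2:(K + 1L)])
  tau <- tau - mean(tau)

  geq <- array(FALSE, c(n, I, K))          # observed exceedance indicators
  for (j in 1:K) geq[, , j] <- obs & !is.na(X) & X >= j
  n_geq <- vapply(1:K, function(j) sum(geq[, , j]), numeric(1))

  obs_idx <- which(obs, arr.ind = TRUE)
  x_obs <- X[obs_idx]
  loglik_at <- function(th, be, ta) {
    lp <- .rsm_prob_array(th, be, ta)$logP
    sum(lp[cbind(obs_idx, x_obs + 1L)])
  }

  cap <- function(x, lim = 1) pmin(pmax(x, -lim), lim)
  no_extremes <- !any(extreme_p) && !any(extreme_i)
  ll_old <- loglik_at(theta, beta, tau)
  trace <- ll_old
  converged <- FALSE
  iter <- 0L
  max_change <- Inf

  while (iter < max_iter) {
    iter <- iter + 1L
    th0 <- theta; be0 <- beta; ta0 <- tau

    # person block
    ew <- .rsm_ew(.rsm_prob_array(theta, beta, tau)$P)
    Esum <- rowSums(ew$E * obs); Wsum <- rowSums(ew$W * obs)
    theta <- theta + cap((r_adj - Esum) / pmax(Wsum, 1e-10))

    # item block
    ew <- .rsm_ew(.rsm_prob_array(theta, beta, tau)$P)
    Esum <- colSums(ew$E * obs); Wsum <- colSums(ew$W * obs)
    beta <- beta + cap((Esum - s_adj) / pmax(Wsum, 1e-10))

    # threshold block
    P <- .rsm_prob_array(theta, beta, tau)$P
    Sj <- array(0, c(n, I, K))
    Sj[, , K] <- P[, , K + 1L]
    if (K > 1L) for (j in (K - 1L):1L) Sj[, , j] <- Sj[, , j + 1L] + P[, , j + 1L]
    for (j in 1:K) {
      s_exp <- sum(Sj[, , j][obs])
      h <- sum((Sj[, , j] * (1 - Sj[, , j]))[obs])
      tau[j] <- tau[j] + cap((s_exp - n_geq[j]) / pmax(h, 1e-10))
    }

    # identification: shift tau-mean into beta, then center beta into theta
    ct <- mean(tau); tau <- tau - ct; beta <- beta - ct
    cb <- mean(beta); beta <- beta - cb; theta <- theta - cb

    # step halving on the actual likelihood (skipped when extreme-score
    # adjustments make the working objective differ from the likelihood)
    ll_new <- loglik_at(theta, beta, tau)
    if (no_extremes) {
      half <- 0L
      while (ll_new < ll_old - 1e-10 && half < 10L) {
        half <- half + 1L
        theta <- (theta + th0) / 2
        beta <- (beta + be0) / 2
        tau <- (tau + ta0) / 2
        ll_new <- loglik_at(theta, beta, tau)
      }
    }
    ll_old <- ll_new
    trace <- c(trace, ll_new)

    max_change <- max(abs(theta - th0), abs(beta - be0), abs(tau - ta0))
    if (max_change < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("JMLE did not converge in ", max_iter,
         " cycles (last max change ", signif(max_change, 3), " logits)")
  }

  if (bias_correction) beta <- beta * (I - 1) / I

  ew <- .rsm_ew(.rsm_prob_array(theta, beta, tau)$P)
  se_theta <- 1 / sqrt(pmax(rowSums(ew$W * obs), 1e-10))
  se_beta <- 1 / sqrt(pmax(colSums(ew$W * obs), 1e-10))

  names(theta) <- names(se_theta) <- names(extreme_p) <- rm$person_ids
  names(beta) <- names(se_beta) <- names(extreme_i) <- rm$item_ids
  names(tau) <- paste0("tau", 1:K)

  structure(
    list(theta = theta, beta = beta, tau = tau,
         se_theta = se_theta, se_beta = se_beta,
         extreme_persons = extreme_p, extreme_items = extreme_i,
         converged = converged, iterations = iter,
         max_last_change = max_change,
         log_likelihood = ll_old, loglik_trace = trace,
         data = rm, dropped_persons = dropped_p, dropped_items = dropped_i),
    class = "rsm_fit"
  )
}

#' Estimate person measures with anchored item parameters
#'
#' Maximum-likelihood person measures for a response matrix given fixed item
#' difficulties and thresholds (e.g. from a previous [fit_rsm()] calibration).
#' Extreme raw scores are handled with the same fractional adjustment as
#' [fit_rsm()].
#'
#' @param rm A [response_matrix()] whose items match `beta` by id/order.
#' @param beta Anchored item difficulties in logits.
#' @param tau Anchored thresholds.
#' @param extreme_adjust Score-point adjustment for extreme raw scores.
#' @param tolerance,max_iter Newton iteration controls.
#' @return A list with `theta`, `se_theta` and logical `extreme` flags.
#' @export
score_persons <- function(rm, beta, tau, extreme_adjust = 0.3,
                          tolerance = 1e-4, max_iter = 50L) {
  stopifnot(inherits(rm, "response_matrix"),
            length(beta) == ncol(rm$responses),
            length(tau) == rm$n_categories - 1L)
  X <- rm$responses
  K <- rm$n_categories - 1L
  obs <- !is.na(X)
  usable <- rowSums(obs) > 0L
  r <- rowSums(X, na.rm = TRUE)
  max_r <- K * rowSums(obs)
  extreme <- usable & (r == 0L | r == max_r)
  r_adj <- pmin(pmax(r, extreme_adjust), pmax(max_r - extreme_adjust,
                                              extreme_adjust))
  theta <- rep(NA_real_, nrow(X))
  theta[usable] <- log(r_adj[usable] / (max_r[usable] - r_adj[usable]))
  for (it in seq_len(max_iter)) {
    ew <- .rsm_ew(.rsm_prob_array(ifelse(is.na(theta), 0, theta), beta, tau)$P)
    Esum <- rowSums(ew$E * obs); Wsum <- pmax(rowSums(ew$W * obs), 1e-10)
    step <- pmin(pmax((r_adj - Esum) / Wsum, -1), 1)
    step[!usable] <- 0
    theta <- theta + ifelse(usable, step, 0)
    if (max(abs(step[usable])) < tolerance) break
  }
  ew <- .rsm_ew(.rsm_prob_array(ifelse(is.na(theta), 0, theta), beta, tau)$P)
  se <- rep(NA_real_, nrow(X))
  se[usable] <- 1 / sqrt(pmax(rowSums(ew$W * obs), 1e-10))[usable]
  list(theta = stats::setNames(theta, rm$person_ids),
       se_theta = stats::setNames(se, rm$person_ids),
       extreme = stats::setNames(extreme, rm$person_ids))
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat("Rating Scale Model fit (JMLE)\n")
  cat("  ", length(x$theta), " persons, ", length(x$beta), " items, ",
      length(x$tau) + 1L, " categories\n", sep = "")
  cat("  converged:", x$converged, "after", x$iterations,
      sprintf("cycles (max change %.2g logits)\n", x$max_last_change))
  cat(sprintf("  log-likelihood: %.2f\n", x$log_likelihood))
  cat(sprintf("  item difficulties: [%.2f, %.2f] logits; thresholds: %s\n",
              min(x$beta), max(x$beta),
              paste(sprintf("%.2f", x$tau), collapse = ", ")))
  ne <- sum(x$extreme_persons)
  if (ne) cat("  ", ne, " extreme-score person(s) flagged\n", sep = "")
  invisible(x)
}

#' Tabulate item calibration results
#'
#' One row per item with measure, standard error, INFIT and OUTFIT
#' mean-squares and the item-total (rest-score) correlation — the layout of a
#' standard Rasch item table.
#'
#' @param fit An [fit_rsm()] result.
#' @return A `data.frame` with columns `item`, `measure`, `se`,
#'   `infit_mnsq`, `outfit_mnsq`, `item_total_r`, `extreme`.
#' @export
item_table <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  fs <- infit_outfit(fit, margin = "items")
  data.frame(item = names(fit$beta),
             measure = unname(fit$beta),
             se = unname(fit$se_beta),
             infit_mnsq = fs$infit_mnsq,
             outfit_mnsq = fs$outfit_mnsq,
             item_total_r = fs$item_total_correlation,
             extreme = unname(fit$extreme_items),
             row.names = NULL)
}
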