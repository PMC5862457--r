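#' Rating Scale Model category probabilities
#'
#' Under the Andrich Rating Scale Model the probability that a person with
#' measure `theta` scores category k (k = 0..K) on an item with difficulty
#' `beta` is
#' \deqn{P(X = k) = \exp\{k(\theta-\beta) - \sum_{j \le k}\tau_j\} /
#'   \sum_{m=0}^{K} \exp\{m(\theta-\beta) - \sum_{j \le m}\tau_j\},}
#' with \eqn{\tau_0 \equiv 0} and thresholds \eqn{\tau_1..\tau_K} shared by
#' all items. Computed with overflow-safe normalization.
#'
#' @param theta Person measure(s) in logits (scalar or vector).
#' @param beta Item difficulty in logits (scalar, or vector recycled against
#'   `theta`).
#' @param tau Numeric vector of K category thresholds.
#' @return If `theta` and `beta` are scalars, a probability vector of length
#'   K + 1; otherwise a matrix with one row per `theta`/`beta` pair and K + 1
#'   columns. Rows sum to 1.
#' @export
rsm_probs <- function(theta, beta, tau) {
  if (!all(is.finite(theta)) || !all(is.finite(beta)) ||
      !all(is.finite(tau))) {
    stop("theta, beta and tau must all be finite", call. = FALSE)
  }
  K <- length(tau)
  eta <- theta - beta                      # recycles
  cumtau <- c(0, cumsum(tau))              # length K + 1, category 0 first
  logits <- outer(eta, 0:K) - rep(cumtau, each = length(eta))
  logits <- logits - apply(logits, 1L, max)
  p <- exp(logits)
  p <- p / rowSums(p)
  if (length(eta) == 1L) drop(p) else p
}

#' Model-expected item score
#'
#' The expected score \eqn{E = \sum_k k P(X=k)} of a person on an item under
#' the Rating Scale Model; strictly increasing in `theta` with limits 0 and K.
#'
#' @inheritParams rsm_probs
#' @return Expected score(s) in `[0, K]`.
#' @export
rsm_expected <- function(theta, beta, tau) {
  p <- rsm_probs(theta, beta, tau)
  K <- length(tau)
  if (is.matrix(p)) drop(p %*% (0:K)) else sum((0:K) * p)
}

#' Model score variance
#'
#' The variance \eqn{W = \sum_k k^2 P(X=k) - E^2} of an item score under the
#' model. In the dichotomous case it reduces to \eqn{p(1-p)}. This is the
#' item's contribution to the test information function, and the weight used
#' by the information-weighted (INFIT) fit statistic.
#'
#' @inheritParams rsm_probs
#' @return Nonnegative variance(s).
#' @export
rsm_variance <- function(theta, beta, tau) {
  p <- rsm_probs(theta, beta, tau)
  K <- length(tau)
  k <- 0:K
  if (is.matrix(p)) {
    e <- drop(p %*% k)
    pmax(drop(p %*% k^2) - e^2, 0)
  } else {
    e <- sum(k * p)
    max(sum(k^2 * p) - e^2, 0)
  }
}

# Internal: log-probability array for a full person x item grid.
# Returns list(logP = n x I x (K+1) array, P = exp(logP)).
.rsm_prob_array <- function(theta, beta, tau) {
  n <- length(theta); I <- length(beta); K <- length(tau)
  cumtau <- c(0, cumsum(tau))
  eta <- outer(theta, beta, "-")                 # n x I
  logits <- array(0, c(n, I, K + 1L))
  for (k in 0:K) logits[, , k + 1L] <- k * eta - cumtau[k + 1L]
  mx <- apply(logits, c(1L, 2L), max)
  logden <- mx + log(apply(exp(logits - as.vector(mx)), c(1L, 2L), sum))
  logP <- logits - as.vector(logden)
  list(logP = logP, P = exp(logP))
}

# Internal: expected score and variance matrices from a probability array.
.rsm_ew <- function(P) {
  K <- dim(P)[3L] - 1L
  E <- matrix(0, dim(P)[1L], dim(P)[2L])
  E2 <- E
  for (k in 1:K) {
    E <- E + k * P[, , k + 1L]
    E2 <- E2 + k^2 * P[, , k + 1L]
  }
  list(E = E, W = pmax(E2 - E^2, 0))
}

#' Joint log-likelihood of a response matrix under the Rating Scale Model
#'
#' Sum over observed (non-missing) responses of the log category
#' probability at the given person, item and threshold parameters.
#'
#' @param rm A [response_matrix()].
#' @param theta,beta Person measures and item difficulties in logits, in the
#'   row/column order of `rm`.
#' @param tau Threshold vector of length `n_categories - 1`.
#' @return The log-likelihood (a single number).
#' @export
rsm_loglik <- function(rm, theta, beta, tau) {
  stopifnot(inherits(rm, "response_matrix"),
            length(theta) == nrow(rm$responses),
            length(beta) == ncol(rm$responses),
            length(tau) == rm$n_categories - 1L)
  logP <- .rsm_prob_array(theta, beta, tau)$logP
  X <- rm$responses
  obs <- which(!is.na(X), arr.ind = TRUE)
  sum(logP[cbind(obs, X[obs] + 1L)])
}
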