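# Small fixtures and independent oracles used across test files.

# tiny complete 0-based response matrix
tiny_rm <- function(m = rbind(c(0, 1), c(1, 2), c(2, 0)), K1 = 3L) {
  response_matrix(m, n_categories = K1)
}

# write a response matrix to a temp CSV in external (1-based) coding
write_temp_responses <- function(rm) {
  f <- tempfile(fileext = ".csv")
  write_responses(rm, f)
  f
}

# Independent joint log-likelihood of an RSM response matrix, computed cell
# by cell from first principles (no package probability machinery).
oracle_loglik <- function(X, theta, beta, tau, K) {
  cumtau <- c(0, cumsum(tau))
  ll <- 0
  for (n in seq_len(nrow(X))) for (i in seq_len(ncol(X))) {
    x <- X[n, i]
    if (is.na(x)) next
    num <- (0:K) * (theta[n] - beta[i]) - cumtau
    ll <- ll + num[x + 1L] - log(sum(exp(num - max(num)))) - max(num)
  }
  ll
}

# Brute-force maximization of the joint RSM likelihood on a tiny problem
# under the identification constraints mean(beta) = 0, sum(tau) = 0.
# Iterative grid refinement, independent of the Newton path.
oracle_grid_fit <- function(X, K, span = 3, levels = 6) {
  n <- nrow(X); I <- ncol(X)
  # free parameters: theta (n), beta[1..I-1] (last = -sum), tau[1..K-1]
  n_free <- n + (I - 1L) + (K - 1L)
  center <- rep(0, n_free)
  width <- span
  unpack <- function(p) {
    theta <- p[1:n]
    b <- p[(n + 1):(n + I - 1L)]
    beta <- c(b, -sum(b))
    t <- p[(n + I):(n + I + K - 2L)]
    tau <- c(t, -sum(t))
    list(theta = theta, beta = beta, tau = tau)
  }
  for (lev in seq_len(levels)) {
    grids <- lapply(center, function(c0) seq(c0 - width, c0 + width,
                                             length.out = 7L))
    best <- -Inf; best_p <- center
    # coordinate-wise sweep over the grid, several passes
    p <- center
    for (pass in 1:4) {
      for (j in seq_len(n_free)) {
        lls <- vapply(grids[[j]], function(v) {
          p2 <- p; p2[j] <- v
          pr <- unpack(p2)
          oracle_loglik(X, pr$theta, pr$beta, pr$tau, K)
        }, numeric(1))
        p[j] <- grids[[j]][which.max(lls)]
      }
    }
    pr <- unpack(p)
    center <- p
    width <- width / 3
  }
  pr <- unpack(center)
  pr$loglik <- oracle_loglik(X, pr$theta, pr$beta, pr$tau, K)
  pr
}

# Dedicated dichotomous-Rasch JMLE oracle (logistic model, Newton updates
# written independently of the package engine). Data must have no extreme
# persons or items.
oracle_dichotomous_fit <- function(X, tol = 1e-8, iter = 500) {
  n <- nrow(X); I <- ncol(X)
  r <- rowSums(X); s <- colSums(X)
  stopifnot(all(r > 0), all(r < I), all(s > 0), all(s < n))
  theta <- qlogis(r / I)
  beta <- -qlogis(s / n); beta <- beta - mean(beta)
  for (k in seq_len(iter)) {
    P <- plogis(outer(theta, beta, "-"))
    W <- P * (1 - P)
    dth <- (r - rowSums(P)) / rowSums(W)
    theta <- theta + pmin(pmax(dth, -1), 1)
    P <- plogis(outer(theta, beta, "-"))
    W <- P * (1 - P)
    dbe <- (colSums(P) - s) / colSums(W)
    beta <- beta + pmin(pmax(dbe, -1), 1)
    m <- mean(beta); beta <- beta - m; theta <- theta - m
    if (max(abs(c(dth, dbe))) < tol) break
  }
  list(theta = theta, beta = beta)
}
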