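#' Configuration for simulating Rating Scale Model responses
#'
#' Defaults emulate a typical single dimension of a five-point Likert
#' impulsivity questionnaire administered to a student sample: 455 persons
#' with a standard-normal trait, item difficulties evenly spread over
#' \[-2, 2\] logits, and symmetric thresholds (-1.5, -0.5, 0.5, 1.5).
#'
#' @param n_persons Number of persons.
#' @param theta_mean,theta_sd Trait distribution (logits).
#' @param item_betas Item difficulties (logits); auto-centered with a warning
#'   if their mean is not 0. Default: `n_items` equally spaced on
#'   `beta_range`.
#' @param n_items,beta_range Used only when `item_betas` is NULL.
#' @param taus Thresholds; must sum to 0 (auto-centered with a warning).
#' @param n_categories Number of response categories (length(taus) + 1).
#' @param seed Integer seed; fully determines the output.
#' @param missing_rate Probability that any response is set missing (MCAR).
#' @param random_responder_fraction Fraction of persons whose responses are
#'   replaced by uniform category draws (injected misfit).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 455L, theta_mean = 0, theta_sd = 1,
                       item_betas = NULL, n_items = 12L,
                       beta_range = c(-2, 2),
                       taus = c(-1.5, -0.5, 0.5, 1.5),
                       n_categories = length(taus) + 1L, seed = 1L,
                       missing_rate = 0, random_responder_fraction = 0) {
  if (is.null(item_betas)) {
    item_betas <- seq(beta_range[1L], beta_range[2L], length.out = n_items)
  }
  if (abs(mean(item_betas)) > 1e-8) {
    warning("item_betas auto-centered to mean 0", call. = FALSE)
    item_betas <- item_betas - mean(item_betas)
  }
  if (abs(sum(taus)) > 1e-8) {
    warning("taus auto-centered to sum 0", call. = FALSE)
    taus <- taus - mean(taus)
  }
  if (length(taus) != n_categories - 1L) {
    stop("length(taus) must equal n_categories - 1", call. = FALSE)
  }
  if (n_persons < 2L || length(item_betas) < 2L) {
    stop("need at least 2 persons and 2 items", call. = FALSE)
  }
  if (theta_sd < 0 || missing_rate < 0 || missing_rate >= 1 ||
      random_responder_fraction < 0 || random_responder_fraction > 1) {
    stop("invalid simulation configuration", call. = FALSE)
  }
  structure(
    list(n_persons = as.integer(n_persons), theta_mean = theta_mean,
         theta_sd = theta_sd, item_betas = item_betas,
         taus = taus, n_categories = as.integer(n_categories),
         seed = as.integer(seed), missing_rate = missing_rate,
         random_responder_fraction = random_responder_fraction),
    class = "sim_config"
  )
}

#' Simulate a response matrix from known Rating Scale Model parameters
#'
#' Draws person measures from Normal(theta_mean, theta_sd) and each response
#' from the model category probabilities; then (optionally) replaces a
#' fraction of persons with uniform random responders and knocks out
#' responses completely at random. A pure function of the configuration:
#' the same config (including seed) always yields the same data.
#'
#' @param config A [sim_config()].
#' @return A list with `responses` (a [response_matrix()]), `truth` (list
#'   with the generating `theta`, `beta`, `tau`) and `random_responders`
#'   (character vector of injected person ids, possibly empty).
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  beta <- config$item_betas
  tau <- config$taus
  K <- config$n_categories - 1L
  theta <- stats::rnorm(n, config$theta_mean, config$theta_sd)
  P <- .rsm_prob_array(theta, beta, tau)$P
  X <- matrix(NA_integer_, n, length(beta))
  u <- matrix(stats::runif(n * length(beta)), n)
  cum <- P[, , 1L]
  X[] <- 0L
  for (k in 1:K) {
    X[u > cum] <- k
    if (k < K) cum <- cum + P[, , k + 1L]
  }
  person_ids <- sprintf("p%03d", seq_len(n))
  item_ids <- if (!is.null(names(beta))) names(beta) else
    paste0("i", seq_along(beta))
  rm <- response_matrix(X, person_ids, item_ids, config$n_categories)
  rr <- character()
  if (config$random_responder_fraction > 0) {
    rm <- inject_random_responders(rm, config$random_responder_fraction,
                                   seed = config$seed + 1L)
    rr <- attr(rm, "injected_persons")
  }
  if (config$missing_rate > 0) {
    rm <- inject_missing(rm, config$missing_rate, seed = config$seed + 2L)
  }
  list(responses = rm,
       truth = list(theta = stats::setNames(theta, person_ids),
                    beta = stats::setNames(beta, item_ids), tau = tau),
       random_responders = rr)
}

#' Simulate a two-version (full and short form) study
#'
#' Simulates one full-form response matrix and takes the short form as a
#' column subset, so both versions share the same true person trait — the
#' common-trait structure a concordance analysis assumes. With
#' `independent_traits = TRUE` the short form is instead generated from a
#' fresh, independent trait draw (a negative control: downstream concordance
#' should collapse toward zero).
#'
#' @param config A [sim_config()]; `item_betas`/`n_items` describe the full
#'   form.
#' @param short_subset Integer indices (or item-id names) of the short-form
#'   items within the full form. Default: 4 items spread over the range.
#' @param independent_traits Break the common trait (negative control).
#' @return A list with `full` and `short` ([response_matrix()] views),
#'   `truth`, and `short_items`.
#' @export
make_two_version_study <- function(config, short_subset = NULL,
                                   independent_traits = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_responses(config)
  full <- sim$responses
  n_items <- length(config$item_betas)
  if (is.null(short_subset)) {
    short_subset <- unique(round(seq(1L, n_items, length.out = 4L)))
  }
  if (is.character(short_subset)) {
    short_subset <- match(short_subset, full$item_ids)
  }
  if (any(is.na(short_subset)) || any(short_subset < 1L) ||
      any(short_subset > n_items)) {
    stop("short_subset must index items of the full form", call. = FALSE)
  }
  short_ids <- full$item_ids[short_subset]
  if (independent_traits) {
    cfg2 <- config
    cfg2$seed <- config$seed + 10000L
    cfg2$item_betas <- config$item_betas[short_subset] -
      mean(config$item_betas[short_subset])
    sim2 <- simulate_responses(cfg2)
    short <- response_matrix(sim2$responses$responses, full$person_ids,
                             short_ids, config$n_categories)
  } else {
    short <- response_matrix(full$responses[, short_subset, drop = FALSE],
                             full$person_ids, short_ids, config$n_categories)
  }
  list(full = full, short = short, truth = sim$truth,
       short_items = short_ids)
}

#' Replace a fraction of persons with uniform random responders
#'
#' Selects `ceiling(fraction * n)` persons at random and replaces each of
#' their observed responses with a uniform draw over the categories —
#' a misfit fixture: such persons should be caught by large OUTFIT values.
#'
#' @param rm A [response_matrix()].
#' @param fraction Fraction of persons to corrupt, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The corrupted [response_matrix()], with the injected person ids
#'   in attribute `"injected_persons"`.
#' @export
inject_random_responders <- function(rm, fraction, seed = 1L) {
  stopifnot(inherits(rm, "response_matrix"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]",
                                         call. = FALSE)
  if (fraction == 0) {
    attr(rm, "injected_persons") <- character()
    return(rm)
  }
  set.seed(seed)
  n <- nrow(rm$responses)
  k <- min(ceiling(fraction * n), n)
  who <- sort(sample.int(n, k))
  m <- rm$responses
  K <- rm$n_categories - 1L
  for (p in who) {
    obs <- !is.na(m[p, ])
    m[p, obs] <- sample(0:K, sum(obs), replace = TRUE)
  }
  out <- response_matrix(m, rm$person_ids, rm$item_ids, rm$n_categories)
  attr(out, "injected_persons") <- rm$person_ids[who]
  out
}

#' Knock out responses completely at random
#'
#' Sets each observed entry to missing independently with probability `rate`
#' (missing completely at random).
#'
#' @param rm A [response_matrix()].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The [response_matrix()] with injected missingness.
#' @export
inject_missing <- function(rm, rate, seed = 1L) {
  stopifnot(inherits(rm, "response_matrix"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(rm)
  set.seed(seed)
  m <- rm$responses
  mask <- matrix(stats::runif(length(m)) < rate, nrow(m))
  m[mask] <- NA_integer_
  response_matrix(m, rm$person_ids, rm$item_ids, rm$n_categories)
}
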