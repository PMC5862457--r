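#' Standardize a vector of person measures
#'
#' Centers and scales to mean 0, SD 1. The sample (n - 1) SD is the default;
#' the population (n) SD is available since conventions differ between
#' reporting traditions. Slopes, correlations and the indices derived from
#' them are invariant to this choice.
#'
#' @param measures Numeric vector with at least 2 distinct finite values.
#' @param type `"sample"` (divide by the n-1 SD) or `"population"`.
#' @return The z-scored vector.
#' @export
standardize_measures <- function(measures, type = c("sample", "population")) {
  type <- match.arg(type)
  measures <- as.numeric(measures)
  if (length(measures) < 2L || length(unique(measures[is.finite(measures)])) < 2L) {
    stop("need at least 2 distinct values to standardize", call. = FALSE)
  }
  s <- stats::sd(measures, na.rm = TRUE)
  if (type == "population") {
    n <- sum(!is.na(measures))
    s <- s * sqrt((n - 1) / n)
  }
  (measures - mean(measures, na.rm = TRUE)) / s
}

#' Regression of full-form on short-form standardized person measures
#'
#' Ordinary least squares of the full-version z scores on the short-version
#' z scores for the same persons. Under perfect concordance the line has
#' slope 1 and intercept 0; with z-scored inputs the slope equals the Pearson
#' correlation. Pairs with a missing member (e.g. persons dropped in one of
#' the two calibrations) are excluded with a message count.
#'
#' @param z_short,z_full Equal-length paired numeric vectors (z scores of the
#'   same persons under the short and full calibration).
#' @return A list with `slope`, `intercept`, `r` (Pearson), `r_squared`, `n`.
#' @export
concordance_regression <- function(z_short, z_full) {
  if (length(z_short) != length(z_full)) {
    stop("paired vectors must have the same length (same persons)",
         call. = FALSE)
  }
  ok <- is.finite(z_short) & is.finite(z_full)
  n_drop <- sum(!ok)
  if (n_drop) message(n_drop, " pair(s) dropped for missing measures")
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  x <- z_short[ok]; y <- z_full[ok]
  coefs <- stats::coef(stats::lm(y ~ x))
  r <- stats::cor(x, y)
  list(slope = unname(coefs[2L]), intercept = unname(coefs[1L]),
       r = r, r_squared = r^2, n = sum(ok))
}

#' Reduction-in-Uncertainty index
#'
#' \deqn{RiU = 1 - \sqrt{1 - r^2}} where r is the correlation between two
#' sets of scores: the fraction of statistical uncertainty about one score
#' removed by knowing the other (one minus the coefficient of alienation).
#' r = 0 gives 0% reduction and r = 1 gives 100%. A short form is judged an
#' acceptable surrogate of the full form when it removes at least 50% of the
#' uncertainty.
#'
#' @param r Correlation coefficient(s), |r| <= 1.
#' @param threshold Concordance threshold on RiU; default 0.5.
#' @return A list with `riu` (same length as `r`) and `verdict`
#'   (`"concordant"` iff `riu >= threshold`).
#' @export
reduction_in_uncertainty <- function(r, threshold = 0.5) {
  if (any(!is.finite(r)) || any(abs(r) > 1)) {
    stop("|r| must be at most 1", call. = FALSE)
  }
  riu <- 1 - sqrt(1 - r^2)
  list(riu = riu,
       verdict = ifelse(riu >= threshold, "concordant", "not-concordant"))
}

#' Item-efficiency index of a short form
#'
#' Efficiency = (short item count / full item count) / r, where r is the
#' "diagonal" correlation between the short- and full-form scores of the
#' same dimension. Lower values mean more information per item; values at or
#' below the criterion (0.80 by default) indicate that the short form is the
#' more efficient measure. The alternative reading of the formula as the
#' item ratio multiplied by the correlation is available via `method`.
#'
#' @param n_short,n_full Item counts, `0 < n_short <= n_full`.
#' @param r Diagonal correlation, in (0, 1].
#' @param criterion Efficiency criterion; default 0.80.
#' @param method `"ratio_over_r"` (default) or `"ratio_times_r"`.
#' @return A list with `efficiency` and `verdict` (`"efficient"` iff
#'   `efficiency <= criterion`).
#' @export
efficiency_index <- function(n_short, n_full, r, criterion = 0.80,
                             method = c("ratio_over_r", "ratio_times_r")) {
  method <- match.arg(method)
  if (n_short <= 0 || n_full <= 0 || n_short > n_full) {
    stop("need 0 < n_short <= n_full", call. = FALSE)
  }
  if (!is.finite(r) || r <= 0 || r > 1) {
    stop("the diagonal correlation must be in (0, 1]", call. = FALSE)
  }
  ratio <- n_short / n_full
  eff <- if (method == "ratio_over_r") ratio / r else ratio * r
  list(efficiency = eff,
       verdict = if (eff <= criterion) "efficient" else "not-efficient")
}

#' Order preservation of shared-item difficulties
#'
#' Kendall rank correlation between the difficulties of the items common to
#' both calibrations (the short-form items, estimated once within the full
#' form and once within the short form). tau = 1 means the difficulty order
#' is fully preserved across versions.
#'
#' @param beta_full,beta_short Named numeric vectors of difficulties for the
#'   same item ids (order may differ; matched by name when named).
#' @return Kendall's tau (a single number).
#' @export
order_preservation <- function(beta_full, beta_short) {
  if (!is.null(names(beta_full)) && !is.null(names(beta_short))) {
    if (!setequal(names(beta_full), names(beta_short))) {
      stop("item-id sets differ between versions", call. = FALSE)
    }
    beta_short <- beta_short[names(beta_full)]
  } else if (length(beta_full) != length(beta_short)) {
    stop("difficulty vectors must pair the same items", call. = FALSE)
  }
  if (length(beta_full) < 3L) stop("need at least 3 shared items", call. = FALSE)
  stats::cor(beta_full, beta_short, method = "kendall")
}

#' Flag substantial gaps between adjacent items on the logit continuum
#'
#' A gap between adjacent items larger than `substantial` logits (0.5 by
#' default) marks a region of the trait the instrument does not cover.
#' Additionally, in the central region of the continuum — where most
#' respondents are located and finer discrimination matters — gaps larger
#' than `central_limit` (0.3) are flagged even if below the substantial
#' threshold.
#'
#' @param map An [item_map()] (or data frame with columns `item`, `beta`,
#'   `gap`).
#' @param substantial Gap size (logits) flagged anywhere on the continuum.
#' @param central_limit Smaller gap size flagged inside the central region.
#' @param central_region Length-2 logit interval; default `c(-1, 1)`.
#' @return A data frame with one row per flagged gap: `item_low`,
#'   `item_high`, `gap`, `flag` (`"substantial"` or `"central-region"`).
#'   Zero rows when nothing is flagged (including single-item maps).
#' @export
adjacent_gap_analysis <- function(map, substantial = 0.5,
                                  central_limit = 0.3,
                                  central_region = c(-1, 1)) {
  stopifnot(all(c("item", "beta", "gap") %in% names(map)))
  empty <- data.frame(item_low = character(), item_high = character(),
                      gap = numeric(), flag = character())
  if (nrow(map) < 2L) return(empty)
  out <- empty
  for (i in 2:nrow(map)) {
    g <- map$gap[i]
    central <- map$beta[i - 1L] >= central_region[1L] &&
      map$beta[i] <= central_region[2L]
    flag <- if (g > substantial) "substantial"
      else if (central && g > central_limit) "central-region"
      else NA_character_
    if (!is.na(flag)) {
      out <- rbind(out, data.frame(item_low = map$item[i - 1L],
                                   item_high = map$item[i],
                                   gap = g, flag = flag))
    }
  }
  out
}

#' Full-vs-short concordance analysis for one dimension
#'
#' Ties the concordance machinery together for a pair of calibrations of the
#' same dimension: standardizes the two sets of person measures, regresses
#' full on short, computes the Reduction-in-Uncertainty index and the
#' efficiency index, checks that the shared items keep their difficulty
#' order, and flags coverage gaps on the short form's item map.
#'
#' Persons flagged extreme in either calibration are excluded pairwise from
#' the regression: their measures rest on the fractional-score adjustment
#' rather than on a finite maximum-likelihood estimate.
#'
#' @param fit_full,fit_short [fit_rsm()] results for the full and short
#'   version (same persons, short items a subset of full items).
#' @param dimension Dimension name used for labeling.
#' @param riu_threshold,efficiency_criterion Verdict thresholds.
#' @param ... Passed to [adjacent_gap_analysis()].
#' @return An object of class `concordance_report`: a list with fields
#'   `dimension`, `n_pairs`, `slope`, `intercept`, `r`, `r_squared`, `riu`,
#'   `riu_verdict`, `efficiency`, `efficiency_verdict`, `order_tau`,
#'   `gap_flags` (data frame), `n_short`, `n_full`.
#' @export
concordance_report <- function(fit_full, fit_short, dimension = "dimension",
                               riu_threshold = 0.5,
                               efficiency_criterion = 0.80, ...) {
  stopifnot(inherits(fit_full, "rsm_fit"), inherits(fit_short, "rsm_fit"))
  shared <- intersect(fit_full$data$person_ids, fit_short$data$person_ids)
  th_f <- fit_full$theta[shared]
  th_s <- fit_short$theta[shared]
  ok <- !fit_full$extreme_persons[shared] & !fit_short$extreme_persons[shared]
  if (sum(!ok)) {
    message(sum(!ok), " extreme-score person(s) excluded pairwise from the ",
            dimension, " concordance regression")
  }
  z_f <- standardize_measures(th_f[ok])
  z_s <- standardize_measures(th_s[ok])
  reg <- concordance_regression(z_s, z_f)
  riu <- reduction_in_uncertainty(reg$r, threshold = riu_threshold)
  eff <- efficiency_index(length(fit_short$beta), length(fit_full$beta),
                          abs(reg$r), criterion = efficiency_criterion)
  shared_items <- intersect(names(fit_short$beta), names(fit_full$beta))
  tau_order <- if (length(shared_items) >= 3L) {
    order_preservation(fit_full$beta[shared_items],
                       fit_short$beta[shared_items])
  } else NA_real_
  gaps <- adjacent_gap_analysis(item_map(fit_short), ...)
  structure(
    list(dimension = dimension, n_pairs = reg$n,
         slope = reg$slope, intercept = reg$intercept,
         r = reg$r, r_squared = reg$r_squared,
         riu = riu$riu, riu_verdict = riu$verdict,
         efficiency = eff$efficiency, efficiency_verdict = eff$verdict,
         order_tau = tau_order, gap_flags = gaps,
         n_short = length(fit_short$beta), n_full = length(fit_full$beta)),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance report:", x$dimension, "\n")
  cat(sprintf("  %d paired persons; slope %.3f, intercept %.3f, r %.3f, R2 %.3f\n",
              x$n_pairs, x$slope, x$intercept, x$r, x$r_squared))
  cat(sprintf("  RiU %.3f (%s); efficiency %.3f (%s; %d of %d items)\n",
              x$riu, x$riu_verdict, x$efficiency, x$efficiency_verdict,
              x$n_short, x$n_full))
  cat(sprintf("  shared-item order: Kendall tau %.2f; %d gap flag(s)\n",
              x$order_tau, nrow(x$gap_flags)))
  invisible(x)
}
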