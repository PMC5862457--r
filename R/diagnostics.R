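#' Standardized response residuals
#'
#' For each observed response, \eqn{z_{ni} = (x_{ni} - E_{ni}) / \sqrt{W_{ni}}}
#' where E and W are the model-expected score and score variance at the
#' fitted parameters. Missing responses propagate as `NA`.
#'
#' @param fit An [fit_rsm()] result.
#' @return A persons-by-items numeric matrix of z residuals.
#' @export
standardized_residuals <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  X <- fit$data$responses
  ew <- .rsm_ew(.rsm_prob_array(fit$theta, fit$beta, fit$tau)$P)
  z <- (X - ew$E) / sqrt(pmax(ew$W, 1e-10))
  z[is.na(X)] <- NA_real_
  dimnames(z) <- dimnames(X)
  z
}

#' INFIT and OUTFIT mean-square fit statistics
#'
#' OUTFIT is the unweighted mean of squared standardized residuals over a
#' unit's observed responses (sensitive to unexpected responses far from the
#' unit's measure); INFIT is the information-weighted version
#' \eqn{\sum (x-E)^2 / \sum W} (sensitive to unexpected behaviour on items
#' near the person measure). Both have expectation 1 under the model.
#'
#' For the items margin, the item-total correlation is also computed: the
#' Pearson correlation between each item's scores and the person rest score
#' (total over the other items), using pairwise-complete observations. The
#' rest score avoids the self-inflation of a total that includes the item.
#'
#' @param fit An [fit_rsm()] result.
#' @param margin `"items"` or `"persons"`.
#' @return An object of class `fit_statistics`: a data frame with columns
#'   `unit`, `infit_mnsq`, `outfit_mnsq`, `classification` (see
#'   [classify_mnsq()], applied to the larger of the two mean-squares) and,
#'   for items, `item_total_correlation`.
#' @export
infit_outfit <- function(fit, margin = c("items", "persons")) {
  stopifnot(inherits(fit, "rsm_fit"))
  margin <- match.arg(margin)
  X <- fit$data$responses
  obs <- !is.na(X)
  ew <- .rsm_ew(.rsm_prob_array(fit$theta, fit$beta, fit$tau)$P)
  sq <- (X - ew$E)^2
  z2 <- sq / pmax(ew$W, 1e-10)
  sq[!obs] <- 0; z2[!obs] <- 0
  W <- ew$W * obs

  agg <- if (margin == "items") colSums else rowSums
  n_obs <- agg(obs)
  if (any(n_obs == 0L)) {
    warning("units with no observed responses get NA fit statistics",
            call. = FALSE)
  }
  outfit <- agg(z2) / pmax(n_obs, 1L)
  infit <- agg(sq) / pmax(agg(W), 1e-10)
  outfit[n_obs == 0L] <- NA_real_
  infit[n_obs == 0L] <- NA_real_

  units <- if (margin == "items") colnames(X) else rownames(X)
  res <- data.frame(unit = units,
                    infit_mnsq = unname(infit),
                    outfit_mnsq = unname(outfit),
                    classification = classify_mnsq(pmax(infit, outfit)),
                    row.names = NULL)
  if (margin == "items") {
    res$item_total_correlation <- vapply(seq_len(ncol(X)), function(j) {
      rest <- rowSums(X[, -j, drop = FALSE], na.rm = TRUE)
      ok <- obs[, j] & rowSums(obs[, -j, drop = FALSE]) > 0L
      if (sum(ok) < 3L || stats::sd(X[ok, j]) == 0 || stats::sd(rest[ok]) == 0)
        return(NA_real_)
      stats::cor(X[ok, j], rest[ok])
    }, numeric(1))
  }
  class(res) <- c("fit_statistics", "data.frame")
  attr(res, "margin") <- margin
  res
}

#' Classify a mean-square fit value into interpretation bands
#'
#' Conventional interpretation bands for INFIT/OUTFIT mean-squares:
#' values in \[0.5, 1.5\] are productive for measurement; values in
#' (1.5, 2.0\] are unproductive but not degrading; values above 2.0 indicate
#' aberrant response patterns that degrade measurement; values below 0.5
#' indicate overly deterministic (muted) response patterns. The four bands
#' partition \[0, Inf).
#'
#' @param value Nonnegative mean-square value(s); `NA` passes through.
#' @return Character vector of band labels: `"degrading"`, `"unproductive"`,
#'   `"productive"` or `"overfit-deterministic"`.
#' @export
classify_mnsq <- function(value) {
  if (any(value < 0, na.rm = TRUE)) {
    stop("mean-square values must be nonnegative", call. = FALSE)
  }
  out <- rep(NA_character_, length(value))
  out[!is.na(value) & value > 2.0] <- "degrading"
  out[!is.na(value) & value > 1.5 & value <= 2.0] <- "unproductive"
  out[!is.na(value) & value >= 0.5 & value <= 1.5] <- "productive"
  out[!is.na(value) & value < 0.5] <- "overfit-deterministic"
  out
}

#' Separation and reliability summary
#'
#' Computes, over the non-extreme units of one margin: the observed SD of
#' the measures, the root-mean-square of their standard errors (RMSE), the
#' error-adjusted "true" SD \eqn{\sqrt{\max(SD^2 - RMSE^2, 0)}}, the
#' separation reliability (adjusted variance over observed variance), the
#' separation index G = adjusted SD / RMSE, and the number of statistically
#' distinct strata (4G + 1)/3. Persons need a separation index of at least 2
#' (items at least 3) for the margin to be judged adequate.
#'
#' @param fit An [fit_rsm()] result.
#' @param margin `"persons"` or `"items"`.
#' @return An object of class `separation_summary` (a list) with fields
#'   `margin`, `n`, `observed_sd`, `rmse`, `adjusted_sd`, `reliability`,
#'   `separation_index`, `strata`, `verdict`.
#' @export
separation <- function(fit, margin = c("persons", "items")) {
  stopifnot(inherits(fit, "rsm_fit"))
  margin <- match.arg(margin)
  if (margin == "persons") {
    m <- fit$theta[!fit$extreme_persons]
    se <- fit$se_theta[!fit$extreme_persons]
    threshold <- 2
  } else {
    m <- fit$beta[!fit$extreme_items]
    se <- fit$se_beta[!fit$extreme_items]
    threshold <- 3
  }
  if (length(m) < 2L) stop("need at least 2 non-extreme units", call. = FALSE)
  obs_sd <- stats::sd(m)
  rmse <- sqrt(mean(se^2))
  adj_var <- max(obs_sd^2 - rmse^2, 0)
  adj_sd <- sqrt(adj_var)
  reliability <- if (obs_sd > 0) adj_var / obs_sd^2 else 0
  sep <- adj_sd / rmse
  structure(
    list(margin = margin, n = length(m), observed_sd = obs_sd, rmse = rmse,
         adjusted_sd = adj_sd, reliability = reliability,
         separation_index = sep, strata = (4 * sep + 1) / 3,
         verdict = if (sep < threshold) "inadequate" else "adequate"),
    class = "separation_summary"
  )
}

#' @export
print.separation_summary <- function(x, ...) {
  cat(sprintf("%s separation: G = %.2f (reliability %.2f, strata %.2f) - %s\n",
              x$margin, x$separation_index, x$reliability, x$strata,
              x$verdict))
  invisible(x)
}

#' Test information function
#'
#' The test information at trait level theta is the sum over items of the
#' model score variance, \eqn{I(\theta) = \sum_i W_i(\theta)}; its inverse
#' square root is the standard error of person measurement at that level.
#' Summing over more items can only increase information, which is why a
#' full-length instrument measures at least as precisely as any subset of
#' its items at every trait level.
#'
#' @param fit An [fit_rsm()] result (the fitted `beta` and `tau` are used).
#' @param theta_grid Trait levels (logits) at which to evaluate; default
#'   -6 to 6 in steps of 0.1.
#' @param items Optional character vector restricting to a subset of items.
#' @return An object of class `information_curve`: a data frame with columns
#'   `theta`, `information`, `se`.
#' @export
information_function <- function(fit, theta_grid = seq(-6, 6, by = 0.1),
                                 items = NULL) {
  stopifnot(inherits(fit, "rsm_fit"))
  beta <- fit$beta
  if (!is.null(items)) {
    unknown <- setdiff(items, names(beta))
    if (length(unknown)) stop("unknown items: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    beta <- beta[items]
  }
  info <- rowSums(matrix(vapply(beta, function(b)
    rsm_variance(theta_grid, b, fit$tau), numeric(length(theta_grid))),
    nrow = length(theta_grid)))
  res <- data.frame(theta = theta_grid, information = info,
                    se = 1 / sqrt(info))
  class(res) <- c("information_curve", "data.frame")
  res
}

#' Item difficulty map
#'
#' Orders items along the logit continuum by their difficulty estimates and
#' reports the gap to the previous item — the numeric content of a Wright
#' item map. Ties are broken by item id.
#'
#' @param fit An [fit_rsm()] result.
#' @return An object of class `item_map`: a data frame with columns `item`,
#'   `beta`, `gap` (logits to the previous item; `NA` for the first).
#' @export
item_map <- function(fit) {
  stopifnot(inherits(fit, "rsm_fit"))
  ord <- order(fit$beta, names(fit$beta))
  b <- fit$beta[ord]
  res <- data.frame(item = names(b), beta = unname(b),
                    gap = c(NA_real_, diff(unname(b))), row.names = NULL)
  class(res) <- c("item_map", "data.frame")
  res
}
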