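#' @title WAIC model comparison and posterior intervals
#' @name waic
NULL

logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Widely applicable information criterion
#'
#' From a draws-by-observations pointwise log-likelihood matrix:
#' `lppd_i = log mean_s exp(ll_si)`, `p_i = var_s(ll_si)`,
#' `WAIC = -2 * sum_i (lppd_i - p_i)`, with the standard error computed from
#' the between-observation variance of the pointwise WAIC contributions.
#'
#' @param pointwise_ll Numeric matrix, posterior draws in rows and
#'   observations in columns (at least 2 draws); or a `stargrid_fit`.
#' @return A list of class `stargrid_waic`: `waic`, `se`, `p_waic`, `lppd`,
#'   `n_obs`, and the per-observation contributions in `pointwise`.
#' @export
compute_waic <- function(pointwise_ll) {
  if (inherits(pointwise_ll, "stargrid_fit")) pointwise_ll <- pointwise_ll$pointwise_ll
  ll <- as.matrix(pointwise_ll)
  if (nrow(ll) < 2) stop("WAIC needs at least 2 posterior draws")
  if (any(!is.finite(ll))) stop("pointwise log-likelihood contains non-finite values")
  lppd_i <- apply(ll, 2, logmeanexp)
  p_i <- apply(ll, 2, stats::var)
  waic_i <- -2 * (lppd_i - p_i)
  n <- ncol(ll)
  structure(list(
    waic = sum(waic_i),
    se = sqrt(n * stats::var(waic_i)),
    p_waic = sum(p_i),
    lppd = sum(lppd_i),
    n_obs = n,
    pointwise = tibble::tibble(lppd = lppd_i, p_waic = p_i, waic = waic_i)
  ), class = "stargrid_waic")
}

#' @export
print.stargrid_waic <- function(x, ...) {
  cat(sprintf("WAIC %.2f (SE %.2f), pWAIC %.2f, %d observations\n",
              x$waic, x$se, x$p_waic, x$n_obs))
  invisible(x)
}

#' Compare fitted models by WAIC
#'
#' Computes WAIC per model, the difference from the best (lowest-WAIC) model
#' (`d_waic`), the standard error of that difference from the pointwise WAIC
#' contributions (`d_se`), and Akaike weights
#' `w_m = exp(-d_waic_m / 2) / sum_m' exp(-d_waic_m' / 2)`.
#'
#' @param fits Named list of `stargrid_fit` objects (or pointwise
#'   log-likelihood matrices) evaluated on the identical observation set.
#' @return A tibble sorted from best to worst with columns `model`, `waic`,
#'   `se`, `d_waic`, `d_se`, `p_waic`, `weight`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2)
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  ws <- lapply(fits, compute_waic)
  n_obs <- vapply(ws, `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1) {
    stop("models must be evaluated on identical observation sets")
  }
  waic <- vapply(ws, `[[`, numeric(1), "waic")
  best <- which.min(waic)
  d_waic <- waic - waic[best]
  d_se <- vapply(seq_along(ws), function(m) {
    if (m == best) return(NA_real_)
    diff_i <- ws[[m]]$pointwise$waic - ws[[best]]$pointwise$waic
    sqrt(n_obs[m] * stats::var(diff_i))
  }, numeric(1))
  weight <- exp(-d_waic / 2)
  weight <- weight / sum(weight)
  out <- tibble::tibble(
    model = nm,
    waic = unname(waic),
    se = unname(vapply(ws, `[[`, numeric(1), "se")),
    d_waic = unname(d_waic),
    d_se = unname(d_se),
    p_waic = unname(vapply(ws, `[[`, numeric(1), "p_waic")),
    weight = unname(weight)
  )
  dplyr::arrange(out, .data$waic)
}

#' Highest-density interval
#'
#' Shortest contiguous interval containing the requested posterior mass
#' (89% by convention here).
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass in `(0, 1)`.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, mass = 0.89) {
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  m <- max(2L, ceiling(mass * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}
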