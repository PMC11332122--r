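#' @title Hierarchical model fitting
#' @description Estimates group-level means and standard deviations plus
#'   per-participant parameters of the P/PL/PLA models. Linear-scale
#'   parameters are sampled directly; learning and attribution rates are
#'   sampled on the logit scale and mapped through the inverse logit. Two
#'   fitters share the same model: an adaptive Metropolis-within-Gibbs
#'   sampler (the reference method) and a fast MAP/Laplace empirical-Bayes
#'   fitter used for large batch runs.
#' @name fitting
NULL

rel_code <- function(relation) {
  unname(c(ingroup = 0L, outgroup = 1L, neutral = 2L)[relation])
}

# compact integer encoding of an event stream for the C++ likelihood
encode_events <- function(events) {
  mates <- events_teammates(events, NULL)
  ids <- sort(unique(c(events$player, as.integer(names(mates)))))
  K <- length(ids)
  mate <- matrix(0L, K, K)
  for (a in seq_len(K)) {
    for (m in mates[[as.character(ids[a])]] %||% integer(0)) {
      mate[a, match(m, ids)] <- 1L
    }
  }
  is_dec <- events$type == "dec"
  list(
    type = as.integer(is_dec),
    pidx = match(events$player, ids) - 1L,
    rel = rel_code(events$relation),
    act = as.integer(ifelse(is_dec, events$choice, events$action == "zap")),
    sd = ifelse(is.na(events$star_dist), 0, events$star_dist),
    td = ifelse(is.na(events$target_dist), 0, events$target_dist),
    mate = mate, K = K,
    n_dec = sum(is_dec), n_zap_turns = length(unique(events$turn[is_dec & events$choice == 1L])),
    ids = ids
  )
}

# sampling-scale active components -> full 18-value natural vector
active_to_nat <- function(theta_active, active) {
  full <- numeric(14)
  full[active] <- theta_active
  nat <- full
  r <- intersect(active, rate_idx())
  nat[r] <- stats::plogis(full[r])
  c(nat,
    (nat[7] + nat[8]) / 2, (nat[9] + nat[10]) / 2,
    (nat[11] + nat[12]) / 2, (nat[13] + nat[14]) / 2)
}

nat_matrix <- function(theta_mat, active) {
  t(apply(theta_mat, 1, active_to_nat, active = active))
}

ll_active <- function(enc, theta_active, active) {
  nat <- active_to_nat(theta_active, active)
  sg_loglik_sum(nat, enc$type, enc$pidx, enc$rel, enc$act,
                enc$sd, enc$td, enc$mate, enc$K)
}

#' Exclude participants with too few zaps
#'
#' Participants who zapped fewer than `min_zaps` times over the whole game
#' are removed before fitting (their sparse behaviour makes estimation
#' unreliable).
#'
#' @param events_list Named list of `stargrid_events` streams, one per
#'   participant.
#' @param min_zaps Minimum number of zap actions (turns on which the
#'   participant zapped) required to be retained.
#' @return A list with `data` (the retained streams) and `report` (a tibble
#'   with per-participant zap counts, opportunity counts, and the exclusion
#'   flag).
#' @export
apply_fitting_exclusions <- function(events_list, min_zaps = 1) {
  nm <- names(events_list) %||% as.character(seq_along(events_list))
  counts <- purrr::map(events_list, function(ev) {
    dec <- ev[ev$type == "dec", ]
    c(n_zaps = length(unique(dec$turn[dec$choice == 1L])),
      n_opportunities = nrow(dec))
  })
  report <- tibble::tibble(
    participant = nm,
    n_zaps = unname(vapply(counts, `[[`, numeric(1), "n_zaps")),
    n_opportunities = unname(vapply(counts, `[[`, numeric(1), "n_opportunities")),
    excluded = .data$n_zaps < min_zaps
  )
  keep <- !report$excluded
  if (!any(keep)) stop("all participants excluded (min_zaps = ", min_zaps, ")")
  list(data = stats::setNames(events_list[keep], nm[keep]), report = report)
}

nearest_pd <- function(S, eps = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  e$vectors %*% (vals * t(e$vectors))
}

#' Fit the hierarchical model
#'
#' Participants' sampling-scale parameter vectors are modelled as draws from
#' independent normal group distributions, `theta_jk ~ N(mu_k, sigma_k)`,
#' with weakly informative priors `mu_k ~ N(0, prior_mean_sd)` and
#' `sigma_k ~ half-N(0, prior_sd_scale)`.
#'
#' `method = "mcmc"` (the reference method) runs an adaptive
#' Metropolis-within-Gibbs sampler: componentwise random-walk updates of the
#' per-participant parameters (proposal scales tuned during warmup), a
#' conjugate Gibbs update of each group mean, and a slice-sampling update of
#' each group standard deviation. `method = "map"` runs an empirical-Bayes
#' EM loop (per-participant penalised optimisation alternating with
#' closed-form group updates) and represents the posterior by Laplace draws
#' around each mode; it is considerably faster but shrinks weakly identified
#' parameters towards the group mean and approximates the pointwise
#' log-likelihood draws WAIC is built from, so model comparison should use
#' the sampler.
#'
#' @param data Named list of `stargrid_events` streams (one per participant),
#'   typically after [apply_fitting_exclusions()].
#' @param variant `"P"`, `"PL"` or `"PLA"`.
#' @param method `"map"` or `"mcmc"`.
#' @param chains,iter,warmup MCMC settings (`iter` counts post-warmup
#'   iterations per chain).
#' @param n_em EM sweeps for the MAP fitter.
#' @param n_draws Posterior draws generated by the MAP fitter.
#' @param prior_mean_sd,prior_sd_scale Prior scales for group means and sds.
#' @param seed Integer seed; identical seeds and settings give identical fits.
#' @return A `stargrid_fit` object holding sampling-scale and natural-scale
#'   group-level draws, per-participant draws, the per-draw pointwise
#'   log-likelihood matrix, and split-Rhat diagnostics (MCMC only).
#' @export
fit_hierarchical <- function(data, variant = c("PLA", "PL", "P"),
                             method = c("map", "mcmc"),
                             chains = 2, iter = 500, warmup = 500,
                             n_em = 4, n_draws = 400,
                             prior_mean_sd = 2.5, prior_sd_scale = 1,
                             seed = 1) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  stopifnot(length(data) >= 1)
  enc_list <- lapply(data, encode_events)
  n_dec <- vapply(enc_list, `[[`, numeric(1), "n_dec")
  if (any(n_dec == 0)) stop("every participant needs at least one zap opportunity")
  fit <- if (method == "map") {
    fit_map(enc_list, variant, n_em = n_em, n_draws = n_draws,
            prior_mean_sd = prior_mean_sd, prior_sd_scale = prior_sd_scale,
            seed = seed)
  } else {
    fit_mcmc(enc_list, variant, chains = chains, iter = iter, warmup = warmup,
             prior_mean_sd = prior_mean_sd, prior_sd_scale = prior_sd_scale,
             seed = seed)
  }
  fit$participants <- names(data) %||% as.character(seq_along(data))
  fit$obs_participant <- rep(fit$participants, times = n_dec)
  fit$variant <- variant
  fit$method <- method
  structure(fit, class = "stargrid_fit")
}

fit_map <- function(enc_list, variant, n_em, n_draws,
                    prior_mean_sd, prior_sd_scale, seed, sd_floor = 0.05) {
  set.seed(seed)
  active <- active_idx(variant)
  p <- length(active)
  J <- length(enc_list)
  mu <- numeric(p)
  sig <- rep(0.75, p)
  theta <- matrix(0, J, p)
  V <- matrix(0.5, J, p)
  Hinv <- vector("list", J)

  for (sweep in seq_len(n_em)) {
    for (j in seq_len(J)) {
      enc <- enc_list[[j]]
      obj <- function(th) {
        -(ll_active(enc, th, active) +
            sum(stats::dnorm(th, mu, sig, log = TRUE)))
      }
      opt <- stats::optim(theta[j, ], obj, method = "BFGS",
                          control = list(maxit = 300, reltol = 1e-10))
      theta[j, ] <- opt$par
      H <- stats::optimHess(opt$par, obj)
      Hi <- tryCatch(solve(nearest_pd(H, 1e-6)), error = function(e) NULL)
      if (is.null(Hi) || any(!is.finite(diag(Hi)))) {
        Hi <- diag(rep(0.25, p))
      }
      Hinv[[j]] <- nearest_pd(Hi)
      V[j, ] <- pmax(diag(Hinv[[j]]), 1e-8)
    }
    prec <- J / sig^2 + 1 / prior_mean_sd^2
    mu <- (colSums(theta) / sig^2) / prec
    S <- colSums((theta - rep(mu, each = J))^2) + colSums(V)
    s2 <- prior_sd_scale^2 * (-J + sqrt(J^2 + 4 * S / prior_sd_scale^2)) / 2
    sig <- sqrt(pmax(s2, sd_floor^2))
  }

  se_mu <- sqrt((sig^2 + colMeans(V)) / J)
  mu_draws <- matrix(stats::rnorm(n_draws * p), n_draws, p)
  mu_draws <- sweep(sweep(mu_draws, 2, se_mu, "*"), 2, mu, "+")
  sig_draws <- matrix(rep(sig, each = n_draws), n_draws, p)

  theta_draws <- array(0, c(n_draws, J, p))
  pointwise <- matrix(NA_real_, n_draws, sum(vapply(enc_list, `[[`, numeric(1), "n_dec")))
  col0 <- 0L
  for (j in seq_len(J)) {
    L <- chol(Hinv[[j]])
    z <- matrix(stats::rnorm(n_draws * p), n_draws, p)
    td <- z %*% L
    td <- sweep(td, 2, theta[j, ], "+")
    theta_draws[, j, ] <- td
    nd <- nat_active_matrix(td, active)
    enc <- enc_list[[j]]
    ll <- sg_loglik_draws(nd, enc$type, enc$pidx, enc$rel, enc$act,
                          enc$sd, enc$td, enc$mate, enc$K)
    pointwise[, col0 + seq_len(enc$n_dec)] <- ll
    col0 <- col0 + enc$n_dec
  }

  list(active = active,
       mu_draws = mu_draws, sigma_draws = sig_draws, theta_draws = theta_draws,
       mu_hat = mu, sigma_hat = sig, theta_hat = theta,
       pointwise_ll = pointwise, rhat = NULL)
}

# matrix version of active_to_nat (rows = draws)
nat_active_matrix <- function(theta_mat, active) {
  out <- matrix(0, nrow(theta_mat), 18)
  out[, active] <- theta_mat
  r <- intersect(active, rate_idx())
  out[, r] <- stats::plogis(out[, r])
  out[, 15] <- (out[, 7] + out[, 8]) / 2
  out[, 16] <- (out[, 9] + out[, 10]) / 2
  out[, 17] <- (out[, 11] + out[, 12]) / 2
  out[, 18] <- (out[, 13] + out[, 14]) / 2
  out
}

# univariate slice sampler (stepping out), used for group sds on the log scale
slice1 <- function(logf, x0, w = 0.5, max_steps = 50) {
  y <- logf(x0) - stats::rexp(1)
  u <- stats::runif(1)
  lo <- x0 - w * u
  hi <- lo + w
  k <- max_steps
  while (k > 0 && logf(lo) > y) { lo <- lo - w; k <- k - 1 }
  k <- max_steps
  while (k > 0 && logf(hi) > y) { hi <- hi + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

fit_mcmc <- function(enc_list, variant, chains, iter, warmup,
                     prior_mean_sd, prior_sd_scale, seed) {
  stopifnot(chains >= 2)
  active <- active_idx(variant)
  p <- length(active)
  J <- length(enc_list)
  n_dec <- vapply(enc_list, `[[`, numeric(1), "n_dec")
  S_keep <- iter
  total <- chains * S_keep

  mu_draws <- matrix(NA_real_, total, p)
  sig_draws <- matrix(NA_real_, total, p)
  theta_draws <- array(NA_real_, c(total, J, p))
  pointwise <- matrix(NA_real_, total, sum(n_dec))
  mu_by_chain <- array(NA_real_, c(S_keep, chains, p))
  sig_by_chain <- array(NA_real_, c(S_keep, chains, p))

  for (ch in seq_len(chains)) {
    set.seed((seed + 104729L * ch) %% .Machine$integer.max)
    theta <- matrix(0, J, p)
    mu <- numeric(p)
    sig <- rep(0.5, p)
    prop <- matrix(0.3, J, p)
    shift_prop <- rep(0.3, p)
    scale_prop <- rep(0.3, p)
    ll_cur <- sg_ll_batch(enc_list, theta, active)
    for (it in seq_len(warmup + iter)) {
      adapting <- it <= warmup
      a_t <- 1 / sqrt(max(it, 5))
      sw <- sg_sweep(enc_list, theta, ll_cur, mu, sig, prop, active,
                     adapting, a_t)
      theta <- sw$theta
      ll_cur <- sw$ll
      prop <- sw$prop
      # joint shift of a group mean and every participant deviation: the
      # group-prior terms cancel, so acceptance is driven by the aggregate
      # likelihood tilt -- this is what mixes weakly identified group means
      for (k in seq_len(p)) {
        dlt <- stats::rnorm(1, 0, shift_prop[k])
        thp <- theta
        thp[, k] <- thp[, k] + dlt
        llp <- sg_ll_batch(enc_list, thp, active)
        d <- sum(llp - ll_cur) +
          stats::dnorm(mu[k] + dlt, 0, prior_mean_sd, log = TRUE) -
          stats::dnorm(mu[k], 0, prior_mean_sd, log = TRUE)
        acc <- is.finite(d) && log(stats::runif(1)) < d
        if (acc) {
          theta <- thp
          ll_cur <- llp
          mu[k] <- mu[k] + dlt
        }
        if (adapting) {
          shift_prop[k] <- min(max(shift_prop[k] *
                                     exp(a_t * ((if (acc) 1 else 0) - 0.3)),
                                   1e-3), 5)
        }
      }
      # joint rescale of a group sd and every participant deviation (the
      # funnel direction): sigma_k' = sigma_k e^c, dev' = dev e^c; the
      # group-prior density change reduces to the +c Jacobian term
      for (k in seq_len(p)) {
        cc <- stats::rnorm(1, 0, scale_prop[k])
        sigp <- sig[k] * exp(cc)
        thp <- theta
        thp[, k] <- mu[k] + (theta[, k] - mu[k]) * exp(cc)
        llp <- sg_ll_batch(enc_list, thp, active)
        d <- sum(llp - ll_cur) + cc - (sigp^2 - sig[k]^2) / (2 * prior_sd_scale^2)
        acc <- is.finite(d) && log(stats::runif(1)) < d
        if (acc) {
          theta <- thp
          ll_cur <- llp
          sig[k] <- sigp
        }
        if (adapting) {
          scale_prop[k] <- min(max(scale_prop[k] *
                                     exp(a_t * ((if (acc) 1 else 0) - 0.3)),
                                   1e-3), 3)
        }
      }
      # the bias enters every decision together with one of the two group
      # priors, so only the sums bias+prior_in and bias+prior_out are data
      # identified; this likelihood-invariant move (bias up, both priors
      # down, for the group mean and every participant) samples the null
      # direction from the mu priors directly
      if (all(1:3 %in% active)) {
        dlt <- stats::rnorm(1, 0, 0.5)
        d <- stats::dnorm(mu[1] + dlt, 0, prior_mean_sd, log = TRUE) +
          stats::dnorm(mu[2] - dlt, 0, prior_mean_sd, log = TRUE) +
          stats::dnorm(mu[3] - dlt, 0, prior_mean_sd, log = TRUE) -
          stats::dnorm(mu[1], 0, prior_mean_sd, log = TRUE) -
          stats::dnorm(mu[2], 0, prior_mean_sd, log = TRUE) -
          stats::dnorm(mu[3], 0, prior_mean_sd, log = TRUE)
        if (log(stats::runif(1)) < d) {
          mu[1] <- mu[1] + dlt
          mu[2] <- mu[2] - dlt
          mu[3] <- mu[3] - dlt
          theta[, 1] <- theta[, 1] + dlt
          theta[, 2] <- theta[, 2] - dlt
          theta[, 3] <- theta[, 3] - dlt
        }
      }
      for (k in seq_len(p)) {
        prec <- J / sig[k]^2 + 1 / prior_mean_sd^2
        mu[k] <- stats::rnorm(1, (sum(theta[, k]) / sig[k]^2) / prec, sqrt(1 / prec))
        ss <- sum((theta[, k] - mu[k])^2)
        logf <- function(u) {
          s <- exp(u)
          (1 - J) * u - ss / (2 * s^2) - s^2 / (2 * prior_sd_scale^2)
        }
        sig[k] <- exp(slice1(logf, log(sig[k])))
        sig[k] <- max(sig[k], 1e-3)
      }
      if (!adapting) {
        s <- it - warmup
        row <- (ch - 1L) * S_keep + s
        mu_draws[row, ] <- mu
        sig_draws[row, ] <- sig
        theta_draws[row, , ] <- theta
        mu_by_chain[s, ch, ] <- mu
        sig_by_chain[s, ch, ] <- sig
        col0 <- 0L
        for (j in seq_len(J)) {
          enc <- enc_list[[j]]
          nat <- active_to_nat(theta[j, ], active)
          pointwise[row, col0 + seq_len(enc$n_dec)] <-
            sg_loglik_pointwise(nat, enc$type, enc$pidx, enc$rel, enc$act,
                                enc$sd, enc$td, enc$mate, enc$K)
          col0 <- col0 + enc$n_dec
        }
      }
    }
  }

  rhat <- c(
    stats::setNames(vapply(seq_len(p), function(k) split_rhat(mu_by_chain[, , k]),
                           numeric(1)),
                    paste0("mu_", param_names()[active])),
    stats::setNames(vapply(seq_len(p), function(k) split_rhat(sig_by_chain[, , k]),
                           numeric(1)),
                    paste0("sigma_", param_names()[active]))
  )
  if (any(rhat > 1.05, na.rm = TRUE)) {
    warning("some split-Rhat values exceed 1.05; inspect fit$rhat")
  }

  list(active = active,
       mu_draws = mu_draws, sigma_draws = sig_draws, theta_draws = theta_draws,
       mu_hat = colMeans(mu_draws), sigma_hat = colMeans(sig_draws),
       theta_hat = apply(theta_draws, c(2, 3), mean),
       pointwise_ll = pointwise, rhat = rhat)
}

#' Rank-normalised split-Rhat
#'
#' @param draws An iterations-by-chains matrix of draws of one quantity.
#' @return The split-Rhat statistic (values near 1 indicate convergence).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- n %/% 2
  if (half < 2) return(NA_real_)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  r <- matrix(rank(split, ties.method = "average"), nrow(split), ncol(split))
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  m <- ncol(z)
  nn <- nrow(z)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# natural-scale group-mean draws (S x 14), inactive parameters fixed at 0
group_natural_draws <- function(fit) {
  S <- nrow(fit$mu_draws)
  out <- matrix(0, S, 14, dimnames = list(NULL, param_names()))
  out[, fit$active] <- fit$mu_draws
  r <- intersect(fit$active, rate_idx())
  out[, r] <- stats::plogis(out[, r, drop = FALSE])
  out
}

#' @export
print.stargrid_fit <- function(x, ...) {
  cat(sprintf("<stargrid_fit> variant %s, method %s: %d participants, %d draws\n",
              x$variant, x$method, length(x$participants), nrow(x$mu_draws)))
  if (!is.null(x$rhat)) {
    cat(sprintf("  max split-Rhat: %.3f\n", max(x$rhat, na.rm = TRUE)))
  }
  invisible(x)
}
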