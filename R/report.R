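#' @title Reporting and orchestration
#' @name reporting
NULL

#' Summarise group-level posteriors
#'
#' One row per group-level parameter with natural-scale mean, median, sd,
#' 89% HDI and (for MCMC fits) split-Rhat of the group mean. Parameters a
#' variant does not include are omitted.
#'
#' @param fit A `stargrid_fit`.
#' @param mass HDI mass.
#' @return A tibble with columns `parameter`, `mean`, `median`, `sd`,
#'   `rhat`, `hdi_lower`, `hdi_upper`, `type`.
#' @export
summarize_posterior <- function(fit, mass = 0.89) {
  nat <- group_natural_draws(fit)[, fit$active, drop = FALSE]
  nms <- param_names()[fit$active]
  his <- apply(nat, 2, hdi, mass = mass)
  rhat <- rep(NA_real_, length(nms))
  if (!is.null(fit$rhat)) {
    rhat <- unname(fit$rhat[paste0("mu_", nms)])
  }
  tibble::tibble(
    parameter = nms,
    mean = unname(colMeans(nat)),
    median = unname(apply(nat, 2, stats::median)),
    sd = unname(apply(nat, 2, stats::sd)),
    rhat = rhat,
    hdi_lower = unname(his[1, ]),
    hdi_upper = unname(his[2, ]),
    type = ifelse(seq_along(param_names())[fit$active] %in% rate_idx(),
                  "rate", "linear")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname summarize_posterior
#' @param x A `stargrid_fit`.
#' @param ... Passed to [summarize_posterior()].
#' @export
tidy.stargrid_fit <- function(x, ...) summarize_posterior(x, ...)

#' One-row fit summary
#'
#' @param x A `stargrid_fit`.
#' @param ... Unused.
#' @return A tibble with WAIC, its standard error, the effective number of
#'   parameters, the log pointwise predictive density, and fit metadata.
#' @export
glance.stargrid_fit <- function(x, ...) {
  w <- compute_waic(x)
  tibble::tibble(
    variant = x$variant, method = x$method,
    n_participants = length(x$participants), n_obs = w$n_obs,
    waic = w$waic, se = w$se, p_waic = w$p_waic, lppd = w$lppd,
    max_rhat = if (is.null(x$rhat)) NA_real_ else max(x$rhat, na.rm = TRUE)
  )
}

#' Score a fit against the generating truth
#'
#' For every group-level parameter of the fitted variant: the generating
#' value (natural scale), the posterior mean, the absolute error, the 89%
#' HDI and whether it covers the truth.
#'
#' @param study A `stargrid_study` (carries the generating parameters).
#' @param fit A `stargrid_fit` estimated on (a subset of) that study.
#' @param mass HDI mass.
#' @return A tibble of class `stargrid_recovery`.
#' @export
recovery_report <- function(study, fit, mass = 0.89) {
  if (!all(fit$participants %in% study$participants$participant)) {
    stop("fit contains participants absent from the study")
  }
  summ <- summarize_posterior(fit, mass = mass)
  truth_all <- study$truth$group_mean_natural
  summ$truth <- unname(truth_all[summ$parameter])
  summ$abs_error <- abs(summ$mean - summ$truth)
  summ$covered <- summ$truth >= summ$hdi_lower & summ$truth <= summ$hdi_upper
  out <- dplyr::select(summ, "parameter", "type", "truth", estimate = "mean",
                       "abs_error", "hdi_lower", "hdi_upper", "covered")
  class(out) <- c("stargrid_recovery", class(out))
  out
}

#' Run the full synthetic pipeline
#'
#' Simulate a study, apply the fitting exclusions, fit the requested model
#' variants, compare them by WAIC, and score parameter recovery for the
#' generating variant. Artifacts (CSV tables and a JSON manifest) are
#' written to `out_dir` when given.
#'
#' @param n_participants Simulated cohort size.
#' @param variants Model variants to fit and compare.
#' @param method Fitting method (see [fit_hierarchical()]).
#' @param n_turns Rounds per game.
#' @param seed Integer seed controlling the whole run.
#' @param out_dir Optional output directory.
#' @param ... Further arguments passed to [fit_hierarchical()].
#' @return A list with `study`, `exclusions`, `fits`, `comparison`,
#'   `recovery`, and `manifest`.
#' @export
pipeline_run <- function(n_participants = 20, variants = c("P", "PL", "PLA"),
                         method = "map", n_turns = 100, seed = 1,
                         out_dir = NULL, ...) {
  study <- simulate_study(n_participants, n_turns = n_turns, seed = seed)
  excl <- apply_fitting_exclusions(study$events)
  fits <- stats::setNames(lapply(variants, function(v) {
    fit_hierarchical(excl$data, variant = v, method = method, seed = seed, ...)
  }), variants)
  comparison <- if (length(fits) >= 2) compare_models(fits) else NULL
  gen_variant <- study$manifest$variant
  recovery <- if (gen_variant %in% names(fits)) {
    recovery_report(study, fits[[gen_variant]])
  } else NULL
  manifest <- c(study$manifest,
                list(method = method, variants = variants, fit_seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(excl$report, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    if (!is.null(comparison)) {
      utils::write.csv(comparison, file.path(out_dir, "model_comparison.csv"),
                       row.names = FALSE)
    }
    if (!is.null(recovery)) {
      utils::write.csv(recovery, file.path(out_dir, "recovery.csv"),
                       row.names = FALSE)
    }
    for (v in names(fits)) {
      utils::write.csv(summarize_posterior(fits[[v]]),
                       file.path(out_dir, paste0("posterior_", v, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(study = study, exclusions = excl$report, fits = fits,
       comparison = comparison, recovery = recovery, manifest = manifest)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot belief trajectories of a replay
#'
#' Mean learned zap belief over time, by the tracked players' scripted
#' behaviour (zapper vs avoider).
#'
#' @param object A `stargrid_replay`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stargrid_replay <- function(object, ...) {
  traj <- dplyr::summarise(
    dplyr::group_by(object$trajectories, .data$turn, .data$behavior),
    belief = mean(.data$belief), .groups = "drop"
  )
  ggplot2::ggplot(traj, ggplot2::aes(.data$turn, .data$belief,
                                     colour = .data$behavior)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "turn", y = "belief target zaps", colour = "bot type",
                  title = paste("Learned zap beliefs,", object$variant, "model")) +
    ggplot2::theme_minimal()
}

#' Plot group-level posterior intervals
#'
#' @param object A `stargrid_fit`.
#' @param ... Passed to [summarize_posterior()].
#' @return A ggplot of posterior means with 89% HDIs.
#' @export
autoplot.stargrid_fit <- function(object, ...) {
  s <- summarize_posterior(object, ...)
  ggplot2::ggplot(s, ggplot2::aes(.data$mean, stats::reorder(.data$parameter, .data$mean))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hdi_lower,
                                         xmax = .data$hdi_upper), height = 0.2) +
    ggplot2::labs(x = "posterior mean (89% HDI)", y = NULL,
                  title = paste("Group-level parameters,", object$variant, "model")) +
    ggplot2::theme_minimal()
}

#' Plot zap rates by relation and bot behaviour
#'
#' @param rates A tibble from [zap_rate()] or [time_binned_rates()].
#' @return A ggplot bar chart (facetted by bin when present).
#' @export
plot_zap_rates <- function(rates) {
  p <- ggplot2::ggplot(rates, ggplot2::aes(.data$relation, .data$rate,
                                           fill = .data$behavior)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "zap rate", fill = "bot type") +
    ggplot2::theme_minimal()
  if ("bin" %in% names(rates)) p <- p + ggplot2::facet_wrap(~bin)
  p
}
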