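#' Parameters of the zap decision and learning model
#'
#' Bundles every free parameter of the trial-by-trial social-learning model:
#' the logistic decision rule (a zapping bias, group-identity priors, and
#' weights on distance-to-star, distance-to-target and the learned belief that
#' the target zaps), the per-player learning rates, and the group-level
#' attribution rates that propagate one player's observed behaviour to their
#' teammate's belief.
#'
#' Linear-scale parameters (`bias`, `prior_in`, `prior_out`, `w_star`,
#' `w_target`, `w_zap`) are unconstrained reals; learning and attribution
#' rates live in `[0, 1]`. Targets with a `neutral` relation (no team) use a
#' single shared learning/attribution rate pair, which defaults to the mean of
#' the ingroup and outgroup rates.
#'
#' @param bias Baseline inclination to zap (logit scale).
#' @param prior_in,prior_out Additive logit-scale prior for ingroup/outgroup
#'   targets; the prior term is 0 for neutral targets.
#' @param w_star Weight on the (scaled) distance from the decider to the
#'   nearest star.
#' @param w_target Weight on the (scaled) distance from the decider to the
#'   candidate target.
#' @param w_zap Weight on the current belief that the target is a zapper.
#' @param lr_zap_in,lr_zap_out Learning rate applied when an ingroup/outgroup
#'   player is observed zapping.
#' @param lr_avoid_in,lr_avoid_out Learning rate applied when an
#'   ingroup/outgroup player is observed avoiding.
#' @param at_zap_in,at_zap_out Attribution rate propagating an observed zap to
#'   the actor's teammates.
#' @param at_avoid_in,at_avoid_out Attribution rate propagating an observed
#'   avoidance to the actor's teammates.
#' @param lr_zap_neutral,lr_avoid_neutral,at_zap_neutral,at_avoid_neutral
#'   Rates used for neutral-relation players; `NULL` means the mean of the
#'   corresponding in/out pair.
#'
#' @return A `stargrid_params` list.
#' @export
#' @examples
#' model_params(bias = -1, prior_out = 0.5, lr_zap_out = 0.8)
model_params <- function(bias = 0, prior_in = 0, prior_out = 0,
                         w_star = 0, w_target = 0, w_zap = 0,
                         lr_zap_in = 0, lr_zap_out = 0,
                         lr_avoid_in = 0, lr_avoid_out = 0,
                         at_zap_in = 0, at_zap_out = 0,
                         at_avoid_in = 0, at_avoid_out = 0,
                         lr_zap_neutral = NULL, lr_avoid_neutral = NULL,
                         at_zap_neutral = NULL, at_avoid_neutral = NULL) {
  p <- list(
    bias = bias, prior_in = prior_in, prior_out = prior_out,
    w_star = w_star, w_target = w_target, w_zap = w_zap,
    lr_zap_in = lr_zap_in, lr_zap_out = lr_zap_out,
    lr_avoid_in = lr_avoid_in, lr_avoid_out = lr_avoid_out,
    at_zap_in = at_zap_in, at_zap_out = at_zap_out,
    at_avoid_in = at_avoid_in, at_avoid_out = at_avoid_out
  )
  linear <- unlist(p[1:6])
  if (any(!is.finite(linear))) stop("linear parameters must be finite")
  rates <- unlist(p[7:14])
  if (any(rates < 0 | rates > 1)) stop("learning/attribution rates must lie in [0, 1]")
  p$lr_zap_neutral <- lr_zap_neutral %||% mean(c(lr_zap_in, lr_zap_out))
  p$lr_avoid_neutral <- lr_avoid_neutral %||% mean(c(lr_avoid_in, lr_avoid_out))
  p$at_zap_neutral <- at_zap_neutral %||% mean(c(at_zap_in, at_zap_out))
  p$at_avoid_neutral <- at_avoid_neutral %||% mean(c(at_avoid_in, at_avoid_out))
  structure(p, class = "stargrid_params")
}

#' @export
print.stargrid_params <- function(x, ...) {
  cat("<stargrid_params>\n")
  v <- unlist(x[param_names()])
  print(round(v, 4))
  invisible(x)
}

#' Model variants
#'
#' `P` uses priors only (all learning and attribution rates forced to 0);
#' `PL` adds per-player learning (attribution rates forced to 0); `PLA` is
#' the full prior + learning + attribution model.
#'
#' @return Character vector of the variant names.
#' @export
model_variants <- function() c("P", "PL", "PLA")

#' Force a parameter set to respect a model variant
#'
#' @param params A [model_params()] object.
#' @param variant One of `"P"`, `"PL"`, `"PLA"`.
#' @return A `stargrid_params` with the rates the variant excludes set to 0.
#' @export
variant_params <- function(params, variant = c("PLA", "PL", "P")) {
  variant <- match.arg(variant)
  if (variant %in% c("P", "PL")) {
    for (nm in grep("^at_", names(params), value = TRUE)) params[[nm]] <- 0
  }
  if (variant == "P") {
    for (nm in grep("^lr_", names(params), value = TRUE)) params[[nm]] <- 0
  }
  params
}

# canonical ordering of the 14 fitted parameters
param_names <- function() {
  c("bias", "prior_in", "prior_out", "w_star", "w_target", "w_zap",
    "lr_zap_in", "lr_zap_out", "lr_avoid_in", "lr_avoid_out",
    "at_zap_in", "at_zap_out", "at_avoid_in", "at_avoid_out")
}

# indices of rate parameters within param_names()
rate_idx <- function() 7:14

# parameters a variant actually fits
active_idx <- function(variant) {
  switch(variant, P = 1:6, PL = 1:10, PLA = 1:14,
         stop("unknown variant: ", variant))
}

#' Convert between sampling scale and natural scale
#'
#' Linear parameters are sampled directly; rate parameters are sampled on the
#' logit scale and mapped through the inverse logit, so the natural scale is
#' the probability scale.
#'
#' @param theta Numeric vector (or matrix with 14 columns) on the sampling
#'   scale, ordered as `param_names()`.
#' @return The same object on the natural scale.
#' @export
to_natural <- function(theta) {
  if (is.matrix(theta)) {
    theta[, rate_idx()] <- stats::plogis(theta[, rate_idx()])
  } else {
    theta[rate_idx()] <- stats::plogis(theta[rate_idx()])
  }
  theta
}

#' @rdname to_natural
#' @param natural Numeric vector/matrix on the natural scale.
#' @export
to_sampling <- function(natural) {
  if (is.matrix(natural)) {
    natural[, rate_idx()] <- stats::qlogis(pmin(pmax(natural[, rate_idx()], 1e-6), 1 - 1e-6))
  } else {
    natural[rate_idx()] <- stats::qlogis(pmin(pmax(natural[rate_idx()], 1e-6), 1 - 1e-6))
  }
  natural
}

#' Build a parameter object from a natural-scale vector
#'
#' @param v Numeric vector of the 14 model parameters in the order of
#'   `param_names()` (rates on the probability scale).
#' @return A [model_params()] object.
#' @export
params_from_vector <- function(v) {
  v <- as.list(v)
  names(v) <- param_names()
  do.call(model_params, v)
}

# stargrid_params -> natural 14-vector (+ 4 neutral rates appended)
params_to_vector <- function(params, neutral = FALSE) {
  v <- unlist(params[param_names()])
  if (neutral) {
    v <- c(v, unlist(params[c("lr_zap_neutral", "lr_avoid_neutral",
                              "at_zap_neutral", "at_avoid_neutral")]))
  }
  unname(v)
}

# look up the learning/attribution rate for an observation
lookup_rate <- function(params, kind, action, relation) {
  suffix <- switch(relation, ingroup = "in", outgroup = "out",
                   neutral = "neutral",
                   stop("unknown relation: ", relation))
  params[[paste0(kind, "_", action, "_", suffix)]]
}
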