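# Composite-likelihood demographic fitting of an observed SFS, with AIC
# model selection over four candidate histories.

#' Candidate demographic models for SFS fitting
#'
#' Four one-population models: `"equilibrium"` (one parameter, N);
#' `"instantaneous_change"` and `"exponential_change"` (Nanc, Ncur, T); and
#' `"instantaneous_bottleneck"` (Nanc, intensity, T). Search ranges are
#' uniform 100..500,000 diploids for sizes, uniform 100..10,000 generations
#' for times, and log-uniform 1e-5..2 for the bottleneck intensity.
#'
#' @param model_id Model name.
#' @return A `demographic_model_spec` with parameter names, bounds, and `k`.
#' @export
demographic_model <- function(model_id = c("equilibrium",
                                           "instantaneous_change",
                                           "exponential_change",
                                           "instantaneous_bottleneck")) {
  model_id <- match.arg(model_id)
  size_b <- c(100, 5e5)
  time_b <- c(100, 1e4)
  int_b <- c(1e-5, 2)
  par <- switch(model_id,
    equilibrium = list(n = size_b),
    instantaneous_change = list(n_anc = size_b, n_cur = size_b, t = time_b),
    exponential_change = list(n_anc = size_b, n_cur = size_b, t = time_b),
    instantaneous_bottleneck = list(n_anc = size_b, intensity = int_b,
                                    t = time_b))
  structure(list(model_id = model_id, bounds = par, k = length(par),
                 log_scale = names(par) %in% c("n", "n_anc", "n_cur",
                                               "intensity", "t")),
            class = "demographic_model_spec")
}

#' Map model parameters onto a demography and expected SFS
#'
#' @param spec A [demographic_model()].
#' @param params Named parameter vector within the model's bounds.
#' @param n_hap Sample size (haplotypes).
#' @return An `expected_sfs`.
#' @export
expected_sfs_model <- function(spec, params, n_hap = 20) {
  b <- spec$bounds
  for (nm in names(b))
    if (params[[nm]] < b[[nm]][1] * (1 - 1e-9) ||
        params[[nm]] > b[[nm]][2] * (1 + 1e-9))
      abort(sprintf("parameter %s out of bounds", nm))
  d <- model_demography(spec, params)
  expected_sfs_pk(d, n_hap = n_hap)
}

model_demography <- function(spec, params) {
  p <- as.list(params)
  switch(spec$model_id,
    equilibrium = demog_constant(p$n),
    instantaneous_change = demog_step(p$n_anc, p$n_cur, p$t),
    exponential_change = demog_exponential(p$n_anc, p$n_cur, p$t),
    instantaneous_bottleneck = demog_bottleneck(p$n_anc, p$intensity, p$t))
}

#' Multinomial composite log-likelihood of an observed SFS
#'
#' Sites are treated as independent draws over SFS classes. With
#' `include_monomorphic`, the polymorphic class probabilities are
#' `mu * length_b` (expected branch length subtending `b`) and the zero
#' class absorbs the remainder, making absolute sizes identifiable; without
#' it, only the relative shape `p_b` is used.
#'
#' @param obs An [sfs()].
#' @param expected An `expected_sfs` (same `n_hap`).
#' @param include_monomorphic Use the monomorphic class (requires `mu`).
#' @param mu Mutation rate per site per generation.
#' @return Log-likelihood (may be `-Inf` if an observed class has zero
#'   expected probability).
#' @export
composite_loglik <- function(obs, expected, include_monomorphic = TRUE,
                             mu = 1e-8) {
  if (obs$n_hap != expected$n_hap) abort("sample size mismatch")
  if (obs$folded) abort("fitting uses the unfolded SFS")
  o_poly <- segregating_counts(obs)
  if (sum(o_poly) == 0) abort("empty SFS")
  p_poly <- if (include_monomorphic) mu * expected$length else expected$p
  if (any(o_poly > 0 & p_poly <= 0)) {
    warn("observed class with zero expected probability")
    return(-Inf)
  }
  ll <- sum(ifelse(o_poly > 0, o_poly * log(p_poly), 0))
  if (include_monomorphic) {
    p0 <- 1 - sum(mu * expected$length)
    if (p0 <= 0) return(-Inf)
    o0 <- obs$counts[1] + obs$counts[obs$n_hap + 1]
    ll <- ll + o0 * log(p0)
  }
  ll
}

#' Akaike information criterion
#'
#' `penalty * k - 2 * lnL`; `penalty = 2` is the standard AIC, `penalty = 25`
#' the stricter variant used for model choice on partially linked SNPs.
#'
#' @param k Number of free parameters.
#' @param lnl Maximised log-likelihood.
#' @param penalty Penalty multiplier per parameter.
#' @export
aic <- function(k, lnl, penalty = 2) {
  stopifnot(k >= 0)
  penalty * k - 2 * lnl
}

#' Fit one demographic model to an observed SFS
#'
#' Bounded multistart maximisation of [composite_loglik()], deterministic
#' given `seed`. Sizes, times and intensities are optimised on log scale.
#'
#' @param obs An [sfs()].
#' @param spec A [demographic_model()] (or model name).
#' @param n_restarts Number of random restarts.
#' @param seed Integer seed.
#' @param include_monomorphic Include the zero class (see
#'   [composite_loglik()]).
#' @param mu Mutation rate per site per generation.
#' @return A `demog_fit` with estimates, `lnl`, `l10`, `aic`, `aic25`.
#' @export
fit_sfs_model <- function(obs, spec, n_restarts = 50, seed = 1,
                          include_monomorphic = TRUE, mu = 1e-8) {
  if (is.character(spec)) spec <- demographic_model(spec)
  if (sum(segregating_counts(obs)) < 1) abort("no polymorphic classes")
  nms <- names(spec$bounds)
  lo <- log(vapply(spec$bounds, `[`, numeric(1), 1))
  hi <- log(vapply(spec$bounds, `[`, numeric(1), 2))
  nll <- function(lpar) {
    params <- as.list(exp(lpar))
    names(params) <- nms
    es <- try(expected_sfs_pk(model_demography(spec, params),
                              n_hap = obs$n_hap, steps = 60, tol = Inf),
              silent = TRUE)
    if (inherits(es, "try-error") || any(!is.finite(es$length)) ||
        any(es$length <= 0)) return(1e12)
    ll <- composite_loglik(obs, es, include_monomorphic, mu)
    if (!is.finite(ll)) return(1e12) else -ll
  }
  starts <- withr_seed(seed, {
    m <- matrix(runif(n_restarts * length(nms)), n_restarts)
    sweep(sweep(m, 2, hi - lo, `*`), 2, lo, `+`)
  })
  best <- NULL
  n_conv <- 0
  for (i in seq_len(n_restarts)) {
    fit <- try(nlminb(starts[i, ], nll, lower = lo, upper = hi,
                      control = list(iter.max = 300)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$objective)) next
    n_conv <- n_conv + 1
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) abort("all restarts failed to converge")
  est <- exp(best$par)
  names(est) <- nms
  lnl <- -best$objective
  structure(list(
    model_id = spec$model_id, estimates = est, lnl = lnl,
    l10 = lnl / log(10), k = spec$k,
    aic = aic(spec$k, lnl, 2), aic25 = aic(spec$k, lnl, 25),
    n_restarts = n_restarts, n_converged = n_conv,
    include_monomorphic = include_monomorphic, mu = mu,
    n_hap = obs$n_hap), class = "demog_fit")
}

#' @export
print.demog_fit <- function(x, ...) {
  cat(sprintf("<demog_fit> %s: lnL = %.2f, AIC = %.2f\n", x$model_id,
              x$lnl, x$aic))
  print(round(x$estimates, 1))
  invisible(x)
}

#' Akaike weights across fitted models
#'
#' `w_i = exp(-0.5 * delta_i) / sum_j exp(-0.5 * delta_j)` with
#' `delta_i = AIC_i - min(AIC)`. The model with the largest weight is
#' selected; ties break towards the smaller AIC then model order.
#'
#' @param fits List of `demog_fit` objects (or a numeric vector of AICs).
#' @param penalty 2 for standard AIC, 25 for the stricter variant.
#' @return A `model_choice` tibble with `model`, `aic`, `delta`, `weight`,
#'   and attribute `selected`.
#' @export
akaike_weights <- function(fits, penalty = 2) {
  if (is.numeric(fits)) {
    aics <- fits
    models <- names(fits) %||% paste0("model", seq_along(fits))
  } else {
    aics <- vapply(fits, function(f)
      if (penalty == 2) f$aic else aic(f$k, f$lnl, penalty), numeric(1))
    models <- vapply(fits, `[[`, character(1), "model_id")
  }
  if (any(is.na(aics))) abort("NaN AIC")
  delta <- aics - min(aics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  out <- tibble(model = models, aic = unname(aics), delta = unname(delta),
                weight = unname(w))
  attr(out, "selected") <- models[order(-w, aics, seq_along(w))[1]]
  class(out) <- c("model_choice", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit all four models and select by Akaike weight
#'
#' @inheritParams fit_sfs_model
#' @param models Model names to fit (default all four).
#' @param penalty AIC penalty for the selection step (2 or 25).
#' @return A `demog_model_selection`: list of fits, the weight table, and
#'   `selected`.
#' @export
fit_sfs_models <- function(obs, models = c("equilibrium",
                                           "instantaneous_change",
                                           "exponential_change",
                                           "instantaneous_bottleneck"),
                           n_restarts = 50, seed = 1, penalty = 2,
                           include_monomorphic = TRUE, mu = 1e-8) {
  fits <- lapply(models, function(m)
    fit_sfs_model(obs, m, n_restarts = n_restarts, seed = seed,
                  include_monomorphic = include_monomorphic, mu = mu))
  names(fits) <- models
  wts <- akaike_weights(fits, penalty)
  structure(list(fits = fits, weights = wts,
                 selected = attr(wts, "selected"), penalty = penalty),
            class = "demog_model_selection")
}

#' @export
print.demog_model_selection <- function(x, ...) {
  cat(sprintf("<demog_model_selection> selected: %s (penalty %g)\n",
              x$selected, x$penalty))
  print(as_tibble(x$weights))
  invisible(x)
}
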