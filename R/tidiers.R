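# broom-style tidiers

#' @export
tidy.demog_fit <- function(x, ...) {
  tibble(model = x$model_id, term = names(x$estimates),
         estimate = unname(x$estimates))
}

#' @export
glance.demog_fit <- function(x, ...) {
  tibble(model = x$model_id, k = x$k, logLik = x$lnl, l10 = x$l10,
         AIC = x$aic, AIC25 = x$aic25, n_restarts = x$n_restarts,
         n_converged = x$n_converged)
}

#' @export
tidy.demog_model_selection <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy)
}

#' @export
glance.demog_model_selection <- function(x, ...) {
  g <- purrr::map_dfr(x$fits, glance)
  left_join(g, as_tibble(x$weights)[, c("model", "delta", "weight")],
            by = "model")
}

#' @export
tidy.abc_posterior <- function(x, ...) {
  qs <- function(v, w) {
    o <- order(v)
    cw <- cumsum(w[o]) / sum(w)
    c(lo = v[o][which(cw >= 0.05)[1]], hi = v[o][which(cw >= 0.95)[1]])
  }
  purrr::map_dfr(names(x$draws), function(p) {
    q <- qs(x$draws[[p]], x$weights)
    tibble(term = p, estimate = unname(x$point_estimates[[p]]),
           conf.low = unname(q["lo"]), conf.high = unname(q["hi"]))
  })
}

#' @export
glance.abc_posterior <- function(x, ...) {
  tibble(n_accepted = nrow(x$draws), method = x$method,
         tolerance = x$tolerance %||% NA_real_)
}

#' @export
tidy.demography <- function(x, ...) x$epochs

#' @export
tidy.expected_sfs <- function(x, ...) as_tibble(x)

#' @export
tidy.sfs <- function(x, ...) as_tibble(x)

#' @export
tidy.haplotype_sample <- function(x, ...) as_tibble(x)
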