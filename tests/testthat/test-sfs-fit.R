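make_obs <- function(counts, n_hap, mono = 0) {
  sfs(c(mono, counts, 0), n_hap)
}

test_that("the composite log-likelihood matches direct arithmetic", {
  obs <- make_obs(c(5, 3, 2), 4)
  es <- structure(list(p = c(0.5, 0.3, 0.2), length = c(0.5, 0.3, 0.2) / 1e-8,
                       n_hap = 4), class = "expected_sfs")
  ll <- composite_loglik(obs, es, include_monomorphic = FALSE)
  expect_equal(ll, 5 * log(0.5) + 3 * log(0.3) + 2 * log(0.2),
               tolerance = 1e-12) # -10.2965 by hand
  expect_lt(abs(ll + 10.2965), 1e-3)
})

test_that("the likelihood is maximal when observations match expectations", {
  # Gibbs inequality: any other p gives a lower multinomial likelihood
  obs <- make_obs(c(50, 30, 20), 4)
  p0 <- c(0.5, 0.3, 0.2)
  base <- sum(c(50, 30, 20) * log(p0))
  set.seed(1)
  for (i in 1:20) {
    q <- stats::runif(3); q <- q / sum(q)
    expect_lte(sum(c(50, 30, 20) * log(q)), base + 1e-12)
  }
  empty <- sfs(c(100, 0, 0, 0, 0), 4)
  es <- expected_sfs_pk(demog_constant(1000), n_hap = 4)
  expect_error(composite_loglik(empty, es), "empty")
})

test_that("AIC and Akaike weights match their formulas", {
  expect_equal(aic(3, -100, 2), 206)
  expect_equal(aic(3, -100, 25), 275)
  expect_equal(aic(0, -100, 2), 200)
  w <- akaike_weights(c(a = 100, b = 102))
  expect_equal(w$weight, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-9)
  expect_equal(round(w$weight, 3), c(0.731, 0.269))
  w4 <- akaike_weights(c(m1 = 10, m2 = 10, m3 = 10, m4 = 10))
  expect_equal(w4$weight, rep(0.25, 4))
  expect_equal(sum(w4$weight), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(c(only = 5))$weight, 1)
  expect_error(akaike_weights(c(1, NA)), "NaN")
})

test_that("model nesting holds: size-change models dominate equilibrium", {
  d <- demog_preset("growth2x")
  m <- sim_neutral(d, 5e5, 20, 1e-7, r = 1e-8, seed = 10, n_rep = 1,
                   output = "sfs")
  obs <- make_obs(as.numeric(m[1, ]), 20, mono = 5e5 - sum(m))
  f_eq <- fit_sfs_model(obs, "equilibrium", n_restarts = 10, seed = 1,
                        mu = 1e-7)
  f_ic <- fit_sfs_model(obs, "instantaneous_change", n_restarts = 10,
                        seed = 1, mu = 1e-7)
  expect_gte(f_ic$lnl, f_eq$lnl - 1e-6)
  expect_equal(f_ic$aic, 2 * 3 - 2 * f_ic$lnl)
})

test_that("degenerate parameter settings reduce to equilibrium", {
  n_hap <- 10
  eq <- expected_sfs_model(demographic_model("equilibrium"), c(n = 2e4),
                           n_hap)
  ic <- expected_sfs_model(demographic_model("instantaneous_change"),
                           c(n_anc = 2e4, n_cur = 2e4, t = 1000), n_hap)
  bt <- expected_sfs_model(demographic_model("instantaneous_bottleneck"),
                           c(n_anc = 2e4, intensity = 1e-5, t = 1000), n_hap)
  expect_equal(ic$p, eq$p, tolerance = 1e-8)
  expect_equal(bt$p, eq$p, tolerance = 1e-4)
  expect_error(expected_sfs_model(demographic_model("equilibrium"),
                                  c(n = 10), n_hap), "out of bounds")
})

test_that("fitting recovers the generating equilibrium size exactly", {
  es <- expected_sfs_pk(demog_constant(1e4), n_hap = 20)
  counts <- round(1e6 * 1e-8 * es$length) # expected counts at mu=1e-8, 1 Mb
  obs <- make_obs(counts, 20, mono = 1e6 - sum(counts))
  fit <- fit_sfs_model(obs, "equilibrium", n_restarts = 10, seed = 2)
  expect_rel(fit$estimates[["n"]], 1e4, 0.01)
})

test_that("fitting recovers sizes and times from simulated spectra", {
  # coalescent-simulated SFS with >= 1e5 segregating sites
  d <- demog_step(2e4, 5e3, 2000)
  errs <- t(vapply(1:5, function(i) {
    m <- sim_neutral(d, 4e7, 20, 1e-8, r = 1e-8, seed = 50 + i, n_rep = 1,
                     output = "sfs", chunk_bp = 2e4)
    obs <- make_obs(as.numeric(m[1, ]), 20, mono = 4e7 - sum(m))
    f <- fit_sfs_model(obs, "instantaneous_change", n_restarts = 12,
                       seed = 3)
    c(f$estimates[["n_anc"]] / 2e4, f$estimates[["n_cur"]] / 5e3,
      f$estimates[["t"]] / 2000)
  }, numeric(3)))
  expect_lt(abs(median(errs[, 1]) - 1), 0.10)
  expect_lt(abs(median(errs[, 2]) - 1), 0.10)
  expect_lt(abs(median(errs[, 3]) - 1), 0.25)
})

test_that("growth-simulated data yields n_cur above n_anc", {
  d <- demog_preset("growth2x")
  m <- sim_neutral(d, 5e6, 20, 1e-8, r = 1e-8, seed = 70, n_rep = 1,
                   output = "sfs", chunk_bp = 2e4)
  obs <- make_obs(as.numeric(m[1, ]), 20, mono = 5e6 - sum(m))
  f <- fit_sfs_model(obs, "exponential_change", n_restarts = 10, seed = 1)
  expect_gt(f$estimates[["n_cur"]], f$estimates[["n_anc"]])
})

test_that("the stricter AIC penalty favours equilibrium on equilibrium data", {
  sel2 <- character(0)
  sel25 <- character(0)
  for (i in 1:3) {
    m <- sim_neutral(demog_constant(1e4), 2e6, 20, 1e-8, r = 1e-8,
                     seed = 80 + i, n_rep = 1, output = "sfs",
                     chunk_bp = 2e4)
    obs <- make_obs(as.numeric(m[1, ]), 20, mono = 2e6 - sum(m))
    fits <- fit_sfs_models(obs, models = c("equilibrium",
                                           "instantaneous_change",
                                           "exponential_change"),
                           n_restarts = 8, seed = 4, penalty = 2)
    sel2 <- c(sel2, fits$selected)
    sel25 <- c(sel25,
               attr(akaike_weights(fits$fits, penalty = 25), "selected"))
  }
  expect_gte(sum(sel25 == "equilibrium"), sum(sel2 == "equilibrium"))
  expect_gte(sum(sel25 == "equilibrium"), 2)
})

test_that("tidiers expose estimates and weights", {
  es <- expected_sfs_pk(demog_constant(5e3), n_hap = 10)
  counts <- round(2e5 * 1e-8 * es$length)
  obs <- make_obs(counts, 10, mono = 2e5 - sum(counts))
  fit <- fit_sfs_models(obs, models = c("equilibrium",
                                        "instantaneous_change"),
                        n_restarts = 5, seed = 5)
  td <- tidy(fit)
  expect_true(all(c("model", "term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 2)
  expect_equal(sum(gl$weight), 1, tolerance = 1e-9)
})
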