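fake_table <- function(n = 200, seed = 1, neutral = FALSE) {
  # synthetic reference table whose statistics are known functions of the
  # parameters; exercises rejection/adjustment without simulation cost
  bgsdemog:::withr_seed(seed, {
    pri <- abc_sample_priors(n, abc_config(size_bounds = c(100, 1000),
                                           dfe_step = 0.25),
                             seed = seed, neutral = neutral)
    stats <- matrix(rnorm(n * 22, sd = 0.05), n)
    colnames(stats) <- bgsdemog:::abc_stat_names()
    stats[, "mean_pi"] <- log(pri$n_anc) + stats[, "mean_pi"]
    stats[, "mean_theta_w"] <- log(pri$n_cur) + stats[, "mean_theta_w"]
    stats[, "var_pi"] <- 1 # zero spread: must be dropped from the distance
    tab <- dplyr::bind_cols(pri, tibble::as_tibble(stats))
    structure(list(table = tab, exons = tibble::tibble(exon_bp = 1000,
                                                       rec_rate = 1e-8),
                   config = abc_config(), neutral = neutral, seed = seed,
                   n_failed = 0), class = "abc_reference_table")
  })
}

test_that("prior draws respect the bounds and the DFE lattice", {
  cfg <- abc_config(size_bounds = c(1e5, 1e7), dfe_step = 0.05)
  pri <- abc_sample_priors(500, cfg, seed = 2)
  expect_true(all(pri$n_anc >= 1e5 & pri$n_anc <= 1e7))
  fmat <- as.matrix(pri[, c("f0", "f1", "f2", "f3")])
  expect_true(all(abs(rowSums(fmat) - 1) < 1e-9))
  expect_true(all(abs(fmat / 0.05 - round(fmat / 0.05)) < 1e-9))
  expect_equal(nrow(abc_sample_priors(0, cfg, seed = 1)), 0)
  neu <- abc_sample_priors(10, cfg, seed = 3, neutral = TRUE)
  expect_true(all(neu$f0 == 1))
})

test_that("rejection keeps exactly the tolerance fraction", {
  tab <- fake_table(200)
  obs <- unlist(tab$table[17, bgsdemog:::abc_stat_names()])
  acc <- suppressWarnings(abc_reject(obs, tab, tolerance = 0.1))
  expect_equal(nrow(acc), 20)
  expect_equal(acc$distance[1], 0) # the matching row is accepted first
  expect_equal(acc$n_anc[1], tab$table$n_anc[17])
  all_acc <- suppressWarnings(abc_reject(obs, tab, tolerance = 1))
  expect_equal(nrow(all_acc), 200)
  expect_error(abc_reject(obs, tab, tolerance = 0), "tolerance")
  expect_warning(abc_reject(obs, tab, tolerance = 0.5), "dropped")
})

test_that("posterior weights are normalised and medians weighted", {
  tab <- fake_table(300, seed = 4)
  obs <- unlist(tab$table[3, bgsdemog:::abc_stat_names()])
  acc <- suppressWarnings(abc_reject(obs, tab, 0.2))
  attr(acc, "tolerance") <- 0.2
  post <- abc_adjust(acc, obs, method = "rejection")
  expect_equal(sum(post$weights), 1, tolerance = 1e-12)
  expect_true(all(post$weights >= 0))
  expect_equal(nrow(post$draws), round(0.2 * 300))
  md <- bgsdemog:::weighted_median(post$draws$n_anc, post$weights)
  expect_equal(post$point_estimates[["n_anc"]], md)
})

test_that("regression adjustment is the identity when stats are flat", {
  tab <- fake_table(120, seed = 5)
  obs <- unlist(tab$table[1, bgsdemog:::abc_stat_names()])
  acc <- suppressWarnings(abc_reject(obs, tab, 0.25))
  attr(acc, "tolerance") <- 0.25
  flat <- acc
  for (s in bgsdemog:::abc_stat_names()) flat[[s]] <- 1
  attr(flat, "usable_stats") <- character(0)
  post <- abc_adjust(flat, obs, method = "loclinear")
  expect_equal(post$draws$n_anc, acc$n_anc)
  expect_equal(post$method, "rejection")
})

test_that("local-linear adjustment sharpens a linear relationship", {
  tab <- fake_table(400, seed = 6)
  obs <- unlist(tab$table[9, bgsdemog:::abc_stat_names()])
  truth <- tab$table$n_anc[9]
  acc <- suppressWarnings(abc_reject(obs, tab, 0.3))
  attr(acc, "tolerance") <- 0.3
  rejo <- abc_adjust(acc, obs, method = "rejection")
  lin <- abc_adjust(acc, obs, method = "loclinear")
  expect_lt(abs(log(lin$point_estimates[["n_anc"]] / truth)),
            abs(log(rejo$point_estimates[["n_anc"]] / truth)) + 0.05)
  # adjusted spread shrinks around the truth
  expect_lt(stats::mad(log(lin$draws$n_anc)), stats::mad(log(acc$n_anc)))
})

test_that("inference modes demand matching reference tables", {
  tab <- fake_table(100, seed = 7)
  obs <- unlist(tab$table[2, bgsdemog:::abc_stat_names()])
  expect_error(abc_infer(obs, tab, mode = "neutral_assumption"),
               "neutral reference table")
  ntab <- fake_table(100, seed = 8, neutral = TRUE)
  expect_error(abc_infer(obs, ntab, mode = "nuisance_dfe"),
               "nuisance-DFE reference table")
})

test_that("a small end-to-end ABC run recovers a neutral equilibrium size", {
  cfg <- abc_config(n_exons = 6, exon_bp = 1000, mu = 2e-6,
                    rec_range = c(1e-6, 1e-5), size_bounds = c(100, 400),
                    t_change = 300, Q = 1, n_sample = 20, dfe_step = 0.25)
  pri <- abc_sample_priors(50, cfg, seed = 11, neutral = TRUE)
  tab <- abc_build_table(pri, cfg, seed = 12, neutral = TRUE)
  expect_equal(nrow(tab$table) + tab$n_failed, 50)
  obs <- abc_simulate_testset(250, 250, f = NULL, table = tab, seed = 13)
  post <- abc_infer(obs, tab, mode = "neutral_assumption", tolerance = 0.2,
                    method = "loclinear")
  est <- post$point_estimates
  expect_true(all(est > 50 & est < 1000))
  expect_lt(abs(log(est[["n_anc"]] / 250)), log(2.5))
  td <- tidy(post)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in%
                    names(td)))
})

test_that("reference-table rows at equilibrium match analytic diversity", {
  cfg <- abc_config(n_exons = 10, exon_bp = 1000, mu = 2e-6,
                    rec_range = c(1e-6, 1e-5), size_bounds = c(150, 250),
                    t_change = 200, Q = 1, n_sample = 20, dfe_step = 0.25)
  exons <- bgsdemog:::abc_exon_set(cfg, seed = 3)
  sv <- bgsdemog:::abc_simulate_one(200, 200, c(1, 0, 0, 0), cfg, exons,
                                    seed = 21, neutral = TRUE)
  # mean per-exon pi -> 4*N*mu*L within Monte-Carlo error
  expect_lt(abs(sv[["mean_pi"]] - 4 * 200 * 2e-6 * 1000),
            4 * sqrt(sv[["var_pi"]] / 10))
})
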