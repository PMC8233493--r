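test_that("constant-size expected SFS is the 1/b law for any B", {
  es4 <- expected_sfs_pk(demog_constant(1e4), n_hap = 4)
  expect_equal(es4$p, c(6, 3, 2) / 11, tolerance = 1e-10)
  es20 <- expected_sfs_pk(demog_constant(5e4), n_hap = 20)
  expect_equal(es20$p, (1 / (1:19)) / sum(1 / (1:19)), tolerance = 1e-9)
  # B rescales lengths but cancels from the proportions
  esb <- expected_sfs_pk(demog_constant(5e4), n_hap = 20, B = 0.4)
  expect_equal(esb$p, es20$p, tolerance = 1e-9)
  expect_equal(esb$length, 0.4 * es20$length, tolerance = 1e-9)
  # absolute lengths: E[xi_b] * mu = theta / b at equilibrium
  expect_equal(es20$length, 4 * 5e4 / (1:19), tolerance = 1e-9)
})

test_that("expected SFS probabilities are positive and sum to one", {
  for (d in list(demog_preset("growth"), demog_preset("decline"),
                 demog_bottleneck(1e4, 0.8, 1500))) {
    es <- expected_sfs_pk(d, n_hap = 20)
    expect_true(all(es$p > 0))
    expect_equal(sum(es$p), 1, tolerance = 1e-10)
  }
  w <- testthat::capture_warnings(expected_sfs_pk(demog_constant(100),
                                                  n_hap = 60))
  expect_true(any(grepl("unstable", w)))
})

test_that("expected SFS matches coalescent simulation for all presets", {
  for (nm in c("equilibrium", "growth", "decline")) {
    d <- demog_preset(nm)
    es <- expected_sfs_pk(d, n_hap = 20)
    m <- sim_neutral(d, 1e6, 20, 1e-7, r = 1e-8, seed = 42, n_rep = 100,
                     output = "sfs")
    p <- colSums(m) / sum(m)
    se <- apply(sweep(m, 1, rowSums(m), `/`), 2, sd) / sqrt(nrow(m))
    expect_true(all(abs(p - es$p) < 3 * pmax(se, 5e-4)), label = nm)
  }
})

test_that("declines with ancestral BGS inflate the singleton class", {
  d <- demog_preset("decline")
  with_b <- expected_sfs_pk(d, n_hap = 20, B = 0.6)
  no_b <- expected_sfs_pk(d, n_hap = 20, B = 1)
  expect_gt(with_b$p[1], no_b$p[1])
})

test_that("pi trajectory has the right limits and continuity", {
  mu <- 1e-8
  traj <- expected_pi_trajectory(demog_constant(5000), B = 1, mu = mu)
  expect_equal(traj(0), 4 * 5000 * mu, tolerance = 1e-6)
  expect_equal(traj(3000), 4 * 5000 * mu, tolerance = 1e-6)
  step <- expected_pi_trajectory(demog_step(1e4, 2e3, 500), B = 1, mu = mu)
  expect_equal(step(0), 4e4 * mu, tolerance = 1e-6) # ancestral diversity
  expect_equal(step(1e7), 4 * 2e3 * mu, tolerance = 1e-4) # new equilibrium
  # continuity across the end of an exponential epoch
  ex <- expected_pi_trajectory(demog_exponential(1e4, 2e4, 1000), B = 1,
                               mu = mu)
  expect_equal(ex(999.9), ex(1000.1), tolerance = 1e-3)
  expect_error(ex(-5), ">= 0")
})

test_that("pi trajectory matches coalescent simulation under growth", {
  d <- demog_preset("growth2x")
  traj <- expected_pi_trajectory(d, B = 1, mu = 1e-7)
  pis <- vapply(1:80, function(i) {
    smp <- sim_neutral(d, 2e5, 10, 1e-7, r = 1e-8, seed = 900 + i)
    theta_pi_sample(smp) / 2e5
  }, numeric(1))
  expect_lt(abs(mean(pis) - traj(1000)), 3 * sd(pis) / sqrt(length(pis)))
})

test_that("apparent B reproduces its closed form for a step change", {
  b0 <- 0.8
  # ~6-fold decline: 10,000 -> 1,667, measured 1,000 generations later
  d <- demog_step(10000, 1667, 1000)
  got <- apparent_b_after_change(b0, d, 1000)$b_hat
  x <- function(B) exp(-1000 / (2 * B * 1667))
  closed <- b0 * (1667 + (10000 - 1667) * x(b0)) /
    (1667 + (10000 - 1667) * x(1))
  expect_equal(got, closed, tolerance = 1e-6)
  expect_lt(abs(got - 0.755), 1e-3)
})

test_that("apparent B starts and ends at the ancestral value", {
  d <- demog_step(1e4, 5e3, 1000)
  expect_equal(apparent_b_after_change(0.7, d, 0)$b_hat, 0.7,
               tolerance = 1e-6)
  expect_equal(apparent_b_after_change(0.7, d, 1e8)$b_hat, 0.7,
               tolerance = 1e-4)
  expect_error(apparent_b_after_change(0.7, d, -1), ">= 0")
})

test_that("apparent B dips after decline and rises after growth", {
  ts <- c(50, 200, 500, 1000, 3000)
  dec <- apparent_b_after_change(0.8, demog_step(3000, 500, 1), ts)
  expect_true(all(dec$b_hat <= 0.8 + 1e-9))
  gro <- apparent_b_after_change(0.8, demog_step(500, 1000, 1), ts)
  expect_true(all(gro$b_hat >= 0.8 - 1e-9))
  expect_true(all(gro$b_hat <= 1 + 1e-9))
})

test_that("equilibrium B approaches 1 for unlinked selected sites", {
  lay <- tibble::tibble(start = 0, end = 1000)
  d <- dfe(c(0, 0, 0, 1), n_anc = 5000)
  far <- equilibrium_b(5e7, lay, d, mu_del = 1e-8, rec_rate = 1e-8)
  expect_gt(far$b, 0.9999)
})

test_that("equilibrium B matches numerical integration over the DFE", {
  # single strongly deleterious class, focal site adjacent to one exon
  lay <- tibble::tibble(start = 1000, end = 2000)
  n_anc <- 5000
  d <- dfe(c(0, 0, 0, 1), n_anc = n_anc)
  u <- 1e-8
  rr <- 1e-8
  got <- equilibrium_b(0, lay, d, mu_del = u, rec_rate = rr)
  slo <- 100 / (2 * n_anc); shi <- 2 * n_anc / (2 * n_anc)
  contrib <- vapply(1000:1999, function(p) {
    rj <- 0.5 * (1 - exp(-2 * rr * p))
    stats::integrate(function(s) {
      t <- s / 2
      u * t / (t + rj * (1 - t))^2 / (shi - slo)
    }, slo, shi)$value
  }, numeric(1))
  expect_equal(got$b, exp(-sum(contrib)), tolerance = 1e-6)
  expect_false(got$weak_selection_warning)
  weak <- equilibrium_b(0, lay, dfe(c(0, 0.5, 0, 0.5), n_anc), u, rr)
  expect_true(weak$weak_selection_warning)
})

test_that("equilibrium B grows with distance from the exon", {
  lay <- tibble::tibble(start = 0, end = 2000)
  d <- dfe(c(0, 0, 0.5, 0.5), n_anc = 5000)
  bs <- vapply(c(2010, 4000, 20000, 2e5),
               function(p) equilibrium_b(p, lay, d, 1e-8, 1e-8)$b,
               numeric(1))
  expect_true(all(diff(bs) > 0))
  expect_true(all(bs > 0 & bs <= 1))
})

test_that("expected lineage-stage durations match the constant-size law", {
  n <- 12
  N <- 3000
  ej <- bgsdemog:::pk_ej(demog_constant(N), B = 1, n = n)
  tk <- bgsdemog:::pk_expected_tk(ej, n)
  expect_equal(tk, 4 * N / ((2:n) * (1:(n - 1))), tolerance = 1e-8)
  # and under a decline they lengthen towards the (larger) ancestral size
  d <- bgsdemog:::discretize_demography(demog_step(4 * N, N, 100))
  tk2 <- bgsdemog:::pk_expected_tk(bgsdemog:::pk_ej(d, 1, n), n)
  expect_true(all(tk2 >= tk - 1e-9))
})
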