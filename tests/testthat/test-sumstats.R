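test_that("SFS tallies derived counts and the monomorphic classes", {
  smp <- toy_sample() # counts 1 and 2 in n_hap = 4, L = 100
  sf <- compute_sfs(smp)
  expect_equal(unname(sf$counts[c("1", "2", "3")]), c(1, 1, 0))
  expect_equal(unname(sf$counts["0"]), 100 - 2)
  expect_equal(sf$total_sites, 100)
  # larger toy case: two sites with derived counts 1 and 10 in n_hap = 20
  geno <- matrix(0L, 20, 2)
  geno[1, 1] <- 1L
  geno[1:10, 2] <- 1L
  smp2 <- bgsdemog:::new_haplotype_sample(geno, pos = c(5L, 9L), L = 50,
                                          s = c(0, 0), class = c(-1L, -1L))
  sf2 <- compute_sfs(smp2)
  expect_equal(unname(sf2$counts[c("1", "10")]), c(1, 1))
  expect_equal(sum(bgsdemog:::segregating_counts(sf2)), 2)
})

test_that("masking removes sites and shrinks the monomorphic class", {
  smp <- toy_sample()
  m <- mask_set(tibble::tibble(start = 0, end = 15), 100) # masks pos 10
  sf <- compute_sfs(smp, mask = m)
  expect_equal(unname(sf$counts["1"]), 0)
  expect_equal(unname(sf$counts["2"]), 1)
  expect_equal(sf$total_sites, 85)
  expect_error(compute_sfs(smp, mask_set(tibble::tibble(start = 0, end = 100),
                                         100)), "whole sequence")
})

test_that("neutral equilibrium SFS is proportional to 1/b", {
  m <- sim_neutral(demog_constant(1000), 1e6, 12, 1e-7, r = 1e-8, seed = 5,
                   n_rep = 60, output = "sfs", chunk_bp = 2000)
  tot <- colSums(m)
  p <- tot / sum(tot)
  expected <- (1 / (1:11)) / sum(1 / (1:11))
  se <- sqrt(expected * (1 - expected) / sum(tot))
  expect_true(all(abs(p - expected) < 4 * pmax(se, 2e-3)))
})

test_that("folding maps derived classes onto minor-allele classes", {
  geno <- matrix(0L, 4, 3)
  geno[1, 1] <- 1L        # count 1
  geno[1:3, 2] <- 1L      # count 3 -> folds onto 1
  geno[1:2, 3] <- 1L      # count 2
  smp <- bgsdemog:::new_haplotype_sample(geno, pos = c(1L, 2L, 3L), L = 10,
                                         s = numeric(3), class = rep(-1L, 3))
  unf <- compute_sfs(smp)
  fol <- compute_sfs(smp, fold = TRUE)
  expect_equal(fol$counts, fold_sfs(unf)$counts)
  expect_equal(unname(fol$counts["1"]), 2)
  expect_equal(unname(fol$counts["2"]), 1)
  expect_equal(unname(fol$counts["3"]), 0)
})

test_that("SNP thinning follows the greedy rule and is idempotent", {
  pos <- c(100, 4000, 5100, 9000, 10200)
  keep <- thin_snps(pos, 5000)
  expect_equal(pos[keep], c(100, 5100, 10200))
  expect_true(thin_snps(42, 5000))
  expect_true(all(thin_snps(pos, 0)))
  kept <- pos[keep]
  expect_true(all(thin_snps(kept, 5000)))
  # per-chromosome restart
  df <- tibble::tibble(chrom = c(1, 1, 2, 2), pos = c(0, 4000, 0, 4000))
  expect_equal(thin_snps(df, 5000), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("zero-class scaling matches the SNP reduction", {
  x <- sfs(c(1e6, 50, 30, 20, 0), 4)
  expect_equal(scale_zero_class(x, 1)$counts, x$counts)
  expect_equal(unname(scale_zero_class(x, 0.01)$counts["0"]), 1e4)
  expect_error(scale_zero_class(x, 1.2), "kept_fraction")
  # consistency through the thinning pipeline
  smp <- sim_neutral(demog_constant(1000), 2e5, 10, 1e-6, r = 1e-8, seed = 8)
  full <- compute_sfs(smp)
  thin <- compute_sfs_thinned(smp, min_gap = 5000)
  kf <- sum(bgsdemog:::segregating_counts(thin)) /
    sum(bgsdemog:::segregating_counts(full))
  expect_equal(unname(thin$counts["0"]),
               round(unname(full$counts["0"]) * kf))
})

test_that("pi and Watterson's theta match hand-computed oracles", {
  smp <- toy_sample() # n=4, derived counts (1, 2)
  ws <- window_stats(smp)
  expect_equal(ws$pi, 3 / 6 + 4 / 6, tolerance = 1e-12) # 7/6
  s7 <- random_sample(4, 7)
  ws7 <- window_stats(s7)
  expect_equal(ws7$theta_w, 7 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)
})

test_that("pi from allele frequencies equals mean pairwise Hamming distance", {
  for (seed in 1:5) {
    smp <- random_sample(n_hap = 8, S = 30, seed = seed)
    ws <- window_stats(smp)
    dmat <- as.matrix(stats::dist(smp$geno, method = "manhattan"))
    hamming <- mean(dmat[lower.tri(dmat)])
    expect_equal(ws$pi, hamming, tolerance = 1e-12)
  }
})

test_that("Tajima's D is near zero at neutral equilibrium", {
  ds <- vapply(1:60, function(i) {
    smp <- sim_neutral(demog_constant(1000), 1e5, 20, 1e-6, r = 1e-8,
                       seed = 300 + i)
    window_stats(smp)$taj_d
  }, numeric(1))
  expect_lt(abs(mean(ds)), 3 * sd(ds) / sqrt(length(ds)))
})

test_that("window statistics handle empty windows", {
  smp <- toy_sample()
  ws <- window_stats(smp, tibble::tibble(start = c(0, 50), end = c(50, 100)))
  expect_equal(ws$n_snps, c(2, 0))
  expect_equal(ws$pi[2], 0)
  expect_true(is.na(ws$taj_d[2]))
  expect_true(is.na(ws$r2[2]))
})

test_that("the ABC statistic vector has the documented shape", {
  smp <- sim_neutral(demog_constant(500), 1e4, 10, 1e-5, r = 1e-8, seed = 21)
  w <- tibble::tibble(start = seq(0, 9000, 1000), end = seq(1000, 10000, 1000))
  st <- window_stats(smp, w)
  v <- abc_stat_vector(st)
  expect_length(v, 22)
  expect_identical(names(v), bgsdemog:::abc_stat_names())
  # permutation invariance
  v2 <- abc_stat_vector(st[sample(nrow(st)), ])
  expect_equal(v, v2)
  # identical windows give zero variances
  v3 <- abc_stat_vector(st[c(1, 1, 1), ])
  expect_true(all(v3[grepl("^var_", names(v3))] %in% c(0, NA) |
                    abs(v3[grepl("^var_", names(v3))]) < 1e-18))
  expect_error(abc_stat_vector(st[1, ]), "at least 2")
})

test_that("unlinked SNP pairs have mean r2 near 1/n", {
  smp <- sim_neutral(demog_constant(1000), 5e5, 50, 1e-6, r = 1e-8,
                     seed = 31, chunk_bp = 500)
  # pairs drawn across distant chunks only
  g <- smp$geno
  set.seed(1)
  pick <- cbind(sample(ncol(g), 4000, TRUE), sample(ncol(g), 4000, TRUE))
  pick <- pick[abs(smp$pos[pick[, 1]] - smp$pos[pick[, 2]]) > 1e4, ]
  r2 <- apply(pick, 1, function(ij) {
    gi <- g[, ij[1]]; gj <- g[, ij[2]]
    p <- mean(gi); q <- mean(gj)
    D <- mean(gi * gj) - p * q
    D^2 / (p * (1 - p) * q * (1 - q))
  })
  expect_lt(abs(mean(r2) - 1 / 50), 0.004)
})
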