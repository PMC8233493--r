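# Shared fixtures. Everything is generated in code; simulations used by many
# tests are kept deliberately small.

tiny_layout <- function() genome_layout(350, 8, 1500, 15750, 29050)

# a 4-haplotype sample with two segregating sites (derived counts 1 and 2)
toy_sample <- function() {
  geno <- matrix(0L, 4, 2)
  geno[1, 1] <- 1L
  geno[c(1, 2), 2] <- 1L
  bgsdemog:::new_haplotype_sample(geno, pos = c(10L, 20L), L = 100,
                       s = c(0, 0), class = c(-1L, -1L),
                       engine = "coalescent")
}

random_sample <- function(n_hap, S, L = 1000L, seed = 1) {
  bgsdemog:::withr_seed(seed, {
    geno <- matrix(0L, n_hap, S)
    for (j in seq_len(S)) {
      k <- sample(n_hap - 1, 1)
      geno[sample(n_hap, k), j] <- 1L
    }
    bgsdemog:::new_haplotype_sample(geno, pos = sort(sample(L, S)), L = L,
                         s = numeric(S), class = rep(-1L, S),
                         engine = "coalescent")
  })
}

expect_rel <- function(x, y, tol) expect_lt(abs(x / y - 1), tol)

theta_pi_sample <- function(smp) {
  if (length(smp$pos) == 0) return(0)
  bgsdemog:::theta_pi_from_counts(colSums(smp$geno), smp$n_hap)
}
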