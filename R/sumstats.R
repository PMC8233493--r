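#' Site frequency spectrum of a haplotype sample
#'
#' Tallies derived-allele counts over unmasked positions. Index 0 holds the
#' monomorphic (non-segregating, ancestral) class, computed as unmasked
#' length minus segregating sites minus sites fixed for the derived allele
#' within the sample (held at index `n_hap`).
#'
#' @param sample A `haplotype_sample`.
#' @param mask Optional [mask_set()] of positions to exclude.
#' @param fold Fold the spectrum by minor-allele count.
#' @return An `sfs` object: counts indexed `0..n_hap`, `n_hap`, `folded`,
#'   `total_sites`.
#' @export
compute_sfs <- function(sample, mask = NULL, fold = FALSE) {
  n <- sample$n_hap
  keep <- !is_masked(mask, sample$pos)
  counts_per_site <- colSums(sample$geno)[keep]
  un_len <- unmasked_length(mask, sample$L)
  if (un_len <= 0) abort("mask covers the whole sequence")
  xi <- tabulate(counts_per_site, nbins = n)
  counts <- c(un_len - sum(xi) - sample$n_mono_derived, xi[-n],
              xi[n] + sample$n_mono_derived)
  sfs(counts, n, folded = FALSE, fold_now = fold)
}

#' Construct an SFS object from class counts
#'
#' @param counts Numeric vector of length `n_hap + 1` (classes `0..n_hap`).
#' @param n_hap Number of haplotypes.
#' @param folded Whether `counts` is already folded.
#' @param fold_now Fold an unfolded spectrum.
#' @export
sfs <- function(counts, n_hap, folded = FALSE, fold_now = FALSE) {
  if (length(counts) != n_hap + 1) abort("counts must have length n_hap + 1")
  if (any(counts < 0)) abort("negative SFS counts")
  names(counts) <- 0:n_hap
  x <- structure(list(counts = counts, n_hap = n_hap, folded = folded,
                      total_sites = sum(counts)), class = "sfs")
  if (fold_now) fold_sfs(x) else x
}

#' @rdname sfs
#' @param x An `sfs`.
#' @export
fold_sfs <- function(x) {
  if (x$folded) return(x)
  n <- x$n_hap
  counts <- x$counts
  out <- numeric(n + 1)
  for (b in 0:n) {
    tgt <- min(b, n - b)
    out[tgt + 1] <- out[tgt + 1] + counts[b + 1]
  }
  sfs(out, n, folded = TRUE)
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("<sfs> n_hap = %d, %s, %s sites (%s segregating)\n", x$n_hap,
              if (x$folded) "folded" else "unfolded",
              format(x$total_sites, big.mark = ","),
              format(sum(x$counts[-c(1, x$n_hap + 1)]), big.mark = ",")))
  invisible(x)
}

#' @export
as_tibble.sfs <- function(x, ...) {
  tibble(derived_copies = 0:x$n_hap, sites = as.numeric(x$counts))
}

segregating_counts <- function(x) x$counts[-c(1, x$n_hap + 1)]

#' Thin SNPs to a minimum spacing
#'
#' Greedy left-to-right scan per chromosome: the first SNP is kept; each
#' subsequent SNP is kept only if it lies at least `min_gap` bp downstream of
#' the last kept SNP. Idempotent.
#'
#' @param pos Sorted positions (bp), or a data frame with `chrom` and `pos`.
#' @param min_gap Minimum spacing in bp.
#' @return Logical keep vector aligned with the input.
#' @export
thin_snps <- function(pos, min_gap) {
  if (is.data.frame(pos)) {
    keep <- logical(nrow(pos))
    for (ch in unique(pos$chrom)) {
      i <- which(pos$chrom == ch)
      keep[i] <- thin_snps(pos$pos[i], min_gap)
    }
    return(keep)
  }
  if (is.unsorted(pos)) abort("positions must be sorted")
  keep <- logical(length(pos))
  if (length(pos) == 0) return(keep)
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= min_gap || !is.finite(last)) {
      keep[i] <- TRUE
      last <- pos[i]
    }
  }
  keep
}

#' Scale the monomorphic class of a thinned SFS
#'
#' After SNP thinning, the monomorphic (and fixed-derived) classes are scaled
#' by the same fraction as the reduction in SNP number, so that the relative
#' weight of the zero class matches the thinned polymorphic classes.
#'
#' @param x An `sfs` whose polymorphic classes already hold thinned tallies.
#' @param kept_fraction Fraction of SNPs kept by thinning, in (0, 1].
#' @export
scale_zero_class <- function(x, kept_fraction) {
  if (kept_fraction <= 0 || kept_fraction > 1)
    abort("kept_fraction must be in (0, 1]")
  counts <- x$counts
  counts[1] <- round(counts[1] * kept_fraction)
  counts[x$n_hap + 1] <- round(counts[x$n_hap + 1] * kept_fraction)
  sfs(counts, x$n_hap, folded = x$folded)
}

#' Thin a sample's SNPs and rebuild its SFS
#'
#' Applies [thin_snps()], retallies the SFS from the kept SNPs, and applies
#' [scale_zero_class()] with the realised kept fraction.
#'
#' @inheritParams compute_sfs
#' @param min_gap Minimum SNP spacing in bp (`0` disables thinning).
#' @export
compute_sfs_thinned <- function(sample, min_gap, mask = NULL, fold = FALSE) {
  full <- compute_sfs(sample, mask, fold = FALSE)
  if (min_gap <= 0) return(if (fold) fold_sfs(full) else full)
  keep_site <- !is_masked(mask, sample$pos)
  pos <- sample$pos[keep_site]
  counts_per_site <- colSums(sample$geno)[keep_site]
  kept <- thin_snps(pos, min_gap)
  xi <- tabulate(counts_per_site[kept], nbins = sample$n_hap)
  n <- sample$n_hap
  counts <- full$counts
  counts[2:n] <- xi[-n]
  counts[n + 1] <- xi[n] + sample$n_mono_derived
  out <- sfs(counts, n)
  out <- scale_zero_class(out, sum(kept) / max(1, length(kept)))
  if (fold) fold_sfs(out) else out
}

# ---- classical estimators from derived-count vectors --------------------

harmonic <- function(n) sum(1 / seq_len(n))
harmonic2 <- function(n) sum(1 / seq_len(n)^2)

theta_pi_from_counts <- function(b, n) sum(2 * b * (n - b)) / (n * (n - 1))

tajima_d <- function(S, pi, n) {
  if (S == 0 || n < 4) return(NA_real_)
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fay & Wu's H (absolute: pi - theta_H) and its variance-normalised form
faywu_h <- function(b, n) {
  S <- length(b)
  if (S == 0 || n < 4) return(c(h = NA_real_, h_norm = NA_real_))
  xi <- tabulate(b, nbins = n - 1)
  bb <- seq_len(n - 1)
  pi <- sum(2 * bb * (n - bb) * xi) / (n * (n - 1))
  th_h <- sum(2 * bb^2 * xi) / (n * (n - 1))
  th_l <- sum(bb * xi) / (n - 1)
  an <- harmonic(n - 1); bn <- harmonic2(n - 1)
  bn1 <- harmonic2(n)
  th_w <- S / an
  th2 <- S * (S - 1) / (an^2 + bn)
  v <- (n - 2) / (6 * (n - 1)) * th_w +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * th2
  c(h = pi - th_h, h_norm = if (v > 0) (pi - th_l) / sqrt(v) else NA_real_)
}

ld_pair_stats <- function(geno, max_pairs = 2000, seed = 1) {
  S <- ncol(geno)
  if (S < 2) return(c(r2 = NA_real_, D = NA_real_, Dprime = NA_real_))
  n <- nrow(geno)
  p <- colMeans(geno)
  n_all <- S * (S - 1) / 2
  if (n_all <= max_pairs) {
    # all pairs at once via the joint-frequency matrix
    pab <- crossprod(geno) / n
    up <- upper.tri(pab)
    D <- pab - tcrossprod(p)
    pi_ <- matrix(p, S, S)
    pj_ <- matrix(p, S, S, byrow = TRUE)
    denom <- pi_ * (1 - pi_) * pj_ * (1 - pj_)
    dmax <- ifelse(D >= 0, pmin(pi_ * (1 - pj_), (1 - pi_) * pj_),
                   pmin(pi_ * pj_, (1 - pi_) * (1 - pj_)))
    r2v <- ifelse(denom > 0, D^2 / denom, NA_real_)[up]
    Dv <- D[up]
    Dpv <- ifelse(dmax > 0, D / dmax, NA_real_)[up]
  } else {
    idx <- withr_seed(seed, {
      i <- sample.int(S, 2 * max_pairs, replace = TRUE)
      j <- sample.int(S, 2 * max_pairs, replace = TRUE)
      keep <- i < j
      cbind(i[keep], j[keep])[seq_len(min(max_pairs, sum(keep))), ,
                              drop = FALSE]
    })
    i <- idx[, 1]; j <- idx[, 2]
    pab <- colMeans(geno[, i, drop = FALSE] * geno[, j, drop = FALSE])
    D <- pab - p[i] * p[j]
    denom <- p[i] * (1 - p[i]) * p[j] * (1 - p[j])
    dmax <- ifelse(D >= 0, pmin(p[i] * (1 - p[j]), (1 - p[i]) * p[j]),
                   pmin(p[i] * p[j], (1 - p[i]) * (1 - p[j])))
    r2v <- ifelse(denom > 0, D^2 / denom, NA_real_)
    Dv <- D
    Dpv <- ifelse(dmax > 0, D / dmax, NA_real_)
  }
  c(r2 = mean(r2v, na.rm = TRUE), D = mean(Dv, na.rm = TRUE),
    Dprime = mean(Dpv, na.rm = TRUE))
}

#' Per-window summary statistics
#'
#' Computes, for each window, the 11 statistics used throughout the package:
#' nucleotide diversity `pi` (sum over sites of expected heterozygosity),
#' Watterson's `theta_w`, Tajima's `D`, Fay & Wu's `H` (absolute,
#' `pi - theta_H`, and variance-normalised), the number of derived
#' singletons, haplotype diversity, mean pairwise `r2`, `D` and `D'` over
#' SNP pairs within the window, and divergence (fixations per site per
#' generation after the burn-in, forward simulations only).
#'
#' @param sample A `haplotype_sample`.
#' @param windows Data frame with `start`, `end` (0-based half-open);
#'   default one window spanning the whole sequence.
#' @param mask Optional [mask_set()].
#' @param max_pairs Cap on SNP pairs per window for the LD statistics
#'   (seeded subsample beyond this).
#' @param seed Seed for the LD pair subsample.
#' @return A tibble, one row per window.
#' @export
window_stats <- function(sample, windows = NULL, mask = NULL,
                         max_pairs = 2000, seed = 1) {
  if (is.null(windows)) windows <- tibble(start = 0, end = sample$L)
  n <- sample$n_hap
  keep <- !is_masked(mask, sample$pos)
  pos <- sample$pos[keep]
  geno <- sample$geno[, keep, drop = FALSE]
  cnt <- colSums(geno)
  gens <- sample$gens_post_burnin
  purrr::pmap_dfr(windows, function(start, end, ...) {
    in_w <- pos >= start & pos < end
    b <- cnt[in_w]
    S <- length(b)
    g <- geno[, in_w, drop = FALSE]
    pi <- if (S) theta_pi_from_counts(b, n) else 0
    thw <- if (S) S / harmonic(n - 1) else 0
    fw <- faywu_h(b, n)
    hapdiv <- if (S) {
      key <- apply(g, 1, paste, collapse = "")
      (1 - sum((table(key) / n)^2)) * n / (n - 1)
    } else 0
    ld <- ld_pair_stats(g, max_pairs, seed)
    div <- if (!is.na(gens) && gens > 0)
      sum(sample$fixations$gen > 0 &
            sample$fixations$pos >= start & sample$fixations$pos < end) /
        ((end - start) * gens)
    else NA_real_
    tibble(start = start, end = end, n_snps = S,
           pi = pi, theta_w = thw,
           taj_d = tajima_d(S, pi, n),
           faywu_h = fw[["h"]], faywu_h_norm = fw[["h_norm"]],
           singletons = sum(b == 1), hap_div = hapdiv,
           r2 = ld[["r2"]], D = ld[["D"]], Dprime = ld[["Dprime"]],
           divergence = div)
  })
}

abc_stat_names <- function() {
  base <- c("pi", "theta_w", "taj_d", "faywu_h", "faywu_h_norm",
            "singletons", "hap_div", "r2", "D", "Dprime", "divergence")
  c(paste0("mean_", base), paste0("var_", base))
}

#' Collapse per-window statistics into the 22-element ABC vector
#'
#' Means and between-window variances of the 11 window statistics, in a
#' fixed documented order (`abc_stat_names()`). Windows with a missing value
#' for a statistic are excluded from that statistic's mean/variance; the
#' number of such windows is recorded in the `n_missing` attribute.
#'
#' @param stats A tibble from [window_stats()] with at least two rows.
#' @return Named numeric vector of length 22.
#' @export
abc_stat_vector <- function(stats) {
  if (nrow(stats) < 2) abort("need at least 2 windows for variances")
  base <- c("pi", "theta_w", "taj_d", "faywu_h", "faywu_h_norm",
            "singletons", "hap_div", "r2", "D", "Dprime", "divergence")
  m <- vapply(base, function(s) mean(stats[[s]], na.rm = TRUE), numeric(1))
  v <- vapply(base, function(s) {
    x <- stats[[s]][!is.na(stats[[s]])]
    if (length(x) >= 2) stats::var(x) else NA_real_
  }, numeric(1))
  out <- c(m, v)
  names(out) <- abc_stat_names()
  nmiss <- vapply(base, function(s) sum(is.na(stats[[s]])), numeric(1))
  attr(out, "n_missing") <- nmiss
  out
}
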