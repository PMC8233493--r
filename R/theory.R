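# Analytical theory: equilibrium B, apparent B through size changes,
# expected pairwise diversity, and the expected SFS under piecewise
# population-size histories via the classical time-inhomogeneous coalescent
# results (exponential functionals of the lineage-count process).

# Discretise exponential epochs into piecewise-constant steps on a geometric
# time grid so that every downstream integral has a closed form per step.
discretize_demography <- function(demog, steps = 50) {
  e <- demog$epochs
  rows <- list()
  for (i in seq_len(nrow(e))) {
    if (e$mode[i] != "exponential") {
      rows[[length(rows) + 1]] <- e[i, ]
      next
    }
    d <- e$duration[i]
    g <- log(e$n_recent[i] / e$n_ancient[i]) / d
    # geometric grid, denser near the recent edge where N changes fastest
    edges <- d * (exp(seq(0, 1, length.out = steps + 1) * log(101)) - 1) / 100
    mid <- (head(edges, -1) + tail(edges, -1)) / 2
    rows[[length(rows) + 1]] <- tibble(
      duration = diff(edges),
      n_recent = e$n_recent[i] * exp(-g * mid),
      n_ancient = e$n_recent[i] * exp(-g * mid),
      mode = "constant", intensity = 0)
  }
  demography(bind_rows(rows), demog$label)
}

# e_j = int_0^Inf exp(-C(j,2) * Omega(t)) dt with Omega = int dt / (2 B N),
# for j = 2..n, computed epoch-by-epoch in closed form (constant epochs and
# pulses only; call discretize_demography() first).
pk_ej <- function(demog, B, n) {
  e <- demog$epochs
  cj <- choose(2:n, 2)
  ej <- numeric(n - 1)
  omega0 <- 0
  for (i in seq_len(nrow(e))) {
    if (e$mode[i] == "pulse") {
      omega0 <- omega0 + e$intensity[i]
      next
    }
    if (e$mode[i] == "exponential")
      abort("internal: discretize before pk_ej")
    rate <- 1 / (2 * B * e$n_recent[i])
    d <- e$duration[i]
    seg <- if (is.infinite(d)) exp(-cj * omega0) / (cj * rate)
           else exp(-cj * omega0) * (1 - exp(-cj * rate * d)) / (cj * rate)
    ej <- ej + seg
    if (!is.infinite(d)) omega0 <- omega0 + rate * d
  }
  ej
}

# Expected duration with k ancestral lineages, k = 2..n, from the classical
# distribution of the lineage-count process under arbitrary N(t):
# E[T_k] = sum_{j>=k} rho_{jk} e_j with alternating-sign coefficients.
# Alternating sums limit usable sample sizes (roughly n <= 50 in doubles).
# (Direct per-coefficient evaluation; expected_sfs_pk uses the cached
# matrix form. At constant size E[T_k] = 4N/(k(k-1)).)
pk_expected_tk <- function(ej, n) {
  tk <- numeric(n - 1) # index k-1
  for (k in 2:n) {
    acc <- 0
    for (j in k:n) {
      lmag <- log(2 * j - 1) +
        (lgamma(k + j - 1) - lgamma(k)) +        # rising (k)_(j-1)
        (lgamma(n + 1) - lgamma(n - j + 1)) -    # falling [n]_(j)
        lgamma(k + 1) - lgamma(j - k + 1) -
        (lgamma(n + j) - lgamma(n))              # rising (n)_(j)
      sgn <- if ((j - k) %% 2 == 0) 1 else -1
      acc <- acc + sgn * exp(lmag) * ej[j - 1]
    }
    tk[k - 1] <- acc
  }
  tk
}

# P(a mutation on a branch present while k lineages subtends b of n leaves)
pk_pbk <- function(n) {
  outer(1:(n - 1), 2:n, function(b, k)
    exp(lchoose(n - b - 1, k - 2) - lchoose(n - 1, k - 1)))
}

# cached (n-1) x (n-1) matrix A with lb = A %*% ej (depends on n only)
.pk_cache <- new.env(parent = emptyenv())
pk_matrix <- function(n) {
  key <- paste0("n", n)
  if (!is.null(.pk_cache[[key]])) return(.pk_cache[[key]])
  rho <- matrix(0, n - 1, n - 1) # [j-1, k-1]
  for (k in 2:n) for (j in k:n) {
    lmag <- log(2 * j - 1) +
      (lgamma(k + j - 1) - lgamma(k)) -
      lgamma(k + 1) - lgamma(j - k + 1) +
      (lgamma(n + 1) - lgamma(n - j + 1)) -
      (lgamma(n + j) - lgamma(n))
    rho[j - 1, k - 1] <- (if ((j - k) %% 2 == 0) 1 else -1) * exp(lmag)
  }
  A <- pk_pbk(n) %*% ((2:n) * t(rho))
  .pk_cache[[key]] <- A
  A
}

#' Expected site frequency spectrum under a piecewise history
#'
#' Expected relative frequencies of derived-allele classes `1..n_hap-1` for
#' an arbitrary piecewise-constant/exponential population-size history,
#' optionally rescaled by a background-selection factor `B` that multiplies
#' every population size (B never reshapes the spectrum directly; it only
#' rescales the time axis of the history). Exponential epochs are
#' discretised into piecewise-constant steps, doubling the step count until
#' the spectrum changes by less than `tol`.
#'
#' @param demog A [demography()].
#' @param n_hap Number of sampled haplotypes (default 20; the alternating
#'   sums behind the computation lose precision beyond roughly 50, where a
#'   warning is issued).
#' @param B Background-selection rescaling in (0, 1].
#' @param steps Initial number of discretisation steps per exponential epoch.
#' @param tol Convergence tolerance on the discretised spectrum.
#' @return An `expected_sfs` object with probabilities `p` (summing to 1)
#'   and expected branch lengths `length` (generations) per class.
#' @examples
#' expected_sfs_pk(demog_constant(1e4), n_hap = 4)$p # (6, 3, 2)/11
#' @export
expected_sfs_pk <- function(demog, n_hap = 20, B = 1, steps = 50,
                            tol = 1e-4) {
  stopifnot(n_hap >= 2, B > 0, B <= 1 + 1e-12)
  if (n_hap > 50)
    warn("n_hap > 50: expected-SFS computation may be numerically unstable")
  A <- pk_matrix(n_hap)
  compute <- function(st) {
    d <- discretize_demography(demog, st)
    as.vector(A %*% pk_ej(d, B, n_hap))
  }
  lb <- compute(steps)
  if (any(demog$epochs$mode == "exponential") && is.finite(tol)) {
    repeat {
      steps <- steps * 2
      lb2 <- compute(steps)
      if (max(abs(lb2 / sum(lb2) - lb / sum(lb))) < tol || steps >= 1600) {
        lb <- lb2
        break
      }
      lb <- lb2
    }
  }
  if (any(lb <= 0))
    warn("non-positive expected class lengths: numerical instability")
  structure(list(p = lb / sum(lb), length = lb, n_hap = n_hap, B = B,
                 demography = demog), class = "expected_sfs")
}

#' @export
print.expected_sfs <- function(x, ...) {
  cat(sprintf("<expected_sfs> n_hap = %d, B = %g\n", x$n_hap, x$B))
  print(round(x$p, 4))
  invisible(x)
}

#' @export
as_tibble.expected_sfs <- function(x, ...) {
  tibble(derived_copies = seq_len(x$n_hap - 1), p = x$p, length = x$length)
}

#' Expected pairwise diversity through a size change
#'
#' Returns a function `pi(t)`: the expected per-site pairwise diversity when
#' sampling `t` generations after the onset of the most recent epoch of
#' `demog` (that epoch is truncated at `t`; during an exponential epoch the
#' population sits on its exponential path). Computed as
#' `2 * mu * E[pairwise coalescence time]` with every size multiplied by
#' `B`; closed form over constant pieces, discretisation for exponentials.
#'
#' @param demog A [demography()]; the first epoch is the "change" epoch.
#' @param B Background-selection rescaling of all sizes.
#' @param mu Mutation rate per site per generation.
#' @return Vectorised function of `t >= 0` (generations).
#' @export
expected_pi_trajectory <- function(demog, B = 1, mu = 1e-8) {
  e <- demog$epochs
  force(B); force(mu)
  function(t) {
    vapply(t, function(ti) {
      if (ti < 0) abort("t must be >= 0")
      ee <- e
      if (ti == 0) {
        ee <- ee[-1, , drop = FALSE]
        if (nrow(ee) == 0) ee <- e
      } else if (is.finite(ee$duration[1])) {
        if (ee$mode[1] == "exponential") {
          d <- ee$duration[1]
          tt <- min(ti, d)
          g <- log(ee$n_recent[1] / ee$n_ancient[1]) / d
          # size at elapsed time tt along the path from the ancient end
          ee$n_recent[1] <- ee$n_ancient[1] * exp(g * tt)
          ee$duration[1] <- tt
          if (ti > d) { # change completed; population sits at the end size
            ee <- bind_rows(tibble(duration = ti - d,
                                   n_recent = ee$n_recent[1],
                                   n_ancient = ee$n_recent[1],
                                   mode = "constant", intensity = 0), ee)
          }
        } else {
          ee$duration[1] <- ti
        }
      }
      d2 <- demography(ee, "trajectory")
      dd <- discretize_demography(d2, 200)
      2 * mu * pk_ej(dd, B, 2)
    }, numeric(1))
  }
}

#' Apparent B after a population-size change
#'
#' The ratio of diversity with background selection to diversity without it,
#' measured `t_elapsed` generations after the onset of the most recent epoch
#' of `demog`, predicted by pure rescaling: both diversities follow neutral
#' pairwise theory, with all population sizes multiplied by `b0` (the
#' equilibrium B in the ancestral population, e.g. measured from simulation)
#' for the selected trajectory and by 1 for the neutral one. For a step
#' change `N0 -> N1` this reduces to
#' `Bhat(t) = b0 * (N1 + (N0-N1) exp(-t/(2 b0 N1))) /
#'                 (N1 + (N0-N1) exp(-t/(2 N1)))`.
#'
#' @param b0 Ancestral equilibrium B, in (0, 1].
#' @param demog A [demography()] whose first epoch is the size change.
#' @param t_elapsed Generations since the onset of the change (vectorised).
#' @return Tibble with `t` and `b_hat`.
#' @export
apparent_b_after_change <- function(b0, demog, t_elapsed) {
  stopifnot(b0 > 0, b0 <= 1)
  if (any(t_elapsed < 0)) abort("t_elapsed must be >= 0")
  sel <- expected_pi_trajectory(demog, B = b0, mu = 1)
  neu <- expected_pi_trajectory(demog, B = 1, mu = 1)
  tibble(t = t_elapsed, b_hat = sel(t_elapsed) / neu(t_elapsed))
}

#' Equilibrium B from the classical background-selection formula
#'
#' Predicted diversity reduction `B = pi/pi0` at a neutral focal position
#' linked to selected sites, in the deterministic (strong-selection) regime:
#' `B = exp(-sum_j u * t_j / (t_j + r_j (1 - t_j))^2)` summing over selected
#' positions `j`, with heterozygous effect `t = s/2` and recombination
#' fraction `r_j` between focal and selected site (Haldane map applied to
#' `rec_rate * distance`). The DFE is integrated by Gauss-Legendre
#' quadrature within each bin. When an appreciable fraction of the DFE mass
#' lies at `2*N*s < 10` the deterministic formula is unreliable and the
#' result carries `weak_selection_warning = TRUE`.
#'
#' @param focal_pos Neutral focal position (bp, 0-based).
#' @param layout A [genome_layout()] or exon-interval data frame.
#' @param dfe A [dfe()].
#' @param mu_del Deleterious mutation rate per exonic site per generation
#'   (the full per-site rate; class proportions come from the DFE).
#' @param rec_rate Recombination rate per site per generation.
#' @param max_sites Cap on evaluated selected positions (positions are
#'   strided beyond this and reweighted).
#' @return A tibble with `b` and `weak_selection_warning`.
#' @export
equilibrium_b <- function(focal_pos, layout, dfe, mu_del, rec_rate,
                          max_sites = 20000) {
  exons <- if (inherits(layout, "genome_layout"))
    layout_intervals(layout, "exon") else as_tibble(layout)
  pos <- unlist(purrr::map2(exons$start, exons$end, seq, by = 1))
  pos <- pos[pos != focal_pos]
  stride <- max(1, ceiling(length(pos) / max_sites))
  pos <- pos[seq(1, length(pos), by = stride)]
  # 16-point Gauss-Legendre nodes on [0,1]
  gl <- legendre_nodes_16()
  expo <- 0
  for (cls in 1:4) {
    if (dfe$f[cls] == 0) next
    lo <- dfe$bin_bounds[cls, "lower"]; hi <- dfe$bin_bounds[cls, "upper"]
    s_nodes <- (lo + gl$x * (hi - lo)) / (2 * dfe$n_anc)
    t_nodes <- s_nodes / 2
    for (q in seq_along(s_nodes)) {
      tt <- t_nodes[q]
      if (tt <= 0) next
      d <- abs(pos - focal_pos)
      rj <- 0.5 * (1 - exp(-2 * rec_rate * d))
      expo <- expo + dfe$f[cls] * gl$w[q] *
        sum(mu_del * tt / (tt + rj * (1 - tt))^2) * stride
    }
  }
  mass_weak <- sum(dfe$f[c(1, 2)])
  tibble(b = exp(-expo),
         weak_selection_warning = mass_weak > 0.01)
}

legendre_nodes_16 <- function() {
  # nodes/weights for Gauss-Legendre on [0, 1]
  x <- c(0.0052995325041750, 0.0277124884633837, 0.0671843988060841,
         0.1222977958224985, 0.1910618777986781, 0.2709916111713863,
         0.3591982246103705, 0.4524937450811813, 0.5475062549188187,
         0.6408017753896295, 0.7290083888286137, 0.8089381222013219,
         0.8777022041775015, 0.9328156011939159, 0.9722875115366163,
         0.9947004674958250)
  w <- c(0.0135762297058770, 0.0311267619693239, 0.0475792558412464,
         0.0623144856277669, 0.0747979944082884, 0.0845782596975012,
         0.0913017075224617, 0.0947253052275342, 0.0947253052275342,
         0.0913017075224617, 0.0845782596975012, 0.0747979944082884,
         0.0623144856277669, 0.0475792558412464, 0.0311267619693239,
         0.0135762297058770)
  list(x = x, w = w)
}
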