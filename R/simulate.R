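#' Neutral coalescent simulation under a piecewise history
#'
#' Samples haplotypes from the neutral coalescent for a chromosome of length
#' `L`. Recombination is handled by splitting the sequence into chunks that
#' are simulated independently (free recombination between chunks, none
#' within); the default chunk length is chosen so that the population-scaled
#' recombination rate per chunk, `4*N*r*chunk_bp`, is about one. Means of
#' diversity, segregating sites and the SFS are unaffected by this
#' approximation; only linkage across chunk boundaries is.
#'
#' @param demog A [demography()].
#' @param L Sequence length in bp.
#' @param n_hap Number of sampled haplotypes (>= 2).
#' @param mu Mutation rate per site per generation.
#' @param r Recombination rate per site per generation (sets the chunking).
#' @param seed Integer seed (required: simulations are reproducible).
#' @param n_rep Number of independent replicates.
#' @param B Background-selection rescaling factor applied to all sizes.
#' @param chunk_bp Override the chunk length in bp.
#' @param output `"haplotypes"` (full sample, single replicate),
#'   `"sites"` (positions + derived counts, single replicate),
#'   `"sfs"` (matrix of SFS counts, `n_rep` rows), or
#'   `"S"` (tibble of segregating-site counts per replicate).
#' @return See `output`.
#' @examples
#' s <- sim_neutral(demog_constant(5000), 1e5, 20, 1e-7, seed = 1)
#' @export
sim_neutral <- function(demog, L, n_hap, mu, r = 1e-8, seed,
                        n_rep = 1, B = 1,
                        chunk_bp = NULL,
                        output = c("haplotypes", "sites", "sfs", "S")) {
  output <- match.arg(output)
  stopifnot(inherits(demog, "demography"), n_hap >= 2, L >= 1, mu >= 0, B > 0)
  if (missing(seed)) abort("seed is required")
  if (is.null(chunk_bp)) {
    n_now <- demog$epochs$n_recent[1]
    chunk_bp <- if (r <= 0) L else max(1000, round(1 / (4 * n_now * r)))
    chunk_bp <- min(chunk_bp, L)
  }
  ep <- as_epoch_matrix(demog)
  mode <- switch(output, S = 0L, sfs = 1L, sites = 2L, haplotypes = 2L)
  res <- coalescent_engine_cpp(as.integer(n_hap), L, mu, ep, B, chunk_bp,
                               as.integer(n_rep), mode, as.integer(seed))
  if (output == "S") return(tibble(rep = seq_len(n_rep), S = res$S))
  if (output == "sfs") {
    m <- res$sfs
    colnames(m) <- as.character(seq_len(n_hap - 1))
    return(m)
  }
  pos <- as.integer(res$pos)
  keep <- !duplicated(pos) # finite-sites: drop rare position collisions
  pos <- pos[keep]
  carriers <- res$carriers[keep]
  counts <- vapply(carriers, length, integer(1))
  if (output == "sites")
    return(tibble(chrom = 1L, pos = pos, count = counts))
  geno <- matrix(0L, n_hap, length(pos))
  for (j in seq_along(carriers)) geno[carriers[[j]] + 1L, j] <- 1L
  new_haplotype_sample(geno, pos, L = L,
                       s = numeric(length(pos)),
                       class = rep(-1L, length(pos)),
                       engine = "coalescent")
}

new_haplotype_sample <- function(geno, pos, L, s, class,
                                 fixations = tibble(pos = integer(),
                                                    gen = integer(),
                                                    class = integer(),
                                                    s = numeric()),
                                 n_mono_derived = 0L,
                                 gens_post_burnin = NA_real_,
                                 engine = "forward") {
  stopifnot(ncol(geno) == length(pos))
  if (is.unsorted(pos, strictly = TRUE) && length(pos) > 1)
    abort("positions must be strictly increasing")
  structure(list(
    geno = geno, pos = as.integer(pos), s = s, class = as.integer(class),
    L = L, n_hap = nrow(geno), fixations = fixations,
    n_mono_derived = as.integer(n_mono_derived),
    gens_post_burnin = gens_post_burnin, engine = engine
  ), class = "haplotype_sample")
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat(sprintf(
    "<haplotype_sample> %d haplotypes x %d segregating sites over %s bp (%s engine)\n",
    x$n_hap, length(x$pos), format(x$L, big.mark = ","), x$engine))
  invisible(x)
}

#' Site table of a haplotype sample
#'
#' @param x A `haplotype_sample`.
#' @param ... Unused.
#' @return Tibble with `pos`, `count` (derived copies), `s`, `class`.
#' @export
as_tibble.haplotype_sample <- function(x, ...) {
  tibble(pos = x$pos, count = colSums(x$geno), s = x$s, class = x$class)
}

#' Forward Wright-Fisher simulation with purifying selection
#'
#' Simulates a diploid Wright-Fisher population along a chromosome whose
#' exonic positions draw selection coefficients from a discrete DFE (other
#' positions are neutral). Fitness is multiplicative across sites with
#' genotype fitnesses `1, 1 - s/2, 1 - s`. A burn-in of
#' `burnin_mult * n_anc` generations at the ancestral size precedes the
#' demographic epochs; fixations after the burn-in are recorded for
#' divergence estimates. All parameters may be rescaled by `Q`
#' (`N/Q, sQ, muQ, rQ, t/Q`), preserving `4Nmu`, `4Nr` and `2Ns`.
#'
#' @param layout A [genome_layout()], or a two-column matrix/data frame of
#'   exon intervals (0-based half-open); use `NULL` for a fully neutral
#'   chromosome of length `L`.
#' @param dfe A [dfe()] (ignored when `layout` is `NULL`).
#' @param demog A [demography()]; its open-ended ancestral size is the
#'   burn-in population size.
#' @param mu,r Per-site per-generation mutation and recombination rates
#'   (unscaled).
#' @param n_sample Diploid individuals sampled without replacement at the end.
#' @param seed Integer seed.
#' @param Q Rescaling factor.
#' @param L Chromosome length (only needed when `layout` is `NULL`).
#' @param burnin_mult Burn-in length in units of the ancestral size
#'   (default 10 for `init = "founder"`, 2 for `init = "coalescent"`).
#' @param init Burn-in initialisation. `"founder"` starts from a
#'   monomorphic population and runs the full burn-in. `"coalescent"` seeds
#'   the population with a neutral-coalescent equilibrium sample of
#'   `2 * n_anc` haplotypes and runs a shortened burn-in during which
#'   selected-site frequencies equilibrate; a speed mode appropriate when
#'   direct selection is strong relative to `1/(2N)` (mutation-selection
#'   balance is reached quickly) and BGS within the simulated region is
#'   weak.
#' @param class0_neutral Treat class-0 (effectively neutral) mutations as
#'   strictly neutral (s = 0).
#' @param mu_map,rec_map Optional [rate_maps()]-style step functions; default
#'   uniform rates.
#' @return A `haplotype_sample`.
#' @export
sim_forward <- function(layout, dfe = NULL, demog, mu, r, n_sample, seed,
                        Q = 1, L = NULL, burnin_mult = NULL,
                        init = c("founder", "coalescent"),
                        class0_neutral = FALSE,
                        mu_map = NULL, rec_map = NULL) {
  init <- match.arg(init)
  if (is.null(burnin_mult))
    burnin_mult <- if (init == "founder") 10 else 2
  if (missing(seed)) abort("seed is required")
  if (inherits(layout, "genome_layout")) {
    exm <- as.matrix(layout_intervals(layout, "exon")[, c("start", "end")])
    L <- layout$chrom_length
  } else if (is.null(layout)) {
    if (is.null(L)) abort("L required when layout is NULL")
    exm <- matrix(integer(0), ncol = 2)
  } else {
    exm <- as.matrix(as.data.frame(layout)[, 1:2])
    if (is.null(L)) L <- max(exm[, 2])
  }
  dm <- if (Q != 1) rescale_demography(demog, Q) else demog
  mu_s <- mu * Q
  r_s <- r * Q
  n_anc_scaled <- demog_n_anc(dm)
  if (n_anc_scaled < 2) abort("scaled ancestral size < 2")
  f <- if (is.null(dfe)) c(1, 0, 0, 0) else dfe$f
  if (is.null(dfe)) class0_neutral <- TRUE
  mu_breaks <- if (is.null(mu_map)) c(0, L) else mu_map$breaks
  mu_rates <- if (is.null(mu_map)) mu_s else mu_map$rates * Q
  rec_breaks <- if (is.null(rec_map)) c(0, L) else rec_map$breaks
  rec_rates <- if (is.null(rec_map)) r_s else rec_map$rates * Q
  ep <- as_forward_epochs(dm)
  init_sites <- NULL
  if (init == "coalescent") {
    n2 <- 2L * as.integer(round(n_anc_scaled))
    cs <- coalescent_engine_cpp(n2, L, mu_s, as_epoch_matrix(
      demog_constant(n_anc_scaled)), 1,
      if (r_s <= 0) L else min(L, max(1000, round(1 / (4 * n_anc_scaled *
                                                         r_s)))),
      1L, 2L, as.integer(seed) + 999331L)
    pos <- as.integer(cs$pos)
    keep <- !duplicated(pos)
    init_sites <- list(pos = pos[keep], carriers = cs$carriers[keep])
  }
  res <- forward_wf_cpp(L, matrix(as.integer(exm), ncol = 2),
                        mu_breaks, mu_rates, rec_breaks, rec_rates,
                        f, n_anc_scaled, class0_neutral,
                        as.integer(round(n_anc_scaled)), burnin_mult, ep,
                        as.integer(n_sample), as.integer(seed),
                        init_sites = init_sites)
  fix <- tibble(pos = res$fix_pos, gen = res$fix_gen,
                class = res$fix_class, s = res$fix_s)
  new_haplotype_sample(res$geno, res$pos, L = L, s = res$s,
                       class = res$class, fixations = fix,
                       n_mono_derived = res$n_mono_derived,
                       gens_post_burnin = res$gens_post_burnin,
                       engine = "forward")
}

#' Mask sets: genomic intervals excluded from analyses
#'
#' @param intervals Data frame with `start`, `end` (0-based half-open) and
#'   optionally `label`.
#' @param chrom_length Chromosome length the mask applies to.
#' @return A `mask_set`; overlapping intervals are merged.
#' @export
mask_set <- function(intervals, chrom_length) {
  iv <- as_tibble(intervals)
  if (nrow(iv) == 0)
    return(structure(list(intervals = tibble(start = integer(),
                                             end = integer(),
                                             label = character()),
                          chrom_length = chrom_length), class = "mask_set"))
  if (!"label" %in% names(iv)) iv$label <- "mask"
  if (any(iv$start < 0 | iv$end > chrom_length))
    abort("mask intervals outside chromosome bounds")
  iv <- dplyr::arrange(iv, .data$start)
  merged <- list()
  cur <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] <= cur$end) {
      cur$end <- max(cur$end, iv$end[i])
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- iv[i, ]
    }
  }
  merged[[length(merged) + 1]] <- cur
  structure(list(intervals = bind_rows(merged), chrom_length = chrom_length),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %d interval(s), %s of %s bp masked\n",
              nrow(x$intervals),
              format(sum(x$intervals$end - x$intervals$start),
                     big.mark = ","),
              format(x$chrom_length, big.mark = ",")))
  invisible(x)
}

#' Random repeat-like masks covering a target fraction of the chromosome
#'
#' Draws non-overlapping segments with lengths from `length_sampler` until
#' the requested fraction of the chromosome is covered (the last segment is
#' truncated), placing them uniformly.
#'
#' @param chrom_length Chromosome length in bp.
#' @param fraction Fraction of the chromosome to mask, in (0, 1).
#' @param length_sampler Function `n -> n segment lengths` (bp). Default
#'   draws log-normal lengths with a median of about 1 kb, loosely shaped
#'   like genomic repeat-length distributions.
#' @param seed Integer seed.
#' @export
sample_repeat_masks <- function(chrom_length, fraction,
                                length_sampler = function(n)
                                  pmax(50, round(exp(rnorm(n, log(1000), 1)))),
                                seed) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  if (missing(seed)) abort("seed is required")
  withr_seed(seed, {
    target <- fraction * chrom_length
    lens <- numeric(0)
    while (sum(lens) < target) {
      new <- as.numeric(length_sampler(64))
      if (any(new <= 0)) abort("length_sampler produced non-positive lengths")
      lens <- c(lens, new)
    }
    over <- which(cumsum(lens) >= target)[1]
    lens <- lens[seq_len(over)]
    lens[over] <- lens[over] - (sum(lens) - target) # truncate the last
    # place uniformly without overlap: sample gaps by a stick-breaking draw
    free <- chrom_length - sum(lens)
    cuts <- sort(runif(length(lens), 0, free))
    starts <- round(cuts + cumsum(c(0, head(lens, -1))))
    iv <- tibble(start = starts, end = round(starts + lens), label = "repeat")
    mask_set(iv, chrom_length)
  })
}

#' Centromere mask for the simulated 150 Mb chromosomes
#'
#' A single 4 Mb interval at 48.5-52.5 Mb.
#'
#' @param chrom_length Chromosome length; must be at least 52.5 Mb.
#' @export
centromere_mask <- function(chrom_length) {
  if (chrom_length < 52.5e6) abort("chromosome shorter than the centromere")
  mask_set(tibble(start = 48.5e6, end = 52.5e6, label = "centromere"),
           chrom_length)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Positions covered by a mask
#'
#' @param mask A `mask_set` (or `NULL` for no masking).
#' @param pos Integer positions (0-based).
#' @return Logical vector, `TRUE` where masked.
#' @export
is_masked <- function(mask, pos) {
  if (is.null(mask) || nrow(mask$intervals) == 0)
    return(rep(FALSE, length(pos)))
  iv <- mask$intervals
  idx <- findInterval(pos, iv$start)
  idx > 0 & pos < iv$end[pmax(idx, 1)]
}

#' Unmasked sequence length
#' @param mask A `mask_set` or `NULL`.
#' @param L Total length.
#' @export
unmasked_length <- function(mask, L) {
  if (is.null(mask)) return(L)
  L - sum(pmin(mask$intervals$end, L) - pmax(mask$intervals$start, 0))
}
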