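#' Build a gene/intron/intergenic genome layout
#'
#' Tiles a chromosome with identical genes separated by intergenic tracts.
#' Each gene consists of `exons_per_gene` exons of `exon_bp` bases alternating
#' with `exons_per_gene - 1` introns of `intron_bp` bases. The chromosome
#' starts with a full intergenic tract, followed by `n_genes` repeats of
#' (gene + intergenic tract), with the final intergenic tract shortened by one
#' base; `n_genes` is `round(target_chrom_bp / (gene_bp + intergenic_bp))`.
#' With the default human-like exon structure this reproduces chromosomes of
#' 150,018,599 / 150,029,949 / 150,003,699 bp carrying 2,737 / 5,164 / 11,278
#' genes for ~5/10/20% functional density.
#'
#' @param exon_bp Exon length in bp.
#' @param exons_per_gene Number of exons per gene.
#' @param intron_bp Intron length in bp.
#' @param intergenic_bp Intergenic tract length in bp.
#' @param target_chrom_bp Desired approximate chromosome length in bp.
#' @param chrom_count Number of identical chromosomes in the genome.
#' @return A `genome_layout` object: a list with `chrom_length`, `n_genes`,
#'   `functional_fraction`, `chrom_count`, and a tibble `intervals` of 0-based
#'   half-open `[start, end)` ranges labelled exon/intron/intergenic.
#' @examples
#' gl <- genome_layout(350, 8, 600, 6300, 150e6)
#' gl$n_genes      # 11278
#' gl$chrom_length # 150003699
#' @export
genome_layout <- function(exon_bp = 350, exons_per_gene = 8, intron_bp = 600,
                          intergenic_bp = 6300, target_chrom_bp = 150e6,
                          chrom_count = 1L) {
  stopifnot(chrom_count >= 1)
  if (any(c(exon_bp, exons_per_gene, intron_bp, intergenic_bp,
            target_chrom_bp) <= 0))
    abort("all layout lengths must be positive")
  gene_bp <- exons_per_gene * exon_bp + (exons_per_gene - 1) * intron_bp
  unit <- gene_bp + intergenic_bp
  if (target_chrom_bp < unit)
    abort("target_chrom_bp smaller than one gene + intergenic unit")
  n_genes <- round(target_chrom_bp / unit)
  chrom_length <- intergenic_bp + n_genes * unit - 1

  # one gene's internal structure, relative to its start
  ex_off <- (seq_len(exons_per_gene) - 1) * (exon_bp + intron_bp)
  gene_starts <- intergenic_bp + (seq_len(n_genes) - 1) * unit

  exon_start <- as.vector(outer(ex_off, gene_starts, `+`))
  exons <- tibble(start = exon_start, end = exon_start + exon_bp,
                  feature = "exon")
  if (exons_per_gene > 1) {
    in_off <- ex_off[-exons_per_gene] + exon_bp
    intr_start <- as.vector(outer(in_off, gene_starts, `+`))
    introns <- tibble(start = intr_start, end = intr_start + intron_bp,
                      feature = "intron")
  } else {
    introns <- tibble(start = integer(), end = integer(), feature = character())
  }
  inter_start <- c(0, gene_starts + gene_bp)
  inter_end <- c(gene_starts, chrom_length)
  inter <- tibble(start = inter_start, end = inter_end, feature = "intergenic")

  intervals <- dplyr::arrange(bind_rows(exons, introns, inter), .data$start)
  structure(list(
    chrom_count = as.integer(chrom_count),
    chrom_length = chrom_length,
    n_genes = n_genes,
    gene_bp = gene_bp,
    exon_bp = exon_bp,
    exons_per_gene = exons_per_gene,
    intron_bp = intron_bp,
    intergenic_bp = intergenic_bp,
    functional_fraction = n_genes * exons_per_gene * exon_bp / chrom_length,
    intervals = intervals
  ), class = "genome_layout")
}

#' Preset genome layouts with 5/10/20% functional density
#'
#' @param density One of "genome5", "genome10", "genome20".
#' @param target_chrom_bp Chromosome length target (default 150 Mb).
#' @param chrom_count Number of chromosomes.
#' @export
genome_layout_preset <- function(density = c("genome20", "genome10", "genome5"),
                                 target_chrom_bp = 150e6, chrom_count = 1L) {
  density <- match.arg(density)
  p <- switch(density,
    genome5  = c(intron = 3000, intergenic = 31000),
    genome10 = c(intron = 1500, intergenic = 15750),
    genome20 = c(intron = 600, intergenic = 6300))
  genome_layout(350, 8, p[["intron"]], p[["intergenic"]], target_chrom_bp,
                chrom_count)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "<genome_layout> %d chromosome(s) of %s bp, %d genes each (%.1f%% exonic)\n",
    x$chrom_count, format(x$chrom_length, big.mark = ","), x$n_genes,
    100 * x$functional_fraction))
  invisible(x)
}

#' Extract feature intervals from a layout as a tibble
#'
#' @param layout A `genome_layout`.
#' @param feature Feature type(s) to keep: "exon", "intron", "intergenic",
#'   or "gene" (exons+introns merged per gene).
#' @return Tibble with columns `start`, `end`, `feature` (0-based half-open).
#' @export
layout_intervals <- function(layout, feature = c("exon", "intron",
                                                 "intergenic", "gene")) {
  feature <- match.arg(feature)
  if (feature == "gene") {
    gene_starts <- layout$intergenic_bp +
      (seq_len(layout$n_genes) - 1) * (layout$gene_bp + layout$intergenic_bp)
    return(tibble(start = gene_starts, end = gene_starts + layout$gene_bp,
                  feature = "gene"))
  }
  filter(layout$intervals, .data$feature == !!feature)
}

#' Discrete four-class DFE
#'
#' A distribution of fitness effects with four fixed classes of scaled
#' selection coefficients `2 * n_anc * s`: effectively neutral `[0, 1)`,
#' weakly `[1, 10)`, moderately `[10, 100)`, and strongly deleterious
#' `[100, 2 * n_anc)`, where `s` is the homozygous fitness reduction and
#' `n_anc` the ancestral diploid population size. `s` is uniform within each
#' bin and mutations are semidominant (h = 0.5).
#'
#' @param f Numeric vector `(f0, f1, f2, f3)` of class proportions, sum 1.
#' @param n_anc Ancestral diploid population size anchoring the bin bounds.
#' @return A `discrete_dfe` object.
#' @examples
#' dfe(c(0.25, 0.25, 0.25, 0.25), n_anc = 1e4)
#' @export
dfe <- function(f, n_anc) {
  f <- as.numeric(f)
  if (length(f) != 4 || any(f < 0) || any(f > 1))
    abort("f must be four proportions in [0, 1]")
  if (abs(sum(f) - 1) > 1e-12) abort("DFE proportions must sum to 1")
  if (n_anc < 50) abort("n_anc too small for the strongly deleterious bin")
  structure(list(
    f = f,
    n_anc = n_anc,
    bin_bounds = cbind(lower = c(0, 1, 10, 100),
                       upper = c(1, 10, 100, 2 * n_anc)),
    h = 0.5
  ), class = "discrete_dfe")
}

#' Named DFE presets
#'
#' Six fixed DFE shapes used throughout the package: three unimodal shapes
#' concentrating 70% of mutations in the weak (DFE1), moderate (DFE2) or
#' strong (DFE3) class with 10% in each other class, a uniform shape (DFE4),
#' and two neutral+strong bimodal shapes (DFE5: 50/50, DFE6: 70/30).
#'
#' @param name "DFE1".."DFE6" or "neutral" (f0 = 1).
#' @param n_anc Ancestral diploid size for the bin bounds.
#' @export
dfe_preset <- function(name, n_anc) {
  tab <- list(
    DFE1 = c(0.1, 0.7, 0.1, 0.1),
    DFE2 = c(0.1, 0.1, 0.7, 0.1),
    DFE3 = c(0.1, 0.1, 0.1, 0.7),
    DFE4 = c(0.25, 0.25, 0.25, 0.25),
    DFE5 = c(0.5, 0.0, 0.0, 0.5),
    DFE6 = c(0.7, 0.0, 0.0, 0.3),
    neutral = c(1, 0, 0, 0))
  if (!name %in% names(tab)) abort("unknown DFE preset")
  dfe(tab[[name]], n_anc)
}

#' @export
print.discrete_dfe <- function(x, ...) {
  cat(sprintf("<discrete_dfe> f = (%s), n_anc = %g\n",
              paste(format(x$f), collapse = ", "), x$n_anc))
  invisible(x)
}

#' Enumerate the grid of discrete DFEs with proportions on a lattice
#'
#' All four-class proportion vectors whose entries are multiples of `step`
#' and sum to one. With `step = 0.05` there are `choose(23, 3) = 1771`.
#'
#' @param step Lattice spacing; `1/step` must be an integer.
#' @return Tibble with columns `f0..f3`, one row per DFE.
#' @export
dfe_grid <- function(step = 0.05) {
  m <- 1 / step
  if (abs(m - round(m)) > 1e-9) abort("1/step must be an integer")
  m <- as.integer(round(m))
  grid <- expand.grid(i0 = 0:m, i1 = 0:m, i2 = 0:m)
  grid$i3 <- m - grid$i0 - grid$i1 - grid$i2
  grid <- grid[grid$i3 >= 0, , drop = FALSE]
  out <- tibble(f0 = grid$i0 / m, f1 = grid$i1 / m,
                f2 = grid$i2 / m, f3 = grid$i3 / m)
  out[order(out$f0, out$f1, out$f2, decreasing = TRUE), ]
}

#' Sample selection coefficients from a discrete DFE
#'
#' Draws the class with probabilities `f`, then `2 * n_anc * s` uniform on
#' the class interval. `s` is the homozygous fitness reduction.
#'
#' @param x A `discrete_dfe`.
#' @param n Number of draws.
#' @return Tibble with columns `class` (0-3), `two_n_s`, `s`.
#' @export
sample_selection_coefficients <- function(x, n = 1) {
  stopifnot(inherits(x, "discrete_dfe"))
  cls <- sample.int(4, n, replace = TRUE, prob = x$f) - 1L
  lo <- x$bin_bounds[cls + 1, "lower"]
  hi <- x$bin_bounds[cls + 1, "upper"]
  tns <- runif(n, lo, hi)
  tibble(class = cls, two_n_s = tns, s = tns / (2 * x$n_anc))
}

#' Rescale population-genetic parameters by a factor Q
#'
#' Applies the standard simulation rescaling: sizes and times are divided
#' by Q while selection, mutation and recombination rates are multiplied by
#' Q, leaving the composite parameters `4*N*mu`, `4*N*r` and `2*N*s`
#' invariant.
#'
#' @param params A list with any of `n` (diploid size), `s`, `mu`, `r`,
#'   `t` (generations).
#' @param Q Rescaling factor, `>= 1`.
#' @return The transformed list with attribute `Q`.
#' @export
rescale_params <- function(params, Q) {
  if (Q < 1) abort("Q must be >= 1")
  out <- params
  if (!is.null(out$n)) {
    out$n <- out$n / Q
    if (any(out$n < 2)) abort("rescaling collapses the population (N/Q < 2)")
  }
  if (!is.null(out$s)) out$s <- out$s * Q
  if (!is.null(out$mu)) out$mu <- out$mu * Q
  if (!is.null(out$r)) out$r <- out$r * Q
  if (!is.null(out$t)) out$t <- out$t / Q
  attr(out, "Q") <- Q
  out
}
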