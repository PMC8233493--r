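# File formats. Everything internal is 0-based half-open; 1-based conversions
# are isolated to the writers that need them (VCF, multihetsep).

#' Write / read an SFS file
#'
#' Plain-text format: a header line `#sfs n_hap=<n> folded=<0|1>` followed by
#' one line of `n_hap + 1` whitespace-separated class counts (classes
#' `0..n_hap`).
#'
#' @param x An [sfs()].
#' @param path Output path.
#' @export
write_sfs <- function(x, path) {
  writeLines(c(sprintf("#sfs n_hap=%d folded=%d", x$n_hap,
                       as.integer(x$folded)),
               paste(format(x$counts, scientific = FALSE, trim = TRUE),
                     collapse = " ")), path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hd <- lines[[1]]
  if (!grepl("^#sfs", hd)) abort("not an SFS file")
  n_hap <- as.integer(sub(".*n_hap=(\\d+).*", "\\1", hd))
  folded <- sub(".*folded=(\\d+).*", "\\1", hd) == "1"
  counts <- as.numeric(strsplit(trimws(lines[[2]]), "\\s+")[[1]])
  sfs(counts, n_hap, folded = folded)
}

#' Write an SFS in a fastsimcoal2-style observed-DAF dialect
#'
#' Two header lines (`1 observations`, tab-separated class labels
#' `d0_0..d0_<n>`) and one line of counts — the `_DAFpop0.obs` layout.
#'
#' @inheritParams write_sfs
#' @export
write_sfs_daf <- function(x, path) {
  n <- x$n_hap
  writeLines(c("1 observations",
               paste(paste0("d0_", 0:n), collapse = "\t"),
               paste(format(x$counts, scientific = FALSE, trim = TRUE),
                     collapse = "\t")), path)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param intervals Data frame with `start`, `end`, optional `feature` name
#'   column; or a [mask_set()] / [genome_layout()].
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_bed <- function(intervals, path, chrom = "chr1") {
  if (inherits(intervals, "mask_set")) intervals <- intervals$intervals
  if (inherits(intervals, "genome_layout")) intervals <- intervals$intervals
  nm <- if ("feature" %in% names(intervals)) intervals$feature
        else if ("label" %in% names(intervals)) intervals$label else "."
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom,
                     as.integer(intervals$start), as.integer(intervals$end),
                     nm), path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "label"),
                          fill = TRUE, stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Write a haplotype sample as phased diploid VCF
#'
#' Haplotypes `2i-1, 2i` form individual `i`. Alleles are encoded as
#' REF=A (ancestral), ALT=T (derived). Positions are converted to 1-based.
#'
#' @param sample A `haplotype_sample` with an even number of haplotypes.
#' @param path Output path.
#' @param chrom Chromosome name.
#' @export
write_vcf <- function(sample, path, chrom = "chr1") {
  n_ind <- sample$n_hap / 2
  if (n_ind != floor(n_ind)) abort("odd number of haplotypes")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", chrom,
                       as.integer(sample$L)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("ind", seq_len(n_ind))),
                     collapse = "\t")), con)
  if (length(sample$pos)) {
    gt <- vapply(seq_len(n_ind), function(i)
      paste(sample$geno[2 * i - 1, ], sample$geno[2 * i, ], sep = "|"),
      character(length(sample$pos)))
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = length(sample$pos))
    lines <- paste(chrom, sample$pos + 1L, ".", "A", "T", ".", "PASS", ".",
                   "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write MSMC multihetsep input
#'
#' Columns: chromosome, 1-based position, number of called sites since the
#' last segregating site (masked sites are not counted as called), and the
#' phased genotype string across individuals. Masked segregating sites are
#' dropped.
#'
#' @param sample A phased diploid `haplotype_sample`.
#' @param mask Optional [mask_set()].
#' @param path Output path (or `""` to return the lines).
#' @param chrom Chromosome name.
#' @export
write_multihetsep <- function(sample, mask = NULL, path = "", chrom = "chr1") {
  if (sample$n_hap %% 2 != 0) abort("multihetsep requires phased diploids")
  keep <- !is_masked(mask, sample$pos)
  pos <- sample$pos[keep]
  geno <- sample$geno[, keep, drop = FALSE]
  alleles <- c("A", "C")
  lines <- character(length(pos))
  prev <- -1L
  for (j in seq_along(pos)) {
    # called (unmasked) sites strictly between the previous SNP and this one
    span <- pos[j] - prev
    if (!is.null(mask) && nrow(mask$intervals)) {
      lo <- prev + 1L
      hi <- pos[j]
      iv <- mask$intervals
      ov <- pmin(iv$end, hi + 1) - pmax(iv$start, lo)
      masked_in <- sum(pmax(0, ov))
      # the SNP itself is unmasked (filtered above)
      span <- span - masked_in
    }
    gt <- paste(alleles[geno[, j] + 1L], collapse = "")
    lines[j] <- sprintf("%s\t%d\t%d\t%s", chrom, pos[j] + 1L, span, gt)
    prev <- pos[j]
  }
  if (nzchar(path)) {
    writeLines(lines, path)
    invisible(path)
  } else lines
}

#' Step-function rate maps for mutation and recombination
#'
#' @param breaks Window boundaries in bp (length `n + 1`, starting at 0).
#' @param rates Per-site per-generation rates (length `n`).
#' @export
rate_map <- function(breaks, rates) {
  if (length(breaks) != length(rates) + 1) abort("breaks/rates mismatch")
  if (is.unsorted(breaks, strictly = TRUE)) abort("breaks must increase")
  if (any(rates < 0)) abort("rates must be >= 0")
  structure(list(breaks = breaks, rates = rates), class = "rate_map")
}

mean_rate <- function(map) {
  w <- diff(map$breaks)
  sum(map$rates * w) / sum(w)
}

#' Read recombination and mutation rate maps
#'
#' The recombination map is HapMap-style text with a header and columns
#' (chromosome, position, rate in cM/Mb, ...); rates are converted to
#' per-site per-generation (1 cM/Mb = 1e-8). The mutation map is a
#' two-column (position, rate) window file. Windows with missing data
#' inherit the previous window's rate; intervals listed in `centromere`
#' get recombination rate 0. The mutation map is rescaled so its
#' genome-wide mean equals `target_mean_mu`.
#'
#' @param rec_file,mut_file Paths (either may be `NULL`).
#' @param L Chromosome length in bp.
#' @param target_mean_mu Normalisation target for the mean mutation rate.
#' @param centromere Optional [mask_set()] interval(s) with zero
#'   recombination.
#' @return List with `rec` and `mut` [rate_map()]s.
#' @export
read_rate_maps <- function(rec_file = NULL, mut_file = NULL, L,
                           target_mean_mu = 1e-8, centromere = NULL) {
  parse_map <- function(path, conv) {
    df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    posc <- names(df)[vapply(df, is.numeric, logical(1))][1]
    ratec <- names(df)[vapply(df, is.numeric, logical(1))][2]
    pos <- df[[posc]]
    rate <- df[[ratec]] * conv
    if (is.unsorted(pos, strictly = TRUE)) abort("map positions must increase")
    # windows [pos_i, pos_{i+1}); leading gap inherits the first rate,
    # missing (NA) windows inherit the previous one
    rate <- fill_forward(rate)
    breaks <- c(0, pos[-1], L)
    keep <- breaks[-length(breaks)] < L
    rate_map(unique(pmin(c(breaks[keep], L), L)), rate[keep])
  }
  rec <- if (is.null(rec_file)) rate_map(c(0, L), 1e-8)
         else parse_map(rec_file, 1e-8)
  mut <- if (is.null(mut_file)) rate_map(c(0, L), target_mean_mu)
         else parse_map(mut_file, 1)
  if (!is.null(centromere)) {
    for (i in seq_len(nrow(centromere$intervals))) {
      s <- centromere$intervals$start[i]
      e <- centromere$intervals$end[i]
      rec <- set_interval_rate(rec, s, e, 0)
    }
  }
  m <- mean_rate(mut)
  if (m > 0) mut$rates <- mut$rates * target_mean_mu / m
  list(rec = rec, mut = mut)
}

fill_forward <- function(x) {
  if (length(x) == 0) return(x)
  if (is.na(x[1])) x[1] <- x[which(!is.na(x))[1]]
  for (i in seq_along(x)[-1]) if (is.na(x[i])) x[i] <- x[i - 1]
  x
}

set_interval_rate <- function(map, s, e, value) {
  breaks <- sort(unique(c(map$breaks, s, e)))
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  idx <- findInterval(mids, map$breaks, rightmost.closed = TRUE)
  rates <- map$rates[pmax(1, pmin(idx, length(map$rates)))]
  rates[mids >= s & mids < e] <- value
  rate_map(breaks, rates)
}

#' Read and hash a declarative run configuration
#'
#' A run configuration is a plain-text file of `key = value` lines (`#`
#' comments allowed) naming the layout, DFE, demography, rates, rescaling
#' factor and seed of a run. Values are parsed as numbers where possible.
#' The configuration hash recorded in outputs is the hash of the sorted
#' key/value list, so semantically identical files hash identically.
#'
#' @param path Path to the configuration file.
#' @return Named list with attribute `hash`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) abort("malformed config line(s)")
  out <- lapply(kv, function(x) {
    num <- suppressWarnings(as.numeric(x[2]))
    if (is.na(num)) x[2] else num
  })
  names(out) <- vapply(kv, `[`, character(1), 1)
  attr(out, "hash") <- config_hash(out)
  out
}

#' @rdname read_run_config
#' @param config A named list.
#' @export
config_hash <- function(config) {
  config <- config[order(names(config))]
  attr(config, "hash") <- NULL
  rlang::hash(config)
}

#' Write / read an ABC reference table (TSV + JSON sidecar)
#'
#' The table itself is a TSV with a header row; provenance (engine, seed,
#' neutral flag, failure count, configuration and its hash, exon set) goes
#' to a `.json` sidecar next to it.
#'
#' @param table An `abc_reference_table`.
#' @param path TSV path; the sidecar is `paste0(path, ".json")`.
#' @export
write_abc_table <- function(table, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("jsonlite is required to write reference tables")
  utils::write.table(table$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cfg <- table$config
  cfg$exon_table <- NULL
  meta <- list(engine = "forward_wf", neutral = table$neutral,
               seed = table$seed, n_failed = table$n_failed,
               config = cfg[!vapply(cfg, is.null, logical(1))],
               config_hash = config_hash(cfg[!vapply(cfg, is.null,
                                                     logical(1))]),
               exons = table$exons)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_abc_table
#' @export
read_abc_table <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("jsonlite is required to read reference tables")
  tab <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(abc_config, meta$config[setdiff(names(meta$config),
                                                 "init")])
  cfg$init <- meta$config$init %||% "founder"
  structure(list(table = tab, exons = as_tibble(meta$exons), config = cfg,
                 neutral = isTRUE(meta$neutral), seed = meta$seed,
                 n_failed = meta$n_failed),
            class = "abc_reference_table")
}
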