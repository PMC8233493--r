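# Nuisance-DFE ABC: infer (n_anc, n_cur) from directly selected regions
# while marginalising over the shape of the DFE.

#' Configuration for the exon-based ABC experiment
#'
#' Defaults follow a Drosophila-like setting: 94 single-exon genes of 1.5 kb,
#' per-exon recombination rates log-uniform over `rec_range`, mutation rate
#' 3e-9 per site per generation, sizes drawn uniform between 1e5 and 1e7
#' diploids, a one-epoch exponential size change starting 1e6 generations
#' ago, and rescaling by Q = 320 (scaled sizes roughly 300..31,000).
#' All values are overridable; reduced-scale studies shrink `n_exons`,
#' the size bounds and Q (see the methods vignette).
#'
#' @param n_exons Number of unlinked exons.
#' @param exon_bp Exon length (bp).
#' @param mu Mutation rate per site per generation (unscaled).
#' @param rec_range Range of per-exon recombination rates (unscaled),
#'   sampled log-uniformly per exon.
#' @param size_bounds Prior bounds on diploid sizes (unscaled).
#' @param t_change Time of the size change in generations (unscaled).
#' @param Q Rescaling factor applied to every simulation.
#' @param n_sample Diploid individuals sampled per simulated data set.
#' @param dfe_step DFE-grid lattice spacing for the nuisance prior.
#' @param exon_table Optional user-supplied tibble with columns `exon_bp`
#'   and `rec_rate`, overriding the generated exon set.
#' @param init Burn-in initialisation passed to [sim_forward()]
#'   (`"founder"` or `"coalescent"`).
#' @export
abc_config <- function(n_exons = 94, exon_bp = 1500, mu = 3e-9,
                       rec_range = c(1e-9, 1e-8),
                       size_bounds = c(1e5, 1e7), t_change = 1e6,
                       Q = 320, n_sample = 50, dfe_step = 0.05,
                       exon_table = NULL, init = "founder") {
  structure(list(n_exons = n_exons, exon_bp = exon_bp, mu = mu,
                 rec_range = rec_range, size_bounds = size_bounds,
                 t_change = t_change, Q = Q, n_sample = n_sample,
                 dfe_step = dfe_step, exon_table = exon_table,
                 init = init),
            class = "abc_config")
}

abc_exon_set <- function(config, seed) {
  if (!is.null(config$exon_table)) return(as_tibble(config$exon_table))
  withr_seed(seed, tibble(
    exon_bp = rep(config$exon_bp, config$n_exons),
    rec_rate = exp(runif(config$n_exons, log(config$rec_range[1]),
                         log(config$rec_range[2])))))
}

#' Draw parameters from the ABC priors
#'
#' Sizes uniform on `size_bounds`; the DFE uniform over the lattice of
#' four-class proportion vectors with spacing `dfe_step` (1,771 points at
#' step 0.05). With `neutral = TRUE` all rows are strictly neutral
#' (`f0 = 1`, selection disabled).
#'
#' @param n Number of draws.
#' @param config An [abc_config()].
#' @param seed Integer seed.
#' @param neutral Draw neutral rows instead of nuisance-DFE rows.
#' @return Tibble with `n_anc`, `n_cur`, `f0..f3`.
#' @export
abc_sample_priors <- function(n, config = abc_config(), seed, neutral = FALSE) {
  if (missing(seed)) abort("seed is required")
  grid <- dfe_grid(config$dfe_step)
  if (nrow(grid) == 0) abort("empty DFE grid")
  withr_seed(seed, {
    out <- tibble(
      n_anc = runif(n, config$size_bounds[1], config$size_bounds[2]),
      n_cur = runif(n, config$size_bounds[1], config$size_bounds[2]))
    if (neutral) {
      out$f0 <- 1; out$f1 <- 0; out$f2 <- 0; out$f3 <- 0
    } else {
      idx <- sample.int(nrow(grid), n, replace = TRUE)
      out <- dplyr::bind_cols(out, grid[idx, ])
    }
    out
  })
}

abc_simulate_one <- function(n_anc, n_cur, f, config, exons, seed,
                             neutral = FALSE) {
  demog <- demog_exponential(n_anc, n_cur, config$t_change)
  stats <- purrr::map_dfr(seq_len(nrow(exons)), function(i) {
    ex_bp <- exons$exon_bp[i]
    lay <- tibble(start = 0, end = ex_bp)
    d <- if (neutral || all(f[-1] == 0) && f[1] == 1) NULL
         else dfe(f, n_anc / config$Q)
    smp <- sim_forward(
      layout = if (is.null(d)) NULL else lay,
      dfe = d, demog = demog, mu = config$mu, r = exons$rec_rate[i],
      n_sample = config$n_sample, seed = seed + i * 131L,
      Q = config$Q, L = ex_bp, class0_neutral = neutral,
      init = config$init %||% "founder")
    window_stats(smp, tibble(start = 0, end = ex_bp), seed = seed)
  })
  abc_stat_vector(stats)
}

#' Build an ABC reference table
#'
#' For each prior draw, forward-simulates every exon under a one-epoch
#' exponential size change with the drawn DFE and computes the 22-statistic
#' vector. Simulation failures are logged and dropped, never imputed.
#'
#' @param priors Tibble from [abc_sample_priors()].
#' @param config An [abc_config()].
#' @param seed Integer seed; every row is independently seeded from it.
#' @param neutral Simulate all rows strictly neutrally (reference table for
#'   the neutral-assumption mode).
#' @param progress Print progress every 50 rows.
#' @return A `abc_reference_table`: tibble of parameters + statistics, with
#'   the exon set and config attached.
#' @export
abc_build_table <- function(priors, config = abc_config(), seed,
                            neutral = FALSE, progress = FALSE) {
  if (missing(seed)) abort("seed is required")
  exons <- abc_exon_set(config, seed)
  rows <- vector("list", nrow(priors))
  n_fail <- 0
  for (i in seq_len(nrow(priors))) {
    f <- as.numeric(priors[i, c("f0", "f1", "f2", "f3")])
    sv <- try(abc_simulate_one(priors$n_anc[i], priors$n_cur[i], f, config,
                               exons, seed = seed + i * 7919L,
                               neutral = neutral), silent = TRUE)
    if (inherits(sv, "try-error") || any(!is.finite(sv[c(1, 2)]))) {
      n_fail <- n_fail + 1
      next
    }
    rows[[i]] <- dplyr::bind_cols(priors[i, ], as_tibble(as.list(sv)))
    if (progress && i %% 50 == 0) message("row ", i, "/", nrow(priors))
  }
  out <- bind_rows(rows)
  structure(list(table = out, exons = exons, config = config,
                 neutral = neutral, seed = seed, n_failed = n_fail),
            class = "abc_reference_table")
}

#' @export
print.abc_reference_table <- function(x, ...) {
  cat(sprintf("<abc_reference_table> %d rows (%s mode, %d failed), %d exons\n",
              nrow(x$table), if (x$neutral) "neutral" else "nuisance-DFE",
              x$n_failed, nrow(x$exons)))
  invisible(x)
}

#' ABC rejection step
#'
#' Statistics are robust-standardised (median absolute deviation) and the
#' nearest `tolerance` fraction of reference rows by Euclidean distance is
#' retained. Zero-spread statistics are dropped from the distance with a
#' warning.
#'
#' @param obs Named 22-statistic vector of the observed data.
#' @param table An `abc_reference_table`.
#' @param tolerance Fraction of rows to accept, in (0, 1].
#' @return Tibble of accepted rows with a `distance` column.
#' @export
abc_reject <- function(obs, table, tolerance = 0.1) {
  if (tolerance <= 0 || tolerance > 1) abort("tolerance must be in (0, 1]")
  tab <- table$table
  stat_cols <- intersect(abc_stat_names(), names(tab))
  X <- as.matrix(tab[, stat_cols])
  o <- obs[stat_cols]
  scale <- apply(X, 2, stats::mad)
  usable <- is.finite(scale) & scale > 0 & is.finite(o)
  drop_n <- sum(!usable)
  if (drop_n > 0)
    warn(sprintf("%d statistic(s) dropped from the ABC distance", drop_n))
  if (!any(usable)) abort("no usable statistics")
  Z <- sweep(X[, usable, drop = FALSE], 2, scale[usable], `/`)
  zo <- o[usable] / scale[usable]
  d <- sqrt(rowSums(sweep(Z, 2, zo, `-`)^2))
  n_keep <- max(1, round(tolerance * nrow(tab)))
  idx <- order(d)[seq_len(n_keep)]
  out <- tab[idx, ]
  out$distance <- d[idx]
  attr(out, "usable_stats") <- stat_cols[usable]
  out
}

#' Regression adjustment of accepted ABC draws
#'
#' Nonlinear regression of each parameter on the standardised statistics
#' within the accepted set (single-hidden-layer neural network, width 5,
#' 10 restarts, Epanechnikov distance weights), adjusted to the observed
#' statistics; sizes are adjusted on log scale. Falls back to local-linear
#' regression, then to rejection-only, on degeneracy.
#'
#' @param accepted Tibble from [abc_reject()].
#' @param obs The observed statistic vector.
#' @param method "neuralnet", "loclinear" or "rejection".
#' @param params Parameter columns to adjust.
#' @param hidden Hidden-layer width.
#' @param restarts Neural-net restarts (averaged).
#' @param bounds Optional named list of `c(lower, upper)` prior bounds per
#'   parameter; when given, regression and adjustment act on the logit of
#'   the rescaled parameter so adjusted draws respect the prior support
#'   (otherwise the log scale is used).
#' @return An `abc_posterior` with draws, weights and point estimates
#'   (weighted medians).
#' @export
abc_adjust <- function(accepted, obs, method = c("neuralnet", "loclinear",
                                                 "rejection"),
                       params = c("n_anc", "n_cur"), hidden = 5,
                       restarts = 10, bounds = NULL) {
  method <- match.arg(method)
  if (nrow(accepted) == 0) abort("no accepted draws")
  stat_cols <- attr(accepted, "usable_stats") %||%
    intersect(abc_stat_names(), names(accepted))
  X <- as.matrix(accepted[, stat_cols])
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  X <- sweep(sweep(X[, keep, drop = FALSE], 2,
                   colMeans(X[, keep, drop = FALSE])), 2, sds[keep], `/`)
  xo <- (obs[stat_cols][keep] - colMeans(as.matrix(accepted[, stat_cols])[,
        keep, drop = FALSE])) / sds[keep]
  dmax <- max(accepted$distance)
  wts <- if (dmax > 0) 1 - (accepted$distance / dmax)^2 else
    rep(1, nrow(accepted))
  wts[wts <= 0] <- min(wts[wts > 0], 1e-6)
  draws <- accepted[, params]
  used <- method
  to_working <- function(x, b) {
    if (is.null(b)) return(log(x))
    z <- pmin(pmax((x - b[1]) / (b[2] - b[1]), 1e-6), 1 - 1e-6)
    log(z / (1 - z))
  }
  from_working <- function(y, b) {
    if (is.null(b)) return(exp(y))
    b[1] + (b[2] - b[1]) / (1 + exp(-y))
  }
  if (method != "rejection" && ncol(X) > 0 && nrow(accepted) > 10) {
    for (p in params) {
      b <- bounds[[p]]
      y <- to_working(accepted[[p]], b)
      pred_obs <- NA_real_
      if (method == "neuralnet") {
        preds <- rep(0, nrow(X)); po <- 0; ok <- 0
        for (rs in seq_len(restarts)) {
          fit <- try(withr_seed(rs * 97 + 1, nnet::nnet(
            X, y, size = hidden, linout = TRUE, trace = FALSE,
            weights = wts, decay = 1e-3, maxit = 500)), silent = TRUE)
          if (inherits(fit, "try-error")) next
          ok <- ok + 1
          preds <- preds + as.vector(stats::predict(fit, X))
          po <- po + as.vector(stats::predict(fit, matrix(xo, 1)))
        }
        if (ok > 0) {
          preds <- preds / ok; pred_obs <- po / ok
        } else used <- "loclinear"
      }
      if (used == "loclinear" || method == "loclinear") {
        fit <- try(stats::lm.wfit(cbind(1, X), y, wts), silent = TRUE)
        if (inherits(fit, "try-error") || any(is.na(fit$coefficients))) {
          used <- "rejection"
        } else {
          co <- fit$coefficients
          preds <- as.vector(cbind(1, X) %*% co)
          pred_obs <- sum(c(1, xo) * co)
          used <- if (method == "neuralnet") used else "loclinear"
        }
      }
      if (used != "rejection")
        draws[[p]] <- from_working(y - preds + pred_obs, b)
    }
  } else if (method != "rejection") {
    used <- "rejection"
  }
  w <- wts / sum(wts)
  pe <- vapply(params, function(p) weighted_median(draws[[p]], w), numeric(1))
  structure(list(draws = as_tibble(draws), weights = w,
                 point_estimates = pe, method = used,
                 tolerance = attr(accepted, "tolerance")),
            class = "abc_posterior")
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> %d draws (%s adjustment)\n",
              nrow(x$draws), x$method))
  print(round(x$point_estimates))
  invisible(x)
}

#' End-to-end ABC demographic inference
#'
#' Computes the 22-statistic vector of the observed exon sample(s), runs
#' rejection against the reference table and regression adjustment, and
#' returns the posterior. `mode = "neutral_assumption"` requires a table
#' built with `neutral = TRUE`; `mode = "nuisance_dfe"` a table whose rows
#' vary the DFE.
#'
#' @param obs_stats Observed 22-statistic vector (from [abc_stat_vector()]
#'   over per-exon [window_stats()]).
#' @param table An `abc_reference_table`.
#' @param mode Inference mode; must match how the table was built.
#' @param tolerance Acceptance fraction.
#' @param method Adjustment method (see [abc_adjust()]).
#' @export
abc_infer <- function(obs_stats, table,
                      mode = c("nuisance_dfe", "neutral_assumption"),
                      tolerance = 0.1, method = "neuralnet") {
  mode <- match.arg(mode)
  if (mode == "neutral_assumption" && !table$neutral)
    abort("neutral_assumption mode needs a neutral reference table")
  if (mode == "nuisance_dfe" && table$neutral)
    abort("nuisance_dfe mode needs a nuisance-DFE reference table")
  acc <- abc_reject(obs_stats, table, tolerance)
  attr(acc, "tolerance") <- tolerance
  sb <- table$config$size_bounds
  abc_adjust(acc, obs_stats, method = method,
             bounds = list(n_anc = sb, n_cur = sb))
}

#' Simulate an observed data set for the ABC experiment
#'
#' Generates test data exactly as reference-table rows are generated.
#'
#' @param n_anc,n_cur True diploid sizes (unscaled).
#' @param f DFE proportions (length 4), or `NULL` for strict neutrality.
#' @param config An [abc_config()].
#' @param table Optionally, a reference table whose exon set should be
#'   reused (recommended).
#' @param seed Integer seed.
#' @return The 22-statistic vector.
#' @export
abc_simulate_testset <- function(n_anc, n_cur, f = NULL,
                                 config = abc_config(), table = NULL,
                                 seed) {
  if (missing(seed)) abort("seed is required")
  exons <- if (!is.null(table)) table$exons else abc_exon_set(config, seed)
  if (!is.null(table)) config <- table$config
  neutral <- is.null(f)
  if (neutral) f <- c(1, 0, 0, 0)
  abc_simulate_one(n_anc, n_cur, f, config, exons, seed, neutral = neutral)
}
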