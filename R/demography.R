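#' Piecewise population-size histories
#'
#' A demography is an ordered set of epochs, backwards in time from the
#' present. Each epoch has a duration in generations (the last is open-ended),
#' diploid sizes at its recent and ancient edges, and a mode: `"constant"`,
#' `"exponential"` (size changes exponentially, forward in time), or
#' `"pulse"` (an instantaneous burst of coalescent intensity with zero
#' duration, used for instantaneous-bottleneck models; `intensity` is the
#' added pairwise coalescent integral, so a pair coalesces during the pulse
#' with probability `1 - exp(-intensity)`).
#'
#' @param epochs A data frame with columns `duration`, `n_recent`,
#'   `n_ancient`, `mode`, and optionally `intensity` (pulses only).
#' @param label Optional text label.
#' @return A `demography` object.
#' @export
demography <- function(epochs, label = "") {
  epochs <- as_tibble(epochs)
  if (!"intensity" %in% names(epochs)) epochs$intensity <- 0
  req <- c("duration", "n_recent", "n_ancient", "mode")
  if (!all(req %in% names(epochs))) abort("missing epoch columns")
  if (!all(epochs$mode %in% c("constant", "exponential", "pulse")))
    abort("epoch mode must be constant, exponential or pulse")
  sizes <- c(epochs$n_recent[epochs$mode != "pulse"],
             epochs$n_ancient[epochs$mode != "pulse"])
  if (any(sizes <= 0)) abort("population sizes must be positive")
  if (any(epochs$duration[epochs$mode != "pulse"] <= 0))
    abort("epoch durations must be positive")
  if (any(epochs$duration[epochs$mode == "pulse"] != 0))
    abort("pulse epochs must have zero duration")
  last <- epochs[nrow(epochs), ]
  if (!(last$mode == "constant" && is.infinite(last$duration)))
    abort("final epoch must be constant with infinite duration")
  if (any(is.infinite(epochs$duration[-nrow(epochs)])))
    abort("only the final epoch may be open-ended")
  structure(list(epochs = epochs, label = label), class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("<demography> %s (%d epoch(s), backwards in time)\n",
              if (nzchar(x$label)) x$label else "unnamed", nrow(x$epochs)))
  print(x$epochs)
  invisible(x)
}

#' @rdname demography
#' @param n Diploid population size.
#' @export
demog_constant <- function(n, label = sprintf("equilibrium N=%g", n)) {
  demography(tibble(duration = Inf, n_recent = n, n_ancient = n,
                    mode = "constant"), label)
}

#' @rdname demography
#' @param n_anc,n_cur Ancestral and current diploid sizes.
#' @param t_change Time of the change, generations before present.
#' @export
demog_step <- function(n_anc, n_cur, t_change,
                       label = sprintf("step %g -> %g at %g", n_anc, n_cur,
                                       t_change)) {
  demography(tibble(
    duration = c(t_change, Inf),
    n_recent = c(n_cur, n_anc),
    n_ancient = c(n_cur, n_anc),
    mode = "constant"), label)
}

#' @rdname demography
#' @export
demog_exponential <- function(n_anc, n_cur, t_change,
                              label = sprintf("exponential %g -> %g over %g",
                                              n_anc, n_cur, t_change)) {
  demography(tibble(
    duration = c(t_change, Inf),
    n_recent = c(n_cur, n_anc),
    n_ancient = c(n_anc, n_anc),
    mode = c("exponential", "constant")), label)
}

#' @rdname demography
#' @param intensity Bottleneck intensity (pairwise coalescent integral).
#' @param t_event Time of the bottleneck, generations before present.
#' @export
demog_bottleneck <- function(n_anc, intensity, t_event,
                             label = sprintf("bottleneck I=%g at %g",
                                             intensity, t_event)) {
  demography(tibble(
    duration = c(t_event, 0, Inf),
    n_recent = c(n_anc, n_anc, n_anc),
    n_ancient = c(n_anc, n_anc, n_anc),
    mode = c("constant", "pulse", "constant"),
    intensity = c(0, intensity, 0)), label)
}

#' Built-in demographic histories
#'
#' Human-motivated defaults: `"equilibrium"` (N = 10,000); `"growth"`, a
#' 30-fold recent exponential growth (1,000 -> 30,000 over 850 generations);
#' `"decline"`, a ~6-fold instantaneous decline (12,300 -> 2,100 at 2,000
#' generations); plus gentler 2-fold variants `"growth2x"` and `"decline2x"`.
#' These are package defaults in the spirit of published human histories, not
#' calibrated estimates; every preset can be rebuilt with other values via
#' [demog_step()] / [demog_exponential()].
#'
#' @param name Preset name.
#' @param Q Optional rescaling factor applied via [rescale_demography()].
#' @export
demog_preset <- function(name = c("equilibrium", "growth", "decline",
                                  "growth2x", "decline2x"), Q = 1) {
  name <- match.arg(name)
  d <- switch(name,
    equilibrium = demog_constant(10000, "equilibrium"),
    growth = demog_exponential(1000, 30000, 850, "30-fold exponential growth"),
    decline = demog_step(12300, 2100, 2000, "~6-fold instantaneous decline"),
    growth2x = demog_exponential(10000, 20000, 1000, "2-fold growth"),
    decline2x = demog_step(10000, 5000, 1000, "2-fold decline"))
  if (Q != 1) d <- rescale_demography(d, Q) else d
}

#' Rescale a demography by a factor Q
#'
#' Sizes `N -> N/Q`, times `t -> t/Q`; pulse intensities are invariant, as
#' are the composite parameters once rates are rescaled with [rescale_params()].
#'
#' @param demog A `demography`.
#' @param Q Rescaling factor.
#' @export
rescale_demography <- function(demog, Q) {
  if (Q < 1) abort("Q must be >= 1")
  e <- demog$epochs
  e$n_recent <- e$n_recent / Q
  e$n_ancient <- e$n_ancient / Q
  e$duration <- e$duration / Q
  if (any(e$n_recent[e$mode != "pulse"] < 2)) abort("N/Q < 2: Q too large")
  demography(e, paste0(demog$label, sprintf(" [Q=%g]", Q)))
}

#' Population size at a time in the past
#'
#' @param demog A `demography`.
#' @param t Time before present, generations (vectorised).
#' @return Diploid size N(t).
#' @export
demog_size_at <- function(demog, t) {
  e <- demog$epochs[demog$epochs$mode != "pulse", ]
  starts <- cumsum(c(0, head(e$duration, -1)))
  vapply(t, function(ti) {
    i <- max(which(starts <= ti))
    x <- ti - starts[i]
    if (e$mode[i] == "exponential") {
      g <- log(e$n_recent[i] / e$n_ancient[i]) / e$duration[i]
      e$n_recent[i] * exp(-g * x)
    } else e$n_recent[i]
  }, numeric(1))
}

# matrix form consumed by the C++ coalescent engine:
# columns duration, n_recent, n_ancient, mode(0 const/1 exp), jump
as_epoch_matrix <- function(demog) {
  e <- demog$epochs
  cbind(e$duration,
        e$n_recent,
        e$n_ancient,
        ifelse(e$mode == "exponential", 1, 0),
        ifelse(e$mode == "pulse", e$intensity, 0))
}

# forward-time epoch matrix for the Wright-Fisher engine: rows oldest first,
# columns gens, Nstart, Nend, mode(0/1); the open-ended ancestral epoch is
# dropped (it is the burn-in population).
as_forward_epochs <- function(demog) {
  e <- demog$epochs
  if (any(e$mode == "pulse"))
    abort("pulse epochs are not supported by the forward engine")
  e <- e[-nrow(e), , drop = FALSE]
  if (nrow(e) == 0)
    return(matrix(numeric(0), ncol = 4))
  e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
  cbind(e$duration, e$n_ancient, e$n_recent,
        ifelse(e$mode == "exponential", 1, 0))
}

# ancestral (pre-change) size
demog_n_anc <- function(demog) {
  tail(demog$epochs$n_ancient, 1)
}
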