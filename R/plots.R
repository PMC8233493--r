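# ggplot2 visualisations

#' @export
autoplot.sfs <- function(object, proportions = TRUE, drop_monomorphic = TRUE,
                         ...) {
  df <- as_tibble(object)
  if (drop_monomorphic)
    df <- df[df$derived_copies > 0 & df$derived_copies < object$n_hap, ]
  if (proportions) df$sites <- df$sites / sum(df$sites)
  ggplot2::ggplot(df, ggplot2::aes(.data$derived_copies, .data$sites)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "derived copies", y = if (proportions) "proportion"
                  else "sites") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.expected_sfs <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$derived_copies, .data$p)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "derived copies", y = "expected proportion") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.demography <- function(object, t_max = NULL, ...) {
  e <- object$epochs[object$epochs$mode != "pulse", ]
  if (is.null(t_max))
    t_max <- 2 * sum(e$duration[is.finite(e$duration)]) + 1000
  t <- seq(0, t_max, length.out = 400)
  df <- tibble(t = t, n = demog_size_at(object, t))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$n)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generations before present", y = "diploid N") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.abc_posterior <- function(object, truth = NULL, ...) {
  df <- tidyr::pivot_longer(object$draws, dplyr::everything(),
                            names_to = "term", values_to = "value")
  w <- rep(object$weights, each = ncol(object$draws))
  df$weight <- w
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$value,
                                        weight = .data$weight)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "diploid N", y = "posterior density") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    tl <- tibble(term = names(truth), value = unname(unlist(truth)))
    p <- p + ggplot2::geom_vline(data = tl,
                                 ggplot2::aes(xintercept = .data$value),
                                 linetype = 2)
  }
  p
}

#' Plot an apparent-B trajectory
#'
#' @param b0 Ancestral equilibrium B.
#' @param demog A [demography()] whose first epoch is the size change.
#' @param t_max Trajectory horizon in generations.
#' @export
plot_b_trajectory <- function(b0, demog, t_max) {
  df <- apparent_b_after_change(b0, demog, seq(0, t_max, length.out = 200))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$b_hat)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = b0, linetype = 2) +
    ggplot2::labs(x = "generations since size change", y = "apparent B") +
    ggplot2::theme_minimal()
}
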