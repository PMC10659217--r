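#' Plot a k-some distribution
#'
#' Column plot of `P_k` with the infinite-lifetime Poisson limit overlaid
#' as points — the standard way to see the low-`k` degradation plateau and
#' the population inversion.
#'
#' @param object A [ksome_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ksome_distribution
#' @export
autoplot.ksome_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$probability), fill = "steelblue", width = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$poisson_limit), colour = "grey30", size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ribosomes per mRNA (k)", y = expression(P[k]),
                  title = sprintf("k-some distribution (alpha_t = %.3g, omega_t = %.3g)",
                                  attr(object, "alpha_t"), attr(object, "omega_t"))) +
    ggplot2::theme_minimal()
}

#' Plot per-codon density profiles
#'
#' Line plot of one or more profiles in the long (`class`, `codon`,
#' `value`) layout, one colour per class.
#'
#' @param profiles Tibble with columns `class`, `codon`, `value`.
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$codon, y = .data$value, colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "codon", y = "ribosome density (ribosomes/codon)") +
    ggplot2::theme_minimal()
}

#' @method autoplot density_profile
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$codon, y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "codon", y = "ribosome density (ribosomes/codon)",
                  title = attr(object, "role")) +
    ggplot2::theme_minimal()
}

#' Plot a benchmark score curve
#'
#' Averaged relative-error score functions against the `R_1(0)` target,
#' with per-profile scores in pale points.
#'
#' @param object A [run_benchmark()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot score_curve
#' @export
autoplot.score_curve <- function(object, ...) {
  long_scores <- tidyr::pivot_longer(object$scores,
                                     cols = c("err_alpha", "err_mean", "err_max"),
                                     names_to = "score", values_to = "error")
  long_summary <- tidyr::pivot_longer(object$summary,
                                      cols = c("err_alpha", "err_mean", "err_max"),
                                      names_to = "score", values_to = "error")
  ggplot2::ggplot(long_summary,
                  ggplot2::aes(x = .data$ratio, y = .data$error, colour = .data$score)) +
    ggplot2::geom_point(data = long_scores, alpha = 0.25, size = 0.8) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(R[1](0)), y = "relative error") +
    ggplot2::theme_minimal()
}

#' Plot the translation phase diagram
#'
#' Boundary curves from [phase_boundaries()] in the
#' `(alpha_t, omega_t)` plane, optionally with classified points (e.g.
#' from [classify_genes()]) overlaid.
#'
#' @param boundaries A [phase_boundaries()] tibble.
#' @param points Optional tibble with `alpha_t`, `omega_t` (and `regime`).
#' @return A ggplot.
#' @export
plot_phase_diagram <- function(boundaries, points = NULL) {
  gg <- ggplot2::ggplot(dplyr::filter(boundaries, !is.na(.data$omega_t)),
                        ggplot2::aes(x = .data$alpha_t, y = .data$omega_t,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tilde(alpha)), y = expression(tilde(omega))) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    gg <- gg + ggplot2::geom_point(data = points, inherit.aes = FALSE,
                                   ggplot2::aes(x = .data$alpha_t, y = .data$omega_t))
  }
  gg
}
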