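#' Degradation-regime classification
#'
#' Places points of the `(alpha_t, omega_t)` plane into the three
#' degradation regimes of the model: high degradation (HD) when
#' `omega_t >= omega_threshold` (polysomes themselves are distorted),
#' intermediate (ID) when `R_1(0) >= r1_threshold` (k-somes feel
#' degradation, polysomes do not — the regime where the inverse fit works),
#' low (LD) otherwise. Points exactly on a boundary go to the
#' higher-degradation regime. Both order-one thresholds are conventions and
#' are exposed as arguments.
#'
#' @param alpha_t,omega_t Dimensionless rates; vectorized (recycled).
#' @param r1_threshold LD/ID boundary value of `R_1(0)` (default 5).
#' @param omega_threshold ID/HD boundary value of `omega_t` (default 1).
#' @return A tibble with columns `alpha_t`, `omega_t`, `r1_entry`,
#'   `mean_k`, `regime` (factor LD/ID/HD).
#' @export
classify_phase <- function(alpha_t, omega_t, r1_threshold = 5, omega_threshold = 1) {
  n <- max(length(alpha_t), length(omega_t))
  alpha_t <- rep_len(alpha_t, n)
  omega_t <- rep_len(omega_t, n)
  r1 <- purrr::map2_dbl(alpha_t, omega_t, ~ transient_ratio_entry(.x, .y, 1))
  regime <- dplyr::case_when(
    omega_t >= omega_threshold ~ "HD",
    r1 >= r1_threshold ~ "ID",
    TRUE ~ "LD"
  )
  tibble(alpha_t = alpha_t, omega_t = omega_t, r1_entry = r1,
         mean_k = mean_ribosomes(alpha_t, omega_t),
         regime = factor(regime, levels = c("LD", "ID", "HD")))
}

#' Phase-boundary curves
#'
#' For a grid of `alpha_t` values, computes the `omega_t` of the LD/ID
#' boundary (`R_1(0) = r1_threshold`, solved on the exact closed form), the
#' ID/HD boundary (`omega_t = omega_threshold`), and constant-`<k>` contours
#' (`alpha_t * f(omega_t) = level`). All roots by bracketed bisection to
#' 1e-10. A contour point with `level >= alpha_t` does not exist (since
#' `f <= 1`) and is returned as `NA`.
#'
#' @param alpha_t Positive grid of dimensionless initiation rates.
#' @param mean_k_levels `<k>` contour levels (default `c(1, 5, 10)`).
#' @inheritParams classify_phase
#' @return A long tibble with columns `curve`, `alpha_t`, `omega_t`.
#' @export
phase_boundaries <- function(alpha_t, mean_k_levels = c(1, 5, 10),
                             r1_threshold = 5, omega_threshold = 1) {
  stopifnot(all(alpha_t > 0))
  root <- function(g, lower = 1e-12, upper = 50) {
    if (g(lower) * g(upper) > 0) return(NA_real_)
    uniroot(g, c(lower, upper), tol = 1e-10)$root
  }
  ld_id <- purrr::map_dbl(alpha_t, function(at) {
    root(function(w) transient_ratio_entry(at, w, 1) - r1_threshold)
  })
  out <- dplyr::bind_rows(
    tibble(curve = sprintf("r1_entry=%g", r1_threshold), alpha_t = alpha_t, omega_t = ld_id),
    tibble(curve = sprintf("omega_t=%g", omega_threshold), alpha_t = alpha_t,
           omega_t = omega_threshold)
  )
  for (lev in mean_k_levels) {
    wk <- purrr::map_dbl(alpha_t, function(at) {
      if (lev >= at) return(NA_real_)
      root(function(w) mean_ribosomes(at, w) - lev)
    })
    out <- dplyr::bind_rows(out, tibble(curve = sprintf("mean_k=%g", lev),
                                        alpha_t = alpha_t, omega_t = wk))
  }
  out
}

#' Classify genes from dimensional kinetic measurements
#'
#' Consumes a per-gene table of measured rates and returns dimensionless
#' coordinates and the degradation regime. The half-life-to-rate conversion
#' is selectable: the standard exponential-decay relation
#' `omega = ln(2) / t_half` (default) or the reciprocal `omega = 1 /
#' t_half` that some published compilations use; the two differ by a factor
#' ~1.44, enough to move borderline genes across a boundary.
#'
#' @param genes Tibble with columns `gene`, `alpha` (1/s), `t_half`
#'   (seconds), and either `total_time` (`T(L)`, s) or both `L` (codons)
#'   and `p` (codons/s, `T(L) = L / p`).
#' @param halflife_convention `"ln2"` or `"reciprocal"`.
#' @inheritParams classify_phase
#' @return The input with added `omega`, `alpha_t`, `omega_t`, `r1_entry`,
#'   `mean_k`, `regime`.
#' @export
classify_genes <- function(genes, halflife_convention = c("ln2", "reciprocal"),
                           r1_threshold = 5, omega_threshold = 1) {
  halflife_convention <- match.arg(halflife_convention)
  stopifnot(all(c("gene", "alpha", "t_half") %in% names(genes)))
  total_time <- if ("total_time" %in% names(genes)) {
    genes$total_time
  } else if (all(c("L", "p") %in% names(genes))) {
    genes$L / genes$p
  } else {
    abort("`genes` needs `total_time` or both `L` and `p`", class = "riboballistic_domain_error")
  }
  omega <- switch(halflife_convention,
                  ln2 = log(2) / genes$t_half,
                  reciprocal = 1 / genes$t_half)
  cls <- classify_phase(genes$alpha * total_time, omega * total_time,
                        r1_threshold = r1_threshold, omega_threshold = omega_threshold)
  dplyr::bind_cols(genes, dplyr::select(cls, "alpha_t", "omega_t", "r1_entry",
                                        "mean_k", "regime"),
                   tibble(omega = omega))
}
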