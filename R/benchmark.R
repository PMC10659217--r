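#' Synthetic-benchmark specification
#'
#' Conditions of the self-consistency benchmark: `n_profiles` random
#' elongation profiles of `L` codons with rates uniform on
#' `[rate_low, rate_high)`, a fixed initiation rate, and a grid of target
#' values for the transient-to-stationary ratio `R_1(0)` reached by tuning
#' the degradation rate per profile.
#'
#' @param n_profiles Number of random profiles (default 10).
#' @param L Codons per transcript (default 100).
#' @param rate_low,rate_high Elongation-rate bounds, 1/s (defaults 0.2, 4).
#' @param alpha Initiation rate, 1/s (default 0.08).
#' @param ratios `R_1(0)` targets (default `1:15`).
#' @param seed Base seed; per-profile seeds are derived as `seed + profile`.
#' @return A `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_profiles = 10, L = 100, rate_low = 0.2, rate_high = 4,
                           alpha = 0.08, ratios = 1:15, seed = 1) {
  stopifnot(n_profiles >= 1, L >= 2, rate_low > 0, rate_high > rate_low,
            alpha > 0, all(ratios > 0))
  structure(list(n_profiles = n_profiles, L = L, rate_low = rate_low,
                 rate_high = rate_high, alpha = alpha, ratios = ratios,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Tune the degradation rate to a target R1(0)
#'
#' Solves `R_1(0) = omega_t (exp(omega_t + alpha_t) - 1) / (omega_t +
#' alpha_t) = target` for `omega_t` by bracketed root-finding (tolerance
#' 1e-10) and converts back to `omega = omega_t / T(L)`. `R_1(0)` is
#' strictly increasing in `omega_t`, so the root is unique.
#'
#' @param profile An [elongation_profile()] (or rate vector).
#' @param alpha Initiation rate, 1/s.
#' @param target_ratio Desired `R_1(0)` (> 0).
#' @return The degradation rate `omega`, 1/s.
#' @export
tune_omega <- function(profile, alpha, target_ratio) {
  stopifnot(target_ratio > 0)
  if (!inherits(profile, "elongation_profile")) profile <- elongation_profile(profile)
  total <- sum(1 / profile$rates)
  alpha_t <- alpha * total
  g <- function(wt) transient_ratio_entry(alpha_t, wt, 1) - target_ratio
  upper <- 1
  while (g(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e6) abort("target R1(0) not bracketable", class = "riboballistic_range_error")
  }
  wt <- uniroot(g, c(1e-15, upper), tol = 1e-10)$root
  wt / total
}

#' Run the parameter-recovery benchmark
#'
#' The proof-of-concept experiment of the inverse method: for each random
#' profile and each `R_1(0)` target, tune `omega`, generate forward
#' monosome and normalized polysome profiles (noiseless by default),
#' recover the rates with [fit_rates()], and score against the truth.
#' Individual fit failures are recorded, not fatal.
#'
#' @param spec A [benchmark_spec()].
#' @param depth If non-`NULL`, overlay finite-depth multinomial read noise
#'   with this many reads per channel ([sample_reads()]) before fitting.
#' @param ... Passed to [fit_rates()].
#' @return An object of class `score_curve`: tibble `scores` with one row
#'   per (profile, ratio) — `ratio`, `profile`, `omega`, `err_alpha`,
#'   `err_mean`, `err_max`, `converged` — and tibble `summary` with the
#'   per-ratio arithmetic means.
#' @export
run_benchmark <- function(spec, depth = NULL, ...) {
  stopifnot(inherits(spec, "benchmark_spec"))
  grid <- tidyr::expand_grid(profile = seq_len(spec$n_profiles), ratio = spec$ratios)
  scores <- purrr::pmap_dfr(grid, function(profile, ratio) {
    prof <- random_elongation_profile(spec$L, c(spec$rate_low, spec$rate_high),
                                      seed = spec$seed + profile)
    omega <- tune_omega(prof, spec$alpha, ratio)
    truth <- kinetic_params(spec$alpha, omega, prof)
    dat <- forward_profiles(truth)
    if (!is.null(depth)) {
      reads <- sample_reads(dat, depth, seed = spec$seed + 1000L * profile + ratio)
      dat <- dplyr::mutate(reads, value = as.double(.data$count))
    }
    fit <- tryCatch(fit_rates(dat, omega = omega, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble(ratio = ratio, profile = profile, omega = omega,
                    err_alpha = NA_real_, err_mean = NA_real_, err_max = NA_real_,
                    converged = FALSE))
    }
    sc <- score_fit(fit, truth)
    tibble(ratio = ratio, profile = profile, omega = omega,
           err_alpha = sc$err_alpha, err_mean = sc$err_mean, err_max = sc$err_max,
           converged = fit$converged)
  })
  summary <- scores |>
    dplyr::group_by(.data$ratio) |>
    dplyr::summarise(dplyr::across(c("err_alpha", "err_mean", "err_max"),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_converged = sum(.data$converged), .groups = "drop")
  structure(list(scores = scores, summary = summary, spec = spec),
            class = "score_curve")
}

#' @export
print.score_curve <- function(x, ...) {
  cat(sprintf("<score_curve> %d profiles x %d R1(0) targets\n",
              x$spec$n_profiles, length(x$spec$ratios)))
  print(x$summary)
  invisible(x)
}

#' @describeIn run_benchmark per-(profile, ratio) scores as a tibble.
#' @param x A `score_curve`.
#' @param ... Passed on or unused.
#' @method tidy score_curve
#' @export
tidy.score_curve <- function(x, ...) x$scores

#' @describeIn run_benchmark per-ratio averaged score curve.
#' @method glance score_curve
#' @export
glance.score_curve <- function(x, ...) x$summary
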