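#' Per-codon elongation rate profile
#'
#' An elongation profile holds the local rate `p_i` (codons/s) at which a
#' ribosome advances from codon `i` to `i + 1`, for `i = 1..L`. Codons are
#' 1-based; internally positions live on a continuous axis `[0, L]` with
#' codon `i` occupying `(i - 1, i]`.
#'
#' @param rates Numeric vector of positive per-codon elongation rates, in
#'   codons per second. Its length defines the transcript length `L`.
#' @return An object of class `elongation_profile` with fields `rates` and
#'   `length`.
#' @examples
#' prof <- elongation_profile(rep(0.5, 100))
#' crossing_times(prof)$total # 200 s
#' @export
elongation_profile <- function(rates) {
  rates <- as.double(rates)
  if (length(rates) < 1L) {
    abort("an elongation profile needs at least one codon", class = "riboballistic_invalid_profile")
  }
  if (anyNA(rates) || any(rates <= 0)) {
    abort("all elongation rates must be positive and finite", class = "riboballistic_invalid_profile")
  }
  structure(list(rates = rates, length = length(rates)),
            class = "elongation_profile")
}

#' @export
print.elongation_profile <- function(x, ...) {
  cat(sprintf("<elongation_profile> L = %d codons, rates %.3g-%.3g /s, T(L) = %.4g s\n",
              x$length, min(x$rates), max(x$rates), sum(1 / x$rates)))
  invisible(x)
}

#' Draw a random elongation profile
#'
#' Rates are i.i.d. uniform on the half-open interval
#' `[rate_range[1], rate_range[2])`, the benchmark condition for synthetic
#' transcripts.
#'
#' @param length Number of codons `L`.
#' @param rate_range Lower (inclusive) and upper (exclusive) rate bounds,
#'   codons/s. Default `c(0.2, 4)`.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return An [elongation_profile()].
#' @export
random_elongation_profile <- function(length, rate_range = c(0.2, 4), seed = NULL) {
  stopifnot(length >= 1, rate_range[1] > 0, rate_range[2] > rate_range[1])
  draw <- function() runif(length, rate_range[1], rate_range[2])
  rates <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  elongation_profile(rates)
}

#' Full kinetic parameterization of the ballistic model
#'
#' Bundles the initiation rate `alpha` (ribosome loading at the start codon,
#' 1/s), the mRNA degradation rate `omega` (1/s; `omega = 0` encodes an
#' infinite lifetime and is handled by analytic limits throughout), and the
#' per-codon elongation profile.
#'
#' @param alpha Initiation rate, 1/s (> 0).
#' @param omega Degradation rate, 1/s (>= 0).
#' @param profile An [elongation_profile()], or a numeric vector of rates.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(alpha, omega, profile) {
  if (!inherits(profile, "elongation_profile")) profile <- elongation_profile(profile)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    abort("`alpha` must be a single positive rate (1/s)", class = "riboballistic_invalid_params")
  }
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) || omega < 0) {
    abort("`omega` must be a single non-negative rate (1/s)", class = "riboballistic_invalid_params")
  }
  structure(list(alpha = as.double(alpha), omega = as.double(omega), profile = profile),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  ct <- crossing_times(x$profile)
  cat(sprintf("<kinetic_params> alpha = %.4g /s, omega = %.4g /s, L = %d, T(L) = %.4g s\n",
              x$alpha, x$omega, x$profile$length, ct$total))
  cat(sprintf("  dimensionless: alpha_t = %.4g, omega_t = %.4g\n",
              x$alpha * ct$total, x$omega * ct$total))
  invisible(x)
}

#' Cumulative crossing times along the transcript
#'
#' The crossing time `T(x)` is the deterministic time a ribosome needs to
#' travel from the start codon to position `x`; at codon boundaries it is
#' the cumulative sum of dwell times `1/p_j`. Midpoint times
#' `T_{i-1} + 1/(2 p_i)` are also returned: per-codon density values are
#' evaluated there, which keeps discrete sums second-order accurate against
#' the continuous formulas.
#'
#' @param profile An [elongation_profile()] or numeric rate vector.
#' @return An object of class `crossing_times` with fields
#'   `cumulative` (`T_0 = 0, ..., T_L`, seconds), `midpoint` (length `L`),
#'   `total` (`T(L)`), `tau` (`T_i / T(L)`), `tau_mid`, and `rates`.
#' @export
crossing_times <- function(profile) {
  if (!inherits(profile, "elongation_profile")) profile <- elongation_profile(profile)
  p <- profile$rates
  dwell <- 1 / p
  cumulative <- c(0, cumsum(dwell))
  total <- cumulative[length(cumulative)]
  midpoint <- cumulative[-length(cumulative)] + dwell / 2
  structure(list(cumulative = cumulative, midpoint = midpoint, total = total,
                 tau = cumulative / total, tau_mid = midpoint / total,
                 rates = p, length = profile$length),
            class = "crossing_times")
}

#' @export
print.crossing_times <- function(x, ...) {
  cat(sprintf("<crossing_times> L = %d codons, T(L) = %.6g s\n", x$length, x$total))
  invisible(x)
}

#' @describeIn crossing_times crossing times as a tibble (codon boundary
#'   `i = 0..L`, time `T_i`, and scaled time `tau_i`).
#' @param x A `crossing_times` object.
#' @param ... Unused.
#' @method tidy crossing_times
#' @export
tidy.crossing_times <- function(x, ...) {
  tibble(boundary = 0:x$length, time = x$cumulative, tau = x$tau)
}

#' Position reached after a given travel time
#'
#' Inverts `T(x)`: returns the continuous codon coordinate `x(a)` a ribosome
#' reaches after travelling for `a` seconds, by piecewise-linear
#' interpolation inside a codon. Saturates at `L` for `a >= T(L)`.
#'
#' @param ct A [crossing_times()] object.
#' @param a Travel time(s), seconds (>= 0); vectorized.
#' @return Numeric position(s) in `[0, L]`.
#' @export
invert_time <- function(ct, a) {
  stopifnot(inherits(ct, "crossing_times"))
  if (any(a < 0)) abort("travel time `a` must be non-negative", class = "riboballistic_domain_error")
  approx(x = ct$cumulative, y = seq_along(ct$cumulative) - 1,
         xout = pmin(a, ct$total), method = "linear", ties = "ordered")$y
}

#' Dimensionless rates
#'
#' Rescales every rate by the total crossing time `T(L)`:
#' `alpha_t = alpha * T(L)`, `omega_t = omega * T(L)`,
#' `p_t_i = p_i * T(L)`. These are the natural coordinates of the model:
#' every closed form below depends on time only through them.
#'
#' @param params A [kinetic_params()] object.
#' @return An object of class `dimensionless_params` with fields `alpha_t`,
#'   `omega_t`, `p_t`, and `total_time` (`T(L)`, seconds, kept for
#'   converting back).
#' @export
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  ct <- crossing_times(params$profile)
  structure(list(alpha_t = params$alpha * ct$total,
                 omega_t = params$omega * ct$total,
                 p_t = params$profile$rates * ct$total,
                 total_time = ct$total,
                 crossing = ct),
            class = "dimensionless_params")
}

#' @export
print.dimensionless_params <- function(x, ...) {
  cat(sprintf("<dimensionless_params> alpha_t = %.4g, omega_t = %.4g, L = %d\n",
              x$alpha_t, x$omega_t, length(x$p_t)))
  invisible(x)
}
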