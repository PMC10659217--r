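#' Ribosome-count probability for an mRNA of known age
#'
#' Ribosome loading is a Poisson process of rate `alpha`, but only ribosomes
#' initiated within the last `min(a, T(L))` seconds are still on the
#' transcript (older ones have terminated). The number of ribosomes on an
#' mRNA of age `a` is therefore Poisson with mean `alpha * min(a, T(L))`,
#' saturating exactly at `a = T(L)`.
#'
#' @param k Ribosome count(s), non-negative integer; vectorized.
#' @param age mRNA age `a`, seconds (>= 0).
#' @param alpha Initiation rate, 1/s.
#' @param total_time Total crossing time `T(L)`, seconds.
#' @return Probability `P(k | a)`.
#' @export
prob_k_given_age <- function(k, age, alpha, total_time) {
  if (any(k < 0)) abort("`k` must be non-negative", class = "riboballistic_domain_error")
  if (any(age < 0)) abort("`age` must be non-negative", class = "riboballistic_domain_error")
  dpois(k, alpha * pmin(age, total_time))
}

#' Exact k-some probability
#'
#' Probability that an mRNA carries exactly `k` ribosomes, irrespective of
#' age, obtained by averaging the age-conditioned Poisson law over the
#' exponential age distribution. In dimensionless form, with
#' `z = alpha_t + omega_t`:
#' \deqn{P_k = \frac{\tilde\omega}{z}\Big(\frac{\tilde\alpha}{z}\Big)^k
#'   \frac{\gamma(k+1, z)}{k!} + \frac{\tilde\alpha^k}{k!} e^{-z}.}
#' The first term collects stationary mRNAs (older than `T(L)`), the second
#' the transient ones. Evaluation is in log space with the regularized
#' incomplete gamma so large `alpha_t` does not overflow; at `omega_t = 0`
#' the Poisson limit `P_k = dpois(k, alpha_t)` is returned exactly.
#'
#' @param alpha_t Dimensionless initiation rate `alpha * T(L)` (> 0).
#' @param omega_t Dimensionless degradation rate `omega * T(L)` (>= 0).
#' @param k Ribosome count(s), non-negative integer; vectorized.
#' @return Probability `P_k`.
#' @seealso [ksome_probability_approx()], [ksome_distribution()]
#' @export
ksome_probability <- function(alpha_t, omega_t, k) {
  stopifnot(alpha_t > 0, omega_t >= 0)
  if (any(k < 0)) abort("`k` must be non-negative", class = "riboballistic_domain_error")
  if (omega_t == 0) return(dpois(k, alpha_t))
  z <- alpha_t + omega_t
  stationary <- exp(log(omega_t) - log(z) + k * (log(alpha_t) - log(z)) +
                      pgamma(z, shape = k + 1, log.p = TRUE))
  transient <- dpois(k, alpha_t) * exp(-omega_t)
  stationary + transient
}

#' Linearized k-some probability
#'
#' First-order expansion of [ksome_probability()] in `omega_t`, valid for
#' `alpha_t >> k`: `P_k ~ P_k_inf + omega_t / alpha_t`, where
#' `P_k_inf = dpois(k, alpha_t)` is the infinite-lifetime Poisson limit.
#' The degradation contribution is independent of `k`, which produces the
#' low-`k` plateau of the distribution.
#'
#' @inheritParams ksome_probability
#' @export
ksome_probability_approx <- function(alpha_t, omega_t, k) {
  stopifnot(alpha_t > 0, omega_t >= 0)
  if (any(k < 0)) abort("`k` must be non-negative", class = "riboballistic_domain_error")
  dpois(k, alpha_t) + omega_t / alpha_t
}

#' Lifetime attenuation factor f
#'
#' `f(omega_t) = (1 - exp(-omega_t)) / omega_t` is the mean ribosome load
#' normalized by its infinite-lifetime value: `<k> = alpha_t * f(omega_t)`.
#' `f(0) = 1` is handled analytically and the small-`omega_t` behavior is
#' `1 - omega_t / 2 + O(omega_t^2)`.
#'
#' @inheritParams ksome_probability
#' @export
lifetime_factor <- function(omega_t) {
  stopifnot(all(omega_t >= 0))
  ifelse(omega_t == 0, 1, -expm1(-omega_t) / ifelse(omega_t == 0, 1, omega_t))
}

#' Mean number of ribosomes per mRNA
#'
#' `<k> = (alpha / omega) * (1 - exp(-omega * T(L))) = alpha_t * f(omega_t)`,
#' with the `omega -> 0` limit `<k> = alpha_t` taken analytically.
#'
#' @inheritParams ksome_probability
#' @export
mean_ribosomes <- function(alpha_t, omega_t) {
  stopifnot(alpha_t > 0)
  alpha_t * lifetime_factor(omega_t)
}

default_kmax <- function(alpha_t, omega_t) {
  as.integer(ceiling(alpha_t + omega_t + 10 * sqrt(alpha_t + 1)))
}

#' Full k-some distribution
#'
#' Tabulates `P_k` for `k = 0..k_max` together with the Poisson limit and
#' the linearized approximation. `k_max` defaults to
#' `ceiling(alpha_t + omega_t + 10 * sqrt(alpha_t + 1))`; if the retained
#' tail mass exceeds 1e-12 a warning is raised.
#'
#' @inheritParams ksome_probability
#' @param k_max Largest `k` tabulated; `NULL` for the default rule.
#' @return A tibble of class `ksome_distribution` with columns `k`,
#'   `probability`, `poisson_limit`, `approximation`, and attributes
#'   `alpha_t`, `omega_t`, `mean_k`, `f_value`.
#' @export
ksome_distribution <- function(alpha_t, omega_t, k_max = NULL) {
  if (is.null(k_max)) k_max <- default_kmax(alpha_t, omega_t)
  k <- 0:k_max
  probs <- ksome_probability(alpha_t, omega_t, k)
  residual <- 1 - sum(probs)
  if (residual > 1e-12) {
    warn(sprintf("k-some tail mass %.3g beyond k_max = %d exceeds 1e-12; increase `k_max`",
                 residual, k_max))
  }
  out <- tibble(k = k,
                probability = probs,
                poisson_limit = dpois(k, alpha_t),
                approximation = ksome_probability_approx(alpha_t, omega_t, k))
  structure(out, class = c("ksome_distribution", class(out)),
            alpha_t = alpha_t, omega_t = omega_t,
            mean_k = mean_ribosomes(alpha_t, omega_t),
            f_value = lifetime_factor(omega_t))
}

#' @describeIn ksome_distribution one-row summary: `alpha_t`, `omega_t`,
#'   `mean_k`, `f_value`, tabulated mass, and `k_max`.
#' @param x A `ksome_distribution`.
#' @param ... Unused.
#' @method glance ksome_distribution
#' @export
glance.ksome_distribution <- function(x, ...) {
  tibble(alpha_t = attr(x, "alpha_t"), omega_t = attr(x, "omega_t"),
         mean_k = attr(x, "mean_k"), f_value = attr(x, "f_value"),
         total_mass = sum(x$probability), k_max = max(x$k))
}

#' Population-inversion degradation threshold
#'
#' As degradation grows, the probability of nearly empty mRNAs rises until
#' it matches the high-occupancy peak of the distribution near
#' `k = alpha_t`: beyond that point low-order k-somes dominate. The
#' threshold is found by bisection (to `tol`) on the exact distribution.
#'
#' Two reference points for the high-occupancy peak are supported:
#' `"poisson_mode"` (default) compares `P_0` against `P_k` at
#' `k = round(alpha_t)`, the mode of the infinite-lifetime Poisson
#' distribution — at `alpha_t = 12` this gives `omega_t ~ 0.83`, the
#' conventional value ~0.8; `"local_max"` compares `P_0` against the running
#' local maximum of `P_k` over `k >= 2`, which tracks the drifting peak and
#' yields a slightly larger threshold (~0.88 at `alpha_t = 12`).
#'
#' With `approximate = TRUE` a closed-form estimate is returned instead:
#' balancing the degradation plateau `omega_t / (alpha_t + omega_t)` against
#' the Poisson peak height `~ 1 / sqrt(2 pi alpha_t)` gives the
#' self-consistent relation
#' `omega_t * (exp(omega_t) - 1/2) = sqrt(alpha_t / (2 pi))`, solved by a
#' cheap 1-D root search.
#'
#' @param alpha_t Dimensionless initiation rate (> 1).
#' @param reference `"poisson_mode"` or `"local_max"` (see Details).
#' @param approximate If `TRUE`, return the closed-form estimate.
#' @param tol Bisection tolerance (default 1e-6).
#' @param bracket Search interval for `omega_t`.
#' @return The threshold `omega_t_inv` (dimensionless).
#' @export
inversion_threshold <- function(alpha_t, reference = c("poisson_mode", "local_max"),
                                approximate = FALSE, tol = 1e-6, bracket = c(1e-6, 10)) {
  stopifnot(alpha_t > 1)
  reference <- match.arg(reference)
  if (approximate) {
    target <- sqrt(alpha_t / (2 * pi))
    return(uniroot(function(w) w * (exp(w) - 0.5) - target,
                   interval = c(1e-8, 20), tol = tol)$root)
  }
  peak <- if (reference == "poisson_mode") {
    k_ref <- max(2L, as.integer(round(alpha_t)))
    function(w) ksome_probability(alpha_t, w, k_ref)
  } else {
    k_grid <- 2:default_kmax(alpha_t, bracket[2])
    function(w) max(ksome_probability(alpha_t, w, k_grid))
  }
  g <- function(w) ksome_probability(alpha_t, w, 0) - peak(w)
  if (g(bracket[1]) * g(bracket[2]) > 0) {
    abort(sprintf("no population inversion inside omega_t bracket [%g, %g] at alpha_t = %g",
                  bracket[1], bracket[2], alpha_t),
          class = "riboballistic_no_inversion")
  }
  uniroot(g, interval = bracket, tol = tol)$root
}
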