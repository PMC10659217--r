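# shared constructor for per-codon density tibbles
new_density_profile <- function(codon, density, role, norm_target, ...) {
  out <- tibble(codon = codon, density = density)
  structure(out, class = c("density_profile", class(out)),
            role = role, norm_target = norm_target, ...)
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> role = %s, L = %d, sum = %.6g (target %.6g)\n",
              attr(x, "role"), nrow(x), sum(x$density), attr(x, "norm_target")))
  NextMethod()
}

#' Ribosome density on an mRNA of known age
#'
#' For a transcript of age `a < T(L)` carrying `k` ribosomes, initiation
#' epochs are uniform on the lookback window, so the density is
#' `k / (a p(x))` up to the frontier `x(a)` (the farthest point a ribosome
#' can have reached) and zero beyond; a ribosome exactly at the frontier is
#' counted. For `a >= T(L)` the profile is the stationary
#' `k / (T(L) p(x))`. Per-codon values are the exact codon averages of this
#' piecewise form (the frontier codon is weighted by its overlap with
#' `[0, x(a)]`), so the discrete sum equals `k` exactly.
#'
#' @param params A [kinetic_params()] object.
#' @param k Ribosome count (>= 1).
#' @param age mRNA age `a`, seconds (> 0; the density is undefined at
#'   `a = 0`).
#' @return A `density_profile` tibble (columns `codon`, `density`,
#'   ribosomes/codon).
#' @export
density_given_age <- function(params, k, age) {
  stopifnot(inherits(params, "kinetic_params"), k >= 1)
  if (length(age) != 1L || age < 0) abort("`age` must be a single non-negative time",
                                          class = "riboballistic_domain_error")
  if (age == 0) abort("the age-conditioned density diverges at age 0; use the age-integrated `ksome_density()`",
                      class = "riboballistic_degenerate_age")
  ct <- crossing_times(params$profile)
  L <- ct$length
  p <- ct$rates
  if (age >= ct$total) {
    dens <- k / (ct$total * p)
  } else {
    frontier <- invert_time(ct, age)
    overlap <- pmax(0, pmin(1, frontier - (seq_len(L) - 1)))
    dens <- k / (age * p) * overlap
  }
  new_density_profile(seq_len(L), dens, role = sprintf("age_conditioned(k=%d)", k),
                      norm_target = k, age = age)
}

# dimensionless stationary/transient k-some density pieces at scaled times tau;
# returns per-codon values (already divided by p_t)
ksome_density_terms <- function(alpha_t, omega_t, k, p_t, tau) {
  z <- alpha_t + omega_t
  pk <- ksome_probability(alpha_t, omega_t, k)
  if (pk < 1e-300) {
    abort(sprintf("P_k underflow: alpha_t = %g, omega_t = %g, k = %d", alpha_t, omega_t, k),
          class = "riboballistic_underflow")
  }
  log_s <- k * log(alpha_t) - z - lgamma(k) - log(pk)
  stationary <- exp(log_s) / p_t
  if (omega_t == 0) {
    transient <- numeric(length(p_t))
  } else {
    # gamma(k, z) - gamma(k, z*tau), regularized upper-tail difference keeps
    # relative accuracy when both arguments are large
    gdiff <- pgamma(z * tau, shape = k, lower.tail = FALSE) -
      pgamma(z, shape = k, lower.tail = FALSE)
    transient <- omega_t / pk * exp(k * (log(alpha_t) - log(z))) * gdiff / p_t
  }
  list(stationary = stationary, transient = transient, pk = pk)
}

#' Age-integrated k-some density profile
#'
#' Closed-form per-codon ribosome density of mRNAs carrying exactly `k`
#' ribosomes, split into the stationary contribution `S_k(x)` (mRNAs old
#' enough that a ribosome may have terminated) and the transient
#' contribution `F_k(x)` (younger mRNAs, responsible for the exponential
#' decay along the transcript). Values are evaluated at codon-midpoint
#' scaled times, and the discrete sum integrates to `k` to second order.
#' At `omega_t = 0` the profile is exactly the flat infinite-lifetime limit
#' `k / (T(L) p(x))` (i.e. `k/L` for homogeneous rates).
#'
#' @param params A [kinetic_params()] object.
#' @param k Ribosome count (>= 1).
#' @return A `density_profile` tibble with columns `codon`, `density`,
#'   `stationary`, `transient`, and `ratio` (`F_k/S_k`, non-increasing along
#'   the transcript), plus attributes `k`, `p_k`, `ratio_at_entry`.
#' @export
ksome_density <- function(params, k) {
  stopifnot(inherits(params, "kinetic_params"), length(k) == 1L, k >= 1)
  dp <- nondimensionalize(params)
  terms <- ksome_density_terms(dp$alpha_t, dp$omega_t, k, dp$p_t, dp$crossing$tau_mid)
  dens <- terms$stationary + terms$transient
  out <- new_density_profile(seq_along(dp$p_t), dens, role = sprintf("ksome(%d)", k),
                             norm_target = k, k = k, p_k = terms$pk,
                             alpha_t = dp$alpha_t, omega_t = dp$omega_t,
                             ratio_at_entry = transient_ratio_entry(dp$alpha_t, dp$omega_t, k))
  out$stationary <- terms$stationary
  out$transient <- terms$transient
  out$ratio <- terms$transient / terms$stationary
  out
}

#' Transient-to-stationary density ratio at the start codon
#'
#' `R_k(0) = F_k(0) / S_k(0)`, the maximal value (attained at `x = 0`) of
#' the ratio between transient and stationary contributions to the k-some
#' density. In closed form, with `z = alpha_t + omega_t`,
#' `R_k(0) = omega_t * gamma(k, z) * exp(z) / z^k`; for `k = 1` this reduces
#' to `omega_t * (exp(z) - 1) / z`. It quantifies how strongly degradation
#' imprints on the k-some profile and serves as the feasibility criterion of
#' the inverse fit. With `approximate = TRUE` the small-`omega_t`,
#' `alpha_t >> k` form `omega_t / (k * P_k_inf)` is returned.
#'
#' @inheritParams ksome_probability
#' @param k Ribosome count (>= 1); vectorized.
#' @param approximate Return the Poisson-limit approximation instead.
#' @export
transient_ratio_entry <- function(alpha_t, omega_t, k, approximate = FALSE) {
  stopifnot(alpha_t > 0, omega_t >= 0, all(k >= 1))
  if (approximate) return(omega_t / (k * dpois(k, alpha_t)))
  if (omega_t == 0) return(rep(0, length(k)))
  z <- alpha_t + omega_t
  # log gamma(k, z) = lgamma(k) + log P(k, z)
  exp(log(omega_t) + lgamma(k) + pgamma(z, shape = k, log.p = TRUE) + z - k * log(z))
}

#' Sensitivity of the k-some density to degradation at the start codon
#'
#' Relative deviation of the k-some density from its infinite-lifetime flat
#' value at `x = 0`, both exactly —
#' `|rho_k(0) - rho_k_inf(0)| / rho_k_inf(0)` from the closed forms — and
#' through the approximation `R_k(0) ~ omega_t / (k P_k_inf)` that controls
#' it for small `omega_t` and `alpha_t >> k`.
#'
#' @inheritParams transient_ratio_entry
#' @return A tibble with columns `k`, `exact`, `ratio_entry`, `approximation`.
#' @export
entry_sensitivity <- function(alpha_t, omega_t, k) {
  stopifnot(all(k >= 1))
  z <- alpha_t + omega_t
  exact <- vapply(k, function(kk) {
    pk <- ksome_probability(alpha_t, omega_t, kk)
    s0 <- exp(kk * log(alpha_t) - z - lgamma(kk) - log(pk)) # p_t * S_k(0)
    r0 <- transient_ratio_entry(alpha_t, omega_t, kk)
    abs(s0 * (1 + r0) - kk) / kk
  }, numeric(1))
  tibble(k = k,
         exact = exact,
         ratio_entry = transient_ratio_entry(alpha_t, omega_t, k),
         approximation = transient_ratio_entry(alpha_t, omega_t, k, approximate = TRUE))
}

#' Polysome (whole-population) density profile
#'
#' Average ribosome density over all mRNAs irrespective of ribosome number:
#' `rho(x) = (alpha / p(x)) * exp(-omega T(x))`. Its discrete sum equals the
#' mean load `<k>`; at `omega = 0` it is the flat conserved-current limit
#' `alpha / p(x)`. Degradation depresses it by at most a factor
#' `1 - exp(-omega_t)`, attained at the last codon.
#'
#' @param params A [kinetic_params()] object.
#' @return A `density_profile` tibble (columns `codon`, `density`).
#' @export
polysome_density <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  ct <- crossing_times(params$profile)
  dens <- params$alpha / ct$rates * exp(-params$omega * ct$midpoint)
  new_density_profile(seq_len(ct$length), dens, role = "polysome",
                      norm_target = mean_ribosomes(params$alpha * ct$total,
                                                   params$omega * ct$total))
}

#' Unit-normalized polysome density profile
#'
#' The polysome profile rescaled to integrate to one:
#' `rho_bar(x) = omega * exp(-omega T(x)) / (p(x) (1 - exp(-omega T(L))))`.
#' It no longer depends on the initiation rate `alpha` — this is the
#' quantity a depth-unaware sequencing experiment actually constrains, and
#' the polysome channel of the inverse fit. The `omega -> 0` limit
#' `1 / (T(L) p(x))` is taken analytically.
#'
#' @param params A [kinetic_params()] object.
#' @return A `density_profile` tibble (columns `codon`, `density`).
#' @export
polysome_density_normalized <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  ct <- crossing_times(params$profile)
  if (params$omega == 0) {
    dens <- 1 / (ct$total * ct$rates)
  } else {
    dens <- params$omega * exp(-params$omega * ct$midpoint) /
      (ct$rates * -expm1(-params$omega * ct$total))
  }
  new_density_profile(seq_len(ct$length), dens, role = "polysome_normalized",
                      norm_target = 1)
}

#' Forward model profiles as a long table
#'
#' Convenience wrapper generating any combination of model profiles for one
#' gene as a long tibble in the package's profile-table layout
#' (`gene`, `class`, `codon`, `value`) — the shape consumed by
#' [fit_rates()], [write_profiles()] and produced by [read_profiles()].
#'
#' @param params A [kinetic_params()] object.
#' @param classes Any of `"monosome"`, `"disome"`, `"trisome"`,
#'   `"tetrasome"`, `"polysome"`, `"polysome_normalized"`.
#' @param gene Gene identifier for the `gene` column.
#' @return A tibble with columns `gene`, `class`, `codon`, `value`.
#' @export
forward_profiles <- function(params,
                             classes = c("monosome", "polysome_normalized"),
                             gene = "synthetic") {
  kmap <- c(monosome = 1, disome = 2, trisome = 3, tetrasome = 4)
  choices <- c(names(kmap), "polysome", "polysome_normalized")
  classes <- match.arg(classes, choices, several.ok = TRUE)
  purrr::map_dfr(classes, function(cl) {
    prof <- if (cl %in% names(kmap)) {
      ksome_density(params, kmap[[cl]])
    } else if (cl == "polysome") {
      polysome_density(params)
    } else {
      polysome_density_normalized(params)
    }
    tibble(gene = gene, class = cl, codon = prof$codon, value = prof$density)
  })
}
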