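# Independent oracles used across the suite: brute-force quadrature of the
# age-averaged definitions, kept free of the closed forms they check.

# P_k by direct numerical integration of the age-conditioned Poisson law
# against the exponential age density (transcript timescale T(L) = 1).
oracle_pk_quadrature <- function(alpha_t, omega_t, k) {
  if (omega_t == 0) return(dpois(k, alpha_t))
  body <- integrate(function(a) dpois(k, alpha_t * a) * omega_t * exp(-omega_t * a),
                    0, 1, rel.tol = 1e-12)$value
  tail <- dpois(k, alpha_t) * exp(-omega_t) # ages beyond T(L), saturated mean
  body + tail
}

# k-some density at scaled position tau by quadrature of the Bayes-weighted
# age integral: rho_k(tau) = int rho_k(tau|a) phi(a) P(k|a) da / P_k,
# with rho_k(tau|a) = k/(a p_t) for a >= tau (frontier beyond tau) on the
# dimensionless time axis, and the stationary branch k/p_t for a >= 1.
oracle_rho_k_quadrature <- function(alpha_t, omega_t, k, p_t, tau) {
  pk <- oracle_pk_quadrature(alpha_t, omega_t, k)
  if (omega_t == 0) {
    return(k / p_t) # flat infinite-lifetime limit
  }
  trans <- integrate(function(a) {
    k / (a * p_t) * dpois(k, alpha_t * a) * omega_t * exp(-omega_t * a)
  }, tau, 1, rel.tol = 1e-11)$value
  stat <- k / p_t * dpois(k, alpha_t) * exp(-omega_t)
  (trans + stat) / pk
}

# piecewise-constant travel-time oracle: integrate 1/p(y) over [0, x] by
# adaptive quadrature on the step function
oracle_travel_time <- function(rates, x) {
  p_of <- function(y) rates[pmin(length(rates), floor(y) + 1)]
  integrate(function(y) 1 / p_of(y), 0, x, rel.tol = 1e-13,
            subdivisions = 10000L)$value
}

homogeneous_params <- function(alpha = 0.06, omega_t = 0.8, p = 0.5, L = 100) {
  total <- L / p
  kinetic_params(alpha, omega_t / total, elongation_profile(rep(p, L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
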