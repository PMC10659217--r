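test_that("age-conditioned density is flat when stationary and truncated when young", {
  pars <- homogeneous_params(omega_t = 0.8)
  # stationary: flat k/L
  old <- density_given_age(pars, 2, 1000)
  expect_equal(old$density, rep(2 / 100, 100))
  # young mRNA: support ends at x(a) = p * a = 50
  young <- density_given_age(pars, 1, 100)
  expect_equal(young$density[1:50], rep(0.02, 50))
  expect_equal(young$density[51:100], rep(0, 50))
  expect_error(density_given_age(pars, 1, 0), class = "riboballistic_degenerate_age")
})

test_that("age-conditioned density integrates to k against a codon-wise quadrature oracle", {
  prof <- random_elongation_profile(60, seed = 21)
  pars <- kinetic_params(0.05, 1e-3, prof)
  ct <- crossing_times(prof)
  withr::with_seed(77, {
    for (i in 1:20) {
      k <- sample(1:4, 1)
      a <- runif(1, 0.05, 1.3) * ct$total
      dens <- density_given_age(pars, k, a)$density
      expect_equal(sum(dens), k, tolerance = 1e-10)
      # per-codon oracle: integrate k/(a p(y)) over codon ∩ [0, x(a)]
      xa <- invert_time(ct, a)
      j <- sample(1:60, 1)
      width <- max(0, min(1, xa - (j - 1)))
      expect_equal(dens[j], k / (min(a, ct$total) * prof$rates[j]) * width,
                   tolerance = 1e-10)
    }
  })
})

test_that("k-some density matches Bayes-weighted age quadrature and splits cleanly", {
  # spot values against the independent quadrature oracle at codon midpoints
  for (wt in c(1e-4, 1e-2, 0.8)) {
    pars <- homogeneous_params(omega_t = wt)
    for (k in c(1, 3)) {
      d <- ksome_density(pars, k)
      for (i in c(1, 50, 100)) {
        expect_equal(d$density[i],
                     oracle_rho_k_quadrature(12, wt, k, 100, (i - 0.5) / 100),
                     tolerance = 1e-8,
                     label = sprintf("rho_%d(codon %d) at omega_t = %g", k, i, wt))
      }
      expect_equal(d$stationary + d$transient, d$density, tolerance = 1e-10)
      # transient/stationary ratio peaks at the entry codon and decays
      expect_true(all(diff(d$ratio) <= 1e-12))
    }
  }
  # infinite lifetime: exactly flat k/L
  pars0 <- homogeneous_params(omega_t = 0)
  expect_equal(ksome_density(pars0, 3)$density, rep(3 / 100, 100))
})

test_that("k-some densities integrate to k and mix back into the polysome", {
  grid <- expand.grid(alpha = c(0.03, 0.06), wt = c(1e-4, 1e-2, 0.8))
  for (r in seq_len(nrow(grid))) {
    pars <- homogeneous_params(alpha = grid$alpha[r], omega_t = grid$wt[r])
    dp <- nondimensionalize(pars)
    kmax <- max(30, ceiling(dp$alpha_t + 10 * sqrt(dp$alpha_t)))
    dens <- vapply(1:kmax, function(k) ksome_density(pars, k)$density,
                   numeric(100))
    sums <- colSums(dens)
    expect_true(all(abs(sums - 1:kmax) / (1:kmax) < 1e-3))
    # mixture identity: sum_k P_k rho_k = rho
    pk <- ksome_probability(dp$alpha_t, dp$omega_t, 1:kmax)
    mix <- as.vector(dens %*% pk)
    expect_equal(mix, polysome_density(pars)$density, tolerance = 1e-6)
  }
})

test_that("at infinite lifetime all k-some shapes collapse onto one line", {
  prof <- random_elongation_profile(80, seed = 5)
  pars <- kinetic_params(0.04, 0, prof)
  shapes <- vapply(1:4, function(k) ksome_density(pars, k)$density / k, numeric(80))
  for (k in 2:4) expect_equal(shapes[, k], shapes[, 1], tolerance = 1e-12)
})

test_that("monosome and tetrasome profiles cross along the transcript", {
  pars <- homogeneous_params(omega_t = 1e-2)
  r1 <- ksome_density(pars, 1)$density / 1
  r4 <- ksome_density(pars, 4)$density / 4
  diff14 <- r1 - r4
  expect_gt(diff14[1], 0) # monosomes enriched near entry
  expect_lt(diff14[100], 0) # tetrasomes take over downstream
  expect_equal(length(rle(sign(diff14))$values), 2) # single crossing
})

test_that("transient-to-stationary entry ratio matches its k = 1 closed form", {
  at <- 12
  for (wt in c(1e-4, 1e-2, 0.5)) {
    z <- at + wt
    expect_equal(transient_ratio_entry(at, wt, 1), wt * expm1(z) / z,
                 tolerance = 1e-12)
  }
  expect_equal(transient_ratio_entry(12, 0.01, 1), 136.8772, tolerance = 1e-6)
  approx <- transient_ratio_entry(12, 0.01, 1, approximate = TRUE)
  expect_equal(approx, 135.629, tolerance = 1e-5)
  expect_lt(abs(approx - 136.8772) / 136.8772, 0.01)
  expect_equal(transient_ratio_entry(12, 0, 1:4), rep(0, 4))
})

test_that("entry sensitivity is controlled by R_k(0) and decreases with k", {
  expect_equal(entry_sensitivity(12, 0, 1)$exact, 0)
  # the entry ratio overestimates the exact deviation by ~18% in this regime
  s1 <- entry_sensitivity(12, 1e-4, 1)
  expect_equal(s1$exact, s1$ratio_entry, tolerance = 0.2)
  sweep <- entry_sensitivity(12, 1e-2, 1:4)
  expect_true(all(diff(sweep$exact) < 0))
})

test_that("polysome density obeys conservation and the degradation bound", {
  pars0 <- homogeneous_params(alpha = 0.06, omega_t = 0, p = 0.5)
  expect_equal(polysome_density(pars0)$density, rep(0.12, 100))
  pars <- homogeneous_params(omega_t = 0.8)
  pol <- polysome_density(pars)
  dp <- nondimensionalize(pars)
  expect_equal(sum(pol$density), mean_ribosomes(dp$alpha_t, dp$omega_t),
               tolerance = 1e-3)
  # max relative deviation from alpha/p approaches 1 - exp(-omega_t) at x = L
  inf_limit <- 0.06 / 0.5
  dev <- abs(pol$density - inf_limit) / inf_limit
  expect_equal(which.max(dev), 100)
  expect_lte(max(dev), -expm1(-0.8))
  expect_equal(max(dev), -expm1(-0.8), tolerance = 5e-3)
})

test_that("normalized polysome integrates to one and forgets alpha", {
  prof <- random_elongation_profile(70, seed = 9)
  a <- polysome_density_normalized(kinetic_params(0.05, 2e-3, prof))
  b <- polysome_density_normalized(kinetic_params(0.11, 2e-3, prof))
  expect_identical(a$density, b$density)
  expect_equal(sum(a$density), 1, tolerance = 1e-3)
  # elementwise equality with polysome / <k>
  pars <- kinetic_params(0.05, 2e-3, prof)
  dp <- nondimensionalize(pars)
  expect_equal(a$density,
               polysome_density(pars)$density / mean_ribosomes(dp$alpha_t, dp$omega_t),
               tolerance = 1e-12)
  # omega -> 0 limit: flat 1/L for homogeneous rates
  flat <- polysome_density_normalized(homogeneous_params(omega_t = 0))
  expect_equal(flat$density, rep(1 / 100, 100))
  # strong degradation (the fit-feasibility edge): last-codon value matches
  # the closed form (omega_t/L) exp(-omega_t tau) / (1 - exp(-omega_t)) and
  # is ~3 orders of magnitude below the entry value
  hard <- polysome_density_normalized(homogeneous_params(omega_t = 5))
  expect_equal(hard$density[100],
               (5 / 100) * exp(-5 * 0.995) / (1 - exp(-5)), tolerance = 1e-12)
  expect_lt(hard$density[100] / hard$density[1], 1e-2)
})
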