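test_that("sliding-window smoothing averages symmetrically with shrinking edges", {
  expect_equal(smooth_profile(rep(3.5, 40)), rep(3.5, 40))
  x <- runif(30)
  expect_identical(smooth_profile(x, window = 1), x)
  # impulse response: 1/19 spread over the 19 centered codons
  imp <- c(rep(0, 49), 1, rep(0, 50))
  sm <- smooth_profile(imp, 19)
  expect_equal(sm[41:59], rep(1 / 19, 19))
  expect_equal(sum(sm[-(41:59)]), 0)
  expect_error(smooth_profile(1:5, 4), class = "riboballistic_domain_error")
  expect_error(smooth_profile(1:5, 11), class = "riboballistic_degenerate_window")
})

test_that("k-some normalization rescales the discrete integral to k", {
  v <- runif(80)
  out <- normalize_ksome(v, 3)
  expect_equal(sum(out$density), 3)
  # already normalized input is unchanged
  again <- normalize_ksome(out$density, 3)
  expect_equal(again$density, out$density, tolerance = 1e-12)
  expect_equal(sum(normalize_ksome(v, 4, unit = TRUE)$density), 1)
  expect_error(normalize_ksome(rep(0, 5), 1), class = "riboballistic_degenerate_profile")
})

test_that("read-depth round trip recovers the generating k-some density", {
  pars <- homogeneous_params(omega_t = 1e-2)
  truth <- ksome_density(pars, 2)$density
  profs <- forward_profiles(pars, classes = "disome")
  cnt <- sample_reads(profs, depth = 1e6, seed = 31)$count
  rec <- normalize_ksome(cnt, 2)$density
  q <- truth / 2
  se <- 2 * sqrt(1e6 * q * (1 - q)) / 1e6
  expect_true(all(abs(rec - truth) < 4 * se + 1e-9))
})

test_that("relative chi-square masks zero-data codons", {
  d <- rep(0.01, 100)
  expect_equal(as.numeric(chi2_profile(d, d)), 0)
  expect_equal(as.numeric(chi2_profile(rep(0.02, 100), d)), 100)
  d2 <- d
  d2[7] <- 0
  c2 <- chi2_profile(rep(0.02, 100), d2)
  expect_equal(as.numeric(c2), 99)
  expect_equal(attr(c2, "n_masked"), 1L)
  expect_error(chi2_profile(d, rep(0, 100)), class = "riboballistic_unusable_data")
})

test_that("the inverse fit refuses the unidentifiable infinite-lifetime limit", {
  pars <- kinetic_params(0.08, 0, random_elongation_profile(30, seed = 2))
  dat <- forward_profiles(pars)
  expect_error(fit_rates(dat, omega = 0), class = "riboballistic_identifiability")
})

test_that("noiseless self-generated data are recovered accurately", {
  prof <- random_elongation_profile(100, seed = 14)
  # moderately informative regime R1(0) = 3
  om3 <- tune_omega(prof, 0.08, 3)
  truth3 <- kinetic_params(0.08, om3, prof)
  fit3 <- fit_rates(forward_profiles(truth3), omega = om3)
  sc3 <- score_fit(fit3, truth3)
  expect_true(fit3$converged)
  expect_lt(sc3$err_mean, 0.10)
  # strongly informative regime R1(0) = 15
  om15 <- tune_omega(prof, 0.08, 15)
  truth15 <- kinetic_params(0.08, om15, prof)
  fit15 <- fit_rates(forward_profiles(truth15), omega = om15)
  sc15 <- score_fit(fit15, truth15)
  expect_lt(sc15$err_mean, 0.05)
  # objective decomposition adds up
  expect_equal(fit15$objective, fit15$chi2_polysome + fit15$chi2_monosome,
               tolerance = 1e-12)
})

test_that("a homogeneous truth is recovered as a near-constant profile", {
  prof <- elongation_profile(rep(1.2, 100))
  om <- tune_omega(prof, 0.08, 5)
  truth <- kinetic_params(0.08, om, prof)
  fit <- fit_rates(forward_profiles(truth), omega = om)
  sc <- score_fit(fit, truth)
  cv <- sd(fit$p_star) / mean(fit$p_star)
  expect_lt(cv, max(sc$err_mean, 1e-3))
})

test_that("the fit is invariant to rescaling the input profiles", {
  prof <- random_elongation_profile(60, seed = 8)
  om <- tune_omega(prof, 0.08, 6)
  truth <- kinetic_params(0.08, om, prof)
  dat <- forward_profiles(truth)
  scaled <- dplyr::mutate(dat, value = .data$value *
                            ifelse(.data$class == "monosome", 731.3, 0.002))
  f1 <- fit_rates(dat, omega = om)
  f2 <- fit_rates(scaled, omega = om)
  expect_equal(f1$p_star, f2$p_star, tolerance = 1e-5)
  expect_equal(f1$alpha_star, f2$alpha_star, tolerance = 1e-5)
})

test_that("score functions are exact relative errors", {
  prof <- elongation_profile(rep(1, 10))
  truth <- kinetic_params(0.08, 1e-3, prof)
  fit <- list(alpha_star = 0.08, p_star = rep(1, 10), L = 10)
  class(fit) <- "ballistic_fit"
  sc <- score_fit(fit, truth)
  expect_equal(unlist(sc[1, ]), c(err_alpha = 0, err_mean = 0, err_max = 0))
  # one rate off by a factor two
  fit$p_star[4] <- 2
  sc2 <- score_fit(fit, truth)
  expect_equal(sc2$err_max, 1)
  expect_equal(sc2$err_mean, 0.1)
  # random perturbations: err_mean is the arithmetic mean of per-codon errors
  withr::with_seed(55, {
    fit$p_star <- rep(1, 10) * exp(rnorm(10, 0, 0.2))
    sc3 <- score_fit(fit, truth)
    expect_equal(sc3$err_mean, mean(abs(1 - fit$p_star)))
    expect_lte(sc3$err_mean, sc3$err_max)
  })
})

test_that("homogeneous per-k fits recover the crossing time", {
  prof <- elongation_profile(rep(100 / 178, 100))
  truth <- kinetic_params(0.06, 3e-4, prof)
  dat <- forward_profiles(truth, classes = c("monosome", "disome", "trisome", "tetrasome"))
  fit <- fit_homogeneous(dat, alpha = 0.06, omega = 3e-4)
  expect_equal(fit$T_fit, 178, tolerance = 0.01)
  expect_true(all(abs(tidy(fit)$T_fit - 178) / 178 < 0.01))
  # pooled value is exactly the mean over k
  expect_identical(fit$T_fit, mean(fit$per_k$T_fit))
  # with finite read depth the recovery degrades gracefully
  noisy <- sample_reads(dat, depth = 1e5, seed = 12)
  noisy <- dplyr::mutate(noisy, value = as.double(.data$count))
  fitn <- fit_homogeneous(noisy, alpha = 0.06, omega = 3e-4)
  expect_equal(fitn$T_fit, 178, tolerance = 0.10)
  expect_error(fit_homogeneous(dplyr::filter(dat, .data$class == "polysome"),
                               0.06, 3e-4),
               class = "riboballistic_unusable_data")
})
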