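#' Sliding-window smoothing of a per-codon signal
#'
#' Centered moving average over `window` codons. Near the edges the window
#' shrinks symmetrically to the available codons (down to a single codon),
#' so no padding value is invented.
#'
#' @param values Numeric per-codon signal.
#' @param window Odd window width in codons (default 19).
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(values, window = 19) {
  L <- length(values)
  if (window %% 2 != 1 || window < 1) {
    abort("`window` must be an odd positive integer", class = "riboballistic_domain_error")
  }
  if (window > 2 * L - 1) {
    abort(sprintf("window %d is degenerate for a %d-codon profile", window, L),
          class = "riboballistic_degenerate_window")
  }
  half <- (window - 1) / 2
  cs <- c(0, cumsum(values))
  vapply(seq_len(L), function(i) {
    h <- min(half, i - 1, L - i)
    (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
  }, numeric(1))
}

#' Normalize a k-some profile to its ribosome count
#'
#' Rescales per-codon values so the discrete integral equals `k` (the
#' defining normalization of a k-some density), or 1 for the unit variant
#' used when overlaying k-some shapes.
#'
#' @param values Non-negative per-codon values (counts or densities).
#' @param k Ribosome count of the class.
#' @param unit If `TRUE`, normalize to 1 instead of `k`.
#' @return A `density_profile` tibble (columns `codon`, `density`).
#' @export
normalize_ksome <- function(values, k, unit = FALSE) {
  total <- sum(values)
  if (!is.finite(total) || total <= 0) {
    abort("cannot normalize an all-zero profile", class = "riboballistic_degenerate_profile")
  }
  target <- if (unit) 1 else k
  new_density_profile(seq_along(values), values * target / total,
                      role = sprintf("ksome(%d)", k), norm_target = target)
}

#' Relative-residual chi-square between model and data profiles
#'
#' `chi2 = sum_i ((data_i - model_i) / data_i)^2` over codons with positive
#' data; zero-data codons are masked (the relative residual is undefined
#' there) and their count is reported.
#'
#' @param model,data Numeric per-codon vectors of equal length.
#' @return The chi-square value, with attribute `n_masked`.
#' @export
chi2_profile <- function(model, data) {
  stopifnot(length(model) == length(data))
  keep <- data > 0
  if (!any(keep)) abort("all codons are masked (zero data); nothing to compare",
                        class = "riboballistic_unusable_data")
  structure(sum(((data[keep] - model[keep]) / data[keep])^2),
            n_masked = sum(!keep))
}

# fast internal forward model: unit-sum monosome shape and unit-sum
# normalized-polysome shape for rates p, initiation alpha, degradation omega
forward_shapes <- function(alpha, omega, p) {
  dwell <- 1 / p
  Tc <- cumsum(dwell)
  TL <- Tc[length(Tc)]
  Tmid <- Tc - dwell / 2
  pol <- omega * exp(-omega * Tmid) / (p * -expm1(-omega * TL))
  at <- alpha * TL
  wt <- omega * TL
  z <- at + wt
  pk1 <- ksome_probability(at, wt, 1)
  pt <- p * TL
  s1 <- at * exp(-z) / (pk1 * pt)
  f1 <- wt / (pk1 * pt) * (at / z) * (exp(-z * Tmid / TL) - exp(-z))
  mono <- s1 + f1
  list(mono = mono / sum(mono), pol = pol / sum(pol))
}

#' Recover initiation and per-codon elongation rates
#'
#' Solves the inverse problem of the ballistic model: given a monosome
#' density profile and a (normalization-free) polysome profile at a known
#' degradation rate `omega`, recovers the initiation rate `alpha` and all
#' `L` elongation rates `p_i` by minimizing
#' `X^2 = chi2_polysome + chi2_monosome`, the sum of squared relative
#' residuals of both channels ([chi2_profile()]). Both data and model
#' profiles are normalized internally to unit sum, so the result is
#' invariant under rescaling of either input (sequencing depth is unknown in
#' real data). Positivity is enforced by optimizing over
#' `(log alpha, log p_1..log p_L)` with the L-BFGS-B quasi-Newton method.
#'
#' At `omega = 0` all k-some and polysome profiles are linearly related and
#' the timescale is unidentifiable; this is refused with an error.
#'
#' @param data Long tibble with columns `class`, `codon`, `value` holding a
#'   `monosome` class and a `polysome` (or `polysome_normalized`) class,
#'   e.g. from [forward_profiles()], [sample_reads()] or [read_profiles()].
#' @param omega Known degradation rate, 1/s (> 0).
#' @param init_alpha,init_p Starting values (defaults 0.05 /s and a uniform
#'   1 /s profile).
#' @param max_iterations,grad_tol L-BFGS-B iteration cap and projected
#'   gradient tolerance (defaults 5000 and 1e-8).
#' @return An object of class `ballistic_fit`: recovered `alpha_star` and
#'   `p_star`, the objective and its per-channel decomposition, masked-codon
#'   count, convergence flag and iteration counts. Non-convergence is
#'   flagged, not thrown. See [tidy.ballistic_fit()],
#'   [glance.ballistic_fit()], [score_fit()].
#' @examples
#' prof <- random_elongation_profile(50, seed = 1)
#' truth <- kinetic_params(0.08, 5e-4, prof)
#' fit <- fit_rates(forward_profiles(truth), omega = 5e-4)
#' glance(fit)
#' @export
fit_rates <- function(data, omega, init_alpha = 0.05, init_p = 1,
                      max_iterations = 5000, grad_tol = 1e-8) {
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0) {
    abort("`omega` must be a single non-negative rate", class = "riboballistic_domain_error")
  }
  if (omega == 0) {
    abort(paste("omega = 0: in the infinite-lifetime limit monosome and polysome",
                "profiles are linearly related and the kinetic rates are not identifiable"),
          class = "riboballistic_identifiability")
  }
  stopifnot(all(c("class", "codon", "value") %in% names(data)))
  pol_class <- intersect(c("polysome_normalized", "polysome"), unique(data$class))
  if (!("monosome" %in% data$class) || length(pol_class) == 0) {
    abort("`data` must contain a 'monosome' and a 'polysome' (or 'polysome_normalized') class",
          class = "riboballistic_unusable_data")
  }
  grab <- function(cl) {
    sub <- dplyr::arrange(dplyr::filter(data, .data$class == cl), .data$codon)
    sub$value
  }
  mono_dat <- grab("monosome")
  pol_dat <- grab(pol_class[1])
  L <- length(mono_dat)
  if (length(pol_dat) != L) {
    abort("monosome and polysome profiles must cover the same codons",
          class = "riboballistic_unusable_data")
  }
  mono_dat <- mono_dat / sum(mono_dat)
  pol_dat <- pol_dat / sum(pol_dat)
  mono_keep <- mono_dat > 0
  pol_keep <- pol_dat > 0
  n_masked <- sum(!mono_keep) + sum(!pol_keep)
  if (!any(mono_keep) || !any(pol_keep)) {
    abort("a whole channel is zero; nothing to fit", class = "riboballistic_unusable_data")
  }

  objective <- function(theta) {
    sh <- forward_shapes(exp(theta[1]), omega, exp(theta[-1]))
    sum(((pol_dat[pol_keep] - sh$pol[pol_keep]) / pol_dat[pol_keep])^2) +
      sum(((mono_dat[mono_keep] - sh$mono[mono_keep]) / mono_dat[mono_keep])^2)
  }
  theta0 <- c(log(init_alpha), rep(log(init_p), L))
  res <- optim(theta0, objective, method = "L-BFGS-B",
               control = list(maxit = max_iterations, factr = 10, pgtol = grad_tol))
  alpha_star <- exp(res$par[1])
  p_star <- exp(res$par[-1])
  sh <- forward_shapes(alpha_star, omega, p_star)
  chi2_pol <- sum(((pol_dat[pol_keep] - sh$pol[pol_keep]) / pol_dat[pol_keep])^2)
  chi2_mono <- sum(((mono_dat[mono_keep] - sh$mono[mono_keep]) / mono_dat[mono_keep])^2)
  structure(list(alpha_star = alpha_star, p_star = p_star,
                 objective = chi2_pol + chi2_mono,
                 chi2_polysome = chi2_pol, chi2_monosome = chi2_mono,
                 n_masked = n_masked,
                 converged = res$convergence == 0,
                 iterations = res$counts[["function"]],
                 message = res$message %||% "",
                 omega = omega, L = L,
                 data = list(monosome = mono_dat, polysome = pol_dat),
                 model = sh),
            class = "ballistic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ballistic_fit <- function(x, ...) {
  cat(sprintf("<ballistic_fit> L = %d codons, alpha* = %.4g /s, X^2 = %.4g (polysome %.3g + monosome %.3g)\n",
              x$L, x$alpha_star, x$objective, x$chi2_polysome, x$chi2_monosome))
  cat(sprintf("  converged: %s after %d objective evaluations; %d codon(s) masked\n",
              x$converged, x$iterations, x$n_masked))
  invisible(x)
}

#' Tidiers for ballistic fits
#'
#' `tidy()` returns the recovered per-codon elongation rates; `glance()`
#' a one-row fit summary.
#'
#' @param x A [fit_rates()] result.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ballistic_fit
#' @export
tidy.ballistic_fit <- function(x, ...) {
  tibble(codon = seq_len(x$L), p_star = x$p_star)
}

#' @rdname tidy.ballistic_fit
#' @method glance ballistic_fit
#' @export
glance.ballistic_fit <- function(x, ...) {
  tibble(alpha_star = x$alpha_star, objective = x$objective,
         chi2_polysome = x$chi2_polysome, chi2_monosome = x$chi2_monosome,
         n_masked = x$n_masked, converged = x$converged,
         iterations = x$iterations, omega = x$omega, L = x$L)
}

#' Score a fit against known true parameters
#'
#' Relative-error score functions `Err_Y = |Y - Y*| / Y`: `err_alpha` for
#' the initiation rate, and over the per-codon elongation rates their mean
#' (`err_mean`) and maximum (`err_max`).
#'
#' @param fit A [fit_rates()] result.
#' @param truth The generating [kinetic_params()].
#' @return A one-row tibble of class `score_report` with columns
#'   `err_alpha`, `err_mean`, `err_max`; the per-codon errors are kept in
#'   attribute `per_codon`.
#' @export
score_fit <- function(fit, truth) {
  stopifnot(inherits(fit, "ballistic_fit"), inherits(truth, "kinetic_params"))
  p <- truth$profile$rates
  if (length(p) != fit$L) abort("fit and truth differ in length", class = "riboballistic_domain_error")
  per_codon <- abs(p - fit$p_star) / p
  out <- tibble(err_alpha = abs(truth$alpha - fit$alpha_star) / truth$alpha,
                err_mean = mean(per_codon),
                err_max = max(per_codon))
  structure(out, class = c("score_report", class(out)), per_codon = per_codon)
}

#' Homogeneous per-k fit of the crossing time
#'
#' The single-gene protocol used when only k-some profiles (no polysome) are
#' available: with `alpha` and `omega` fixed from external measurements, fit
#' a constant elongation rate by 1-D least squares over the total crossing
#' time `T(L)` — one fit per k-some class, relative residuals on profiles
#' normalized to integral `k` — and pool the per-k estimates by their
#' arithmetic mean. The elongation rate follows as `p = L / T(L)`.
#'
#' @param data Long tibble with columns `class`, `codon`, `value`, classes
#'   among `monosome`, `disome`, `trisome`, `tetrasome`.
#' @param alpha Fixed initiation rate, 1/s.
#' @param omega Fixed degradation rate, 1/s.
#' @param interval Search interval for `T(L)` in seconds.
#' @return An object of class `homogeneous_fit`: per-k tibble (`k`,
#'   `T_fit`, `p_fit`, `objective`) plus pooled `T_fit` and `p_fit`.
#' @export
fit_homogeneous <- function(data, alpha, omega, interval = c(1, 1e5)) {
  kmap <- c(monosome = 1, disome = 2, trisome = 3, tetrasome = 4)
  present <- intersect(names(kmap), unique(data$class))
  if (length(present) == 0) {
    abort("`data` holds no k-some class (monosome..tetrasome)", class = "riboballistic_unusable_data")
  }
  per_k <- purrr::map_dfr(present, function(cl) {
    k <- kmap[[cl]]
    sub <- dplyr::arrange(dplyr::filter(data, .data$class == cl), .data$codon)
    L <- nrow(sub)
    dat <- normalize_ksome(sub$value, k)$density
    tau_mid <- (seq_len(L) - 0.5) / L
    obj <- function(TT) {
      terms <- ksome_density_terms(alpha * TT, omega * TT, k, rep(L, L), tau_mid)
      model <- terms$stationary + terms$transient
      chi2_profile(model, dat)
    }
    # the relative-residual objective is multimodal in T over wide intervals:
    # coarse log-spaced scan first, then local refinement around the best cell
    grid <- exp(seq(log(interval[1]), log(interval[2]), length.out = 200))
    vals <- vapply(grid, function(TT) as.numeric(obj(TT)), numeric(1))
    best <- which.min(vals)
    lo <- grid[max(1, best - 1)]
    hi <- grid[min(length(grid), best + 1)]
    opt <- optimize(obj, interval = c(lo, hi), tol = 1e-6)
    if (!is.finite(opt$objective)) {
      abort(sprintf("homogeneous fit failed for k = %d (non-finite objective)", k),
            class = "riboballistic_fit_error")
    }
    tibble(k = k, T_fit = opt$minimum, p_fit = L / opt$minimum, objective = opt$objective)
  })
  L <- sum(data$class == present[1])
  pooled_T <- mean(per_k$T_fit)
  structure(list(per_k = per_k, T_fit = pooled_T, p_fit = L / pooled_T,
                 alpha = alpha, omega = omega, L = L),
            class = "homogeneous_fit")
}

#' @export
print.homogeneous_fit <- function(x, ...) {
  cat(sprintf("<homogeneous_fit> pooled T(L) = %.4g s (p = %.3g codons/s) over %d k-classes\n",
              x$T_fit, x$p_fit, nrow(x$per_k)))
  invisible(x)
}

#' @describeIn fit_homogeneous per-k crossing-time estimates as a tibble.
#' @param x A `homogeneous_fit`.
#' @param ... Unused.
#' @method tidy homogeneous_fit
#' @export
tidy.homogeneous_fit <- function(x, ...) x$per_k

#' @describeIn fit_homogeneous one-row pooled summary.
#' @method glance homogeneous_fit
#' @export
glance.homogeneous_fit <- function(x, ...) {
  tibble(T_fit = x$T_fit, p_fit = x$p_fit, n_classes = nrow(x$per_k),
         alpha = x$alpha, omega = x$omega, L = x$L)
}
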