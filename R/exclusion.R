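#' Continuous-time exclusion-process comparator
#'
#' Gillespie simulation of translation as a totally asymmetric exclusion
#' process on `L` lattice sites: entry at rate `alpha` when the first
#' `footprint` sites are free, hop `i -> i+1` at rate `p_i` blocked by a
#' particle within `footprint` sites downstream, exit from the last site at
#' rate `p_L`. No degradation (the comparator probes the infinite-lifetime
#' low-density regime where the ballistic prediction is `alpha / p(x)`).
#' Site occupancies are time-averaged after a burn-in.
#'
#' In the low-density regime (`alpha << p`) the stationary bulk occupancy
#' approaches the ballistic `alpha / p`; the residual discrepancy measures
#' the excluded-volume corrections the ballistic model neglects. With the
#' default horizon the per-site Monte Carlo standard error is a few percent
#' of `alpha / p`; increase `horizon_factor` (run time is roughly linear in
#' it) when the comparison itself must resolve percent-level deviations.
#'
#' @param params A [kinetic_params()] object; `omega` must be 0.
#' @param footprint Particle size in codons (default 1, matching the
#'   ballistic point-particle assumption).
#' @param seed Integer seed.
#' @param burn_in_factor,horizon_factor Burn-in and sampling horizon as
#'   multiples of the mean crossing time `T(L)` (defaults 10 and 100).
#' @return A tibble with columns `codon` and `occupancy` (probability the
#'   site is the leftmost site of a particle), with attributes `n_events`,
#'   `horizon`, `seed`.
#' @export
simulate_exclusion <- function(params, footprint = 1, seed,
                               burn_in_factor = 10, horizon_factor = 100) {
  stopifnot(inherits(params, "kinetic_params"), footprint >= 1)
  if (params$omega != 0) {
    abort("the exclusion comparator runs without degradation; set omega = 0",
          class = "riboballistic_domain_error")
  }
  p <- params$profile$rates
  L <- params$profile$length
  alpha <- params$alpha
  if (alpha >= min(p) / 2) {
    warn("entry rate is not small compared to elongation: outside the low-density regime the ballistic comparison is expected to fail")
  }
  total <- sum(1 / p)
  burn <- burn_in_factor * total
  horizon <- horizon_factor * total
  t_end <- burn + horizon
  f <- as.integer(footprint)

  run <- function() {
    occ <- numeric(L)
    pos <- integer(0)
    t <- 0
    n_events <- 0L
    repeat {
      n <- length(pos)
      entry_ok <- n == 0L || pos[1] > f
      rates <- numeric(n + 1L)
      rates[1L] <- if (entry_ok) alpha else 0
      if (n > 0L) {
        nxt <- c(pos[-1L], .Machine$integer.max)
        free <- nxt > pos + f
        rates[-1L] <- ifelse(pos == L | free, p[pos], 0)
      }
      dt <- rexp(1L, sum(rates))
      t_new <- t + dt
      if (n > 0L) {
        lo <- max(t, burn); hi <- min(t_new, t_end)
        if (hi > lo) occ[pos] <- occ[pos] + (hi - lo)
      }
      t <- t_new
      if (t >= t_end) break
      ev <- sample.int(n + 1L, 1L, prob = rates)
      if (ev == 1L) {
        pos <- c(1L, pos)
      } else {
        i <- ev - 1L
        if (pos[i] == L) pos <- pos[-i] else pos[i] <- pos[i] + 1L
      }
      n_events <- n_events + 1L
    }
    list(occ = occ / horizon, n_events = n_events)
  }
  res <- withr::with_seed(seed, run())
  structure(tibble(codon = seq_len(L), occupancy = res$occ),
            n_events = res$n_events, horizon = horizon, seed = seed)
}
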