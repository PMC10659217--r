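#' Exact stochastic sample of the ballistic ensemble
#'
#' Draws an ensemble of mRNAs from the ballistic model without
#' time-stepping: the process is a Poisson arrival stream plus deterministic
#' drift, so a snapshot can be sampled exactly. For each mRNA an age
#' `a ~ Exp(omega)` is drawn (`a = Inf` when `omega = 0`); the ribosomes
#' still aboard are those initiated within the lookback window
#' `w = min(a, T(L))`, a Poisson number with mean `alpha * w` whose
#' initiation lags are uniform on `[0, w]`; each lag `t` maps to the
#' position `x(t)` via [invert_time()].
#'
#' @param params A [kinetic_params()] object.
#' @param n_mrna Number of mRNAs to sample (>= 1).
#' @param seed Integer seed (required: the sampler is a reproducibility
#'   contract).
#' @return A tibble of class `ribosome_ensemble`, one row per mRNA:
#'   `mrna`, `age` (s), `n_ribosomes`, and `positions` (list-column of
#'   increasing continuous codon coordinates in `(0, L]`). Attributes
#'   `params` and `seed`.
#' @export
sample_ensemble <- function(params, n_mrna, seed) {
  stopifnot(inherits(params, "kinetic_params"), n_mrna >= 1)
  ct <- crossing_times(params$profile)
  draw <- function() {
    age <- if (params$omega == 0) rep(Inf, n_mrna) else rexp(n_mrna, params$omega)
    window <- pmin(age, ct$total)
    counts <- rpois(n_mrna, params$alpha * window)
    lags <- runif(sum(counts)) * rep(window, counts)
    positions <- invert_time(ct, lags)
    split_idx <- rep.int(seq_len(n_mrna), counts)
    pos_list <- vector("list", n_mrna)
    pos_list[] <- list(numeric(0))
    if (length(positions)) {
      filled <- split(positions, factor(split_idx, levels = seq_len(n_mrna)))
      pos_list <- lapply(filled, function(x) sort(x, decreasing = FALSE))
    }
    tibble(mrna = seq_len(n_mrna), age = age, n_ribosomes = counts,
           positions = unname(pos_list))
  }
  out <- withr::with_seed(seed, draw())
  structure(out, class = c("ribosome_ensemble", class(out)),
            params = params, seed = seed)
}

#' @export
print.ribosome_ensemble <- function(x, ...) {
  cat(sprintf("<ribosome_ensemble> %d mRNAs, mean load %.3f ribosomes (seed %d)\n",
              nrow(x), mean(x$n_ribosomes), attr(x, "seed")))
  NextMethod()
}

#' Empirical k-some frequencies of an ensemble
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param k_max Highest count tabulated (zero-count classes included).
#' @return A tibble with columns `k`, `n`, `frequency`.
#' @export
ksome_counts <- function(ensemble, k_max = max(ensemble$n_ribosomes)) {
  tab <- tabulate(ensemble$n_ribosomes + 1L, nbins = k_max + 1L)
  tibble(k = 0:k_max, n = tab, frequency = tab / nrow(ensemble))
}

#' Per-codon binned ribosome density of an ensemble
#'
#' Bins ribosome positions into codons (`codon i` covers `(i-1, i]`),
#' optionally restricted to mRNAs with exactly `k` ribosomes, and normalizes
#' to ribosomes per codon per mRNA — directly comparable to
#' [ksome_density()] or [polysome_density()].
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param k Restrict to k-somes with this count; `NULL` for all mRNAs.
#' @return A tibble with columns `codon`, `count`, `density`, and attribute
#'   `n_mrna` (the number of mRNAs in the selected class).
#' @export
binned_density <- function(ensemble, k = NULL) {
  params <- attr(ensemble, "params")
  L <- params$profile$length
  sel <- if (is.null(k)) ensemble else dplyr::filter(ensemble, .data$n_ribosomes == k)
  n_class <- nrow(sel)
  pos <- unlist(sel$positions, use.names = FALSE)
  codon <- pmin(pmax(ceiling(pos), 1L), L)
  counts <- tabulate(codon, nbins = L)
  out <- tibble(codon = seq_len(L), count = counts,
                density = if (n_class > 0) counts / n_class else rep(NA_real_, L))
  structure(out, n_mrna = n_class)
}

#' Finite-depth sequencing-read emulation
#'
#' Draws per-codon read counts as a multinomial over codons with
#' probabilities proportional to a density profile, one draw per profile
#' class — emulating finite read depth in a per-codon coverage table.
#'
#' @param profiles A long tibble with columns `class`, `codon`, `value`
#'   (e.g. from [forward_profiles()]); a `gene` column is carried through if
#'   present.
#' @param depth Reads per class: a single number or a named vector keyed by
#'   class.
#' @param seed Integer seed.
#' @return A tibble with columns (`gene`,) `class`, `codon`, `count`.
#' @export
sample_reads <- function(profiles, depth, seed) {
  stopifnot(all(c("class", "codon", "value") %in% names(profiles)), all(depth >= 1))
  classes <- unique(profiles$class)
  depths <- if (length(depth) == 1L && is.null(names(depth))) {
    setNames(rep(depth, length(classes)), classes)
  } else depth
  draw <- function() {
    purrr::map_dfr(classes, function(cl) {
      sub <- dplyr::filter(profiles, .data$class == cl)
      if (all(sub$value == 0)) {
        abort(sprintf("profile class '%s' is identically zero; cannot sample reads", cl),
              class = "riboballistic_degenerate_profile")
      }
      counts <- as.vector(rmultinom(1, size = depths[[cl]], prob = sub$value))
      out <- tibble(class = cl, codon = sub$codon, count = counts)
      if ("gene" %in% names(sub)) out <- dplyr::mutate(out, gene = sub$gene, .before = 1)
      out
    })
  }
  withr::with_seed(seed, draw())
}
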