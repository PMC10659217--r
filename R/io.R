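#' Read a per-codon profile table
#'
#' The package's single on-disk profile dialect: UTF-8 tab-separated values
#' with a header `gene  class  codon  value`, 1-based contiguous codon
#' indices per (gene, class), `#` comment lines allowed (provenance headers
#' written by [write_profiles()] are such comments). Several genes and
#' classes may share one file.
#'
#' @param path File to read.
#' @return A validated tibble with columns `gene`, `class`, `codon`
#'   (integer), `value` (double).
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path),
                                class = "riboballistic_io_error")
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           gene = readr::col_character(),
                           class = readr::col_character(),
                           codon = readr::col_integer(),
                           value = readr::col_double()))
  missing_cols <- setdiff(c("gene", "class", "codon", "value"), names(tbl))
  if (length(missing_cols)) {
    abort(sprintf("profile table lacks column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "riboballistic_io_error")
  }
  if (anyNA(tbl$value) || any(!is.finite(tbl$value))) {
    abort("profile values must be finite and non-missing", class = "riboballistic_validation_error")
  }
  if (any(tbl$value < 0)) {
    abort("profile values must be non-negative", class = "riboballistic_validation_error")
  }
  check <- tbl |>
    dplyr::group_by(.data$gene, .data$class) |>
    dplyr::summarise(gaps = list(setdiff(seq_len(max(.data$codon)), .data$codon)),
                     .groups = "drop")
  bad <- purrr::map_lgl(check$gaps, ~ length(.x) > 0)
  if (any(bad)) {
    first <- check[which(bad)[1], ]
    abort(sprintf("gene %s / class %s is missing codon index(es): %s",
                  first$gene, first$class,
                  paste(utils::head(first$gaps[[1]], 10), collapse = ", ")),
          class = "riboballistic_gap_error")
  }
  tbl
}

#' Write a per-codon profile table
#'
#' Writes the TSV dialect of [read_profiles()], preceded by `#` provenance
#' comment lines (package version, generating parameters and seed when
#' supplied) sufficient to regenerate the file.
#'
#' @param profiles Tibble with columns `gene`, `class`, `codon`, `value`
#'   (a `count` column is accepted and renamed to `value`).
#' @param path Output file.
#' @param params Optional [kinetic_params()] recorded in the header.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, params = NULL, seed = NULL) {
  if (!("value" %in% names(profiles)) && "count" %in% names(profiles)) {
    profiles <- dplyr::rename(profiles, value = "count")
  }
  if (!("gene" %in% names(profiles))) profiles <- dplyr::mutate(profiles, gene = "unnamed")
  profiles <- dplyr::select(profiles, "gene", "class", "codon", "value")
  header <- c(sprintf("# riboballistic %s profile table",
                      as.character(utils::packageVersion("riboballistic"))))
  if (!is.null(params)) {
    header <- c(header,
                sprintf("# alpha=%.10g omega=%.10g L=%d", params$alpha, params$omega,
                        params$profile$length),
                sprintf("# rates=%s", paste(signif(params$profile$rates, 10), collapse = ",")))
  }
  if (!is.null(seed)) header <- c(header, sprintf("# seed=%d", seed))
  writeLines(header, path)
  readr::write_tsv(profiles, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
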