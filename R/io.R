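#' Read a wide replicate-level expression matrix
#'
#' Reads a TSV (or CSV) with a first column `gene_id` and remaining columns
#' named `<time>_<replicate>` (e.g. `3_2` = time point 3, replicate 2) into
#' the long replicate-level tibble the preprocessing functions consume.
#'
#' @param path Path to the delimited file.
#' @param site Site label to attach to every row.
#' @param delim Field delimiter (default tab).
#' @return A tibble with columns `gene_id`, `site`, `time`, `replicate`,
#'   `value`.
#' @export
read_expression_matrix <- function(path, site, delim = "\t") {
  wide <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (names(wide)[1] != "gene_id") names(wide)[1] <- "gene_id"
  if (ncol(wide) < 2) {
    rlang::abort("expression matrix has no data columns.", class = "alignhmm_input_error")
  }
  bad <- !grepl("^[0-9]+_[0-9]+$", names(wide)[-1])
  if (any(bad)) {
    rlang::abort(
      paste0("data columns must be named <time>_<replicate>; offending: ",
             paste(names(wide)[-1][bad], collapse = ", ")),
      class = "alignhmm_input_error"
    )
  }
  wide |>
    tidyr::pivot_longer(-"gene_id", names_to = c("time", "replicate"),
                        names_sep = "_", values_to = "value") |>
    dplyr::mutate(
      site      = site,
      time      = as.integer(.data$time),
      replicate = as.integer(.data$replicate)
    ) |>
    dplyr::select("gene_id", "site", "time", "replicate", "value")
}

#' Read and write long profile tibbles as TSV
#'
#' Plain TSV with columns `gene_id`, `site`, `time`, `value`; time and state
#' indices are 1-based throughout the package's outputs.
#'
#' @param profiles A profile tibble.
#' @param path File path.
#' @return `write_profiles_tsv()` returns `path` invisibly;
#'   `read_profiles_tsv()` returns a tibble.
#' @export
write_profiles_tsv <- function(profiles, path) {
  readr::write_tsv(profiles[, c("gene_id", "site", "time", "value")], path)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = readr::col_character(),
                    site    = readr::col_character(),
                    time    = readr::col_integer(),
                    value   = readr::col_double()
                  ))
}

#' Write a gap-search likelihood surface as TSV
#'
#' Columns `g1`, `g2`, `loglik` in the two-gap case (the heat-map input),
#' otherwise `gaps`, `loglik`.
#'
#' @param x A `gap_search` object from [search_gaps()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gap_surface <- function(x, path) {
  readr::write_tsv(tidy(x), path)
  invisible(path)
}
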