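#' Profile and profile-pair tibbles
#'
#' The package's data currency is a long tibble of expression profiles with
#' columns `gene_id`, `site`, `time` and `value`: one row per observed time
#' point of one gene at one site. A *profile pair* collection is such a tibble
#' with exactly two sites, where every gene is observed at both sites, all
#' profiles within a site have the same length, and the first site (the
#' "long" site, e.g. a 19-week season) has at least as many time points as
#' the second (e.g. a 17-week season). `as_profile_pairs()` checks these
#' contracts and orders rows canonically.
#'
#' @param x A data frame with columns `gene_id`, `site`, `time`, `value`.
#' @param sites Optional character vector of length 2 naming the long and the
#'   short site, in that order. By default the site with more time points is
#'   taken as the long site (ties are an error: use `sites` to disambiguate).
#'
#' @return A tibble with columns `gene_id`, `site`, `time`, `value`, ordered
#'   by gene, site (long first) and time, with an attribute `sites` giving
#'   `c(long, short)`.
#' @export
as_profile_pairs <- function(x, sites = NULL) {
  need <- c("gene_id", "site", "time", "value")
  if (!all(need %in% names(x))) {
    rlang::abort(
      paste0("`x` must have columns ", paste(need, collapse = ", "), "."),
      class = "alignhmm_input_error"
    )
  }
  x <- tibble::as_tibble(x)
  if (!all(is.finite(x$value))) {
    rlang::abort("all `value`s must be finite.", class = "alignhmm_input_error")
  }
  site_len <- x |>
    dplyr::count(.data$site, .data$gene_id) |>
    dplyr::distinct(.data$site, len = .data$n)
  if (anyDuplicated(site_len$site)) {
    rlang::abort("all profiles within a site must have the same length.",
                 class = "alignhmm_input_error")
  }
  if (nrow(site_len) != 2L) {
    rlang::abort("`x` must contain exactly two sites.", class = "alignhmm_input_error")
  }
  if (is.null(sites)) {
    if (site_len$len[1] == site_len$len[2]) {
      rlang::abort("both sites have the same profile length; name the long site via `sites`.",
                   class = "alignhmm_input_error")
    }
    sites <- site_len$site[order(-site_len$len)]
  } else {
    if (!setequal(sites, site_len$site) || length(sites) != 2L) {
      rlang::abort("`sites` must name the two sites present in `x`.",
                   class = "alignhmm_input_error")
    }
  }
  len <- stats::setNames(site_len$len, site_len$site)
  if (len[sites[1]] < len[sites[2]] || len[sites[2]] < 2L) {
    rlang::abort("the long site must have T1 >= T2 >= 2 time points.",
                 class = "alignhmm_input_error")
  }
  genes <- x |>
    dplyr::distinct(.data$gene_id, .data$site) |>
    dplyr::count(.data$gene_id)
  if (any(genes$n != 2L)) {
    rlang::abort("every gene must be observed at both sites.",
                 class = "alignhmm_input_error")
  }
  out <- x |>
    dplyr::mutate(site = factor(.data$site, levels = sites)) |>
    dplyr::arrange(.data$gene_id, .data$site, .data$time) |>
    dplyr::mutate(site = as.character(.data$site))
  attr(out, "sites") <- as.character(sites)
  out
}

# Long/short observation matrices from a pair tibble.
# Returns list(W: K x T1, C: K x T2, gene_ids, sites).
pairs_to_matrices <- function(pairs) {
  pairs <- as_profile_pairs(pairs, sites = attr(pairs, "sites"))
  sites <- attr(pairs, "sites")
  to_mat <- function(s) {
    d <- pairs[pairs$site == s, ]
    gid <- unique(d$gene_id)
    tl <- nrow(d) / length(gid)
    # rows already ordered gene, time
    matrix(d$value, nrow = length(gid), ncol = tl, byrow = TRUE,
           dimnames = list(gid, NULL))
  }
  W <- to_mat(sites[1])
  C <- to_mat(sites[2])
  stopifnot(identical(rownames(W), rownames(C)))
  list(W = W, C = C, gene_ids = rownames(W), sites = sites)
}

# Inverse of pairs_to_matrices
matrices_to_pairs <- function(W, C, gene_ids, sites = c("site1", "site2")) {
  long_tbl <- function(M, s) {
    tibble::tibble(
      gene_id = rep(gene_ids, each = ncol(M)),
      site    = s,
      time    = rep(seq_len(ncol(M)), length(gene_ids)),
      value   = as.numeric(t(M))
    )
  }
  as_profile_pairs(dplyr::bind_rows(long_tbl(W, sites[1]), long_tbl(C, sites[2])),
                   sites = sites)
}

# Split a profile tibble (possibly paired) into a list of numeric vectors,
# one per (gene_id, site) profile, ordered by time.
profiles_to_list <- function(profiles) {
  need <- c("gene_id", "site", "time", "value")
  if (!all(need %in% names(profiles))) {
    rlang::abort(paste0("`profiles` must have columns ", paste(need, collapse = ", "), "."),
                 class = "alignhmm_input_error")
  }
  if (!all(is.finite(profiles$value))) {
    rlang::abort("all `value`s must be finite.", class = "alignhmm_input_error")
  }
  profiles |>
    dplyr::arrange(.data$gene_id, .data$site, .data$time) |>
    dplyr::group_by(.data$gene_id, .data$site) |>
    dplyr::group_map(~ .x$value) |>
    stats::setNames(
      profiles |>
        dplyr::distinct(.data$gene_id, .data$site) |>
        dplyr::arrange(.data$gene_id, .data$site) |>
        dplyr::mutate(key = paste(.data$gene_id, .data$site, sep = "/")) |>
        dplyr::pull(.data$key)
    )
}
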