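#' Average replicate observations at each time point
#'
#' Collapses replicate-level expression data to one value per gene, site and
#' time point by the arithmetic mean. Missing values within a replicate set
#' are dropped from the mean with a warning; a time point whose replicates
#' are all missing is an input error (the alignment model has no notion of a
#' missing time point in the weekly design).
#'
#' @param raw A tibble with columns `gene_id`, `site`, `time`, `replicate`,
#'   `value` (see [read_expression_matrix()] for the wide TSV reader).
#' @return A profile tibble with columns `gene_id`, `site`, `time`, `value`.
#' @export
average_replicates <- function(raw) {
  need <- c("gene_id", "site", "time", "replicate", "value")
  if (!all(need %in% names(raw))) {
    rlang::abort(paste0("`raw` must have columns ", paste(need, collapse = ", "), "."),
                 class = "alignhmm_input_error")
  }
  if (anyNA(raw$value)) {
    rlang::warn("missing replicate values; averaging the non-missing replicates.")
  }
  out <- raw |>
    dplyr::group_by(.data$gene_id, .data$site, .data$time) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  if (any(is.nan(out$value))) {
    rlang::abort("a time point has no non-missing replicate observations.",
                 class = "alignhmm_input_error")
  }
  out
}

#' Fold-change filter for a pair of unscaled profiles
#'
#' A pair is kept when at least one of its two profiles shows at least a
#' `threshold`-fold change, i.e. `max(value) / min(value) >= threshold`.
#' Computed on the unlogged intensity scale after replicate averaging, so all
#' values must be strictly positive; the rule is invariant to multiplying a
#' profile by any positive constant.
#'
#' @param w,c_short Numeric vectors: the unscaled averaged profiles of the
#'   two sites (any lengths).
#' @param threshold Minimum fold change (default 2).
#' @return `TRUE` (keep) or `FALSE` (drop).
#' @seealso [filter_fold_change()] for the data-frame interface.
#' @export
fold_change_filter <- function(w, c_short, threshold = 2) {
  if (any(c(w, c_short) <= 0)) {
    rlang::abort("fold change requires strictly positive (unlogged) intensities.",
                 class = "alignhmm_input_error")
  }
  max(w) / min(w) >= threshold || max(c_short) / min(c_short) >= threshold
}

#' @describeIn fold_change_filter Filter a profile tibble, keeping the genes
#'   whose pair passes; dropped genes are recorded in the `"drop_log"`
#'   attribute (a tibble with columns `gene_id`, `reason`).
#' @param profiles A profile tibble (`gene_id`, `site`, `time`, `value`) with
#'   two sites, on the unlogged scale.
#' @export
filter_fold_change <- function(profiles, threshold = 2) {
  if (any(profiles$value <= 0)) {
    rlang::abort("fold change requires strictly positive (unlogged) intensities.",
                 class = "alignhmm_input_error")
  }
  keep <- profiles |>
    dplyr::group_by(.data$gene_id, .data$site) |>
    dplyr::summarise(fc = max(.data$value) / min(.data$value), .groups = "drop_last") |>
    dplyr::summarise(keep = any(.data$fc >= threshold), .groups = "drop")
  out <- profiles |> dplyr::filter(.data$gene_id %in% keep$gene_id[keep$keep])
  attr(out, "drop_log") <- tibble::tibble(
    gene_id = keep$gene_id[!keep$keep],
    reason  = sprintf("fold change below %g at both sites", threshold)
  )
  out
}

#' Linear scaling of a profile to the unit interval
#'
#' Maps a profile to `[0, 1]` by `x -> (x - min) / (max - min)`, so the
#' scaled values attain 0 and 1 exactly and the ordering is preserved. Each
#' profile is scaled individually; after scaling, the state space and
#' emission distributions of the HMM can be treated as common to all genes.
#' A constant profile cannot be scaled and is an error — filter first.
#'
#' @param values Numeric vector with `max > min`.
#' @return Numeric vector of the same length in `[0, 1]`.
#' @seealso [scale_profiles()] for the data-frame interface.
#' @export
scale_unit_interval <- function(values) {
  r <- range(values)
  if (!all(is.finite(r)) || r[1] >= r[2]) {
    rlang::abort("cannot scale a constant (or non-finite) profile to [0, 1].",
                 class = "alignhmm_scaling_error")
  }
  (values - r[1]) / (r[2] - r[1])
}

#' @describeIn scale_unit_interval Scale every `(gene_id, site)` profile of a
#'   profile tibble individually.
#' @param profiles A profile tibble (`gene_id`, `site`, `time`, `value`).
#' @export
scale_profiles <- function(profiles) {
  profiles |>
    dplyr::group_by(.data$gene_id, .data$site) |>
    dplyr::mutate(value = scale_unit_interval(.data$value)) |>
    dplyr::ungroup()
}

#' Preprocess replicate-level expression tables into scaled profile pairs
#'
#' The full preprocessing pipeline upstream of the alignment model:
#' replicate averaging, the fold-change filter, removal of genes with a
#' constant profile at either site (unscalable), and per-profile scaling to
#' `[0, 1]`. Differential-expression filtering (e.g. a moderated-t test over
#' time) is assumed to have been applied upstream; this function accepts
#' pre-filtered matrices.
#'
#' @param raw A replicate-level tibble (`gene_id`, `site`, `time`,
#'   `replicate`, `value`) containing exactly two sites, on the unlogged
#'   intensity scale.
#' @param fold_change Minimum fold change required at at least one site
#'   (default 2); `NULL` disables the filter.
#' @param sites Optional `c(long, short)` site names, passed to
#'   [as_profile_pairs()].
#' @return A list with `pairs` (a scaled profile-pair tibble) and `drop_log`
#'   (a tibble with columns `gene_id`, `reason` for every removed gene).
#' @export
preprocess_pairs <- function(raw, fold_change = 2, sites = NULL) {
  prof <- average_replicates(raw)
  drop_log <- tibble::tibble(gene_id = character(), reason = character())
  if (!is.null(fold_change)) {
    prof <- filter_fold_change(prof, threshold = fold_change)
    drop_log <- dplyr::bind_rows(drop_log, attr(prof, "drop_log"))
  }
  constant <- prof |>
    dplyr::group_by(.data$gene_id, .data$site) |>
    dplyr::summarise(constant = max(.data$value) == min(.data$value), .groups = "drop_last") |>
    dplyr::summarise(constant = any(.data$constant), .groups = "drop")
  bad <- constant$gene_id[constant$constant]
  if (length(bad) > 0) {
    drop_log <- dplyr::bind_rows(
      drop_log,
      tibble::tibble(gene_id = bad, reason = "constant profile at one site")
    )
    prof <- prof |> dplyr::filter(!.data$gene_id %in% bad)
  }
  if (nrow(prof) == 0) {
    rlang::abort("no genes left after filtering.", class = "alignhmm_input_error")
  }
  pairs <- scale_profiles(prof) |> as_profile_pairs(sites = sites)
  list(pairs = pairs, drop_log = dplyr::arrange(drop_log, .data$gene_id))
}
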