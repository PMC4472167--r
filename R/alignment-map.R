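#' Alignment map between a pair of profiles and the common state sequence
#'
#' The alignment HMM assumes both profiles of a pair are emitted from one
#' latent state sequence of length `T`. The long profile (length `T1 = T`)
#' maps to state positions by identity; the short profile (length
#' `T2 = T - G`) maps through a strictly increasing index vector `tau_short`
#' determined by `G` *gap positions*: state positions at which the short site
#' has no observation. The first time points of both sites are constrained to
#' align (`tau_short[1] = 1`), so position 1 can never be a gap.
#'
#' @param total_positions Length `T` of the common state sequence.
#' @param gaps Integer vector of gap positions, each in `2..T`, distinct.
#' @return An object of class `alignment_map`: a list with
#'   `total_positions`, `tau_long` (identity, `1:T`), `tau_short`
#'   (the complement of `gaps` in `1:T`), and `gap_positions` (sorted).
#' @seealso [tau_from_gaps()] for the two-gap case in the notation
#'   `(g1, g2)`.
#' @export
alignment_map <- function(total_positions, gaps) {
  T_ <- as.integer(total_positions)
  gaps <- as.integer(gaps)
  if (T_ < 2L) {
    rlang::abort("`total_positions` must be at least 2.", class = "alignhmm_domain_error")
  }
  if (anyDuplicated(gaps) || any(gaps < 2L) || any(gaps > T_)) {
    rlang::abort(
      "gap positions must be distinct integers in 2..T (position 1 is constrained to align).",
      class = "alignhmm_domain_error"
    )
  }
  gaps <- sort(gaps)
  tau_short <- setdiff(seq_len(T_), gaps)
  structure(
    list(
      total_positions = T_,
      tau_long        = seq_len(T_),
      tau_short       = tau_short,
      gap_positions   = gaps
    ),
    class = "alignment_map"
  )
}

#' Two-gap alignment map from gap positions `(g1, g2)`
#'
#' Convenience constructor for the grapevine geometry: a long site of `T`
#' weekly time points and a short site of `T - 2`, aligned by choosing two
#' gap positions `1 < g1 < g2 <= T`. The short site's index map is then
#' `tau_short[t] = t` for `t < g1`, `t + 1` for `g1 <= t <= g2 - 2`, and
#' `t + 2` for `t >= g2 - 1`.
#'
#' @param g1,g2 Gap positions with `1 < g1 < g2 <= total_positions`.
#' @param total_positions Length `T` of the common state sequence
#'   (default 19).
#' @return An `alignment_map` with `gap_positions = c(g1, g2)`.
#' @examples
#' tau_from_gaps(2, 11)$tau_short
#' @export
tau_from_gaps <- function(g1, g2, total_positions = 19) {
  if (length(g1) != 1L || length(g2) != 1L ||
      g1 <= 1 || g1 >= g2 || g2 > total_positions) {
    rlang::abort("need 1 < g1 < g2 <= total_positions.", class = "alignhmm_domain_error")
  }
  alignment_map(total_positions, c(g1, g2))
}

#' @export
print.alignment_map <- function(x, ...) {
  cat("<alignment_map> T =", x$total_positions,
      " T2 =", length(x$tau_short), "\n")
  cat("  gaps:     ", paste(x$gap_positions, collapse = " "), "\n")
  cat("  tau_short:", paste(x$tau_short, collapse = " "), "\n")
  invisible(x)
}

check_amap_lengths <- function(w, c_short, amap) {
  if (length(w) != amap$total_positions || length(c_short) != length(amap$tau_short)) {
    rlang::abort(
      sprintf("profile lengths (%d, %d) do not match the alignment map (T = %d, T2 = %d).",
              length(w), length(c_short), amap$total_positions, length(amap$tau_short)),
      class = "alignhmm_input_error"
    )
  }
  invisible(NULL)
}
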