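#' Alignment log-likelihood of one profile pair
#'
#' Forward log-likelihood of a pair of profiles under the alignment HMM: a
#' single latent state sequence of length `T` emits the long profile at every
#' position and the short profile at its mapped positions, so non-gap
#' positions carry two Gaussian emission terms and gap positions one. The
#' recursion runs in log space over the `T` state positions.
#'
#' @param w Numeric vector, the long profile (length `T`).
#' @param c_short Numeric vector, the short profile (length `T2`).
#' @param params An [hmm_params()] object.
#' @param amap An [alignment_map()] matching the two lengths.
#' @return The pair's alignment log-likelihood (a single number).
#' @export
pair_loglik <- function(w, c_short, params, amap) {
  validate_hmm_params(params)
  check_profile_values(w)
  check_amap_lengths(w, c_short, amap)
  lb <- composite_log_emission(w, c_short, params, amap)
  la <- log(params$initial_probs)
  lA <- log(params$transition_matrix)
  lalpha <- la + lb[1, ]
  for (u in seq_len(amap$total_positions)[-1]) {
    lalpha <- vapply(
      seq_len(params$n_states),
      function(j) logsumexp(lalpha + lA[, j]),
      numeric(1)
    ) + lb[u, ]
  }
  logsumexp(lalpha)
}

# T x N matrix of per-position log emission weights for one pair:
# long-profile density everywhere, short-profile density added at mapped
# positions.
composite_log_emission <- function(w, c_short, params, amap) {
  lb <- .log_emission(w, params)
  if (length(c_short) > 0) {
    lb[amap$tau_short, ] <- lb[amap$tau_short, ] + .log_emission(c_short, params)
  }
  lb
}

#' Joint Viterbi decoding of one profile pair
#'
#' The most probable common state sequence for a pair under the alignment
#' HMM, using the same composite per-position emission weights as
#' [pair_loglik()] and the same smallest-index tie-breaking as
#' [viterbi_path()].
#'
#' @inheritParams pair_loglik
#' @return A `viterbi_result` of length `T` (see [viterbi_path()]); its
#'   `log_prob` never exceeds [pair_loglik()] on the same input.
#' @export
joint_viterbi <- function(w, c_short, params, amap) {
  validate_hmm_params(params)
  check_profile_values(w)
  check_amap_lengths(w, c_short, amap)
  lb <- composite_log_emission(w, c_short, params, amap)
  viterbi_decode(lb, log(params$initial_probs), log(params$transition_matrix))
}

#' Average-profile common representation of an aligned pair
#'
#' One of the two aligned representations: at state positions where both
#' sites are observed the mean of the two values, at gap positions the long
#' site's value alone. (The other representation is the joint Viterbi path,
#' see [joint_viterbi()] and [align_pairs()].)
#'
#' @inheritParams pair_loglik
#' @return Numeric vector of length `T`.
#' @export
average_profile <- function(w, c_short, amap) {
  check_amap_lengths(w, c_short, amap)
  out <- w
  out[amap$tau_short] <- (w[amap$tau_short] + c_short) / 2
  out
}

#' Total alignment log-likelihood of a pair collection at fixed gaps
#'
#' Sum of [pair_loglik()] over all pairs, with one shared alignment map
#' built from the gap positions — the objective the gap grid search
#' maximises.
#'
#' @param pairs A profile-pair tibble (see [as_profile_pairs()]); all pairs
#'   share the common lengths `T1`, `T2`.
#' @param params An [hmm_params()] object.
#' @param gaps Integer vector of `T1 - T2` gap positions (e.g. `c(g1, g2)`).
#' @return The total log-likelihood (a single number).
#' @export
total_loglik <- function(pairs, params, gaps) {
  validate_hmm_params(params)
  mats <- pairs_to_matrices(pairs)
  amap <- alignment_map(ncol(mats$W), gaps)
  if (length(amap$tau_short) != ncol(mats$C)) {
    rlang::abort("number of gaps must equal T1 - T2.", class = "alignhmm_input_error")
  }
  ld <- pair_log_densities(mats, params)
  sum(pair_forward_ll_vec(ld, amap, params))
}

# Precompute per-state log densities of every observation:
# list(LW = list over states of K x T1, LC = list over states of K x T2).
pair_log_densities <- function(mats, params) {
  N <- params$n_states
  mu <- params$emission_means
  sd_ <- sqrt(params$emission_variances)
  LW <- lapply(seq_len(N), function(j) {
    matrix(stats::dnorm(mats$W, mu[j], sd_[j], log = TRUE), nrow(mats$W))
  })
  LC <- lapply(seq_len(N), function(j) {
    matrix(stats::dnorm(mats$C, mu[j], sd_[j], log = TRUE), nrow(mats$C))
  })
  list(LW = LW, LC = LC, K = nrow(mats$W))
}

# Vectorised (across pairs) scaled forward pass of the alignment HMM.
# Returns the K per-pair log-likelihoods for one alignment map.
pair_forward_ll_vec <- function(ld, amap, params) {
  T_ <- amap$total_positions
  N <- params$n_states
  K <- ld$K
  A <- params$transition_matrix
  # short-profile index observed at each position (NA at gaps)
  m_at <- rep(NA_integer_, T_)
  m_at[amap$tau_short] <- seq_along(amap$tau_short)
  lb_at <- function(u) {
    lb <- vapply(seq_len(N), function(j) ld$LW[[j]][, u], numeric(K))
    lb <- matrix(lb, K, N)
    if (!is.na(m_at[u])) {
      lb <- lb + matrix(vapply(seq_len(N), function(j) ld$LC[[j]][, m_at[u]],
                               numeric(K)), K, N)
    }
    lb
  }
  ll <- numeric(K)
  lb1 <- lb_at(1)
  m1 <- do.call(pmax, as.data.frame(lb1))
  al <- matrix(params$initial_probs, K, N, byrow = TRUE) * exp(lb1 - m1)
  cs <- rowSums(al)
  ll <- log(cs) + m1
  al <- al / cs
  for (u in seq_len(T_)[-1]) {
    lbu <- lb_at(u)
    mu_ <- do.call(pmax, as.data.frame(lbu))
    al <- (al %*% A) * exp(lbu - mu_)
    cs <- rowSums(al)
    ll <- ll + log(cs) + mu_
    al <- al / cs
  }
  ll
}

#' Exhaustive grid search over gap positions
#'
#' Evaluates the total alignment log-likelihood at fixed parameters for every
#' admissible gap set (`G = T1 - T2` gap positions chosen from `2..T1`) and
#' returns the full likelihood surface together with its argmax — step two of
#' the two-step fit. For the grapevine geometry (`T1 = 19`, `T2 = 17`) the
#' surface has `choose(18, 2) = 153` entries `1 < g1 < g2 <= 19`.
#'
#' Ties in the argmax are broken toward the lexicographically smallest gap
#' set; any exact ties are reported in `ties`.
#'
#' @inheritParams total_loglik
#' @param max_candidates Refuse to enumerate more than this many gap sets
#'   (default `1e5`).
#' @return An object of class `gap_search`: a list with `surface` (a tibble;
#'   columns `g1`, `g2`, `loglik` when `G = 2`, otherwise a `gaps` string
#'   column plus `loglik`), `best_gaps` (integer vector), `best_loglik`,
#'   `ties` (list of tied gap sets, usually length 1) and `n_pairs`.
#' @seealso [fit_two_step()], [autoplot.gap_search()]
#' @export
search_gaps <- function(pairs, params, max_candidates = 1e5) {
  validate_hmm_params(params)
  mats <- pairs_to_matrices(pairs)
  search_gaps_mats(mats, params, max_candidates)
}

search_gaps_mats <- function(mats, params, max_candidates = 1e5) {
  T_ <- ncol(mats$W)
  G <- T_ - ncol(mats$C)
  if (G < 1L) {
    rlang::abort("the long site must have more time points than the short site.",
                 class = "alignhmm_input_error")
  }
  combos <- utils::combn(2:T_, G)
  if (ncol(combos) > max_candidates) {
    rlang::abort(
      sprintf("gap grid has %d candidates, above `max_candidates` = %g.",
              ncol(combos), max_candidates),
      class = "alignhmm_domain_error"
    )
  }
  ld <- pair_log_densities(mats, params)
  ll <- vapply(
    seq_len(ncol(combos)),
    function(i) sum(pair_forward_ll_vec(ld, alignment_map(T_, combos[, i]), params)),
    numeric(1)
  )
  best_i <- which.max(ll)
  tie_i <- which(ll == ll[best_i])
  surface <- if (G == 2L) {
    tibble::tibble(g1 = combos[1, ], g2 = combos[2, ], loglik = ll)
  } else {
    tibble::tibble(gaps = apply(combos, 2, paste, collapse = ","), loglik = ll)
  }
  structure(
    list(
      surface     = surface,
      best_gaps   = combos[, best_i],
      best_loglik = ll[best_i],
      ties        = lapply(tie_i, function(i) combos[, i]),
      n_pairs     = ld$K
    ),
    class = "gap_search"
  )
}

#' @export
print.gap_search <- function(x, ...) {
  cat("<gap_search> ", nrow(x$surface), " candidate gap sets over ",
      x$n_pairs, " pairs\n", sep = "")
  cat("  best gaps: (", paste(x$best_gaps, collapse = ", "), ")  log-likelihood ",
      format(x$best_loglik), "\n", sep = "")
  if (length(x$ties) > 1) cat("  NOTE:", length(x$ties), "tied argmax gap sets\n")
  invisible(x)
}

#' @describeIn search_gaps The likelihood surface as a tibble.
#' @param x A `gap_search` object.
#' @param ... Unused.
#' @method tidy gap_search
#' @export
tidy.gap_search <- function(x, ...) x$surface

#' @describeIn search_gaps One-row summary: best gaps, best log-likelihood,
#'   numbers of candidates, ties and pairs.
#' @method glance gap_search
#' @export
glance.gap_search <- function(x, ...) {
  tibble::tibble(
    g1           = x$best_gaps[1],
    g2           = if (length(x$best_gaps) >= 2) x$best_gaps[2] else NA_integer_,
    best_loglik  = x$best_loglik,
    n_candidates = nrow(x$surface),
    n_ties       = length(x$ties),
    n_pairs      = x$n_pairs
  )
}

#' Two-step fit of the alignment HMM
#'
#' The recommended, robust estimation procedure: (1) fit one standard
#' Gaussian HMM by pooled Baum-Welch to all individual profiles from both
#' sites, ignoring the pairing ([fit_hmm_pooled()]); (2) with those
#' parameters fixed, choose the gap positions by exhaustive grid search over
#' the alignment log-likelihood ([search_gaps()]). Because step 1 never uses
#' the pairing, profile pairs that are not alignable (e.g. genes driven by
#' site-specific environment rather than development) cannot bias the
#' parameter estimate, and the grid search tolerates a large contaminated
#' fraction.
#'
#' @inheritParams fit_hmm_pooled
#' @param pairs A profile-pair tibble (see [as_profile_pairs()]).
#' @param max_candidates Passed to [search_gaps()].
#' @return An object of class `two_step_fit`: a list with `hmm` (the pooled
#'   `hmm_fit`) and `gaps` (the `gap_search`).
#' @export
fit_two_step <- function(pairs, n_states = 5, variance_floor = 0.001,
                         tol = 1e-6, max_iter = 500, n_starts = 1,
                         seed = NULL, max_candidates = 1e5) {
  pairs <- as_profile_pairs(pairs, sites = attr(pairs, "sites"))
  hmm <- fit_hmm_pooled(pairs, n_states = n_states,
                        variance_floor = variance_floor, tol = tol,
                        max_iter = max_iter, n_starts = n_starts, seed = seed)
  gaps <- search_gaps(pairs, hmm$params, max_candidates = max_candidates)
  structure(list(hmm = hmm, gaps = gaps), class = "two_step_fit")
}

#' @export
print.two_step_fit <- function(x, ...) {
  cat("<two_step_fit>\n")
  print(x$hmm)
  print(x$gaps)
  invisible(x)
}

#' @describeIn fit_two_step Per-state parameters of the pooled fit.
#' @param x A `two_step_fit` object.
#' @param ... Unused.
#' @method tidy two_step_fit
#' @export
tidy.two_step_fit <- function(x, ...) tidy(x$hmm)

#' @describeIn fit_two_step One-row summary combining the pooled fit and the
#'   gap search.
#' @method glance two_step_fit
#' @export
glance.two_step_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$hmm) |> dplyr::rename(pooled_loglik = "loglik"),
    glance(x$gaps) |> dplyr::rename(alignment_loglik = "best_loglik")
  )
}

#' Full maximum-likelihood fit of the alignment HMM at fixed gaps
#'
#' EM for the alignment HMM itself: the E-step runs forward-backward over the
#' `T` common state positions with the composite emission weights of
#' [pair_loglik()], and the M-step weights *both* observations mapped to a
#' position by that position's posterior, so non-gap positions contribute two
#' emission terms. This is the profile-likelihood alternative to the pooled
#' estimate; unlike the two-step fit it is sensitive to non-alignable pairs,
#' which inflate the fitted emission variances (misaligned values from the
#' two sites are forced onto common states).
#'
#' @inheritParams fit_two_step
#' @param gaps Integer vector of `T1 - T2` fixed gap positions.
#' @return An `hmm_fit` (see [fit_hmm_pooled()]) with an extra element
#'   `gaps`.
#' @export
fit_alignment_hmm <- function(pairs, gaps, n_states = 5,
                              variance_floor = 0.001, tol = 1e-6,
                              max_iter = 500, n_starts = 1, seed = NULL) {
  mats <- pairs_to_matrices(pairs)
  amap <- alignment_map(ncol(mats$W), gaps)
  if (length(amap$tau_short) != ncol(mats$C)) {
    rlang::abort("number of gaps must equal T1 - T2.", class = "alignhmm_input_error")
  }
  fit <- em_multi_start(
    list(mats), n_states = n_states, variance_floor = variance_floor,
    tol = tol, max_iter = max_iter, n_starts = n_starts, seed = seed,
    estep = estep_alignment, amap = amap
  )
  fit$gaps <- amap$gap_positions
  fit$n_profiles <- nrow(mats$W)
  fit
}

# E-step for the alignment HMM: `groups` is list(mats); positions carry one
# or two observations.
estep_alignment <- function(groups, params, amap) {
  mats <- groups[[1]]
  T_ <- amap$total_positions
  N <- params$n_states
  m_at <- rep(NA_integer_, T_)
  m_at[amap$tau_short] <- seq_along(amap$tau_short)
  lb <- lapply(seq_len(T_), function(u) {
    l <- .log_emission(mats$W[, u], params)
    if (!is.na(m_at[u])) l <- l + .log_emission(mats$C[, m_at[u]], params)
    l
  })
  fb <- forward_backward_mat(lb, params$initial_probs, params$transition_matrix)
  g_sum <- numeric(N); gx_sum <- numeric(N); gx2_sum <- numeric(N)
  for (u in seq_len(T_)) {
    g <- fb$gamma[[u]]
    x <- mats$W[, u]
    g_sum <- g_sum + colSums(g)
    gx_sum <- gx_sum + colSums(g * x)
    gx2_sum <- gx2_sum + colSums(g * x^2)
    if (!is.na(m_at[u])) {
      x2 <- mats$C[, m_at[u]]
      g_sum <- g_sum + colSums(g)
      gx_sum <- gx_sum + colSums(g * x2)
      gx2_sum <- gx2_sum + colSums(g * x2^2)
    }
  }
  list(loglik = fb$loglik, a_num = colSums(fb$gamma1), xi_sum = fb$xi_sum,
       g_sum = g_sum, gx_sum = gx_sum, gx2_sum = gx2_sum)
}

#' Aligned common representations for every pair
#'
#' Builds, for each gene, the two single-profile representations of its
#' aligned pair: the [average_profile()] and the [joint_viterbi()] state
#' path, on the `T` common state positions.
#'
#' @inheritParams total_loglik
#' @return A tibble with columns `gene_id`, `position` (1..T),
#'   `average_value`, `viterbi_state`.
#' @export
align_pairs <- function(pairs, params, gaps) {
  validate_hmm_params(params)
  mats <- pairs_to_matrices(pairs)
  amap <- alignment_map(ncol(mats$W), gaps)
  if (length(amap$tau_short) != ncol(mats$C)) {
    rlang::abort("number of gaps must equal T1 - T2.", class = "alignhmm_input_error")
  }
  avg <- mats$W
  avg[, amap$tau_short] <- (mats$W[, amap$tau_short] + mats$C) / 2
  states <- t(vapply(
    seq_along(mats$gene_ids),
    function(k) joint_viterbi(mats$W[k, ], mats$C[k, ], params, amap)$states,
    integer(amap$total_positions)
  ))
  tibble::tibble(
    gene_id       = rep(mats$gene_ids, each = amap$total_positions),
    position      = rep(seq_len(amap$total_positions), length(mats$gene_ids)),
    average_value = as.numeric(t(avg)),
    viterbi_state = as.integer(t(states))
  )
}
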