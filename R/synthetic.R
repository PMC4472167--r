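#' Default generating parameters for synthetic alignment data
#'
#' The documented simulation regime used throughout the package's tests and
#' robustness experiments: 5 states with emission means evenly spaced on
#' `[0, 1]` (0, 0.25, 0.5, 0.75, 1), a common emission variance of 0.01, a
#' uniform initial distribution, and a sticky transition matrix with 0.6 on
#' the diagonal and 0.1 elsewhere. This mirrors the grapevine geometry
#' (scaled expression in `[0, 1]`, evenly spaced fitted state means) while
#' keeping states well separated relative to the emission noise.
#'
#' @param n_states Number of states (default 5).
#' @param variance Common emission variance (default 0.01).
#' @param diag_prob Self-transition probability (default 0.6); the remaining
#'   mass is spread uniformly over the other states.
#' @param variance_floor Variance floor carried in the parameter object
#'   (default 0.001).
#' @return An [hmm_params()] object.
#' @export
default_alignment_params <- function(n_states = 5, variance = 0.01,
                                     diag_prob = 0.6, variance_floor = 0.001) {
  off <- if (n_states > 1) (1 - diag_prob) / (n_states - 1) else 0
  A <- matrix(off, n_states, n_states)
  diag(A) <- if (n_states > 1) diag_prob else 1
  mu <- if (n_states > 1) seq(0, 1, length.out = n_states) else 0.5
  hmm_params(
    initial_probs      = rep(1 / n_states, n_states),
    transition_matrix  = A,
    emission_means     = mu,
    emission_variances = rep(variance, n_states),
    variance_floor     = variance_floor
  )
}

# K state sequences of length T from (a, A), vectorised over sequences.
sim_states <- function(K, T_, params) {
  N <- params$n_states
  S <- matrix(0L, K, T_)
  S[, 1] <- sample.int(N, K, replace = TRUE, prob = params$initial_probs)
  cumA <- t(apply(params$transition_matrix, 1, cumsum))
  for (t in seq_len(T_)[-1]) {
    u <- stats::runif(K)
    S[, t] <- rowSums(u > cumA[S[, t - 1], , drop = FALSE]) + 1L
  }
  S
}

# Gaussian emissions for a state matrix (sd may be 0 for noiseless output).
sim_emissions <- function(S, params) {
  mu <- params$emission_means
  sd_ <- sqrt(params$emission_variances)
  matrix(stats::rnorm(length(S), mu[S], sd_[S]), nrow(S))
}

#' Generate one alignable profile pair
#'
#' Draws a single state sequence of length `T` from the Markov chain and
#' emits the long profile at every position and the short profile at the
#' mapped positions, each observation an independent Gaussian draw around
#' the state mean. With zero emission variances the profiles equal the state
#' means exactly (the variance floor applies to fitting, not generation).
#'
#' @param params An [hmm_params()]-like object; `emission_variances` may be
#'   zero for noiseless generation.
#' @param amap An [alignment_map()].
#' @param seed Optional integer seed.
#' @return A list with `w` (length `T`), `c_short` (length `T2`) and
#'   `states` (the generating state sequence, length `T`).
#' @export
generate_pair <- function(params, amap, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  S <- sim_states(1L, amap$total_positions, params)
  w <- sim_emissions(S, params)[1, ]
  Sc <- S[, amap$tau_short, drop = FALSE]
  c_short <- sim_emissions(Sc, params)[1, ]
  list(w = w, c_short = c_short, states = S[1, ])
}

#' Generate one non-alignable (contaminated) profile pair
#'
#' Two contamination mechanisms model genes not driven by the shared
#' developmental program: `"independent_states"` emits the two profiles from
#' two independently drawn state sequences (no common latent structure at
#' all); `"different_gaps"` keeps a shared state sequence but maps the short
#' profile through a different gap set than the rest of the data, modelling
#' a discordant timing shift.
#'
#' @inheritParams generate_pair
#' @param mode `"independent_states"` or `"different_gaps"`.
#' @param alt_gaps For `"different_gaps"`: the discordant gap positions;
#'   must differ from `amap$gap_positions`.
#' @return A list with `w`, `c_short`, `states` (driving the long profile)
#'   and `states_short` (the states driving each short-profile observation).
#' @export
generate_contaminated_pair <- function(params, amap,
                                       mode = c("independent_states", "different_gaps"),
                                       alt_gaps = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  S <- sim_states(1L, amap$total_positions, params)
  w <- sim_emissions(S, params)[1, ]
  if (mode == "independent_states") {
    S2 <- sim_states(1L, amap$total_positions, params)
    Sc <- S2[, amap$tau_short, drop = FALSE]
  } else {
    if (is.null(alt_gaps) || setequal(alt_gaps, amap$gap_positions)) {
      rlang::abort("`alt_gaps` must be supplied and differ from the true gaps.",
                   class = "alignhmm_domain_error")
    }
    alt <- alignment_map(amap$total_positions, alt_gaps)
    Sc <- S[, alt$tau_short, drop = FALSE]
  }
  c_short <- sim_emissions(Sc, params)[1, ]
  list(w = w, c_short = c_short, states = S[1, ], states_short = Sc[1, ])
}

#' Generate a synthetic dataset of profile pairs with contamination
#'
#' Emulates the statistical structure the alignment model assumes: a
#' collection of pairs (`T1 = 19`, `T2 = 17` by default) emitted from a
#' common Gaussian HMM with shared gap positions, of which a requested
#' fraction is replaced by contaminated (non-alignable) pairs. Exactly
#' `floor(n_pairs * contamination)` pairs are contaminated, at seeded random
#' positions; flags, state paths and values are reproducible bit-for-bit
#' under `seed`.
#'
#' @param n_pairs Number of pairs `K`.
#' @param contamination Fraction in `[0, 1)` of non-alignable pairs
#'   (default 0).
#' @param params Generating parameters (default
#'   [default_alignment_params()]).
#' @param gaps True gap positions (default `c(2, 11)`).
#' @param total_positions Common state-sequence length `T` (default 19).
#' @param mode Contamination mechanism, see [generate_contaminated_pair()].
#' @param alt_gaps Discordant gaps for `mode = "different_gaps"`.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param sites Site names for the long and short profiles.
#' @return An object of class `synthetic_pairs`: a list with `pairs` (a
#'   profile-pair tibble ready for [fit_two_step()]), `truth` (tibble:
#'   `gene_id`, `contaminated`, comma-joined `states`), `states` (K x T
#'   matrix driving the long profiles), `states_short` (K x T2 matrix
#'   driving the short observations), `params`, `gaps`, `mode` and `seed`.
#' @export
simulate_alignment_data <- function(n_pairs, contamination = 0,
                                    params = default_alignment_params(),
                                    gaps = c(2, 11), total_positions = 19,
                                    mode = c("independent_states", "different_gaps"),
                                    alt_gaps = NULL, seed = NULL,
                                    sites = c("site1", "site2")) {
  mode <- match.arg(mode)
  if (n_pairs < 1) {
    rlang::abort("`n_pairs` must be at least 1.", class = "alignhmm_domain_error")
  }
  if (contamination < 0 || contamination >= 1) {
    rlang::abort("`contamination` must be in [0, 1).", class = "alignhmm_domain_error")
  }
  if (mode == "different_gaps" && contamination > 0 &&
      (is.null(alt_gaps) || setequal(alt_gaps, gaps))) {
    rlang::abort("`alt_gaps` must be supplied and differ from the true gaps.",
                 class = "alignhmm_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  amap <- alignment_map(total_positions, gaps)
  T_ <- amap$total_positions
  K <- as.integer(n_pairs)
  n_cont <- floor(K * contamination)
  contaminated <- rep(FALSE, K)
  if (n_cont > 0) contaminated[sample.int(K, n_cont)] <- TRUE
  S <- sim_states(K, T_, params)
  # states driving each short-profile observation
  Sc <- S[, amap$tau_short, drop = FALSE]
  if (n_cont > 0) {
    if (mode == "independent_states") {
      S2 <- sim_states(n_cont, T_, params)
      Sc[contaminated, ] <- S2[, amap$tau_short, drop = FALSE]
    } else {
      alt <- alignment_map(T_, alt_gaps)
      Sc[contaminated, ] <- S[contaminated, alt$tau_short, drop = FALSE]
    }
  }
  W <- sim_emissions(S, params)
  C <- sim_emissions(Sc, params)
  gene_ids <- sprintf("gene%0*d", nchar(K), seq_len(K))
  rownames(W) <- rownames(C) <- gene_ids
  pairs <- matrices_to_pairs(W, C, gene_ids, sites)
  structure(
    list(
      pairs = pairs,
      truth = tibble::tibble(
        gene_id      = gene_ids,
        contaminated = contaminated,
        states       = apply(S, 1, paste, collapse = ",")
      ),
      states = S, states_short = Sc,
      params = params, gaps = amap$gap_positions, mode = mode, seed = seed
    ),
    class = "synthetic_pairs"
  )
}

#' @export
print.synthetic_pairs <- function(x, ...) {
  cat("<synthetic_pairs>", nrow(x$states), "pairs, T =", ncol(x$states),
      "/ T2 =", ncol(x$states_short), "\n")
  cat("  true gaps: (", paste(x$gaps, collapse = ", "), "),  ",
      sum(x$truth$contaminated), " contaminated (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Gap-recovery robustness experiment
#'
#' For each contamination fraction and replicate: generate a synthetic
#' dataset, run the full two-step fit (pooled Baum-Welch then gap grid
#' search), and record whether the generating gap positions were recovered
#' and how sharp the likelihood surface's peak is (maximum minus median of
#' the surface). The whole experiment is deterministic given `seed`:
#' replicate r at fraction index i uses seed `seed + 1000 * i + r`.
#'
#' @param fractions Numeric vector of contamination fractions in `[0, 1)`.
#' @param n_pairs Pairs per dataset (default 1000).
#' @param reps Replicates per fraction (default 5).
#' @param params,gaps,total_positions,mode,alt_gaps Passed to
#'   [simulate_alignment_data()].
#' @param n_states States used for fitting (default 5).
#' @param seed Base integer seed (default 1).
#' @param ... Further arguments to [fit_two_step()].
#' @return A tibble with one row per (fraction, rep): `fraction`, `rep`,
#'   `seed`, `g1`, `g2`, `recovered`, `peak_sharpness`.
#' @export
robustness_experiment <- function(fractions, n_pairs = 1000, reps = 5,
                                  params = default_alignment_params(),
                                  gaps = c(2, 11), total_positions = 19,
                                  mode = "independent_states", alt_gaps = NULL,
                                  n_states = 5, seed = 1, ...) {
  if (any(fractions < 0 | fractions >= 1)) {
    rlang::abort("`fractions` must lie in [0, 1).", class = "alignhmm_domain_error")
  }
  if (reps < 1) rlang::abort("`reps` must be at least 1.", class = "alignhmm_domain_error")
  grid <- tidyr::expand_grid(fraction = fractions, rep = seq_len(reps))
  purrr::pmap_dfr(grid, function(fraction, rep) {
    cell_seed <- seed + 1000L * (match(fraction, fractions) - 1L) + rep
    dat <- simulate_alignment_data(
      n_pairs, contamination = fraction, params = params, gaps = gaps,
      total_positions = total_positions, mode = mode, alt_gaps = alt_gaps,
      seed = cell_seed
    )
    fit <- fit_two_step(dat$pairs, n_states = n_states, ...)
    best <- fit$gaps$best_gaps
    tibble::tibble(
      fraction       = fraction,
      rep            = rep,
      seed           = cell_seed,
      g1             = best[1],
      g2             = if (length(best) >= 2) best[2] else NA_integer_,
      recovered      = identical(sort(as.integer(best)), sort(as.integer(gaps))),
      peak_sharpness = fit$gaps$best_loglik - stats::median(fit$gaps$surface$loglik)
    )
  })
}
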