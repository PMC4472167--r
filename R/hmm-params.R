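#' Parameters of a Gaussian-emission hidden Markov model
#'
#' Bundles the parameter set of an N-state HMM with Gaussian emissions:
#' initial state probabilities, a row-stochastic transition matrix, per-state
#' emission means and variances, and the variance floor used during fitting.
#' Expression profiles modelled with these parameters are assumed to be on a
#' common scale (typically each profile linearly rescaled to `[0, 1]`, see
#' [scale_profiles()]), so that one set of states can describe every gene.
#'
#' The variance floor guards against degenerate fits: scaled expression values
#' have point masses at the interval endpoints 0 and 1, and an unconstrained
#' maximum-likelihood fit can collapse a state's variance onto such a point
#' mass. Fitted variances are clamped to the floor after every M-step.
#'
#' @param initial_probs Numeric vector of initial state probabilities; must
#'   sum to 1. Its length defines the number of states `N`.
#' @param transition_matrix `N x N` row-stochastic transition matrix.
#' @param emission_means Numeric vector of per-state emission means, length `N`.
#' @param emission_variances Numeric vector of per-state emission variances,
#'   length `N`; each must be at least `variance_floor`.
#' @param variance_floor Positive lower bound on emission variances
#'   (default `0.001`).
#'
#' @return An object of class `hmm_params`: a list with elements `n_states`,
#'   `initial_probs`, `transition_matrix`, `emission_means`,
#'   `emission_variances` and `variance_floor`.
#'
#' @examples
#' hmm_params(
#'   initial_probs      = c(0.5, 0.5),
#'   transition_matrix  = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
#'   emission_means     = c(0, 1),
#'   emission_variances = c(0.01, 0.01)
#' )
#' @export
hmm_params <- function(initial_probs, transition_matrix, emission_means,
                       emission_variances, variance_floor = 0.001) {
  n <- length(initial_probs)
  transition_matrix <- as.matrix(transition_matrix)
  x <- structure(
    list(
      n_states           = n,
      initial_probs      = as.numeric(initial_probs),
      transition_matrix  = matrix(as.numeric(transition_matrix), n, n),
      emission_means     = as.numeric(emission_means),
      emission_variances = as.numeric(emission_variances),
      variance_floor     = as.numeric(variance_floor)
    ),
    class = "hmm_params"
  )
  validate_hmm_params(x)
}

#' Validate an `hmm_params` object
#'
#' Checks dimensions, non-negativity, that `initial_probs` and every row of
#' the transition matrix sum to 1 (tolerance `1e-10`), and that all emission
#' variances respect the variance floor.
#'
#' @param x An `hmm_params` object.
#' @return `x`, invisibly unchanged, if valid; otherwise an error is thrown.
#' @export
validate_hmm_params <- function(x) {
  if (!inherits(x, "hmm_params")) {
    rlang::abort("`x` must be an `hmm_params` object.", class = "alignhmm_parameter_error")
  }
  n <- x$n_states
  bad <- function(msg) rlang::abort(msg, class = "alignhmm_parameter_error")
  if (!is.numeric(n) || length(n) != 1L || n < 1L) bad("`n_states` must be a positive integer.")
  if (length(x$initial_probs) != n) bad("`initial_probs` must have length `n_states`.")
  if (!all(is.finite(x$initial_probs)) || any(x$initial_probs < 0)) {
    bad("`initial_probs` must be finite and nonnegative.")
  }
  if (abs(sum(x$initial_probs) - 1) > 1e-10) bad("`initial_probs` must sum to 1 (tolerance 1e-10).")
  A <- x$transition_matrix
  if (!is.matrix(A) || any(dim(A) != n)) bad("`transition_matrix` must be `n_states` x `n_states`.")
  if (!all(is.finite(A)) || any(A < 0)) bad("`transition_matrix` entries must be finite and nonnegative.")
  if (any(abs(rowSums(A) - 1) > 1e-10)) bad("every row of `transition_matrix` must sum to 1 (tolerance 1e-10).")
  if (length(x$emission_means) != n || !all(is.finite(x$emission_means))) {
    bad("`emission_means` must be finite and of length `n_states`.")
  }
  if (length(x$emission_variances) != n || !all(is.finite(x$emission_variances))) {
    bad("`emission_variances` must be finite and of length `n_states`.")
  }
  if (!is.finite(x$variance_floor) || x$variance_floor <= 0) {
    bad("`variance_floor` must be a positive number.")
  }
  if (any(x$emission_variances < x$variance_floor - 1e-12)) {
    bad("all `emission_variances` must be >= `variance_floor`.")
  }
  invisible(x)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> Gaussian-emission HMM,", x$n_states, "states\n")
  cat("  means:     ", paste(signif(x$emission_means, 4), collapse = " "), "\n")
  cat("  variances: ", paste(signif(x$emission_variances, 4), collapse = " "),
      " (floor ", x$variance_floor, ")\n", sep = "")
  cat("  initial:   ", paste(signif(x$initial_probs, 4), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn hmm_params Tidy the per-state parameters into a tibble with
#'   columns `state`, `initial_prob`, `mean`, `variance`.
#' @param ... Unused, for generic consistency.
#' @method tidy hmm_params
#' @export
tidy.hmm_params <- function(x, ...) {
  tibble::tibble(
    state        = seq_len(x$n_states),
    initial_prob = x$initial_probs,
    mean         = x$emission_means,
    variance     = x$emission_variances
  )
}

#' Read and write HMM parameters as JSON
#'
#' Serialises an [hmm_params()] object to a JSON document with fields
#' `n_states`, `initial_probs`, `transition_matrix`, `emission_means`,
#' `emission_variances` and `variance_floor`, and reads it back. The
#' round-trip reproduces the object exactly (full double precision).
#'
#' @param params An `hmm_params` object.
#' @param path File path of the JSON document.
#' @return `write_hmm_params()` returns `path` invisibly; `read_hmm_params()`
#'   returns an `hmm_params` object.
#' @export
write_hmm_params <- function(params, path) {
  validate_hmm_params(params)
  doc <- list(
    n_states           = params$n_states,
    initial_probs      = params$initial_probs,
    transition_matrix  = params$transition_matrix,
    emission_means     = params$emission_means,
    emission_variances = params$emission_variances,
    variance_floor     = params$variance_floor
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_hmm_params
#' @export
read_hmm_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_params(
    initial_probs      = doc$initial_probs,
    transition_matrix  = matrix(doc$transition_matrix, doc$n_states, doc$n_states),
    emission_means     = doc$emission_means,
    emission_variances = doc$emission_variances,
    variance_floor     = doc$variance_floor
  )
}

# per-state log N(x | mu_j, var_j) for a vector/matrix of observations:
# returns length(x) x N matrix (x flattened column-major)
.log_emission <- function(x, params) {
  x <- as.numeric(x)
  out <- vapply(
    seq_len(params$n_states),
    function(j) {
      stats::dnorm(x, params$emission_means[j],
                   sqrt(params$emission_variances[j]), log = TRUE)
    },
    numeric(length(x))
  )
  matrix(out, nrow = length(x), ncol = params$n_states)
}
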