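#' Forward log-likelihood of a single profile under a Gaussian HMM
#'
#' Computes `log p(x_1, ..., x_T | lambda)` by the forward recursion in log
#' space (log-sum-exp), marginalising over all latent state sequences.
#'
#' @param values Numeric vector of observations (one scaled expression value
#'   per time point), length at least 2, all finite.
#' @param params An [hmm_params()] object.
#' @return The log-likelihood, a single finite number.
#' @seealso [viterbi_path()] for the decoded state sequence,
#'   [hmm_loglik()] for the data-frame interface.
#' @export
forward_loglik <- function(values, params) {
  validate_hmm_params(params)
  check_profile_values(values)
  lb <- .log_emission(values, params)       # T x N
  la <- log(params$initial_probs)
  lA <- log(params$transition_matrix)
  lalpha <- la + lb[1, ]
  for (t in seq_along(values)[-1]) {
    lalpha <- vapply(
      seq_len(params$n_states),
      function(j) logsumexp(lalpha + lA[, j]),
      numeric(1)
    ) + lb[t, ]
  }
  logsumexp(lalpha)
}

#' Viterbi decoding of a single profile
#'
#' Finds the latent state sequence maximising the joint probability of states
#' and emissions. Ties are broken deterministically toward the smallest state
#' index at every backtracking step.
#'
#' @inheritParams forward_loglik
#' @return A list of class `viterbi_result` with elements `states` (integer
#'   vector of 1-based state indices, one per time point) and `log_prob`
#'   (log joint probability of the decoded path with its emissions; never
#'   exceeds [forward_loglik()] on the same input).
#' @export
viterbi_path <- function(values, params) {
  validate_hmm_params(params)
  check_profile_values(values)
  lb <- .log_emission(values, params)
  viterbi_decode(lb, log(params$initial_probs), log(params$transition_matrix))
}

# Shared Viterbi over arbitrary per-position log emission weights (T x N).
viterbi_decode <- function(lb, la, lA) {
  T_ <- nrow(lb)
  N <- ncol(lb)
  delta <- matrix(NA_real_, T_, N)
  psi <- matrix(NA_integer_, T_, N)
  delta[1, ] <- la + lb[1, ]
  for (t in seq_len(T_)[-1]) {
    for (j in seq_len(N)) {
      cand <- delta[t - 1, ] + lA[, j]
      psi[t, j] <- which.max(cand)       # first maximum = smallest state index
      delta[t, j] <- cand[psi[t, j]] + lb[t, j]
    }
  }
  states <- integer(T_)
  states[T_] <- which.max(delta[T_, ])
  if (T_ > 1) {
    for (t in rev(seq_len(T_ - 1))) states[t] <- psi[t + 1, states[t + 1]]
  }
  structure(
    list(states = states, log_prob = delta[T_, states[T_]]),
    class = "viterbi_result"
  )
}

#' @export
print.viterbi_result <- function(x, ...) {
  cat("<viterbi_result> log_prob =", format(x$log_prob), "\n")
  cat("  states:", paste(x$states, collapse = " "), "\n")
  invisible(x)
}

#' Per-profile log-likelihoods and Viterbi paths for a profile tibble
#'
#' Data-frame-first wrappers over [forward_loglik()] and [viterbi_path()]:
#' each `(gene_id, site)` group of `profiles` is decoded independently under
#' one common parameter set.
#'
#' @param profiles A tibble with columns `gene_id`, `site`, `time`, `value`.
#' @param params An [hmm_params()] object.
#' @return `hmm_loglik()`: a tibble with one row per profile, columns
#'   `gene_id`, `site`, `loglik`. `hmm_viterbi()`: a tibble with one row per
#'   observation, columns `gene_id`, `site`, `time`, `state`, `log_prob`
#'   (path log probability, repeated within a profile).
#' @export
hmm_loglik <- function(profiles, params) {
  validate_hmm_params(params)
  profiles |>
    dplyr::arrange(.data$gene_id, .data$site, .data$time) |>
    dplyr::group_by(.data$gene_id, .data$site) |>
    dplyr::summarise(loglik = forward_loglik(.data$value, params), .groups = "drop")
}

#' @rdname hmm_loglik
#' @export
hmm_viterbi <- function(profiles, params) {
  validate_hmm_params(params)
  profiles |>
    dplyr::arrange(.data$gene_id, .data$site, .data$time) |>
    dplyr::group_by(.data$gene_id, .data$site) |>
    dplyr::group_modify(function(d, ...) {
      v <- viterbi_path(d$value, params)
      tibble::tibble(time = d$time, state = v$states, log_prob = v$log_prob)
    }) |>
    dplyr::ungroup()
}

#' Pooled Baum-Welch estimation over many independent profiles
#'
#' Fits one Gaussian-emission HMM to a collection of expression profiles
#' treated as independent emission sequences sharing a single parameter set
#' (both sites pooled, pairing ignored). This is the first step of the
#' two-step alignment fit: the pooled estimate is robust to profile pairs
#' that are not alignable, because it never uses the pairing.
#'
#' Initialisation is deterministic by default: emission means evenly spaced
#' over the observed data range, variances at the pooled sample variance,
#' uniform initial distribution, and a uniform transition matrix with a
#' diagonal boost of 0.1 (renormalised). With `n_starts > 1`, additional
#' seeded starts jitter the initial means and the best final likelihood wins.
#' Emission variances are clamped to `variance_floor` after every M-step.
#'
#' @param profiles A tibble with columns `gene_id`, `site`, `time`, `value`
#'   (all profiles on a common scale, typically `[0, 1]`).
#' @param n_states Number of latent states `N` (default 5).
#' @param variance_floor Lower bound enforced on fitted emission variances
#'   (default 0.001).
#' @param tol Convergence tolerance: EM stops when the relative change in
#'   total log-likelihood falls below `tol` (default `1e-6`).
#' @param max_iter Maximum EM iterations (default 500). Non-convergence at
#'   `max_iter` raises a warning, not an error.
#' @param n_starts Number of EM starts (default 1, deterministic).
#' @param seed Integer seed for the jittered extra starts; unused when
#'   `n_starts = 1`.
#' @return An object of class `hmm_fit`: a list with `params` (the fitted
#'   [hmm_params()]), `loglik` (final total log-likelihood), `loglik_trace`
#'   (per-iteration log-likelihoods, non-decreasing), `iterations`,
#'   `converged` and `n_profiles`.
#' @seealso [fit_two_step()], [fit_alignment_hmm()]
#' @export
fit_hmm_pooled <- function(profiles, n_states = 5, variance_floor = 0.001,
                           tol = 1e-6, max_iter = 500, n_starts = 1,
                           seed = NULL) {
  seqs <- profiles_to_list(profiles)
  if (length(seqs) == 0L) {
    rlang::abort("`profiles` contains no profiles.", class = "alignhmm_input_error")
  }
  groups <- group_by_length(seqs)
  fit <- em_multi_start(
    groups, n_states = n_states, variance_floor = variance_floor,
    tol = tol, max_iter = max_iter, n_starts = n_starts, seed = seed,
    estep = estep_pooled
  )
  fit$n_profiles <- length(seqs)
  fit
}

# stack equal-length sequences into matrices: list of K_g x T_g matrices
group_by_length <- function(seqs) {
  lens <- vapply(seqs, length, integer(1))
  if (any(lens < 2L)) {
    rlang::abort("every profile must have length >= 2.", class = "alignhmm_input_error")
  }
  lapply(split(seqs, lens), function(s) do.call(rbind, s))
}

# Scaled forward-backward over a K x T observation matrix with per-position
# log emission matrices lb[[t]] (K x N). Per-row max shift before
# exponentiation keeps the scaling constants representable even when some
# states' densities underflow. Returns sufficient statistics and logliks.
forward_backward_mat <- function(lb, a, A) {
  T_ <- length(lb)
  K <- nrow(lb[[1]])
  N <- length(a)
  e <- vector("list", T_)   # shifted emission weights
  m <- vector("list", T_)   # per-row shifts
  for (t in seq_len(T_)) {
    mt <- do.call(pmax, c(as.data.frame(lb[[t]]), list(na.rm = FALSE)))
    e[[t]] <- exp(lb[[t]] - mt)
    m[[t]] <- mt
  }
  alpha <- vector("list", T_)
  cs <- matrix(NA_real_, K, T_)
  a_row <- matrix(a, K, N, byrow = TRUE)
  al <- a_row * e[[1]]
  cs[, 1] <- rowSums(al)
  alpha[[1]] <- al / cs[, 1]
  for (t in seq_len(T_)[-1]) {
    al <- (alpha[[t - 1]] %*% A) * e[[t]]
    cs[, t] <- rowSums(al)
    alpha[[t]] <- al / cs[, t]
  }
  loglik_k <- rowSums(log(cs)) + Reduce(`+`, m)
  # backward + accumulation
  beta <- matrix(1, K, N)
  gamma <- vector("list", T_)
  gamma[[T_]] <- alpha[[T_]] * beta
  xi_sum <- matrix(0, N, N)
  for (t in rev(seq_len(T_ - 1))) {
    w <- e[[t + 1]] * beta / cs[, t + 1]     # K x N
    xi_sum <- xi_sum + A * crossprod(alpha[[t]], w)
    beta <- w %*% t(A)
    gamma[[t]] <- alpha[[t]] * beta
  }
  list(gamma = gamma, xi_sum = xi_sum, loglik = sum(loglik_k),
       loglik_k = loglik_k, gamma1 = gamma[[1]])
}

# E-step over all length groups for the pooled (standard) HMM.
# groups: list of K_g x T_g matrices. Returns loglik + M-step stats.
estep_pooled <- function(groups, params) {
  N <- params$n_states
  a_num <- numeric(N)
  xi_sum <- matrix(0, N, N)
  g_sum <- numeric(N)        # sum of posteriors per state
  gx_sum <- numeric(N)       # sum of posterior * x
  gx2_sum <- numeric(N)      # sum of posterior * x^2
  loglik <- 0
  for (X in groups) {
    T_ <- ncol(X)
    lb <- lapply(seq_len(T_), function(t) .log_emission(X[, t], params))
    fb <- forward_backward_mat(lb, params$initial_probs, params$transition_matrix)
    loglik <- loglik + fb$loglik
    a_num <- a_num + colSums(fb$gamma1)
    xi_sum <- xi_sum + fb$xi_sum
    for (t in seq_len(T_)) {
      g <- fb$gamma[[t]]
      g_sum <- g_sum + colSums(g)
      gx_sum <- gx_sum + colSums(g * X[, t])
      gx2_sum <- gx2_sum + colSums(g * X[, t]^2)
    }
  }
  list(loglik = loglik, a_num = a_num, xi_sum = xi_sum,
       g_sum = g_sum, gx_sum = gx_sum, gx2_sum = gx2_sum)
}

mstep <- function(stats, variance_floor, old) {
  a <- stats$a_num / sum(stats$a_num)
  A <- stats$xi_sum / rowSums(stats$xi_sum)
  mu <- stats$gx_sum / stats$g_sum
  v <- stats$gx2_sum / stats$g_sum - mu^2
  # a state with (numerically) no posterior mass keeps its previous values
  starved <- stats$g_sum < 1e-10
  if (any(starved)) {
    mu[starved] <- old$emission_means[starved]
    v[starved] <- old$emission_variances[starved]
  }
  row0 <- rowSums(stats$xi_sum) < 1e-12
  if (any(row0)) A[row0, ] <- old$transition_matrix[row0, ]
  v <- pmax(v, variance_floor)
  hmm_params(a, A, mu, v, variance_floor)
}

# deterministic default initialisation from pooled data values
init_params <- function(values, n_states, variance_floor, jitter = 0) {
  rng <- range(values)
  if (n_states == 1L) {
    mu <- mean(rng)
  } else {
    mu <- seq(rng[1], rng[2], length.out = n_states)
  }
  if (jitter > 0) mu <- mu + stats::rnorm(n_states, 0, jitter)
  v <- max(stats::var(values), variance_floor)
  a <- rep(1 / n_states, n_states)
  A <- matrix(1 / n_states, n_states, n_states) + diag(0.1, n_states)
  A <- A / rowSums(A)
  hmm_params(a, A, mu, rep(v, n_states), variance_floor)
}

run_em <- function(groups, params0, variance_floor, tol, max_iter, estep, ...) {
  params <- params0
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- estep(groups, params, ...)
    trace <- c(trace, st$loglik)
    if (st$loglik < prev - 1e-8 * max(1, abs(prev))) {
      rlang::abort("EM log-likelihood decreased; this indicates a numerical problem.")
    }
    if (is.finite(prev) &&
        abs(st$loglik - prev) < tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
    prev <- st$loglik
    params <- mstep(st, variance_floor, params)
  }
  if (!converged) {
    rlang::warn(sprintf("EM did not converge in %d iterations.", max_iter))
  }
  structure(
    list(params = params, loglik = trace[length(trace)], loglik_trace = trace,
         iterations = length(trace), converged = converged),
    class = "hmm_fit"
  )
}

em_multi_start <- function(groups, n_states, variance_floor, tol, max_iter,
                           n_starts, seed, estep, ...) {
  values <- unlist(lapply(groups, function(g) {
    if (is.list(g)) c(as.numeric(g$W), as.numeric(g$C)) else as.numeric(g)
  }))
  best <- NULL
  if (n_starts > 1 && !is.null(seed)) set.seed(seed)
  for (s in seq_len(n_starts)) {
    p0 <- init_params(values, n_states, variance_floor,
                      jitter = if (s == 1) 0 else 0.05)
    fit <- run_em(groups, p0, variance_floor, tol, max_iter, estep, ...)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("<hmm_fit> ", x$params$n_states, "-state Gaussian HMM, log-likelihood ",
      format(x$loglik), "\n", sep = "")
  cat("  ", x$iterations, " EM iterations, ",
      if (isTRUE(x$converged)) "converged" else "NOT converged", "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' @describeIn fit_hmm_pooled Per-state fitted parameters as a tibble
#'   (columns `state`, `initial_prob`, `mean`, `variance`).
#' @param x An `hmm_fit` object.
#' @param ... Unused.
#' @method tidy hmm_fit
#' @export
tidy.hmm_fit <- function(x, ...) tidy(x$params)

#' @describeIn fit_hmm_pooled One-row fit summary: `n_states`, `loglik`,
#'   `iterations`, `converged`.
#' @method glance hmm_fit
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble::tibble(
    n_states   = x$params$n_states,
    loglik     = x$loglik,
    iterations = x$iterations,
    converged  = x$converged
  )
}

check_profile_values <- function(values) {
  if (length(values) < 2L || !is.numeric(values)) {
    rlang::abort("a profile needs at least two numeric values.",
                 class = "alignhmm_input_error")
  }
  if (!all(is.finite(values))) {
    rlang::abort("profile values must all be finite.", class = "alignhmm_input_error")
  }
  invisible(values)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
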