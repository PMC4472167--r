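test_that("forward log-likelihood matches closed form for a single state", {
  p <- hmm_params(1, matrix(1, 1, 1), 0, 1, variance_floor = 0.001)
  expect_equal(forward_loglik(c(0, 0), p), -log(2 * pi), tolerance = 1e-12)
})

test_that("forward log-likelihood matches brute-force enumeration", {
  cases <- list(
    list(n = 2, T_ = 3, seed = 1),
    list(n = 2, T_ = 10, seed = 2),
    list(n = 3, T_ = 7, seed = 3),
    list(n = 4, T_ = 5, seed = 4),
    list(n = 7, T_ = 4, seed = 5)
  )
  for (cs in cases) {
    p <- random_params(cs$n, seed = cs$seed)
    x <- runif(cs$T_)   # RNG continues from random_params' seed
    expect_equal(forward_loglik(x, p), oracle_forward_loglik(x, p),
                 tolerance = 1e-10, label = sprintf("N=%d T=%d", cs$n, cs$T_))
  }
})

test_that("forward log-likelihood is invariant to permuting state labels", {
  p <- random_params(3, seed = 42)
  x <- runif(8)
  perm <- c(3, 1, 2)
  q <- hmm_params(
    initial_probs      = p$initial_probs[perm],
    transition_matrix  = p$transition_matrix[perm, perm],
    emission_means     = p$emission_means[perm],
    emission_variances = p$emission_variances[perm]
  )
  expect_equal(forward_loglik(x, p), forward_loglik(x, q), tolerance = 1e-12)
})

test_that("forward rejects invalid input", {
  p <- random_params(2, seed = 9)
  expect_error(forward_loglik(c(0.1, NA), p), class = "alignhmm_input_error")
  expect_error(forward_loglik(0.4, p), class = "alignhmm_input_error")
  expect_error(forward_loglik(c(0.1, 0.2), "not params"),
               class = "alignhmm_parameter_error")
})

test_that("Viterbi matches brute-force argmax and its log_prob bounds hold", {
  for (seed in 1:6) {
    p <- random_params(2 + seed %% 3, seed = 100 + seed)
    x <- runif(4)
    v <- viterbi_path(x, p)
    o <- oracle_viterbi(x, p)
    expect_equal(v$log_prob, o$log_prob, tolerance = 1e-10)
    if (o$unique) expect_equal(v$states, o$states)
    expect_lte(v$log_prob, forward_loglik(x, p) + 1e-12)
    expect_true(all(v$states >= 1 & v$states <= p$n_states))
  }
})

test_that("Viterbi handles degenerate geometry and breaks ties to state 1", {
  p1 <- hmm_params(1, matrix(1, 1, 1), 0.5, 0.01)
  expect_equal(viterbi_path(c(0.2, 0.8, 0.4), p1)$states, c(1, 1, 1))

  # widely separated means, emissions dominate
  p2 <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), c(0, 1), c(1e-3, 1e-3))
  expect_equal(viterbi_path(c(0, 1, 0), p2)$states, c(1, 2, 1))

  # fully symmetric model: every path tied; documented rule picks all-1s
  p3 <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2), c(0.5, 0.5), c(0.02, 0.02))
  expect_equal(viterbi_path(c(0.1, 0.9, 0.5), p3)$states, c(1, 1, 1))
})

test_that("pooled Baum-Welch reduces to the closed form for one state", {
  set.seed(7)
  prof <- dplyr::bind_rows(
    profile_tbl(runif(10), "g1"),
    profile_tbl(runif(8), "g2")
  )
  fit <- suppressWarnings(fit_hmm_pooled(prof, n_states = 1))
  vals <- prof$value
  expect_equal(fit$params$emission_means, mean(vals), tolerance = 1e-8)
  # MLE variance (1/n), not the sample variance
  expect_equal(fit$params$emission_variances,
               max(mean((vals - mean(vals))^2), 0.001), tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone, variances floored, fit deterministic", {
  dat <- simulate_alignment_data(60, seed = 31)
  fit <- fit_hmm_pooled(dat$pairs, n_states = 4, tol = 1e-6, max_iter = 200)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8 * pmax(1, abs(fit$loglik_trace[-1]))))
  expect_true(all(fit$params$emission_variances >= 0.001 - 1e-12))
  fit2 <- fit_hmm_pooled(dat$pairs, n_states = 4, tol = 1e-6, max_iter = 200)
  expect_identical(fit$params, fit2$params)
  expect_identical(glance(fit), glance(fit2))
})

test_that("pooled EM recovers well-separated generating parameters", {
  gen <- hmm_params(
    initial_probs      = c(1, 1, 1) / 3,
    transition_matrix  = matrix(c(0.8, 0.1, 0.1,
                                  0.1, 0.8, 0.1,
                                  0.1, 0.1, 0.8), 3, byrow = TRUE),
    emission_means     = c(0, 0.5, 1),
    emission_variances = c(0.01, 0.01, 0.01)
  )
  set.seed(55)
  S <- alignhmm:::sim_states(500, 19, gen)
  X <- alignhmm:::sim_emissions(S, gen)
  prof <- tibble::tibble(
    gene_id = rep(sprintf("g%03d", 1:500), each = 19),
    site    = "s",
    time    = rep(1:19, 500),
    value   = as.numeric(t(X))
  )
  fit <- fit_hmm_pooled(prof, n_states = 3)
  ord <- order(fit$params$emission_means)
  expect_equal(fit$params$emission_means[ord], gen$emission_means,
               tolerance = 0.05)
  expect_equal(unname(fit$params$transition_matrix[ord, ord]),
               unname(gen$transition_matrix), tolerance = 0.1)
})

test_that("data-frame wrappers agree with the vector-level functions", {
  p <- random_params(3, seed = 77)
  prof <- dplyr::bind_rows(profile_tbl(runif(6), "a"), profile_tbl(runif(6), "b"))
  ll <- hmm_loglik(prof, p)
  expect_equal(nrow(ll), 2)
  expect_equal(ll$loglik[ll$gene_id == "a"],
               forward_loglik(prof$value[prof$gene_id == "a"], p))
  vt <- hmm_viterbi(prof, p)
  expect_equal(vt$state[vt$gene_id == "b"],
               viterbi_path(prof$value[prof$gene_id == "b"], p)$states)
})
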