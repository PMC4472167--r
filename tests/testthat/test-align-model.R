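test_that("pair log-likelihood matches the single-state closed form", {
  # every observation at the state mean: four identical density factors
  p <- hmm_params(1, matrix(1, 1, 1), 0.5, 0.25)
  m <- alignment_map(3, gaps = c(2, 3))
  ll <- pair_loglik(c(0.5, 0.5, 0.5), 0.5, p, m)
  expect_equal(ll, 4 * dnorm(0.5, 0.5, 0.5, log = TRUE), tolerance = 1e-12)
  expect_equal(ll, -0.9031654, tolerance = 1e-6)
})

test_that("pair log-likelihood and joint Viterbi match brute-force enumeration", {
  for (seed in 1:6) {
    p <- random_params(2 + seed %% 2, seed = 200 + seed)
    T_ <- 4
    m <- alignment_map(T_, gaps = sample(2:T_, 2))
    w <- runif(T_)
    cs <- runif(length(m$tau_short))
    expect_equal(pair_loglik(w, cs, p, m), oracle_pair_loglik(w, cs, p, m),
                 tolerance = 1e-10)
    jv <- joint_viterbi(w, cs, p, m)
    ov <- oracle_joint_viterbi(w, cs, p, m)
    expect_equal(jv$log_prob, ov$log_prob, tolerance = 1e-10)
    if (ov$unique) expect_equal(jv$states, ov$states)
    expect_lte(jv$log_prob, pair_loglik(w, cs, p, m) + 1e-12)
  }
})

test_that("pair functions validate lengths against the map", {
  p <- random_params(2, seed = 5)
  m <- alignment_map(5, gaps = c(3, 5))
  expect_error(pair_loglik(runif(4), runif(3), p, m), class = "alignhmm_input_error")
  expect_error(joint_viterbi(runif(5), runif(2), p, m), class = "alignhmm_input_error")
  expect_error(average_profile(runif(5), runif(4), m), class = "alignhmm_input_error")
})

test_that("total log-likelihood is additive over pairs", {
  p <- random_params(3, seed = 301)
  set.seed(301)
  K <- 10
  T_ <- 6
  m <- alignment_map(T_, gaps = c(3, 5))
  W <- matrix(runif(K * T_), K)
  C <- matrix(runif(K * 4), K)
  ids <- sprintf("g%02d", 1:K)
  pairs <- alignhmm:::matrices_to_pairs(W, C, ids)
  total <- total_loglik(pairs, p, gaps = c(3, 5))
  singles <- vapply(1:K, function(k) pair_loglik(W[k, ], C[k, ], p, m), numeric(1))
  expect_equal(total, sum(singles), tolerance = 1e-9)

  # duplicating every pair doubles the total
  pairs2 <- alignhmm:::matrices_to_pairs(rbind(W, W), rbind(C, C),
                                         c(ids, sprintf("h%02d", 1:K)))
  expect_equal(total_loglik(pairs2, p, gaps = c(3, 5)), 2 * total, tolerance = 1e-9)
})

test_that("grid search recovers the generating gaps from noiseless pairs", {
  gen <- hmm_params(
    initial_probs      = rep(0.2, 5),
    transition_matrix  = matrix(0.1, 5, 5) + diag(0.5, 5),
    emission_means     = c(0, 0.25, 0.5, 0.75, 1),
    emission_variances = rep(1e-12, 5),  # effectively noiseless generation
    variance_floor     = 1e-12
  )
  dat <- simulate_alignment_data(200, params = gen, gaps = c(5, 12), seed = 99)
  fitp <- default_alignment_params(variance = 0.005)
  gs <- search_gaps(dat$pairs, fitp)
  expect_equal(sort(gs$best_gaps), c(5, 12))
  expect_equal(nrow(gs$surface), choose(18, 2))
  expect_equal(length(gs$ties), 1)
  # the true gaps score strictly higher than every other candidate
  others <- gs$surface$loglik[!(gs$surface$g1 == 5 & gs$surface$g2 == 12)]
  expect_true(all(others < gs$best_loglik))
})

test_that("the surface is invariant to pair ordering and matches total_loglik", {
  p <- default_alignment_params()
  dat <- simulate_alignment_data(40, seed = 13)
  gs <- search_gaps(dat$pairs, p)
  shuf <- dat$pairs[order(dat$pairs$gene_id, decreasing = TRUE), ]
  gs2 <- search_gaps(as_profile_pairs(shuf), p)
  expect_equal(gs$surface$loglik, gs2$surface$loglik, tolerance = 1e-9)
  i <- which(gs$surface$g1 == 4 & gs$surface$g2 == 9)
  expect_equal(gs$surface$loglik[i], total_loglik(dat$pairs, p, c(4, 9)),
               tolerance = 1e-9)
})

test_that("average profile combines mapped observations and keeps gaps single", {
  m <- alignment_map(3, gaps = c(2, 3))
  expect_equal(average_profile(c(0.2, 0.4, 0.6), 0.8, m), c(0.5, 0.4, 0.6))

  m2 <- alignment_map(5, gaps = c(2, 4))
  w <- rep(0, 5)
  cs <- rep(1, 3)
  expect_equal(average_profile(w, cs, m2), c(0.5, 0, 0.5, 0, 0.5))

  # identical aligned profiles: average equals the long profile
  w3 <- runif(5)
  expect_equal(average_profile(w3, w3[m2$tau_short], m2), w3)
})

test_that("align_pairs returns per-gene representations on common positions", {
  p <- default_alignment_params()
  dat <- simulate_alignment_data(5, seed = 21)
  rep_ <- align_pairs(dat$pairs, p, dat$gaps)
  expect_named(rep_, c("gene_id", "position", "average_value", "viterbi_state"))
  expect_equal(nrow(rep_), 5 * 19)
  mats <- alignhmm:::pairs_to_matrices(dat$pairs)
  m <- alignment_map(19, dat$gaps)
  g3 <- rep_[rep_$gene_id == mats$gene_ids[3], ]
  expect_equal(g3$average_value, average_profile(mats$W[3, ], mats$C[3, ], m))
  expect_equal(g3$viterbi_state, joint_viterbi(mats$W[3, ], mats$C[3, ], p, m)$states)
})

test_that("alignment-HMM EM obeys its contracts at one state and in general", {
  dat <- simulate_alignment_data(40, seed = 17)
  vals <- dat$pairs$value
  f1 <- suppressWarnings(fit_alignment_hmm(dat$pairs, gaps = c(2, 11), n_states = 1))
  expect_equal(f1$params$emission_means, mean(vals), tolerance = 1e-8)
  expect_equal(f1$params$emission_variances,
               max(mean((vals - mean(vals))^2), 0.001), tolerance = 1e-8)

  f5 <- fit_alignment_hmm(dat$pairs, gaps = c(2, 11), n_states = 5)
  expect_true(all(diff(f5$loglik_trace) >= -1e-8 * pmax(1, abs(f5$loglik_trace[-1]))))
  expect_true(all(f5$params$emission_variances >= 0.001 - 1e-12))
})

test_that("full-MLE alignment fit recovers generating means on clean data", {
  dat <- simulate_alignment_data(500, seed = 71)
  fit <- fit_alignment_hmm(dat$pairs, gaps = c(2, 11), n_states = 5)
  mu <- sort(fit$params$emission_means)
  expect_equal(mu, c(0, 0.25, 0.5, 0.75, 1), tolerance = 0.05)
})

test_that("full MLE dominates the two-step estimate at the same gaps", {
  dat <- simulate_alignment_data(120, contamination = 0.3, seed = 41)
  ts <- fit_two_step(dat$pairs, n_states = 5)
  gaps <- ts$gaps$best_gaps
  full <- fit_alignment_hmm(dat$pairs, gaps = gaps, n_states = 5)
  expect_gte(full$loglik, total_loglik(dat$pairs, ts$hmm$params, gaps) - 1e-6)
})

test_that("contamination inflates the alignment-fit variances", {
  dat <- simulate_alignment_data(300, contamination = 0.5, seed = 61)
  pooled <- fit_hmm_pooled(dat$pairs, n_states = 5)
  full <- fit_alignment_hmm(dat$pairs, gaps = c(2, 11), n_states = 5)
  expect_gt(mean(full$params$emission_variances),
            mean(pooled$params$emission_variances))
  expect_gt(max(full$params$emission_variances),
            1.5 * max(pooled$params$emission_variances))
})

test_that("the two-step fit is deterministic and recovers true gaps cleanly", {
  dat <- simulate_alignment_data(300, seed = 83)
  f1 <- fit_two_step(dat$pairs, n_states = 5)
  f2 <- fit_two_step(dat$pairs, n_states = 5)
  expect_identical(f1$hmm$params, f2$hmm$params)
  expect_identical(f1$gaps$best_gaps, f2$gaps$best_gaps)
  expect_equal(sort(f1$gaps$best_gaps), c(2, 11))
  g <- glance(f1)
  expect_equal(c(g$g1, g$g2), c(2, 11))
})
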