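vres <- function(states) structure(list(states = states, log_prob = 0),
                                   class = "viterbi_result")

test_that("Hamming distance counts disagreements at mapped positions", {
  m <- alignment_map(3, gaps = 2)
  expect_equal(
    hamming_distance(vres(c(1, 2, 2)), vres(c(1, 1, 2)), vres(c(1, 2)), m),
    1
  )

  # agreement everywhere -> 0; disagreement everywhere -> T1 + T2
  m19 <- alignment_map(19, gaps = c(2, 11))
  s <- rep(1L, 19)
  expect_equal(hamming_distance(vres(s), vres(s), vres(s[m19$tau_short]), m19), 0)
  expect_equal(
    hamming_distance(vres(s), vres(s + 1L), vres(s[m19$tau_short] + 1L), m19),
    36
  )
  expect_error(
    hamming_distance(vres(s), vres(s[1:5]), vres(s[m19$tau_short]), m19),
    class = "alignhmm_input_error"
  )
})

test_that("Hamming distance is invariant under consistent state relabelling", {
  set.seed(12)
  m <- alignment_map(8, gaps = c(3, 6))
  for (i in 1:5) {
    j <- sample(1:4, 8, replace = TRUE)
    l <- sample(1:4, 8, replace = TRUE)
    s <- sample(1:4, 6, replace = TRUE)
    perm <- sample(1:4)
    h1 <- hamming_distance(vres(j), vres(l), vres(s), m)
    h2 <- hamming_distance(vres(perm[j]), vres(perm[l]), vres(perm[s]), m)
    expect_equal(h1, h2)
  }
})

test_that("classification is inclusive at the threshold", {
  expect_equal(classify_hamming(c(0, 10, 11), threshold = 10),
               c("developmental", "developmental", "non-developmental"))
  expect_equal(classify_hamming(0, threshold = 0), "developmental")
  expect_error(classify_hamming(-1), class = "alignhmm_domain_error")
})

test_that("pair diagnostics assemble likelihood, paths and distance", {
  p <- default_alignment_params()
  dat <- simulate_alignment_data(20, contamination = 0.5, seed = 9)
  d <- diagnose_pairs(dat$pairs, p, gaps = c(2, 11))
  expect_equal(nrow(d), 20)
  mats <- alignhmm:::pairs_to_matrices(dat$pairs)
  m <- alignment_map(19, c(2, 11))
  k <- 7
  expect_equal(d$loglik[k], pair_loglik(mats$W[k, ], mats$C[k, ], p, m),
               tolerance = 1e-9)
  jv <- joint_viterbi(mats$W[k, ], mats$C[k, ], p, m)
  expect_equal(d$joint_path[k], paste(jv$states, collapse = ","))
  expect_equal(
    d$hamming[k],
    hamming_distance(jv, viterbi_path(mats$W[k, ], p),
                     viterbi_path(mats$C[k, ], p), m)
  )
  expect_equal(d$label, classify_hamming(d$hamming, 10))
})

test_that("noiseless aligned pairs have zero Hamming distance", {
  gen <- hmm_params(rep(0.2, 5), matrix(0.1, 5, 5) + diag(0.5, 5),
                    c(0, 0.25, 0.5, 0.75, 1), rep(1e-12, 5),
                    variance_floor = 1e-12)
  dat <- simulate_alignment_data(30, params = gen, gaps = c(2, 11), seed = 15)
  # decode with tight emissions so the data, not the sticky transition prior,
  # determines every position
  dec <- default_alignment_params(variance = 0.001)
  d <- diagnose_pairs(dat$pairs, dec, gaps = c(2, 11))
  expect_true(all(d$hamming == 0))
})

test_that("a single state forces zero Hamming distance on any pair", {
  p1 <- hmm_params(1, matrix(1, 1, 1), 0.5, 0.04)
  dat <- simulate_alignment_data(10, contamination = 0.5, seed = 33)
  d <- diagnose_pairs(dat$pairs, p1, gaps = c(2, 11))
  expect_true(all(d$hamming == 0))
})

test_that("independent random pairs score large Hamming distances", {
  dat <- simulate_alignment_data(50, contamination = 0.9, seed = 27)
  p <- default_alignment_params()
  d <- diagnose_pairs(dat$pairs, p, gaps = c(2, 11)) |>
    dplyr::left_join(dat$truth, by = "gene_id")
  expect_gt(mean(d$hamming[d$contaminated]), 5)
})

test_that("ROC handles perfect, uninformative and tied separations", {
  r1 <- roc_hamming(c(2, 4, 12, 20), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1.0)

  r2 <- roc_hamming(rep(7, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r2$auc, 0.5)

  r3 <- roc_hamming(c(1, 5, 3, 7), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r3$auc, 0.75)

  expect_error(roc_hamming(1:4, rep(TRUE, 4)), class = "alignhmm_input_error")
})

test_that("trapezoidal AUC equals the pairwise probability estimator", {
  set.seed(8)
  for (i in 1:10) {
    h <- sample(0:15, 40, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (all(lab) || !any(lab)) next
    r <- roc_hamming(h, lab)
    expect_equal(r$auc, oracle_auc(h, lab), tolerance = 1e-12)
    expect_true(all(diff(r$curve$tpr) >= 0) && all(diff(r$curve$fpr) >= 0))
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  h <- sample(0:20, 60, replace = TRUE)
  lab <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.4, 0.6))
  r <- roc_hamming(h, lab)
  ref <- pROC::auc(pROC::roc(response = lab, predictor = -h,
                             direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("Hamming classifier separates alignable from contaminated pairs", {
  dat <- simulate_alignment_data(1000, contamination = 0.5, seed = 2024)
  fit <- fit_two_step(dat$pairs, n_states = 5)
  d <- diagnose_pairs(dat$pairs, fit$hmm$params, gaps = fit$gaps$best_gaps) |>
    dplyr::left_join(dat$truth, by = "gene_id")
  r <- roc_hamming(d$hamming, !d$contaminated)
  expect_gt(r$auc, 0.8)
})
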