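# Brute-force oracles: direct enumeration over all state sequences, kept
# independent of the package's recursions. Only usable for N^T small.

enum_state_seqs <- function(n_states, T_) {
  as.matrix(expand.grid(rep(list(seq_len(n_states)), T_)))
}

# log p(sequence of states) under (a, A)
oracle_path_logprob <- function(s, params) {
  lp <- log(params$initial_probs[s[1]])
  if (length(s) > 1) {
    for (t in 2:length(s)) {
      lp <- lp + log(params$transition_matrix[s[t - 1], s[t]])
    }
  }
  lp
}

# forward log-likelihood by summation over all N^T sequences
oracle_forward_loglik <- function(x, params) {
  seqs <- enum_state_seqs(params$n_states, length(x))
  terms <- apply(seqs, 1, function(s) {
    oracle_path_logprob(s, params) +
      sum(dnorm(x, params$emission_means[s], sqrt(params$emission_variances[s]),
                log = TRUE))
  })
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

# pair (alignment) log-likelihood: every sequence weighted by the long
# profile's emissions at all T positions and the short profile's at mapped
# positions
oracle_pair_terms <- function(w, c_short, params, amap) {
  seqs <- enum_state_seqs(params$n_states, amap$total_positions)
  apply(seqs, 1, function(s) {
    lp <- oracle_path_logprob(s, params) +
      sum(dnorm(w, params$emission_means[s], sqrt(params$emission_variances[s]),
                log = TRUE))
    sm <- s[amap$tau_short]
    lp + sum(dnorm(c_short, params$emission_means[sm],
                   sqrt(params$emission_variances[sm]), log = TRUE))
  })
}

oracle_pair_loglik <- function(w, c_short, params, amap) {
  terms <- oracle_pair_terms(w, c_short, params, amap)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

# Viterbi by enumeration; returns max log joint prob and whether the argmax
# is unique (path comparison is only meaningful when it is)
oracle_viterbi <- function(x, params) {
  seqs <- enum_state_seqs(params$n_states, length(x))
  terms <- apply(seqs, 1, function(s) {
    oracle_path_logprob(s, params) +
      sum(dnorm(x, params$emission_means[s], sqrt(params$emission_variances[s]),
                log = TRUE))
  })
  i <- which.max(terms)
  list(states = unname(seqs[i, ]), log_prob = terms[i],
       unique = sum(terms > terms[i] - 1e-9) == 1)
}

oracle_joint_viterbi <- function(w, c_short, params, amap) {
  seqs <- enum_state_seqs(params$n_states, amap$total_positions)
  terms <- oracle_pair_terms(w, c_short, params, amap)
  i <- which.max(terms)
  list(states = unname(seqs[i, ]), log_prob = terms[i],
       unique = sum(terms > terms[i] - 1e-9) == 1)
}

# tie-aware pairwise AUC estimator: P(H_pos < H_neg) + 0.5 P(tie)
oracle_auc <- function(hamming, labels) {
  hp <- hamming[as.logical(labels)]
  hn <- hamming[!as.logical(labels)]
  cmp <- outer(hp, hn, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

# a reproducible arbitrary-but-valid parameter set
random_params <- function(n_states, seed, variance_floor = 0.001) {
  set.seed(seed)
  a <- runif(n_states) + 0.2
  A <- matrix(runif(n_states^2) + 0.2, n_states)
  hmm_params(
    initial_probs      = a / sum(a),
    transition_matrix  = A / rowSums(A),
    emission_means     = sort(runif(n_states)),
    emission_variances = runif(n_states, 0.02, 0.2),
    variance_floor     = variance_floor
  )
}

# wrap plain vectors as a one-gene profile tibble
profile_tbl <- function(values, gene_id = "g1", site = "site1") {
  tibble::tibble(gene_id = gene_id, site = site,
                 time = seq_along(values), value = values)
}

pair_tbl <- function(w, c_short, gene_id = "g1", sites = c("site1", "site2")) {
  dplyr::bind_rows(
    profile_tbl(w, gene_id, sites[1]),
    profile_tbl(c_short, gene_id, sites[2])
  )
}
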