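#' Hamming distance between joint and individual Viterbi paths
#'
#' The alignment-quality diagnostic: the number of state positions at which
#' the pair's joint Viterbi path disagrees with the long profile's individual
#' Viterbi path, plus the number of mapped positions at which it disagrees
#' with the short profile's path. A well aligned pair decodes to (almost) the
#' same states jointly and individually, giving a small distance; the maximum
#' is `T1 + T2` (36 for the grapevine geometry).
#'
#' @param joint A `viterbi_result` of length `T` from [joint_viterbi()].
#' @param ind_long,ind_short `viterbi_result`s of lengths `T1`, `T2` from
#'   [viterbi_path()] on the two individual profiles.
#' @param amap The [alignment_map()] used for the joint decoding.
#' @return A nonnegative integer.
#' @export
hamming_distance <- function(joint, ind_long, ind_short, amap) {
  sj <- joint$states
  sl <- ind_long$states
  ss <- ind_short$states
  if (length(sj) != amap$total_positions ||
      length(sl) != length(amap$tau_long) ||
      length(ss) != length(amap$tau_short)) {
    rlang::abort("path lengths do not match the alignment map.",
                 class = "alignhmm_input_error")
  }
  sum(sj[amap$tau_long] != sl) + sum(sj[amap$tau_short] != ss)
}

#' Classify a pair as developmental from its Hamming distance
#'
#' Pairs whose profiles align well across sites are taken as evidence that
#' the gene is under developmental control; poorly aligning pairs point to
#' site-specific (e.g. environmental) drivers. The rule is inclusive:
#' `hamming <= threshold` is classified `"developmental"`.
#'
#' @param hamming Nonnegative integer vector of Hamming distances.
#' @param threshold Classification threshold (default 10).
#' @return Character vector: `"developmental"` or `"non-developmental"`.
#' @export
classify_hamming <- function(hamming, threshold = 10) {
  if (any(hamming < 0)) {
    rlang::abort("Hamming distances must be nonnegative.", class = "alignhmm_domain_error")
  }
  ifelse(hamming <= threshold, "developmental", "non-developmental")
}

#' Per-pair alignment diagnostics
#'
#' For every pair: the alignment log-likelihood, the joint Viterbi path, the
#' two individual Viterbi paths under the same parameters, the Hamming
#' distance between them, and the threshold classification.
#'
#' @inheritParams total_loglik
#' @param threshold Hamming-distance classification threshold (default 10).
#' @return A tibble with one row per gene: `gene_id`, `loglik`, `hamming`,
#'   `label`, and comma-joined state paths `joint_path`, `path_long`,
#'   `path_short`.
#' @export
diagnose_pairs <- function(pairs, params, gaps, threshold = 10) {
  validate_hmm_params(params)
  mats <- pairs_to_matrices(pairs)
  amap <- alignment_map(ncol(mats$W), gaps)
  if (length(amap$tau_short) != ncol(mats$C)) {
    rlang::abort("number of gaps must equal T1 - T2.", class = "alignhmm_input_error")
  }
  ld <- pair_log_densities(mats, params)
  ll <- pair_forward_ll_vec(ld, amap, params)
  res <- purrr::map(seq_along(mats$gene_ids), function(k) {
    w <- mats$W[k, ]
    cs <- mats$C[k, ]
    jv <- joint_viterbi(w, cs, params, amap)
    vl <- viterbi_path(w, params)
    vs <- viterbi_path(cs, params)
    list(
      hamming    = hamming_distance(jv, vl, vs, amap),
      joint_path = paste(jv$states, collapse = ","),
      path_long  = paste(vl$states, collapse = ","),
      path_short = paste(vs$states, collapse = ",")
    )
  })
  tibble::tibble(
    gene_id    = mats$gene_ids,
    loglik     = ll,
    hamming    = purrr::map_int(res, "hamming"),
    label      = classify_hamming(purrr::map_int(res, "hamming"), threshold),
    joint_path = purrr::map_chr(res, "joint_path"),
    path_long  = purrr::map_chr(res, "path_long"),
    path_short = purrr::map_chr(res, "path_short")
  )
}

#' ROC curve and AUC for the Hamming-distance classifier
#'
#' Evaluates how well a *low* Hamming distance separates the positive
#' ("developmental" / alignable) class from the negative class. Thresholds
#' sweep the distinct observed distances with the inclusive rule
#' `hamming <= threshold` predicting positive; the AUC is computed by the
#' trapezoidal rule, which with this sweep equals the tie-aware pairwise
#' probability `P(H_pos < H_neg) + P(H_pos = H_neg) / 2`.
#'
#' @param hamming Integer vector of Hamming distances.
#' @param labels Logical vector (or coercible): `TRUE` for the positive
#'   (developmental) class. Both classes must be present.
#' @return An object of class `hmm_roc`: a list with `curve` (tibble with
#'   columns `threshold`, `tpr`, `fpr`, including the all-negative row at
#'   threshold `-Inf`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_hamming <- function(hamming, labels) {
  labels <- as.logical(labels)
  if (length(labels) != length(hamming) || anyNA(labels) || anyNA(hamming)) {
    rlang::abort("`hamming` and `labels` must match in length and contain no missing values.",
                 class = "alignhmm_input_error")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("both classes must be present to compute a ROC curve.",
                 class = "alignhmm_input_error")
  }
  thr <- sort(unique(hamming))
  tpr <- vapply(thr, function(t) sum(labels & hamming <= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & hamming <= t) / n_neg, numeric(1))
  curve <- tibble::tibble(
    threshold = c(-Inf, thr),
    tpr       = c(0, tpr),
    fpr       = c(0, fpr)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
  structure(
    list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "hmm_roc"
  )
}

#' @export
print.hmm_roc <- function(x, ...) {
  cat("<hmm_roc> AUC =", format(x$auc), " (", x$n_pos, "positive /",
      x$n_neg, "negative )\n")
  invisible(x)
}

#' @describeIn roc_hamming The ROC curve points as a tibble.
#' @param x An `hmm_roc` object.
#' @param ... Unused.
#' @method tidy hmm_roc
#' @export
tidy.hmm_roc <- function(x, ...) x$curve

#' @describeIn roc_hamming One-row summary with `auc`, `n_pos`, `n_neg`.
#' @method glance hmm_roc
#' @export
glance.hmm_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
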