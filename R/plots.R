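#' Heat-map of the gap-search likelihood surface
#'
#' The total alignment log-likelihood over all admissible `(g1, g2)` gap
#' pairs, with the argmax marked. A single sharp peak indicates that the gap
#' positions are well determined by the data; contamination by non-alignable
#' pairs flattens and spreads the peak.
#'
#' @param object A `gap_search` object from [search_gaps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gap_search
#' @export
autoplot.gap_search <- function(object, ...) {
  if (!all(c("g1", "g2") %in% names(object$surface))) {
    rlang::abort("surface heat-map is only available for the two-gap case.",
                 class = "alignhmm_domain_error")
  }
  ggplot2::ggplot(object$surface, ggplot2::aes(x = .data$g1, y = .data$g2,
                                               fill = .data$loglik)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = tibble::tibble(g1 = object$best_gaps[1], g2 = object$best_gaps[2]),
      ggplot2::aes(x = .data$g1, y = .data$g2), fill = NA,
      shape = 4, size = 3, colour = "white"
    ) +
    ggplot2::scale_fill_viridis_c(name = "log-likelihood") +
    ggplot2::labs(
      x = expression(g[1]), y = expression(g[2]),
      title = "Alignment log-likelihood over gap positions"
    )
}

#' ROC curve of the Hamming-distance classifier
#'
#' @param object An `hmm_roc` object from [roc_hamming()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hmm_roc
#' @export
autoplot.hmm_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Hamming-distance classifier (AUC = %.3f)", object$auc)
    )
}

#' Plot aligned profile pairs on the common state positions
#'
#' Shows, for selected genes, both site profiles placed at their mapped
#' state positions together with the average-profile representation; gap
#' positions are where the short site has no point.
#'
#' @param pairs A profile-pair tibble.
#' @param params An [hmm_params()] object (used for the Viterbi overlay;
#'   optional).
#' @param gaps Gap positions.
#' @param genes Character vector of gene ids to plot (default: first 4).
#' @return A ggplot object, faceted by gene.
#' @export
plot_alignment <- function(pairs, params = NULL, gaps, genes = NULL) {
  mats <- pairs_to_matrices(pairs)
  amap <- alignment_map(ncol(mats$W), gaps)
  if (is.null(genes)) genes <- utils::head(mats$gene_ids, 4)
  sites <- mats$sites
  sel <- pairs$gene_id %in% genes
  d <- pairs[sel, ]
  d$position <- ifelse(d$site == sites[1], d$time, amap$tau_short[d$time])
  avg <- align_pairs(pairs[sel, ],
                     params %||% default_alignment_params(), gaps) |>
    dplyr::mutate(site = "average")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$value,
                                  colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = avg,
                       ggplot2::aes(x = .data$position, y = .data$average_value),
                       colour = "grey30", linetype = "dotted") +
    ggplot2::facet_wrap(~gene_id) +
    ggplot2::labs(x = "Common state position", y = "Scaled expression",
                  colour = "Site")
}
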