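# ggplot2 displays for the main result types

#' 3/75-rule scatter of physicochemical profiles
#'
#' logP against TPSA with the rule boundaries (logP = 3, TPSA = 75) and the
#' quadrant classification coloured.
#'
#' @param profiles tibble from [physchem_table()]; classified on the fly if
#'   `rule_3_75` is absent.
#' @return A ggplot object.
#' @export
plot_rule_3_75 <- function(profiles) {
  if (!"rule_3_75" %in% names(profiles)) {
    profiles <- classify_rule_3_75(profiles)
  }
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$logp, y = .data$tpsa,
                               colour = .data$rule_3_75)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 3, linetype = 2) +
    ggplot2::geom_hline(yintercept = 75, linetype = 2) +
    ggplot2::labs(x = "logP", y = expression(TPSA ~ (ring(A)^2)),
                  colour = "3/75 rule") +
    ggplot2::theme_minimal()
}

#' Method-score heatmap for consensus predictions
#'
#' Per-method scores and the pseudo-score, one tile per (drug, target).
#'
#' @param predictions tibble from [consensus_predictions()].
#' @param max_rows cap on displayed (drug, target) rows (default 40, by
#'   pseudo-score).
#' @return A ggplot object.
#' @export
plot_method_scores <- function(predictions, max_rows = 40) {
  df <- predictions %>%
    arrange(desc(.data$pseudo_score)) %>%
    utils::head(max_rows) %>%
    mutate(pair = paste(.data$drug_id, .data$target_id, sep = " / ")) %>%
    tidyr::pivot_longer(dplyr::all_of(c(METHOD_NAMES, "pseudo_score")),
                        names_to = "method", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                   y = stats::reorder(.data$pair, .data$score,
                                                      FUN = max),
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal()
}

#' Autoplot a SEA background fit
#'
#' Raw-score draws against the set-size product with the fitted mean curve.
#'
#' @param object a `sea_background`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sea_background <- function(object, ...) {
  grid <- tibble(n = seq(min(object$draws$n), max(object$draws$n),
                         length.out = 100))
  grid$mu <- sea_mu(object, grid$n)
  ggplot2::ggplot(object$draws, ggplot2::aes(x = .data$n, y = .data$rs)) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$mu),
                       colour = "firebrick") +
    ggplot2::labs(x = "set-size product n", y = "raw score RS",
                  title = sprintf("SEA background (tau = %.2f)", object$tau)) +
    ggplot2::theme_minimal()
}

#' Autoplot an expression atlas
#'
#' Row-z-scored tile heatmap in clustered row order.
#'
#' @param object an `expression_atlas`.
#' @param genes optional subset of genes.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.expression_atlas <- function(object, genes = NULL, ...) {
  m <- object$mat
  if (!is.null(genes)) m <- m[intersect(genes, rownames(m)), , drop = FALSE]
  ord <- if (nrow(m) >= 2) cluster_rows(m)$order else rownames(m)
  sds <- apply(m, 1, sd)
  z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  df <- as_tibble(z, rownames = "gene") %>%
    tidyr::pivot_longer(-"gene", names_to = "tissue", values_to = "z") %>%
    mutate(gene = factor(.data$gene, levels = rev(ord)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$gene,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row z",
                  title = sprintf("%s atlas", object$species)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
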