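#' Plot a flux comparison as a signed log2 fold profile
#'
#' Bars of per-reaction log2 mesenchymal/epithelial fold changes; negative
#' values (higher flux in the epithelial model) point left. Exchange
#' reactions can be dropped to focus on internal signaling steps.
#'
#' @param object a `flux_comparison` from [compare_fluxes()].
#' @param include_exchanges keep exchange reactions (default FALSE)?
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.flux_comparison <- function(object, include_exchanges = FALSE, ...) {
  df <- tibble::as_tibble(object)
  if (!include_exchanges) df <- df[df$kind != "exchange", ]
  df$reaction_id <- factor(df$reaction_id, levels = rev(df$reaction_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fold,
                                   y = .data$reaction_id,
                                   fill = .data$log2_fold > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "#2166ac")) +
    ggplot2::labs(x = "log2 fold (mesenchymal / epithelial mean flux)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Heat map of per-pathway log2 fold changes
#'
#' @param object a `pathway_report` from [pathway_report()].
#' @param ... unused.
#' @return a ggplot object (reactions by pathway, tile fill = log2 fold).
#' @export
autoplot.pathway_report <- function(object, ...) {
  mat <- attr(object, "log2_matrix")
  df <- tibble::as_tibble(as.table(mat), .name_repair = "minimal")
  names(df) <- c("pathway", "reaction_id", "log2_fold")
  df <- df[!is.na(df$log2_fold), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reaction_id, y = .data$pathway,
                                   fill = .data$log2_fold)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 fold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Overlay flux density estimates of paired context models
#'
#' The paired analogue of a per-reaction probability density plot: kernel
#' density estimates of a reaction's sampled flux in the epithelial (blue)
#' and mesenchymal (red) models.
#'
#' @param set_E,set_M `flux_samples` of the paired models.
#' @param reaction_ids one or more reactions to show (facetted).
#' @return a ggplot object.
#' @export
plot_flux_density <- function(set_E, set_M, reaction_ids) {
  one <- function(s, lab) {
    dplyr::bind_rows(lapply(reaction_ids, function(rid) {
      d <- density_estimate(s, rid)
      tibble::tibble(reaction_id = rid, condition = lab,
                     flux = d$flux, density = d$density)
    }))
  }
  df <- dplyr::bind_rows(one(set_E, "epithelial"), one(set_M, "mesenchymal"))
  df <- df[is.finite(df$density), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flux, y = .data$density,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~reaction_id, scales = "free") +
    ggplot2::scale_colour_manual(values = c(epithelial = "#2166ac",
                                            mesenchymal = "#b2182b")) +
    ggplot2::labs(x = "flux (AU)", y = "probability density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
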