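#' Plot the two tail probabilities of every codon pair
#'
#' Scatter of -log10(P1) against -log10(P2) for all tested hexamers,
#' colored by rare/normal status, with the cutoff -log10(P0) drawn as
#' dashed lines: rare pairs sit in the upper-right quadrant. Zero
#' probabilities are capped at the smallest positive value in the data for
#' display.
#'
#' @param object A `pair_test` tibble from [test_codon_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pair_test <- function(object, ...) {
  p0 <- attr(object, "p0")
  df <- dplyr::filter(object, .data$status != "excluded")
  cap <- function(p) {
    floor_p <- min(p[p > 0], na.rm = TRUE)
    -log10(pmax(p, floor_p))
  }
  df <- dplyr::mutate(df, lp1 = cap(.data$p1), lp2 = cap(.data$p2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lp1, y = .data$lp2,
    colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = -log10(p0), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p0), linetype = "dashed") +
    ggplot2::labs(
      x = expression(-log[10] ~ P[1] ~ "(in-frame, encoding-rule null)"),
      y = expression(-log[10] ~ P[2] ~ "(any-frame, composition null)"),
      colour = NULL,
      title = "Codon-pair under-representation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an index across gene groups
#'
#' Jittered per-gene points with group medians — the scatter comparison of
#' F_rare between gene groups (e.g. essential vs non-essential).
#'
#' @param idx Tibble from [gene_indices()].
#' @param groups Tibble with columns `gene_id`, `group`, or a character
#'   vector of ids forming one group (the rest are labelled `"rest"`).
#' @param value Index column to plot.
#' @return A ggplot object.
#' @export
plot_index_groups <- function(idx, groups, value = "f_rare") {
  if (!is.data.frame(groups)) {
    groups <- tibble::tibble(
      gene_id = idx$gene_id,
      group = ifelse(idx$gene_id %in% groups, "subset", "rest")
    )
  }
  df <- dplyr::inner_join(idx, groups, by = "gene_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[value]],
    colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
      width = 0.5, colour = "black", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = value, colour = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot the ranked codon-contribution table
#'
#' Bar chart of -log10 hypergeometric upper-tail probability per codon in
#' rank order, marking the codons called rare.
#'
#' @param object A `codon_contribution` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.codon_contribution <- function(object, ...) {
  df <- dplyr::mutate(object,
    lp = -log10(pmax(.data$p_hyp, .Machine$double.xmin)),
    codon = factor(.data$codon, levels = .data$codon)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$lp,
    fill = .data$is_rare_codon)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha_codon")),
      linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ P[hyp]), fill = "rare") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 6))
}
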