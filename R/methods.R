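# broom-style and ggplot2 methods for the package's result classes.

#' Tidy a table of epistasis fits
#'
#' @param x A `dil_epistasis_fits` tibble.
#' @param ... Unused.
#' @return A tibble with the per-DIL result columns (genotype, replicate
#'   count, observed and expected mean fitness, epsilon, model code,
#'   log-likelihood, P, q, tier, direction).
#' @exportS3Method generics::tidy
tidy.dil_epistasis_fits <- function(x, ...) {
  cols <- c("dil", "il_i", "il_j", "phenotype", "n", "observed", "expected",
            "epsilon", "model", "logL", "lrt", "p_value", "q_value", "tier",
            "direction", "apm_model", "apm_eps", "apm_p_value")
  as_tibble(x)[, intersect(cols, names(x))]
}

#' Summarise a table of epistasis fits
#'
#' @inheritParams tidy.dil_epistasis_fits
#' @return One row per phenotype: DILs analyzed, calls per tier and
#'   direction, mean epsilon among significant calls, realized FDR.
#' @exportS3Method generics::glance
glance.dil_epistasis_fits <- function(x, ...) {
  if (!"tier" %in% names(x))
    abort("run fdr_and_tiers() before glance()")
  rf <- attr(x, "realized_fdr")
  out <- x |>
    group_by(.data$phenotype) |>
    summarise(
      n_analyzed = dplyr::n(),
      n_significant = sum(.data$tier >= "significant"),
      n_highly_significant = sum(.data$tier == "highly-significant"),
      n_antagonistic = sum(.data$tier >= "significant" &
                             .data$direction == "antagonistic"),
      n_synergistic = sum(.data$tier >= "significant" &
                            .data$direction == "synergistic"),
      mean_eps_significant = ifelse(any(.data$tier >= "significant"),
                                    mean(.data$epsilon[.data$tier >= "significant"]),
                                    NA_real_),
      .groups = "drop")
  if (!is.null(rf))
    out <- left_join(out, rf[, c("phenotype", "realized_fdr")],
                     by = "phenotype")
  out
}

#' Tidy an interaction network into its edge list
#'
#' @param x A `dmi_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dmi_network <- function(x, ...) {
  tibble(phenotype = x$phenotype, tier = x$tier, x$edges)
}

#' One-row summary of an interaction network
#'
#' @inheritParams tidy.dmi_network
#' @exportS3Method generics::glance
glance.dmi_network <- function(x, ...) {
  d <- degree_summary(x)
  tibble(phenotype = x$phenotype, tier = x$tier,
         n_nodes = d$n_nodes, n_edges = d$n_edges,
         mean_degree = d$mean_degree,
         mean_degree_sterile = d$mean_degree_sterile,
         mean_degree_non_sterile = d$mean_degree_non_sterile,
         n_components = length(d$component_sizes),
         largest_component = max(d$component_sizes))
}

#' Plot observed vs expected DIL fitness from epistasis fits
#'
#' Scatter of each DIL's observed mean relative fitness against the
#' best-null expectation; points above the identity line are antagonistic
#' (less unfit than expected), below synergistic. Colour encodes the
#' significance tier.
#'
#' @param object A `dil_epistasis_fits` tibble after [fdr_and_tiers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dil_epistasis_fits <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$expected, y = .data$observed,
                               colour = .data$tier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$phenotype)) +
    ggplot2::labs(x = "expected relative fitness (best null model)",
                  y = "observed relative fitness",
                  colour = "tier") +
    ggplot2::theme_minimal()
}

#' Plot an IL interaction network
#'
#' Force-directed layout (deterministic given `layout_seed`); red nodes
#' are individually sterile ILs, solid edges antagonistic interactions
#' and dashed edges synergistic ones.
#'
#' @param object A `dmi_network`.
#' @param layout_seed Seed for the layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dmi_network <- function(object, layout_seed = 1, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- tibble(il = object$nodes$il, sterile = object$nodes$sterile,
                  x = xy[, 1], y = xy[, 2])
  pos <- setNames(seq_len(nrow(nodes)), nodes$il)
  edges <- object$edges
  seg <- tibble(
    x = nodes$x[pos[edges$il_a]], y = nodes$y[pos[edges$il_a]],
    xend = nodes$x[pos[edges$il_b]], yend = nodes$y[pos[edges$il_b]],
    direction = edges$direction)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$direction),
      colour = "grey40") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$sterile),
      size = 5) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$il),
      vjust = -1.2, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red3")) +
    ggplot2::scale_linetype_manual(values = c(antagonistic = "solid",
                                              synergistic = "dashed")) +
    ggplot2::labs(title = sprintf("%s interactions (tier >= %s)",
                                  object$phenotype, object$tier),
                  colour = "sterile IL", linetype = "direction") +
    ggplot2::theme_void()
}

#' Plot a snowball trajectory
#'
#' DMI count and involved-locus count against divergence; past
#' saturation the two curves decouple.
#'
#' @param object A `snowball_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.snowball_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("k", "mean_dmis", "mean_loci")],
    cols = c("mean_dmis", "mean_loci"),
    names_to = "quantity", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$count,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(
      values = c(mean_dmis = "black", mean_loci = "red3"),
      labels = c(mean_dmis = "pairwise DMIs",
                 mean_loci = "loci involved")) +
    ggplot2::labs(x = "substitutions (K)", y = "mean count over replicates",
                  colour = NULL,
                  title = sprintf("p = %g", attr(object, "p"))) +
    ggplot2::theme_minimal()
}
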