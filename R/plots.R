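#' Plot a PCoA ordination
#'
#' Scatter plot of the first two principal coordinate axes, optionally
#' coloured by a per-sample grouping (e.g. treatment).
#'
#' @param object A `pcoa_ord` from [pcoa()].
#' @param colour Optional vector (aligned with samples) or name-matched named
#'   vector used for point colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcoa_ord <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (ncol(df) < 3L) stop("need at least two axes to plot", call. = FALSE)
  if (!is.null(colour)) {
    if (!is.null(names(colour))) colour <- colour[df$sample_id]
    df$group <- colour
  }
  lab <- function(i) {
    pe <- object$prop_explained
    if (length(pe) >= i) sprintf("Axis %d (%.1f%%)", i, 100 * pe[i]) else paste("Axis", i)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2)) +
    ggplot2::labs(x = lab(1L), y = lab(2L)) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout (seeded for reproducibility) with nodes
#' coloured by module when [detect_modules()] has been run, or by indicator
#' class when present.
#'
#' @param object A `conet`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.conet <- function(object, seed = 1L, ...) {
  g <- object$graph
  if (igraph::vcount(g) == 0L) stop("network is empty", call. = FALSE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(taxon_id = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L])
  if (!is.null(object$modules)) {
    nodes$colour <- factor(object$modules[nodes$taxon_id])
    legend <- "module"
  } else if (!is.null(igraph::V(g)$indicator_class)) {
    nodes$colour <- igraph::V(g)$indicator_class
    legend <- "indicator"
  } else {
    nodes$colour <- "node"
    legend <- NULL
  }
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1L], nodes$taxon_id)],
    y = nodes$y[match(el[, 1L], nodes$taxon_id)],
    xend = nodes$x[match(el[, 2L], nodes$taxon_id)],
    yend = nodes$y[match(el[, 2L], nodes$taxon_id)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y, colour = .data$colour),
                        size = 1.5) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = legend)
}

#' Frequency distribution of correlation strengths
#'
#' Histogram of all pairwise Spearman rho values of one or more correlation
#' sets — the view used to compare the sign and strength of couplings between
#' communities.
#'
#' @param ... Named `correlation_set` objects (names become facet labels; an
#'   unnamed single set uses its own label).
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_correlation_distribution <- function(..., bins = 60) {
  sets <- list(...)
  nm <- names(sets) %||% rep("", length(sets))
  df <- purrr::map2_dfr(sets, seq_along(sets), function(cs, i) {
    lab <- if (nzchar(nm[i])) nm[i] else cs$label %||% paste0("set", i)
    dplyr::mutate(tidy(cs), set = lab)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, fill = .data$set)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "Spearman rho", y = "pairs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Diversity trajectories by treatment and sampling
#'
#' Box plots of a diversity metric across samplings, split by treatment.
#'
#' @param div Tibble from [diversity_metrics()].
#' @param meta Metadata tibble (joined on `sample_id`).
#' @param metric One of `"richness"`, `"shannon_H"`, `"evenness_J"`.
#' @return A ggplot.
#' @export
plot_diversity <- function(div, meta, metric = c("richness", "shannon_H", "evenness_J")) {
  metric <- match.arg(metric)
  df <- dplyr::inner_join(div, meta, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sampling, y = .data[[metric]],
                                   fill = .data$treatment)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Control-drought similarity over time
#'
#' @param object A `resilience` result.
#' @param ... Unused.
#' @return A ggplot of per-pair similarities with sampling means.
#' @export
autoplot.resilience <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$sampling, y = .data$similarity)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4, colour = "red") +
    ggplot2::labs(x = NULL, y = "Bray-Curtis similarity (control vs drought)") +
    ggplot2::theme_minimal()
}
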