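#' All-pairs Spearman rank correlations for a community
#'
#' Computes Spearman's rho between every pair of taxa across the samples of
#' the table: mid-ranks (average ranks for ties, zeros tying at the bottom)
#' followed by Pearson correlation of the rank vectors. Two-sided p-values use
#' the t approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of
#' freedom; |rho| = 1 is assigned the smallest representable p. Taxa that are
#' constant across samples have no defined rank correlation; their pairs are
#' excluded and the taxa reported in `dropped`.
#'
#' The table should already be prevalence-filtered (see [prevalence_filter()])
#' so that correlations are estimated only for taxa observed in enough
#' samples.
#'
#' @param table An [otu_table()] with >= 4 samples.
#' @param label Optional community label (e.g. "drought x end_drought")
#'   carried into downstream objects.
#' @return A `correlation_set`: list with `rho` and `p` matrices (taxa x
#'   taxa), `n_samples`, `label`, `dropped`.
#' @export
spearman_matrix <- function(table, label = NULL) {
  if (ncol(table) < 4L) stop("need at least 4 samples", call. = FALSE)
  m <- unclass(table)
  constant <- apply(m, 1L, function(x) length(unique(x)) == 1L)
  dropped <- rownames(m)[constant]
  if (length(dropped)) {
    message("spearman_matrix: excluding ", length(dropped),
            " constant taxa (undefined rank correlation)")
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 variable taxa", call. = FALSE)
  rk <- t(apply(m, 1L, rank))  # mid-ranks
  rho <- stats::cor(t(rk))
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  n <- ncol(m)
  p <- spearman_p(rho, n)
  diag(p) <- 1
  structure(list(rho = rho, p = p, n_samples = n,
                 label = label %||% organism_tag(table), dropped = dropped),
            class = "correlation_set")
}

# two-sided p for Spearman rho via the t approximation; exact +/-1 -> minimal p
spearman_p <- function(rho, n) {
  p <- rho
  at_one <- !is.na(rho) & abs(rho) >= 1 - 1e-15
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p[] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[at_one] <- .Machine$double.xmin
  p[] <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[is.na(rho)] <- NA_real_
  p
}

#' @export
print.correlation_set <- function(x, ...) {
  T <- nrow(x$rho)
  cat(sprintf("<correlation_set> %s: %d taxa, %d pairs, n = %d samples\n",
              x$label, T, T * (T - 1) / 2, x$n_samples))
  invisible(x)
}

#' Summary statistics of a correlation set
#'
#' Mean absolute rho over all pairs, the proportion of negative correlations
#' among all pairs, and the proportion of negative correlations among the
#' significant set (|rho| > `rho_min`, p < `p_max`) — the quantities used to
#' contrast the overall coupling strength and antagonism of two communities.
#'
#' @param cset A `correlation_set`.
#' @param rho_min,p_max Significance thresholds for the "significant" subset.
#' @return A one-row tibble.
#' @export
correlation_summary <- function(cset, rho_min = 0.6, p_max = 0.01) {
  ut <- upper.tri(cset$rho)
  rho <- cset$rho[ut]
  p <- cset$p[ut]
  sig <- abs(rho) > rho_min & p < p_max
  tibble::tibble(
    label = cset$label %||% NA_character_,
    n_taxa = nrow(cset$rho),
    n_pairs = length(rho),
    n_samples = cset$n_samples,
    mean_abs_rho = mean(abs(rho)),
    prop_negative = mean(rho < 0),
    n_significant = sum(sig),
    prop_negative_significant = if (any(sig)) mean(rho[sig] < 0) else NA_real_
  )
}

#' Build a positive co-occurrence network from a correlation set
#'
#' Co-occurrence edges are taxon pairs with rho > `rho_min` AND p < `p_max`
#' (positive correlations only); isolated taxa are excluded from the graph. A
#' parallel "signed significant set" — pairs with |rho| > `rho_min` and
#' p < `p_max`, either sign — is retained for negative-correlation-proportion
#' analyses.
#'
#' @param cset A `correlation_set` from [spearman_matrix()].
#' @param rho_min Minimum rho for an edge (default 0.6).
#' @param p_max Maximum p for an edge (default 0.01).
#' @param table Optional source [otu_table()]: attaches mean relative
#'   abundance as a node attribute.
#' @param indicator_class Optional named character vector (taxon ->
#'   tolerant/sensitive/none) attached as a node attribute.
#' @return A `conet` object: list with `graph` (igraph, edge attribute `rho`),
#'   `signed_edges` (tibble: `taxon_a`, `taxon_b`, `rho`, `p`),
#'   `eligible_taxa` (taxa in the correlation set), `rho_min`, `p_max`,
#'   `label`.
#' @export
threshold_network <- function(cset, rho_min = 0.6, p_max = 0.01,
                              table = NULL, indicator_class = NULL) {
  stopifnot(inherits(cset, "correlation_set"))
  ut <- which(upper.tri(cset$rho), arr.ind = TRUE)
  rho <- cset$rho[ut]
  p <- cset$p[ut]
  ok <- !is.na(rho)
  sig <- ok & abs(rho) > rho_min & p < p_max
  ids <- rownames(cset$rho)
  signed <- tibble::tibble(taxon_a = ids[ut[sig, 1L]], taxon_b = ids[ut[sig, 2L]],
                           rho = rho[sig], p = p[sig])
  pos <- dplyr::filter(signed, .data$rho > 0)
  if (nrow(pos) == 0L) {
    warning("no edges survive thresholds (rho > ", rho_min, ", p < ", p_max, ")",
            call. = FALSE)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(pos, directed = FALSE)
  }
  if (!is.null(table) && igraph::vcount(g) > 0L) {
    rel <- rowMeans(relative_abundance(table))
    igraph::V(g)$mean_relabund <- unname(rel[igraph::V(g)$name])
  }
  if (!is.null(indicator_class) && igraph::vcount(g) > 0L) {
    cls <- indicator_class[igraph::V(g)$name]
    cls[is.na(cls)] <- "none"
    igraph::V(g)$indicator_class <- unname(cls)
  }
  structure(list(graph = g, signed_edges = signed,
                 eligible_taxa = nrow(cset$rho),
                 rho_min = rho_min, p_max = p_max,
                 label = cset$label), class = "conet")
}

#' @export
print.conet <- function(x, ...) {
  cat(sprintf("<conet> %s: %d nodes, %d positive edges (rho > %.2g, p < %.2g) of %d eligible taxa\n",
              x$label %||% "", igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$rho_min, x$p_max, x$eligible_taxa))
  invisible(x)
}

#' Per-node connectedness and centrality
#'
#' Degree, normalised degree and (unweighted, unnormalised) shortest-path
#' betweenness for every node. The default normalisation divides degree by
#' n - 1 (the maximum possible), bounding it in \[0, 1\]; dividing by twice the
#' edge count ("total connections in the network") is available via
#' `normalise`.
#'
#' @param net A `conet`.
#' @param normalise `"n_minus_1"` (default) or `"total_edges"`.
#' @return A tibble: `taxon_id`, `degree`, `normalised_degree`, `betweenness`,
#'   plus `module` if [detect_modules()] has been run.
#' @export
node_metrics <- function(net, normalise = c("n_minus_1", "total_edges")) {
  normalise <- match.arg(normalise)
  stopifnot(inherits(net, "conet"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(tibble::tibble(taxon_id = character(), degree = integer(),
                          normalised_degree = double(), betweenness = double()))
  }
  deg <- igraph::degree(g)
  denom <- if (normalise == "n_minus_1") max(n - 1L, 1L) else max(2L * igraph::ecount(g), 1L)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
  out <- tibble::tibble(taxon_id = igraph::V(g)$name,
                        degree = as.integer(deg),
                        normalised_degree = unname(deg / denom),
                        betweenness = unname(btw))
  if (!is.null(net$modules)) out$module <- unname(net$modules[out$taxon_id])
  out
}

#' Global clustering coefficient (transitivity)
#'
#' 3 x triangles / connected triples over the whole graph; defined as 0 for
#' graphs without any connected triple.
#'
#' @param net A `conet` or igraph object.
#' @return A single number in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  g <- if (inherits(net, "conet")) net$graph else net
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Detect network modules by edge-betweenness (Girvan-Newman)
#'
#' Divisive community detection: repeatedly remove the edge with the highest
#' edge betweenness and, among the nested partitions produced, keep the one
#' maximising Newman-Girvan modularity Q (via
#' [igraph::cluster_edge_betweenness()]). Modular, compartmentalised networks
#' are expected to confine disturbance effects better than highly
#' interconnected ones.
#'
#' @param net A `conet` with >= 1 node.
#' @return The `conet` with `modules` (named membership vector) and
#'   `modularity_Q` filled in.
#' @export
detect_modules <- function(net) {
  stopifnot(inherits(net, "conet"))
  g <- net$graph
  if (igraph::vcount(g) == 0L) {
    net$modules <- integer(0)
    net$modularity_Q <- NA_real_
    return(net)
  }
  if (igraph::ecount(g) == 0L) {
    net$modules <- stats::setNames(seq_len(igraph::vcount(g)), igraph::V(g)$name)
    net$modularity_Q <- 0
    return(net)
  }
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL, directed = FALSE)
  net$modules <- stats::setNames(igraph::membership(cl), igraph::V(g)$name)
  net$modularity_Q <- igraph::modularity(g, igraph::membership(cl))
  net
}

#' Compare observed clustering against Erdos-Renyi G(n, m) random graphs
#'
#' Draws an ensemble of uniform random graphs with exactly the observed node
#' and edge counts (no loops or multi-edges) and compares the observed global
#' clustering coefficient against the null distribution:
#' empirical p = (1 + #\{null >= observed\}) / (1 + ensemble).
#'
#' @param net A non-empty `conet`.
#' @param ensemble Number of random graphs (default 1000).
#' @param seed Integer RNG seed.
#' @return A `null_model_result`: list with `observed_clustering`,
#'   `null_mean`, `null_sd`, `empirical_p`, `ensemble_size`, `null_values`.
#' @export
random_network_null <- function(net, ensemble = 1000, seed = 1L) {
  stopifnot(inherits(net, "conet"))
  g <- net$graph
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (n == 0L || m == 0L) stop("network is empty", call. = FALSE)
  obs <- clustering_coefficient(g)
  set.seed(seed)
  null_values <- vapply(seq_len(ensemble), function(i) {
    tr <- igraph::transitivity(igraph::sample_gnm(n, m), type = "global")
    if (is.nan(tr)) 0 else tr
  }, numeric(1))
  structure(list(observed_clustering = obs,
                 null_mean = mean(null_values),
                 null_sd = stats::sd(null_values),
                 empirical_p = (1 + sum(null_values >= obs)) / (1 + ensemble),
                 ensemble_size = ensemble,
                 null_values = null_values), class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("G(n,m) null: observed clustering %.4f vs null %.4f +/- %.4f (p = %.4g, %d graphs)\n",
              x$observed_clustering, x$null_mean, x$null_sd, x$empirical_p,
              x$ensemble_size))
  invisible(x)
}

#' Jaccard overlap of two networks' node sets
#'
#' |A intersect B| / |A union B| over taxon ids — the measure of how constant
#' network membership stays across time points or treatments.
#'
#' @param net_a,net_b `conet` objects (same organism).
#' @return A number in \[0, 1\]; 0 (with a warning) if both are empty.
#' @export
membership_overlap <- function(net_a, net_b) {
  a <- igraph::V(net_a$graph)$name
  b <- igraph::V(net_b$graph)$name
  if (length(a) == 0L && length(b) == 0L) {
    warning("both networks are empty; overlap defined as 0", call. = FALSE)
    return(0)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' One-row summary of a co-occurrence network
#'
#' Node and edge counts, edge density, inclusion proportion (nodes / taxa that
#' passed the prevalence filter), global clustering coefficient, mean
#' normalised degree, and modularity Q when modules have been detected.
#'
#' @param net A `conet`.
#' @param eligible_taxa Number of taxa eligible for inclusion; defaults to the
#'   taxa of the correlation set the network was built from.
#' @return A one-row tibble.
#' @export
network_summary <- function(net, eligible_taxa = net$eligible_taxa) {
  stopifnot(inherits(net, "conet"))
  if (is.null(eligible_taxa) || eligible_taxa == 0L) {
    stop("eligible_taxa must be positive", call. = FALSE)
  }
  g <- net$graph
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  nm <- node_metrics(net)
  tibble::tibble(
    label = net$label %||% NA_character_,
    nodes = n, edges = m,
    density = if (n >= 2L) m / (n * (n - 1) / 2) else 0,
    inclusion_proportion = n / eligible_taxa,
    clustering_coefficient = if (m > 0L) clustering_coefficient(g) else NA_real_,
    mean_normalised_degree = if (n > 0L) mean(nm$normalised_degree) else NA_real_,
    mean_betweenness = if (n > 0L) mean(nm$betweenness) else NA_real_,
    modularity_Q = net$modularity_Q %||% NA_real_
  )
}
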