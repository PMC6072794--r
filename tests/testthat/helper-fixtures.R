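# quick otu_table from a bare matrix (ids filled in if missing)
make_table <- function(m, tag = "other") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("OTU%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  otu_table(m, tag)
}

random_table <- function(n_taxa, n_samples, lambda = 20, seed = 1, tag = "other") {
  set.seed(seed)
  make_table(matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples), tag)
}

# metadata for a simple two-treatment x sampling design
make_meta <- function(table, treatment, sampling = "pre_drought", block = NULL) {
  n <- n_samples(table)
  validate_metadata(tibble::tibble(
    sample_id = sample_ids(table),
    treatment = rep_len(treatment, n),
    sampling = rep_len(sampling, n),
    block = block %||% rep_len(1:4, n)
  ))
}

# undirected edge key for set comparisons
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# conet wrapper around a bare igraph for metric tests
as_conet <- function(g, eligible = igraph::vcount(g)) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  }
  structure(list(graph = g, signed_edges = tibble::tibble(),
                 eligible_taxa = eligible, rho_min = 0.6, p_max = 0.01,
                 label = "test"), class = "conet")
}
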