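test_that("Spearman rho matches a rank-then-Pearson oracle, ties included", {
  x <- c(1, 2, 2, 4); y <- c(2, 1, 3, 4)
  m <- rbind(x = c(1L, 2L, 2L, 4L), y = c(2L, 1L, 3L, 4L),
             z = c(5L, 6L, 7L, 8L), w = c(8L, 7L, 6L, 5L))
  cs <- spearman_matrix(make_table(m))
  expect_equal(cs$rho["x", "y"], oracle_rank_pearson(x, y), tolerance = 1e-12)
  expect_equal(cs$rho["z", "x"], oracle_rank_pearson(c(5, 6, 7, 8), x), tolerance = 1e-12)
  expect_equal(cs$rho["z", "w"], -1)   # strictly decreasing pair
  expect_equal(cs$p["z", "w"], .Machine$double.xmin)
  # random tables with heavy ties
  set.seed(13)
  for (i in 1:3) {
    mm <- matrix(rpois(5 * 10, 3), 5, 10)
    cs2 <- spearman_matrix(make_table(mm))
    for (a in 1:4) for (b in (a + 1):5) {
      expect_equal(cs2$rho[a, b], oracle_rank_pearson(mm[a, ], mm[b, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("Spearman p-values follow the t approximation and flag constants", {
  set.seed(2)
  m <- matrix(rpois(4 * 20, 50), 4, 20)
  cs <- spearman_matrix(make_table(m))
  r <- cs$rho[1, 2]; n <- 20
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(cs$p[1, 2], 2 * pt(-abs(tstat), n - 2), tolerance = 1e-12)
  rownames(m) <- paste0("t", 1:4)
  mc <- rbind(m, konst = rep(7L, 20))
  expect_message(cs2 <- spearman_matrix(make_table(mc)), "constant taxa")
  expect_equal(cs2$dropped, "konst")
  expect_false("konst" %in% rownames(cs2$rho))
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(3)
  m <- matrix(rpois(6 * 15, 40), 6, 15)
  cs <- spearman_matrix(make_table(m))
  m2 <- m; m2[1, ] <- as.integer(m[1, ]^2)          # strictly monotone on row 1
  m3 <- m; m3[2, ] <- as.integer(3L * m[2, ] + 7L)  # affine on row 2
  expect_equal(spearman_matrix(make_table(m2))$rho, cs$rho, tolerance = 1e-12)
  expect_equal(spearman_matrix(make_table(m3))$rho, cs$rho, tolerance = 1e-12)
})

test_that("network thresholding keeps positive significant edges only", {
  cs <- structure(list(
    rho = matrix(c(1, .7, .7, -.9, .7, 1, .1, 0, .7, .1, 1, 0, -.9, 0, 0, 1), 4, 4,
                 dimnames = list(letters[1:4], letters[1:4])),
    p = matrix(c(0, .001, .02, 1e-6, .001, 0, .5, .9, .02, .5, 0, .9, 1e-6, .9, .9, 0),
               4, 4, dimnames = list(letters[1:4], letters[1:4])),
    n_samples = 36, label = "toy", dropped = character(0)),
    class = "correlation_set")
  net <- threshold_network(cs, rho_min = 0.6, p_max = 0.01)
  el <- igraph::as_edgelist(net$graph)
  expect_equal(nrow(el), 1L)                          # only (a, b): rho .7, p .001
  expect_setequal(el[1, ], c("a", "b"))
  expect_false("c" %in% igraph::V(net$graph)$name)    # p-gated pair leaves c isolated
  # the signed set retains the strong negative pair
  expect_true(any(net$signed_edges$rho < 0))
  expect_setequal(edge_key(net$signed_edges$taxon_a, net$signed_edges$taxon_b),
                  c(edge_key("a", "b"), edge_key("a", "d")))
})

test_that("edge sets shrink monotonically as thresholds tighten", {
  set.seed(31)
  gen <- generate_community(synth_preset("strong_coupling", n_taxa = 60,
                                         loaded_fraction = 0.5), seed = 31)
  cs <- spearman_matrix(prevalence_filter(gen$table, 8))
  edges_at <- function(r, p) {
    net <- suppressWarnings(threshold_network(cs, r, p))
    igraph::ecount(net$graph)
  }
  e1 <- edges_at(0.4, 0.05); e2 <- edges_at(0.6, 0.05); e3 <- edges_at(0.8, 0.05)
  expect_true(e1 >= e2 && e2 >= e3)
  expect_gte(edges_at(0.4, 0.05), edges_at(0.4, 0.001))
})

test_that("node metrics match closed forms on canonical graphs", {
  path3 <- igraph::make_graph(~ A - B, B - C)
  nm <- node_metrics(as_conet(path3))
  expect_equal(nm$betweenness[match(c("A", "B", "C"), nm$taxon_id)], c(0, 1, 0))
  expect_equal(nm$normalised_degree[match(c("A", "B", "C"), nm$taxon_id)], c(.5, 1, .5))

  k4 <- igraph::make_full_graph(4)
  net4 <- as_conet(k4)
  nm4 <- node_metrics(net4)
  expect_equal(nm4$betweenness, rep(0, 4))
  expect_equal(nm4$normalised_degree, rep(1, 4))
  expect_equal(clustering_coefficient(net4), 1)
  # alternative normalisation: degree / total connection ends
  nm4b <- node_metrics(net4, normalise = "total_edges")
  expect_equal(nm4b$normalised_degree, rep(3 / 12, 4))
})

test_that("betweenness and transitivity equal brute force on random graphs", {
  set.seed(17)
  for (i in 1:12) {
    g <- igraph::sample_gnm(10, 18)
    igraph::V(g)$name <- paste0("n", 1:10)
    adj <- adj_of(g)
    nm <- node_metrics(as_conet(g))
    expect_equal(nm$betweenness, oracle_betweenness(adj), tolerance = 1e-9)
    tr <- clustering_coefficient(as_conet(g))
    o <- oracle_transitivity(adj)
    expect_equal(tr, if (is.nan(o)) 0 else o, tolerance = 1e-12)
  }
})

test_that("module detection recovers the two-triangle bridge and scores Q correctly", {
  g <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d, a - d)
  net <- detect_modules(as_conet(g))
  expect_equal(length(unique(net$modules)), 2L)
  expect_equal(unname(net$modules[c("a", "b", "c")]), rep(net$modules[["a"]], 3))
  expect_equal(unname(net$modules[c("d", "e", "f")]), rep(net$modules[["d"]], 3))
  expect_equal(net$modularity_Q, 6 / 7 - 2 * 0.25, tolerance = 1e-9)
  # the returned Q equals the partition's Q by the longhand formula, and no
  # 2-way split scores higher (brute force over all 2-partitions)
  adj <- adj_of(g)
  expect_equal(net$modularity_Q, oracle_modularity(adj, net$modules), tolerance = 1e-12)
  best2 <- max(vapply(0:(2^6 - 1), function(mask) {
    oracle_modularity(adj, as.integer(intToBits(mask))[1:6])
  }, numeric(1)))
  expect_gte(net$modularity_Q + 1e-12, best2)

  # single clique: one module, Q = 0
  k5 <- detect_modules(as_conet(igraph::make_full_graph(5)))
  expect_equal(length(unique(k5$modules)), 1L)
  expect_equal(k5$modularity_Q, 0)

  # disconnected components split into (at least) their components
  two <- igraph::disjoint_union(igraph::make_full_graph(3), igraph::make_full_graph(3))
  igraph::V(two)$name <- paste0("v", 1:6)
  nett <- detect_modules(as_conet(two))
  expect_gte(length(unique(nett$modules)), 2L)
  expect_gte(nett$modularity_Q, oracle_modularity(adj_of(two), rep(1:2, each = 3)) - 1e-12)
})

test_that("G(n,m) nulls preserve size and match the density expectation", {
  g <- igraph::sample_gnm(30, 60)
  igraph::V(g)$name <- paste0("n", 1:30)
  net <- as_conet(g)
  res <- random_network_null(net, ensemble = 300, seed = 5)
  expect_equal(res$ensemble_size, 300)
  # mean null clustering ~ density 2m/(n(n-1))
  dens <- 2 * 60 / (30 * 29)
  expect_lt(abs(res$null_mean - dens), 3 * res$null_sd / sqrt(300) + 0.02)
  # clique union with the same n, m maximises clustering -> minimal p
  cl <- igraph::disjoint_union(lapply(rep(6, 5), igraph::make_full_graph))
  igraph::V(cl)$name <- paste0("c", 1:30)
  res2 <- random_network_null(as_conet(cl), ensemble = 300, seed = 6)
  expect_equal(res2$observed_clustering, 1)
  expect_equal(res2$empirical_p, 1 / 301)
})

test_that("membership overlap is Jaccard on node id sets", {
  ga <- igraph::make_full_graph(10); igraph::V(ga)$name <- paste0("t", 1:10)
  gb <- igraph::make_full_graph(10); igraph::V(gb)$name <- paste0("t", 6:15)
  expect_equal(membership_overlap(as_conet(ga), as_conet(gb)), 5 / 15)
  expect_equal(membership_overlap(as_conet(ga), as_conet(ga)), 1)
  gc <- igraph::make_full_graph(3); igraph::V(gc)$name <- paste0("x", 1:3)
  expect_equal(membership_overlap(as_conet(ga), as_conet(gc)), 0)
  e <- as_conet(igraph::make_empty_graph(0, directed = FALSE), eligible = 1)
  expect_warning(expect_equal(membership_overlap(e, e), 0), "empty")
})

test_that("network summary reports inclusion against eligible taxa", {
  g <- igraph::make_full_graph(40); igraph::V(g)$name <- paste0("t", 1:40)
  s <- network_summary(as_conet(g, eligible = 100))
  expect_equal(s$inclusion_proportion, 0.4)
  expect_equal(s$density, 1)
  expect_error(network_summary(as_conet(g, eligible = 0)), "positive")
})
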