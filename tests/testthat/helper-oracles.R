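# Brute-force graph oracles, deliberately naive: they enumerate rather than
# use any library algorithm, so they can arbitrate the packaged metrics.

# adjacency matrix of an igraph (0/1, no weights)
adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
}

# all simple paths from s to t as lists of vertex indices (DFS on adjacency)
enumerate_simple_paths <- function(adj, s, t) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path, visited) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ])) {
      if (!visited[w]) walk(c(path, w), `[<-`(visited, w, TRUE))
    }
  }
  walk(s, `[<-`(logical(n), s, TRUE))
  out
}

# betweenness by exhaustive shortest-path enumeration
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- enumerate_simple_paths(adj, s, t)
      if (length(paths) == 0L) next
      lens <- lengths(paths)
      short <- paths[lens == min(lens)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        thru <- sum(vapply(short, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + thru / length(short)  # undirected: each pair once
      }
    }
  }
  b
}

# global transitivity from the adjacency matrix: 3*triangles / triples
oracle_transitivity <- function(adj) {
  diag(adj) <- FALSE
  a <- adj * 1
  triangles <- sum(diag(a %*% a %*% a)) / 6
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1) / 2)
  if (triples == 0) return(NaN)
  3 * triangles / triples
}

# Newman-Girvan modularity of a partition: sum_g (e_gg - a_g^2)
oracle_modularity <- function(adj, membership) {
  diag(adj) <- FALSE
  m <- sum(adj) / 2
  groups <- unique(membership)
  q <- 0
  for (g in groups) {
    idx <- which(membership == g)
    e_gg <- sum(adj[idx, idx]) / 2 / m
    a_g <- sum(adj[idx, ]) / 2 / m
    q <- q + e_gg - a_g^2
  }
  q
}

# Pearson correlation of mid-ranks, computed from raw sums (no stats::cor)
oracle_rank_pearson <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# PERMANOVA pseudo-F written out longhand from a plain distance matrix
oracle_pseudo_F <- function(dm, labels) {
  n <- nrow(dm)
  groups <- unique(labels)
  a <- length(groups)
  ss_tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) ss_tot <- ss_tot + dm[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in groups) {
    idx <- which(labels == g)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + dm[i, j]^2
    ss_w <- ss_w + acc / length(idx)
  }
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# exact permutation p for a two-group statistic by full enumeration
oracle_exact_p_two_groups <- function(stat_fn, n1, n2, stat_obs, tol = 1e-12) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  hits <- 0L
  for (j in seq_len(ncol(combos))) {
    lab <- rep("b", n)
    lab[combos[, j]] <- "a"
    if (stat_fn(lab) >= stat_obs - tol) hits <- hits + 1L
  }
  hits / ncol(combos)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
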