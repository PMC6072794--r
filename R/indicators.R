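# group means / occupancy / indval matrices for a relative-abundance matrix X
# (taxa x samples) and a label factor; returns list(A, B, indval), each T x G
indval_components <- function(X, labels) {
  labels <- factor(labels)
  ng <- as.vector(table(labels))
  gm <- t(rowsum(t(X), labels)) / rep(ng, each = nrow(X))      # group mean abundance
  occ <- t(rowsum(t(X > 0) + 0, labels)) / rep(ng, each = nrow(X))  # occupancy fraction
  tot <- rowSums(gm)
  A <- gm / ifelse(tot > 0, tot, 1)  # relative mean abundance; all-zero taxon -> 0
  list(A = A, B = occ, indval = A * occ, groups = levels(labels))
}

#' Dufrene-Legendre indicator values (IndVal)
#'
#' For each taxon i and group g, IndVal_ig = A_ig * B_ig where A_ig is the
#' taxon's mean relative abundance in g divided by the sum of its group means
#' (abundance concentration) and B_ig is the fraction of group-g samples in
#' which the taxon occurs (fidelity). Computed on relative abundances, so the
#' score is unchanged by per-sample depth rescaling; on rarefied tables this
#' is equivalent to using counts. A taxon absent everywhere scores 0 in every
#' group.
#'
#' @param table An [otu_table()].
#' @param labels Group label per sample (e.g. control/drought).
#' @return A tibble: `taxon_id`, `group`, `A`, `B`, `indval`.
#' @export
indval_scores <- function(table, labels) {
  labels <- factor(labels)
  stopifnot(length(labels) == ncol(table))
  if (nlevels(labels) < 2L || any(table(labels) == 0L)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  X <- relative_abundance(table)
  cmp <- indval_components(X, labels)
  G <- length(cmp$groups)
  tibble::tibble(
    taxon_id = rep(rownames(X), times = G),
    group = rep(cmp$groups, each = nrow(X)),
    A = as.vector(cmp$A),
    B = as.vector(cmp$B),
    indval = as.vector(cmp$indval)
  )
}

#' Permutation significance of maximum IndVal scores
#'
#' The test statistic per taxon is its maximum IndVal across groups; the null
#' distribution comes from randomly reassigning sample labels. One label
#' permutation per iteration is shared by all taxa, preserving between-taxon
#' dependence. p = (1 + #\{indval_max_perm >= indval_max_obs\}) / (1 + n_perm).
#'
#' @param table An [otu_table()].
#' @param labels Group label per sample.
#' @param n_perm Number of permutations (default 1000, minimum 99).
#' @param seed Integer RNG seed.
#' @return A tibble: `taxon_id`, `best_group`, `indval_max`, `p_perm`.
#' @export
indval_permutation_test <- function(table, labels, n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 99)
  labels <- factor(labels)
  stopifnot(length(labels) == ncol(table))
  X <- relative_abundance(table)
  obs <- indval_components(X, labels)
  iv_obs <- obs$indval
  best <- max.col(iv_obs, ties.method = "first")
  stat_obs <- iv_obs[cbind(seq_len(nrow(iv_obs)), best)]
  tol <- 1e-12
  set.seed(seed)
  hits <- integer(nrow(X))
  n <- ncol(X)
  for (b in seq_len(n_perm)) {
    perm <- indval_components(X, labels[sample.int(n)])
    stat_perm <- do.call(pmax, as.data.frame(perm$indval))
    hits <- hits + (stat_perm >= stat_obs - tol)
  }
  tibble::tibble(
    taxon_id = rownames(X),
    best_group = obs$groups[best],
    indval_max = unname(stat_obs),
    p_perm = (1 + hits) / (1 + n_perm)
  )
}

#' Classify significant indicator taxa as tolerant or sensitive
#'
#' A taxon is an indicator when its permutation p is below `p_max` and its
#' mean relative abundance in its best group exceeds `min_relabund` (the
#' abundance gate keeps the focus on taxa abundant enough to matter for
#' network structure). Indicators whose best group is the disturbed
#' (`drought`) treatment increased under disturbance and are classed
#' `tolerant`; those peaking in `control` decreased and are `sensitive`;
#' everything else is `none`.
#'
#' @param perm_results Tibble from [indval_permutation_test()].
#' @param table The same [otu_table()].
#' @param labels The same group labels.
#' @param p_max Significance threshold (default 0.05).
#' @param min_relabund Abundance gate as a fraction (default 0.01 = 1%).
#' @param abundance Gate on the `"best_group"` mean (default) or the
#'   `"overall"` mean relative abundance.
#' @return `perm_results` with columns `mean_relabund` and `class` added.
#' @export
classify_indicators <- function(perm_results, table, labels, p_max = 0.05,
                                min_relabund = 0.01,
                                abundance = c("best_group", "overall")) {
  abundance <- match.arg(abundance)
  labels <- factor(labels)
  X <- relative_abundance(table)
  X <- X[perm_results$taxon_id, , drop = FALSE]
  ng <- as.vector(table(labels))
  gm <- t(rowsum(t(X), labels)) / rep(ng, each = nrow(X))
  rel <- if (abundance == "best_group") {
    gm[cbind(seq_len(nrow(gm)), match(perm_results$best_group, levels(labels)))]
  } else {
    rowMeans(X)
  }
  is_ind <- perm_results$p_perm < p_max & rel > min_relabund
  cls <- rep("none", nrow(perm_results))
  cls[is_ind & perm_results$best_group == "drought"] <- "tolerant"
  cls[is_ind & perm_results$best_group == "control"] <- "sensitive"
  dplyr::mutate(perm_results, mean_relabund = unname(rel), class = cls)
}

#' Full indicator analysis for one community
#'
#' Convenience wrapper: [indval_scores()] + [indval_permutation_test()] +
#' [classify_indicators()] in one call.
#'
#' @inheritParams indval_permutation_test
#' @inheritParams classify_indicators
#' @return An `indicator_result` tibble: `taxon_id`, `best_group`,
#'   `indval_max`, `p_perm`, `mean_relabund`, `class`.
#' @export
indicator_analysis <- function(table, labels, n_perm = 1000, seed = 1L,
                               p_max = 0.05, min_relabund = 0.01,
                               abundance = "best_group") {
  perm <- indval_permutation_test(table, labels, n_perm = n_perm, seed = seed)
  out <- classify_indicators(perm, table, labels, p_max = p_max,
                             min_relabund = min_relabund, abundance = abundance)
  class(out) <- c("indicator_result", class(out))
  out
}

#' Compare the proportions of drought responders between two communities
#'
#' A taxon "increased" under disturbance when its mean relative abundance in
#' the drought samples strictly exceeds that in the control samples (ties
#' count as not increased). Taxa absent from both groups are excluded from the
#' denominator. The two communities' responder proportions are compared with a
#' two-sided chi-square test of proportions.
#'
#' @param table_a,table_b [otu_table()] objects for the two communities.
#' @param labels_a,labels_b control/drought label per sample of each table.
#' @return A one-row tibble: `k_1`, `n_1`, `prop_1`, `k_2`, `n_2`, `prop_2`,
#'   `statistic`, `df`, `p`, `effect_direction`.
#' @export
responder_proportions <- function(table_a, labels_a, table_b, labels_b) {
  count_up <- function(table, labels) {
    labels <- factor(labels, levels = .treatment_levels)
    stopifnot(length(labels) == ncol(table))
    X <- relative_abundance(table)
    present <- rowSums(X) > 0
    if (any(!present)) {
      message("responder_proportions: excluding ", sum(!present),
              " taxa absent everywhere")
    }
    X <- X[present, , drop = FALSE]
    md <- rowMeans(X[, labels == "drought", drop = FALSE])
    mc <- rowMeans(X[, labels == "control", drop = FALSE])
    c(k = sum(md > mc), n = nrow(X))
  }
  a <- count_up(table_a, labels_a)
  b <- count_up(table_b, labels_b)
  test <- chi2_proportions(a[["k"]], a[["n"]], b[["k"]], b[["n"]])
  tibble::tibble(k_1 = a[["k"]], n_1 = a[["n"]], prop_1 = test$prop_1,
                 k_2 = b[["k"]], n_2 = b[["n"]], prop_2 = test$prop_2,
                 statistic = test$statistic, df = test$df, p = test$p,
                 effect_direction = test$effect_direction)
}
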