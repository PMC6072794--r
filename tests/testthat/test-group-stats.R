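test_that("chi-square of proportions matches the closed form and is symmetric", {
  res <- chi2_proportions(30, 100, 10, 100)
  # closed form: N (ad - bc)^2 / (r1 r2 c1 c2)
  expect_equal(res$statistic, 200 * (30 * 90 - 70 * 10)^2 / (100 * 100 * 40 * 160),
               tolerance = 1e-12)
  expect_equal(res$statistic, 12.5)
  expect_equal(res$df, 1L)
  expect_equal(res$effect_direction, "A>B")
  swapped <- chi2_proportions(10, 100, 30, 100)
  expect_equal(swapped$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(swapped$effect_direction, "B>A")

  eq <- chi2_proportions(10, 100, 10, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_error(chi2_proportions(0, 10, 0, 10), "degenerate")
})

test_that("one-way ANOVA matches hand-worked sums of squares and guards 0/0", {
  # textbook-style: groups (1,2,3), (2,3,4), (6,7,8)
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  means <- tapply(v, g, mean)           # 2, 3, 7
  ssb <- 3 * sum((means - mean(v))^2)   # 42
  ssw <- sum((v - means[g])^2)          # 6
  f_hand <- (ssb / 2) / (ssw / 6)
  res <- anova_oneway(v, g)
  expect_equal(res$statistic, f_hand, tolerance = 1e-10)
  expect_equal(c(res$df1, res$df2), c(2L, 6L))

  const <- anova_oneway(rep(5, 8), rep(c("a", "b"), each = 4))
  expect_equal(const$statistic, 0)
  expect_equal(const$p, 1)
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "at least two values")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    res <- anova_oneway(c(x, y), rep(c("a", "b"), c(12, 15)))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("factorial ANOVA reports crossed effects and warns when unbalanced", {
  set.seed(14)
  f1 <- rep(c("pre", "post"), each = 8)
  f2 <- rep(rep(c("control", "drought"), each = 4), 2)
  v <- rnorm(16) + 2 * (f1 == "post") * (f2 == "drought")
  res <- anova_factorial(v, f1, f2)
  expect_equal(res$term, c("f1", "f2", "f1:f2"))
  ref <- anova(lm(v ~ f1 * f2))
  expect_equal(res$statistic, ref$`F value`[1:3], tolerance = 1e-12)
  expect_warning(anova_factorial(v[-1], f1[-1], f2[-1]), "unbalanced")
})

test_that("linear regression matches the normal equations", {
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  res <- linreg(x, y)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res$slope, slope_hand, tolerance = 1e-12)
  expect_equal(res$intercept, mean(y) - slope_hand * mean(x), tolerance = 1e-12)

  exact <- suppressWarnings(linreg(x, 2 * x + 1))  # "perfect fit" note
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  # constructed orthogonality: slope and R2 are exactly zero
  xo <- c(-2, -1, 0, 1, 2); yo <- c(1, -1, 0, -1, 1)
  orth <- linreg(xo, yo)
  expect_equal(orth$slope, 0, tolerance = 1e-12)
  expect_equal(orth$r_squared, 0, tolerance = 1e-12)
  expect_error(linreg(rep(1, 5), 1:5), "zero variance")
  expect_error(linreg(1:2, 1:2), "at least 3")
})

test_that("covariate-node association recovers a node's own profile", {
  gen <- generate_community(synth_preset("strong_coupling"), seed = 2)
  tbl <- prevalence_filter(gen$table, 8)
  cs <- spearman_matrix(tbl)
  net <- suppressWarnings(threshold_network(cs, 0.6, 0.01, table = tbl))
  node <- igraph::V(net$graph)$name[1]
  cov <- unclass(tbl)[node, ]  # covariate equal to the node's own profile
  assoc <- covariate_node_association(net, tbl, cov)
  expect_equal(assoc$rho[assoc$taxon_id == node], 1)
  expect_error(covariate_node_association(net, tbl, rep(1, ncol(tbl))), "constant")
})

test_that("slope contrast detects hub-loaded covariates and stays null otherwise", {
  # covariate = the shared factor itself: nodes loading on it correlate more,
  # and those nodes are the central ones, so |rho| rises with degree
  cfg <- synth_preset("bacteria_like", n_taxa = 600, treatments = "control",
                      samplings = "end_drought")
  gen <- generate_community(cfg, seed = 33)
  tbl <- prevalence_filter(filter_low_count_taxa(gen$table, 10), 8)
  cs <- spearman_matrix(tbl)
  net <- suppressWarnings(threshold_network(cs, 0.6, 0.01, table = tbl))
  # proxy for the shared driver: summed abundance of the strongest loaders
  glob <- names(sort(abs(gen$truth$lambda[, 1]), decreasing = TRUE))[1:10]
  cov <- colSums(relative_abundance(gen$table)[glob, sample_ids(tbl)])
  assoc <- covariate_node_association(net, tbl, cov)
  fit <- linreg(assoc$normalised_degree, assoc$abs_rho)
  expect_gt(fit$slope, 0)
  expect_lt(fit$p, 0.01)

  # an independent covariate: slopes of two halves do not differ
  set.seed(44)
  cov0 <- rnorm(ncol(tbl))
  assoc0 <- covariate_node_association(net, tbl, cov0)
  half <- seq_len(nrow(assoc0)) %% 2 == 0
  contrast <- covariate_slope_contrast(assoc0[half, ], assoc0[!half, ],
                                       metric = "normalised_degree")
  expect_gt(contrast$interaction$p, 0.01)
  expect_equal(nrow(contrast$slopes), 2L)
})
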