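test_that("IndVal matches hand-worked examples", {
  # 3 drought samples (2,2,2) vs 3 control (0,0,6):
  # A_drought = 2/(2+2) = 0.5, B_drought = 1 -> 0.5
  # A_control = 0.5, B_control = 1/3 -> 0.1667
  m <- rbind(tax = c(0L, 0L, 6L, 2L, 2L, 2L),
             other = c(10L, 10L, 4L, 8L, 8L, 8L))  # keeps depths equal
  colnames(m) <- sprintf("S%d", 1:6)
  labels <- rep(c("control", "drought"), each = 3)
  iv <- indval_scores(make_table(m), labels)
  tax <- iv[iv$taxon_id == "tax", ]
  expect_equal(tax$indval[tax$group == "drought"], 0.5, tolerance = 1e-12)
  expect_equal(tax$indval[tax$group == "control"], 1 / 6, tolerance = 1e-12)

  # perfect indicator: present in every drought sample, absent from controls
  m2 <- rbind(perfect = c(0L, 0L, 0L, 5L, 5L, 5L),
              filler = c(5L, 5L, 5L, 0L, 0L, 0L))
  colnames(m2) <- sprintf("S%d", 1:6)
  iv2 <- indval_scores(make_table(m2), labels)
  expect_equal(iv2$indval[iv2$taxon_id == "perfect" & iv2$group == "drought"], 1)
  expect_equal(iv2$indval[iv2$taxon_id == "perfect" & iv2$group == "control"], 0)

  # equal mean abundance and full occupancy in both groups -> 0.5 each
  m3 <- rbind(flat = c(4L, 4L, 4L, 4L, 4L, 4L), other = c(6L, 6L, 6L, 6L, 6L, 6L))
  colnames(m3) <- sprintf("S%d", 1:6)
  iv3 <- indval_scores(make_table(m3), labels)
  expect_equal(iv3$indval[iv3$taxon_id == "flat"], c(0.5, 0.5))
})

test_that("IndVal group shares sum to one and scores stay within [0, 1]", {
  for (seed in 1:4) {
    ot <- random_table(30, 12, lambda = 8, seed = seed)
    labels <- rep(c("control", "drought"), each = 6)
    iv <- indval_scores(ot, labels)
    sums <- tapply(iv$A, iv$taxon_id, sum)
    present <- rowSums(ot) > 0
    expect_equal(as.vector(sums[names(present)[present]]),
                 rep(1, sum(present)), tolerance = 1e-12)
    expect_true(all(iv$indval >= 0 & iv$indval <= 1))
  }
})

test_that("IndVal is invariant to per-sample depth rescaling", {
  ot <- random_table(20, 10, seed = 6)
  labels <- rep(c("control", "drought"), each = 5)
  iv1 <- indval_scores(ot, labels)
  scaled <- unclass(ot)
  scaled[, 3] <- scaled[, 3] * 7L  # one sample sequenced 7x deeper
  iv2 <- indval_scores(make_table(scaled), labels)
  expect_equal(iv1$indval, iv2$indval, tolerance = 1e-12)
})

test_that("permutation p is exact for a perfectly exclusive taxon", {
  m <- rbind(excl = c(rep(0L, 6), rep(5L, 6)),
             bg1 = rep(c(7L, 3L), 6), bg2 = rep(c(2L, 8L), 6))
  colnames(m) <- sprintf("S%d", 1:12)
  labels <- rep(c("control", "drought"), each = 6)
  ot <- make_table(m)
  perm <- indval_permutation_test(ot, labels, n_perm = 999, seed = 3)
  row <- perm[perm$taxon_id == "excl", ]
  expect_equal(row$indval_max, 1)
  # exact enumeration over all 924 label splits: indval_max = 1 only when the
  # permuted groups reproduce the split (2 of 924 arrangements)
  X <- relative_abundance(ot)["excl", , drop = FALSE]
  p_exact <- oracle_exact_p_two_groups(function(lb) {
    g2 <- lb == "a"
    A <- mean(X[, g2]) / (mean(X[, g2]) + mean(X[, !g2]))
    max(A * mean(X[, g2] > 0), (1 - A) * mean(X[, !g2] > 0))
  }, 6, 6, 1)
  expect_equal(p_exact, 2 / choose(12, 6))
  # Monte-Carlo p agrees within 2 Monte-Carlo SE (plus the +1 correction)
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(row$p_perm - p_exact), 2 * se + 2 / 1000)

  # constant taxon: indval identical under every permutation -> p = 1
  flat <- make_table(rbind(flat = rep(4L, 12), other = rep(6L, 12)))
  pflat <- indval_permutation_test(flat, labels, n_perm = 99, seed = 1)
  expect_equal(pflat$p_perm[pflat$taxon_id == "flat"], 1)
})

test_that("indicator classification applies the p and abundance gates", {
  res <- tibble::tibble(taxon_id = c("a", "b", "c", "d"),
                        best_group = c("drought", "drought", "control", "drought"),
                        indval_max = c(0.9, 0.9, 0.8, 0.9),
                        p_perm = c(0.04, 0.04, 0.01, 0.2))
  m <- rbind(a = c(0L, 0L, 40L, 40L),   # abundant in drought
             b = c(0L, 0L, 1L, 1L),     # significant but rare
             c = c(30L, 30L, 0L, 0L),   # abundant in control
             d = c(0L, 0L, 40L, 40L))   # abundant but not significant
  filler <- matrix(1000L, 1, 4, dimnames = list("bg", NULL))
  ot <- make_table(rbind(m, filler))
  labels <- c("control", "control", "drought", "drought")
  cls <- classify_indicators(res, ot, labels, p_max = 0.05, min_relabund = 0.01)
  expect_equal(cls$class, c("tolerant", "none", "sensitive", "none"))
  # overall-mean abundance gate is the documented alternative
  cls2 <- classify_indicators(res, ot, labels, abundance = "overall")
  expect_equal(cls2$class[1], "tolerant")
})

test_that("planted responders at a 4-fold shift are recovered with correct direction", {
  cfg <- synth_preset("strong_responder", n_taxa = 150, samplings = "end_drought",
                      effect_size = log(4), tolerant_fraction = 0.1,
                      sensitive_fraction = 0.1)
  gen <- generate_community(cfg, seed = 21)
  meta <- align_metadata(gen$table, gen$metadata)
  ind <- indicator_analysis(gen$table, meta$treatment, n_perm = 299, seed = 4)
  truth <- gen$truth$responders
  # among responders abundant enough to pass the 1% gate, >= 90% are
  # classified with the planted direction
  called <- dplyr::inner_join(ind, truth, by = "taxon_id")
  eligible <- called[called$mean_relabund > 0.01, ]
  expect_gt(nrow(eligible), 5)
  expect_gte(mean(eligible$class.x == eligible$class.y), 0.9)
})

test_that("responder proportion comparison behaves at its anchors", {
  # community A: nine taxa double under drought while a single "sink" taxon
  # absorbs the loss (shares must sum to 1, so not every taxon can increase)
  up <- cbind(matrix(10L, 10, 6), rbind(matrix(20L, 9, 6), matrix(0L, 1, 6)))
  # community B: drought columns repeat the control columns -> ties, so no
  # taxon counts as increased
  flat <- cbind(matrix(c(5L, 8L, 12L), 3, 6), matrix(c(5L, 8L, 12L), 3, 6))
  labels <- rep(c("control", "drought"), each = 6)
  ot_up <- make_table(up); ot_flat <- make_table(flat)

  # small-count table: the chi-square approximation note is expected here
  res <- suppressWarnings(responder_proportions(ot_up, labels, ot_flat, labels))
  expect_equal(res$prop_1, 0.9)
  expect_equal(res$prop_2, 0)
  expect_lt(res$p, 1e-2)
  expect_equal(res$effect_direction, "A>B")

  same <- suppressWarnings(responder_proportions(ot_up, labels, ot_up, labels))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
})
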