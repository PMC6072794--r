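#' Two-sided chi-square test of two proportions
#'
#' Pearson chi-square on the 2x2 table of successes/failures, by default
#' without Yates continuity correction (immaterial at the sample sizes these
#' comparisons run at, and matching the closed form
#' chi2 = N (ad - bc)^2 / (row and column margins)).
#'
#' @param k1,n1 Successes and trials in the first sample.
#' @param k2,n2 Successes and trials in the second sample.
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return A one-row tibble: `statistic_name`, `statistic`, `df`, `p`,
#'   `prop_1`, `prop_2`, `effect_direction` (`"A>B"`, `"B>A"`, `"none"`).
#' @export
chi2_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  m <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  ct <- stats::chisq.test(m, correct = correct)
  p1 <- k1 / n1; p2 <- k2 / n2
  tibble::tibble(
    statistic_name = "chi2",
    statistic = unname(ct$statistic),
    df = as.integer(ct$parameter),
    p = max(ct$p.value, .Machine$double.xmin),
    prop_1 = p1, prop_2 = p2,
    effect_direction = if (p1 > p2) "A>B" else if (p2 > p1) "B>A" else "none"
  )
}

#' One-way fixed-effects ANOVA
#'
#' Classical F test of equal group means. When the total sum of squares is
#' zero (all values identical) the 0/0 statistic is reported as F = 0 with
#' p = 1 rather than NaN.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (>= 2 levels, each with >= 2 values).
#' @return A one-row tibble: `statistic_name`, `statistic`, `df1`, `df2`, `p`,
#'   `effect_direction` (for 2 groups; `"none"` otherwise).
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs at least two values", call. = FALSE)
  df1 <- length(tab) - 1L
  df2 <- length(values) - length(tab)
  if (stats::var(values) == 0 || sum((values - mean(values))^2) < 1e-300) {
    return(tibble::tibble(statistic_name = "F", statistic = 0, df1 = df1,
                          df2 = df2, p = 1, effect_direction = "none"))
  }
  fit <- stats::anova(stats::lm(values ~ groups))
  dir <- "none"
  if (length(tab) == 2L) {
    m <- tapply(values, groups, mean)
    dir <- if (m[1L] > m[2L]) "A>B" else if (m[2L] > m[1L]) "B>A" else "none"
  }
  tibble::tibble(statistic_name = "F", statistic = fit$`F value`[1L],
                 df1 = fit$Df[1L], df2 = fit$Df[2L],
                 p = max(fit$`Pr(>F)`[1L], .Machine$double.xmin),
                 effect_direction = dir)
}

#' Two-factor crossed ANOVA with interaction
#'
#' Fixed-effects factorial ANOVA (Type I sequential sums of squares, entered
#' `f1`, then `f2`, then the interaction) for sampling x treatment style
#' contrasts. On unbalanced designs Type I sums depend on entry order, so a
#' warning is issued.
#'
#' @param values Numeric response.
#' @param f1,f2 Crossed factors.
#' @return A tibble with one row per term: `term`, `statistic`, `df1`, `df2`,
#'   `p`.
#' @export
anova_factorial <- function(values, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  stopifnot(length(values) == length(f1), length(values) == length(f2))
  cell_n <- table(f1, f2)
  if (any(cell_n == 0)) stop("empty design cell", call. = FALSE)
  if (length(unique(as.vector(cell_n))) > 1L) {
    warning("unbalanced design: Type I sums of squares in order f1, f2, f1:f2",
            call. = FALSE)
  }
  fit <- stats::anova(stats::lm(values ~ f1 * f2))
  terms <- rownames(fit)
  res <- fit[terms != "Residuals", , drop = FALSE]
  tibble::tibble(term = rownames(res), statistic = res$`F value`,
                 df1 = res$Df, df2 = fit["Residuals", "Df"],
                 p = res$`Pr(>F)`)
}

#' Ordinary least-squares regression of y on x
#'
#' Simple linear regression with the two-sided t test on the slope.
#'
#' @param x,y Numeric vectors (>= 3 points; `x` must vary).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `statistic`
#'   (slope t), `df`, `p`.
#' @export
linreg <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  tibble::tibble(slope = co["x", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 r_squared = sm$r.squared,
                 statistic = co["x", "t value"],
                 df = fit$df.residual,
                 p = co["x", "Pr(>|t|)"])
}

#' Correlate network node abundances with an external covariate
#'
#' For every node of a co-occurrence network, computes the Spearman rank
#' correlation between the taxon's abundance profile and a per-sample
#' covariate (e.g. biomass of a dominant plant species), with a two-sided
#' t-approximation p-value, alongside the node's centrality metrics. A strong
#' abundance-covariate coupling concentrated in central, highly connected
#' nodes marks potential keystone taxa.
#'
#' @param net A `conet` from [threshold_network()].
#' @param table The [otu_table()] the network was built from (same samples).
#' @param covariate Numeric vector, one value per sample of `table` (or named
#'   by sample id).
#' @return A tibble: `taxon_id`, `rho`, `p`, `abs_rho`, `degree`,
#'   `normalised_degree`, `betweenness`.
#' @export
covariate_node_association <- function(net, table, covariate) {
  stopifnot(inherits(net, "conet"))
  if (!is.null(names(covariate))) {
    covariate <- covariate[sample_ids(table)]
  }
  if (length(covariate) != ncol(table) || anyNA(covariate)) {
    stop("covariate must supply one value per sample of the table", call. = FALSE)
  }
  if (stats::var(covariate) == 0) stop("covariate is constant", call. = FALSE)
  nm <- node_metrics(net)
  missing <- setdiff(nm$taxon_id, taxon_ids(table))
  if (length(missing)) stop("network nodes absent from table: ",
                            paste(utils::head(missing, 3L), collapse = ", "), call. = FALSE)
  X <- relative_abundance(table)[nm$taxon_id, , drop = FALSE]
  n <- ncol(X)
  rv <- rank(covariate)
  rho <- apply(X, 1L, function(x) {
    if (stats::var(x) == 0) return(NA_real_)
    stats::cor(rank(x), rv)
  })
  p <- spearman_p(rho, n)
  tibble::tibble(taxon_id = nm$taxon_id, rho = unname(rho), p = unname(p),
                 abs_rho = abs(unname(rho)),
                 degree = nm$degree, normalised_degree = nm$normalised_degree,
                 betweenness = nm$betweenness)
}

#' Does covariate coupling increase with centrality, and differently by group?
#'
#' Regresses |rho| (node-covariate correlation strength from
#' [covariate_node_association()]) on a centrality metric within each of two
#' node sets (e.g. drought vs control networks), and tests whether the slopes
#' differ via the interaction term of the pooled model
#' `abs_rho ~ metric * group` (difference-of-slopes t test).
#'
#' @param assoc_a,assoc_b Tibbles from [covariate_node_association()].
#' @param metric `"normalised_degree"` or `"betweenness"`.
#' @param labels Length-2 character vector naming the groups.
#' @return A list: `slopes` (per-group [linreg()] rows with a `group` column)
#'   and `interaction` (one-row tibble: `estimate`, `statistic`, `df`, `p`).
#' @export
covariate_slope_contrast <- function(assoc_a, assoc_b,
                                     metric = c("normalised_degree", "betweenness"),
                                     labels = c("A", "B")) {
  metric <- match.arg(metric)
  a <- dplyr::filter(assoc_a, !is.na(.data$abs_rho))
  b <- dplyr::filter(assoc_b, !is.na(.data$abs_rho))
  slopes <- dplyr::bind_rows(
    dplyr::mutate(linreg(a[[metric]], a$abs_rho), group = labels[1L], .before = 1L),
    dplyr::mutate(linreg(b[[metric]], b$abs_rho), group = labels[2L], .before = 1L)
  )
  df <- dplyr::bind_rows(
    tibble::tibble(y = a$abs_rho, x = a[[metric]], g = labels[1L]),
    tibble::tibble(y = b$abs_rho, x = b[[metric]], g = labels[2L])
  )
  fit <- stats::lm(y ~ x * g, data = df)
  co <- summary(fit)$coefficients
  term <- grep("^x:", rownames(co), value = TRUE)
  interaction <- tibble::tibble(estimate = co[term, "Estimate"],
                                statistic = co[term, "t value"],
                                df = fit$df.residual,
                                p = co[term, "Pr(>|t|)"])
  list(slopes = slopes, interaction = interaction)
}
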