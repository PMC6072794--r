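#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) over taxa, computed between all
#' sample pairs of the table (via [vegan::vegdist()]). On equal-depth
#' (rarefied) tables this is identical on counts and on relative abundances.
#'
#' @param table An [otu_table()] with at least two samples.
#' @return A `dist` object labelled by sample ids, values in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  if (ncol(table) < 2L) stop("need at least two samples", call. = FALSE)
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(colnames(table)[totals == 0], collapse = ", "), call. = FALSE)
  }
  vegan::vegdist(t(unclass(table)), method = "bray")
}

#' Principal coordinates analysis (classical scaling)
#'
#' Embeds a distance matrix in Euclidean space by double-centring -D^2/2 and
#' eigendecomposing; coordinates are eigenvectors scaled by the square root of
#' their (positive) eigenvalues. Axis scores on Bray-Curtis distances serve as
#' low-dimensional proxies for community composition. Negative eigenvalues
#' (possible for non-Euclidean distances like Bray-Curtis) are reported but
#' their axes are not returned.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param k Number of axes requested (default 2); truncated with a warning if
#'   fewer positive eigenvalues exist.
#' @return A `pcoa_ord` object: list with `scores` (tibble: `sample_id`,
#'   `Axis.1`, ...), `eigenvalues` (all, sorted descending), and
#'   `prop_explained` (relative to the sum of positive eigenvalues).
#' @export
pcoa <- function(d, k = 2) {
  dm <- as.matrix(d)
  ids <- rownames(dm) %||% paste0("s", seq_len(nrow(dm)))
  n <- nrow(dm)
  # double-centred Gower matrix J %*% (-D^2/2) %*% J via sequential sweeps
  B <- -0.5 * dm^2
  B <- sweep(B, 1L, rowMeans(B))
  B <- sweep(B, 2L, colMeans(B))
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  if (length(pos) == 0L) {
    scores <- matrix(0, n, 1L)
    pos <- integer(0)
    k_use <- 1L
    axes <- scores
  } else {
    if (k > length(pos)) {
      warning("only ", length(pos), " positive eigenvalue(s); returning that many axes",
              call. = FALSE)
      k <- length(pos)
    }
    k_use <- k
    axes <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(eig$values[pos[seq_len(k)]]), k)
  }
  colnames(axes) <- paste0("Axis.", seq_len(ncol(axes)))
  structure(list(
    scores = tibble::tibble(sample_id = ids, tibble::as_tibble(axes)),
    eigenvalues = eig$values,
    prop_explained = if (length(pos)) eig$values[pos] / sum(eig$values[pos]) else numeric(0)
  ), class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("<pcoa_ord> %d samples, %d axes", nrow(x$scores), ncol(x$scores) - 1L))
  if (length(x$prop_explained)) {
    cat(sprintf(" (axis 1: %.1f%% of positive inertia)", 100 * x$prop_explained[1L]))
  }
  cat("\n")
  invisible(x)
}

# pseudo-F from squared distances for a given grouping; returns c(F, SSb, SSw)
permanova_F <- function(d2, labels) {
  N <- nrow(d2)
  a <- length(unique(labels))
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    ss_within <- ss_within + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  Fv <- (ss_between / (a - 1)) / (ss_within / (N - a))
  c(F = Fv, ss_between = ss_between, ss_within = ss_within, ss_total = ss_total)
}

#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' The one-factor pseudo-F test of Anderson (the "adonis" test): total and
#' within-group sums of squared distances give
#' F = (SS_between/(a-1)) / (SS_within/(N-a)); significance comes from
#' permuting group labels. The reported p uses the +1 Monte-Carlo correction,
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm), and therefore never returns 0.
#' With `permutations = "exhaustive"` all distinct label arrangements are
#' enumerated (feasible for small N) and the exact p
#' #\{F_perm >= F_obs\} / #arrangements is returned.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param labels Group label per sample (>= 2 groups, each with >= 2 samples).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param permutations `"random"` (default) or `"exhaustive"`.
#' @return A `permanova` object with fields `pseudo_F`, `df_between`,
#'   `df_within`, `R2`, `p`, `n_perm`, `method`.
#' @seealso [vegan::adonis2()] for the multi-factor model-based version.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L,
                      permutations = c("random", "exhaustive")) {
  permutations <- match.arg(permutations)
  dm <- as.matrix(d)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(dm))
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  }
  d2 <- dm^2
  N <- nrow(d2)
  a <- length(tab)
  obs <- permanova_F(d2, labels)
  tol <- abs(obs[["F"]]) * 1e-12 + 1e-300

  if (permutations == "exhaustive") {
    perms <- label_arrangements(labels)
    Fs <- vapply(perms, function(lb) permanova_F(d2, lb)[["F"]], numeric(1))
    p <- mean(Fs >= obs[["F"]] - tol)
    n_used <- length(perms)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      Fp <- permanova_F(d2, labels[sample.int(N)])[["F"]]
      if (Fp >= obs[["F"]] - tol) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(
    pseudo_F = unname(obs[["F"]]),
    df_between = a - 1L, df_within = N - a,
    R2 = unname(obs[["ss_between"]] / obs[["ss_total"]]),
    p = p, n_perm = n_used, method = permutations
  ), class = "permanova")
}

# all distinct arrangements of a label multiset (2 groups via combinations,
# otherwise all N! index permutations — only sensible for small N)
label_arrangements <- function(labels) {
  N <- length(labels)
  lv <- unique(labels)
  if (length(lv) == 2L) {
    n1 <- sum(labels == lv[1L])
    combos <- utils::combn(N, n1)
    lapply(seq_len(ncol(combos)), function(j) {
      lb <- rep(lv[2L], N)
      lb[combos[, j]] <- lv[1L]
      lb
    })
  } else {
    if (N > 8L) stop("exhaustive enumeration limited to N <= 8 for >2 groups", call. = FALSE)
    perms <- all_permutations(N)
    lapply(perms, function(idx) labels[idx])
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F(%d, %d) = %.4g, R2 = %.3f, p = %.4g (%s, %d perms)\n",
              x$df_between, x$df_within, x$pseudo_F, x$R2, x$p, x$method, x$n_perm))
  invisible(x)
}

#' Control-drought community similarity (resistance / resilience)
#'
#' For every sampling time, pairs control with drought samples and reports
#' their Bray-Curtis similarity (1 - dissimilarity). During the disturbance
#' this measures resistance; afterwards, its recovery towards pre-disturbance
#' levels measures resilience. With `pairing = "matched"` (default) a control
#' and a drought sample are paired when they share `block` and, when present,
#' `plant_treatment` — mirroring a split-block design; unmatched samples are
#' skipped with a message. `"all_pairs"` crosses every control with every
#' drought sample within a sampling. A one-way ANOVA of similarity across
#' samplings is attached.
#'
#' @param table An [otu_table()] (rarefied).
#' @param meta Metadata for the table's samples (see [read_metadata()]).
#' @param pairing `"matched"` or `"all_pairs"`.
#' @return A `resilience` object: list with `pairs` (tibble: `sampling`,
#'   `control_sample`, `drought_sample`, `similarity`) and `anova`
#'   (tibble from [anova_oneway()], or NULL if fewer than 2 samplings).
#' @export
resilience_similarity <- function(table, meta, pairing = c("matched", "all_pairs")) {
  pairing <- match.arg(pairing)
  meta <- align_metadata(table, meta)
  dm <- as.matrix(bray_curtis(table))
  rows <- list()
  for (sm in levels(meta$sampling)) {
    sub <- meta[meta$sampling == sm, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ctrl <- sub[sub$treatment == "control", , drop = FALSE]
    drt <- sub[sub$treatment == "drought", , drop = FALSE]
    if (nrow(ctrl) == 0L || nrow(drt) == 0L) next
    if (pairing == "matched") {
      key <- function(x) {
        if ("plant_treatment" %in% names(x)) paste(x$block, x$plant_treatment) else as.character(x$block)
      }
      kc <- key(ctrl); kd <- key(drt)
      hit <- match(kc, kd)
      if (anyNA(hit)) {
        message("resilience_similarity: ", sum(is.na(hit)),
                " unmatched control sample(s) at ", sm)
      }
      pairs <- tibble::tibble(control_sample = ctrl$sample_id[!is.na(hit)],
                              drought_sample = drt$sample_id[hit[!is.na(hit)]])
    } else {
      pairs <- tidyr::expand_grid(control_sample = ctrl$sample_id,
                                  drought_sample = drt$sample_id)
    }
    if (nrow(pairs) == 0L) next
    pairs$similarity <- 1 - dm[cbind(pairs$control_sample, pairs$drought_sample)]
    pairs$sampling <- sm
    rows[[sm]] <- pairs
  }
  pairs <- dplyr::bind_rows(rows)
  if (nrow(pairs) == 0L) stop("no control-drought pairs found", call. = FALSE)
  pairs <- dplyr::select(pairs, "sampling", "control_sample", "drought_sample", "similarity")
  pairs$sampling <- factor(pairs$sampling, levels = .sampling_levels, ordered = TRUE)
  an <- NULL
  if (length(unique(pairs$sampling)) >= 2L && all(table(pairs$sampling) >= 2L)) {
    an <- anova_oneway(pairs$similarity, pairs$sampling)
  }
  structure(list(pairs = pairs, anova = an), class = "resilience")
}

#' @export
print.resilience <- function(x, ...) {
  s <- dplyr::summarise(dplyr::group_by(x$pairs, .data$sampling),
                        mean_similarity = mean(.data$similarity), n = dplyr::n())
  print(s)
  if (!is.null(x$anova)) {
    cat(sprintf("sampling effect: F(%d, %d) = %.3g, p = %.3g\n",
                x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p))
  }
  invisible(x)
}
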