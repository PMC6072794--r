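#' Tidiers for conetstab result objects
#'
#' broom-style `tidy()` (one row per element) and `glance()` (one-row summary)
#' methods, so results drop straight into dplyr/ggplot2 workflows.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name conetstab-tidiers
NULL

#' @rdname conetstab-tidiers
#' @export
tidy.permanova <- function(x, ...) {
  tibble::tibble(term = "groups", df = x$df_between, pseudo_F = x$pseudo_F,
                 R2 = x$R2, p = x$p)
}

#' @rdname conetstab-tidiers
#' @export
glance.permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, df_between = x$df_between,
                 df_within = x$df_within, R2 = x$R2, p = x$p,
                 n_perm = x$n_perm, method = x$method)
}

#' @rdname conetstab-tidiers
#' @export
tidy.correlation_set <- function(x, ...) {
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  ids <- rownames(x$rho)
  tibble::tibble(taxon_a = ids[idx[, 1L]], taxon_b = ids[idx[, 2L]],
                 rho = x$rho[idx], p = x$p[idx])
}

#' @rdname conetstab-tidiers
#' @export
glance.correlation_set <- function(x, ...) correlation_summary(x)

#' @rdname conetstab-tidiers
#' @export
tidy.conet <- function(x, ...) node_metrics(x)

#' @rdname conetstab-tidiers
#' @export
glance.conet <- function(x, ...) network_summary(x)

#' @rdname conetstab-tidiers
#' @export
tidy.resilience <- function(x, ...) x$pairs

#' @rdname conetstab-tidiers
#' @export
glance.resilience <- function(x, ...) {
  s <- dplyr::summarise(dplyr::group_by(x$pairs, .data$sampling),
                        mean_similarity = mean(.data$similarity),
                        n_pairs = dplyr::n(), .groups = "drop")
  out <- tidyr::pivot_wider(s, names_from = "sampling",
                            values_from = c("mean_similarity", "n_pairs"))
  if (!is.null(x$anova)) {
    out$F_sampling <- x$anova$statistic
    out$p_sampling <- x$anova$p
  }
  out
}

#' @rdname conetstab-tidiers
#' @export
tidy.pcoa_ord <- function(x, ...) x$scores

#' @rdname conetstab-tidiers
#' @export
glance.pcoa_ord <- function(x, ...) {
  tibble::tibble(n_axes = ncol(x$scores) - 1L,
                 n_positive_eig = sum(x$eigenvalues > 0),
                 n_negative_eig = sum(x$eigenvalues < 0),
                 prop_axis1 = if (length(x$prop_explained)) x$prop_explained[1L] else NA_real_)
}

#' @rdname conetstab-tidiers
#' @export
tidy.null_model_result <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_values),
                 null_clustering = x$null_values)
}

#' @rdname conetstab-tidiers
#' @export
glance.null_model_result <- function(x, ...) {
  tibble::tibble(observed_clustering = x$observed_clustering,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 empirical_p = x$empirical_p, ensemble_size = x$ensemble_size)
}
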