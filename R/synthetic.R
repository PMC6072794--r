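#' Configuration for the synthetic community generator
#'
#' The generator emulates the statistical structure the analysis chain
#' assumes: taxa co-oscillate through shared latent factors (the mechanism
#' behind positive co-occurrence), antagonistic pairs load on a factor with
#' opposite signs, and treatment responders shift their mean log abundance
#' under drought. Per sample s, taxon i:
#' log a_is = mu_i + delta_i * decay(sampling) * 1\[drought\] + sum_k lambda_ik f_ks + eps_is
#' with f_ks ~ N(0,1), eps_is ~ N(0, sigma^2), mu_i ~ N(0, mu_sd^2); read
#' counts are Multinomial(depth, a_.s / sum a_.s), so compositional closure is
#' present exactly as in rarefied real tables.
#'
#' @param organism_tag Tag for the generated table.
#' @param n_taxa,n_factors Numbers of taxa and latent factors (>= 2, >= 1).
#' @param loaded_fraction Fraction of taxa assigned a primary factor loading;
#'   primary factors are dealt round-robin, so factors form equal-size blocks
#'   (the planted modules).
#' @param hub_fraction Fraction of the loaded taxa that also receive a second
#'   factor ("hub" taxa bridging two blocks).
#' @param global_fraction Fraction of the loaded taxa that additionally load
#'   on factor 1, a shared "environmental" factor driving community-wide
#'   co-oscillation (when > 0, primary blocks use factors 2..K only). Many
#'   taxa responding in tandem to a common driver is the signature of a
#'   tightly coupled, potentially unstable community.
#' @param global_loading Magnitude of the shared-factor loading.
#' @param global_loading_spread Relative half-width of the uniform spread of
#'   shared-factor loading magnitudes (0 = all equal). A spread produces a
#'   graded core-periphery guild: strongly loading taxa correlate with almost
#'   everyone in the guild, weakly loading ones only with the core.
#' @param global_mu_boost Added to the baseline log abundance of shared-factor
#'   taxa: the co-oscillating guild is drawn from the dominant part of the
#'   community, as abundant taxa both drive and dominate co-occurrence
#'   networks.
#' @param loading_mean,loading_sd Mean and SD of primary loading magnitudes.
#' @param loaded_mu_shift Added to the baseline log abundance of all loaded
#'   taxa (negative values down-weight the coupled guilds' share of reads,
#'   limiting the compositional footprint of their co-oscillation).
#' @param hub_loading Magnitude of the secondary loading of hub taxa.
#' @param neg_fraction Probability that any given loading is negative
#'   (antagonistic coupling).
#' @param sigma Residual log-abundance noise SD.
#' @param mu_sd SD of baseline log abundances (log-normal abundance spread).
#' @param depth Reads per sample (>= 100).
#' @param n_per_cell Mesocosms per treatment arm; every sampling revisits the
#'   same mesocosms (default 36).
#' @param n_blocks Number of experimental blocks the mesocosms are spread
#'   over (default 4); block and plant-community treatment jointly identify a
#'   mesocosm for matched control-drought pairing.
#' @param treatments,samplings Which design cells to generate.
#' @param tolerant_fraction,sensitive_fraction Fractions of taxa that
#'   increase / decrease under drought.
#' @param effect_size Drought shift of responder log abundance (log-fold
#'   units; default log(4), i.e. a 4-fold shift).
#' @param effect_decay Named multipliers of `effect_size` per sampling;
#'   defaults to 0 before drought, 1 at the end of drought, then decaying
#'   (0.5, 0.25) to emulate recovery.
#' @return A `synth_config` list.
#' @export
synth_config <- function(organism_tag = "other",
                         n_taxa = 400, n_factors = 10,
                         loaded_fraction = 0.5, hub_fraction = 0,
                         global_fraction = 0, global_loading = 1.2,
                         global_loading_spread = 0, global_mu_boost = 0,
                         loading_mean = 1.0, loading_sd = 0.1,
                         hub_loading = 1.0, loaded_mu_shift = 0,
                         neg_fraction = 0, sigma = 0.3, mu_sd = 1,
                         depth = 4000, n_per_cell = 36, n_blocks = 4,
                         treatments = c("control", "drought"),
                         samplings = .sampling_levels,
                         tolerant_fraction = 0, sensitive_fraction = 0,
                         effect_size = log(4),
                         effect_decay = c(pre_drought = 0, end_drought = 1,
                                          early_recovery = 0.5, late_recovery = 0.25)) {
  cfg <- as.list(environment())
  check <- function(ok, field) if (!ok) stop("invalid synth_config field: ", field, call. = FALSE)
  check(cfg$n_taxa >= 2, "n_taxa")
  check(cfg$n_factors >= 1, "n_factors")
  check(cfg$depth >= 100, "depth")
  check(cfg$loaded_fraction >= 0 && cfg$loaded_fraction <= 1, "loaded_fraction")
  check(cfg$hub_fraction >= 0 && cfg$hub_fraction <= 1, "hub_fraction")
  check(cfg$global_fraction >= 0 && cfg$global_fraction <= 1, "global_fraction")
  check(cfg$global_fraction == 0 || cfg$n_factors >= 2, "global_fraction")
  check(cfg$global_loading_spread >= 0 && cfg$global_loading_spread < 1, "global_loading_spread")
  check(cfg$neg_fraction >= 0 && cfg$neg_fraction <= 1, "neg_fraction")
  check(cfg$sigma > 0, "sigma")
  check(cfg$n_per_cell >= 1, "n_per_cell")
  check(all(cfg$treatments %in% .treatment_levels), "treatments")
  check(all(cfg$samplings %in% .sampling_levels), "samplings")
  check(cfg$tolerant_fraction + cfg$sensitive_fraction <= 1, "tolerant_fraction")
  check(all(cfg$samplings %in% names(cfg$effect_decay)), "effect_decay")
  class(cfg) <- "synth_config"
  cfg
}

#' Named generator presets
#'
#' Ready-made configurations for the community archetypes the package is
#' validated against:
#' * `"bacteria_like"` — ~2000 taxa, many factors with dense, strong loadings,
#'   bridging hub taxa, 15% antagonistic loadings: rich, tightly coupled
#'   communities of the kind 16S tables show.
#' * `"fungi_like"` — ~400 taxa, fewer factors, sparser and weaker loadings,
#'   5% antagonistic: looser ITS-style communities.
#' * `"strong_coupling"` — 150 taxa, 25 planted pairs at loading 1.2 and
#'   sigma 0.3 (population log-scale correlation 0.94), planted taxa
#'   down-weighted in abundance to limit their compositional footprint: the
#'   edge-recovery benchmark.
#' * `"strong_responder"` — 30% of taxa respond to drought at 1.5 log-fold
#'   units: the ordination/resilience benchmark.
#' * `"planted_modules"` — five clean 12-taxon factor blocks: the module
#'   recovery benchmark.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_preset <- function(name = c("bacteria_like", "fungi_like", "strong_coupling",
                                  "strong_responder", "planted_modules"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    bacteria_like = list(organism_tag = "bacteria_like", n_taxa = 2000,
                         n_factors = 40, loaded_fraction = 0.7,
                         hub_fraction = 0.1, global_fraction = 0.3,
                         global_loading = 2.0, global_loading_spread = 0.5,
                         global_mu_boost = 2.6, loading_mean = 0.9,
                         loading_sd = 0.15, hub_loading = 0.9,
                         neg_fraction = 0.15, sigma = 0.3, mu_sd = 1,
                         tolerant_fraction = 0.08, sensitive_fraction = 0.12),
    fungi_like = list(organism_tag = "fungi_like", n_taxa = 400,
                      n_factors = 15, loaded_fraction = 0.3,
                      hub_fraction = 0, loading_mean = 0.85,
                      loading_sd = 0.15, neg_fraction = 0.05,
                      sigma = 0.375, mu_sd = 1,
                      tolerant_fraction = 0.12, sensitive_fraction = 0.08),
    strong_coupling = list(organism_tag = "other", n_taxa = 150, n_factors = 25,
                           loaded_fraction = 1 / 3, hub_fraction = 0,
                           loading_mean = 1.2, loading_sd = 0,
                           loaded_mu_shift = -1.2,
                           neg_fraction = 0, sigma = 0.3, mu_sd = 0.5,
                           treatments = "control", samplings = "pre_drought"),
    strong_responder = list(organism_tag = "other", n_taxa = 300, n_factors = 8,
                            loaded_fraction = 0.4, hub_fraction = 0,
                            loading_mean = 0.9, loading_sd = 0.15,
                            neg_fraction = 0.05, sigma = 0.4, mu_sd = 1,
                            tolerant_fraction = 0.15, sensitive_fraction = 0.15,
                            effect_size = 1.5),
    planted_modules = list(organism_tag = "other", n_taxa = 60, n_factors = 5,
                           loaded_fraction = 1, hub_fraction = 0,
                           loading_mean = 1.2, loading_sd = 0.1,
                           neg_fraction = 0, sigma = 0.3, mu_sd = 0.5,
                           treatments = "control", samplings = "pre_drought")
  )
  do.call(synth_config, utils::modifyList(base, list(...)))
}

#' Generate a synthetic community with ground truth
#'
#' Draws baseline abundances, factor loadings and responder assignments, then
#' simulates every sample of the configured design and multinomially samples
#' reads. Identical (config, seed) pairs reproduce identical output.
#'
#' @param config A [synth_config()] or [synth_preset()].
#' @param seed Integer seed for all randomness.
#' @return A list: `table` ([otu_table()]), `metadata` (validated tibble with
#'   `block` and `plant_treatment`), `truth` (`synth_truth`: `lambda` loading
#'   matrix, `factor_primary`, `mu`, `responders` tibble, `config`, `seed`).
#' @export
generate_community <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  T <- config$n_taxa; K <- config$n_factors
  ids <- sprintf("OTU%04d", seq_len(T))

  mu <- stats::rnorm(T, 0, config$mu_sd)
  lambda <- matrix(0, T, K, dimnames = list(ids, paste0("F", seq_len(K))))
  n_loaded <- round(config$loaded_fraction * T)
  loaded <- if (n_loaded > 0) sort(sample.int(T, n_loaded)) else integer(0)
  factor_primary <- rep(NA_integer_, T)
  if (n_loaded > 0) {
    mu[loaded] <- mu[loaded] + config$loaded_mu_shift
    has_global <- config$global_fraction > 0
    block_factors <- if (has_global) 2L:K else seq_len(K)
    factor_primary[loaded] <- block_factors[rep_len(seq_along(block_factors), n_loaded)]
    mag <- pmax(stats::rnorm(n_loaded, config$loading_mean, config$loading_sd), 0.1)
    sign <- ifelse(stats::runif(n_loaded) < config$neg_fraction, -1, 1)
    lambda[cbind(loaded, factor_primary[loaded])] <- mag * sign
    n_hub <- round(config$hub_fraction * n_loaded)
    if (n_hub > 0) {
      hubs <- sample(loaded, n_hub)
      second <- factor_primary[hubs] %% K + 1L  # a different factor
      if (has_global) second <- pmax(second, 2L)
      hsign <- ifelse(stats::runif(n_hub) < config$neg_fraction, -1, 1)
      lambda[cbind(hubs, second)] <- config$hub_loading * hsign
    }
    n_glob <- round(config$global_fraction * n_loaded)
    if (n_glob > 0) {
      # the shared environmental factor is carried by the dominant community
      # fraction: abundant taxa drive community-wide co-oscillation
      glob <- loaded[order(mu[loaded], decreasing = TRUE)][seq_len(n_glob)]
      gsign <- ifelse(stats::runif(n_glob) < config$neg_fraction, -1, 1)
      gmag <- config$global_loading *
        stats::runif(n_glob, 1 - config$global_loading_spread,
                     1 + config$global_loading_spread)
      lambda[glob, 1L] <- gmag * gsign
      mu[glob] <- mu[glob] + config$global_mu_boost
    }
  }

  delta <- rep(0, T)
  n_tol <- round(config$tolerant_fraction * T)
  n_sen <- round(config$sensitive_fraction * T)
  resp_idx <- sample.int(T, n_tol + n_sen)
  tol_idx <- resp_idx[seq_len(n_tol)]
  sen_idx <- resp_idx[n_tol + seq_len(n_sen)]
  delta[tol_idx] <- config$effect_size
  delta[sen_idx] <- -config$effect_size
  responders <- tibble::tibble(
    taxon_id = ids[resp_idx],
    class = c(rep("tolerant", n_tol), rep("sensitive", n_sen)),
    delta = delta[resp_idx]
  )

  n_plant <- ceiling(config$n_per_cell / config$n_blocks)
  meso <- tibble::tibble(
    mesocosm = seq_len(config$n_per_cell),
    block = ((seq_len(config$n_per_cell) - 1L) %% config$n_blocks) + 1L,
    plant_treatment = sprintf("P%d", ((seq_len(config$n_per_cell) - 1L) %/% config$n_blocks) + 1L)
  )
  abbr <- c(pre_drought = "pre", end_drought = "end",
            early_recovery = "rec1", late_recovery = "rec2")
  design <- tidyr::expand_grid(
    sampling = factor(config$samplings, levels = .sampling_levels, ordered = TRUE),
    treatment = factor(config$treatments, levels = .treatment_levels),
    meso
  )
  design$sample_id <- sprintf("%s%02d_%s",
                              ifelse(design$treatment == "drought", "D", "C"),
                              design$mesocosm, abbr[as.character(design$sampling)])

  counts <- matrix(0L, T, nrow(design), dimnames = list(ids, design$sample_id))
  for (s in seq_len(nrow(design))) {
    f <- stats::rnorm(K)
    eps <- stats::rnorm(T, 0, config$sigma)
    shift <- if (design$treatment[s] == "drought") {
      delta * config$effect_decay[[as.character(design$sampling[s])]]
    } else 0
    loga <- mu + shift + as.vector(lambda %*% f) + eps
    pr <- exp(loga - max(loga))
    counts[, s] <- stats::rmultinom(1L, config$depth, pr)
  }

  metadata <- validate_metadata(tibble::tibble(
    sample_id = design$sample_id, treatment = as.character(design$treatment),
    sampling = as.character(design$sampling), block = design$block,
    plant_treatment = design$plant_treatment, mesocosm = design$mesocosm
  ))
  truth <- structure(list(lambda = lambda, factor_primary = factor_primary,
                          mu = mu, sigma = config$sigma, responders = responders,
                          config = config, seed = seed), class = "synth_truth")
  list(table = otu_table(counts, config$organism_tag),
       metadata = metadata, truth = truth)
}

#' Taxon pairs expected to correlate under the planted factor model
#'
#' From the loading matrix the population covariance of log abundances is
#' Lambda Lambda' + sigma^2 I; pairs whose population correlation exceeds
#' `rho_min` in magnitude are the edges the generator planted. For two taxa
#' sharing a single factor with loadings lambda_1, lambda_2 this reduces to
#' lambda_1 lambda_2 / sqrt((lambda_1^2 + sigma^2)(lambda_2^2 + sigma^2)).
#'
#' @param truth A `synth_truth` from [generate_community()].
#' @param rho_min Magnitude threshold (default 0.6).
#' @return A tibble: `taxon_a`, `taxon_b`, `expected_rho`, `sign`
#'   (`"positive"` / `"negative"`).
#' @export
expected_edges <- function(truth, rho_min = 0.6) {
  stopifnot(inherits(truth, "synth_truth"))
  S <- tcrossprod(truth$lambda)
  diag(S) <- diag(S) + truth$sigma^2
  sds <- sqrt(diag(S))
  C <- S / tcrossprod(sds)
  idx <- which(upper.tri(C) & abs(C) > rho_min, arr.ind = TRUE)
  ids <- rownames(truth$lambda)
  tibble::tibble(taxon_a = ids[idx[, 1L]], taxon_b = ids[idx[, 2L]],
                 expected_rho = C[idx],
                 sign = ifelse(C[idx] > 0, "positive", "negative"))
}

#' @export
print.synth_truth <- function(x, ...) {
  cat(sprintf("<synth_truth> %d taxa, %d factors, %d responders, sigma = %.2f\n",
              nrow(x$lambda), ncol(x$lambda), nrow(x$responders), x$sigma))
  invisible(x)
}
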