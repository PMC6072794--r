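#' Configuration for a full pipeline run
#'
#' Bundles every threshold of the analysis chain with the generator presets
#' (or input file paths) and the master seed, so a run is reproducible from
#' the config alone. Defaults follow the standard chain: rarefaction depth
#' 4000, taxa with fewer than 10 reads excluded, prevalence >= 8 samples per
#' network cell, edges at rho > 0.6 and p < 0.01, indicators at p < 0.05 and
#' > 1% abundance.
#'
#' @param out_dir Output directory (created if needed).
#' @param communities Named list. Each element is either a [synth_config()] /
#'   [synth_preset()] (community is simulated) or a list with `otu` and
#'   `metadata` file paths plus an `organism_tag`.
#' @param seed Master seed; every stochastic stage derives its own seed from it.
#' @param depth,min_total,max_H,min_occurrence Preprocessing thresholds;
#'   `max_H` (Shannon ceiling in nats, e.g. 6 for 16S and 3.2 for ITS data)
#'   may be a single value, a vector named by community, or NULL to skip the
#'   outlier filter.
#' @param rho_min,p_max Network edge thresholds.
#' @param indicator_p_max,indicator_min_relabund,n_perm_indval Indicator
#'   analysis settings.
#' @param n_perm_permanova Permutations for the treatment PERMANOVA.
#' @param null_ensemble Random graphs per network null comparison (0 skips).
#' @param pairing Control-drought pairing for resilience
#'   (`"matched"`/`"all_pairs"`).
#' @param run_indicators Run the (permutation-heavy) indicator analysis.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            communities = list(bacteria = synth_preset("bacteria_like"),
                                               fungi = synth_preset("fungi_like")),
                            seed = 1L, depth = 4000, min_total = 10,
                            max_H = NULL, min_occurrence = 8,
                            rho_min = 0.6, p_max = 0.01,
                            indicator_p_max = 0.05, indicator_min_relabund = 0.01,
                            n_perm_indval = 1000, n_perm_permanova = 999,
                            null_ensemble = 1000,
                            pairing = c("matched", "all_pairs"),
                            run_indicators = TRUE) {
  pairing <- match.arg(pairing)
  cfg <- as.list(environment())
  if (is.null(names(cfg$communities)) || any(!nzchar(names(cfg$communities)))) {
    stop("communities must be a named list", call. = FALSE)
  }
  stopifnot(rho_min > 0, rho_min < 1, p_max > 0, p_max <= 1, depth >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

max_H_for <- function(cfg, name) {
  h <- cfg$max_H
  if (is.null(h)) return(NULL)
  if (!is.null(names(h))) {
    if (name %in% names(h)) return(h[[name]]) else return(NULL)
  }
  h[[1L]]
}

#' Run the full analysis pipeline
#'
#' For every configured community: simulate (or read) the OTU table, apply the
#' quality filters, compute diversity, resilience, the per-sampling treatment
#' PERMANOVA and (optionally) indicator analysis, then build one co-occurrence
#' network per treatment x sampling cell — prevalence filter, all-pairs
#' Spearman correlations, thresholding, node metrics, modules and the random
#' graph null — and write everything as TSV/GraphML plus a JSON report. When
#' two or more communities are configured, their networks are compared cell by
#' cell (inclusion proportions and negative-correlation proportions by
#' chi-square) and their responder proportions per post-drought sampling.
#'
#' The run is a pure function of (config, inputs): rerunning an identical
#' config reproduces identical outputs. Any stage failure aborts the run,
#' names the stage, and removes the partial output directory.
#'
#' @param config A [pipeline_config()].
#' @return The report (a nested list, also written to `report.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  report <- list(seed = config$seed, communities = list(), comparisons = list())
  state <- list()  # per community: filtered table, metadata, summaries

  result <- tryCatch({
    for (name in names(config$communities)) {
      spec <- config$communities[[name]]
      cdir <- file.path(out, name)
      dir.create(cdir, showWarnings = FALSE)
      log <- list()

      stage <- paste0(name, ":input")
      if (inherits(spec, "synth_config")) {
        gen <- generate_community(spec, seed = config$seed + 1000L * match(name, names(config$communities)))
        tbl <- gen$table; meta <- gen$metadata
      } else {
        tbl <- read_otu_table(spec$otu, organism_tag = spec$organism_tag %||% "other")
        meta <- read_metadata(spec$metadata)
      }
      log$taxa_in <- n_taxa(tbl); log$samples_in <- n_samples(tbl)

      stage <- paste0(name, ":preprocess")
      tbl <- rarefy(tbl, depth = config$depth, seed = config$seed)
      log$samples_after_rarefy <- n_samples(tbl)
      tbl <- filter_low_count_taxa(tbl, min_total = config$min_total)
      log$taxa_after_low_count <- n_taxa(tbl)
      mh <- max_H_for(config, name)
      if (!is.null(mh)) tbl <- filter_shannon_outliers(tbl, max_H = mh)
      log$samples_after_shannon <- n_samples(tbl)
      meta <- align_metadata(tbl, meta)

      stage <- paste0(name, ":diversity")
      div <- diversity_metrics(tbl)
      readr::write_tsv(dplyr::inner_join(div, meta, by = "sample_id"),
                       file.path(cdir, "diversity.tsv"))

      stage <- paste0(name, ":resilience")
      resil <- NULL
      if (length(unique(meta$treatment)) == 2L) {
        resil <- resilience_similarity(tbl, meta, pairing = config$pairing)
        readr::write_tsv(resil$pairs, file.path(cdir, "resilience.tsv"))
      }

      stage <- paste0(name, ":permanova")
      permas <- list()
      for (sm in unique(as.character(meta$sampling))) {
        sel <- meta$sampling == sm
        if (length(unique(meta$treatment[sel])) < 2L) next
        sub <- otu_subset(tbl, samples = which(sel))
        pm <- permanova(bray_curtis(sub), meta$treatment[sel],
                        n_perm = config$n_perm_permanova, seed = config$seed + 7L)
        permas[[sm]] <- glance(pm)
      }

      stage <- paste0(name, ":indicators")
      indicators <- list()
      if (config$run_indicators) {
        for (sm in unique(as.character(meta$sampling))) {
          sel <- meta$sampling == sm
          if (length(unique(meta$treatment[sel])) < 2L) next
          sub <- otu_subset(tbl, samples = which(sel))
          ind <- indicator_analysis(sub, meta$treatment[sel],
                                    n_perm = config$n_perm_indval,
                                    seed = config$seed + 11L,
                                    p_max = config$indicator_p_max,
                                    min_relabund = config$indicator_min_relabund)
          readr::write_tsv(ind, file.path(cdir, paste0("indicators_", sm, ".tsv")))
          indicators[[sm]] <- ind
        }
      }

      stage <- paste0(name, ":networks")
      summaries <- list(); csummaries <- list(); nets <- list()
      for (sm in unique(as.character(meta$sampling))) {
        for (trt in unique(as.character(meta$treatment))) {
          sel <- meta$sampling == sm & meta$treatment == trt
          if (sum(sel) < 4L) next
          cell <- paste(trt, sm, sep = "_")
          sub <- prevalence_filter(otu_subset(tbl, samples = which(sel)),
                                   min_occurrence = config$min_occurrence)
          if (n_taxa(sub) < 2L) next
          cset <- spearman_matrix(sub, label = paste(name, cell))
          csummaries[[cell]] <- correlation_summary(cset, config$rho_min, config$p_max)
          cls <- NULL
          if (!is.null(indicators[[sm]])) {
            cls <- stats::setNames(indicators[[sm]]$class, indicators[[sm]]$taxon_id)
          }
          net <- suppressWarnings(
            threshold_network(cset, rho_min = config$rho_min, p_max = config$p_max,
                              table = sub, indicator_class = cls))
          net <- detect_modules(net)
          nets[[cell]] <- net
          nm <- node_metrics(net)
          readr::write_tsv(nm, file.path(cdir, paste0("nodes_", cell, ".tsv")))
          write_network(net, file.path(cdir, paste0("network_", cell, ".tsv")),
                        "edge_list_tsv")
          if (igraph::ecount(net$graph) > 0L) {
            write_network(net, file.path(cdir, paste0("network_", cell, ".graphml")),
                          "graphml")
          }
          smry <- network_summary(net)
          if (config$null_ensemble > 0L && igraph::ecount(net$graph) > 0L) {
            nullr <- random_network_null(net, ensemble = config$null_ensemble,
                                         seed = config$seed + 13L)
            smry$null_clustering_mean <- nullr$null_mean
            smry$null_p <- nullr$empirical_p
          }
          summaries[[cell]] <- smry
        }
      }
      net_tbl <- dplyr::bind_rows(summaries, .id = "cell")
      if (nrow(net_tbl)) readr::write_tsv(net_tbl, file.path(cdir, "networks.tsv"))

      stage <- paste0(name, ":membership")
      overlap <- list()
      for (trt in unique(as.character(meta$treatment))) {
        cells <- paste(trt, .sampling_levels, sep = "_")
        cells <- cells[cells %in% names(nets)]
        if (length(cells) >= 2L) {
          for (i in seq_len(length(cells) - 1L)) {
            overlap[[paste(cells[i], cells[i + 1L], sep = " -> ")]] <-
              membership_overlap(nets[[cells[i]]], nets[[cells[i + 1L]]])
          }
        }
      }

      report$communities[[name]] <- list(
        log = log,
        permanova = permas,
        resilience = if (!is.null(resil)) glance(resil) else NULL,
        networks = net_tbl,
        correlations = dplyr::bind_rows(csummaries, .id = "cell"),
        membership_overlap = overlap
      )
      state[[name]] <- list(table = tbl, meta = meta)
    }

    stage <- "comparisons"
    if (length(state) >= 2L) {
      nm <- names(state)[1:2]
      a <- report$communities[[nm[1L]]]; b <- report$communities[[nm[2L]]]
      comp <- list()
      shared <- intersect(a$networks$cell, b$networks$cell)
      for (cell in shared) {
        ra <- a$networks[a$networks$cell == cell, ]
        rb <- b$networks[b$networks$cell == cell, ]
        comp[[cell]] <- list(inclusion = glance_chi2(
          ra$nodes, round(ra$nodes / ra$inclusion_proportion),
          rb$nodes, round(rb$nodes / rb$inclusion_proportion)))
      }
      # responder proportions per post-drought sampling
      resp <- list()
      for (sm in c("end_drought", "early_recovery", "late_recovery")) {
        ok <- vapply(state[nm], function(s) {
          sel <- s$meta$sampling == sm
          length(unique(s$meta$treatment[sel])) == 2L
        }, logical(1))
        if (!all(ok)) next
        sub <- lapply(state[nm], function(s) {
          sel <- which(s$meta$sampling == sm)
          list(tbl = otu_subset(s$table, samples = sel),
               lab = s$meta$treatment[sel])
        })
        resp[[sm]] <- responder_proportions(sub[[1L]]$tbl, sub[[1L]]$lab,
                                            sub[[2L]]$tbl, sub[[2L]]$lab)
      }
      report$comparisons <- list(by_cell = comp, responders = resp,
                                 communities = nm)
    }

    stage <- "report"
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    report
  }, error = function(e) {
    unlink(out, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# chi-square on two node-count/eligible-count pairs, tolerant of empty nets
glance_chi2 <- function(k1, n1, k2, n2) {
  out <- tryCatch(chi2_proportions(k1, n1, k2, n2),
                  error = function(e) tibble::tibble(
                    statistic_name = "chi2", statistic = NA_real_,
                    df = NA_integer_, p = NA_real_,
                    prop_1 = k1 / n1, prop_2 = k2 / n2,
                    effect_direction = NA_character_))
  out
}
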