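#' Rarefy an OTU table to a fixed read depth
#'
#' Subsamples each sample's reads without replacement down to `depth`, the
#' standard way of removing library-size differences before diversity and
#' correlation analysis. Samples with fewer than `depth` total reads are
#' dropped (and reported via a message). Each sample's subsample is drawn with
#' its own RNG seed derived from the global `seed` and a hash of the sample id,
#' so results do not depend on sample order.
#'
#' @param table An [otu_table()].
#' @param depth Target reads per sample (default 4000).
#' @param seed Integer seed governing all subsampling.
#' @return A rarefied [otu_table()] whose columns each sum to `depth`.
#' @export
rarefy <- function(table, depth = 4000, seed = 1L) {
  stopifnot(depth >= 1)
  totals <- colSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("no samples survive rarefaction at depth ", depth, call. = FALSE)
  if (any(!keep)) {
    message("rarefy: dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(colnames(table)[!keep], collapse = ", "))
  }
  m <- unclass(table)[, keep, drop = FALSE]
  out <- m
  for (j in seq_len(ncol(m))) {
    if (totals[keep][j] == depth) next  # already at depth: keep as is
    counts <- m[, j]
    pool <- rep.int(seq_along(counts), counts)
    set.seed(sample_seed(seed, colnames(m)[j]))
    take <- pool[sample.int(length(pool), depth)]
    out[, j] <- tabulate(take, nbins = length(counts))
  }
  otu_table(out, organism_tag(table))
}

# deterministic 31-bit seed from (global seed, sample id); polynomial string
# hash so the per-sample stream is independent of column order
sample_seed <- function(seed, id) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Drop taxa with few reads overall
#'
#' Removes taxa whose total read count across all samples is below
#' `min_total`; the default of 10 drops taxa with fewer than ten reads.
#'
#' @param table An [otu_table()].
#' @param min_total Minimum total reads for a taxon to be retained.
#' @return A filtered [otu_table()].
#' @export
filter_low_count_taxa <- function(table, min_total = 10) {
  stopifnot(min_total >= 0)
  keep <- rowSums(table) >= min_total
  if (!any(keep)) message("filter_low_count_taxa: no taxa retained")
  otu_subset(table, taxa = which(keep))
}

#' Drop samples whose Shannon diversity exceeds a ceiling
#'
#' Implausibly high Shannon diversity in an amplicon sample usually signals
#' contamination or failed clustering; such samples are removed before
#' analysis. Shannon H is computed on relative abundances with the natural
#' logarithm.
#'
#' @param table An [otu_table()].
#' @param max_H Maximum allowed Shannon diversity in nats (e.g. 6 for 16S
#'   tables, 3.2 for ITS tables).
#' @return A filtered [otu_table()].
#' @export
filter_shannon_outliers <- function(table, max_H) {
  stopifnot(max_H > 0)
  H <- apply(relative_abundance(table), 2L, shannon_entropy)
  drop <- H > max_H
  if (any(drop)) {
    message("filter_shannon_outliers: dropping ", sum(drop), " sample(s): ",
            paste(colnames(table)[drop], collapse = ", "))
  }
  otu_subset(table, samples = which(!drop))
}

#' Keep taxa occurring in enough samples
#'
#' Retains taxa with a non-zero count in at least `min_occurrence` samples of
#' this table. Applied to each network-building sample set (e.g. the 36
#' communities of one treatment x sampling cell) before correlation analysis,
#' so that correlations are not driven by shared absences.
#'
#' @param table An [otu_table()].
#' @param min_occurrence Minimum number of samples with a positive count
#'   (default 8).
#' @return A filtered [otu_table()].
#' @export
prevalence_filter <- function(table, min_occurrence = 8) {
  stopifnot(min_occurrence >= 1)
  keep <- rowSums(unclass(table) > 0) >= min_occurrence
  otu_subset(table, taxa = which(keep))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-sample richness, Shannon diversity and Pielou evenness
#'
#' Richness is the number of taxa with a positive count; Shannon
#' H = -sum p_i log p_i in nats; evenness J = H / log(richness) (Pielou),
#' defined as 0 when richness <= 1. Metrics are comparable across samples only
#' at equal depth, so a warning is issued on unrarefied input.
#'
#' @param table An [otu_table()], normally rarefied.
#' @return A tibble with columns `sample_id`, `richness`, `shannon_H`,
#'   `evenness_J`.
#' @export
diversity_metrics <- function(table) {
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(colnames(table)[totals == 0], collapse = ", "), call. = FALSE)
  }
  if (length(unique(totals)) > 1L) {
    warning("samples have unequal depths; rarefy before comparing diversity",
            call. = FALSE)
  }
  rel <- relative_abundance(table)
  richness <- colSums(rel > 0)
  H <- apply(rel, 2L, shannon_entropy)
  J <- ifelse(richness > 1, H / log(richness), 0)
  tibble::tibble(sample_id = colnames(table), richness = as.integer(richness),
                 shannon_H = unname(H), evenness_J = unname(J))
}
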