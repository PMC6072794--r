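#' Read an OTU count table from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids and a first
#' column of taxon ids; every other cell is a non-negative integer read count.
#' Lines starting with `#` are treated as comments and skipped. Row and column
#' order are preserved.
#'
#' @param path Path to a TSV file.
#' @param organism_tag Community tag attached to the table; see [otu_table()].
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, organism_tag = "other") {
  df <- suppressWarnings(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(readr::col_character(),
                                            .default = readr::col_double()),
                    name_repair = "minimal"))
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty OTU table: ", path, call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  otu_table(m, organism_tag)
}

#' Write an OTU table to TSV
#'
#' Inverse of [read_otu_table()]: first column `taxon_id`, remaining columns
#' one per sample. `read_otu_table(write_otu_table(x, p))` reproduces `x`.
#'
#' @param table An [otu_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  df <- tibble::as_tibble(unclass(table), rownames = "taxon_id")
  readr::write_tsv(df, path)
  invisible(path)
}

.treatment_levels <- c("control", "drought")
.sampling_levels <- c("pre_drought", "end_drought", "early_recovery", "late_recovery")

normalise_level <- function(x, levels, what) {
  x <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read sample metadata from TSV
#'
#' Requires columns `sample_id`, `treatment` (control/drought), `sampling`
#' (pre_drought, end_drought, early_recovery, late_recovery) and `block`.
#' Values of `treatment` and `sampling` are case-folded before validation.
#' A `plant_treatment` column is used for matched control-drought pairing when
#' present; any further columns are carried along as covariates.
#'
#' @param path Path to a TSV file.
#' @return A tibble with validated columns; `sampling` is an ordered factor.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        name_repair = "minimal")
  validate_metadata(df)
}

#' Validate a metadata data frame
#'
#' Applies the same checks and normalisation as [read_metadata()] to an
#' in-memory data frame (useful when metadata comes from the synthetic
#' generator rather than a file).
#'
#' @param df A data frame with at least `sample_id`, `treatment`, `sampling`,
#'   `block`.
#' @return A validated tibble.
#' @export
validate_metadata <- function(df) {
  required <- c("sample_id", "treatment", "sampling", "block")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1L], call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$treatment <- factor(normalise_level(df$treatment, .treatment_levels, "treatment"),
                         levels = .treatment_levels)
  df$sampling <- factor(normalise_level(df$sampling, .sampling_levels, "sampling"),
                        levels = .sampling_levels, ordered = TRUE)
  df$block <- as.integer(df$block)
  df
}

#' Join an OTU table with metadata
#'
#' Checks that every sample column of `table` resolves to exactly one metadata
#' row, and returns the metadata subset in table column order.
#'
#' @param table An [otu_table()].
#' @param meta Metadata tibble from [read_metadata()] / [validate_metadata()].
#' @return The metadata rows for `table`'s samples, in sample order.
#' @export
align_metadata <- function(table, meta) {
  idx <- match(sample_ids(table), meta$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from metadata: ",
         paste(sample_ids(table)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  meta[idx, , drop = FALSE]
}

#' Read a taxonomy table from TSV
#'
#' Optional plumbing: a `taxon_id` column plus any number of rank columns
#' (e.g. phylum, class). No validation beyond id uniqueness.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!"taxon_id" %in% names(df)) stop("taxonomy needs a taxon_id column", call. = FALSE)
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon_id in taxonomy", call. = FALSE)
  df
}

#' Write a co-occurrence network to file
#'
#' `edge_list_tsv` writes one row per edge (`taxon_a`, `taxon_b`, `rho`);
#' an empty network yields a header-only file. `graphml` writes the full graph
#' with node attributes (normalised degree, betweenness, module, indicator
#' class, mean relative abundance — whichever have been computed) via igraph's
#' GraphML writer.
#'
#' @param net A `conet` object from [threshold_network()].
#' @param path Output file path.
#' @param format `"edge_list_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_list_tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "conet"))
  g <- net$graph
  if (format == "edge_list_tsv") {
    if (igraph::ecount(g) == 0L) {
      edges <- tibble::tibble(taxon_a = character(), taxon_b = character(),
                              rho = double())
    } else {
      el <- igraph::as_edgelist(g)
      edges <- tibble::tibble(taxon_a = el[, 1L], taxon_b = el[, 2L],
                              rho = igraph::E(g)$rho)
    }
    readr::write_tsv(edges, path)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
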