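#' Construct an OTU count table
#'
#' The basic container for the whole analysis chain: a non-negative integer
#' count matrix with taxa as rows and samples as columns, tagged with the
#' community it describes (16S-style bacterial tables and ITS-style fungal
#' tables behave very differently downstream, so the tag travels with the
#' counts).
#'
#' @param counts Integer matrix, taxa x samples, with unique rownames
#'   (taxon ids) and colnames (sample ids). All entries must be non-negative
#'   whole numbers.
#' @param organism_tag One of `"bacteria_like"`, `"fungi_like"`, `"other"`.
#' @return An object of class `otu_table`: the validated matrix with an
#'   `organism_tag` attribute.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 7L, 1L), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
#' ot <- otu_table(m, "bacteria_like")
#' n_taxa(ot)
#' @export
otu_table <- function(counts, organism_tag = c("other", "bacteria_like", "fungi_like")) {
  organism_tag <- match.arg(organism_tag)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("OTU table is empty", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("OTU table needs taxon rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1L]
    stop("duplicate taxon id: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1L]
    stop("duplicate sample id: ", dup, call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("non-integer or negative count at taxon '%s', sample '%s'",
                 rownames(counts)[i[1L]], colnames(counts)[i[2L]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(counts, organism_tag = organism_tag, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d taxa x %d samples (%s), %s reads total\n",
              nrow(x), ncol(x), organism_tag(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' @rdname otu_table
#' @param table An `otu_table`.
#' @export
n_taxa <- function(table) nrow(table)

#' @rdname otu_table
#' @export
n_samples <- function(table) ncol(table)

#' @rdname otu_table
#' @export
organism_tag <- function(table) attr(table, "organism_tag") %||% "other"

#' @rdname otu_table
#' @export
taxon_ids <- function(table) rownames(table)

#' @rdname otu_table
#' @export
sample_ids <- function(table) colnames(table)

# subset rows/columns keeping class and tag
otu_subset <- function(table, taxa = NULL, samples = NULL) {
  tag <- organism_tag(table)
  m <- unclass(table)
  if (!is.null(taxa)) m <- m[taxa, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  if (nrow(m) == 0L || ncol(m) == 0L) {
    # keep a valid (possibly degenerate) object; callers decide whether empty is fatal
    structure(m, organism_tag = tag, class = c("otu_table", "matrix", "array"))
  } else {
    otu_table(m, tag)
  }
}

#' Relative abundances of an OTU table
#'
#' Divides each sample column by its total read count, giving per-sample
#' relative abundances (fractions summing to 1 per sample).
#'
#' @param table An [otu_table()].
#' @return A numeric matrix of the same dimensions.
#' @export
relative_abundance <- function(table) {
  totals <- colSums(table)
  zero <- which(totals == 0)
  if (length(zero)) {
    stop("sample(s) with zero total reads: ",
         paste(colnames(table)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(unclass(table), 2L, totals, "/")
}

#' @importFrom rlang %||%
NULL

#' Convert an OTU table to a long tibble
#'
#' @param x An `otu_table`.
#' @param ... Unused.
#' @return A tibble with columns `taxon_id`, `sample_id`, `count`.
#' @export
as_tibble.otu_table <- function(x, ...) {
  tibble::tibble(
    taxon_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    count = as.integer(x)
  )
}
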