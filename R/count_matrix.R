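#' Gene-level count matrix with lengths and library sizes
#'
#' Container for integer read counts per gene per library, together with the
#' gene lengths (bp) needed for RPKM normalization and the per-library totals
#' of mapped reads.  Library sizes default to the column sums of the count
#' matrix, since count tables rarely carry alignment totals.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), one
#'   column per library (colnames = sample labels).
#' @param gene_lengths numeric vector of gene lengths in bp, one per row of
#'   `counts`; if named, names must match the rownames.
#' @param library_sizes numeric vector of total mapped reads per sample;
#'   defaults to `colSums(counts)`.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `gene_lengths` and `library_sizes`.
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 2L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' count_matrix(m, gene_lengths = c(1000, 500))
#' @export
count_matrix <- function(counts, gene_lengths, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene ids as rownames and sample labels as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated sample label(s): ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative numbers with no missing values")
  if (any(counts != round(counts)))
    stop("counts must be integers (read counts, not normalized values)")
  storage.mode(counts) <- "double"  # avoid integer overflow on column sums

  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(rownames(counts), names(gene_lengths))
    if (length(missing))
      stop("gene_lengths missing for: ", paste(utils::head(missing, 5), collapse = ", "))
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  if (length(gene_lengths) != nrow(counts))
    stop("gene_lengths must have one entry per gene")
  if (anyNA(gene_lengths) || any(gene_lengths <= 0))
    stop("gene_lengths must be positive")
  names(gene_lengths) <- rownames(counts)

  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (!is.null(names(library_sizes))) {
    missing <- setdiff(colnames(counts), names(library_sizes))
    if (length(missing))
      stop("library_sizes missing for sample(s): ", paste(missing, collapse = ", "))
    library_sizes <- library_sizes[colnames(counts)]
  }
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per sample")
  bad <- which(is.na(library_sizes) | library_sizes <= 0)
  if (length(bad))
    stop("library size must be positive for sample(s): ",
         paste(colnames(counts)[bad], collapse = ", "))
  names(library_sizes) <- colnames(counts)

  structure(list(counts = counts,
                 gene_lengths = stats::setNames(as.numeric(gene_lengths),
                                                rownames(counts)),
                 library_sizes = stats::setNames(as.numeric(library_sizes),
                                                 colnames(counts))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "libraries\n")
  cat("samples:", paste(utils::head(colnames(x$counts), 8), collapse = ", "),
      if (ncol(x$counts) > 8) "..." else "", "\n")
  cat("library sizes:",
      paste(format(utils::head(x$library_sizes, 4), big.mark = ","), collapse = ", "),
      if (ncol(x$counts) > 4) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by gene and/or sample
#'
#' @param x a [count_matrix()].
#' @param i,j gene and sample indices (any form accepted by matrix indexing).
#' @param ... ignored.
#' @return A `count_matrix` restricted to the selected genes/samples.
#' Library sizes are retained from the parent object (subsetting genes does
#' not change sequencing depth).
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  structure(list(counts = x$counts[i, j, drop = FALSE],
                 gene_lengths = x$gene_lengths[i],
                 library_sizes = x$library_sizes[j]),
            class = "count_matrix")
}

gene_ids <- function(x) rownames(x$counts)
sample_labels <- function(x) colnames(x$counts)
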