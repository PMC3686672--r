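#' Read a gene-level count table from TSV
#'
#' Expected format: a header row `gene_id<TAB>length<TAB><sample1><TAB>...`
#' followed by one row per gene.  Counts must be non-negative integers;
#' duplicated gene ids or sample labels are rejected.
#'
#' @param path path to a tab-separated count table.
#' @param library_sizes optional named vector of total mapped reads per
#'   sample; defaults to column sums.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, library_sizes = NULL) {
  if (!file.exists(path)) stop("count table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3)
    stop("count table needs at least gene_id, length and one sample column: ", path)
  if (!identical(tolower(names(tab)[1:2]), c("gene_id", "length")))
    stop("first two columns must be 'gene_id' and 'length', got: ",
         paste(names(tab)[1:2], collapse = ", "))
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicated gene id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- suppressWarnings(as.numeric(tab[[2]]))
  bad <- which(is.na(lens) | lens <= 0)
  if (length(bad))
    stop("malformed length at data line ", bad[1], " of ", path,
         " (gene ", ids[bad[1]], ")")
  cnt <- as.matrix(tab[, -(1:2), drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cnt), nrow = nrow(cnt)))
  badrow <- which(apply(num, 1, function(z) anyNA(z) || any(z < 0) || any(z != round(z))))
  if (length(badrow))
    stop("non-integer or malformed count at data line ", badrow[1], " of ", path,
         " (gene ", ids[badrow[1]], ")")
  dimnames(num) <- list(ids, colnames(cnt))
  count_matrix(num, gene_lengths = lens, library_sizes = library_sizes)
}

#' Write a count matrix as TSV
#'
#' Inverse of [read_count_matrix()]: `gene_id`, `length`, then one column
#' per sample.  Tab-separated, UTF-8, no quoting.
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x),
                   length = x$gene_lengths,
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

# fixed TSV writing convention for all outputs (no quoting, no rownames)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a samples manifest
#'
#' A manifest ties count-matrix columns to experimental roles.  Columns:
#' `sample` (matching a count-matrix column), `role`
#' (`organ_atlas` or `timecourse`), `side` (`left`/`right`, or `NA` for
#' atlas samples), `date` (day label, or `"control"`), `organ` (organ label
#' for atlas samples).
#'
#' @param path path to the manifest TSV.
#' @param counts optional [count_matrix()] to validate sample labels against.
#' @return A data.frame with the columns above.
#' @export
read_samples_manifest <- function(path, counts = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  validate_manifest(man, counts)
}

validate_manifest <- function(man, counts = NULL) {
  need <- c("sample", "role", "side", "date", "organ")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(man$sample))
    stop("duplicated sample in manifest: ",
         paste(unique(man$sample[duplicated(man$sample)]), collapse = ", "))
  badrole <- setdiff(unique(man$role), c("organ_atlas", "timecourse"))
  if (length(badrole)) stop("unknown role(s) in manifest: ", paste(badrole, collapse = ", "))
  tc <- man[man$role == "timecourse", , drop = FALSE]
  if (nrow(tc)) {
    if (any(!tc$side %in% c("left", "right")))
      stop("timecourse manifest rows need side 'left' or 'right'")
    if (any(is.na(tc$date) | tc$date == ""))
      stop("timecourse manifest rows need a date label or 'control'")
  }
  at <- man[man$role == "organ_atlas", , drop = FALSE]
  if (nrow(at) && any(is.na(at$organ) | at$organ == ""))
    stop("organ_atlas manifest rows need an organ label")
  if (!is.null(counts)) {
    unknown <- setdiff(man$sample, sample_labels(counts))
    if (length(unknown))
      stop("manifest sample(s) absent from count matrix: ",
           paste(unknown, collapse = ", "))
  }
  man
}

#' Read a gene list (one id per line)
#'
#' @param path path to a plain-text file, one gene id per line; blank lines
#'   and lines starting with `#` are skipped.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a gene-to-term annotation map
#'
#' Annotation input is a two-column TSV (`gene_id`, `term_id`); an optional
#' second TSV supplies term metadata (`term_id`, `term_label`, `class`, e.g.
#' GO BP/MF/CC or `pathway`).
#'
#' @param path two-column annotation TSV.
#' @param term_info_path optional term metadata TSV.
#' @return A list of class `annotation_map` with elements `gene2term`
#'   (data.frame `gene_id`, `term_id`, duplicates removed) and `term_info`
#'   (data.frame or NULL).
#' @export
read_annotation_map <- function(path, term_info_path = NULL) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  g2t <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  annotation_map(g2t, if (!is.null(term_info_path))
    utils::read.delim(term_info_path, sep = "\t", quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE))
}

#' Construct an annotation map from data.frames
#'
#' @param gene2term data.frame with columns `gene_id` and `term_id`.
#' @param term_info optional data.frame with columns `term_id`,
#'   `term_label`, `class`.
#' @return An `annotation_map` object.
#' @export
annotation_map <- function(gene2term, term_info = NULL) {
  if (!all(c("gene_id", "term_id") %in% names(gene2term)))
    stop("annotation needs columns 'gene_id' and 'term_id'")
  g2t <- unique(gene2term[, c("gene_id", "term_id")])
  g2t <- g2t[nzchar(g2t$gene_id) & nzchar(g2t$term_id), , drop = FALSE]
  if (!is.null(term_info)) {
    if (!"term_id" %in% names(term_info))
      stop("term_info needs a 'term_id' column")
    if (anyDuplicated(term_info$term_id))
      stop("duplicated term_id in term_info")
  }
  structure(list(gene2term = g2t, term_info = term_info), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", length(unique(x$gene2term$gene_id)), "genes,",
      length(unique(x$gene2term$term_id)), "terms,",
      nrow(x$gene2term), "assignments\n")
  invisible(x)
}
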