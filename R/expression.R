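#' RPKM normalization
#'
#' Converts read counts to RPKM (reads per kilobase of gene model per million
#' mapped reads): `rpkm = 1e9 * count / (length_bp * library_size)`.
#'
#' @param x a [count_matrix()].
#' @return An object of class `rpkm_matrix`: list with elements `rpkm`
#'   (numeric matrix, same dimnames as the counts), `gene_lengths` and
#'   `library_sizes`.
#' @examples
#' m <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' cm <- count_matrix(m, gene_lengths = c(1000, 500),
#'                    library_sizes = c(s1 = 1e6))
#' compute_rpkm(cm)$rpkm  # g1 -> 10, g2 -> 0
#' @export
compute_rpkm <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  bad <- which(x$library_sizes <= 0)
  if (length(bad))
    stop("library size must be positive for sample(s): ",
         paste(colnames(x$counts)[bad], collapse = ", "))
  rpkm <- 1e9 * sweep(x$counts, 1, x$gene_lengths, `/`)
  rpkm <- sweep(rpkm, 2, x$library_sizes, `/`)
  structure(list(rpkm = rpkm,
                 gene_lengths = x$gene_lengths,
                 library_sizes = x$library_sizes),
            class = "rpkm_matrix")
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat("rpkm_matrix:", nrow(x$rpkm), "genes x", ncol(x$rpkm), "libraries\n")
  invisible(x)
}

#' Expression thresholds
#'
#' The two thresholds governing expressed-gene calling and origin
#' classification: a gene is *expressed* in a library when its RPKM strictly
#' exceeds `expressed_min_rpkm` (default 5), and a candidate non-mantle organ
#' must show at least `fold_min` (default 2) times the mantle RPKM.
#'
#' @param expressed_min_rpkm RPKM above which a gene counts as expressed.
#' @param fold_min minimum other-organ / mantle RPKM ratio.
#' @return A list of class `expression_thresholds`.
#' @export
expression_thresholds <- function(expressed_min_rpkm = 5, fold_min = 2) {
  if (!is.numeric(expressed_min_rpkm) || expressed_min_rpkm <= 0)
    stop("expressed_min_rpkm must be positive")
  if (!is.numeric(fold_min) || fold_min <= 0)
    stop("fold_min must be positive")
  structure(list(expressed_min_rpkm = expressed_min_rpkm, fold_min = fold_min),
            class = "expression_thresholds")
}

#' Call expressed genes
#'
#' A (gene, library) cell is expressed iff RPKM strictly exceeds the
#' threshold; RPKM exactly at the threshold is *not* expressed.
#'
#' @param expr an `rpkm_matrix` from [compute_rpkm()].
#' @param thresholds an [expression_thresholds()] object.
#' @return Logical matrix, same dimnames as the RPKM matrix.
#' @export
call_expressed <- function(expr, thresholds = expression_thresholds()) {
  stopifnot(inherits(expr, "rpkm_matrix"))
  expr$rpkm > thresholds$expressed_min_rpkm
}

#' Classify shell-protein genes by organ of origin
#'
#' Applies the multi-organ origin rules to a set of shell matrix protein
#' (SMP) genes profiled across an organ atlas:
#' * `non_mantle` — mantle RPKM below the expressed threshold, while some
#'   other organ is expressed (RPKM > threshold) at `fold_min` times the
#'   mantle RPKM or more;
#' * `non_mantle_non_hemolymph` — as above, with the hemolymph also below
#'   the threshold (a subclass of the non-mantle condition; in the exclusive
#'   `class` column hemolymph-quiet genes take this more specific label);
#' * `mantle_expressed` — mantle RPKM above the threshold;
#' * `unexpressed_everywhere` — none of the above.
#'
#' Because the hemolymph-quiet rule nests inside the non-mantle rule, the
#' result also carries the two rules as logical flags `is_non_mantle` and
#' `is_non_mantle_non_hemolymph` (with
#' `is_non_mantle_non_hemolymph => is_non_mantle`), so both the full
#' non-mantle set and its hemolymph-quiet subset can be recovered directly.
#' The fold comparison is taken relative to the same gene's mantle RPKM;
#' when the mantle RPKM is 0 any expressed other organ satisfies it.
#'
#' @param expr an `rpkm_matrix` covering the organ atlas.
#' @param smp_gene_ids character vector of SMP gene ids (subset of the
#'   matrix rownames).
#' @param mantle_label,hemolymph_label sample labels of the mantle and
#'   hemolymph libraries.
#' @param thresholds an [expression_thresholds()] object.
#' @return A data.frame of class `origin_classification` with columns
#'   `gene_id`, `class`, `is_non_mantle`, `is_non_mantle_non_hemolymph`,
#'   `mantle_rpkm`, `hemolymph_rpkm`, `best_other_organ`, `best_other_rpkm`.
#' @export
classify_shell_protein_origin <- function(expr, smp_gene_ids,
                                          mantle_label = "Man",
                                          hemolymph_label = "Hem",
                                          thresholds = expression_thresholds()) {
  stopifnot(inherits(expr, "rpkm_matrix"))
  organs <- colnames(expr$rpkm)
  for (lab in c(mantle_label, hemolymph_label))
    if (!lab %in% organs) stop("unknown organ label: ", lab)
  missing <- setdiff(smp_gene_ids, rownames(expr$rpkm))
  if (length(missing))
    stop("SMP gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))

  r <- expr$rpkm[smp_gene_ids, , drop = FALSE]
  tmin <- thresholds$expressed_min_rpkm
  mant <- r[, mantle_label]
  hemo <- r[, hemolymph_label]
  other <- r[, setdiff(organs, mantle_label), drop = FALSE]

  best_idx <- max.col(other, ties.method = "first")
  best_organ <- colnames(other)[best_idx]
  best_rpkm <- other[cbind(seq_len(nrow(other)), best_idx)]

  # elsewhere-expressed condition: some non-mantle organ with RPKM above the
  # threshold and >= fold_min x the gene's mantle RPKM
  has_other <- rowSums(other > tmin & other >= thresholds$fold_min * mant) > 0

  is_nm <- mant < tmin & has_other
  # hemolymph-quiet subclass; hemolymph below threshold cannot itself be the
  # supporting organ, so no extra exclusion is needed there
  is_nm_nh <- is_nm & hemo < tmin

  cls <- ifelse(is_nm_nh, "non_mantle_non_hemolymph",
         ifelse(is_nm, "non_mantle",
         ifelse(mant > tmin, "mantle_expressed", "unexpressed_everywhere")))

  out <- data.frame(gene_id = smp_gene_ids,
                    class = cls,
                    is_non_mantle = unname(is_nm),
                    is_non_mantle_non_hemolymph = unname(is_nm_nh),
                    mantle_rpkm = unname(mant),
                    hemolymph_rpkm = unname(hemo),
                    best_other_organ = best_organ,
                    best_other_rpkm = unname(best_rpkm),
                    stringsAsFactors = FALSE)
  class(out) <- c("origin_classification", "data.frame")
  out
}

#' Per-organ summary of SMP gene expression
#'
#' For each organ of the atlas, the number of SMP genes expressed
#' (RPKM above the threshold) and the total SMP RPKM.
#'
#' @inheritParams classify_shell_protein_origin
#' @return data.frame with columns `organ`, `n_expressed`, `total_rpkm`.
#' @export
summarize_organ_distribution <- function(expr, smp_gene_ids,
                                         thresholds = expression_thresholds()) {
  stopifnot(inherits(expr, "rpkm_matrix"))
  missing <- setdiff(smp_gene_ids, rownames(expr$rpkm))
  if (length(missing))
    stop("SMP gene(s) absent from expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  r <- expr$rpkm[smp_gene_ids, , drop = FALSE]
  data.frame(organ = colnames(r),
             n_expressed = unname(colSums(r > thresholds$expressed_min_rpkm)),
             total_rpkm = unname(colSums(r)),
             stringsAsFactors = FALSE)
}
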