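#' Hypergeometric term over-representation test
#'
#' For each annotation term, tests whether the study set contains more
#' term-annotated genes than expected from drawing `n` genes at random from
#' the population of `N`.  With `K` population genes carrying the term and
#' `x` of them in the study set, the one-sided upper-tail p-value is
#'
#' \deqn{p = \sum_{i=x}^{\min(K,n)} \frac{\binom{K}{i}\binom{N-K}{n-i}}
#'   {\binom{N}{n}}}
#'
#' evaluated in log space through [stats::phyper()].  Genes without any
#' annotation stay in the population by default (they dilute every term);
#' `restrict_to_annotated = TRUE` drops them from both population and study
#' set, which raises every `p` comparison onto the annotated universe only —
#' the choice changes every p-value and is therefore exposed, not hidden.
#'
#' @param study_set character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of population gene ids.
#' @param annotations an [annotation_map()].
#' @param restrict_to_annotated if TRUE, use only annotated genes as the
#'   universe.
#' @param min_genes report only terms with at least this many study-set
#'   genes (default 0: every term with annotated population genes is
#'   reported, terms absent from the study set with `p = 1`).
#' @return A data.frame of class `enrichment_result`, sorted by `p`, with
#'   columns `term_id`, `term_label`, `class`, `K`, `n`, `x`, `N`, `p`, `q`
#'   (`q` = Benjamini-Hochberg adjusted over all tested terms).
#' @examples
#' ann <- annotation_map(data.frame(
#'   gene_id = c("g1", "g2", "g3", "g4", "g5"),
#'   term_id = "T1"))
#' hypergeom_enrich(c("g1", "g2", "g3", "g4"), paste0("g", 1:10), ann)
#' @export
hypergeom_enrich <- function(study_set, population, annotations,
                             restrict_to_annotated = FALSE, min_genes = 0) {
  stopifnot(inherits(annotations, "annotation_map"))
  study_set <- unique(as.character(study_set))
  population <- unique(as.character(population))
  offenders <- setdiff(study_set, population)
  if (length(offenders))
    stop("study gene(s) absent from population: ",
         paste(utils::head(offenders, 10), collapse = ", "))

  g2t <- annotations$gene2term
  g2t <- g2t[g2t$gene_id %in% population, , drop = FALSE]
  if (restrict_to_annotated) {
    annotated <- unique(g2t$gene_id)
    population <- intersect(population, annotated)
    study_set <- intersect(study_set, annotated)
  }
  N <- length(population)
  n <- length(study_set)
  terms <- unique(g2t$term_id)
  if (!length(terms))
    stop("no annotated population genes; nothing to test")

  K <- tapply(g2t$gene_id, g2t$term_id, function(g) length(unique(g)))
  in_study <- g2t[g2t$gene_id %in% study_set, , drop = FALSE]
  x <- tapply(in_study$gene_id, factor(in_study$term_id, levels = names(K)),
              function(g) length(unique(g)))
  x[is.na(x)] <- 0

  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(K),
                    K = as.integer(K), n = n, x = as.integer(x), N = N,
                    p = unname(p), stringsAsFactors = FALSE)
  out <- out[out$x >= min_genes, , drop = FALSE]
  out$q <- bh_adjust(out$p)

  ti <- annotations$term_info
  if (!is.null(ti)) {
    idx <- match(out$term_id, ti$term_id)
    out$term_label <- if ("term_label" %in% names(ti)) ti$term_label[idx] else NA_character_
    out$class <- if ("class" %in% names(ti)) ti$class[idx] else NA_character_
  } else {
    out$term_label <- NA_character_
    out$class <- NA_character_
  }
  out <- out[order(out$p, out$term_id),
             c("term_id", "term_label", "class", "K", "n", "x", "N", "p", "q")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values (a thin validated wrapper
#' over `p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("enrichment_result:", nrow(x), "terms tested; study n =",
      x$n[1], "of N =", x$N[1], "\n")
  print.data.frame(utils::head(x, 10), digits = 3)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more terms\n")
  invisible(x)
}
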