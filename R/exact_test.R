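#' Exact test for one gene between two unreplicated libraries
#'
#' The Audic-Claverie conditional test for comparing a single count `x`
#' (library of size `n1`) against a single count `y` (library of size `n2`),
#' the standard exact test for SAGE/RNA-seq designs without biological
#' replicates.  Conditioned on `x`, the count in the second library follows
#'
#' \deqn{P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}}}
#'
#' which is the negative binomial with size `x + 1` and success probability
#' `n1 / (n1 + n2)`; tail probabilities are therefore evaluated through
#' [stats::pnbinom()], which is accurate in log space for counts well beyond
#' one million.  The two-sided p-value doubles the smaller of the two
#' inclusive tails and caps at 1:
#' `p = min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`.
#'
#' The conditional distribution is written given `x`, so the construction is
#' not exactly invariant under swapping the two libraries (it is so only
#' asymptotically); `method = "fisher"` gives the symmetric 2x2 Fisher exact
#' alternative for sensitivity analysis.
#'
#' @param x,y non-negative integer counts (vectorized; recycled together).
#' @param n1,n2 library sizes (total mapped reads) for the `x` and `y`
#'   libraries.
#' @param method `"ac"` (Audic-Claverie, default) or `"fisher"` (two-sided
#'   Fisher exact test on the 2x2 table of in-gene vs rest-of-library reads).
#' @return Numeric vector of two-sided p-values in \[0, 1\].
#' @examples
#' exact_two_library_test(0, 0, 1e6, 1e6)   # 1
#' exact_two_library_test(0, 50, 1e6, 1e6)  # 2^-49
#' @export
exact_two_library_test <- function(x, y, n1, n2, method = c("ac", "fisher")) {
  method <- match.arg(method)
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0))
    stop("counts must be non-negative")
  if (any(x != round(x)) || any(y != round(y)))
    stop("counts must be integers")
  if (any(n1 <= 0) || any(n2 <= 0))
    stop("library sizes must be positive")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)

  if (method == "fisher") {
    return(vapply(seq_len(n), function(i) {
      stats::fisher.test(matrix(c(x[i], n1[i] - x[i], y[i], n2[i] - y[i]), 2))$p.value
    }, numeric(1)))
  }

  prob <- n1 / (n1 + n2)                      # NB success prob, size x + 1
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  upper <- ifelse(y == 0, 1,
                  stats::pnbinom(y - 1, size = x + 1, prob = prob,
                                 lower.tail = FALSE))
  pmin(1, 2 * pmin(lower, upper))
}

#' Per-date differential expression calls against a same-side control
#'
#' For every treated (side, date) library, each gene is compared with the
#' same-side control library by [exact_two_library_test()].  A gene is
#' called `up` when `p < alpha` and its depth-normalized treated rate
#' exceeds the control rate, `down` for the reverse, and `none` otherwise
#' (including exact rate ties, where no direction is defensible).  The alpha
#' cut is strict: `p` exactly equal to `alpha` is not called.
#'
#' @param counts a [count_matrix()] whose columns cover the time course.
#' @param manifest samples manifest (see [read_samples_manifest()]) with
#'   `role == "timecourse"` rows: one `date == "control"` column per side
#'   plus treated columns.
#' @param alpha per-comparison significance threshold (default `1e-3`).
#' @param method test passed to [exact_two_library_test()].
#' @return A data.frame of class `de_calls` with columns `gene_id`, `side`,
#'   `date`, `p_value`, `direction`, and attributes `alpha` and `dates`.
#' @export
call_de <- function(counts, manifest, alpha = 1e-3, method = c("ac", "fisher")) {
  stopifnot(inherits(counts, "count_matrix"))
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  man <- validate_manifest(manifest, counts)
  man <- man[man$role == "timecourse", , drop = FALSE]
  if (!nrow(man)) stop("manifest has no timecourse samples")

  out <- list()
  for (side in unique(man$side)) {
    ms <- man[man$side == side, , drop = FALSE]
    ctrl <- ms$sample[ms$date == "control"]
    if (length(ctrl) != 1)
      stop("side '", side, "' needs exactly one control column, found ",
           length(ctrl))
    treated <- ms[ms$date != "control", , drop = FALSE]
    if (!nrow(treated))
      stop("side '", side, "' has no treated columns")
    x <- counts$counts[, ctrl]
    nx <- counts$library_sizes[ctrl]
    for (i in seq_len(nrow(treated))) {
      smp <- treated$sample[i]
      y <- counts$counts[, smp]
      ny <- counts$library_sizes[smp]
      p <- exact_two_library_test(x, y, nx, ny, method = method)
      rate_diff <- y / ny - x / nx
      dir <- ifelse(p < alpha & rate_diff > 0, "up",
             ifelse(p < alpha & rate_diff < 0, "down", "none"))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gene_ids(counts), side = side, date = treated$date[i],
        p_value = unname(p), direction = dir, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "dates") <- unique(man$date[man$date != "control"])
  class(res) <- c("de_calls", "data.frame")
  res
}

#' Count up/down calls per side and date
#'
#' @param calls a `de_calls` object from [call_de()].
#' @return data.frame with columns `side`, `date`, `n_up`, `n_down`.
#' @export
de_count_table <- function(calls) {
  stopifnot(inherits(calls, "de_calls"))
  key <- unique(calls[, c("side", "date")])
  key$n_up <- mapply(function(s, d)
    sum(calls$direction == "up" & calls$side == s & calls$date == d),
    key$side, key$date)
  key$n_down <- mapply(function(s, d)
    sum(calls$direction == "down" & calls$side == s & calls$date == d),
    key$side, key$date)
  rownames(key) <- NULL
  class(key) <- "data.frame"
  key
}

#' @export
print.de_calls <- function(x, ...) {
  cat("de_calls:", length(unique(x$gene_id)), "genes,",
      nrow(unique(x[, c("side", "date")])), "treated libraries, alpha =",
      attr(x, "alpha"), "\n")
  tab <- table(x$direction)
  cat("calls:", paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}
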