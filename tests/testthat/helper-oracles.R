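# Independent oracles and small fixture builders used across the suite.

# Audic-Claverie conditional pmf, log space:
# P(y | x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1)),  r = n2/n1
ac_pmf <- function(j, x, n1, n2) {
  r <- n2 / n1
  exp(j * log(r) + lgamma(x + j + 1) - lgamma(x + 1) - lgamma(j + 1) -
        (x + j + 1) * log1p(r))
}

# brute-force two-sided p by direct pmf summation over outcomes 0..jmax
ac_bruteforce <- function(x, y, n1, n2, jmax = 5000) {
  j <- 0:jmax
  pj <- ac_pmf(j, x, n1, n2)
  lower <- sum(pj[j <= y])
  upper <- sum(pj[j >= y])
  min(1, 2 * min(lower, upper))
}

# exhaustive hypergeometric upper tail using exact binomial coefficients
hyper_bruteforce <- function(x, K, N, n) {
  i <- x:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hand-stepped Benjamini-Hochberg, independent of p.adjust
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# tiny count matrix with explicit values
make_counts <- function(counts, lengths = NULL, lib = NULL) {
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  count_matrix(counts, gene_lengths = lengths, library_sizes = lib)
}

# rpkm_matrix straight from a numeric RPKM matrix (for classifier tests)
make_rpkm <- function(rpkm) {
  structure(list(rpkm = rpkm,
                 gene_lengths = rep(1000, nrow(rpkm)),
                 library_sizes = rep(1e6, ncol(rpkm))),
            class = "rpkm_matrix")
}

# manifest for a two-side time course from column names side_control/side_dD
make_tc_manifest <- function(cols) {
  data.frame(sample = cols, role = "timecourse",
             side = sub("_(control|d.*)$", "", cols),
             date = ifelse(grepl("_control$", cols), "control",
                           sub(".*_d", "", cols)),
             organ = NA_character_, stringsAsFactors = FALSE)
}

# small scenarios used by several files (kept light for test runtime)
small_timecourse <- function(..., n_genes = 3000, seed = 11)
  timecourse_scenario(n_genes = n_genes, seed = seed, ...)

small_atlas <- function(..., n_genes = 3000, seed = 11)
  atlas_scenario(n_genes = n_genes, seed = seed, ...)
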