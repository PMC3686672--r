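# build a de_calls object directly from a logical gene x date up-call matrix
calls_from_matrix <- function(up, side = "left") {
  genes <- rownames(up); dates <- colnames(up)
  df <- expand.grid(gene_id = genes, date = dates, stringsAsFactors = FALSE)
  df$side <- side
  df$p_value <- ifelse(up[cbind(df$gene_id, df$date)], 1e-6, 0.5)
  df$direction <- ifelse(up[cbind(df$gene_id, df$date)], "up", "none")
  attr(df, "alpha") <- 1e-3
  attr(df, "dates") <- dates
  class(df) <- c("de_calls", "data.frame")
  df
}

test_that("recurrence counts dates with the requested call", {
  up <- matrix(FALSE, 3, 7,
               dimnames = list(c("g135", "gAll", "gNone"), paste0("d", 1:7)))
  up["g135", c(1, 3, 5)] <- TRUE
  up["gAll", ] <- TRUE
  calls <- calls_from_matrix(up)
  prof <- count_recurrence(calls, "left", "up")
  k <- stats::setNames(prof$k, prof$gene_id)
  expect_equal(unname(k[c("g135", "gAll", "gNone")]), c(3, 7, 0))
  expect_equal(attr(prof, "n_dates"), 7)
  # no down calls at all -> every k zero in the down profile
  prof_down <- count_recurrence(calls, "left", "down")
  expect_true(all(prof_down$k == 0))
})

test_that("Poisson-binomial pmf matches binomial closed form and edge cases", {
  p <- rep(0.1, 7)
  expect_equal(unname(poisson_binomial_pmf(p)), dbinom(0:7, 7, 0.1),
               tolerance = 1e-12)
  # G = 10000, p = 0.1: expected count at k = 7 is 10^4 * 10^-7 = 0.001
  null <- null_recurrence("binomial", n_genes = 10000, p_dates = p)
  expect_equal(unname(null$expected["7"]), 0.001, tolerance = 1e-12)
  # all-zero probabilities put all mass at k = 0
  expect_equal(unname(poisson_binomial_pmf(rep(0, 7))), c(1, rep(0, 7)))
  # heterogeneous case against direct enumeration over date subsets
  pd <- c(0.02, 0.05, 0.1, 0.01, 0.2, 0.15, 0.08)
  direct <- sapply(0:7, function(k) {
    sets <- utils::combn(7, k, simplify = FALSE)
    if (k == 0) sets <- list(integer(0))
    sum(vapply(sets, function(s) prod(pd[s]) * prod(1 - pd[setdiff(1:7, s)]),
               numeric(1)))
  })
  expect_equal(unname(poisson_binomial_pmf(pd)), direct, tolerance = 1e-12)
})

test_that("expected counts sum to the number of genes in both null modes", {
  pd <- c(0.02, 0.05, 0.1, 0.01, 0.2, 0.15, 0.08)
  nb <- null_recurrence("binomial", n_genes = 5000, p_dates = pd)
  expect_equal(sum(nb$expected), 5000, tolerance = 1e-9)
  set.seed(5)
  up <- matrix(runif(200 * 7) < 0.1, 200, 7,
               dimnames = list(sprintf("g%03d", 1:200), paste0("d", 1:7)))
  calls <- calls_from_matrix(up)
  np <- null_recurrence("permutation", calls = calls, side = "left",
                        n_permutations = 50)
  expect_equal(sum(np$expected), 200, tolerance = 1e-9)
  expect_true(all(abs(rowSums(np$replicates) - 200) < 1e-9))
})

test_that("permutation null matches the Poisson-binomial closed form", {
  set.seed(20)
  G <- 2000
  pd <- c(0.05, 0.12, 0.08, 0.15, 0.03, 0.1, 0.07)
  up <- sapply(pd, function(p) runif(G) < p)
  dimnames(up) <- list(sprintf("g%04d", 1:G), paste0("d", 1:7))
  calls <- calls_from_matrix(up)
  B <- 1000
  null_p <- null_recurrence("permutation", calls = calls, side = "left",
                            n_permutations = B)
  # closed form at the empirical per-date rates the permutation preserves
  closed <- G * poisson_binomial_pmf(colMeans(up))
  # Monte-Carlo SE of the mean histogram: empirical, floored by the
  # Poisson-scale SE sqrt(expected / B) where rare bins defeat the
  # empirical estimate
  se <- pmax(apply(null_p$replicates, 2, stats::sd), sqrt(closed)) / sqrt(B)
  diff <- abs(null_p$expected - closed)
  expect_true(all(diff <= 3 * se),
              info = paste("max z:", max(diff / pmax(se, 1e-12))))
})

test_that("binomial-mode expectation decays monotonically when rates are small", {
  set.seed(9)
  for (rep in 1:20) {
    pd <- runif(7, 0, 0.249)
    ex <- null_recurrence("binomial", n_genes = 10000, p_dates = pd)$expected
    expect_true(all(diff(ex[-1]) < 0),
                info = paste("p_d =", paste(round(pd, 3), collapse = ",")))
  }
})

test_that("excess and tail p behave at the null median and under injection", {
  set.seed(31)
  G <- 3000
  up <- matrix(runif(G * 7) < 0.08, G, 7,
               dimnames = list(sprintf("g%04d", 1:G), paste0("d", 1:7)))
  calls <- calls_from_matrix(up)
  prof <- count_recurrence(calls, "left", "up")
  null <- null_recurrence("permutation", calls = calls, side = "left",
                          n_permutations = 400)
  # independent calls: observed tail should sit inside the null body
  ex <- excess_statistic(prof, null, k_min = 4)
  expect_gte(ex$tail_p, 0.05)
  expect_equal(sum(ex$excess), 0, tolerance = 1e-9)

  # inject 60 persistent genes: excess at k >= 6 recovers them
  up2 <- up
  up2[1:60, ] <- TRUE
  calls2 <- calls_from_matrix(up2)
  prof2 <- count_recurrence(calls2, "left", "up")
  null2 <- null_recurrence("permutation", calls = calls2, side = "left",
                           n_permutations = 400)
  ex2 <- excess_statistic(prof2, null2, k_min = 6)
  expect_gte(ex2$tail_observed, 60)
  expect_lte(ex2$tail_p, 0.01)
  expect_gt(sum(ex2$excess[c("6", "7")]), 50)
})

test_that("selection keeps genes at or above the persistence threshold", {
  up <- matrix(FALSE, 4, 7,
               dimnames = list(c("k5", "k6", "k7", "k0"), paste0("d", 1:7)))
  up["k5", 1:5] <- TRUE; up["k6", 1:6] <- TRUE; up["k7", ] <- TRUE
  prof <- count_recurrence(calls_from_matrix(up), "left", "up")
  expect_setequal(select_persistent_genes(prof, 6), c("k6", "k7"))
  expect_setequal(select_persistent_genes(prof, 0),
                  c("k5", "k6", "k7", "k0"))
  expect_error(select_persistent_genes(prof, 8), "exceeds")
})

test_that("histogram reports both exact-k and cumulative conventions", {
  up <- matrix(FALSE, 3, 7,
               dimnames = list(c("a", "b", "c"), paste0("d", 1:7)))
  up["a", 1:6] <- TRUE; up["b", ] <- TRUE
  prof <- count_recurrence(calls_from_matrix(up), "left", "up")
  h <- recurrence_histogram(prof)
  expect_equal(h$n_at_k[h$k == 6], 1)
  expect_equal(h$n_at_least_k[h$k == 6], 2)
  expect_equal(h$n_at_least_k[h$k == 0], 3)
})

test_that("parameter recovery: persistent genes selected, transient excluded", {
  sim <- simulate_damage_timecourse(
    small_timecourse(n_genes = 5000, frac_damage_responsive = 0.02,
                     frac_transient = 0.02, persistence = 7,
                     effect_fold = 4, seed = 19))
  calls <- call_de(sim$counts, sim$manifest, alpha = 1e-3)
  prof <- count_recurrence(calls, "left", "up")
  sel <- select_persistent_genes(prof, 6)
  resp <- sim$truth$gene_id[sim$truth$is_damage_responsive]
  trans <- sim$truth$gene_id[sim$truth$is_transient]
  nullg <- sim$truth$gene_id[!sim$truth$is_damage_responsive &
                               !sim$truth$is_transient]
  expect_gte(mean(resp %in% sel), 0.9)
  expect_lte(mean(nullg %in% sel), 0.01)
  expect_equal(sum(trans %in% sel), 0)  # 1-2 date effects never reach k = 6
})
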