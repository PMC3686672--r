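test_that("closed-form cases: empty libraries and a pure geometric tail", {
  expect_equal(exact_two_library_test(0, 0, 1e6, 1e6), 1)
  # x = 0, equal depths: tail from y is a geometric series summing to 2^-y
  expect_equal(exact_two_library_test(0, 50, 1e6, 1e6), 2^-49,
               tolerance = 1e-12)
  expect_error(exact_two_library_test(-1, 0, 1, 1), "non-negative")
  expect_error(exact_two_library_test(0, 0, 0, 1), "positive")
})

test_that("p-values agree with brute-force pmf summation on a depth grid", {
  for (ratio in c(0.5, 1, 2)) {
    n1 <- 1e6; n2 <- ratio * 1e6
    for (x in 0:10) for (y in 0:(20 - x)) {
      expect_equal(exact_two_library_test(x, y, n1, n2),
                   ac_bruteforce(x, y, n1, n2),
                   tolerance = 1e-10,
                   label = sprintf("x=%d y=%d ratio=%g", x, y, ratio))
    }
  }
})

test_that("log-space implementation tracks direct summation up to x+y=200", {
  set.seed(3)
  cases <- data.frame(x = sample(0:150, 40, replace = TRUE))
  cases$y <- pmin(200 - cases$x, sample(0:150, 40, replace = TRUE))
  for (i in seq_len(nrow(cases))) {
    x <- cases$x[i]; y <- cases$y[i]
    p1 <- exact_two_library_test(x, y, 2e6, 1e6)
    p2 <- ac_bruteforce(x, y, 2e6, 1e6)
    expect_equal(p1, p2, tolerance = 1e-9,  # relative
                 label = sprintf("x=%d y=%d", x, y))
  }
})

test_that("p-values are valid and decay as y moves away from expectation", {
  x <- 40; n1 <- 1e6; n2 <- 2e6
  # the conditional law given x has mean (x + 1) * n2 / n1
  center <- (x + 1) * n2 / n1
  y <- 0:300
  p <- exact_two_library_test(rep(x, length(y)), y, n1, n2)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p[y >= ceiling(center)]) <= 1e-12))
  expect_true(all(diff(p[y <= floor(x * n2 / n1)]) >= -1e-12))
})

test_that("the test remains finite and sane at depth-scale counts", {
  p_null <- exact_two_library_test(1e6, 1e6, 1e7, 1e7)
  expect_gt(p_null, 0.5)
  p_eff <- exact_two_library_test(1e6, 1.01e6, 1e7, 1e7)
  expect_lt(p_eff, 1e-6)  # 1% shift on a million counts is detectable
  expect_gt(p_eff, 0)
})

test_that("Fisher alternative is swap-symmetric; AC nearly so at moderate counts", {
  cases <- list(c(10, 30), c(55, 70), c(120, 80))
  for (cs in cases) {
    pf1 <- exact_two_library_test(cs[1], cs[2], 1e6, 2e6, method = "fisher")
    pf2 <- exact_two_library_test(cs[2], cs[1], 2e6, 1e6, method = "fisher")
    expect_equal(pf1, pf2, tolerance = 1e-12)
    pa1 <- exact_two_library_test(cs[1], cs[2], 1e6, 2e6)
    pa2 <- exact_two_library_test(cs[2], cs[1], 2e6, 1e6)
    expect_equal(log(pa1), log(pa2), tolerance = 0.2)
  }
})

test_that("DE calling applies a strict alpha and rate-based direction", {
  # construct counts whose p-values straddle the threshold
  m <- matrix(c(100L, 0L,  100L,
                190L, 20L, 100L), 3, 2,
              dimnames = list(c("gUp", "gUp2", "gNull"),
                              c("left_control", "left_d1")))
  cm <- count_matrix(m, gene_lengths = rep(1000, 3),
                     library_sizes = c(left_control = 1e6, left_d1 = 1e6))
  calls <- call_de(cm, make_tc_manifest(colnames(m)), alpha = 1e-3)
  expect_equal(calls$direction[calls$gene_id == "gUp"], "up")
  expect_equal(calls$direction[calls$gene_id == "gUp2"], "up")
  expect_equal(calls$direction[calls$gene_id == "gNull"], "none")

  # p exactly at alpha is NOT called: use alpha equal to an achievable p
  p_exact <- exact_two_library_test(0, 9, 1e6, 1e6)
  m2 <- matrix(c(0L, 9L), 1, 2,
               dimnames = list("g", c("left_control", "left_d1")))
  cm2 <- count_matrix(m2, gene_lengths = 1000,
                      library_sizes = c(left_control = 1e6, left_d1 = 1e6))
  calls_at <- call_de(cm2, make_tc_manifest(colnames(m2)), alpha = p_exact)
  expect_equal(calls_at$direction, "none")
  calls_above <- call_de(cm2, make_tc_manifest(colnames(m2)),
                         alpha = p_exact * 1.0001)
  expect_equal(calls_above$direction, "up")

  # equal depth-normalized rates give no direction even when p < alpha
  m3 <- matrix(c(5L, 5L), 1, 2,
               dimnames = list("g", c("left_control", "left_d1")))
  cm3 <- count_matrix(m3, gene_lengths = 1000,
                      library_sizes = c(left_control = 1e6, left_d1 = 1e6))
  calls_tie <- call_de(cm3, make_tc_manifest(colnames(m3)), alpha = 0.999)
  expect_equal(calls_tie$direction, "none")
})

test_that("a missing control column is an error", {
  m <- matrix(1:2, 1, 2, dimnames = list("g", c("left_d1", "left_d3")))
  cm <- count_matrix(m, gene_lengths = 1000)
  expect_error(call_de(cm, make_tc_manifest(colnames(m))),
               "exactly one control")
})

test_that("de_count_table tallies calls per side and date", {
  m <- matrix(c(10L, 10L, 10L,
                200L, 10L, 10L,
                10L, 10L, 200L), 3, 3,
              dimnames = list(c("g1", "g2", "g3"),
                              c("left_control", "left_d1", "left_d3")))
  cm <- count_matrix(m, gene_lengths = rep(1000, 3),
                     library_sizes = stats::setNames(rep(1e6, 3), colnames(m)))
  calls <- call_de(cm, make_tc_manifest(colnames(m)))
  tab <- de_count_table(calls)
  expect_equal(tab$n_up[tab$date == "1"], 1)   # g1 on date 1
  expect_equal(tab$n_up[tab$date == "3"], 1)   # g3 on date 3
  expect_equal(sum(tab$n_down), 0)
  expect_false(inherits(tab, "de_calls"))
})

test_that("null call rate at alpha is conservative on simulated data", {
  sim <- simulate_damage_timecourse(
    small_timecourse(n_genes = 5000, frac_damage_responsive = 0,
                     frac_transient = 0, seed = 77))
  calls <- call_de(sim$counts, sim$manifest, alpha = 1e-3)
  rate <- mean(calls$direction != "none")
  expect_lte(rate, 2e-3)   # <= 2x alpha, documented conservativeness
})
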